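# Sequence-conservation module: per-column identity and residue-class
# (hydrophobic) conservation mapped to reference residue numbering.

#' Hydrophobic residue class used for conservation profiling
#'
#' The one-letter codes M, A, V, I, L, C, Y, F, W. The occurrence of these
#' residues down an alignment column gives the "hydrophobic conservation"
#' of the corresponding reference position, a signal that tracks the buried
#' faces of transmembrane helices.
#' @export
HYDROPHOBIC_CLASS <- c("M", "A", "V", "I", "L", "C", "Y", "F", "W")

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHARS <- c("-", ".")

new_alignment <- function(rows, ids, reference_id) {
  rows <- toupper(as.character(rows))
  ids <- as.character(ids)
  if (length(rows) < 1L) stop("alignment must contain at least one sequence")
  if (length(rows) != length(ids)) stop("ids and rows differ in length")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(widths), collapse = ", "), ")")
  }
  if (widths[1] < 1L) stop("alignment has zero columns")
  if (!reference_id %in% ids) {
    stop("reference sequence '", reference_id, "' not found in alignment")
  }
  structure(list(ids = ids, rows = setNames(rows, ids),
                 reference_id = reference_id),
            class = "msa_alignment")
}

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file into an alignment object with a
#' designated reference row. The reference row defines residue numbering for
#' all downstream per-position reports (1-based over its ungapped sequence).
#'
#' @param path file path.
#' @param reference_id identifier of the reference sequence; for FASTA the
#'   part of the header line before the first whitespace.
#' @param format `"fasta"`, `"clustal"`, or `"auto"` (default) to infer from
#'   the file extension (`.fasta`/`.fa`/`.fst` vs `.aln`/`.clustal`/`.clw`).
#' @return an object of class `msa_alignment` with elements `ids`, `rows`
#'   (named gapped sequences of equal length) and `reference_id`.
#' @export
read_alignment <- function(path, reference_id,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("aln", "clustal", "clw")) "clustal" else "fasta"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    rows <- as.character(seqs)
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    seqs <- Biostrings::unmasked(msa)
    ids <- names(seqs)
    rows <- as.character(seqs)
  }
  if (length(rows) == 0L) stop("no sequences found in ", path)
  new_alignment(rows, ids, reference_id)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

#' Per-position conservation profile of an alignment
#'
#' For every non-gap position of the reference row, computes the percentage
#' of aligned sequences carrying the modal (most frequent) residue
#' (`identity_pct`) and the percentage carrying any residue from
#' `residue_class` (`class_pct`, hydrophobic conservation by default).
#' Columns in which the reference has a gap are skipped, so positions map
#' directly onto reference residue numbers (e.g. W300, D670).
#'
#' @param aln an `msa_alignment` from [read_alignment()] or [gen_msa()].
#' @param residue_class character vector of one-letter codes defining the
#'   class; defaults to [HYDROPHOBIC_CLASS].
#' @param gap_policy denominator for the percentages: `"all_rows"` (default;
#'   gaps count against conservation) or `"nongap_rows"` (gapped rows are
#'   dropped from the column before computing percentages).
#' @return a data.frame of class `conservation_profile` with columns
#'   `position`, `reference_residue`, `modal_residue`, `identity_pct`,
#'   `class_pct`. Ties for the modal residue are broken alphabetically.
#'   Non-standard letters (B, Z, X, ...) count as neither class nor identity
#'   matches; their presence triggers a single warning.
#' @export
conservation_profile <- function(aln, residue_class = HYDROPHOBIC_CLASS,
                                 gap_policy = c("all_rows", "nongap_rows")) {
  stopifnot(inherits(aln, "msa_alignment"))
  gap_policy <- match.arg(gap_policy)
  residue_class <- toupper(residue_class)
  if (length(residue_class) == 0L ||
      !all(residue_class %in% AA_STANDARD)) {
    stop("residue_class must be a non-empty subset of the 20 standard codes")
  }
  mat <- alignment_matrix(aln)
  ref <- mat[match(aln$reference_id, aln$ids), ]
  keep <- !(ref %in% GAP_CHARS)
  if (!any(keep)) stop("reference row contains only gaps; empty profile")

  nonstd <- setdiff(unique(as.vector(mat)), c(AA_STANDARD, GAP_CHARS))
  if (length(nonstd) > 0L) {
    warning("non-standard letters treated as non-class, non-identity: ",
            paste(sort(nonstd), collapse = ", "))
  }

  cols <- which(keep)
  n_rows <- nrow(mat)
  out <- lapply(seq_along(cols), function(k) {
    col <- mat[, cols[k]]
    std <- col[col %in% AA_STANDARD]
    denom <- if (gap_policy == "all_rows") n_rows else sum(!(col %in% GAP_CHARS))
    if (length(std) == 0L) {
      return(data.frame(position = k, reference_residue = ref[cols[k]],
                        modal_residue = NA_character_,
                        identity_pct = 0, class_pct = 0,
                        stringsAsFactors = FALSE))
    }
    tab <- table(std)
    modal <- sort(names(tab)[tab == max(tab)])[1]  # alphabetical tie-break
    data.frame(
      position = k,
      reference_residue = ref[cols[k]],
      modal_residue = modal,
      identity_pct = 100 * as.numeric(tab[modal]) / denom,
      class_pct = 100 * sum(std %in% residue_class) / denom,
      stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, out)
  attr(prof, "gap_policy") <- gap_policy
  attr(prof, "residue_class") <- residue_class
  class(prof) <- c("conservation_profile", "data.frame")
  prof
}

#' Arrange class-conservation values for heat-map plotting
#'
#' Exports `class_pct` values in position order, optionally wrapped into
#' rows of `window` positions (padded with `NA`) so long profiles can be
#' rendered as a rectangular heat map. Values are taken verbatim from the
#' profile.
#'
#' @param profile a `conservation_profile`.
#' @param window positions per heat-map row; default one single row.
#' @return a numeric matrix with `window` columns; `dimnames` carry the
#'   starting position of each row and the within-row offsets.
#' @export
conservation_heatmap_matrix <- function(profile, window = nrow(profile)) {
  stopifnot(inherits(profile, "conservation_profile"), nrow(profile) >= 1L,
            window >= 1L)
  v <- profile$class_pct
  n <- length(v)
  n_rows <- ceiling(n / window)
  padded <- c(v, rep(NA_real_, n_rows * window - n))
  m <- matrix(padded, nrow = n_rows, ncol = window, byrow = TRUE)
  rownames(m) <- profile$position[seq(1, n, by = window)]
  m
}

#' Write a conservation profile to TSV or JSON
#'
#' @param profile a `conservation_profile`.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`; both carry identical content.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(profile)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read a conservation profile back from TSV or JSON
#'
#' Round-trip counterpart of [write_conservation()]; values are preserved to
#' full precision by the JSON writer and to `write.table` precision by TSV.
#'
#' @inheritParams write_conservation
#' @return a `conservation_profile` data.frame.
#' @export
read_conservation <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (format == "tsv") {
    read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  class(df) <- c("conservation_profile", "data.frame")
  df
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " sequences x ",
      nchar(x$rows[[1]]), " columns (reference: ", x$reference_id, ")\n",
      sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `msa_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "msa_alignment"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(unname(aln$rows), aln$ids)), path)
  invisible(path)
}
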