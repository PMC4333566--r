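# Topology-consensus module: majority voting over per-residue TM predictor
# tracks, with gap merging and a minimum helix length, replacing the manual
# reconciliation usually applied to SOSUI/HMMTop/JPRED/PSIPRED output.

#' Read per-residue transmembrane predictor tracks
#'
#' Expects a tab-separated file with one row per residue and one column per
#' predictor; entries must be 0 (non-TM) or 1 (TM). A header line with
#' predictor names is required.
#'
#' @param path TSV file path.
#' @return an integer matrix, residues x predictors, with predictor names as
#'   column names.
#' @export
read_tm_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty track file (header only): ", path)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1))) {
    bad <- unique(as.vector(m[!(m %in% c(0, 1)) | is.na(m)]))
    stop("track entries must be binary 0/1; found: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  m
}

#' Consensus transmembrane segments from multiple predictor tracks
#'
#' Computes the per-residue fraction of tracks voting TM, thresholds it,
#' merges qualifying runs separated by at most `max_gap` non-qualifying
#' residues, and discards merged runs shorter than `min_len`. Residues at
#' exactly the threshold count as TM.
#'
#' @param tracks matrix (residues x predictors) of 0/1 marks, a list of
#'   equal-length 0/1 vectors, or a single vector.
#' @param threshold minimum vote fraction for a residue to qualify
#'   (default 0.5, simple majority).
#' @param min_len minimum segment length kept after merging (default 15,
#'   a canonical TM helix span).
#' @param max_gap maximum run separation bridged when merging (default 3).
#' @param expected_segments optional expected helix count (e.g. 12 for an
#'   MFS-fold transporter); a mismatch raises a diagnostic warning, never an
#'   error.
#' @return an object of class `tm_consensus`: list with `segments`
#'   (data.frame `name`, `start`, `end`, 1-based inclusive) and
#'   `vote_fraction` (per residue).
#' @export
tm_consensus <- function(tracks, threshold = 0.5, min_len = 15, max_gap = 3,
                         expected_segments = NULL) {
  if (is.list(tracks) && !is.data.frame(tracks)) {
    len <- unique(vapply(tracks, length, 1L))
    if (length(len) != 1L) stop("tracks have differing lengths")
    tracks <- do.call(cbind, tracks)
  }
  tracks <- as.matrix(tracks)
  if (ncol(tracks) < 1L || nrow(tracks) < 1L) stop("need at least one track")
  if (!all(tracks %in% c(0, 1))) stop("track entries must be 0/1")
  stopifnot(threshold > 0, threshold <= 1, min_len >= 1, max_gap >= 0)

  vote <- rowMeans(tracks)
  qual <- vote >= threshold
  runs <- binary_runs(qual)
  segs <- merge_runs(runs, max_gap = max_gap)
  if (nrow(segs) > 0L) segs <- segs[segs$end - segs$start + 1L >= min_len, , drop = FALSE]
  segs <- if (nrow(segs) > 0L) {
    data.frame(name = paste0("TM", seq_len(nrow(segs))),
               start = segs$start, end = segs$end, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }
  if (!is.null(expected_segments) && nrow(segs) != expected_segments) {
    warning("consensus found ", nrow(segs), " segments; expected ",
            expected_segments)
  }
  structure(list(segments = segs, vote_fraction = vote,
                 threshold = threshold, min_len = min_len, max_gap = max_gap),
            class = "tm_consensus")
}

# start/end table of TRUE runs in a logical vector.
binary_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Merge runs whose separation (in residues) is <= max_gap.
merge_runs <- function(runs, max_gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    gap <- runs$start[i] - out$end[nrow(out)] - 1L
    if (gap <= max_gap) {
      out$end[nrow(out)] <- runs$end[i]
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

#' Write consensus TM segments and vote fractions
#'
#' Segments go to a BED-like 1-based inclusive TSV (`name`, `start`, `end`);
#' with `json = TRUE` a JSON document with the per-residue vote fractions is
#' written alongside (same path with `.json` appended).
#'
#' @param x a `tm_consensus`.
#' @param path output TSV path.
#' @param json also write the JSON companion? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_tm_segments <- function(x, path, json = TRUE) {
  stopifnot(inherits(x, "tm_consensus"))
  utils::write.table(x$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (json) {
    jsonlite::write_json(
      list(segments = x$segments, vote_fraction = x$vote_fraction,
           threshold = x$threshold),
      paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @export
print.tm_consensus <- function(x, ...) {
  cat("Consensus TM topology: ", nrow(x$segments), " segments over ",
      length(x$vote_fraction), " residues (threshold ", x$threshold, ")\n",
      sep = "")
  if (nrow(x$segments) > 0L) print(x$segments, row.names = FALSE)
  invisible(x)
}
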