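# Hydrogen-bond-energy secondary-structure assignment (Kabsch-Sander style)
# and per-residue helicity-conservation profiles across replicas.
#
# The electrostatic H-bond energy between an acceptor carbonyl (C=O of
# residue i) and a donor amide (N-H of residue j) is
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# and a hydrogen bond is assigned when E < -0.5 kcal/mol. An n-turn at i is
# the H-bond (i -> i+n); two consecutive 4-turns define a minimal
# alpha-helix spanning residues i..i+3.

HB_Q <- 0.084 * 332
HB_CUTOFF <- -0.5
CHAIN_BREAK_CN <- 2.5   # Angstroms; peptide C-N bond is ~1.33 A

# Backbone table for one frame: per residue, coordinates of N, CA, C, O and
# the reconstructed amide H. Residues are ordered as they appear.
backbone_table <- function(traj, frame) {
  at <- traj$atom
  key <- paste(at$chain, at$resno, sep = "|")
  res_keys <- unique(key)
  co <- frame_coords(traj, frame)
  need <- c("N", "CA", "C", "O")
  idx <- lapply(need, function(nm) {
    i <- integer(length(res_keys))
    hit <- at$elety == nm
    i[match(key[hit], res_keys)] <- which(hit)
    i
  })
  names(idx) <- need
  missing <- res_keys[idx$N == 0L | idx$CA == 0L | idx$C == 0L | idx$O == 0L]
  if (length(missing) > 0L) {
    stop("missing backbone atoms (N/CA/C/O) for residues: ",
         paste(utils::head(sub(".*\\|", "", missing), 10), collapse = ", "))
  }
  list(
    resno = at$resno[idx$CA],
    resid = at$resid[idx$CA],
    chain = at$chain[idx$CA],
    N = co[idx$N, , drop = FALSE],
    CA = co[idx$CA, , drop = FALSE],
    C = co[idx$C, , drop = FALSE],
    O = co[idx$O, , drop = FALSE]
  )
}

# Split residues into continuous segments: same chain label and
# C(i)-N(i+1) distance <= CHAIN_BREAK_CN.
segment_ids <- function(bb) {
  n <- length(bb$resno)
  if (n == 1L) return(rep(1L, 1L))
  dcn <- sqrt(rowSums((bb$C[-n, , drop = FALSE] - bb$N[-1, , drop = FALSE])^2))
  breaks <- (bb$chain[-n] != bb$chain[-1]) | (dcn > CHAIN_BREAK_CN)
  cumsum(c(TRUE, breaks))
}

# Assign codes for one frame given a backbone table.
ss_codes_frame <- function(bb) {
  n <- length(bb$resno)
  seg <- segment_ids(bb)
  # reconstructed amide H: N + unit(C_prev - O_prev); none for segment-first
  # residues or prolines (no amide hydrogen, never a donor)
  H <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    if (j == 1L || seg[j] != seg[j - 1L] || bb$resid[j] == "PRO") next
    H[j, ] <- bb$N[j, ] + vunit(bb$C[j - 1L, ] - bb$O[j - 1L, ])
  }
  hbond <- function(i, j) {   # acceptor C=O of i, donor N-H of j
    if (j > n || seg[i] != seg[j] || is.na(H[j, 1])) return(FALSE)
    rON <- sqrt(sum((bb$O[i, ] - bb$N[j, ])^2))
    rCH <- sqrt(sum((bb$C[i, ] - H[j, ])^2))
    rOH <- sqrt(sum((bb$O[i, ] - H[j, ])^2))
    rCN <- sqrt(sum((bb$C[i, ] - bb$N[j, ])^2))
    if (min(rON, rCH, rOH, rCN) < 0.5) return(TRUE)  # clash convention
    e <- HB_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    e < HB_CUTOFF
  }
  turn <- function(k) vapply(seq_len(n), function(i) hbond(i, i + k), logical(1))
  t3 <- turn(3L); t4 <- turn(4L); t5 <- turn(5L)
  codes <- rep("-", n)
  mark <- function(codes, tn, span, code) {
    for (i in 2:max(2L, n)) {
      if (i > n) break
      if (isTRUE(tn[i - 1L]) && isTRUE(tn[i])) {
        sel <- i:min(n, i + span - 1L)
        sel <- sel[codes[sel] == "-"]
        codes[sel] <- code
      }
    }
    codes
  }
  codes <- mark(codes, t4, 4L, "H")   # alpha first: H takes priority
  codes <- mark(codes, t3, 3L, "G")
  codes <- mark(codes, t5, 5L, "I")
  codes
}

#' Secondary-structure assignment from backbone hydrogen-bond energies
#'
#' Assigns per-residue codes from the Kabsch-Sander electrostatic H-bond
#' criterion: `H` (alpha-helix, consecutive i->i+4 bonds), `G` (3-10),
#' `I` (pi), `-` otherwise. The amide hydrogen is reconstructed 1 Angstrom
#' from N along the direction of the preceding C=O; the first residue of a
#' chain has no donor, proline never donates, and chains are split where
#' the C(i)-N(i+1) distance exceeds 2.5 Angstroms.
#'
#' @param traj an `mtraj` whose residues carry complete N, CA, C, O
#'   backbone records.
#' @param frame a single frame index, or `NULL` (default) for all frames.
#' @return for a single frame, a character vector of codes named by residue
#'   number; otherwise a `frames x residues` character matrix.
#' @export
assign_secondary_structure <- function(traj, frame = NULL) {
  stopifnot(inherits(traj, "mtraj"))
  frames <- if (is.null(frame)) seq_len(n_frames(traj)) else frame
  bb0 <- backbone_table(traj, frames[1])
  out <- matrix("-", length(frames), length(bb0$resno),
                dimnames = list(NULL, bb0$resno))
  for (k in seq_along(frames)) {
    bb <- if (k == 1L) bb0 else backbone_table(traj, frames[k])
    out[k, ] <- ss_codes_frame(bb)
  }
  if (!is.null(frame) && length(frame) == 1L) {
    setNames(out[1, ], colnames(out))
  } else {
    out
  }
}

#' Per-residue helicity conservation across replicas
#'
#' For each replica, the fraction of frames in which a residue is assigned
#' a code in `helical_codes`; then the mean and standard deviation (n-1
#' denominator) across replicas, plus a classification against the
#' conservation criterion (replica-mean fraction >= `criterion`; ties count
#' as conserved).
#'
#' @param trajs a list of `mtraj` replicas (or a single `mtraj`).
#' @param helical_codes codes counted as helical; default `"H"` (alpha
#'   only), use `c("H","G","I")` to include 3-10 and pi.
#' @param criterion conservation threshold on the replica mean
#'   (default 0.6).
#' @return a data.frame of class `helicity_profile`: `residue`, one
#'   `fraction_<replica>` column per replica, `mean`, `sd`, `conserved`.
#' @export
helicity_profile <- function(trajs, helical_codes = "H", criterion = 0.6) {
  if (inherits(trajs, "mtraj")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  fracs <- lapply(trajs, function(tr) {
    ss <- assign_secondary_structure(tr)
    colMeans(matrix(ss %in% helical_codes, nrow = nrow(ss),
                    dimnames = dimnames(ss)))
  })
  resno <- names(fracs[[1]])
  same <- vapply(fracs, function(f) identical(names(f), resno), logical(1))
  if (!all(same)) stop("replicas cover different residue ranges")
  m <- do.call(cbind, fracs)
  colnames(m) <- vapply(seq_along(trajs),
                        function(i) trajs[[i]]$replica_id %||% paste0("rep", i),
                        character(1))
  mu <- rowMeans(m)
  sdv <- if (ncol(m) > 1L) apply(m, 1, sd) else rep(NA_real_, nrow(m))
  out <- data.frame(residue = as.integer(resno), m, mean = mu, sd = sdv,
                    conserved = mu >= criterion, check.names = FALSE,
                    row.names = NULL)
  names(out)[2:(1 + ncol(m))] <- paste0("fraction_", colnames(m))
  attr(out, "criterion") <- criterion
  attr(out, "helical_codes") <- helical_codes
  class(out) <- c("helicity_profile", "data.frame")
  out
}
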