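# Kabsch least-squares superposition and RMSD time series.

#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` via singular value decomposition of the
#' cross-covariance matrix, with the determinant correction that excludes
#' reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, matched
#'   row-for-row.
#' @return a list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3; `mobile %*% rotation + translation` superposes onto
#'   `reference`), `rmsd` (Angstroms) and `collinear` (TRUE when the mobile
#'   set is rank-deficient beyond a plane, i.e. nearly collinear — the
#'   optimum is still returned but is not unique).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("coordinate matrices must have 3 columns")
  }
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("superposition is underdetermined with fewer than 3 points")
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    stop("non-finite coordinates")
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  p <- sweep(mobile, 2, mc)
  q <- sweep(reference, 2, rc)
  cov <- crossprod(p, q)             # 3x3: t(P) %*% Q
  s <- svd(cov)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  # residual-based RMSD avoids the catastrophic cancellation the closed-form
  # trace expression suffers near zero
  rmsd <- sqrt(mean(rowSums((p %*% rot - q)^2)))
  collinear <- s$d[2] <= 1e-8 * max(s$d[1], 1e-12)
  list(rotation = rot,
       translation = as.numeric(rc - mc %*% rot),
       rmsd = rmsd,
       collinear = collinear)
}

#' RMSD time series over a residue selection
#'
#' Each frame is superposed (Kabsch) onto the reference over the C-alpha
#' atoms of the selected residues, and the RMSD is computed over the same
#' atoms — the standard backbone-drift measure used to judge whether a
#' model has stabilised during simulation.
#'
#' @param traj an `mtraj`.
#' @param selection residue numbers whose CA atoms define the fit and the
#'   RMSD.
#' @param reference_frame frame index used as reference (default 1).
#' @param reference optional external reference: an `n x 3` matrix of CA
#'   coordinates for `selection` (e.g. the initial snapshot of another
#'   simulation); overrides `reference_frame`.
#' @return an object of class `rmsd_series`: list with `values` (Angstroms,
#'   one per frame), `selection`, and `reference_frame`.
#' @export
rmsd_series <- function(traj, selection, reference_frame = 1,
                        reference = NULL) {
  stopifnot(inherits(traj, "mtraj"))
  if (length(selection) == 0L) stop("empty residue selection")
  idx <- select_atoms(traj, resno = selection, elety = "CA")
  found <- unique(traj$atom$resno[idx])
  missing <- setdiff(selection, found)
  if (length(missing) > 0L) {
    stop("no CA atom for residues: ", paste(missing, collapse = ", "))
  }
  ref <- if (is.null(reference)) {
    frame_coords(traj, reference_frame, idx)
  } else {
    as.matrix(reference)
  }
  if (nrow(ref) != length(idx)) stop("reference size does not match selection")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f, idx), ref)$rmsd
  }, numeric(1))
  structure(list(values = vals, selection = selection,
                 reference_frame = if (is.null(reference)) reference_frame
                                   else NA_integer_),
            class = "rmsd_series")
}

#' Plateau statistics of an RMSD series
#'
#' Mean and standard deviation (n-1 denominator) over the final
#' `last_fraction` of frames, the usual way a "stabilises to x ± y Angstrom"
#' statement is quantified.
#'
#' @param series an `rmsd_series` or numeric vector.
#' @param last_fraction fraction of trailing frames used (default 0.25).
#' @return list with `mean`, `sd` and `n_frames` used.
#' @export
rmsd_plateau <- function(series, last_fraction = 0.25) {
  v <- if (inherits(series, "rmsd_series")) series$values else as.numeric(series)
  stopifnot(last_fraction > 0, last_fraction <= 1)
  k <- max(2L, ceiling(length(v) * last_fraction))
  tailv <- tail(v, k)
  list(mean = mean(tailv), sd = sd(tailv), n_frames = k)
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("RMSD series: ", length(x$values), " frames over ",
      length(x$selection), " residues; final value ",
      round(tail(x$values, 1), 3), " A\n", sep = "")
  invisible(x)
}
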