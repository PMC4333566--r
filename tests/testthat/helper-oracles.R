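# Independent oracles used to validate the package's implementations.
# Each is coded from the definitions on its own path (brute-force loops,
# dense grids, matrix enumeration) and never calls the implementation it
# checks.

# Minimum RMSD over a dense Z-Y-Z Euler-angle rotation grid. Returns the
# grid minimum and a bound on how far it can sit above the true optimum
# (from the grid's angular cover radius and the nuclear norm of the
# cross-covariance).
grid_rmsd_oracle <- function(p, q, step_deg = 3) {
  p <- sweep(as.matrix(p), 2, colMeans(p))
  q <- sweep(as.matrix(q), 2, colMeans(q))
  n <- nrow(p)
  M <- crossprod(p, q)
  sp <- sum(p^2); sq <- sum(q^2)
  ga <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  cg <- cos(ga); sg <- sin(ga)
  al_seq <- ga
  be_seq <- seq(0, 180, by = step_deg) * pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  best <- -Inf
  for (al in al_seq) {
    Rza <- rz(al)
    for (be in be_seq) {
      A <- Rza %*% ry(be)
      B <- crossprod(A, M)          # t(A) %*% M
      vals <- cg * (B[1, 1] + B[2, 2]) + sg * (B[2, 1] - B[1, 2]) + B[3, 3]
      m <- max(vals)
      if (m > best) best <- m
    }
  }
  rmsd <- sqrt(max(0, (sp + sq - 2 * best) / n))
  # cover radius of the Euler grid is below 2*step; trace gap bounded by
  # nuclear_norm(M) * angular gap
  gap2 <- 2 * sum(svd(M)$d) * (2 * step_deg * pi / 180) / n
  list(rmsd = rmsd, rmsd2_gap_bound = gap2)
}

# Independent Kabsch-Sander assigner: full pairwise H-bond energy matrix
# built with vectorised distance matrices, then the turn/helix rules.
oracle_ss <- function(traj, frame = 1) {
  at <- traj$atom
  co <- memqc::frame_coords(traj, frame)
  key <- paste(at$chain, at$resno)
  res <- unique(key)
  n <- length(res)
  pick <- function(name) {
    co[vapply(res, function(r) which(key == r & at$elety == name)[1],
              integer(1)), , drop = FALSE]
  }
  N <- pick("N"); CA <- pick("CA"); C <- pick("C"); O <- pick("O")
  resid <- at$resid[vapply(res, function(r)
    which(key == r & at$elety == "CA")[1], integer(1))]
  chain <- at$chain[vapply(res, function(r)
    which(key == r & at$elety == "CA")[1], integer(1))]
  seg <- 1L
  segs <- integer(n); segs[1] <- 1L
  for (i in 2:n) {
    brk <- chain[i] != chain[i - 1] ||
      sqrt(sum((C[i - 1, ] - N[i, ])^2)) > 2.5
    if (brk) seg <- seg + 1L
    segs[i] <- seg
  }
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (segs[i] == segs[i - 1] && resid[i] != "PRO") {
      v <- C[i - 1, ] - O[i - 1, ]
      H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
    }
  }
  dmat <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(pmax(d2, 0))
  }
  rON <- dmat(O, N); rCN <- dmat(C, N); rOH <- dmat(O, H); rCH <- dmat(C, H)
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  hb <- E < -0.5
  hb[is.na(hb)] <- FALSE
  clash <- pmin(rON, rCN, rOH, rCH) < 0.5
  clash[is.na(clash)] <- FALSE
  hb[clash] <- TRUE
  for (i in 1:n) for (j in 1:n) if (segs[i] != segs[j]) hb[i, j] <- FALSE
  turn <- function(k) {
    t <- rep(FALSE, n)
    for (i in 1:(n - k)) t[i] <- hb[i, i + k]
    t
  }
  codes <- rep("-", n)
  mark <- function(codes, tn, span, code) {
    for (i in 2:n) {
      if (tn[i - 1] && tn[i]) {
        sel <- i:min(n, i + span - 1)
        sel <- sel[codes[sel] == "-"]
        codes[sel] <- code
      }
    }
    codes
  }
  if (n >= 5) codes <- mark(codes, turn(4), 4, "H")
  if (n >= 4) codes <- mark(codes, turn(3), 3, "G")
  if (n >= 6) codes <- mark(codes, turn(5), 5, "I")
  codes
}

# Naive per-column conservation counter: explicit loops, no shared code
# with conservation_profile().
brute_conservation <- function(rows, reference_id, ids,
                               residue_class, gap_policy) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- do.call(rbind, strsplit(rows, ""))
  ref <- mat[which(ids == reference_id), ]
  out <- NULL
  pos <- 0L
  for (j in seq_len(ncol(mat))) {
    if (ref[j] %in% c("-", ".")) next
    pos <- pos + 1L
    col <- mat[, j]
    denom <- 0L
    counts <- setNames(integer(length(std)), std)
    n_class <- 0L
    for (r in col) {
      if (gap_policy == "all_rows") denom <- denom + 1L
      else if (!(r %in% c("-", "."))) denom <- denom + 1L
      if (r %in% std) counts[r] <- counts[r] + 1L
      if (r %in% residue_class) n_class <- n_class + 1L
    }
    if (all(counts == 0L)) {
      modal <- NA_character_; ident <- 0
    } else {
      modal <- names(counts)[counts == max(counts)][1]  # std is sorted
      ident <- 100 * counts[modal] / denom
    }
    out <- rbind(out, data.frame(position = pos, modal_residue = modal,
                                 identity_pct = as.numeric(ident),
                                 class_pct = 100 * n_class / denom))
  }
  out
}

# Alternative consensus-segment construction: dilate qualifying gaps of
# length <= max_gap that are flanked by qualifying runs, then take runs.
brute_consensus_segments <- function(qual, min_len, max_gap) {
  n <- length(qual)
  filled <- qual
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= max_gap) {
      filled[starts[k]:ends[k]] <- TRUE
    }
  }
  r2 <- rle(filled)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= min_len
  data.frame(start = starts2[keep], end = ends2[keep])
}
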