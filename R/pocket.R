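# Binding-pocket statistics: grid flood-fill cavity volume, ligand contact
# occupancy, salt-bridge distance traces, and area-per-lipid bookkeeping.
# All distance thresholds in this module are strict (<).

#' Cavity volume by seeded flood fill on a probe-accessible grid
#'
#' Lays a cubic grid of the given spacing over an axis-aligned region,
#' removes grid points within (van der Waals radius + probe radius) of any
#' atom, and flood-fills (6-connected) from a seed point known to lie in
#' the cavity. The volume is the number of reached points times
#' `spacing^3`. With no atoms in range, the full region volume is returned.
#'
#' van der Waals radii: C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Angstroms
#' (default 1.7 for anything else), inferred from atom names.
#'
#' @param traj an `mtraj` (atoms define the exclusion spheres).
#' @param region list with numeric `x`, `y`, `z`, each `c(min, max)` in
#'   Angstroms, bounding the search slab.
#' @param seed_point length-3 coordinate inside the cavity.
#' @param frame frame index (default 1).
#' @param spacing grid spacing in Angstroms (default 1.0).
#' @param probe probe radius in Angstroms (default 1.4, a water molecule).
#' @return list with `volume` (Angstrom^3), `n_points` reached, `n_total`
#'   grid points in the region, and `spacing`.
#' @export
cavity_volume <- function(traj, region, seed_point, frame = 1,
                          spacing = 1.0, probe = 1.4) {
  stopifnot(inherits(traj, "mtraj"), spacing > 0, probe >= 0,
            length(seed_point) == 3)
  for (ax in c("x", "y", "z")) {
    r <- region[[ax]]
    if (is.null(r) || length(r) != 2L || r[2] <= r[1]) {
      stop("region$", ax, " must be c(min, max) with max > min")
    }
  }
  gx <- seq(region$x[1], region$x[2], by = spacing)
  gy <- seq(region$y[1], region$y[2], by = spacing)
  gz <- seq(region$z[1], region$z[2], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  if (seed_point[1] < region$x[1] || seed_point[1] > region$x[2] ||
      seed_point[2] < region$y[1] || seed_point[2] > region$y[2] ||
      seed_point[3] < region$z[1] || seed_point[3] > region$z[2]) {
    stop("seed point lies outside the region")
  }
  free <- array(TRUE, dim = c(nx, ny, nz))
  co <- frame_coords(traj, frame)
  rad <- vdw_radius(traj$atom$elety) + probe
  for (a in seq_len(nrow(co))) {
    r <- rad[a]; p <- co[a, ]
    ix <- which(abs(gx - p[1]) <= r)
    iy <- which(abs(gy - p[2]) <= r)
    iz <- which(abs(gz - p[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((gx[ix] - p[1])^2, (gy[iy] - p[2])^2, "+"),
                (gz[iz] - p[3])^2, "+")
    free[ix, iy, iz] <- free[ix, iy, iz] & (d2 >= r^2)
  }
  seed_idx <- c(which.min(abs(gx - seed_point[1])),
                which.min(abs(gy - seed_point[2])),
                which.min(abs(gz - seed_point[3])))
  seed_lin <- seed_idx[1] + (seed_idx[2] - 1L) * nx +
    (seed_idx[3] - 1L) * nx * ny
  if (!free[seed_lin]) stop("seed point is occluded by an atom")

  # vectorised 6-connected flood fill over linear indices
  reached <- logical(nx * ny * nz)
  reached[seed_lin] <- TRUE
  frontier <- seed_lin
  freev <- as.vector(free)
  nxy <- nx * ny
  while (length(frontier) > 0L) {
    x <- ((frontier - 1L) %% nx) + 1L
    y <- (((frontier - 1L) %/% nx) %% ny) + 1L
    z <- ((frontier - 1L) %/% nxy) + 1L
    nb <- c(frontier[x > 1L] - 1L, frontier[x < nx] + 1L,
            frontier[y > 1L] - nx, frontier[y < ny] + nx,
            frontier[z > 1L] - nxy, frontier[z < nz] + nxy)
    nb <- unique(nb[freev[nb] & !reached[nb]])
    reached[nb] <- TRUE
    frontier <- nb
  }
  list(volume = sum(reached) * spacing^3, n_points = sum(reached),
       n_total = nx * ny * nz, spacing = spacing)
}

#' Per-residue ligand contact occupancy
#'
#' Fraction of frames in which at least one atom of a residue lies within
#' the cutoff of any ligand atom (strict `<`). Heavy atoms only by default.
#' With several replicas the pooled fraction is frame-weighted: total
#' contact frames over total frames across replicas, alongside per-replica
#' fractions.
#'
#' @param trajs an `mtraj` or list of replicas.
#' @param ligand list of filters passed to [select_atoms()] identifying
#'   the ligand (e.g. `list(resid = "LIG")`).
#' @param residues residue numbers to report.
#' @param cutoff contact distance in Angstroms (default 6.0).
#' @param include_hydrogens count hydrogen atoms too? Default `FALSE`.
#' @return a data.frame of class `contact_occupancy`: `residue`,
#'   per-replica fraction columns, and pooled `fraction`.
#' @export
contact_occupancy <- function(trajs, ligand, residues, cutoff = 6.0,
                              include_hydrogens = FALSE) {
  if (inherits(trajs, "mtraj")) trajs <- list(trajs)
  stopifnot(cutoff > 0, length(residues) > 0)
  per <- lapply(trajs, function(tr) {
    lig_idx <- do.call(select_atoms,
                       c(list(traj = tr, heavy_only = !include_hydrogens),
                         ligand))
    if (length(lig_idx) == 0L) stop("ligand selection matched no atoms")
    res_idx <- lapply(residues, function(r) {
      i <- select_atoms(tr, resno = r, heavy_only = !include_hydrogens)
      i[!(i %in% lig_idx)]
    })
    hits <- matrix(FALSE, n_frames(tr), length(residues))
    for (f in seq_len(n_frames(tr))) {
      lig <- frame_coords(tr, f, lig_idx)
      for (j in seq_along(residues)) {
        if (length(res_idx[[j]]) == 0L) next
        ra <- frame_coords(tr, f, res_idx[[j]])
        d2 <- outer(rowSums(ra^2), rowSums(lig^2), "+") -
          2 * ra %*% t(lig)
        hits[f, j] <- min(d2) < cutoff^2
      }
    }
    hits
  })
  contact_frames <- Reduce(`+`, lapply(per, colSums))
  total_frames <- sum(vapply(per, nrow, 1L))
  out <- data.frame(residue = residues, check.names = FALSE)
  for (i in seq_along(per)) {
    out[[paste0("fraction_", trajs[[i]]$replica_id %||% paste0("rep", i))]] <-
      colMeans(per[[i]])
  }
  out$fraction <- contact_frames / total_frames
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_occupancy", "data.frame")
  out
}

#' Donor-acceptor minimum-distance trace and sub-threshold occupancy
#'
#' Per frame, the minimum distance over all donor-acceptor atom pairs
#' (e.g. the amino hydrogens of a lysine against the carboxylate oxygens
#' of an aspartate); the occupancy is the fraction of frames strictly
#' below the threshold, with the mean and SD (n-1) of the distance trace.
#'
#' @param traj an `mtraj`.
#' @param donor,acceptor lists of filters passed to [select_atoms()]
#'   naming the two atom sets (e.g.
#'   `list(resno = 694, elety = c("HZ1","HZ2","HZ3"))`).
#' @param threshold distance threshold in Angstroms (default 3.5).
#' @return object of class `distance_trace`: list with `distances` (per
#'   frame), `occupancy`, `mean`, `sd`, `threshold`.
#' @export
salt_bridge_trace <- function(traj, donor, acceptor, threshold = 3.5) {
  stopifnot(inherits(traj, "mtraj"), threshold > 0)
  d_idx <- do.call(select_atoms, c(list(traj = traj), donor))
  a_idx <- do.call(select_atoms, c(list(traj = traj), acceptor))
  if (length(d_idx) == 0L) {
    stop("donor selection matched no atoms: ", deparse(donor))
  }
  if (length(a_idx) == 0L) {
    stop("acceptor selection matched no atoms: ", deparse(acceptor))
  }
  dist <- vapply(seq_len(n_frames(traj)), function(f) {
    dco <- frame_coords(traj, f, d_idx)
    aco <- frame_coords(traj, f, a_idx)
    d2 <- outer(rowSums(dco^2), rowSums(aco^2), "+") - 2 * dco %*% t(aco)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  structure(list(distances = dist,
                 occupancy = mean(dist < threshold),
                 mean = mean(dist),
                 sd = if (length(dist) > 1L) sd(dist) else NA_real_,
                 threshold = threshold),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf(
    "Distance trace: %d frames; < %.2f A for %.1f%% of frames; mean %.2f +/- %.2f A\n",
    length(x$distances), x$threshold, 100 * x$occupancy, x$mean,
    ifelse(is.na(x$sd), 0, x$sd)))
  invisible(x)
}

#' Area per lipid from box dimensions
#'
#' Per frame, `(box_x * box_y - protein_area) / (n_lipids_total / 2)`,
#' assuming two equally populated leaflets. The protein cross-section
#' correction is off by default (`protein_area = 0`).
#'
#' @param traj an `mtraj` carrying box information.
#' @param n_lipids_total total lipid count over both leaflets (even, > 0).
#' @param protein_area cross-sectional area occupied by protein in each
#'   leaflet plane, Angstrom^2 (default 0).
#' @return list of class `lipid_area_series`: `values` (Angstrom^2 per
#'   frame), `mean`, `sd`.
#' @export
area_per_lipid <- function(traj, n_lipids_total, protein_area = 0) {
  stopifnot(inherits(traj, "mtraj"))
  if (is.null(traj$box)) stop("trajectory carries no box dimensions")
  if (n_lipids_total <= 0 || n_lipids_total %% 2 != 0) {
    stop("n_lipids_total must be even and positive")
  }
  v <- (traj$box[, 1] * traj$box[, 2] - protein_area) / (n_lipids_total / 2)
  if (any(v <= 0)) stop("non-positive area per lipid; check protein_area")
  structure(list(values = v, mean = mean(v),
                 sd = if (length(v) > 1L) sd(v) else NA_real_),
            class = "lipid_area_series")
}
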