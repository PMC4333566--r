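# Trajectory container and multi-model PDB I/O. Atom records and coordinate
# frames are held bio3d-style: an atom table plus an (n_frames x 3*n_atoms)
# coordinate matrix, with optional per-frame orthorhombic box lengths.

#' Construct a trajectory object
#'
#' @param atom data.frame with one row per atom and columns `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `chain`.
#' @param xyz numeric matrix, `n_frames x 3*n_atoms`, coordinates in
#'   Angstroms ordered x1,y1,z1,x2,...; a single frame may be given as a
#'   vector.
#' @param box optional per-frame orthorhombic box lengths in Angstroms:
#'   an `n_frames x 3` matrix or a length-3 vector recycled to all frames.
#' @param replica_id label for the replica this trajectory represents.
#' @return an object of class `mtraj`.
#' @export
new_trajectory <- function(atom, xyz, box = NULL, replica_id = "rep1") {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  stopifnot(is.data.frame(atom),
            all(c("elety", "resid", "resno", "chain") %in% names(atom)))
  if (ncol(xyz) != 3L * nrow(atom)) {
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x ",
         nrow(atom), " atoms")
  }
  if (nrow(xyz) < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nrow(xyz), ncol = 3,
                                         byrow = TRUE)
    box <- as.matrix(box)
    stopifnot(nrow(box) == nrow(xyz), ncol(box) == 3, all(box > 0))
  }
  structure(list(atom = atom, xyz = xyz, box = box, replica_id = replica_id),
            class = "mtraj")
}

#' @export
print.mtraj <- function(x, ...) {
  cat("Trajectory '", x$replica_id, "': ", nrow(x$xyz), " frames, ",
      nrow(x$atom), " atoms",
      if (!is.null(x$box)) " (+box)", "\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

#' Extract the coordinates of one frame
#'
#' @param traj an `mtraj`.
#' @param frame frame index (1-based).
#' @param idx optional atom indices to subset.
#' @return an `n x 3` coordinate matrix.
#' @export
frame_coords <- function(traj, frame = 1, idx = NULL) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  m <- matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Select atom indices by residue number, atom name or residue name
#'
#' All supplied filters are combined with AND; `NULL` filters match
#' everything.
#'
#' @param traj an `mtraj`.
#' @param resno residue numbers, or `NULL`.
#' @param elety atom names, or `NULL`.
#' @param resid residue names, or `NULL`.
#' @param heavy_only drop hydrogens (atom names starting with H after any
#'   leading digits)? Default `FALSE`.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, resno = NULL, elety = NULL, resid = NULL,
                         heavy_only = FALSE) {
  keep <- rep(TRUE, nrow(traj$atom))
  if (!is.null(resno)) keep <- keep & traj$atom$resno %in% resno
  if (!is.null(elety)) keep <- keep & traj$atom$elety %in% elety
  if (!is.null(resid)) keep <- keep & traj$atom$resid %in% resid
  if (heavy_only) keep <- keep & !is_hydrogen(traj$atom$elety)
  which(keep)
}

is_hydrogen <- function(elety) grepl("^[0-9]*H", elety)

# van der Waals radius by element symbol inferred from the atom name.
vdw_radius <- function(elety) {
  el <- substr(sub("^[0-9]+", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)[el]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a multi-model PDB trajectory
#'
#' One `StructureFrame` per MODEL record. Atom parsing is delegated to
#' [bio3d::read.pdb()]; orthorhombic box lengths are recovered from CRYST1
#' records (one per file, or one inside each MODEL block for per-frame
#' boxes).
#'
#' @param path PDB file path.
#' @param replica_id label stored on the returned trajectory.
#' @return an `mtraj`.
#' @export
read_trajectory <- function(path, replica_id = basename(path)) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  if (!any(grepl("^ATOM|^HETATM", lines))) {
    stop("empty trajectory: no atom records in ", path)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atom <- data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                     resno = pdb$atom$resno,
                     chain = ifelse(is.na(pdb$atom$chain), "A",
                                    pdb$atom$chain),
                     stringsAsFactors = FALSE)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- NULL
  if (length(cryst) > 0L) {
    parse1 <- function(l) as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                       substr(l, 25, 33)))
    b <- t(vapply(cryst, parse1, numeric(3)))
    box <- if (nrow(b) == nrow(xyz)) b else
      matrix(b[1, ], nrow = nrow(xyz), ncol = 3, byrow = TRUE)
    dimnames(box) <- NULL
  }
  new_trajectory(atom, unclass(xyz), box = box, replica_id = replica_id)
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are written at standard PDB precision (3 decimals) via
#' [bio3d::write.pdb()]; if the trajectory carries box information, a CRYST1
#' record is inserted inside each MODEL block.
#'
#' @param traj an `mtraj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mtraj"))
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = traj$atom$resno, resid = traj$atom$resid,
                   elety = traj$atom$elety, chain = traj$atom$chain)
  if (!is.null(traj$box)) {
    lines <- readLines(path)
    model_at <- grep("^MODEL", lines)
    if (length(model_at) == 0L) {   # single frame: bio3d omits MODEL records
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[1, 1], traj$box[1, 2], traj$box[1, 3],
                       90, 90, 90)
      lines <- c(cryst, lines)
    } else {
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$box[, 1], traj$box[, 2], traj$box[, 3],
                       90, 90, 90)
      # insert after each MODEL line, back to front to keep indices valid
      for (k in rev(seq_along(model_at))) {
        lines <- append(lines, cryst[k], after = model_at[k])
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}
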