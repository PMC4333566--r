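# Fixture builders shared across test files. Everything is generated in
# code; no binary or stored data.

make_alignment <- function(rows, reference_id = names(rows)[1]) {
  memqc:::new_alignment(unname(rows), names(rows), reference_id)
}

write_fasta_fixture <- function(rows, path) {
  writeLines(as.vector(rbind(paste0(">", names(rows)), unname(rows))), path)
  path
}

# Minimal Clustal writer mirroring the classic header + padded-id layout.
write_clustal_fixture <- function(rows, path) {
  ids <- format(names(rows), width = 36)
  writeLines(c("CLUSTAL X (1.81) multiple sequence alignment", "", "",
               paste0(ids, unname(rows)), "", ""), path)
  path
}

# Alignment rows from a character matrix (rows x columns).
rows_from_matrix <- function(mat, ids = NULL) {
  out <- apply(mat, 1, paste, collapse = "")
  names(out) <- ids %||% c("ref", paste0("s", seq_len(nrow(mat) - 1) + 1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random peptide backbone trajectory frame with mixed dihedrals, used for
# oracle-agreement checks. Returns a single-frame mtraj.
random_backbone <- function(n_residues, seed) {
  set.seed(seed)
  regions <- sample(c("helix", "extended", "coil"), n_residues,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
  phi <- ifelse(regions == "helix", rnorm(n_residues, -57, 10),
                ifelse(regions == "extended", rnorm(n_residues, -140, 20),
                       runif(n_residues, -180, 180)))
  psi <- ifelse(regions == "helix", rnorm(n_residues, -47, 10),
                ifelse(regions == "extended", rnorm(n_residues, 145, 20),
                       runif(n_residues, -180, 180)))
  memqc::build_backbone(phi, psi, n_residues = n_residues)
}

# Apply a rigid transform (random rotation + translation) to every frame.
rigid_transform_traj <- function(traj, seed) {
  set.seed(seed)
  R <- memqc:::random_rotation()
  t <- rnorm(3, 0, 20)
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m <- m %*% R + matrix(t, nrow(m), 3, byrow = TRUE)
    xyz[f, ] <- as.vector(t(m))
  }
  memqc::new_trajectory(traj$atom, xyz, box = traj$box,
                        replica_id = traj$replica_id)
}
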