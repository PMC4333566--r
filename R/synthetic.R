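# Deterministic synthetic-data generators. Every generator takes a seed and
# carries its ground truth as an attribute, so estimates can be checked
# against construction mechanically. Per-component RNG streams are derived
# with derive_seed(), so adding a generator never perturbs existing streams.

#' Generate an alignment with prescribed per-column class frequencies
#'
#' Each column draws residues from the hydrophobic class with the target
#' frequency and from the non-class standard residues otherwise; optional
#' per-column gap probability. Row 1 is the gap-free reference sequence
#' (id `"ref"`).
#'
#' @param n_rows number of sequences.
#' @param length number of alignment columns.
#' @param class_freq target class frequency, scalar or per column.
#' @param gap_prob gap probability, scalar or per column (default 0).
#' @param seed integer seed (mandatory; generation is deterministic).
#' @param residue_class class set (default [HYDROPHOBIC_CLASS]).
#' @return an `msa_alignment`; attribute `ground_truth` holds the
#'   per-column `class_freq` and `gap_prob`.
#' @export
gen_msa <- function(n_rows, length, class_freq, gap_prob = 0, seed,
                    residue_class = HYDROPHOBIC_CLASS) {
  stopifnot(n_rows >= 1, length >= 1,
            all(class_freq >= 0 & class_freq <= 1),
            all(gap_prob >= 0 & gap_prob <= 1))
  class_freq <- rep_len(class_freq, length)
  gap_prob <- rep_len(gap_prob, length)
  nonclass <- setdiff(AA_STANDARD, residue_class)
  mat <- with_seed(derive_seed(seed, "msa"), {
    m <- matrix("", n_rows, length)
    for (j in seq_len(length)) {
      in_class <- runif(n_rows) < class_freq[j]
      m[, j] <- ifelse(in_class,
                       sample(residue_class, n_rows, replace = TRUE),
                       sample(nonclass, n_rows, replace = TRUE))
      gapped <- runif(n_rows) < gap_prob[j]
      gapped[1] <- FALSE           # reference row stays gap-free
      m[gapped, j] <- "-"
    }
    m
  })
  ids <- c("ref", paste0("seq", seq_len(n_rows - 1) + 1))[seq_len(n_rows)]
  aln <- new_alignment(apply(mat, 1, paste, collapse = ""), ids, "ref")
  attr(aln, "ground_truth") <- list(class_freq = class_freq,
                                    gap_prob = gap_prob, seed = seed)
  aln
}

# Standard backbone geometry (bond lengths in Angstroms, angles in degrees).
BB_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.6, a_C_N_CA = 121.9, a_CA_C_O = 120.8
)

#' Build a peptide backbone from dihedral angles
#'
#' Internal-coordinate (NeRF) chain construction with standard peptide
#' geometry: N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Angstroms;
#' angles N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.9 degrees. Carbonyl
#' oxygens are placed anti to the following amide nitrogen
#' (dihedral N-CA-C-O = psi + 180).
#'
#' @param phi,psi backbone dihedrals in degrees, recycled to `n_residues`;
#'   `phi[1]` is undefined by construction and ignored.
#' @param omega peptide-bond dihedral (default 180, trans).
#' @param n_residues chain length (>= 2).
#' @param resid residue name used for every residue (default `"ALA"`).
#' @param chain chain identifier.
#' @return a single-frame `mtraj` with N, CA, C, O atoms per residue.
#' @export
build_backbone <- function(phi, psi, omega = 180, n_residues,
                           resid = "ALA", chain = "A") {
  stopifnot(n_residues >= 2)
  phi <- rep_len(phi, n_residues)
  psi <- rep_len(psi, n_residues)
  omega <- rep_len(omega, n_residues)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n_residues, 3)
  # residue 1 in a canonical frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  thet <- deg2rad(g$a_N_CA_C)
  C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(thet), sin(thet), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                             g$b_C_N, g$a_CA_C_N, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                              g$b_N_CA, g$a_C_N_CA, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                             g$b_CA_C, g$a_N_CA_C, phi[i + 1])
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_C_O, g$a_CA_C_O, psi[i] + 180)
  }
  atom <- data.frame(
    elety = rep(c("N", "CA", "C", "O"), n_residues),
    resid = resid,
    resno = rep(seq_len(n_residues), each = 4),
    chain = chain, stringsAsFactors = FALSE)
  xyz <- as.vector(t(do.call(rbind, lapply(seq_len(n_residues), function(i) {
    rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
  }))))
  new_trajectory(atom, xyz)
}

#' Measure backbone dihedrals from coordinates
#'
#' Round-trip counterpart of [build_backbone()]: phi(i) =
#' C(i-1)-N(i)-CA(i)-C(i) (NA for the first residue), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1); the final psi is recovered from the carbonyl
#' oxygen (psi = dihedral(N,CA,C,O) - 180).
#'
#' @param traj a single-frame `mtraj` with backbone atoms.
#' @param frame frame index (default 1).
#' @return list with numeric vectors `phi` and `psi` in degrees.
#' @export
measure_dihedrals <- function(traj, frame = 1) {
  bb <- backbone_table(traj, frame)
  n <- length(bb$resno)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    psi[i] <- if (i < n) {
      dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
    } else {
      d <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ]) - 180
      ((d + 180) %% 360) - 180
    }
  }
  list(phi = phi, psi = psi)
}

#' Generate alpha-helical trajectories with controlled per-residue unwinding
#'
#' Frames are built from ideal helical dihedrals (phi -57, psi -47 degrees)
#' plus Gaussian dihedral noise and coordinate noise. Residues flagged in
#' `unwind` have their dihedrals redrawn from the extended region
#' (phi in \[-180, -120\], psi in \[120, 180\] degrees) in an exact,
#' deterministically chosen fraction of frames, so ground-truth helicity is
#' known by construction. Per-replica seeds derive from `seed`, so replicas
#' are independent but reproducible.
#'
#' The attached `ground_truth` gives the expected helicity where the
#' construction determines it: `1 - unwind_fraction` at flagged residues,
#' `1` at interior residues at least 5 positions away from every flagged
#' residue, `NA` elsewhere (unwinding residue r perturbs the i->i+4
#' hydrogen bonds that span r, so nearby residues have no closed-form
#' truth).
#'
#' @param n_residues helix length (>= 5; default 30).
#' @param n_frames frames per replica.
#' @param n_replicas number of replicas (default 3).
#' @param unwind residue numbers to unwind (default none).
#' @param unwind_fraction fraction of frames in which flagged residues are
#'   unwound, scalar or one value per `unwind` entry.
#' @param dihedral_noise_sd Gaussian SD on phi/psi in degrees (default 4).
#' @param coord_noise_sd Gaussian SD added to every coordinate in
#'   Angstroms (default 0.05).
#' @param seed integer master seed.
#' @param box optional box lengths (passed to every replica).
#' @return a list of `mtraj` replicas with attribute `ground_truth`
#'   (list: `unwind`, `unwind_fraction`, `expected_helicity`).
#' @export
gen_helix_trajectory <- function(n_residues = 30, n_frames = 100,
                                 n_replicas = 3, unwind = integer(),
                                 unwind_fraction = 0,
                                 dihedral_noise_sd = 4,
                                 coord_noise_sd = 0.05, seed, box = NULL) {
  stopifnot(n_residues >= 5, n_frames >= 1, n_replicas >= 1,
            all(unwind >= 1 & unwind <= n_residues),
            all(unwind_fraction >= 0 & unwind_fraction <= 1),
            dihedral_noise_sd >= 0, coord_noise_sd >= 0)
  unwind_fraction <- rep_len(unwind_fraction, max(1L, length(unwind)))
  trajs <- lapply(seq_len(n_replicas), function(rep_i) {
    rep_seed <- derive_seed(seed, paste0("helix-rep", rep_i))
    with_seed(rep_seed, {
      # exact unwound-frame subsets, one per flagged residue
      unwound_frames <- lapply(seq_along(unwind), function(k) {
        sample(n_frames, round(unwind_fraction[k] * n_frames))
      })
      xyz <- matrix(NA_real_, n_frames, 4L * n_residues * 3L)
      for (f in seq_len(n_frames)) {
        phi <- rnorm(n_residues, -57, dihedral_noise_sd)
        psi <- rnorm(n_residues, -47, dihedral_noise_sd)
        for (k in seq_along(unwind)) {
          if (f %in% unwound_frames[[k]]) {
            phi[unwind[k]] <- runif(1, -180, -120)
            psi[unwind[k]] <- runif(1, 120, 180)
          }
        }
        fr <- build_backbone(phi, psi, n_residues = n_residues)
        co <- fr$xyz[1, ]
        if (coord_noise_sd > 0) {
          co <- co + rnorm(length(co), 0, coord_noise_sd)
        }
        xyz[f, ] <- co
      }
      atom <- build_backbone(-57, -47, n_residues = n_residues)$atom
      new_trajectory(atom, xyz, box = box,
                     replica_id = paste0("rep", rep_i))
    })
  })
  expected <- rep(1, n_residues)
  expected[c(1, 2, n_residues - 1, n_residues)] <- NA  # helix ends fray
  for (k in seq_along(unwind)) {
    near <- setdiff(max(1, unwind[k] - 4):min(n_residues, unwind[k] + 4),
                    unwind[k])
    expected[near] <- NA
    expected[unwind[k]] <- 1 - unwind_fraction[k]
  }
  attr(trajs, "ground_truth") <- list(unwind = unwind,
                                      unwind_fraction = unwind_fraction,
                                      expected_helicity = expected,
                                      seed = seed)
  trajs
}

#' Generate a trajectory with a pseudo-ligand at a prescribed contact fraction
#'
#' A short rigid helix plus one ligand pseudo-atom (residue `LIG`,
#' atom `C1`) placed 3 Angstroms from the CA of the target residue in
#' exactly `round(target_fraction * n_frames)` deterministically chosen
#' frames, and far outside the cutoff otherwise.
#'
#' @param n_frames number of frames.
#' @param target_fraction prescribed contact fraction in `[0, 1]`.
#' @param cutoff contact cutoff the trace is built against (default 6).
#' @param target_residue protein residue contacted (default 3).
#' @param n_residues protein length (default 5).
#' @param seed integer seed.
#' @return an `mtraj`; attribute `ground_truth` holds `target_fraction`,
#'   the realised `contact_frames`, and `target_residue`.
#' @export
gen_contact_trace <- function(n_frames, target_fraction, cutoff = 6,
                              target_residue = 3, n_residues = 5, seed) {
  stopifnot(target_fraction >= 0, target_fraction <= 1, n_frames >= 1)
  base <- build_backbone(-57, -47, n_residues = n_residues)
  atom <- rbind(base$atom,
                data.frame(elety = "C1", resid = "LIG", resno = 999,
                           chain = "L", stringsAsFactors = FALSE))
  ca <- frame_coords(base, 1)[which(base$atom$elety == "CA" &
                                      base$atom$resno == target_residue), ]
  n_contact <- round(target_fraction * n_frames)
  contact_frames <- with_seed(derive_seed(seed, "contact"),
                              sort(sample(n_frames, n_contact)))
  near <- ca + c(3, 0, 0)
  far <- ca + c(cutoff + 20, 0, 0)
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    lig <- if (f %in% contact_frames) near else far
    c(base$xyz[1, ], lig)
  }, numeric(ncol(base$xyz) + 3)))
  out <- new_trajectory(atom, xyz, replica_id = "contact")
  attr(out, "ground_truth") <- list(target_fraction = target_fraction,
                                    contact_frames = contact_frames,
                                    target_residue = target_residue)
  out
}

#' Generate a donor-acceptor distance trace with prescribed occupancy
#'
#' Two pseudo-residues — carboxylate oxygens (`OD1`, `OD2`) and amino
#' hydrogens (`HZ1`) — separated per frame by `below` Angstroms in exactly
#' `round(target_occupancy * n_frames)` deterministically chosen frames
#' and by `above` otherwise, emulating an intermittent salt bridge.
#'
#' @param n_frames number of frames.
#' @param target_occupancy prescribed sub-threshold fraction.
#' @param below,above distances (Angstroms) used inside/outside the
#'   sub-threshold frames (defaults 3.0 and 5.0).
#' @param seed integer seed.
#' @return an `mtraj` with `ground_truth` attribute
#'   (`target_occupancy`, `bridge_frames`, `below`, `above`).
#' @export
gen_salt_bridge_trace <- function(n_frames, target_occupancy, below = 3.0,
                                  above = 5.0, seed) {
  stopifnot(target_occupancy >= 0, target_occupancy <= 1,
            below > 0, above > 0)
  atom <- data.frame(
    elety = c("OD1", "OD2", "HZ1"),
    resid = c("ASP", "ASP", "LYS"),
    resno = c(670, 670, 694),
    chain = "A", stringsAsFactors = FALSE)
  n_in <- round(target_occupancy * n_frames)
  bridge_frames <- with_seed(derive_seed(seed, "saltbridge"),
                             sort(sample(n_frames, n_in)))
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    d <- if (f %in% bridge_frames) below else above
    # OD1 at origin, OD2 offset 2.2 A away on y, donor H at distance d on x
    c(0, 0, 0, 0, 2.2, 0, d, 0, 0)
  }, numeric(9)))
  out <- new_trajectory(atom, xyz, replica_id = "saltbridge")
  attr(out, "ground_truth") <- list(target_occupancy = target_occupancy,
                                    bridge_frames = bridge_frames,
                                    below = below, above = above)
  out
}

#' Generate synthetic predictor tracks around true TM segments
#'
#' Builds per-predictor binary tracks from a true segment set, flipping
#' each residue's mark independently with probability `flip_prob` per
#' predictor.
#'
#' @param n_residues sequence length.
#' @param segments data.frame with `start`, `end` (1-based inclusive).
#' @param n_predictors number of tracks (default 4).
#' @param flip_prob per-residue label noise (default 0.05).
#' @param seed integer seed.
#' @return integer matrix residues x predictors with `ground_truth`
#'   attribute carrying `segments`.
#' @export
gen_tm_tracks <- function(n_residues, segments, n_predictors = 4,
                          flip_prob = 0.05, seed) {
  truth <- integer(n_residues)
  for (i in seq_len(nrow(segments))) {
    truth[segments$start[i]:segments$end[i]] <- 1L
  }
  m <- with_seed(derive_seed(seed, "tmtracks"), {
    vapply(seq_len(n_predictors), function(p) {
      flip <- runif(n_residues) < flip_prob
      as.integer(xor(truth == 1L, flip))
    }, integer(n_residues))
  })
  colnames(m) <- paste0("predictor", seq_len(n_predictors))
  attr(m, "ground_truth") <- list(segments = segments)
  m
}

#' Generate a dose-response curve from known 4PL parameters
#'
#' Forward model identical to the one fitted by [fit_dose_response()],
#' plus Gaussian noise (additive in signal units, or multiplicative as a
#' fraction of each signal).
#'
#' @param pIC50 true -log10(IC50 in M).
#' @param hill true hill slope.
#' @param top,bottom true asymptotes.
#' @param concentrations molar concentrations (> 0).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param noise `"additive"` (signal units) or `"multiplicative"`
#'   (`noise_sd` is a relative SD, e.g. 0.01 for 1%).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return a `dose_response` with `ground_truth` attribute.
#' @export
gen_dose_response <- function(pIC50, hill, top, bottom, concentrations,
                              noise_sd = 0,
                              noise = c("additive", "multiplicative"),
                              seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(all(concentrations > 0), noise_sd >= 0)
  y <- fourpl(concentrations, pIC50, hill, top, bottom)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed is required when noise_sd > 0")
    y <- with_seed(derive_seed(seed, "dose"), {
      if (noise == "additive") y + rnorm(length(y), 0, noise_sd)
      else y * (1 + rnorm(length(y), 0, noise_sd))
    })
  }
  out <- dose_response(concentrations, y, b0 = top)
  attr(out, "ground_truth") <- list(pIC50 = pIC50, hill = hill, top = top,
                                    bottom = bottom, noise_sd = noise_sd,
                                    noise = noise)
  out
}
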