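test_that("an ideal alpha helix is assigned H in its interior", {
  helix <- build_backbone(-57, -47, n_residues = 20)
  ss <- assign_secondary_structure(helix, frame = 1)
  expect_true(all(ss[3:18] == "H"))
  expect_equal(unname(ss[1]), "-")
  expect_equal(unname(ss[20]), "-")
})

test_that("a fully extended chain has no helical residues", {
  ext <- build_backbone(180, 180, n_residues = 20)
  ss <- assign_secondary_structure(ext, frame = 1)
  expect_false(any(ss == "H"))
})

test_that("chains shorter than 5 residues can never be alpha", {
  pep <- build_backbone(-57, -47, n_residues = 4)
  ss <- assign_secondary_structure(pep, frame = 1)
  expect_false(any(ss == "H"))
})

test_that("assignment is invariant under rigid transforms", {
  for (seed in 1:5) {
    tr <- random_backbone(15, seed = seed)
    moved <- rigid_transform_traj(tr, seed = seed + 100)
    expect_identical(assign_secondary_structure(tr, frame = 1),
                     assign_secondary_structure(moved, frame = 1))
  }
})

test_that("assignment agrees with the independent Kabsch-Sander oracle", {
  mismatch <- 0L; total <- 0L
  for (seed in 1:25) {
    tr <- random_backbone(20, seed = 1000 + seed)
    got <- assign_secondary_structure(tr, frame = 1)
    want <- oracle_ss(tr, frame = 1)
    mismatch <- mismatch + sum(got != want)
    total <- total + length(want)
  }
  expect_gte(1 - mismatch / total, 0.99)
})

test_that("first and last residues of a chain are never alpha", {
  for (seed in 1:10) {
    tr <- random_backbone(12, seed = 2000 + seed)
    ss <- assign_secondary_structure(tr, frame = 1)
    expect_false(ss[1] == "H")
    expect_false(ss[12] == "H")
  }
})

test_that("proline never donates: a proline stretch interrupts the helix", {
  helix <- build_backbone(-57, -47, n_residues = 20)
  pro <- helix
  # prolines at 8..11 remove the donors of the 4->8 .. 7->11 bonds, so the
  # 4-turn ladder has a hole even though the geometry is unchanged
  pro$atom$resid[pro$atom$resno %in% 8:11] <- "PRO"
  ss_pro <- assign_secondary_structure(pro, frame = 1)
  ss_ref <- assign_secondary_structure(helix, frame = 1)
  expect_true(all(ss_ref[3:18] == "H"))
  expect_gt(sum(ss_ref == "H"), sum(ss_pro == "H"))
  expect_false(any(ss_pro[7:8] == "H"))
  # single lost donor is bridged by the overlapping turns on either side
  one <- helix
  one$atom$resid[one$atom$resno == 8] <- "PRO"
  expect_true(all(assign_secondary_structure(one, frame = 1)[3:18] == "H"))
})

test_that("a gap in the backbone splits assignment into independent chains", {
  helix <- build_backbone(-57, -47, n_residues = 24)
  xyz <- helix$xyz
  second <- which(helix$atom$resno > 12)
  cols <- as.vector(t(cbind((second - 1) * 3 + 1, (second - 1) * 3 + 2,
                            (second - 1) * 3 + 3)))
  xyz[1, cols[seq(1, length(cols), 3)]] <-
    xyz[1, cols[seq(1, length(cols), 3)]] + 100  # shift x by 100 A
  broken <- new_trajectory(helix$atom, xyz)
  ss <- assign_secondary_structure(broken, frame = 1)
  # residue 12 ends a chain, residue 13 starts one: neither can be alpha
  expect_false(ss[12] == "H")
  expect_false(ss[13] == "H")
  # both halves keep helical interiors
  expect_true(all(ss[4:9] == "H"))
  expect_true(all(ss[16:21] == "H"))
})

test_that("helicity fractions, replica mean/SD and the 60% rule are exact", {
  # three replicas built by construction: fractions 0.5, 0.6, 0.7 at the
  # unwound residue give mean 0.6 (conserved at the boundary) and SD 0.1
  helix <- build_backbone(-57, -47, n_residues = 15)
  make_rep <- function(n_hel, n_ext, id) {
    # frames alternate between intact helix and a chain unwound at residue 8
    unwound <- build_backbone(c(rep(-57, 7), -150, rep(-57, 7)),
                              c(rep(-47, 7), 150, rep(-47, 7)),
                              n_residues = 15)
    xyz <- rbind(matrix(rep(helix$xyz, n_hel), n_hel, byrow = TRUE),
                 matrix(rep(unwound$xyz, n_ext), n_ext, byrow = TRUE))
    new_trajectory(helix$atom, xyz, replica_id = id)
  }
  reps <- list(make_rep(5, 5, "r1"), make_rep(6, 4, "r2"),
               make_rep(7, 3, "r3"))
  hp <- helicity_profile(reps, criterion = 0.6)
  at8 <- hp[hp$residue == 8, ]
  expect_equal(unname(unlist(at8[paste0("fraction_r", 1:3)])),
               c(0.5, 0.6, 0.7))
  expect_equal(at8$mean, 0.6)
  expect_equal(at8$sd, 0.1, tolerance = 1e-12)
  expect_true(at8$conserved)   # ties at the criterion count as conserved
  expect_true(all(hp$sd[hp$residue %in% c(4, 5)] == 0))
})

test_that("identical replicas give SD zero; fractions ignore frame order", {
  trajs <- gen_helix_trajectory(n_residues = 10, n_frames = 12,
                                n_replicas = 1, unwind = 5,
                                unwind_fraction = 0.5, seed = 77,
                                dihedral_noise_sd = 0, coord_noise_sd = 0)
  tr <- trajs[[1]]
  hp_same <- helicity_profile(list(tr, tr, tr))
  expect_true(all(hp_same$sd == 0))
  set.seed(4)
  shuffled <- new_trajectory(tr$atom, tr$xyz[sample(12), ],
                             replica_id = "shuf")
  hp1 <- helicity_profile(tr)
  hp2 <- helicity_profile(shuffled)
  expect_equal(hp1$mean, hp2$mean)
})

test_that("replicas with different residue ranges are rejected", {
  a <- build_backbone(-57, -47, n_residues = 8)
  b <- build_backbone(-57, -47, n_residues = 9)
  expect_error(helicity_profile(list(a, b)), "different residue ranges")
})
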