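empty_traj <- function() {
  # a single faraway atom so the container is valid but the region is empty
  new_trajectory(data.frame(elety = "C", resid = "ALA", resno = 1,
                            chain = "A", stringsAsFactors = FALSE),
                 c(1000, 1000, 1000))
}

test_that("an atom-free region returns the exact grid volume", {
  cv <- cavity_volume(empty_traj(),
                      region = list(x = c(0, 19), y = c(0, 19), z = c(0, 19)),
                      seed_point = c(10, 10, 10), spacing = 1.0)
  expect_equal(cv$volume, 8000)       # 20^3 points x 1 A^3
  expect_equal(cv$n_points, cv$n_total)
})

test_that("a single occluding sphere removes close to its analytic volume", {
  tr <- new_trajectory(data.frame(elety = "X", resid = "SPH", resno = 1,
                                  chain = "A", stringsAsFactors = FALSE),
                       c(10, 10, 10))
  # unknown element -> default vdW 1.7; with probe 1.2 exclusion radius 2.9
  r_excl <- 1.7 + 1.2
  cv <- cavity_volume(tr, region = list(x = c(0, 20), y = c(0, 20),
                                        z = c(0, 20)),
                      seed_point = c(1, 1, 1), spacing = 0.5, probe = 1.2)
  full <- cavity_volume(empty_traj(),
                        region = list(x = c(0, 20), y = c(0, 20),
                                      z = c(0, 20)),
                        seed_point = c(1, 1, 1), spacing = 0.5)
  excluded <- full$volume - cv$volume
  analytic <- 4 / 3 * pi * r_excl^3
  expect_lt(abs(excluded - analytic) / analytic, 0.05)
})

test_that("volume converges as the grid is refined", {
  # a smooth pocket: the sealed interior of a dense spherical shell of
  # carbon atoms (Fibonacci lattice, radius 9 A)
  n <- 800; r <- 9; c0 <- c(12, 12, 12)
  i <- seq(0, n - 1)
  ph <- acos(1 - 2 * (i + 0.5) / n); th <- pi * (1 + sqrt(5)) * i
  pts <- cbind(c0[1] + r * sin(ph) * cos(th),
               c0[2] + r * sin(ph) * sin(th),
               c0[3] + r * cos(ph))
  tr <- new_trajectory(data.frame(elety = "C", resid = "ALA",
                                  resno = seq_len(n), chain = "A",
                                  stringsAsFactors = FALSE),
                       as.vector(t(pts)))
  region <- list(x = c(2, 22), y = c(2, 22), z = c(2, 22))
  v1 <- cavity_volume(tr, region, c0, spacing = 1.0)$volume
  v2 <- cavity_volume(tr, region, c0, spacing = 0.5)$volume
  expect_lt(abs(v1 - v2) / v2, 0.02)
  # the sealed interior is close to the analytic inner-sphere volume
  expect_lt(abs(v2 - 4 / 3 * pi * (r - 3.1)^3) / v2, 0.1)
})

test_that("adding atoms never increases the cavity volume", {
  region <- list(x = c(0, 12), y = c(0, 12), z = c(0, 12))
  set.seed(9)
  pts <- matrix(runif(30, 2, 10), 10, 3)
  vols <- vapply(1:10, function(k) {
    tr <- new_trajectory(data.frame(elety = "C", resid = "ALA",
                                    resno = 1:k, chain = "A",
                                    stringsAsFactors = FALSE),
                         as.vector(t(pts[1:k, , drop = FALSE])))
    cavity_volume(tr, region, c(0.5, 0.5, 0.5), spacing = 1.0)$volume
  }, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("occluded seeds and bad regions raise errors", {
  tr <- new_trajectory(data.frame(elety = "C", resid = "ALA", resno = 1,
                                  chain = "A", stringsAsFactors = FALSE),
                       c(5, 5, 5))
  region <- list(x = c(0, 10), y = c(0, 10), z = c(0, 10))
  expect_error(cavity_volume(tr, region, seed_point = c(5, 5, 5)),
               "occluded")
  expect_error(cavity_volume(tr, region, seed_point = c(50, 5, 5)),
               "outside")
  expect_error(cavity_volume(tr, list(x = c(0, 10), y = c(10, 0),
                                      z = c(0, 10)), c(5, 5, 5)),
               "region")
})

test_that("contact occupancy reproduces constructed fractions exactly", {
  always <- gen_contact_trace(n_frames = 20, target_fraction = 1, seed = 1)
  occ <- contact_occupancy(always, ligand = list(resid = "LIG"),
                           residues = 3)
  expect_equal(occ$fraction, 1.0)
  partial <- gen_contact_trace(n_frames = 100, target_fraction = 0.21,
                               seed = 2)
  occ2 <- contact_occupancy(partial, ligand = list(resid = "LIG"),
                            residues = 1:5)
  expect_equal(occ2$fraction[occ2$residue == 3], 0.21)
  none <- contact_occupancy(partial, ligand = list(resid = "LIG"),
                            residues = 1:5, cutoff = 0.1)
  expect_true(all(none$fraction == 0))
})

test_that("pooled occupancy is frame-weighted and order-invariant", {
  a <- gen_contact_trace(n_frames = 50, target_fraction = 0.2, seed = 3)
  b <- gen_contact_trace(n_frames = 150, target_fraction = 0.6, seed = 4)
  pooled <- contact_occupancy(list(a, b), ligand = list(resid = "LIG"),
                              residues = 3)
  # (0.2*50 + 0.6*150) / 200 = 0.5, not the replica mean 0.4
  expect_equal(pooled$fraction, 0.5)
  swapped <- contact_occupancy(list(b, a), ligand = list(resid = "LIG"),
                               residues = 3)
  expect_equal(swapped$fraction, pooled$fraction)
  concat <- new_trajectory(a$atom, rbind(a$xyz, b$xyz))
  one <- contact_occupancy(concat, ligand = list(resid = "LIG"),
                           residues = 3)
  expect_equal(one$fraction, pooled$fraction)
})

test_that("contact statistics are rigid-transform invariant", {
  tr <- gen_contact_trace(n_frames = 40, target_fraction = 0.3, seed = 5)
  moved <- rigid_transform_traj(tr, seed = 55)
  o1 <- contact_occupancy(tr, ligand = list(resid = "LIG"), residues = 1:5)
  o2 <- contact_occupancy(moved, ligand = list(resid = "LIG"),
                          residues = 1:5)
  expect_equal(o1$fraction, o2$fraction, tolerance = 1e-12)
})

test_that("salt-bridge occupancy uses a strict threshold", {
  tr <- gen_salt_bridge_trace(n_frames = 100, target_occupancy = 0.35,
                              seed = 6)
  trace <- salt_bridge_trace(tr, donor = list(elety = "HZ1"),
                             acceptor = list(elety = c("OD1", "OD2")),
                             threshold = 3.5)
  expect_equal(trace$occupancy, 0.35)
  expect_equal(trace$mean, 0.35 * 3 + 0.65 * 5, tolerance = 1e-9)
  # frames at exactly the threshold do not count (strict <)
  at_threshold <- gen_salt_bridge_trace(n_frames = 10, target_occupancy = 1,
                                        below = 3.5, seed = 7)
  trace2 <- salt_bridge_trace(at_threshold, donor = list(elety = "HZ1"),
                              acceptor = list(elety = c("OD1", "OD2")),
                              threshold = 3.5)
  expect_equal(trace2$occupancy, 0)
})

test_that("the per-frame distance is the minimum over all pairs", {
  atoms <- data.frame(elety = c("HZ1", "OD1", "OD2"),
                      resid = c("LYS", "ASP", "ASP"),
                      resno = c(694, 670, 670), chain = "A",
                      stringsAsFactors = FALSE)
  xyz <- c(0, 0, 0, 4, 0, 0, 2, 0, 0)   # acceptors at 4 A and 2 A
  tr <- new_trajectory(atoms, xyz)
  trace <- salt_bridge_trace(tr, donor = list(elety = "HZ1"),
                             acceptor = list(elety = c("OD1", "OD2")))
  expect_equal(trace$distances, 2)
})

test_that("occupancy equals the empirical CDF just below the threshold", {
  tr <- gen_salt_bridge_trace(n_frames = 200, target_occupancy = 0.4,
                              below = 2.8, above = 6.1, seed = 8)
  for (thr in c(2.0, 2.8, 3.0, 3.5, 6.1, 6.2)) {
    trace <- salt_bridge_trace(tr, donor = list(elety = "HZ1"),
                               acceptor = list(elety = c("OD1", "OD2")),
                               threshold = thr)
    ecdf_below <- mean(trace$distances < thr)
    expect_equal(trace$occupancy, ecdf_below)
  }
})

test_that("missing atoms in selections are reported by name", {
  tr <- gen_salt_bridge_trace(n_frames = 5, target_occupancy = 0.2, seed = 9)
  expect_error(salt_bridge_trace(tr, donor = list(elety = "NZ9"),
                                 acceptor = list(elety = "OD1")),
               "donor")
})

test_that("area per lipid follows the box and the leaflet convention", {
  atoms <- data.frame(elety = "CA", resid = "ALA", resno = 1, chain = "A",
                      stringsAsFactors = FALSE)
  tr <- new_trajectory(atoms, rbind(c(0, 0, 0), c(0, 0, 0)),
                       box = rbind(c(80, 80, 100), c(80, 80, 100)))
  apl <- area_per_lipid(tr, n_lipids_total = 200)
  expect_equal(apl$values, c(64, 64))   # 6400 / 100
  expect_equal(apl$sd, 0)
  corrected <- area_per_lipid(tr, n_lipids_total = 200, protein_area = 400)
  expect_equal(corrected$values[1], (6400 - 400) / 100)
  expect_error(area_per_lipid(tr, n_lipids_total = 199), "even")
  no_box <- new_trajectory(atoms, c(0, 0, 0))
  expect_error(area_per_lipid(no_box, 200), "box")
})
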