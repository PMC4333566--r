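test_that("unanimous and mixed columns give the hand-counted percentages", {
  aln <- make_alignment(c(ref = "LL", s2 = "LV", s3 = "LK", s4 = "LE"))
  prof <- conservation_profile(aln)
  # column 1: L,L,L,L
  expect_equal(prof$identity_pct[1], 100)
  expect_equal(prof$class_pct[1], 100)
  expect_equal(prof$modal_residue[1], "L")
  # column 2: L,V,K,E -> identity 1/4, class {L,V} 2/4
  expect_equal(prof$identity_pct[2], 25)
  expect_equal(prof$class_pct[2], 50)
})

test_that("gap policy switches the percentage denominator", {
  aln <- make_alignment(c(ref = "L", s2 = "V", s3 = "-", s4 = "E"))
  all_rows <- conservation_profile(aln, gap_policy = "all_rows")
  nongap <- conservation_profile(aln, gap_policy = "nongap_rows")
  expect_equal(all_rows$class_pct, 50)               # 2 of 4
  expect_equal(nongap$class_pct, 100 * 2 / 3, tolerance = 1e-12)
})

test_that("reference gaps are skipped without renumbering", {
  aln <- make_alignment(c(ref = "L-V", s2 = "LAV", s3 = "LAV"))
  prof <- conservation_profile(aln)
  expect_equal(prof$position, c(1, 2))
  expect_equal(prof$reference_residue, c("L", "V"))
})

test_that("profile is invariant to row order and to row duplication", {
  aln <- gen_msa(8, 20, class_freq = 0.6, seed = 42)
  prof <- conservation_profile(aln)
  set.seed(11)
  perm <- c(1, sample(2:8))  # keep reference row present, shuffle the rest
  shuffled <- make_alignment(aln$rows[perm], reference_id = "ref")
  expect_equal(as.data.frame(conservation_profile(shuffled)),
               as.data.frame(prof))
  doubled <- make_alignment(setNames(rep(unname(aln$rows), 2),
                                     c(aln$ids, paste0(aln$ids, "_dup"))),
                            reference_id = "ref")
  prof2 <- conservation_profile(doubled, gap_policy = "all_rows")
  expect_equal(prof2$identity_pct, prof$identity_pct)
  expect_equal(prof2$class_pct, prof$class_pct)
})

test_that("single-row alignment has identity 100 and class in {0, 100}", {
  aln <- make_alignment(c(ref = "MAVKDE"))
  prof <- conservation_profile(aln)
  expect_true(all(prof$identity_pct == 100))
  expect_true(all(prof$class_pct %in% c(0, 100)))
  expect_equal(prof$class_pct, c(100, 100, 100, 0, 0, 0))  # M,A,V vs K,D,E
})

test_that("class_pct >= identity_pct whenever the modal residue is in class", {
  for (seed in 1:5) {
    aln <- gen_msa(10, 30, class_freq = 0.5, gap_prob = 0.1, seed = seed)
    prof <- conservation_profile(aln)
    in_class <- prof$modal_residue %in% HYDROPHOBIC_CLASS
    expect_true(all(prof$class_pct[in_class] >=
                      prof$identity_pct[in_class] - 1e-12))
  }
})

test_that("profile matches the brute-force counter on random alignments", {
  for (seed in 1:10) {
    aln <- gen_msa(10, 50, class_freq = runif(1), gap_prob = 0.15,
                   seed = seed)
    for (policy in c("all_rows", "nongap_rows")) {
      prof <- conservation_profile(aln, gap_policy = policy)
      bf <- brute_conservation(unname(aln$rows), "ref", aln$ids,
                               HYDROPHOBIC_CLASS, policy)
      expect_equal(prof$identity_pct, bf$identity_pct, tolerance = 1e-12)
      expect_equal(prof$class_pct, bf$class_pct, tolerance = 1e-12)
      expect_equal(prof$modal_residue, bf$modal_residue)
    }
  }
})

test_that("FASTA and Clustal readers produce the identical alignment", {
  rows <- c(ref = "MAVIL-KDEF", seqB = "MAVILCKDEF", seqC = "MGVIL-KDEY")
  fa <- write_fasta_fixture(rows, tempfile(fileext = ".fasta"))
  cl <- write_clustal_fixture(rows, tempfile(fileext = ".aln"))
  a <- read_alignment(fa, "ref")
  b <- read_alignment(cl, "ref")
  expect_equal(a$rows[sort(a$ids)], b$rows[sort(b$ids)])
  expect_identical(a$reference_id, b$reference_id)
})

test_that("ragged alignments and missing references are rejected", {
  fa <- write_fasta_fixture(c(ref = "MAVILKDEFW", s2 = "MAVILKDEF"),
                            tempfile(fileext = ".fa"))
  expect_error(read_alignment(fa, "ref"), "ragged")
  fa2 <- write_fasta_fixture(c(a = "MAVK", b = "MAVK"),
                             tempfile(fileext = ".fa"))
  expect_error(read_alignment(fa2, "ref"), "not found")
  expect_error(
    conservation_profile(make_alignment(c(ref = "---", s2 = "MAV"))),
    "only gaps")
})

test_that("non-standard letters count as non-class non-identity, with warning", {
  aln <- make_alignment(c(ref = "L", s2 = "X", s3 = "L", s4 = "L"))
  expect_warning(prof <- conservation_profile(aln), "non-standard")
  expect_equal(prof$identity_pct, 75)   # X is not an identity match
  expect_equal(prof$class_pct, 75)
})

test_that("heatmap export preserves values, order and shape", {
  aln <- gen_msa(6, 10, class_freq = 0.5, seed = 3)
  prof <- conservation_profile(aln)
  m1 <- conservation_heatmap_matrix(prof)
  expect_equal(dim(m1), c(1, 10))
  expect_equal(as.numeric(m1), prof$class_pct)
  m2 <- conservation_heatmap_matrix(prof, window = 4)
  expect_equal(dim(m2), c(3, 4))
  expect_equal(as.numeric(t(m2))[1:10], prof$class_pct)
  zero <- prof; zero$class_pct <- rep(0, 10)
  expect_true(all(conservation_heatmap_matrix(zero) == 0))
})

test_that("TSV and JSON round trips preserve the profile", {
  aln <- gen_msa(6, 8, class_freq = 1 / 3, seed = 9)
  prof <- conservation_profile(aln)
  js <- tempfile(fileext = ".json")
  write_conservation(prof, js, format = "json")
  back <- read_conservation(js, format = "json")
  expect_equal(back$class_pct, prof$class_pct, tolerance = 1e-14)
  expect_equal(back$identity_pct, prof$identity_pct, tolerance = 1e-14)
  tsv <- tempfile(fileext = ".tsv")
  write_conservation(prof, tsv, format = "tsv")
  back2 <- read_conservation(tsv, format = "tsv")
  expect_equal(back2$position, prof$position)
  expect_equal(back2$class_pct, prof$class_pct, tolerance = 1e-10)
})
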