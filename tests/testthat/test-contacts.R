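test_that("native contacts match the brute-force double loop exactly", {
  cases <- c(
    lapply(1:6, function(s) make_unfolded_fixture(25, seed = s)),
    lapply(1:6, function(s) make_folded_fixture(24, "helix_loop_helix",
                                                seed = s)),
    list(make_folded_fixture(50, "helix_loop_helix", seed = 1))
  )
  for (m in cases) {
    got <- native_contacts(m)
    ref <- brute_force_contacts(m)
    expect_equal(got$i, ref$i)
    expect_equal(got$j, ref$j)
    expect_equal(got$r_ref, ref$r_ref, tolerance = 1e-12)
  }
})

test_that("short chains and unfolded chains have no native contacts", {
  m4 <- structure_model(matrix(c(0, 0, 0, 0.1, 0, 0, 0.2, 0, 0, 0.3, 0, 0),
                               4, 3, byrow = TRUE))
  expect_equal(nrow(native_contacts(m4)), 0)
  expect_equal(nrow(native_contacts(make_unfolded_fixture(20, seed = 1))), 0)
})

test_that("a lone close pair is detected at the cutoff", {
  # residues 1 and 5 placed 0.55 nm apart, everything else far away
  co <- cbind(seq(0, by = 2, length.out = 8), 0, 0)
  co[5, ] <- c(0.55, 0, 0)
  co[2, ] <- c(10, 5, 0); co[3, ] <- c(20, 5, 0); co[4, ] <- c(30, 5, 0)
  m <- structure_model(co)
  nc <- native_contacts(m)
  expect_equal(nrow(nc), 1)
  expect_equal(c(nc$i, nc$j), c(1L, 5L))
  expect_equal(nc$r_ref, 0.55, tolerance = 1e-12)
})

test_that("all nine neighbor combinations of a native contact are excluded", {
  # engineered structure: only native contact is (5, 10)
  co <- cbind(seq(0, by = 1.5, length.out = 14), 0, 0)
  co[10, ] <- co[5, ] + c(0.5, 0.2, 0)
  m <- structure_model(co)
  nc <- native_contacts(m)
  expect_equal(nrow(nc), 1)
  expect_equal(c(nc$i, nc$j), c(5L, 10L))
  cand <- nonnative_candidates(m)
  forbidden <- expand.grid(i = 4:6, j = 9:11)
  for (r in seq_len(nrow(forbidden))) {
    expect_false(any(cand$i == forbidden$i[r] & cand$j == forbidden$j[r]),
                 label = sprintf("pair (%d,%d) excluded",
                                 forbidden$i[r], forbidden$j[r]))
  }
  # pairs just outside the 3x3 neighborhood survive
  expect_true(any(cand$i == 3 & cand$j == 9))
  expect_true(any(cand$i == 7 & cand$j == 11))
})

test_that("with no native contacts every far pair is a candidate", {
  u <- make_unfolded_fixture(10, seed = 1)
  cand <- nonnative_candidates(u)
  # pairs with |i-j| >= 4 among 10 residues: 6+5+4+3+2+1 = 21
  expect_equal(nrow(cand), 21)
})

test_that("candidates are always disjoint from native contacts", {
  for (seed in 1:5) {
    m <- make_folded_fixture(22, "helix_loop_helix", seed = seed)
    nat <- native_contacts(m)
    cand <- nonnative_candidates(m)
    overlap <- merge(as.data.frame(nat[, 1:2]), as.data.frame(cand[, 1:2]))
    expect_equal(nrow(overlap), 0)
    expect_true(all(abs(cand$j - cand$i) >= 4))
  }
})

test_that("restraint selection honors Table-style TPR arithmetic", {
  ref <- make_folded_fixture(40, "helix_loop_helix", seed = 1)
  nat <- native_contacts(ref)
  non <- nonnative_candidates(ref)
  rs <- select_restraints(nat, non, n_total = 48, tpr = 0.75, seed = 1)
  expect_equal(sum(rs$label == "native"), 36)
  expect_equal(sum(rs$label == "non_native"), 12)
  rs2 <- select_restraints(nat, non, n_total = 12, tpr = 1, seed = 1)
  expect_equal(sum(rs2$label == "native"), 12)
  expect_equal(sum(rs2$label == "non_native"), 0)
  rs0 <- select_restraints(nat, non, n_total = 0, tpr = 0, seed = 1)
  expect_equal(nrow(rs0), 0)
})

test_that("selection is reproducible, seed-sensitive and duplicate-free", {
  ref <- make_folded_fixture(30, "helix_loop_helix", seed = 2)
  nat <- native_contacts(ref)
  non <- nonnative_candidates(ref)
  a <- select_restraints(nat, non, 20, 0.5, seed = 7)
  b <- select_restraints(nat, non, 20, 0.5, seed = 7)
  c <- select_restraints(nat, non, 20, 0.5, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  expect_equal(anyDuplicated(paste(a$i, a$j)), 0)
  expect_equal(attr(a, "seed"), 7L)
  # tpr = 1 restraints all satisfy the native definition on the reference
  all_nat <- select_restraints(nat, non, 15, 1, seed = 3)
  expect_true(all(all_nat$r_ref <= 0.6))
  # tpr = 0 restraints never do
  all_non <- select_restraints(nat, non, 15, 0, seed = 3)
  expect_true(all(all_non$r_ref > 0.6))
})

test_that("insufficient pools error with counts", {
  ref <- make_folded_fixture(20, "helix_loop_helix", seed = 1)
  nat <- native_contacts(ref)
  non <- nonnative_candidates(ref)
  expect_error(select_restraints(nat, non, 1000, 1, seed = 1),
               "only \\d+ available")
  expect_error(select_restraints(nat, non, 10, 1.5, seed = 1), "0, 1")
})

test_that("contact map is symmetric, band-masked and agrees with the list", {
  m <- make_folded_fixture(25, "helix_loop_helix", seed = 4)
  map <- contact_map(m)
  expect_true(isSymmetric(map))
  sep <- abs(outer(m$res_id, m$res_id, "-"))
  expect_false(any(map[sep < 4]))
  nat <- native_contacts(m)
  expect_equal(sum(map) / 2, nrow(nat))
  for (r in seq_len(nrow(nat))) {
    expect_true(map[as.character(nat$i[r]), as.character(nat$j[r])])
  }
  expect_false(any(contact_map(make_unfolded_fixture(20, seed = 1))))
})

test_that("scenario grid reproduces the benchmark bookkeeping", {
  g <- scenario_grid()
  expect_equal(nrow(g), 14)
  expect_equal(g$n_cp, c(0L, 6L, 12L, 24L, 36L, 48L,
                         12L, 24L, 36L, 48L, 12L, 24L, 36L, 48L))
  expect_equal(g$n_native, c(0L, 6L, 12L, 24L, 36L, 48L,
                             9L, 18L, 27L, 36L, 6L, 12L, 18L, 24L))
  expect_equal(g$n_native + g$n_nonnative, g$n_cp)
})

test_that("restraint files round trip with provenance", {
  ref <- make_folded_fixture(20, "helix_loop_helix", seed = 1)
  rs <- build_scenario(ref, tpr = 0.75, n_cp = 8, seed = 11)
  f <- tempfile(fileext = ".csv")
  write_restraints(rs, f)
  back <- read_restraints(f)
  expect_equal(back$i, rs$i)
  expect_equal(back$label, rs$label)
  expect_equal(back$r_ref, rs$r_ref, tolerance = 1e-6)
  expect_equal(attr(back, "seed"), 11L)
  expect_equal(attr(back, "tpr_nominal"), 0.75)
})
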