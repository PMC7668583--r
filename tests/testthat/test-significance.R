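test_that("percentiles are nearest-rank over observed scores", {
  scores <- tibble::tibble(scenario = "a",
                           value = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100))
  p <- gdt_percentiles(scores)
  expect_equal(p$value, c(80, 90, 90, 100, 100))
  # every reported percentile is an attained score
  expect_true(all(p$value %in% scores$value))
  # non-decreasing across 80 -> 100
  expect_true(all(diff(p$value) >= 0))
})

test_that("a scenario identical to the reference shades but never bolds", {
  vals <- seq(5, 100, by = 5)  # 20 frames; P95 (19th) stays below P100
  scores <- tibble::tibble(scenario = rep(c("ref", "same"), each = 20),
                           value = rep(vals, 2))
  tab <- percentile_table(scores, reference = "ref")
  same <- tab[tab$scenario == "same", ]
  expect_true(all(same$shaded))
  expect_false(any(same$bold[same$pct < 100]))
  # at the 100th percentile the headroom is zero, so equality is "bold"
  expect_true(same$bold[same$pct == 100])
  refrow <- tab[tab$scenario == "ref", ]
  expect_false(any(refrow$shaded) || any(refrow$bold))
})

test_that("w = 1 reduces the bold rule to beating the reference maximum", {
  scores <- tibble::tibble(
    scenario = rep(c("ref", "x"), each = 5),
    value = c(10, 20, 30, 40, 50, 49, 50, 51, 60, 70))
  tab <- percentile_table(scores, reference = "ref", w = 1)
  x <- tab[tab$scenario == "x", ]
  expect_equal(x$bold, x$value >= 50)
})

test_that("printed Trp-Cage percentile table reproduces every printed flag", {
  path <- system.file("extdata", "trp_cage_gdt_percentiles.csv",
                      package = "remdguide")
  long <- read_printed_percentiles(path, method = NULL)
  flagged <- flag_significance(long, reference = "ref", w = 0.5)
  expect_equal(nrow(flagged), 16 * 10)
  expect_identical(flagged$bold, flagged$printed_bold)
  # shading is >= the reference percentile, reference row exempt
  ref <- long[long$scenario == "ref", ]
  for (r in seq_len(nrow(flagged))) {
    row <- flagged[r, ]
    if (row$scenario == "ref") next
    rv <- ref$value[ref$score == row$score & ref$pct == row$pct]
    expect_identical(row$shaded, row$value >= rv)
  }
  # bold implies shaded everywhere
  expect_true(all(!flagged$bold | flagged$shaded))
})

test_that("printed VHP percentile table reproduces every printed flag", {
  path <- system.file("extdata", "vhp_gdt_percentiles.csv",
                      package = "remdguide")
  long <- read_printed_percentiles(path, method = NULL)
  flagged <- flag_significance(long, reference = "ref", w = 0.5)
  expect_equal(nrow(flagged), 16 * 10)
  expect_identical(flagged$bold, flagged$printed_bold)
  expect_true(all(!flagged$bold | flagged$shaded))
  # spot-check the threshold arithmetic on one cell:
  # TS80 threshold = 50.00 + 0.5 * (79.17 - 50.00) = 64.585
  cell <- flagged[flagged$scenario == "REMD_tpr100_cp6" &
                    flagged$score == "TS" & flagged$pct == 80, ]
  expect_equal(cell$threshold, 64.585)
  expect_true(cell$bold)
})

test_that("percentile tables export in wide benchmark layout", {
  scores <- tibble::tibble(
    scenario = rep(c("ref", "x"), each = 20),
    score = rep(rep(c("TS", "HA"), each = 10), 2),
    value = c(seq(30, 75, 5), seq(20, 65, 5), seq(60, 105, 5),
              seq(50, 95, 5)))
  tab <- percentile_table(scores, reference = "ref")
  f <- tempfile(fileext = ".csv")
  wide <- write_percentile_table(tab, f)
  expect_true(file.exists(f))
  expect_true(all(c("PTS80", "PHA100", "shaded_mask", "bold_mask") %in%
                    names(utils::read.csv(f))))
})

test_that("missing reference rows are an error", {
  scores <- tibble::tibble(scenario = "x", value = 1:10)
  expect_error(percentile_table(scores, reference = "ref"), "not present")
})

test_that("delta histograms conserve the count difference", {
  withr::with_seed(1, {
    a <- runif(200, 0, 8)
    b <- runif(200, 1, 9)
  })
  dh <- delta_histogram(a, b, bin_width = 0.2)
  expect_equal(sum(dh$delta_n), 0)
  expect_equal(sum(dh$n_scenario), 200)
  # identical series: all-zero histogram
  dh0 <- delta_histogram(a, a)
  expect_true(all(dh0$delta_n == 0))
  # disjoint supports: positive where the scenario lives, negative where
  # the reference lives
  lo <- runif(50, 0, 1); hi <- runif(50, 5, 6)
  dhd <- delta_histogram(hi, lo, bin_edges = seq(0, 6, 0.5))
  expect_true(all(dhd$delta_n[dhd$bin_hi <= 1] <= 0))
  expect_true(all(dhd$delta_n[dhd$bin_lo >= 5] >= 0))
  expect_equal(sum(dhd$delta_n), 0)
})

test_that("delta histograms conserve counts for arbitrary binnings", {
  withr::with_seed(7, {
    a <- rexp(150, 0.5)
    b <- rexp(150, 0.4)
  })
  top <- max(a, b) + 0.1
  for (bw in c(0.1, 0.25, 1)) {
    dh <- delta_histogram(a, b, bin_edges = seq(0, top + bw, bw))
    expect_equal(sum(dh$delta_n), 0)
    expect_equal(sum(dh$n_scenario) - sum(dh$n_reference), 0)
  }
})

test_that("unequal-length series error unless truncation is requested", {
  expect_error(delta_histogram(runif(10, 0, 1), runif(12, 0, 1)),
               "truncate")
  dh <- delta_histogram(seq(0.1, 0.9, 0.1), seq(0.1, 1.1, 0.1),
                        truncate = TRUE, bin_width = 0.5)
  expect_equal(sum(dh$delta_n), 0)
})

test_that("local accuracy ranks frames by HA and bins displacements", {
  target <- make_folded_fixture(12, "helix_loop_helix", seed = 1)
  good <- target
  medium <- structure_model(as.matrix(target[, 3:5]) +
                              matrix(c(rep(0, 18), rep(0.25, 18)), 12, 3),
                            res_id = target$res_id)
  set.seed(2)
  bad <- structure_model(matrix(rnorm(36, sd = 2), 12, 3),
                         res_id = target$res_id)
  traj <- remdguide:::trajectory_from_frames(list(bad, good, medium))
  la <- local_accuracy(traj, target, n_top = 2)
  expect_equal(unique(la$frame[la$rank == 1]), 2)  # identity ranks first
  expect_true(all(la$class[la$rank == 1] == 0))
  expect_equal(nrow(la), 2 * 12)
  # classes are monotone in displacement
  expect_true(all(diff(la$class[order(la$displacement)]) >= 0))
  # a 3 A displacement falls in class 2 with default edges {1,2,4,8}
  expect_equal(findInterval(3, c(1, 2, 4, 8)), 2)
  la_all <- local_accuracy(traj, target, n_top = 10)
  expect_equal(length(unique(la_all$rank)), 3)
  expect_error(local_accuracy(traj, target, class_edges = c(2, 1)),
               "increasing")
})

test_that("autoplot methods return ggplot objects", {
  p <- sigmoid_params()
  expect_s3_class(autoplot(tabulate_potential(p, r_max = 3, spacing = 0.05)),
                  "ggplot")
  target <- make_folded_fixture(10, "helix", seed = 1)
  traj <- remdguide:::trajectory_from_frames(list(target, target))
  hm <- rmsd_heatmap(list(rmsd_series(traj, target)))
  expect_s3_class(autoplot(hm), "ggplot")
  dh <- delta_histogram(runif(20, 0, 5), runif(20, 0, 5))
  expect_s3_class(autoplot(dh), "ggplot")
  la <- local_accuracy(traj, target, n_top = 2)
  expect_s3_class(autoplot(la), "ggplot")
  lad <- build_ladder(ladder_params(300, 0.02, 6))
  expect_s3_class(autoplot(lad), "ggplot")
})
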