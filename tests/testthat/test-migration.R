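test_that("straight and stationary tracks give the expected speeds", {
  tr <- data.frame(track_id = 1, t_min = seq(0, 60, 10),
                   x_um = seq(0, 15, 2.5), y_um = 0, z_um = 0)
  s <- compute_speeds(tr)
  expect_equal(s$intervals$speed, rep(15, 6))   # 2.5 um / 10 min = 15 um/h
  still <- data.frame(track_id = 2, t_min = seq(0, 60, 10),
                      x_um = 3, y_um = -1, z_um = 7)
  expect_equal(compute_speeds(still)$intervals$speed, rep(0, 6))
})

test_that("speeds use 3-D displacement and flag gapped intervals", {
  tr <- data.frame(track_id = 1, t_min = c(0, 10, 30),
                   x_um = c(0, 3, 3), y_um = c(0, 4, 4), z_um = c(0, 0, 12))
  s <- compute_speeds(tr)$intervals
  expect_equal(s$speed[1], 5 / 10 * 60)         # 3-4-5 triangle in 10 min
  expect_equal(s$speed[2], 12 / 20 * 60)        # over the actual 20-min gap
  expect_equal(s$gap, c(FALSE, TRUE))
  bad <- data.frame(track_id = 1, t_min = c(0, 0), x_um = 0, y_um = 0, z_um = 0)
  expect_error(compute_speeds(bad), "strictly increasing")
  lone <- data.frame(track_id = 1, t_min = 0, x_um = 0, y_um = 0, z_um = 0)
  expect_error(compute_speeds(lone), ">= 2")
})

test_that("speed computation is invariant under rigid translation", {
  set.seed(4)
  tr <- simulate_tracks(make_oxygen_field("uniform", value = 10),
                        walk_model(), n_cells = 30, seed = 14)
  shifted <- tr
  shifted$x_um <- shifted$x_um + 123.4
  shifted$y_um <- shifted$y_um - 77
  shifted$z_um <- shifted$z_um + 5
  expect_equal(compute_speeds(shifted)$intervals$speed,
               compute_speeds(tr)$intervals$speed, tolerance = 1e-12)
})

test_that("normalized window series starts at one", {
  tr <- simulate_tracks(make_oxygen_field("uniform", value = 21),
                        walk_model(), n_cells = 100, seed = 8)
  s <- compute_speeds(tr)
  expect_equal(s$normalized$relative[1], 1)
  expect_equal(s$normalized$mean_speed / s$normalized$mean_speed[1],
               s$normalized$relative)
})

test_that("subpopulation split behaves at the threshold boundaries", {
  slow_only <- data.frame(track_id = rep(1:5, each = 7),
                          t_min = rep(seq(0, 60, 10), 5),
                          x_um = as.vector(replicate(5, cumsum(c(0, rep(1, 6))))),
                          y_um = 0, z_um = 0)   # 6 um/h
  s <- compute_speeds(slow_only)
  sp <- split_subpopulations(s)
  expect_length(sp$fast, 0L)
  expect_length(sp$slow, 5L)
  expect_true(is.na(sp$modes[["fast"]]))
  # threshold 0: every track is fast
  sp0 <- split_subpopulations(s, threshold = 0)
  expect_length(sp0$slow, 0L)
})

test_that("bimodal mixture is split with high label agreement", {
  w <- walk_model(slow_median = 7, fast_median_normoxia = 25,
                  fast_fraction = 0.5)
  tr <- simulate_tracks(make_oxygen_field("uniform", value = 21), w,
                        n_cells = 200, seed = 17)
  s <- compute_speeds(tr)
  sp <- split_subpopulations(s, threshold = 15)
  # generator truth: fast flag is drawn per cell; recover it from the modes
  expect_false(is.na(sp$modes[["slow"]]))
  expect_false(is.na(sp$modes[["fast"]]))
  expect_lt(sp$modes[["slow"]], 15)
  expect_gt(sp$modes[["fast"]], 15)
  # split labels agree with the generator's ground-truth membership
  truth_fast <- attr(tr, "fast_tracks")
  agreement <- mean(sp$per_track$exceeds ==
                      (sp$per_track$track_id %in% truth_fast))
  expect_gt(agreement, 0.9)
})

test_that("region counts are conserved and respect the half-open boundaries", {
  tr <- data.frame(track_id = 1:6, t_min = 0,
                   x_um = c(-450, -150, 0, 150, 450, 500),
                   y_um = 0, z_um = 0)
  tr24 <- tr; tr24$t_min <- 1440
  rc <- region_increase(rbind(tr, tr24))
  expect_equal(unname(rc$counts$n_t0), c(1, 2, 2, 1))  # L, M, R, outside
  expect_equal(sum(rc$counts$n_t0), 6L)                # conservation
  expect_equal(unname(rc$increase), c(0, 0, 0, 0))
  expect_equal(rc$fold, 1)
})

test_that("uniform division probability is recovered in the whole-gel fold", {
  p24 <- 0.4
  w <- walk_model(division_oxygen = c(0, 21), division_prob = c(p24, p24))
  folds <- vapply(1:4, function(i) {
    tr <- simulate_tracks(make_oxygen_field("uniform", value = 10), w,
                          n_cells = 300, seed = 40 + i)
    region_increase(tr)$fold
  }, numeric(1))
  n_tot <- 4 * 300
  ci <- 1 + p24 + c(-1, 1) * 1.96 * sqrt(p24 * (1 - p24) / n_tot)
  expect_gte(mean(folds), ci[1])
  expect_lte(mean(folds), ci[2])
})

test_that("Kruskal-Wallis H matches a hand-ranked brute-force oracle", {
  # 3 groups x 5 observations, all values distinct so ranks are unambiguous
  g1 <- c(2.1, 3.4, 1.2, 5.6, 4.3)
  g2 <- c(7.8, 6.5, 9.1, 8.2, 10.4)
  g3 <- c(3.9, 2.8, 5.1, 4.7, 6.0)
  values <- c(g1, g2, g3)
  groups <- rep(c("a", "b", "c"), each = 5)
  # brute-force H from first principles: rank all N, sum rank per group
  N <- length(values)
  r <- rank(values)
  Rsum <- tapply(r, groups, sum)
  H_oracle <- 12 / (N * (N + 1)) * sum(Rsum^2 / 5) - 3 * (N + 1)
  cc <- compare_conditions(list(a = g1, b = g2, c = g3))
  expect_equal(unname(cc$kruskal$statistic), H_oracle, tolerance = 1e-12)
})

test_that("identical groups are not significant; shifted groups are", {
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(1, 2, 3, 4, 5))
  cc <- compare_conditions(same)
  expect_equal(cc$kruskal$p.value, 1, tolerance = 1e-9)
  expect_true(all(!cc$dunn$significant))
  set.seed(123)
  shifted <- list(lo = stats::rnorm(100, 0, 1), hi = stats::rnorm(100, 10, 1))
  cc2 <- compare_conditions(shifted)
  expect_lt(cc2$kruskal$p.value, 0.001)
})

test_that("Dunn decisions are symmetric in group order", {
  set.seed(9)
  v <- stats::rnorm(30)
  g <- rep(c("x", "y", "z"), 10)
  d1 <- dunn_test(v, g)
  d2 <- dunn_test(v, factor(g, levels = c("z", "y", "x")))
  key <- function(d) {
    pair <- paste(pmin(d$group1, d$group2), pmax(d$group1, d$group2))
    stats::setNames(d$p_adj, pair)[order(pair)]
  }
  expect_equal(key(d1), key(d2), tolerance = 1e-12)
  expect_equal(abs(d1$z[d1$group1 == "x" & d1$group2 == "y"]),
               abs(d2$z[(d2$group1 == "x" & d2$group2 == "y") |
                        (d2$group1 == "y" & d2$group2 == "x")]),
               tolerance = 1e-12)
})

test_that("small groups are dropped with a warning", {
  expect_warning(
    cc <- compare_conditions(list(a = 1:10, b = 11:20, tiny = c(1, 2))),
    "tiny")
  expect_false("tiny" %in% c(cc$dunn$group1, cc$dunn$group2))
  expect_error(
    suppressWarnings(compare_conditions(list(a = 1:10, tiny = 1:2))),
    ">= 2 conditions")
})

test_that("Welch t and two-way ANOVA components run on study-shaped inputs", {
  prolif <- list(H0 = c(1.7, 1.65, 1.8), N = c(1.4, 1.35, 1.45))
  series <- expand.grid(condition = c("H0", "N"), window = 1:6,
                        device = 1:3)
  set.seed(2)
  series$relative <- ifelse(series$condition == "H0",
                            1 + 0.02 * series$window,
                            1 - 0.02 * series$window) + stats::rnorm(nrow(series), 0, 0.01)
  cc <- compare_conditions(list(a = stats::rnorm(20), b = stats::rnorm(20)),
                           proliferation = prolif, series = series)
  expect_s3_class(cc$anova, "aov")
  expect_equal(nrow(cc$welch), 1L)
  expect_true(cc$welch$p < 0.05)   # folds clearly differ
  an <- summary(cc$anova)[[1]]
  expect_lt(an[["Pr(>F)"]][1], 0.05)   # condition main effect
})

test_that("track tables round-trip through delimited files", {
  tr <- simulate_tracks(make_oxygen_field("uniform", value = 5),
                        walk_model(), n_cells = 10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(back$x_um, tr$x_um, tolerance = 1e-9)
  expect_equal(back$track_id, tr$track_id)
})
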