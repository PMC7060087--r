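test_that("Peclet-to-flow conversions reproduce the published operating points", {
  # gas: Pe = 100 in a 1 mm channel is the 18 ml/min supply setting
  expect_equal(pe_to_flow(100, "gas", W = 1e-3, h = 150e-6)$Q_ml_min, 18,
               tolerance = 1e-12)
  expect_equal(pe_to_flow(10, "gas", W = 1e-3, h = 150e-6)$Q_ml_min, 1.8,
               tolerance = 1e-12)
  # medium: Pe = 100 in a 500 um channel is 1.8e-3 ml/min; Pe = 500 is 2 mm/s
  expect_equal(pe_to_flow(100, "medium", W = 500e-6, h = 150e-6)$Q_ml_min,
               1.8e-3, tolerance = 1e-12)
  expect_equal(pe_to_flow(500, "medium", W = 500e-6, h = 150e-6)$U, 2.0e-3,
               tolerance = 1e-12)
  z <- pe_to_flow(0, "medium", W = 500e-6, h = 150e-6)
  expect_equal(z$U, 0)
  expect_equal(z$Q_ml_min, 0)
  expect_error(pe_to_flow(100, "water", W = 1e-3, h = 1e-4))
  expect_error(pe_to_flow(-1, "gas", W = 1e-3, h = 1e-4))
})

test_that("boundary set validates tensions and warns on low gas Pe", {
  expect_error(boundary_set(gas_left = 25), "\\[0, 21\\]")
  expect_warning(
    boundary_set(0, 0, gas_flow = pe_to_flow(5, "gas", 1e-3, 150e-6)),
    "Pe < 10")
  expect_silent(boundary_set(0, 0, gas_flow = pe_to_flow(100, "gas", 1e-3, 150e-6)))
})

test_that("uniform boundary values give the constant solution", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(gas_left = 21, gas_right = 21, ambient = 21))
  expect_equal(max(abs(f$phi - 21)), 0, tolerance = 1e-9)
})

test_that("1-D composite column matches the series-resistance closed form", {
  g <- column_grid()
  bc <- boundary_set(gas_left = 0, gas_right = 0, ambient = 21,
                     floor = 0, sides = "noflux")
  f <- solve_steady(g, bc)
  zc <- g$zc
  expected <- column_analytic(zc, phi_bottom = 0, phi_top = 21)
  rel_err <- abs(f$phi[, 1] - expected) / 21
  expect_lt(max(rel_err), 0.005)
})

test_that("steady fields obey the discrete maximum principle", {
  g <- coarse_grid()
  cases <- list(boundary_set(0, 0), boundary_set(0, 21),
                boundary_set(5, 10, ambient = 21),
                boundary_set(21, 21, ambient = 0))
  for (bc in cases) {
    f <- solve_steady(g, bc)
    lo <- min(bc$gas_left, bc$gas_right, bc$ambient)
    hi <- max(bc$gas_left, bc$gas_right, bc$ambient)
    expect_gte(min(f$phi), lo - 1e-9)
    expect_lte(max(f$phi), hi + 1e-9)
  }
})

test_that("symmetric boundary conditions give an x-symmetric field", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(0, 0))
  expect_equal(f$phi, f$phi[, rev(seq_len(g$nx))], tolerance = 1e-8)
})

test_that("boundary fluxes balance at steady state", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(0, 0))
  bf <- boundary_flux(f)
  expect_lt(abs(bf["net"]), 1e-3 * max(abs(bf[c("gas_left", "gas_right",
                                               "ambient")])))
  # oxygen enters from the ambient surface and leaves through the channels
  expect_gt(bf[["ambient"]], 0)
  expect_lt(bf[["gas_left"]], 0)
})

test_that("a solve without any fixed-tension surface is rejected", {
  g <- column_grid()
  bc <- boundary_set(0, 0, ambient = NULL, sides = "noflux")  # fully insulated
  expect_error(solve_steady(g, bc), "singular")
})

test_that("concentration conversion applies the per-material solubility", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(21, 21, ambient = 21))
  cc <- concentration(f)
  m <- default_materials()
  # at uniform 21% O2: water-phase 0.218 * 0.21 mM, PDMS 1.25 * 0.21 mM
  expect_equal(cc[g$material == "gel"][1], 0.218 * 0.21, tolerance = 1e-9)
  expect_equal(cc[g$material == "PDMS"][1], 1.25 * 0.21, tolerance = 1e-9)
  # partial pressure is continuous but concentration jumps at interfaces
  expect_true(is.na(cc[g$material == "gas"][1]))
})

test_that("gel profile of a uniform field is flat with zero slope", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(21, 21, ambient = 21))
  p <- gel_gradient_profile(f)
  expect_equal(unname(p$endpoints), c(21, 21), tolerance = 1e-9)
  expect_equal(p$slope_per_mm, 0, tolerance = 1e-9)
})

test_that("fitted gel slope equals the endpoint difference over the width", {
  g <- coarse_grid()
  f <- solve_steady(g, boundary_set(0, 21))
  p <- gel_gradient_profile(f)
  span_mm <- 1.3
  expect_equal(p$slope_per_mm,
               (p$endpoints[["right"]] - p$endpoints[["left"]]) / span_mm,
               tolerance = 1e-9)
  expect_gt(p$endpoints[["right"]], p$endpoints[["left"]])
  # linearity of the profile itself: residuals small relative to the range
  expect_lt(max(abs(stats::resid(p$fit))), 0.05 * diff(range(p$profile$phi)))
})

test_that("transient solve starts at the initial field and relaxes monotonically", {
  g <- coarse_grid()
  bc <- boundary_set(0, 0)
  steady <- solve_steady(g, bc)
  tr <- solve_transient(g, bc, initial = 21, t_end = 600, dt = 10,
                        snapshot_times = c(0.0, 600))
  expect_equal(tr$trace$phi_center[1], 21)
  expect_true(all(diff(tr$trace$phi_center) <= 1e-9))
  expect_gte(min(tr$trace$phi_center), center_oxygen(steady) - 1e-6)
  # last snapshot: the channel region has settled (the far-field PDMS bulk
  # relaxes on a much longer time scale and is already near steady at 21)
  id <- which.min(abs(tr$grid$zc - 75e-6))
  ix <- which.min(abs(tr$grid$xc))
  expect_lt(abs(tr$snapshots[[length(tr$snapshots)]][id, ix] -
                  steady$phi[id, ix]), 0.5)
  expect_error(solve_transient(g, bc, 21, t_end = 600, dt = -1), "dt")
  expect_error(solve_transient(g, bc, 21, t_end = 1, dt = 10), "t_end")
})

test_that("equilibration time is robust to halving the time step", {
  g <- coarse_grid()
  bc <- boundary_set(0, 0)
  target <- center_oxygen(solve_steady(g, bc))
  t_a <- equilibration_time(solve_transient(g, bc, 21, t_end = 900, dt = 10),
                            target, tol = 0.5)
  t_b <- equilibration_time(solve_transient(g, bc, 21, t_end = 900, dt = 5),
                            target, tol = 0.5)
  expect_lt(abs(t_a - t_b) / t_b, 0.05)
})

test_that("center tension responds linearly to a uniform supply value", {
  g <- coarse_grid()
  cg <- c(0, 1, 3, 5, 10, 21)
  centers <- vapply(cg, function(v) {
    center_oxygen(solve_steady(g, boundary_set(v, v)))
  }, numeric(1))
  fit <- stats::lm(centers ~ cg)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
})

test_that("steady sweep rows agree with direct solves and errors annotate rows", {
  specs <- sweep_geometries(c(0.5e-3, 1.0e-3))
  tab <- sweep_steady(specs, list(H0 = boundary_set(0, 0)),
                      resolution = c(100e-6, 100e-6))
  expect_equal(nrow(tab), 2L)
  direct <- center_oxygen(solve_steady(coarse_grid(specs[[1]]),
                                       boundary_set(0, 0)))
  expect_equal(tab$center_phi[1], direct, tolerance = 1e-12)
  expect_true(all(is.na(tab$error)))
  expect_lt(tab$center_phi[1], tab$center_phi[2])   # higher channels leak more
})

test_that("channel axis model relaxes exponentially toward the wall value", {
  flow <- pe_to_flow(100, "medium", W = 500e-6, h = 150e-6)
  prof <- channel_axis_model(flow, wall_value = 0, inlet_value = 21,
                             length = 0.02, n = 4000)
  lambda <- attr(prof, "lambda")
  analytic <- 0 + (21 - 0) * exp(-prof$y / lambda)
  expect_lt(max(abs(prof$phi - analytic)), 0.05)
  # static fluid sits at the wall composition
  still <- channel_axis_model(pe_to_flow(0, "medium", 500e-6, 150e-6),
                              wall_value = 3, inlet_value = 21, length = 0.02)
  expect_true(all(still$phi == 3))
  # the faster the flow, the further the exit deviates from the wall value
  exits <- vapply(c(1, 10, 100, 500), function(pe) {
    p <- channel_axis_model(pe_to_flow(pe, "medium", 500e-6, 150e-6),
                            wall_value = 0, inlet_value = 21, length = 0.02)
    p$phi[nrow(p)]
  }, numeric(1))
  expect_true(all(diff(exits) > 0))
})
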