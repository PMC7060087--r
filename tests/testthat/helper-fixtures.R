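# shared fixtures, all built in code

# coarse device grid for fast unit tests (100 um cells)
coarse_grid <- function(spec = device_spec(), res = 100e-6) {
  build_cross_section(spec, resolution = c(res, res))
}

# one-dimensional vertical composite column: gel | PDMS | PC film,
# with Dirichlet floor/top and no-flux sides
column_grid <- function(dz = 25e-6) {
  ze <- sort(unique(c(seq(0, 150e-6, dz),
                      seq(150e-6, 1000e-6, dz),
                      seq(1000e-6, 1500e-6, dz))))
  zc <- (ze[-1] + ze[-length(ze)]) / 2
  mat <- matrix(ifelse(zc < 150e-6, "gel",
                       ifelse(zc < 1000e-6, "PDMS", "PC_film")), ncol = 1)
  material_grid(c(0, 1e-3), ze, mat)
}

# closed-form series-resistance solution of the column, evaluated at z
column_analytic <- function(z, phi_bottom = 0, phi_top = 21) {
  m <- default_materials()
  k <- stats::setNames(m$k, m$name)[c("gel", "PDMS", "PC_film")]
  thick <- c(150e-6, 850e-6, 500e-6)
  R <- thick / k
  J <- (phi_top - phi_bottom) / sum(R)
  bounds <- c(0, cumsum(thick))
  lay <- findInterval(z, bounds, rightmost.closed = TRUE)
  phi_if <- phi_bottom + c(0, J * cumsum(R))
  phi_if[lay] + J * (z - bounds[lay]) / k[lay]
}

# calibration points rendered through the forward camera model at the
# given supply oxygen levels (one stack per level, distinct seeds)
render_calibration_points <- function(levels = c(0, 2, 5, 10, 21),
                                      cam_args = list(), seed0 = 100) {
  do.call(rbind, lapply(seq_along(levels), function(i) {
    cam <- do.call(camera_model, c(cam_args, list(seed = seed0 + i)))
    st <- render_calibration_stack(
      make_oxygen_field("uniform", value = levels[i]), cam, times = 0)
    r <- reduce_roi(st$F, st$P, pixel_size_um = cam$pixel_size_um)
    data.frame(section = r$section,
               I_norm = normalize_intensity(r$I_P, r$I_F, r$I_F0),
               oxygen = levels[i])
  }))
}

# noiseless calibration points straight from the Stern-Volmer law
exact_points <- function(levels = c(0, 2, 5, 10, 21),
                         I_A = 1000, I_BG = 100, K_q = 3, section = 1) {
  data.frame(section = section, oxygen = levels,
             I_norm = sv_oxygen_to_intensity(levels, I_A, I_BG, K_q))
}
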