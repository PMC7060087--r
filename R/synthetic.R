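# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Analytic oxygen field over the gel imaging region
#'
#' Test-fixture oxygen profiles on the gel ROI coordinates (x in um,
#' centered on the gel channel): spatially `uniform`, `linear` between the
#' gel walls (the shape of a gradient condition), or a linear fit of a
#' transport-solver gel profile (`from_solver`).
#'
#' @param kind `"uniform"`, `"linear"` or `"from_solver"`.
#' @param value Uniform tension (%O2), for `kind = "uniform"`.
#' @param left,right Gel-wall tensions (%O2), for `kind = "linear"`.
#' @param field A steady `oxygen_field`, for `kind = "from_solver"`.
#' @param span Gel half-width (um) over which the linear profile is
#'   defined, default 650.
#' @return An object of class `oxygen_profile_model`: list with the
#'   parameters and `oxygen_at(x)`, a vectorized function of x (um).
#' @examples
#' f <- make_oxygen_field("linear", left = 3, right = 17)
#' f$oxygen_at(0)   # midpoint: 10
#' @export
make_oxygen_field <- function(kind = c("uniform", "linear", "from_solver"),
                              value = 21, left = NULL, right = NULL,
                              field = NULL, span = 650) {
  kind <- match.arg(kind)
  chk <- function(v) {
    if (any(v < 0 | v > 21)) stop("oxygen tensions must lie in [0, 21] %O2")
    v
  }
  fun <- switch(kind,
    uniform = {
      chk(value)
      local({ v <- value; function(x) rep(v, length(x)) })
    },
    linear = {
      stopifnot(!is.null(left), !is.null(right))
      chk(c(left, right))
      local({
        l <- left; r <- right; s <- span
        function(x) l + (r - l) * (x + s) / (2 * s)
      })
    },
    from_solver = {
      stopifnot(inherits(field, "oxygen_field"))
      prof <- gel_gradient_profile(field)
      cf <- stats::coef(prof$fit)
      local({
        a <- cf[[1]]; b <- cf[[2]]
        function(x) a + b * (x * 1e-6)   # solver x is in meters
      })
    }
  )
  structure(list(kind = kind, oxygen_at = fun, span = span,
                 value = value, left = left, right = right),
            class = "oxygen_profile_model")
}

#' Forward camera model for synthetic calibration stacks
#'
#' Describes how the imaging system turns a known oxygen field into paired
#' fluorescence/phosphorescence frames: per-section true Stern-Volmer
#' parameters, a multiplicative illumination drift `g(t)` shared by both
#' channels (with `g` at the first frame equal to 1, the drift-free
#' normalization anchor), additive Gaussian read noise, and a
#' signal-dependent (Poisson-like) component with standard deviation
#' `shot_gain * sqrt(signal)`.
#'
#' @param I_A,I_BG,K_q True Stern-Volmer parameters (recycled per section).
#' @param F0 Mean fluorescence baseline (drift-free).
#' @param drift Function of time returning the illumination factor;
#'   must satisfy `drift(t0) = 1` for the anchor frame.
#' @param read_sd Additive Gaussian noise sd (intensity units).
#' @param shot_gain Signal-dependent noise scale.
#' @param pixel_size_um Pixel pitch, default 1.3 um/px.
#' @param seed RNG seed for rendering.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(I_A = 1000, I_BG = 100, K_q = 3, F0 = 1000,
                         drift = function(t) rep(1, length(t)),
                         read_sd = 5, shot_gain = 1,
                         pixel_size_um = 1.3, seed = 1L) {
  stopifnot(all(I_A > I_BG), all(I_BG >= 0), all(K_q > 0), F0 > 0,
            read_sd >= 0, shot_gain >= 0)
  structure(list(I_A = I_A, I_BG = I_BG, K_q = K_q, F0 = F0, drift = drift,
                 read_sd = read_sd, shot_gain = shot_gain,
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "camera_model")
}

#' Render paired fluorescence/phosphorescence stacks from an oxygen field
#'
#' Forward model: noiseless fluorescence is `F0 * g(t)` per pixel;
#' noiseless phosphorescence follows the Stern-Volmer law at the local
#' oxygen tension, times the same drift. Both channels then receive
#' additive read noise and signal-dependent noise. Rendering is
#' deterministic for a fixed `cam$seed`.
#'
#' @param field An `oxygen_profile_model` from [make_oxygen_field()].
#' @param cam A [camera_model()].
#' @param times Frame times; the first frame is the drift anchor (g = 1).
#' @param nx,ny Frame size in pixels (default 1024 x 50, the published
#'   ROI).
#' @return List with arrays `F` and `P` (`ny x nx x nt`), `times` and the
#'   pixel x-coordinates `x_um` (device coordinates, ROI centered at 0).
#' @export
render_calibration_stack <- function(field, cam, times = 0,
                                     nx = 1024L, ny = 50L) {
  stopifnot(inherits(field, "oxygen_profile_model"),
            inherits(cam, "camera_model"))
  g <- cam$drift(times)
  if (abs(g[1] - 1) > 1e-12) {
    stop("drift must equal 1 at the first frame (normalization anchor)")
  }
  roi_um <- nx * cam$pixel_size_um
  x_um <- (seq_len(nx) - 0.5) * cam$pixel_size_um - roi_um / 2
  c_x <- field$oxygen_at(x_um)
  # map per-section parameters to pixels (100-um sections unless scalar)
  param_at <- function(p) {
    if (length(p) == 1L) return(rep(p, nx))
    sec <- pmin(length(p), pmax(1L, findInterval(x_um + roi_um / 2,
                                                 (seq_len(length(p)) - 1L) * 100) ))
    p[sec]
  }
  I_A <- param_at(cam$I_A); I_BG <- param_at(cam$I_BG); K_q <- param_at(cam$K_q)
  P0 <- sv_forward(c_x, I_A, I_BG, K_q)   # noiseless, drift-free
  nt <- length(times)
  with_seed(cam$seed, {
    Fs <- array(0, c(ny, nx, nt))
    Ps <- array(0, c(ny, nx, nt))
    for (f in seq_len(nt)) {
      muF <- matrix(cam$F0 * g[f], ny, nx)
      muP <- matrix(P0 * g[f], ny, nx, byrow = TRUE)
      noise <- function(mu) {
        mu + stats::rnorm(length(mu), 0, cam$read_sd) +
          stats::rnorm(length(mu), 0, cam$shot_gain * sqrt(pmax(mu, 0)))
      }
      Fs[, , f] <- noise(muF)
      Ps[, , f] <- noise(muP)
    }
    list(F = Fs, P = Ps, times = times, x_um = x_um)
  })
}

#' Oxygen-dependent random-walk model for synthetic cell tracks
#'
#' Encodes how the emulated cells respond to oxygen. Migration speed is a
#' two-component lognormal mixture: the slow mode is fixed across oxygen
#' (the observed slow subpopulation peak does not shift), while the fast
#' mode scales with a piecewise-linear response curve over the oxygen
#' tensions realized in the device (0.3, 1.3, 3.4, 5.3, 10.1, 21 %O2).
#' The default response has a local maximum at ~5 %O2, is elevated under
#' strong hypoxia relative to normoxia, and is flat between 10 and 21 %O2.
#' Division over 24 h is Bernoulli per cell with an oxygen-dependent
#' probability (defaults mirror 1.7/1.8-fold hypoxic and 1.4-fold
#' normoxic daily increases). After an oxygen switch the effective oxygen
#' driving the speed follows a first-order lag (default 4 h), emulating
#' the slow adaptation of migration speed.
#'
#' @param slow_median Median speed of the slow mode (um/h).
#' @param fast_median_normoxia Median speed of the fast mode at 21 %O2
#'   (um/h).
#' @param sdlog Lognormal shape of both modes.
#' @param fast_fraction Fraction of cells in the fast subpopulation.
#' @param response_oxygen,response_scale Control points of the fast-mode
#'   response curve (piecewise linear, constant beyond the end points).
#' @param division_oxygen,division_prob Control points of the per-24 h
#'   division probability curve.
#' @param persistence Directional persistence in \[0, 1) (0 = uncorrelated
#'   steps).
#' @param adaptation_h First-order lag of the speed response to oxygen
#'   changes (h).
#' @param frame_min Frame interval (min), default 10.
#' @return An object of class `walk_model`.
#' @export
walk_model <- function(slow_median = 7, fast_median_normoxia = 22,
                       sdlog = 0.35, fast_fraction = 0.4,
                       response_oxygen = c(0.3, 1.3, 3.4, 5.3, 10.1, 21),
                       response_scale = c(1.25, 1.30, 1.35, 1.45, 1.02, 1.00),
                       division_oxygen = c(0.3, 5.3, 21),
                       division_prob = c(0.7, 0.8, 0.4),
                       persistence = 0.6, adaptation_h = 4,
                       frame_min = 10) {
  stopifnot(slow_median > 0, fast_median_normoxia > 0, sdlog > 0,
            fast_fraction >= 0, fast_fraction <= 1,
            length(response_oxygen) == length(response_scale),
            length(division_oxygen) == length(division_prob),
            all(division_prob >= 0), all(division_prob <= 1),
            persistence >= 0, persistence < 1, adaptation_h >= 0,
            frame_min > 0)
  resp <- stats::approxfun(response_oxygen, response_scale, rule = 2)
  # ordering the observed biology imposes: peak near 5%, hypoxia above
  # normoxia, 10% ~ 21%
  if (!(resp(5) > resp(0.3) && resp(0.3) > resp(21) &&
        abs(resp(10) - resp(21)) < 0.1)) {
    stop("response curve must satisfy s(5) > s(0.3) > s(21) and s(10) ~ s(21)")
  }
  structure(list(slow_median = slow_median,
                 fast_median_normoxia = fast_median_normoxia,
                 sdlog = sdlog, fast_fraction = fast_fraction,
                 response = resp,
                 division = stats::approxfun(division_oxygen, division_prob,
                                             rule = 2),
                 persistence = persistence, adaptation_h = adaptation_h,
                 frame_min = frame_min),
            class = "walk_model")
}

#' Expected mean speed of the walk model at a given oxygen tension
#'
#' Closed-form mixture mean (lognormal mean = median * exp(sdlog^2/2)),
#' used as the generator ground truth in recovery tests.
#'
#' @param walk A `walk_model`.
#' @param oxygen Oxygen tension(s), %O2.
#' @return Mean per-step speed (um/h).
#' @export
expected_speed <- function(walk, oxygen) {
  lnmean <- function(med) med * exp(walk$sdlog^2 / 2)
  (1 - walk$fast_fraction) * lnmean(walk$slow_median) +
    walk$fast_fraction * lnmean(walk$fast_median_normoxia * walk$response(oxygen))
}

#' Number of cells matching the seeding density in the imaged gel volume
#'
#' The published seeding density is 2e5 cells/ml; the imaged gel region is
#' 1300 um wide x 150 um high x `y_span_um` long.
#'
#' @param y_span_um Imaged length of the gel channel (um), default 2000.
#' @param density_per_ml Seeding density, default 2e5.
#' @return Integer cell count.
#' @export
seeding_cell_count <- function(y_span_um = 2000, density_per_ml = 2e5) {
  vol_ml <- 1300e-4 * 150e-4 * y_span_um * 1e-4   # cm^3 = ml
  max(1L, round(density_per_ml * vol_ml))
}

#' Simulate oxygen-dependent persistent random-walk cell tracks
#'
#' Cells perform persistent random walks in the gel channel
#' (x in +/-650 um, z in 0-150 um, y in +/- `y_span_um`/2; reflected at
#' the walls), sampled at the frame interval. Each cell belongs to the
#' slow or fast subpopulation; per-step speeds are lognormal with the
#' fast-mode location scaled by the oxygen response at the cell's
#' (lag-filtered) local oxygen. Divisions terminate the parent track and
#' spawn two daughter tracks at the same position. With `schedule`, the
#' whole gel follows a time-varying uniform oxygen (e.g. an 8-h
#' intermittent-hypoxia alternation) instead of a spatial field.
#'
#' @param field An `oxygen_profile_model` (spatial oxygen), or `NULL` when
#'   `schedule` is given.
#' @param walk A [walk_model()].
#' @param n_cells Initial number of cells; default matches the published
#'   seeding density over the imaged volume.
#' @param duration_h Duration (h), default 24.
#' @param schedule Optional function of time (h) returning the uniform
#'   oxygen tension (%O2), e.g. [ih_schedule()].
#' @param condition Condition label stored with the tracks.
#' @param device_id Device label.
#' @param y_span_um Gel length represented (um).
#' @param seed RNG seed.
#' @return Data frame with columns `track_id`, `t_min`, `x_um`, `y_um`,
#'   `z_um`, `condition`, `device_id`. The attribute `fast_tracks` holds
#'   the generator's ground-truth fast-subpopulation track ids for
#'   recovery tests.
#' @export
simulate_tracks <- function(field = NULL, walk = walk_model(),
                            n_cells = seeding_cell_count(),
                            duration_h = 24, schedule = NULL,
                            condition = "synthetic", device_id = "sim1",
                            y_span_um = 2000, seed = 1L) {
  stopifnot(n_cells >= 1)
  if (is.null(field) && is.null(schedule)) {
    stop("provide a spatial oxygen field or a temporal schedule")
  }
  dt_min <- walk$frame_min
  nt <- floor(duration_h * 60 / dt_min)
  x_half <- 650; z_lo <- 0; z_hi <- 150; y_half <- y_span_um / 2

  with_seed(seed, {
    n <- n_cells
    x <- stats::runif(n, -x_half, x_half)
    y <- stats::runif(n, -y_half, y_half)
    z <- stats::runif(n, z_lo, z_hi)
    fast <- stats::runif(n) < walk$fast_fraction
    can_div <- rep(TRUE, n)   # each seeded cell divides at most once per run
    dir <- matrix(stats::rnorm(3 * n), n, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    id <- seq_len(n)
    next_id <- n + 1L
    oxy_at <- function(xp, t_h) {
      if (!is.null(schedule)) rep(schedule(t_h), length(xp))
      else field$oxygen_at(xp)
    }
    o_eff <- oxy_at(x, 0)
    alpha <- if (walk$adaptation_h > 0) {
      1 - exp(-(dt_min / 60) / walk$adaptation_h)
    } else 1
    step_div_p <- function(p24) 1 - (1 - p24)^(dt_min / 60 / 24)

    fast_by_id <- stats::setNames(fast, id)
    rows <- vector("list", nt + 1L)
    rows[[1]] <- data.frame(track_id = id, t_min = 0, x_um = x, y_um = y,
                            z_um = z)
    for (s in seq_len(nt)) {
      t_h <- s * dt_min / 60
      o_now <- oxy_at(x, t_h)
      o_eff <- o_eff + alpha * (o_now - o_eff)
      med <- ifelse(fast, walk$fast_median_normoxia * walk$response(o_eff),
                    walk$slow_median)
      speed <- stats::rlnorm(length(x), log(med), walk$sdlog)
      stepl <- speed * dt_min / 60
      rnd <- matrix(stats::rnorm(3 * length(x)), ncol = 3)
      rnd <- rnd / sqrt(rowSums(rnd^2))
      dir <- walk$persistence * dir + (1 - walk$persistence) * rnd
      dir <- dir / sqrt(rowSums(dir^2))
      x <- x + stepl * dir[, 1]
      y <- y + stepl * dir[, 2]
      z <- z + stepl * dir[, 3]
      # reflect at the gel walls
      refl <- function(v, lo, hi) {
        v <- ifelse(v < lo, 2 * lo - v, v)
        ifelse(v > hi, 2 * hi - v, v)
      }
      x <- refl(x, -x_half, x_half)
      y <- refl(y, -y_half, y_half)
      z <- refl(z, z_lo, z_hi)
      # divisions: parent track ends, two daughters start here
      p_div <- step_div_p(walk$division(o_eff)) * can_div
      divides <- stats::runif(length(x)) < p_div
      if (any(divides)) {
        di <- which(divides)
        n_new <- 2L * length(di)
        x <- c(x, rep(x[di], each = 2))
        y <- c(y, rep(y[di], each = 2))
        z <- c(z, rep(z[di], each = 2))
        fast <- c(fast, rep(fast[di], each = 2))
        can_div <- c(can_div, rep(FALSE, n_new))
        dir <- rbind(dir, dir[rep(di, each = 2), , drop = FALSE])
        o_eff <- c(o_eff, rep(o_eff[di], each = 2))
        new_ids <- next_id + seq_len(n_new) - 1L
        next_id <- next_id + n_new
        fast_by_id[as.character(new_ids)] <- rep(fast[di], each = 2)
        id <- c(id, new_ids)
        live <- setdiff(seq_along(x), di)
        x <- x[live]; y <- y[live]; z <- z[live]
        fast <- fast[live]; can_div <- can_div[live]
        dir <- dir[live, , drop = FALSE]
        o_eff <- o_eff[live]; id <- id[live]
      }
      rows[[s + 1L]] <- data.frame(track_id = id, t_min = s * dt_min,
                                   x_um = x, y_um = y, z_um = z)
    }
    out <- do.call(rbind, rows)
    out$condition <- condition
    out$device_id <- device_id
    out <- out[order(out$track_id, out$t_min), , drop = FALSE]
    rownames(out) <- NULL
    # generator ground truth: which tracks belong to the fast subpopulation
    attr(out, "fast_tracks") <- as.integer(names(fast_by_id))[fast_by_id]
    out
  })
}

#' Intermittent-hypoxia supply schedule
#'
#' Alternates between a normoxic and a hypoxic uniform oxygen tension at a
#' fixed interval, starting normoxic (the published IH protocol: 21% and
#' 0%-supply tensions switched every 8 h).
#'
#' @param normoxic Tension during normoxic phases (%O2), default 21.
#' @param hypoxic Tension during hypoxic phases (%O2), default 0.3 (the
#'   hypoxic floor the device reaches with a 0% supply).
#' @param interval_h Switching interval (h), default 8.
#' @return Function of time (h) returning the supplied tension.
#' @export
ih_schedule <- function(normoxic = 21, hypoxic = 0.3, interval_h = 8) {
  function(t_h) {
    phase <- floor(t_h / interval_h) %% 2
    ifelse(phase == 0, normoxic, hypoxic)
  }
}
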