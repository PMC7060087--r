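#' Ratiometric normalization of phosphorescence intensity
#'
#' The oxygen-sensitive nanoparticles emit oxygen-quenched red
#' phosphorescence and oxygen-insensitive blue fluorescence. Multiplicative
#' illumination drift affects both channels equally, so normalizing the
#' phosphorescence by the same-frame fluorescence and re-scaling by the
#' first-frame fluorescence cancels the drift:
#' \eqn{\bar I' = \bar I_P \times \bar I_{F0} / \bar I_F}.
#'
#' @param I_P Mean phosphorescence intensity (arbitrary units).
#' @param I_F Mean fluorescence intensity at the same time point; must be
#'   positive.
#' @param I_F0 Mean fluorescence at the experiment's first (drift-free)
#'   time point; must be positive.
#' @return Normalized phosphorescence, same shape as the inputs.
#' @examples
#' normalize_intensity(I_P = 250, I_F = 500, I_F0 = 1000)  # 2x dimming cancels
#' @export
normalize_intensity <- function(I_P, I_F, I_F0) {
  if (any(!is.finite(I_F)) || any(I_F <= 0)) {
    stop("I_F must be positive (fluorescence divides the phosphorescence)")
  }
  if (any(!is.finite(I_F0)) || any(I_F0 <= 0)) {
    stop("I_F0 must be positive")
  }
  I_P * I_F0 / I_F
}

# forward Stern-Volmer: normalized intensity at oxygen tension c (%O2)
sv_forward <- function(c, I_A, I_BG, K_q) {
  I_BG + (I_A - I_BG) / (1 + K_q * c / 100)
}

#' Fit per-section Stern-Volmer calibration models
#'
#' Each ROI section gets its own calibration: the anoxia intensity
#' \eqn{\bar I'_A} is pinned to the measured 0 %O2 point, while the
#' background \eqn{\bar I'_{BG}} and quenching constant \eqn{K_q} are
#' fitted by least squares on the nonlinear Stern-Volmer form
#' \eqn{\bar I'(c) = \bar I'_{BG} + (\bar I'_A - \bar I'_{BG}) /
#' (1 + K_q c / 100)}. A linearized Stern-Volmer fit supplies starting
#' values; the nonlinear fit avoids the variance distortion the linearized
#' plot suffers at low intensities.
#'
#' @param points Data frame with columns `section` (id), `I_norm`
#'   (normalized phosphorescence) and `oxygen` (known supply tension,
#'   %O2). At least 3 distinct oxygen levels per section; 0 and 21 should
#'   be among them (a warning is issued if not).
#' @return An object of class `calibration_model`: data frame with one row
#'   per section (`section`, `I_A`, `I_BG`, `K_q`, `rss`, `n_points`).
#' @examples
#' pts <- data.frame(section = 1,
#'                   oxygen = c(0, 5, 21),
#'                   I_norm = sv_oxygen_to_intensity(c(0, 5, 21), 1000, 100, 3))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points) {
  stopifnot(all(c("section", "I_norm", "oxygen") %in% names(points)))
  out <- lapply(split(points, points$section), function(df) {
    sec <- df$section[1]
    if (nrow(df) < 3L || length(unique(df$oxygen)) < 3L) {
      stop("section ", sec, ": need measurements at >= 3 distinct oxygen ",
           "levels to fit I_BG and K_q")
    }
    if (stats::sd(df$I_norm) == 0) {
      stop("section ", sec, ": degenerate points (identical intensities)")
    }
    if (!any(df$oxygen == 0) || !any(df$oxygen == 21)) {
      warning("section ", sec, ": calibration points should include both ",
              "0% and 21% O2")
    }
    I_A <- if (any(df$oxygen == 0)) {
      mean(df$I_norm[df$oxygen == 0])
    } else {
      warning("section ", sec, ": no anoxia (0% O2) point; pinning I_A to ",
              "the brightest measurement")
      max(df$I_norm)
    }
    # linearized initialization: (I_A - I_BG)/(I' - I_BG) = 1 + K_q c/100
    I_BG0 <- max(0, 0.5 * min(df$I_norm))
    ratio <- (I_A - I_BG0) / (df$I_norm - I_BG0) - 1
    pos <- df$oxygen > 0 & ratio > 0
    K_q0 <- if (any(pos)) {
      stats::coef(stats::lm(ratio[pos] ~ 0 + I(df$oxygen[pos] / 100)))[[1]]
    } else 1
    if (!is.finite(K_q0) || K_q0 <= 0) K_q0 <- 1
    fit <- minpack.lm::nlsLM(
      I_norm ~ I_BG + (I_A - I_BG) / (1 + K_q * oxygen / 100),
      data = df,
      start = list(I_BG = I_BG0, K_q = K_q0),
      lower = c(I_BG = 0, K_q = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    if (cf[["K_q"]] <= 0) {
      stop("section ", sec, ": fit yielded non-positive quenching constant")
    }
    if (cf[["I_BG"]] >= I_A) {
      stop("section ", sec, ": fitted background exceeds the anoxia intensity")
    }
    data.frame(section = sec, I_A = I_A, I_BG = cf[["I_BG"]],
               K_q = cf[["K_q"]], rss = sum(stats::resid(fit)^2),
               n_points = nrow(df))
  })
  structure(do.call(rbind, c(out, list(make.row.names = FALSE))),
            class = c("calibration_model", "data.frame"))
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Stern-Volmer calibration model (", nrow(x), " section(s))\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Forward Stern-Volmer model: oxygen tension to normalized intensity
#'
#' @param oxygen Oxygen tension (%O2).
#' @param I_A Normalized intensity under anoxia.
#' @param I_BG Background intensity, `0 <= I_BG < I_A`.
#' @param K_q Quenching constant (per unit %O2/100).
#' @return Normalized phosphorescence intensity.
#' @export
sv_oxygen_to_intensity <- function(oxygen, I_A, I_BG, K_q) {
  stopifnot(I_A > I_BG, I_BG >= 0, K_q > 0)
  sv_forward(oxygen, I_A, I_BG, K_q)
}

#' Invert normalized phosphorescence to oxygen tension
#'
#' Stern-Volmer inversion
#' \eqn{c = [(\bar I'_A - \bar I'_{BG}) / (\bar I' - \bar I'_{BG}) - 1] /
#' K_q \times 100}. Intensities above the anoxia level would give negative
#' oxygen; these are clamped to 0 and flagged `"clamped"`. Intensities at
#' or below the background are outside the invertible range and return
#' `NA` flagged `"undefined"` (not clamped).
#'
#' @param I_norm Normalized phosphorescence intensities.
#' @param model A `calibration_model` from [fit_calibration()].
#' @param section Section id(s), recycled against `I_norm`.
#' @return Data frame with columns `section`, `I_norm`, `oxygen` (%O2) and
#'   `status` (`"ok"`, `"clamped"`, `"undefined"`).
#' @export
intensity_to_oxygen <- function(I_norm, model, section = model$section[1]) {
  stopifnot(inherits(model, "calibration_model"))
  n <- max(length(I_norm), length(section))
  I_norm <- rep_len(I_norm, n)
  section <- rep_len(section, n)
  i <- match(section, model$section)
  if (anyNA(i)) stop("no fitted calibration for section(s): ",
                     paste(unique(section[is.na(i)]), collapse = ", "))
  I_A <- model$I_A[i]; I_BG <- model$I_BG[i]; K_q <- model$K_q[i]
  oxygen <- ((I_A - I_BG) / (I_norm - I_BG) - 1) / K_q * 100
  status <- rep("ok", n)
  undef <- I_norm <= I_BG
  clamped <- !undef & I_norm > I_A
  oxygen[undef] <- NA_real_
  oxygen[clamped] <- 0
  status[undef] <- "undefined"
  status[clamped] <- "clamped"
  data.frame(section = section, I_norm = I_norm, oxygen = oxygen,
             status = status)
}

#' Reduce a paired image stack to per-section mean intensities
#'
#' Splits the rectangular ROI (by default 1024 x 50 px = 1331 x 65 um at
#' 1.3 um/px) into fixed-width sections along x and space-averages each
#' channel per section and frame. A trailing section narrower than the
#' nominal width is dropped (1331 um yields 13 full 100-um sections).
#' Section centers are reported in device coordinates with the ROI
#' centered on the gel channel.
#'
#' @param stack_F,stack_P Fluorescence / phosphorescence stacks:
#'   `ny x nx x nt` arrays (or `ny x nx` matrices for a single frame) with
#'   x along columns.
#' @param times Time stamps, one per frame.
#' @param pixel_size_um Pixel pitch (um/px), default 1.3.
#' @param section_um Section width (um), default 100.
#' @param roi_center_um Device x-coordinate of the ROI center (um),
#'   default 0 (centered on the gel channel).
#' @return Data frame of [normalize_intensity()]-ready records: `t`,
#'   `section`, `section_x` (um), `I_F`, `I_P`, `I_F0`.
#' @export
reduce_roi <- function(stack_F, stack_P, times = NULL,
                       pixel_size_um = 1.3, section_um = 100,
                       roi_center_um = 0) {
  as_stack <- function(a) {
    if (is.matrix(a)) a <- array(a, c(nrow(a), ncol(a), 1L))
    stopifnot(length(dim(a)) == 3L)
    a
  }
  stack_F <- as_stack(stack_F); stack_P <- as_stack(stack_P)
  if (!identical(dim(stack_F), dim(stack_P))) {
    stop("fluorescence and phosphorescence stacks must have identical dimensions")
  }
  nx <- dim(stack_F)[2]; nt <- dim(stack_F)[3]
  if (is.null(times)) times <- seq_len(nt) - 1
  stopifnot(length(times) == nt)
  roi_um <- nx * pixel_size_um
  n_sec <- floor(roi_um / section_um)
  if (n_sec < 1L) stop("ROI narrower than one section")
  # pixel column range of section j: centers within [(j-1), j) * section_um
  px_x <- (seq_len(nx) - 0.5) * pixel_size_um
  sec_of_px <- findInterval(px_x, (0:n_sec) * section_um)
  keep <- sec_of_px >= 1L & sec_of_px <= n_sec
  sec_x <- (seq_len(n_sec) - 0.5) * section_um - roi_um / 2 + roi_center_um

  sec_f <- factor(sec_of_px[keep], levels = seq_len(n_sec))
  rows <- vector("list", nt)
  for (f in seq_len(nt)) {
    mF <- tapply(colMeans(stack_F[, keep, f, drop = FALSE][, , 1]),
                 sec_f, mean)
    mP <- tapply(colMeans(stack_P[, keep, f, drop = FALSE][, , 1]),
                 sec_f, mean)
    rows[[f]] <- data.frame(t = times[f], section = seq_len(n_sec),
                            section_x = sec_x,
                            I_F = as.numeric(mF), I_P = as.numeric(mP))
  }
  out <- do.call(rbind, rows)
  f0 <- out[out$t == min(out$t), c("section", "I_F")]
  out$I_F0 <- f0$I_F[match(out$section, f0$section)]
  out
}

#' Full oxygen-profile reconstruction from an image-stack reduction
#'
#' Convenience wrapper chaining [normalize_intensity()] and
#' [intensity_to_oxygen()] over a reduced ROI table.
#'
#' @param records Data frame from [reduce_roi()].
#' @param model A `calibration_model`.
#' @return The records with `I_norm`, `oxygen` and `status` columns added.
#' @export
oxygen_profile <- function(records, model) {
  records$I_norm <- normalize_intensity(records$I_P, records$I_F, records$I_F0)
  inv <- intensity_to_oxygen(records$I_norm, model, records$section)
  records$oxygen <- inv$oxygen
  records$status <- inv$status
  records
}
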