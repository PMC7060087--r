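#' Per-interval migration speeds and their aggregations
#'
#' Computes the 3-D Euclidean step distance between consecutive
#' observations of each track, converted to um/h. Aggregations follow how
#' time-lapse migration data are usually summarized: a cross-track mean at
#' every time point (all interval speeds ending at that frame, pooled
#' across tracks), a mean per 4-h window, and the window series normalized
#' by its first window (so the first element is 1). Intervals longer than
#' the nominal frame spacing (missing frames) are computed over the actual
#' gap and flagged.
#'
#' @param tracks Data frame with columns `track_id`, `t_min`, `x_um`,
#'   `y_um`, `z_um` (additional columns are ignored). Tracks need >= 2
#'   observations; single-observation tracks are dropped.
#' @param frame_min Nominal frame interval (min), default 10.
#' @param window_h Averaging window for the time series (h), default 4.
#' @return An object of class `speed_series`: list with `intervals`
#'   (`track_id`, `t_min` of the interval end, `dt_min`, `speed`,
#'   `gap` flag), `per_time` (`t_min`, `mean_speed`, `n`), `windows`
#'   (`window`, `t_mid_h`, `mean_speed`, `n`), `normalized` (`windows`
#'   with `relative` = mean/first), and `per_track` (`track_id`,
#'   `median_speed`, `mean_speed`, `n`).
#' @examples
#' tr <- data.frame(track_id = 1, t_min = c(0, 10, 20),
#'                  x_um = c(0, 2.5, 5), y_um = 0, z_um = 0)
#' compute_speeds(tr)$intervals$speed   # 15 um/h
#' @export
compute_speeds <- function(tracks, frame_min = 10, window_h = 4) {
  need <- c("track_id", "t_min", "x_um", "y_um", "z_um")
  stopifnot(all(need %in% names(tracks)))
  tracks <- tracks[order(tracks$track_id, tracks$t_min), need]
  spl <- split(tracks, tracks$track_id)
  ivl <- lapply(spl, function(df) {
    if (nrow(df) < 2L) return(NULL)
    if (any(diff(df$t_min) <= 0)) {
      stop("track ", df$track_id[1], ": timestamps must be strictly increasing")
    }
    dt <- diff(df$t_min)
    dist <- sqrt(diff(df$x_um)^2 + diff(df$y_um)^2 + diff(df$z_um)^2)
    data.frame(track_id = df$track_id[1], t_min = df$t_min[-1],
               dt_min = dt, speed = dist / dt * 60,
               gap = dt > frame_min + 1e-9)
  })
  intervals <- do.call(rbind, ivl)
  if (is.null(intervals) || nrow(intervals) == 0L) {
    stop("no track has >= 2 observations")
  }
  rownames(intervals) <- NULL

  agg <- function(x, by) {
    s <- stats::aggregate(x, by, FUN = mean)
    n <- stats::aggregate(x, by, FUN = length)
    s$n <- n$x
    s
  }
  per_time <- agg(list(x = intervals$speed), list(t_min = intervals$t_min))
  names(per_time)[2] <- "mean_speed"

  w_min <- window_h * 60
  intervals$window <- floor((intervals$t_min - 1e-9) / w_min) + 1L
  windows <- agg(list(x = intervals$speed), list(window = intervals$window))
  names(windows)[2] <- "mean_speed"
  windows$t_mid_h <- (windows$window - 0.5) * window_h
  normalized <- windows
  normalized$relative <- normalized$mean_speed / normalized$mean_speed[1]

  pt_med <- stats::aggregate(list(median_speed = intervals$speed),
                             list(track_id = intervals$track_id), stats::median)
  pt_mean <- stats::aggregate(list(mean_speed = intervals$speed),
                              list(track_id = intervals$track_id), mean)
  pt_n <- stats::aggregate(list(n = intervals$speed),
                           list(track_id = intervals$track_id), length)
  per_track <- merge(merge(pt_med, pt_mean), pt_n)

  structure(list(intervals = intervals, per_time = per_time,
                 windows = windows, normalized = normalized,
                 per_track = per_track, frame_min = frame_min,
                 window_h = window_h),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("speed_series: %d tracks, %d intervals, mean speed %.2f um/h\n",
              nrow(x$per_track), nrow(x$intervals), mean(x$intervals$speed)))
  invisible(x)
}

#' Split tracks into slow and fast migrating subpopulations
#'
#' Cells separate into a slow and a fast subpopulation when thresholded at
#' around 15 um/h (about twice the speed at which the frequency
#' distribution peaks). Each track is assigned by its median interval
#' speed, a summary robust to single-frame jumps, and each subpopulation's
#' histogram peak (mode) is reported.
#'
#' @param speeds A `speed_series` from [compute_speeds()].
#' @param threshold Split threshold (um/h), default 15. Tracks at or above
#'   it are "fast".
#' @param bin Histogram bin width for the mode estimate (um/h), default
#'   2.5.
#' @return List with `slow` and `fast` (track id vectors), `per_track`
#'   (with an `exceeds` logical), and `modes` (named numeric: histogram
#'   peak of each subpopulation's per-track median speeds; `NA` for an
#'   empty set).
#' @export
split_subpopulations <- function(speeds, threshold = 15, bin = 2.5) {
  stopifnot(inherits(speeds, "speed_series"), bin > 0)
  pt <- speeds$per_track
  pt$exceeds <- pt$median_speed >= threshold
  mode_of <- function(v) {
    if (length(v) == 0L) return(NA_real_)
    br <- seq(0, max(v) + bin, by = bin)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
  list(slow = pt$track_id[!pt$exceeds],
       fast = pt$track_id[pt$exceeds],
       per_track = pt,
       modes = c(slow = mode_of(pt$median_speed[!pt$exceeds]),
                 fast = mode_of(pt$median_speed[pt$exceeds])))
}

#' Regional cell-count increase across the gel channel
#'
#' Counts cells present at two time points in the three equal 300-um
#' regions spanning the gel readout window (-450 <= x <= 450 um):
#' L = \[-450, -150), M = \[-150, 150), R = \[150, 450\] (half-open with
#' the right edge closed). Cells outside the window are tallied in an
#' `outside` bucket so counts are conserved. Divisions are represented as
#' parent-track termination plus new daughter tracks, so the counts at
#' each time point are live-cell counts.
#'
#' @param tracks Track table (see [compute_speeds()]).
#' @param t0,t24 Time points (min), defaults 0 and 1440.
#' @return An object of class `region_counts`: list with `counts` (data
#'   frame: region x time with counts), `increase` (named L/M/R/outside),
#'   and `fold` (whole-gel N24/N0 over all cells present).
#' @export
region_increase <- function(tracks, t0 = 0, t24 = 1440) {
  stopifnot(all(c("track_id", "t_min", "x_um") %in% names(tracks)))
  classify <- function(x) {
    r <- rep("outside", length(x))
    r[x >= -450 & x < -150] <- "L"
    r[x >= -150 & x < 150] <- "M"
    r[x >= 150 & x <= 450] <- "R"
    factor(r, levels = c("L", "M", "R", "outside"))
  }
  at <- function(tp) {
    df <- tracks[abs(tracks$t_min - tp) < 1e-9, ]
    if (nrow(df) == 0L) stop("no observations at t = ", tp, " min")
    table(classify(df$x_um))
  }
  n0 <- at(t0); n24 <- at(t24)
  counts <- data.frame(region = names(n0),
                       n_t0 = as.integer(n0), n_t24 = as.integer(n24))
  structure(list(counts = counts,
                 increase = stats::setNames(counts$n_t24 - counts$n_t0,
                                            counts$region),
                 fold = sum(n24) / sum(n0),
                 t0 = t0, t24 = t24),
            class = "region_counts")
}

#' @export
print.region_counts <- function(x, ...) {
  cat("Regional cell counts (gel window -450..450 um):\n")
  print(x$counts)
  cat(sprintf("whole-gel fold change N(t24)/N(t0) = %.3f\n", x$fold))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons after a Kruskal-Wallis test
#'
#' Rank-based z statistics on the pooled ranks with the tie-corrected
#' variance: for groups i, j with mean ranks \eqn{\bar R_i, \bar R_j},
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{ \left( \frac{N(N+1)}{12} -
#' \frac{\sum (t^3 - t)}{12 (N - 1)} \right) (1/n_i + 1/n_j) }}
#' with two-sided normal p-values adjusted for multiplicity (Holm by
#' default; no particular adjustment is canonical, so it is configurable).
#'
#' @param values Numeric observations.
#' @param groups Group labels (same length).
#' @param method Multiplicity adjustment passed to [stats::p.adjust()].
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, method = "holm") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(sigma2 * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = method))
}

#' Omnibus and pairwise statistics for migration data across conditions
#'
#' The study's statistical battery: a Kruskal-Wallis test on migration
#' speeds across oxygen conditions followed by Dunn's pairwise post-hoc
#' comparisons; optionally Welch's t tests on proliferation folds between
#' condition pairs, and a two-way ANOVA (condition x time window) on
#' normalized 4-h speed series. Groups with fewer than 3 observations are
#' dropped with a warning. Significance threshold alpha = 0.05.
#'
#' @param speeds Named list of numeric speed vectors (one per condition;
#'   typically per-track median speeds), or a data frame with columns
#'   `condition` and `speed`.
#' @param proliferation Optional named list of per-device proliferation
#'   folds per condition; Welch's t is run on every pair.
#' @param series Optional data frame with columns `condition`, `window`
#'   and `relative` (normalized window speed, e.g. pooled from
#'   `compute_speeds()$normalized` across devices) for the two-way ANOVA.
#' @param dunn_method Multiplicity adjustment for Dunn's test.
#' @param alpha Significance threshold, default 0.05.
#' @return An object of class `condition_comparison`: list with `kruskal`
#'   (htest), `dunn` (data frame), `welch` (data frame or NULL), `anova`
#'   (summary or NULL), `alpha` and `dropped` (conditions removed for
#'   n < 3).
#' @export
compare_conditions <- function(speeds, proliferation = NULL, series = NULL,
                               dunn_method = "holm", alpha = 0.05) {
  if (is.data.frame(speeds)) {
    stopifnot(all(c("condition", "speed") %in% names(speeds)))
    speeds <- split(speeds$speed, speeds$condition)
  }
  stopifnot(is.list(speeds), length(speeds) >= 2, !is.null(names(speeds)))
  sizes <- vapply(speeds, length, integer(1))
  dropped <- names(speeds)[sizes < 3]
  if (length(dropped) > 0L) {
    warning("dropping condition(s) with < 3 observations: ",
            paste(dropped, collapse = ", "))
    speeds <- speeds[sizes >= 3]
  }
  if (length(speeds) < 2L) stop("need >= 2 conditions with >= 3 observations")
  values <- unlist(speeds, use.names = FALSE)
  groups <- factor(rep(names(speeds), vapply(speeds, length, integer(1))))
  kw <- stats::kruskal.test(values, groups)
  dn <- dunn_test(values, groups, method = dunn_method)
  dn$significant <- dn$p_adj < alpha

  welch <- NULL
  if (!is.null(proliferation)) {
    stopifnot(is.list(proliferation), !is.null(names(proliferation)))
    pr <- utils::combn(names(proliferation), 2)
    welch <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
      a <- proliferation[[pr[1, k]]]; b <- proliferation[[pr[2, k]]]
      tt <- stats::t.test(a, b, var.equal = FALSE)
      data.frame(group1 = pr[1, k], group2 = pr[2, k],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, significant = tt$p.value < alpha)
    }))
  }

  av <- NULL
  if (!is.null(series)) {
    stopifnot(all(c("condition", "window", "relative") %in% names(series)))
    series$condition <- factor(series$condition)
    series$window <- factor(series$window)
    av <- stats::aov(relative ~ condition * window, data = series)
  }

  structure(list(kruskal = kw, dunn = dn, welch = welch, anova = av,
                 alpha = alpha, dropped = dropped),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.3g\n",
              unname(x$kruskal$statistic), unname(x$kruskal$parameter),
              x$kruskal$p.value))
  cat("Dunn post-hoc (", attr(x$dunn, "method"), "):\n", sep = "")
  print(x$dunn)
  if (!is.null(x$welch)) { cat("Welch t (proliferation):\n"); print(x$welch) }
  if (!is.null(x$anova)) { cat("Two-way ANOVA (condition x window):\n")
    print(summary(x$anova)) }
  invisible(x)
}

#' Read / write cell-track tables
#'
#' Delimited track tables use the schema `track_id, t_min, x_um, y_um,
#' z_um, condition, device_id` (the same schema [simulate_tracks()]
#' emits).
#'
#' @param path File path (TSV or CSV by extension).
#' @param tracks Track data frame.
#' @return `read_tracks` returns the data frame; `write_tracks` returns
#'   `path` invisibly.
#' @export
read_tracks <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("track_id", "t_min", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) {
    stop("track table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_tracks
#' @export
write_tracks <- function(tracks, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(tracks, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
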