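#' Time-averaged mean square displacement of a trajectory
#'
#' For a uniformly sampled trajectory X_1..X_N the MSD at lag n is
#' `MSD(n) = sum_{i=1}^{N-n} (X_{i+n} - X_i)^2 / (N - n)` for
#' n = 1..N-1, the standard overlapping time average.
#'
#' @param traj A [Trajectory] (sampling interval must be uniform).
#' @param rtol Relative tolerance on sampling-interval uniformity.
#' @return Data frame of class `MSDCurve`: `lag_s`, `msd_um2`, `count`
#'   (number of displacement pairs per lag, strictly decreasing).
#' @export
compute_msd <- function(traj, rtol = 1e-6) {
  stopifnot(inherits(traj, "Trajectory"), nrow(traj) >= 2L)
  dt <- diff(traj$time_s)
  if (max(dt) - min(dt) > rtol * stats::median(dt))
    stop("compute_msd requires uniform sampling; resample or split the ",
         "trajectory at gaps")
  x <- traj$position_um
  N <- length(x)
  lags <- seq_len(N - 1L)
  msd <- vapply(lags, function(n)
    mean((x[(1L + n):N] - x[seq_len(N - n)])^2), numeric(1))
  out <- data.frame(lag_s = lags * stats::median(dt), msd_um2 = msd,
                    count = N - lags)
  class(out) <- c("MSDCurve", "data.frame")
  out
}

#' Split a trajectory into uniformly sampled segments
#'
#' Linked trajectories may contain gaps where lines were missed; the MSD
#' time average requires uniform sampling. This splits at every sampling
#' interval differing from the modal interval and returns the segments
#' (longest first), each a valid [Trajectory].
#'
#' @param traj A [Trajectory].
#' @param rtol Relative tolerance on interval uniformity.
#' @return List of [Trajectory] segments, longest first (segments shorter
#'   than 2 samples are dropped).
#' @export
split_uniform <- function(traj, rtol = 1e-6) {
  stopifnot(inherits(traj, "Trajectory"))
  dt <- diff(traj$time_s)
  dt0 <- sort(dt)[ceiling(length(dt) / 2)]
  brk <- which(abs(dt - dt0) > rtol * dt0)
  bounds <- c(0L, brk, nrow(traj))
  segs <- lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    if (length(idx) < 2L) return(NULL)
    s <- Trajectory(traj$time_s[idx], traj$position_um[idx],
                    id = attr(traj, "id"), channel = attr(traj, "channel"),
                    frame = traj$frame[idx])
    if (!is.null(traj$msd_eligible)) s$msd_eligible <- traj$msd_eligible[idx]
    s
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  segs[order(-vapply(segs, nrow, numeric(1)))]
}

#' Fit the MSD curve for a diffusion coefficient and anomaly exponent
#'
#' Ordinary least squares of MSD against lag time over the fitting window
#' (strict inequalities, default 0.25 s < tau < 2 s, chosen to exclude
#' stochastic scatter at long lags and confinement by the finite tether).
#' Two slope conventions are supported: `"paper"` reports the fitted slope
#' itself as D (the printed form `MSD = D t + b`), `"physical"` reports
#' slope/2 per the 1D law `MSD = 2 D tau`. The anomaly exponent alpha is
#' fit by log-log OLS on the same window, and the linear vs power-law
#' description is selected by r-squared.
#'
#' @param msd An `MSDCurve` from [compute_msd()].
#' @param window_s Length-2 fitting window (s), open interval.
#' @param convention `"paper"` or `"physical"`.
#' @param static_threshold,alpha_directed_margin Passed to
#'   [classify_motion()].
#' @return List of class `DiffusionFit`: `D_um2_s`, `intercept_b_um2`,
#'   `alpha`, `r_squared` (linear fit), `r_squared_alpha`, `fit_window_s`,
#'   `slope_convention`, `model` (`"linear"` or `"power"`), `motion_class`,
#'   `n_lags`.
#' @export
fit_msd <- function(msd, window_s = c(0.25, 2.0),
                    convention = c("paper", "physical"),
                    static_threshold = 0.01, alpha_directed_margin = 0.2) {
  stopifnot(inherits(msd, "MSDCurve"))
  convention <- match.arg(convention)
  sel <- msd$lag_s > window_s[1] & msd$lag_s < window_s[2]
  if (sum(sel) < 3L)
    stop(sprintf("only %d lag(s) inside the fitting window; need >= 3",
                 sum(sel)))
  tau <- msd$lag_s[sel]; y <- msd$msd_um2[sel]
  fit <- stats::lm(y ~ tau)
  slope <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  r2 <- if (stats::var(y) > 0)
    suppressWarnings(summary(fit)$r.squared) else 0
  pos <- y > 0
  if (sum(pos) >= 3L) {
    lfit <- stats::lm(log(y[pos]) ~ log(tau[pos]))
    alpha <- unname(stats::coef(lfit)[2])
    r2a <- if (stats::var(log(y[pos])) > 0)
      suppressWarnings(summary(lfit)$r.squared) else 0
  } else {
    alpha <- 0; r2a <- 0  # flat/zero MSD: immobile
  }
  D <- if (convention == "paper") slope else slope / 2
  out <- structure(list(D_um2_s = D, intercept_b_um2 = b, alpha = alpha,
                        r_squared = r2, r_squared_alpha = r2a,
                        fit_window_s = window_s,
                        slope_convention = convention,
                        model = if (r2a > r2) "power" else "linear",
                        n_lags = sum(sel)),
                   class = "DiffusionFit")
  out$motion_class <- classify_motion(out, static_threshold,
                                      alpha_directed_margin)
  out
}

#' @export
print.DiffusionFit <- function(x, ...) {
  cat(sprintf(
    "DiffusionFit: D = %.4g um^2/s (%s convention), b = %.3g um^2,\n",
    x$D_um2_s, x$slope_convention, x$intercept_b_um2))
  cat(sprintf("  alpha = %.3g, r^2 = %.3g, class = %s\n",
              x$alpha, x$r_squared, x$motion_class))
  invisible(x)
}

#' Classify motion from a diffusion fit
#'
#' Static if D is at or below the static threshold (0.01 um^2/s, the size
#' of the first histogram bin used to separate the static/slow population);
#' directed (super-diffusive) if alpha exceeds 1 by more than the margin;
#' free diffusion otherwise.
#'
#' @param fit A `DiffusionFit`.
#' @param static_threshold D cutoff (um^2/s).
#' @param alpha_directed_margin Margin above 1 for the directed call.
#' @return One of `"static"`, `"free"`, `"directed"`.
#' @export
classify_motion <- function(fit, static_threshold = 0.01,
                            alpha_directed_margin = 0.2) {
  stopifnot(inherits(fit, "DiffusionFit"))
  if (fit$D_um2_s <= static_threshold) "static"
  else if (fit$alpha > 1 + alpha_directed_margin) "directed"
  else "free"
}

#' Ensemble summary of per-molecule diffusion coefficients
#'
#' Mean, 95% confidence interval (t-based), a histogram at 0.01-um^2/s
#' bins, and the static fraction. With `exclude_static = TRUE`, fits with
#' D at or below the threshold are removed before summarizing (the
#' "corrected" D); individual fits are never modified.
#'
#' @param fits List of `DiffusionFit` objects.
#' @param exclude_static Remove the static/slow population first.
#' @param static_threshold D cutoff (um^2/s) for the static fraction and
#'   the exclusion.
#' @param bin_width Histogram bin width (um^2/s).
#' @return List: `n`, `mean_D`, `ci95`, `static_fraction`, `histogram`
#'   (data frame `bin_lo`, `bin_hi`, `count`), `excluded_static`.
#' @export
ensemble_D <- function(fits, exclude_static = FALSE,
                       static_threshold = 0.01, bin_width = 0.01) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "DiffusionFit")))
  D <- vapply(fits, function(f) f$D_um2_s, numeric(1))
  static_fraction <- mean(D <= static_threshold)
  used <- if (exclude_static) D[D > static_threshold] else D
  if (length(used) == 0L)
    stop("no fits remain after excluding the static fraction")
  m <- mean(used)
  ci <- if (length(used) > 1L && stats::sd(used) > 0)
    m + stats::qt(c(0.025, 0.975), length(used) - 1L) *
      stats::sd(used) / sqrt(length(used))
  else c(m, m)
  breaks <- seq(0, max(used, bin_width) + bin_width, by = bin_width)
  h <- graphics::hist(pmax(used, 0), breaks = breaks, plot = FALSE)
  list(n = length(used), mean_D = m, ci95 = ci,
       static_fraction = static_fraction,
       histogram = data.frame(bin_lo = utils::head(h$breaks, -1),
                              bin_hi = h$breaks[-1], count = h$counts),
       excluded_static = exclude_static)
}

#' Average speed of a trajectory
#'
#' The total route (sum of absolute frame-to-frame displacements) divided
#' by the total trajectory time. Apply Savitzky-Golay smoothing first
#' ([smooth_trajectory()]) to suppress tracking noise, which otherwise
#' inflates the route.
#'
#' @param traj A [Trajectory].
#' @param smoothed Apply the default Savitzky-Golay smoother first.
#' @param cfg [tracking_config()] used when `smoothed = TRUE`.
#' @return List of class `SpeedResult`: `mean_speed_um_s`,
#'   `total_route_um`, `total_time_s`.
#' @export
mean_speed <- function(traj, smoothed = FALSE, cfg = tracking_config()) {
  stopifnot(inherits(traj, "Trajectory"), nrow(traj) >= 2L)
  if (smoothed) traj <- smooth_trajectory(traj, cfg)
  route <- sum(abs(diff(traj$position_um)))
  total_t <- max(traj$time_s) - min(traj$time_s)
  structure(list(mean_speed_um_s = route / total_t, total_route_um = route,
                 total_time_s = total_t), class = "SpeedResult")
}

#' Linear regression of a quantity against an experimental condition
#'
#' Weighted least squares of per-condition means against the condition
#' value (e.g. diffusion coefficient vs NaCl concentration, or binding
#' frequency vs force), weights equal to the per-condition sample sizes.
#'
#' @param condition Numeric condition values, one per observation.
#' @param values Observed values (same length).
#' @return List: `slope`, `slope_se`, `intercept`, `r_squared` (0 when
#'   undefined), `n_conditions`, `means` (per-condition table).
#' @export
regress_condition <- function(condition, values) {
  stopifnot(length(condition) == length(values), length(condition) >= 2L)
  ok <- is.finite(condition) & is.finite(values)
  condition <- condition[ok]; values <- values[ok]
  if (length(unique(condition)) < 2L)
    stop("need at least 2 distinct condition values")
  agg <- stats::aggregate(values, by = list(condition = condition),
                          FUN = mean)
  n_per <- as.vector(table(factor(condition, levels = agg$condition)))
  fit <- stats::lm(agg$x ~ agg$condition, weights = n_per)
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(agg$x) > 0) sm$r.squared else 0
  list(slope = unname(stats::coef(fit)[2]),
       slope_se = sm$coefficients[2, 2],
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n_conditions = nrow(agg),
       means = data.frame(condition = agg$condition, mean = agg$x,
                          n = n_per))
}
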