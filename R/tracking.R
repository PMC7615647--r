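#' Tracking configuration
#'
#' Parameters of the kymograph particle tracker. Defaults reproduce the
#' experiment's procedure: a 3-line moving window for the 1D Gaussian
#' sub-pixel fit, a window-51 Savitzky-Golay smoother, and a 3-SD
#' detection threshold over a robust local background.
#'
#' @param window_frames Odd number of scan lines averaged before each
#'   Gaussian fit (1 = fit every line independently).
#' @param detect_threshold_sd Peak detection threshold in background SDs.
#' @param max_step_um Per-line linking gate (um); scaled by the gap length
#'   when lines are missed.
#' @param max_gap_frames Missed lines tolerated within one trajectory.
#' @param min_track_frames Minimum localizations per kept trajectory.
#' @param sg_window,sg_order Savitzky-Golay window (odd) and polynomial
#'   order.
#' @param overlap_radius_px Exclusion radius: frames where two trajectories
#'   approach within this many pixels are flagged ineligible for MSD.
#' @param fit_halfwidth_px Half-width of the column window used for each
#'   Gaussian fit.
#' @param sigma_bounds_px Admissible PSF-width range for accepted fits.
#' @param min_amplitude_sd Minimum fitted amplitude, in background SDs,
#'   for a localization to be accepted (suppresses fits to noise
#'   fluctuations that cleared the detection threshold).
#' @return List of class `TrackingConfig`.
#' @export
tracking_config <- function(window_frames = 3L, detect_threshold_sd = 3,
                            max_step_um = 0.5, max_gap_frames = 3L,
                            min_track_frames = 10L, sg_window = 51L,
                            sg_order = 3L, overlap_radius_px = 3,
                            fit_halfwidth_px = 5L,
                            sigma_bounds_px = c(0.7, 3),
                            min_amplitude_sd = 5) {
  if (window_frames %% 2L != 1L) stop("window_frames must be odd")
  if (sg_window %% 2L != 1L || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  structure(list(window_frames = as.integer(window_frames),
                 detect_threshold_sd = detect_threshold_sd,
                 max_step_um = max_step_um,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_track_frames = as.integer(min_track_frames),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 overlap_radius_px = overlap_radius_px,
                 fit_halfwidth_px = as.integer(fit_halfwidth_px),
                 sigma_bounds_px = sigma_bounds_px,
                 min_amplitude_sd = min_amplitude_sd),
            class = "TrackingConfig")
}

#' Crop saturated bead columns from a kymograph
#'
#' Removes the contiguous blocks of saturated columns (the bead contours)
#' at both image edges. A column counts as saturated when more than half of
#' its pixels, in any channel, reach the global `saturation_quantile`
#' intensity quantile. `origin_offset` is updated so physical coordinates
#' are preserved.
#'
#' @param kymo A [Kymograph].
#' @param saturation_quantile Quantile defining the saturation level
#'   (default 0.999).
#' @return The cropped [Kymograph].
#' @export
crop_beads <- function(kymo, saturation_quantile = 0.999) {
  stopifnot(inherits(kymo, "Kymograph"))
  thr <- stats::quantile(unlist(kymo$channels, use.names = FALSE),
                         saturation_quantile, names = FALSE)
  sat_col <- Reduce(`|`, lapply(kymo$channels, function(m)
    colMeans(m >= thr) > 0.5))
  w <- length(sat_col)
  left <- if (sat_col[1]) which.min(sat_col) - 1L else 0L
  if (all(sat_col)) stop("entire kymograph is saturated")
  right <- if (sat_col[w]) which.min(rev(sat_col)) - 1L else 0L
  if (left == 0L && right == 0L) return(kymo)
  keep <- (left + 1L):(w - right)
  Kymograph(lapply(kymo$channels, function(m) m[, keep, drop = FALSE]),
            pixel_size_nm = kymo$pixel_size_nm,
            line_time_s = kymo$line_time_s,
            origin_offset = kymo$origin_offset + left)
}

#' Sub-pixel localization on a kymograph channel
#'
#' For each scan line, the column profile averaged over the centred
#' `window_frames` lines is searched for local maxima exceeding the local
#' background plus `detect_threshold_sd` robust SDs; each candidate is fit
#' with a 1D Gaussian (amplitude, centre, width, offset) over a
#' `2 * fit_halfwidth_px + 1` column window. Fits with out-of-bounds width
#' or non-positive amplitude are discarded.
#'
#' Background is the median of the lowest intensity quartile of the
#' profile; noise is the MAD of the below-median values about that
#' background.
#'
#' @param kymo A (cropped) [Kymograph].
#' @param channel Channel name to localize in.
#' @param cfg A [tracking_config()].
#' @return Data frame of class `Localization`: `frame` (0-based),
#'   `position_px` (0-based sub-pixel column), `amplitude`, `sigma_px`,
#'   `background`, `channel`.
#' @export
localize <- function(kymo, channel = names(kymo$channels)[1],
                     cfg = tracking_config()) {
  stopifnot(inherits(kymo, "Kymograph"), channel %in% names(kymo$channels))
  img <- kymo$channels[[channel]]
  n <- nrow(img); w <- ncol(img)
  h <- (cfg$window_frames - 1L) %/% 2L
  out <- vector("list", n)
  for (t in seq_len(n)) {
    rows <- max(1L, t - h):min(n, t + h)
    p <- colMeans(img[rows, , drop = FALSE])
    q1 <- stats::quantile(p, 0.25, names = FALSE)
    bg <- stats::median(p[p <= q1])
    sig <- stats::mad(p)  # robust to the sparse emitter columns
    if (!is.finite(sig) || sig == 0) sig <- max(sqrt(max(bg, 1)), 1e-6)
    thr <- bg + cfg$detect_threshold_sd * sig
    dd <- diff(sign(diff(p)))
    peaks <- which(dd < 0) + 1L
    peaks <- peaks[p[peaks] > thr]
    if (length(peaks) == 0L) next
    fits <- lapply(peaks, function(pk)
      fit_gaussian_1d(p, pk, cfg$fit_halfwidth_px, bg, cfg$sigma_bounds_px))
    fits <- fits[!vapply(fits, is.null, logical(1))]
    # the fitted amplitude must clear a slightly stricter bar than the
    # detection threshold, or the fit was chasing a noise fluctuation
    fits <- fits[vapply(fits, function(d)
      d$amplitude >= cfg$min_amplitude_sd * sig, logical(1))]
    if (length(fits) == 0L) next
    df <- do.call(rbind, fits)
    # collapse duplicate detections converging onto one emitter: centres
    # closer than ~1.5 PSF widths are unresolvable; keep the brighter fit
    df <- df[order(df$position_px), , drop = FALSE]
    if (nrow(df) > 1L) {
      cl <- cumsum(c(TRUE, diff(df$position_px) > 2))
      df <- do.call(rbind, lapply(split(df, cl), function(g)
        g[which.max(g$amplitude), , drop = FALSE]))
    }
    df$frame <- t - 1L
    df$background <- bg
    out[[t]] <- df
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(amplitude = numeric(), position_px = numeric(),
                         sigma_px = numeric(), offset = numeric(),
                         frame = integer(), background = numeric())
  res$channel <- if (nrow(res)) channel else character(0)
  res <- res[order(res$frame, res$position_px),
             c("frame", "position_px", "amplitude", "sigma_px",
               "background", "channel")]
  rownames(res) <- NULL
  class(res) <- c("Localization", "data.frame")
  res
}

# Least-squares 1D Gaussian + offset fit around a peak column (1-based
# index `pk`) of profile `p`. Returns NULL for rejected fits. Positions are
# reported in 0-based column coordinates.
fit_gaussian_1d <- function(p, pk, halfwidth, bg, sigma_bounds) {
  idx <- max(1L, pk - halfwidth):min(length(p), pk + halfwidth)
  if (length(idx) < 5L) return(NULL)
  x <- idx - 1
  y <- p[idx]
  a0 <- max(p[pk] - bg, 1e-6)
  w <- pmax(y - bg, 0)
  mu0 <- if (sum(w) > 0) sum(w * x) / sum(w) else pk - 1
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c0,
               start = list(A = a0, mu = mu0, s = 1.2, c0 = bg),
               algorithm = "port",
               lower = c(A = 0, mu = min(x), s = sigma_bounds[1] / 2,
                         c0 = -Inf),
               upper = c(A = Inf, mu = max(x), s = sigma_bounds[2] * 2,
                         c0 = Inf),
               control = stats::nls.control(maxiter = 100,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (cf["A"] <= 0 || cf["s"] < sigma_bounds[1] || cf["s"] > sigma_bounds[2])
    return(NULL)
  if (cf["mu"] <= min(x) || cf["mu"] >= max(x)) return(NULL)
  data.frame(amplitude = unname(cf["A"]), position_px = unname(cf["mu"]),
             sigma_px = unname(cf["s"]), offset = unname(cf["c0"]))
}

#' Link localizations into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking with gate
#' `max_step_um * gap` (gap = number of lines since the trajectory was last
#' seen, at most `max_gap_frames + 1`). Ties are broken by smaller column
#' index. Tracks shorter than `min_track_frames` are dropped. Frames where
#' two trajectories approach within `overlap_radius_px` are flagged
#' `msd_eligible = FALSE` so overlapping segments can be excluded from MSD
#' analysis.
#'
#' @param locs A `Localization` data frame (sorted by frame).
#' @param cfg A [tracking_config()].
#' @param pixel_size_nm,line_time_s Imaging geometry used to convert to
#'   physical units.
#' @param origin_offset Column origin offset of the (cropped) kymograph.
#' @return List of [Trajectory] objects (columns `frame`, `time_s`,
#'   `position_um`, `msd_eligible`).
#' @export
link <- function(locs, cfg = tracking_config(), pixel_size_nm = 100,
                 line_time_s = 0.25, origin_offset = 0) {
  if (nrow(locs) == 0L) return(list())
  if (is.unsorted(locs$frame)) stop("localizations must be sorted by frame")
  px_um <- pixel_size_nm / 1000
  tracks <- list()   # each: list(rows = integer indices into locs, open)
  open <- integer(0) # indices into `tracks`
  frames <- sort(unique(locs$frame))
  for (f in frames) {
    cand <- which(locs$frame == f)
    # retire tracks with too large a gap
    if (length(open)) {
      last <- vapply(open, function(i) locs$frame[tail(tracks[[i]]$rows, 1)],
                     numeric(1))
      open <- open[f - last <= cfg$max_gap_frames + 1L]
    }
    assigned_loc <- rep(FALSE, length(cand))
    if (length(open) && length(cand)) {
      last_rows <- vapply(open, function(i) tail(tracks[[i]]$rows, 1),
                          numeric(1))
      lp <- locs$position_px[last_rows]
      lf <- locs$frame[last_rows]
      pairs <- expand.grid(ti = seq_along(open), ci = seq_along(cand))
      pairs$gap <- f - lf[pairs$ti]
      pairs$d_px <- abs(locs$position_px[cand[pairs$ci]] - lp[pairs$ti])
      gate_px <- cfg$max_step_um / px_um * pairs$gap
      pairs <- pairs[pairs$d_px <= gate_px, , drop = FALSE]
      # deterministic greedy: smallest distance first, ties by column index
      pairs <- pairs[order(pairs$d_px, locs$position_px[cand[pairs$ci]]), ,
                     drop = FALSE]
      used_t <- rep(FALSE, length(open))
      for (k in seq_len(nrow(pairs))) {
        ti <- pairs$ti[k]; ci <- pairs$ci[k]
        if (used_t[ti] || assigned_loc[ci]) next
        used_t[ti] <- TRUE; assigned_loc[ci] <- TRUE
        ii <- open[ti]
        tracks[[ii]]$rows <- c(tracks[[ii]]$rows, cand[ci])
      }
    }
    for (ci in which(!assigned_loc)) {
      tracks[[length(tracks) + 1L]] <- list(rows = cand[ci])
      open <- c(open, length(tracks))
    }
  }
  keep <- vapply(tracks, function(t) length(t$rows) >= cfg$min_track_frames,
                 logical(1))
  tracks <- tracks[keep]
  trajs <- lapply(seq_along(tracks), function(i) {
    r <- tracks[[i]]$rows
    pos_um <- (locs$position_px[r] + 0.5 + origin_offset) * px_um
    tr <- Trajectory(locs$frame[r] * line_time_s, pos_um, id = i,
                     channel = locs$channel[r[1]], frame = locs$frame[r])
    tr$msd_eligible <- TRUE
    tr
  })
  flag_overlaps(trajs, cfg$overlap_radius_px * px_um)
}

# Flag frames where two trajectories approach within `radius_um`.
flag_overlaps <- function(trajs, radius_um) {
  if (length(trajs) < 2L) return(trajs)
  for (a in seq_len(length(trajs) - 1L)) for (b in (a + 1L):length(trajs)) {
    common <- intersect(trajs[[a]]$frame, trajs[[b]]$frame)
    if (length(common) == 0L) next
    ia <- match(common, trajs[[a]]$frame)
    ib <- match(common, trajs[[b]]$frame)
    close <- abs(trajs[[a]]$position_um[ia] -
                 trajs[[b]]$position_um[ib]) < radius_um
    trajs[[a]]$msd_eligible[ia[close]] <- FALSE
    trajs[[b]]$msd_eligible[ib[close]] <- FALSE
  }
  trajs
}

#' Savitzky-Golay smoothing of a trajectory
#'
#' Replaces positions by their Savitzky-Golay filtered values (window
#' `sg_window`, order `sg_order`); times are unchanged. Trajectories not
#' longer than the window are returned unsmoothed with attribute
#' `smoothed = FALSE`. Edge samples are taken from the polynomial fitted
#' to the first/last full window.
#'
#' @param traj A [Trajectory].
#' @param cfg A [tracking_config()] (uses `sg_window`, `sg_order`).
#' @return The smoothed [Trajectory] with attribute `smoothed`.
#' @export
smooth_trajectory <- function(traj, cfg = tracking_config()) {
  stopifnot(inherits(traj, "Trajectory"))
  if (nrow(traj) <= cfg$sg_window) {
    attr(traj, "smoothed") <- FALSE
    return(traj)
  }
  traj$position_um <- savitzky_golay(traj$position_um, cfg$sg_window,
                                     cfg$sg_order)
  attr(traj, "smoothed") <- TRUE
  traj
}

#' Savitzky-Golay filter
#'
#' Local least-squares polynomial smoothing. Polynomials of degree at most
#' `order` pass through unchanged (up to numerical tolerance).
#'
#' @param y Numeric vector, length > `window`.
#' @param window Odd window length.
#' @param order Polynomial order (< window).
#' @return Smoothed numeric vector, same length.
#' @export
savitzky_golay <- function(y, window = 51L, order = 3L) {
  n <- length(y)
  if (window %% 2L != 1L || window <= order)
    stop("window must be odd and greater than order")
  if (n <= window) stop("series must be longer than the window")
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:order, `^`)
  H <- A %*% solve(crossprod(A), t(A))  # projection onto local polynomials
  out <- stats::filter(y, H[m + 1L, ], sides = 2)
  out <- as.numeric(out)
  out[1:m] <- (H %*% y[1:window])[1:m]
  out[(n - m + 1L):n] <- (H %*% y[(n - window + 1L):n])[(m + 2L):window]
  out
}
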