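# Synthetic-data generators. Every simulator takes an explicit seed, is
# bit-reproducible, and returns its ground truth alongside the data so that
# downstream recovery tests consume only the data.

#' Photon budget for a target signal-to-noise ratio
#'
#' The study does not state emitter photon budgets, so the generator's
#' brightness is parameterized by SNR: the pixel-integrated peak amplitude
#' of the PSF over the Poisson background noise SD. This returns the
#' photons per scan line giving the requested SNR.
#'
#' @param snr Target peak amplitude / background noise SD.
#' @param background_counts Mean background photons per pixel.
#' @param psf_sigma_px PSF standard deviation (pixels).
#' @return Photons per line (numeric).
#' @export
photons_for_snr <- function(snr, background_counts = 10,
                            psf_sigma_px = 1.3) {
  peak_frac <- 2 * stats::pnorm(0.5 / psf_sigma_px) - 1
  snr * sqrt(background_counts) / peak_frac
}

#' Emitter model for trajectory simulation
#'
#' @param kind `"static"`, `"diffusive"` or `"directed"`.
#' @param D_um2_s Diffusion coefficient (um^2/s) for diffusive emitters;
#'   the study's sliding complexes fall in ~0.01-0.1, mean 0.040.
#' @param velocity_um_s Drift velocity for directed emitters (um/s).
#' @param start_position_um Initial position along the tether (um).
#' @param bind_time_s Time of first appearance (s).
#' @param dwell_mean_s Mean of the exponential dwell before dissociation
#'   (s); `Inf` disables dissociation.
#' @param photons_per_line Expected photons emitted per scan line; the
#'   default gives SNR ~ 5 at the default background of 10 counts
#'   ([photons_for_snr()]), a free parameter of the generator since the
#'   study states no photon budget.
#' @param bleach_mean_lines Expected number of lines before photobleaching;
#'   `Inf` disables bleaching.
#' @return List of class `EmitterModel`.
#' @export
emitter_model <- function(kind = c("static", "diffusive", "directed"),
                          D_um2_s = 0.04, velocity_um_s = 0.1,
                          start_position_um = 1, bind_time_s = 0,
                          dwell_mean_s = Inf,
                          photons_per_line = photons_for_snr(5),
                          bleach_mean_lines = Inf) {
  kind <- match.arg(kind)
  stopifnot(D_um2_s >= 0, dwell_mean_s > 0, photons_per_line > 0,
            bleach_mean_lines > 0)
  structure(list(kind = kind, D_um2_s = D_um2_s,
                 velocity_um_s = velocity_um_s,
                 start_position_um = start_position_um,
                 bind_time_s = bind_time_s, dwell_mean_s = dwell_mean_s,
                 photons_per_line = photons_per_line,
                 bleach_mean_lines = bleach_mean_lines),
            class = "EmitterModel")
}

#' Tether model: a lambda-DNA-like substrate with an optional ssDNA gap
#'
#' Defaults describe the study's substrate: a 48,502-bp lambda dsDNA tether
#' carrying a 5,374-nt internal ssDNA gap. Positions in micrometres are
#' mapped from nucleotides at the dsDNA rise (0.34 nm/bp), a linear
#' approximation adequate for stretched tethers.
#'
#' @param total_bp Tether length in base pairs.
#' @param gap_start_nt,gap_end_nt Half-open 0-based gap interval along the
#'   tether (nt); `NULL` for an ungapped tether.
#' @param obstacle_positions_um Positions of reflecting point obstacles
#'   (nucleosomes), um.
#' @param bypass_prob Probability that a diffusing emitter crosses an
#'   obstacle on contact (default 0: perfectly reflecting, matching the
#'   observed >90% blocking).
#' @param bead_margin_px Saturated columns rendered at each image edge.
#' @param rise_per_bp nm per base pair (0.34).
#' @return List of class `TetherModel` with derived `length_um` and
#'   `gap_span_um`.
#' @export
tether_model <- function(total_bp = 48502, gap_start_nt = 33786,
                         gap_end_nt = 39160, obstacle_positions_um = numeric(),
                         bypass_prob = 0, bead_margin_px = 5,
                         rise_per_bp = 0.34) {
  stopifnot(total_bp > 0, bypass_prob >= 0, bypass_prob <= 1)
  if (!is.null(gap_start_nt)) {
    stopifnot(gap_start_nt >= 0, gap_start_nt < gap_end_nt,
              gap_end_nt <= total_bp)
  }
  nt2um <- rise_per_bp / 1000
  structure(list(total_bp = total_bp, gap_start_nt = gap_start_nt,
                 gap_end_nt = gap_end_nt,
                 obstacle_positions_um = sort(obstacle_positions_um),
                 bypass_prob = bypass_prob, bead_margin_px = bead_margin_px,
                 rise_per_bp = rise_per_bp,
                 length_um = total_bp * nt2um,
                 gap_span_um = if (is.null(gap_start_nt)) NULL
                               else c(gap_start_nt, gap_end_nt) * nt2um),
            class = "TetherModel")
}

#' Simulate one emitter trajectory
#'
#' Static emitters stay put; diffusive emitters take Gaussian increments
#' with variance `2 * D * line_time` per line, reflecting at the tether
#' ends and at obstacles (crossed with probability `tether$bypass_prob`);
#' directed emitters drift at constant velocity. The trajectory is
#' truncated at the smaller of the dwell and photobleaching draws.
#'
#' @param model An [emitter_model()].
#' @param tether A [tether_model()].
#' @param n_lines Number of scan lines available (>= 2).
#' @param line_time_s Seconds per line.
#' @param seed Integer seed (required for reproducibility).
#' @return A [Trajectory] with attribute `truth` (the generating model and
#'   realized dwell/bleach times).
#' @export
simulate_trajectory <- function(model, tether, n_lines, line_time_s = 0.25,
                                seed = NULL) {
  stopifnot(inherits(model, "EmitterModel"), inherits(tether, "TetherModel"),
            n_lines >= 2)
  x0 <- model$start_position_um
  if (x0 < 0 || x0 > tether$length_um)
    stop("start position outside tether")
  local_seed(seed, {
    dwell_s <- if (is.finite(model$dwell_mean_s))
      stats::rexp(1, 1 / model$dwell_mean_s) else Inf
    bleach_lines <- if (is.finite(model$bleach_mean_lines))
      stats::rexp(1, 1 / model$bleach_mean_lines) else Inf
    n_eff <- min(n_lines, max(2, ceiling(dwell_s / line_time_s)),
                 max(2, ceiling(bleach_lines)))
    start_frame <- round(model$bind_time_s / line_time_s)
    pos <- switch(model$kind,
      static = rep(x0, n_eff),
      directed = x0 + model$velocity_um_s * line_time_s * (seq_len(n_eff) - 1),
      diffusive = {
        sd_step <- sqrt(2 * model$D_um2_s * line_time_s)
        steps <- stats::rnorm(n_eff - 1, 0, sd_step)
        walk_reflect(x0, steps, tether$length_um,
                     tether$obstacle_positions_um, tether$bypass_prob)
      })
    pos <- pmin(pmax(pos, 0), tether$length_um)  # directed drift clamps
    frames <- start_frame + seq_len(n_eff) - 1L
    tr <- Trajectory(frames * line_time_s, pos, id = 1L, channel = "eGFP",
                     frame = frames)
    attr(tr, "truth") <- list(model = model, dwell_s = dwell_s,
                              bleach_lines = bleach_lines, n_lines = n_eff)
    tr
  })
}

# Reflecting random walk on [0, L] with point obstacles. Obstacles reflect
# unless a uniform draw falls below bypass_prob, in which case the step
# crosses. Steps are assumed small relative to segment sizes.
walk_reflect <- function(x0, steps, L, obstacles, bypass_prob) {
  pos <- numeric(length(steps) + 1L); pos[1] <- x0
  bounds <- c(0, L)
  for (i in seq_along(steps)) {
    x <- pos[i]; target <- x + steps[i]
    repeat {
      crossed <- obstacles[(obstacles - x) * (obstacles - target) < 0]
      if (length(crossed)) {
        ob <- crossed[which.min(abs(crossed - x))]
        if (bypass_prob > 0 && stats::runif(1) < bypass_prob) {
          x <- ob  # pass through; continue toward target from the obstacle
          next
        }
        target <- 2 * ob - target  # reflect remainder of the step
        next
      }
      if (target < 0) { target <- -target; next }
      if (target > L) { target <- 2 * L - target; next }
      break
    }
    pos[i + 1L] <- target
  }
  pos
}

#' Render trajectories into a synthetic kymograph
#'
#' Each trajectory contributes a pixel-integrated 1D Gaussian PSF profile
#' per scan line at its current position; constant background is added and
#' Poisson noise applied. Bead contours are rendered as saturated columns
#' at both edges. The ground-truth per-frame positions are attached as
#' attribute `truth`.
#'
#' @param trajs List of [Trajectory] objects (channel taken from each).
#' @param tether A [tether_model()] (sets tether length and bead margins).
#' @param n_lines Number of scan lines to render.
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param background_counts Mean background photons per pixel per line.
#' @param pixel_size_nm,line_time_s Imaging geometry.
#' @param channels Channel names to render (default: those present in
#'   `trajs`, else `"eGFP"`).
#' @param saturation_level Intensity written into bead-margin columns.
#' @param noise Apply Poisson noise (`TRUE` by default).
#' @param seed Integer seed.
#' @return A [Kymograph] with attribute `truth`: a data frame
#'   `trajectory_id, channel, frame, position_um, position_px`.
#' @export
render_kymograph <- function(trajs, tether, n_lines, psf_sigma_px = 1.3,
                             background_counts = 10, pixel_size_nm = 100,
                             line_time_s = 0.25, channels = NULL,
                             saturation_level = 65535, noise = TRUE,
                             seed = NULL) {
  stopifnot(psf_sigma_px > 0, inherits(tether, "TetherModel"))
  margin <- tether$bead_margin_px
  n_dna <- ceiling(tether$length_um * 1000 / pixel_size_nm)
  width <- n_dna + 2L * margin
  if (is.null(channels)) {
    channels <- unique(vapply(trajs, function(t) attr(t, "channel"),
                              character(1)))
    if (length(channels) == 0L) channels <- "eGFP"
  }
  imgs <- stats::setNames(
    lapply(channels, function(ch) matrix(background_counts, n_lines, width)),
    channels)
  truth <- list()
  px_of <- function(x_um) margin + x_um * 1000 / pixel_size_nm - 0.5
  edges <- 0:width - 0.5  # pixel boundaries in 0-based column coordinates
  for (tr in trajs) {
    ch <- attr(tr, "channel")
    if (!ch %in% channels) next
    photons <- attr(tr, "truth")$model$photons_per_line %||% 300
    keep <- tr$frame >= 0 & tr$frame < n_lines
    for (k in which(keep)) {
      mu <- px_of(tr$position_um[k])
      prof <- photons * diff(stats::pnorm(edges, mu, psf_sigma_px))
      imgs[[ch]][tr$frame[k] + 1L, ] <- imgs[[ch]][tr$frame[k] + 1L, ] + prof
    }
    truth[[length(truth) + 1L]] <- data.frame(
      trajectory_id = attr(tr, "id"), channel = ch, frame = tr$frame[keep],
      position_um = tr$position_um[keep],
      position_px = px_of(tr$position_um[keep]))
  }
  local_seed(seed, {
    for (ch in channels) {
      m <- imgs[[ch]]
      if (noise) m <- matrix(stats::rpois(length(m), m), nrow(m), ncol(m))
      if (margin > 0) {
        m[, seq_len(margin)] <- saturation_level
        m[, width - seq_len(margin) + 1L] <- saturation_level
      }
      imgs[[ch]] <- m
    }
    # origin chosen so physical coordinates are tether coordinates:
    # column (margin - 0.5) sits at x = 0, and cropping the bead margins
    # brings origin_offset back to 0
    k <- Kymograph(imgs, pixel_size_nm = pixel_size_nm,
                   line_time_s = line_time_s, origin_offset = -margin)
    attr(k, "truth") <- if (length(truth)) do.call(rbind, truth)
                        else data.frame()
    k
  })
}

#' Simulate a force-extension curve with planted rips
#'
#' Distance at each force on the grid follows the eWLC ([ewlc_length()]),
#' with contour length increasing stepwise by `delta_bp * rise_per_bp` at
#' each rip force, plus Gaussian distance noise.
#'
#' @param ewlc An [ewlc_params()] (its `Lc_nm` is the initial contour length).
#' @param rips Data frame (or list) with columns/fields `force_pN` and
#'   `delta_bp`; may be empty.
#' @param force_grid_pN Increasing force grid (pN); rip forces must lie
#'   within its range.
#' @param noise_sd_nm SD of additive Gaussian distance noise (nm); 0 for a
#'   noiseless curve.
#' @param seed Integer seed.
#' @return A [ForceExtensionCurve] with attribute `truth` (rip table and
#'   per-sample true contour length).
#' @export
simulate_fec <- function(ewlc, rips = NULL, force_grid_pN = seq(2, 40, 0.2),
                         noise_sd_nm = 1, seed = NULL) {
  stopifnot(inherits(ewlc, "EWLCParams"), all(diff(force_grid_pN) > 0))
  rips <- if (is.null(rips) || NROW(rips) == 0L)
    data.frame(force_pN = numeric(), delta_bp = numeric())
  else as.data.frame(rips)
  if (NROW(rips) && (any(rips$force_pN < min(force_grid_pN)) ||
                     any(rips$force_pN > max(force_grid_pN))))
    stop("rip forces must lie within the force grid")
  Lc <- vapply(force_grid_pN, function(f)
    ewlc$Lc_nm + sum(rips$delta_bp[rips$force_pN <= f]) * ewlc$rise_per_bp,
    numeric(1))
  ext_nm <- vapply(seq_along(force_grid_pN), function(i) {
    p <- ewlc; p$Lc_nm <- Lc[i]
    ewlc_length(force_grid_pN[i], p)
  }, numeric(1))
  local_seed(seed, {
    d <- ext_nm + if (noise_sd_nm > 0)
      stats::rnorm(length(ext_nm), 0, noise_sd_nm) else 0
    # enforce the strict monotonicity invariant of a pull (noise can rarely
    # invert adjacent samples by < ~1 nm)
    for (i in seq_along(d)[-1])
      if (d[i] <= d[i - 1]) d[i] <- d[i - 1] + 1e-9
    curve <- ForceExtensionCurve(d / 1000, force_grid_pN)
    attr(curve, "truth") <- list(rips = rips, Lc_nm = Lc)
    curve
  })
}

#' Simulate exponential dwell times with frame discretization and censoring
#'
#' @param mean_s True mean dwell (s), e.g. the study's 27.2 s or 101.9 s.
#' @param n Number of events (0 allowed).
#' @param frame_s Scan-line time used to discretize durations (0 = none).
#' @param observation_limit_s Right-censoring limit (Inf = none).
#' @param seed Integer seed.
#' @return Data frame `duration_s, censored` with attribute
#'   `truth = list(mean_s = mean_s)`.
#' @export
simulate_dwells <- function(mean_s, n, frame_s = 0,
                            observation_limit_s = Inf, seed = NULL) {
  stop_if_not_scalar_pos(mean_s, "mean_s")
  stopifnot(n >= 0)
  local_seed(seed, {
    d <- if (n > 0) stats::rexp(n, 1 / mean_s) else numeric()
    if (frame_s > 0) d <- ceiling(d / frame_s) * frame_s
    cens <- d >= observation_limit_s
    d[cens] <- observation_limit_s
    out <- data.frame(duration_s = d, censored = cens)
    attr(out, "truth") <- list(mean_s = mean_s)
    out
  })
}

#' Simulate a photobleaching staircase trace
#'
#' Intensity starts at `background + n_steps * photons_per_level` and drops
#' by one level at each bleaching event; Poisson noise is applied. Event
#' spacings are exponential with mean `frames_per_step_mean`, redrawn until
#' successive events are at least `min_separation_frames` apart and all fall
#' inside the trace: coincident bleaching events are unresolvable in
#' principle, so the generator emulates the resolvable traces used for
#' stoichiometry counting (see the methods vignette).
#'
#' @param n_steps True fluorophore count (>= 0).
#' @param photons_per_level Mean intensity contributed by one fluorophore.
#' @param frames_per_step_mean Mean frames between bleaching events.
#' @param n_frames Trace length in frames (>= 10 recommended).
#' @param background Mean background intensity.
#' @param frame_s Seconds per frame (for the time axis).
#' @param min_separation_frames Minimum spacing between events (and from
#'   the trace ends).
#' @param noise Apply Poisson noise.
#' @param seed Integer seed.
#' @return Data frame of class `BleachTrace` (`time_s`, `intensity`) with
#'   attribute `truth = list(n_steps, step_frames)`.
#' @export
simulate_bleach_trace <- function(n_steps, photons_per_level = 100,
                                  frames_per_step_mean = 30, n_frames = 200,
                                  background = 20, frame_s = 0.25,
                                  min_separation_frames = 5, noise = TRUE,
                                  seed = NULL) {
  stopifnot(n_steps >= 0, n_frames >= 2)
  local_seed(seed, {
    step_frames <- integer(0)
    if (n_steps > 0) {
      for (try in 1:1000) {
        gaps <- stats::rexp(n_steps, 1 / frames_per_step_mean)
        t <- cumsum(pmax(gaps, 1))
        sf <- floor(t) + min_separation_frames
        ok <- all(diff(sf) >= min_separation_frames) &&
          sf[1] >= min_separation_frames &&
          sf[n_steps] <= n_frames - min_separation_frames
        if (ok) { step_frames <- as.integer(sf); break }
      }
      if (length(step_frames) == 0L)
        stop("could not place ", n_steps, " separated steps in ", n_frames,
             " frames; increase n_frames or reduce frames_per_step_mean")
    }
    frames <- seq_len(n_frames) - 1L
    alive <- n_steps - vapply(frames, function(f) sum(step_frames <= f),
                              numeric(1))
    level <- background + photons_per_level * alive
    intensity <- if (noise) stats::rpois(n_frames, level) else level
    out <- data.frame(time_s = frames * frame_s, intensity = intensity)
    class(out) <- c("BleachTrace", "data.frame")
    attr(out, "truth") <- list(n_steps = as.integer(n_steps),
                               step_frames = step_frames)
    out
  })
}

#' Simulate Poisson nucleation events on an ssDNA gap
#'
#' Homogeneous Poisson process with intensity
#' `rate_per_knt_min * gap_knt` events per minute; event times are uniform
#' over the observation window and positions uniform over the gap unless a
#' junction-bias weight function is supplied.
#'
#' @param rate_per_knt_min Nucleation rate per kilonucleotide per minute
#'   (the study reports 0.277 without RPA and 0.003 with RPA).
#' @param gap_knt Gap length in knt (5.374 for the study's substrate).
#' @param duration_s Observation window (s).
#' @param junction_weight Optional vectorized function `w(position_nt)`
#'   giving an unnormalized sampling density over `[0, gap_nt)`.
#' @param seed Integer seed.
#' @return Data frame `time_s, position_nt` with attribute `truth`.
#' @export
simulate_nucleation <- function(rate_per_knt_min, gap_knt, duration_s,
                                junction_weight = NULL, seed = NULL) {
  stopifnot(rate_per_knt_min >= 0, gap_knt > 0, duration_s > 0)
  local_seed(seed, {
    lambda <- rate_per_knt_min * gap_knt * duration_s / 60
    n <- stats::rpois(1, lambda)
    gap_nt <- gap_knt * 1000
    pos <- if (n == 0) numeric() else if (is.null(junction_weight))
      stats::runif(n, 0, gap_nt)
    else {  # rejection sampling from the supplied density
      grid <- seq(0, gap_nt, length.out = 2048)
      wmax <- max(junction_weight(grid))
      out <- numeric(0)
      while (length(out) < n) {
        cand <- stats::runif(2 * n, 0, gap_nt)
        acc <- stats::runif(2 * n) < junction_weight(cand) / wmax
        out <- c(out, cand[acc])
      }
      out[seq_len(n)]
    }
    res <- data.frame(time_s = sort(stats::runif(n, 0, duration_s)),
                      position_nt = pos)
    attr(res, "truth") <- list(rate_per_knt_min = rate_per_knt_min,
                               gap_knt = gap_knt, duration_s = duration_s)
    res
  })
}
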