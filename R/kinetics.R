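# Binding-event detection and kinetic quantification: event order classes,
# dwell-time fitting, nucleation rates, binding frequencies, positional
# profiles over the ssDNA gap, and nucleosome-collision outcomes.

#' Detect binding events on a kymograph channel
#'
#' An event is a connected above-threshold region in (time x position).
#' The threshold is the robust background (median) plus
#' `threshold_sd` robust SDs; a morphological closing of
#' `close_lines` lines by `close_px` pixels bridges blinking gaps. Events
#' still present on the last scan line are flagged censored.
#'
#' @param kymo A (cropped) [Kymograph].
#' @param channel Channel to analyse.
#' @param region_um Optional `c(lo, hi)` physical window (um), e.g. the
#'   ssDNA gap span; events whose mean position falls outside are dropped.
#' @param threshold_sd Detection threshold in robust background SDs.
#' @param close_lines,close_px Closing radii (lines, pixels).
#' @param min_lines Minimum event duration in lines.
#' @param min_px Minimum component area in pixels (rejects isolated noise
#'   excursions above the threshold).
#' @return Data frame of class `EventRecord`: `channel`, `start_s`,
#'   `end_s`, `position_um`, `n_px`, `intensity`, `censored`.
#' @export
detect_events <- function(kymo, channel = names(kymo$channels)[1],
                          region_um = NULL, threshold_sd = 3,
                          close_lines = 2L, close_px = 2L, min_lines = 2L,
                          min_px = 12L) {
  stopifnot(inherits(kymo, "Kymograph"), channel %in% names(kymo$channels))
  img <- kymo$channels[[channel]]
  bg <- stats::median(img)
  noise <- stats::mad(img)
  if (noise == 0) noise <- max(sqrt(max(bg, 1)), 1e-6)
  mask0 <- img > bg + threshold_sd * noise
  mask <- morph_close(mask0, close_lines, close_px)
  lab <- label_components(mask)
  pos_um <- column_positions_um(kymo)
  lt <- kymo$line_time_s
  n_lines <- nrow(img)
  events <- lapply(seq_len(max(lab, 0)), function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    # extent and position from genuinely above-threshold pixels; closing
    # only serves to bridge blinking gaps into one component
    core <- px[mask0[px], , drop = FALSE]
    if (nrow(core)) px <- core
    if (nrow(px) < min_px) return(NULL)
    # a single stray pixel bridged onto the event must not stretch its
    # timing: the extent is delimited by lines holding >= 2 event pixels
    per_line <- table(px[, 1])
    solid <- as.integer(names(per_line)[per_line >= 2L])
    lines <- if (length(solid)) range(solid) else range(px[, 1])
    if (diff(lines) + 1L < min_lines) return(NULL)
    wts <- pmax(img[px] - bg, 0)
    if (sum(wts) == 0) wts <- rep(1, nrow(px))
    data.frame(channel = channel,
               start_s = (lines[1] - 1L) * lt,
               end_s = (lines[2] - 1L) * lt,
               position_um = sum(pos_um[px[, 2]] * wts) / sum(wts),
               n_px = nrow(px),
               intensity = sum(img[px] - bg),
               censored = lines[2] == n_lines)
  })
  events <- events[!vapply(events, is.null, logical(1))]
  out <- if (length(events)) do.call(rbind, events)
         else data.frame(channel = character(), start_s = numeric(),
                         end_s = numeric(), position_um = numeric(),
                         n_px = integer(), intensity = numeric(),
                         censored = logical())
  if (!is.null(region_um) && nrow(out))
    out <- out[out$position_um >= region_um[1] &
               out$position_um <= region_um[2], ]
  out <- out[order(out$start_s, out$position_um), ]
  rownames(out) <- NULL
  class(out) <- c("EventRecord", "data.frame")
  out
}

# Binary morphological closing with a rectangular (2a+1) x (2b+1) element.
morph_close <- function(mask, a, b) {
  if (a == 0 && b == 0) return(mask)
  erode_ <- function(m, a, b) !dilate_(!m, a, b)
  erode_(dilate_(mask, a, b), a, b)
}

dilate_ <- function(m, a, b) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in seq_len(a)) {
    out[seq_len(nr - dr), ] <- out[seq_len(nr - dr), ] | m[(dr + 1):nr, ]
    out[(dr + 1):nr, ] <- out[(dr + 1):nr, ] | m[seq_len(nr - dr), ]
  }
  m2 <- out
  for (dc in seq_len(b)) {
    out[, seq_len(nc - dc)] <- out[, seq_len(nc - dc)] | m2[, (dc + 1):nc]
    out[, (dc + 1):nc] <- out[, (dc + 1):nc] | m2[, seq_len(nc - dc)]
  }
  out
}

# 8-connected component labelling by breadth-first flood fill.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  todo <- which(mask)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nb <- unique(unlist(lapply(seq_len(nrow(offs)), function(k) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        (cc[ok] - 1L) * nr + rr[ok]
      })))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

#' Classify the binding order of two-channel events
#'
#' Pairs events from two channels (canonically a mediator channel such as
#' BRCA2-eGFP and a recombinase channel such as RAD51-A647) by
#' colocalization within `coloc_radius_um`, then classifies each event of
#' the first channel: `co_complex` if both channels appear within
#' `co_tolerance_s`; `first_alone_then_partner` (mediator binds first,
#' partner joins); `on_preassembled_partner` (partner was already bound);
#' `alone` if no partner event colocalizes. Simultaneous arrivals are
#' `co_complex` regardless of which channel is read first.
#'
#' @param events_a,events_b `EventRecord` tables for the two channels
#'   (classification is reported per event of `events_a`).
#' @param co_tolerance_s Arrival-time tolerance for the co-complex call (s);
#'   1 scan line by default at 0.25 s.
#' @param coloc_radius_um Colocalization radius (um); 2 px at 100 nm/px.
#' @return List: `classes` (factor per `events_a` row), `counts`,
#'   `proportions`.
#' @export
classify_event_order <- function(events_a, events_b, co_tolerance_s = 0.25,
                                 coloc_radius_um = 0.2) {
  lv <- c("co_complex", "first_alone_then_partner",
          "on_preassembled_partner", "alone")
  n <- nrow(events_a)
  cls <- character(n)
  for (i in seq_len(n)) {
    a <- events_a[i, ]
    near <- events_b[abs(events_b$position_um - a$position_um) <=
                     coloc_radius_um, , drop = FALSE]
    # temporal overlap (with tolerance) with the a event
    near <- near[near$start_s <= a$end_s + co_tolerance_s &
                 near$end_s >= a$start_s - co_tolerance_s, , drop = FALSE]
    cls[i] <- if (nrow(near) == 0L) "alone"
    else if (any(abs(near$start_s - a$start_s) <= co_tolerance_s))
      "co_complex"
    else if (min(near$start_s) < a$start_s) "on_preassembled_partner"
    else "first_alone_then_partner"
  }
  classes <- factor(cls, levels = lv)
  counts <- table(classes)
  list(classes = classes, counts = counts,
       proportions = if (n > 0) counts / n else counts)
}

#' Fit a single-exponential dwell-time distribution
#'
#' Uncensored durations are binned into `bin_width_s`-wide bins (7 s, as
#' used for the study's dwell histograms) and the histogram is fit with
#' `A * exp(-t / tau)` at the bin centres by least squares. Censored
#' dwells are excluded from the fit (the binned-histogram method cannot
#' use them) but counted in the output.
#'
#' @param durations_s Event durations (s), or a data frame with columns
#'   `duration_s` and `censored` (as from [simulate_dwells()]).
#' @param censored Logical vector (recycled `FALSE` if missing).
#' @param bin_width_s Histogram bin width (s).
#' @return List of class `DwellFit`: `tau_s`, `amplitude`, `bin_width_s`,
#'   `n_events`, `n_censored`, `r_squared`, `histogram`.
#' @export
fit_dwell <- function(durations_s, censored = NULL, bin_width_s = 7) {
  if (is.data.frame(durations_s)) {
    censored <- durations_s$censored
    durations_s <- durations_s$duration_s
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations_s))
  d <- durations_s[!censored]
  if (length(d) < 10L)
    stop("need at least 10 uncensored events for a dwell fit")
  breaks <- seq(0, max(d) + bin_width_s, by = bin_width_s)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  ctr <- h$mids; cnt <- h$counts
  tau0 <- max(mean(d), bin_width_s / 2)
  fit <- tryCatch(suppressWarnings(
    stats::nls(cnt ~ A * exp(-ctr / tau), start = list(A = max(cnt),
                                                       tau = tau0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    pred <- stats::fitted(fit)
  } else {  # fall back to log-linear LS on non-empty bins
    pos <- cnt > 0
    lf <- stats::lm(log(cnt[pos]) ~ ctr[pos])
    cf <- c(A = exp(unname(stats::coef(lf)[1])),
            tau = -1 / unname(stats::coef(lf)[2]))
    pred <- cf[["A"]] * exp(-ctr / cf[["tau"]])
  }
  ss_res <- sum((cnt - pred)^2); ss_tot <- sum((cnt - mean(cnt))^2)
  structure(list(tau_s = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
                 bin_width_s = bin_width_s, n_events = length(d),
                 n_censored = sum(censored),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 histogram = data.frame(center_s = ctr, count = cnt)),
            class = "DwellFit")
}

#' Nucleation rate per kilonucleotide per minute
#'
#' Number of nuclei appearing within the observation window, normalized by
#' gap length and window duration: `rate = count / (gap_knt * window_s/60)`.
#' Early windows (60 s, or 120 s for slower conditions) avoid saturation
#' of the gap at later times.
#'
#' @param event_times_s Event start times (s); only those `<= window_s`
#'   are counted.
#' @param gap_knt Gap length (knt).
#' @param window_s Observation window (s).
#' @return List: `rate_per_knt_min`, `count`, `gap_knt`, `window_s`.
#' @export
nucleation_rate <- function(event_times_s, gap_knt, window_s = 60) {
  stop_if_not_scalar_pos(gap_knt, "gap_knt")
  stop_if_not_scalar_pos(window_s, "window_s")
  count <- sum(event_times_s <= window_s)
  list(rate_per_knt_min = count / (gap_knt * window_s / 60),
       count = count, gap_knt = gap_knt, window_s = window_s)
}

#' Binding frequency per unit length per minute
#'
#' Event starts normalized by region length and observation time. Both
#' per-um and (when `span_knt` is supplied) per-knt frequencies are
#' returned, with units recorded.
#'
#' @param event_times_s Event start times within the observation (s).
#' @param span_um Region length (um).
#' @param observation_s Observation duration (s).
#' @param span_knt Optional region length in knt.
#' @return List: `per_um_min`, `per_knt_min` (or `NA`), `count`, `units`.
#' @export
binding_frequency <- function(event_times_s, span_um, observation_s,
                              span_knt = NULL) {
  stop_if_not_scalar_pos(span_um, "span_um")
  stop_if_not_scalar_pos(observation_s, "observation_s")
  count <- length(event_times_s)
  minutes <- observation_s / 60
  list(per_um_min = count / (span_um * minutes),
       per_knt_min = if (is.null(span_knt)) NA_real_
                     else count / (span_knt * minutes),
       count = count,
       units = c("um^-1 min^-1", "knt^-1 min^-1"))
}

#' Positional intensity profile over the ssDNA gap
#'
#' Integrates background-subtracted intensity per pixel over the analysis
#' window, maps pixel positions to nucleotides along the gap, aggregates
#' into `bin_nt`-wide bins (27 bins for a 5,374-nt gap at 200 nt), and
#' normalizes to fractions summing to 1. The final partial bin
#' (5,374 = 26 x 200 + 174) is kept and rescaled to its nt width before
#' normalization to avoid edge bias.
#'
#' @param kymo A (cropped) [Kymograph].
#' @param channel Channel to integrate.
#' @param gap_span_um `c(lo, hi)` physical span of the gap (um).
#' @param gap_nt Gap length in nucleotides.
#' @param bin_nt Bin width (nt).
#' @param time_range_s Optional `c(lo, hi)` analysis window (s), e.g. from
#'   first to last binding event; default whole kymograph.
#' @param orientation Which physical end of the gap is the 3' ds-ssDNA
#'   junction: `"left_3prime"` (default) or `"left_5prime"`. Required
#'   metadata; it cannot be inferred from the image.
#' @return Data frame of class `PositionProfile` (`bin`, `nt_lo`, `nt_hi`,
#'   `fraction`) with attributes `gap_nt`, `bin_nt`, `orientation`.
#' @export
position_profile <- function(kymo, channel = names(kymo$channels)[1],
                             gap_span_um, gap_nt = 5374, bin_nt = 200,
                             time_range_s = NULL,
                             orientation = c("left_3prime", "left_5prime")) {
  stopifnot(inherits(kymo, "Kymograph"), length(gap_span_um) == 2L)
  orientation <- match.arg(orientation)
  img <- kymo$channels[[channel]]
  lt <- kymo$line_time_s
  rows <- if (is.null(time_range_s)) seq_len(nrow(img))
          else which((seq_len(nrow(img)) - 1) * lt >= time_range_s[1] &
                     (seq_len(nrow(img)) - 1) * lt <= time_range_s[2])
  if (length(rows) == 0L) stop("time_range_s selects no scan lines")
  pos <- column_positions_um(kymo)
  px_w_um <- kymo$pixel_size_nm / 1000
  cols <- which(pos + px_w_um / 2 > gap_span_um[1] &
                pos - px_w_um / 2 < gap_span_um[2])
  if (length(cols) == 0L) stop("gap span contains no kymograph columns")
  bg <- stats::median(img[rows, , drop = FALSE])
  colsum <- pmax(colSums(img[rows, cols, drop = FALSE]) -
                 bg * length(rows), 0)
  # nt interval covered by each pixel (clipped to the gap)
  lo_um <- pmax(pos[cols] - px_w_um / 2, gap_span_um[1])
  hi_um <- pmin(pos[cols] + px_w_um / 2, gap_span_um[2])
  to_nt <- function(u) (u - gap_span_um[1]) / diff(gap_span_um) * gap_nt
  lo_nt <- to_nt(lo_um); hi_nt <- to_nt(hi_um)
  n_bins <- ceiling(gap_nt / bin_nt)
  edges <- c(seq(0, gap_nt, by = bin_nt), if (gap_nt %% bin_nt) gap_nt)
  binsum <- numeric(n_bins)
  for (k in seq_along(cols)) {
    if (hi_nt[k] <= lo_nt[k]) next
    dens <- colsum[k] / (hi_nt[k] - lo_nt[k])
    for (b in seq_len(n_bins)) {
      ov <- min(hi_nt[k], edges[b + 1]) - max(lo_nt[k], edges[b])
      if (ov > 0) binsum[b] <- binsum[b] + dens * ov
    }
  }
  widths <- diff(edges)
  adj <- binsum * (bin_nt / widths)  # rescale the partial bin to full width
  frac <- if (sum(adj) > 0) adj / sum(adj) else rep(1 / n_bins, n_bins)
  out <- data.frame(bin = seq_len(n_bins), nt_lo = utils::head(edges, -1),
                    nt_hi = edges[-1], fraction = frac)
  attr(out, "gap_nt") <- gap_nt
  attr(out, "bin_nt") <- bin_nt
  attr(out, "orientation") <- orientation
  class(out) <- c("PositionProfile", "data.frame")
  out
}

#' Junction vs middle statistics of positional profiles
#'
#' Mean per-bin fraction within the first `junction_bins` bins (one
#' ds-ssDNA junction), the last `junction_bins` bins (the other junction)
#' and the middle bins (21 of 27 for the canonical gap), averaged per
#' molecule, with paired t tests between groups across molecules.
#' Profiles are re-oriented using their `orientation` attribute so the
#' groups are reported as 3' and 5' junctions.
#'
#' @param profiles A `PositionProfile` or list of them (one per molecule).
#' @param junction_bins Bins per junction edge.
#' @return List: `group_means` (per-molecule data frame with columns
#'   `junction_3p`, `middle`, `junction_5p`), `means`, `n_middle_bins`,
#'   `p_3p_vs_middle`, `p_5p_vs_middle`, `p_5p_vs_3p` (NA when n < 2).
#' @export
junction_stat <- function(profiles, junction_bins = 3L) {
  if (inherits(profiles, "PositionProfile")) profiles <- list(profiles)
  per_mol <- lapply(profiles, function(p) {
    f <- p$fraction
    if (identical(attr(p, "orientation"), "left_5prime")) f <- rev(f)
    nb <- length(f)
    if (nb < 2L * junction_bins + 1L)
      stop("profile needs at least 2*junction_bins + 1 bins")
    mid <- (junction_bins + 1L):(nb - junction_bins)
    data.frame(junction_3p = mean(f[seq_len(junction_bins)]),
               middle = mean(f[mid]),
               junction_5p = mean(f[nb - junction_bins + seq_len(junction_bins)]))
  })
  gm <- do.call(rbind, per_mol)
  n <- nrow(gm)
  pt <- function(a, b) if (n >= 2L && stats::sd(a - b) > 0)
    stats::t.test(a, b, paired = TRUE)$p.value else NA_real_
  nb <- length(profiles[[1]]$fraction)
  list(group_means = gm,
       means = colMeans(gm),
       n_middle_bins = nb - 2L * junction_bins,
       p_3p_vs_middle = pt(gm$junction_3p, gm$middle),
       p_5p_vs_middle = pt(gm$junction_5p, gm$middle),
       p_5p_vs_3p = pt(gm$junction_5p, gm$junction_3p))
}

#' Score trajectory collisions with point obstacles
#'
#' Each approach of the trajectory to within `approach_radius_um` of an
#' obstacle (e.g. a labelled nucleosome) is scored: `bypassed` if the
#' trajectory exits on the far side, `dissociated_at_obstacle` if the
#' track ends while within the radius, `blocked` otherwise.
#'
#' @param traj A [Trajectory].
#' @param obstacle_positions_um Obstacle positions (um).
#' @param approach_radius_um Contact radius (um); 2 px at 100 nm/px by
#'   default.
#' @return List: `counts` (named vector), `episodes` (data frame per
#'   approach: obstacle, enter/exit frames, outcome).
#' @export
collision_outcomes <- function(traj, obstacle_positions_um,
                               approach_radius_um = 0.2) {
  stopifnot(inherits(traj, "Trajectory"))
  x <- traj$position_um
  eps <- list()
  for (ob in obstacle_positions_um) {
    inside <- abs(x - ob) <= approach_radius_um
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      outcome <- if (e == length(x)) "dissociated_at_obstacle"
      else {
        before <- if (s > 1L) sign(x[s - 1L] - ob) else sign(x[s] - ob)
        after <- sign(x[e + 1L] - ob)
        if (before != 0 && after != 0 && before != after) "bypassed"
        else "blocked"
      }
      eps[[length(eps) + 1L]] <- data.frame(
        obstacle_um = ob, enter_frame = traj$frame[s],
        exit_frame = traj$frame[e], outcome = outcome)
    }
  }
  episodes <- if (length(eps)) do.call(rbind, eps)
              else data.frame(obstacle_um = numeric(),
                              enter_frame = integer(),
                              exit_frame = integer(), outcome = character())
  counts <- c(blocked = sum(episodes$outcome == "blocked"),
              bypassed = sum(episodes$outcome == "bypassed"),
              dissociated_at_obstacle =
                sum(episodes$outcome == "dissociated_at_obstacle"))
  list(counts = counts, episodes = episodes)
}

#' Fraction of mobile molecules per tether region
#'
#' Assigns each trajectory to the ssDNA gap or the flanking dsDNA by
#' majority residence of its samples, then reports the fraction whose
#' motion class is not `"static"` per region. Straddling trajectories are
#' assigned by majority and listed in `straddling`.
#'
#' @param trajs List of [Trajectory] objects.
#' @param fits List of `DiffusionFit` objects, parallel to `trajs`.
#' @param gap_span_um `c(lo, hi)` gap span (um).
#' @return List: `table` (data frame region/n/fraction_mobile),
#'   `straddling` (indices with 25-75% residence).
#' @export
diffusive_fraction <- function(trajs, fits, gap_span_um) {
  stopifnot(length(trajs) == length(fits))
  inside_frac <- vapply(trajs, function(tr)
    mean(tr$position_um >= gap_span_um[1] &
         tr$position_um <= gap_span_um[2]), numeric(1))
  region <- ifelse(inside_frac > 0.5, "ssDNA", "dsDNA")
  mobile <- vapply(fits, function(f) f$motion_class != "static", logical(1))
  tab <- do.call(rbind, lapply(c("ssDNA", "dsDNA"), function(rg) {
    sel <- region == rg
    data.frame(region = rg, n = sum(sel),
               fraction_mobile = if (any(sel)) mean(mobile[sel]) else NA_real_)
  }))
  list(table = tab,
       straddling = which(inside_frac > 0.25 & inside_frac < 0.75))
}
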