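# Photobleaching step counting: estimate fluorophore stoichiometry of a
# diffraction-limited spot from the number of discrete downward intensity
# steps.

#' Piecewise-constant change-point segmentation (binary segmentation)
#'
#' Recursive binary segmentation of a sequence under a piecewise-constant
#' mean model. A split is accepted when it reduces the residual sum of
#' squares by more than `penalty` (default `penalty_factor * sigma^2 *
#' log(n)`, a BIC-style rule with `sigma` the MAD-based robust noise SD),
#' subject to a minimum segment length. The procedure is deterministic and
#' invariant to additive offsets and to rescaling (the penalty scales with
#' the variance estimate).
#'
#' @param y Numeric sequence.
#' @param min_segment Minimum segment length.
#' @param penalty Explicit penalty; `NULL` to use the BIC-style default.
#' @param penalty_factor Multiplier of `sigma^2 * log(n)`.
#' @return Integer vector of change-point indices: position i means the
#'   level changes between `y[i]` and `y[i+1]`. Empty when no change.
#' @export
segment_stepwise <- function(y, min_segment = 3L, penalty = NULL,
                             penalty_factor = 2) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L * min_segment) return(integer(0))
  if (is.null(penalty)) {
    sig <- robust_noise_sd(y)
    if (sig == 0) sig <- 1e-12  # noiseless staircase: any true step wins
    penalty <- penalty_factor * sig^2 * log(n)
  }
  cps <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_segment) return(invisible())
    seg <- y[lo:hi]
    cs <- cumsum(seg); tot <- cs[len]
    ks <- min_segment:(len - min_segment)
    # RSS reduction of a split after k: n1*n2/n * (mean1 - mean2)^2
    m1 <- cs[ks] / ks
    m2 <- (tot - cs[ks]) / (len - ks)
    gain <- ks * (len - ks) / len * (m1 - m2)^2
    k <- ks[which.max(gain)]
    if (max(gain) > penalty) {
      cps <<- c(cps, lo + k - 1L)
      recurse(lo, lo + k - 1L)
      recurse(lo + k, hi)
    }
    invisible()
  }
  recurse(1L, n)
  sort(cps)
}

#' Extract an intensity trace around a binding event
#'
#' Per-line sum over `integration_px` columns centred on the event
#' position, minus a local background estimated from flanking windows of
#' the same width on both sides. Events at the image edge get a narrowed
#' window and are flagged.
#'
#' @param kymo A [Kymograph].
#' @param event One row of an `EventRecord` (uses `position_um`,
#'   `channel`), or a list with those fields.
#' @param integration_px Width of the integration window (columns).
#' @return Data frame of class `BleachTrace` (`time_s`, `intensity`) with
#'   attributes `narrowed` and `integration_px`.
#' @export
extract_trace <- function(kymo, event, integration_px = 5L) {
  stopifnot(inherits(kymo, "Kymograph"))
  ch <- as.character(event$channel)
  img <- kymo$channels[[ch]]
  w <- ncol(img)
  pos_px <- event$position_um * 1000 / kymo$pixel_size_nm -
    kymo$origin_offset - 0.5  # 0-based column
  half <- integration_px %/% 2L
  ctr <- round(pos_px) + 1L  # 1-based
  if (ctr < 1L || ctr > w) stop("event position outside image")
  lo <- max(1L, ctr - half); hi <- min(w, ctr + half)
  narrowed <- (hi - lo + 1L) < integration_px
  sig <- rowSums(img[, lo:hi, drop = FALSE])
  n_cols <- hi - lo + 1L
  flank <- c(max(1L, lo - n_cols):max(1L, lo - 1L),
             min(w, hi + 1L):min(w, hi + n_cols))
  flank <- setdiff(unique(flank), lo:hi)
  bg_per_col <- if (length(flank))
    rowMeans(img[, flank, drop = FALSE]) else 0
  out <- data.frame(time_s = (seq_len(nrow(img)) - 1L) * kymo$line_time_s,
                    intensity = sig - bg_per_col * n_cols)
  class(out) <- c("BleachTrace", "data.frame")
  attr(out, "narrowed") <- narrowed
  attr(out, "integration_px") <- n_cols
  out
}

#' Count photobleaching steps in an intensity trace
#'
#' Piecewise-constant change-point segmentation ([segment_stepwise()])
#' followed by filtering: level changes smaller than `min_step_sd` robust
#' noise SDs are merged away, and the first upward step (an arrival)
#' terminates the analysed prefix. The remaining downward level changes
#' are the bleaching steps.
#'
#' @param trace A `BleachTrace` (or numeric vector), length >= 10.
#' @param min_segment Minimum segment length (lines).
#' @param min_step_sd Minimum step height in robust noise SDs.
#' @param penalty_factor Passed to [segment_stepwise()].
#' @return List of class `StepCountResult`: `n_steps`, `step_times_s`,
#'   `step_heights`, `levels`, `truncated_at_arrival`, `residual_rms`.
#' @export
count_steps <- function(trace, min_segment = 3L, min_step_sd = 2,
                        penalty_factor = 2) {
  if (is.data.frame(trace)) {
    y <- trace$intensity; t_s <- trace$time_s
  } else {
    y <- as.numeric(trace); t_s <- seq_along(y) - 1
  }
  if (length(y) < 10L) stop("trace must have at least 10 samples")
  # Photon-counting noise is heteroscedastic (variance ~ level), so a
  # global noise estimate over- or under-penalizes depending on which
  # level dominates the trace. Segment a variance-stabilized
  # (Anscombe-type) transform instead, shifted so it is invariant to
  # additive offsets; levels and step heights are then read off the raw
  # trace. The transform is monotone, so up/down steps are preserved.
  z <- 2 * sqrt(y - min(y) + 1)
  sig_z <- robust_noise_sd(z)
  if (sig_z == 0) sig_z <- 1e-12
  min_step <- min_step_sd * sig_z
  cps <- segment_stepwise(z, min_segment = min_segment,
                          penalty_factor = penalty_factor)
  # merge segments whose level difference is below the minimum step height
  repeat {
    bounds <- c(0L, cps, length(y))
    zlev <- vapply(seq_len(length(bounds) - 1L), function(i)
      mean(z[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
    if (length(cps) == 0L) break
    dl <- abs(diff(zlev))
    weak <- which(dl < min_step)
    if (length(weak) == 0L) break
    cps <- cps[-weak[which.min(dl[weak])]]
  }
  bounds <- c(0L, cps, length(y))
  bounds <- c(0L, cps, length(y))
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(y[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  heights <- diff(levels)
  # an upward step is an arrival: analyse only the prefix before it
  up <- which(heights > 0)
  truncated <- length(up) > 0L
  prefix_end <- if (truncated) bounds[up[1] + 1L] else length(y)
  if (truncated) {
    keep <- seq_len(up[1] - 1L)
    cps <- cps[keep]
    heights <- heights[keep]
    levels <- levels[seq_len(up[1])]
  }
  seg_len <- diff(c(0L, cps, prefix_end))
  fitted <- rep(levels, seg_len)
  rms <- sqrt(mean((y[seq_len(prefix_end)] - fitted)^2))
  structure(list(n_steps = length(cps),
                 step_times_s = t_s[cps],
                 step_heights = heights,
                 levels = levels,
                 truncated_at_arrival = truncated,
                 residual_rms = rms),
            class = "StepCountResult")
}

#' Oligomer distribution from step-count results
#'
#' Histogram of fluorophore counts (bleaching steps per spot). Traces
#' whose analysis was truncated by an arrival and yielded no steps are
#' excluded and counted separately.
#'
#' @param results List of `StepCountResult` objects.
#' @return List: `counts` (named table by n_steps), `fractions`,
#'   `n_excluded`.
#' @export
oligomer_distribution <- function(results) {
  stopifnot(length(results) >= 1L)
  excl <- vapply(results, function(r)
    isTRUE(r$truncated_at_arrival) && r$n_steps == 0L, logical(1))
  ns <- vapply(results[!excl], function(r) r$n_steps, integer(1))
  if (length(ns) == 0L)
    return(list(counts = table(integer(0)), fractions = numeric(0),
                n_excluded = sum(excl)))
  counts <- table(ns)
  list(counts = counts, fractions = counts / sum(counts),
       n_excluded = sum(excl))
}
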