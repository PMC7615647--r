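# tracking: bead cropping, sub-pixel localization, linking, smoothing.

test_that("crop_beads strips saturated margins and preserves coordinates", {
  # spec case: origin-0 image with 5 saturated columns per side
  withr::with_seed(3, body <- matrix(rpois(40 * 50, 10), 40, 50))
  img <- cbind(matrix(65535, 40, 5), body, matrix(65535, 40, 5))
  k0 <- Kymograph(list(a = img), 100, 0.25)
  k0c <- crop_beads(k0)
  expect_equal(ncol(k0c$channels$a), 50L)
  expect_equal(k0c$origin_offset, 5)
  # rendered kymograph: margins removed, origin returns to the tether frame
  teth <- tether_model(total_bp = 20000, gap_start_nt = NULL,
                       bead_margin_px = 5)
  k <- static_kymo(3.05, tether = teth, photons = 2000, seed = 2)
  w0 <- ncol(k$channels$eGFP)
  kc <- crop_beads(k)
  expect_equal(ncol(kc$channels$eGFP), w0 - 10L)
  expect_equal(kc$origin_offset, k$origin_offset + 5)
  # physical position of the emitter is invariant under cropping
  pos_before <- column_positions_um(k)[which.max(colMeans(k$channels$eGFP[,
    6:(w0 - 5)])) + 5L]
  pos_after <- column_positions_um(kc)[which.max(colMeans(kc$channels$eGFP))]
  expect_equal(pos_before, pos_after)
  # no saturated columns: identity
  k2 <- static_kymo(3.05, tether = bare_tether(), seed = 2)
  expect_identical(crop_beads(k2), k2)
  # fully saturated image errors
  sat <- Kymograph(list(a = matrix(65535, 10, 10)), 100, 0.25)
  expect_error(crop_beads(sat), "saturated")
})

test_that("localization is accurate and unbiased for static emitters", {
  # noiseless emitter at a deliberately fractional column
  teth <- bare_tether()
  tr <- simulate_trajectory(
    emitter_model("static", start_position_um = 1.234 + 0.05,
                  photons_per_line = 1000), teth, 50, seed = 1)
  k <- render_kymograph(list(tr), teth, n_lines = 50, noise = FALSE,
                        background_counts = 5, seed = 1)
  truth_px <- attr(k, "truth")$position_px[1]
  locs <- localize(k, "eGFP", tracking_config())
  expect_equal(nrow(locs), 50L)
  expect_lt(max(abs(locs$position_px - truth_px)), 0.01)
  # SNR 10, Poisson noise: small RMS error and |bias| < 0.05 px
  tr2 <- simulate_trajectory(
    emitter_model("static", start_position_um = 5.0,
                  photons_per_line = photons_for_snr(10)),
    teth, 300, seed = 2)
  k2 <- render_kymograph(list(tr2), teth, n_lines = 300, seed = 3)
  truth2 <- attr(k2, "truth")$position_px[1]
  locs2 <- localize(k2, "eGFP", tracking_config())
  # per-frame nearest localization to the emitter
  err <- vapply(0:299, function(f) {
    cand <- locs2$position_px[locs2$frame == f]
    if (!length(cand)) NA_real_ else cand[which.min(abs(cand - truth2))] -
      truth2
  }, numeric(1))
  expect_gt(mean(!is.na(err)), 0.95)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.15)
  expect_lt(abs(mean(err, na.rm = TRUE)), 0.05)
  # flat background yields no localizations
  flat <- render_kymograph(list(), teth, n_lines = 60, seed = 4)
  expect_equal(nrow(localize(flat, "eGFP")), 0L)
})

test_that("single-line fitting (window_frames = 1) is exposed", {
  teth <- bare_tether()
  tr <- simulate_trajectory(
    emitter_model("static", start_position_um = 2.5,
                  photons_per_line = 1000), teth, 30, seed = 5)
  k <- render_kymograph(list(tr), teth, n_lines = 30, seed = 6)
  locs <- localize(k, "eGFP", tracking_config(window_frames = 1L))
  truth_px <- attr(k, "truth")$position_px[1]
  near <- locs$position_px[abs(locs$position_px - truth_px) < 2]
  expect_gt(length(near), 25)
  expect_lt(abs(mean(near) - truth_px), 0.1)
})

test_that("linking follows gaps, splits identities, never doubles up", {
  mk_locs <- function(df) {
    df$amplitude <- 100; df$sigma_px <- 1.3; df$background <- 10
    df$channel <- "eGFP"
    class(df) <- c("Localization", "data.frame")
    df
  }
  # one emitter with a 2-line gap: one unbroken trajectory
  fr <- setdiff(0:49, c(20, 21))
  locs <- mk_locs(data.frame(frame = fr, position_px = 10 + 0.01 * fr))
  trajs <- link(locs, tracking_config())
  expect_length(trajs, 1L)
  expect_equal(nrow(trajs[[1]]), 48L)
  # a gap beyond max_gap_frames splits the track
  fr2 <- setdiff(0:49, 20:25)
  locs2 <- mk_locs(data.frame(frame = fr2, position_px = 10))
  trajs2 <- link(locs2, tracking_config())
  expect_length(trajs2, 2L)
  # two static emitters 30 px apart: two tracks, no swaps
  withr::with_seed(7, {
    df <- data.frame(frame = rep(0:99, each = 2),
                     position_px = rep(c(10, 40), 100) + rnorm(200, 0, 0.2))
  })
  trajs3 <- link(mk_locs(df), tracking_config())
  expect_length(trajs3, 2L)
  centers <- sort(vapply(trajs3, function(t) mean(t$position_um), numeric(1)))
  expect_equal(centers, (c(10, 40) + 0.5) * 0.1, tolerance = 0.01)
  # invariant: never two localizations from one line in one trajectory
  for (t in trajs3) expect_false(any(duplicated(t$frame)))
})

test_that("overlap frames are flagged ineligible for MSD", {
  mk <- function(frame, pos) {
    df <- data.frame(frame = frame, position_px = pos, amplitude = 100,
                     sigma_px = 1.3, background = 10, channel = "eGFP")
    class(df) <- c("Localization", "data.frame"); df
  }
  # two tracks drifting to within the exclusion radius mid-way
  f <- 0:39
  pa <- seq(10, 20, length.out = 40)
  pb <- seq(30, 21, length.out = 40)
  locs <- mk(rep(f, each = 2), as.vector(rbind(pa, pb)))
  locs <- locs[order(locs$frame, locs$position_px), ]
  trajs <- link(locs, tracking_config())
  expect_length(trajs, 2L)
  elig <- lapply(trajs, function(t) t$msd_eligible)
  expect_true(all(vapply(trajs, function(t)
    any(!t$msd_eligible), logical(1))))
  # the early, well-separated frames stay eligible
  expect_true(all(trajs[[1]]$msd_eligible[trajs[[1]]$frame < 20]))
})

test_that("Savitzky-Golay smoothing: polynomial preservation, noise", {
  x <- seq(0, 10, length.out = 200)
  cubic <- 1 + 2 * x - 0.3 * x^2 + 0.01 * x^3
  expect_equal(savitzky_golay(cubic, 51, 3), cubic, tolerance = 1e-8)
  withr::with_seed(1, noisy <- 5 + rnorm(300, 0, 0.5))
  sm <- savitzky_golay(noisy, 51, 3)
  expect_lt(stats::var(sm), stats::var(noisy))
  expect_error(savitzky_golay(1:10, 51, 3), "longer than")
  expect_error(savitzky_golay(1:100, 50, 3), "odd")
})

test_that("smooth_trajectory honours the length precondition", {
  tr <- random_trajectory(40, seed = 1)
  out <- smooth_trajectory(tr, tracking_config())  # sg_window 51 > 40
  expect_identical(out$position_um, tr$position_um)
  expect_false(attr(out, "smoothed"))
  tr2 <- random_trajectory(200, seed = 2)
  out2 <- smooth_trajectory(tr2, tracking_config())
  expect_true(attr(out2, "smoothed"))
  expect_identical(out2$time_s, tr2$time_s)
  expect_lt(stats::var(diff(out2$position_um)),
            stats::var(diff(tr2$position_um)))
})
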