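# synth: generators are deterministic, follow their stated laws, and
# return ground truth alongside the data.

test_that("simulators are bit-reproducible for identical seeds", {
  t1 <- simulate_trajectory(emitter_model("diffusive"), bare_tether(),
                            100, seed = 7)
  t2 <- simulate_trajectory(emitter_model("diffusive"), bare_tether(),
                            100, seed = 7)
  expect_identical(t1$position_um, t2$position_um)
  k1 <- static_kymo(2, seed = 5)
  k2 <- static_kymo(2, seed = 5)
  expect_identical(k1$channels, k2$channels)
  expect_identical(simulate_dwells(27.2, 50, seed = 3),
                   simulate_dwells(27.2, 50, seed = 3))
})

test_that("trajectory kinds follow their stated laws", {
  teth <- bare_tether()
  st <- simulate_trajectory(emitter_model("static", start_position_um = 2),
                            teth, 100, seed = 1)
  expect_true(all(st$position_um == 2))
  dr <- simulate_trajectory(
    emitter_model("directed", velocity_um_s = 0.2, start_position_um = 1),
    teth, 100, seed = 1)
  expect_equal(diff(dr$position_um), rep(0.2 * 0.25, 99), tolerance = 1e-12)
  expect_error(simulate_trajectory(
    emitter_model("static", start_position_um = 99), teth, 10, seed = 1),
    "outside tether")
})

test_that("diffusive increments have variance 2*D*dt (variance-ratio test)", {
  teth <- tether_model(total_bp = 1e6, gap_start_nt = NULL)
  tr <- simulate_trajectory(
    emitter_model("diffusive", D_um2_s = 0.04, start_position_um = 170),
    teth, n_lines = 10001, line_time_s = 0.25, seed = 11)
  inc <- diff(tr$position_um)
  expected <- 2 * 0.04 * 0.25
  # chi-square variance-ratio test at n = 1e4: p > 0.01 under the true law
  stat <- (length(inc) - 1) * stats::var(inc) / expected
  p <- 2 * min(stats::pchisq(stat, length(inc) - 1),
               1 - stats::pchisq(stat, length(inc) - 1))
  expect_gt(p, 0.01)
})

test_that("reflecting boundaries and obstacles confine the walk", {
  teth <- tether_model(total_bp = 20000, gap_start_nt = NULL,
                       obstacle_positions_um = 5, bead_margin_px = 0)
  tr <- simulate_trajectory(
    emitter_model("diffusive", D_um2_s = 0.1, start_position_um = 4),
    teth, n_lines = 2000, seed = 21)
  expect_true(all(tr$position_um <= 5))
  expect_true(all(tr$position_um >= 0))
  # with bypass probability 1 the obstacle is transparent
  teth2 <- tether_model(total_bp = 20000, gap_start_nt = NULL,
                        obstacle_positions_um = 5, bypass_prob = 1,
                        bead_margin_px = 0)
  tr2 <- simulate_trajectory(
    emitter_model("diffusive", D_um2_s = 0.1, start_position_um = 4.9),
    teth2, n_lines = 2000, seed = 22)
  expect_gt(max(tr2$position_um), 5)
})

test_that("dwell and bleach draws truncate the trajectory", {
  tr <- simulate_trajectory(
    emitter_model("static", start_position_um = 1, dwell_mean_s = 2),
    bare_tether(), n_lines = 10000, line_time_s = 0.25, seed = 31)
  expect_lt(nrow(tr), 10000)
  expect_equal(nrow(tr),
               max(2, ceiling(attr(tr, "truth")$dwell_s / 0.25)))
})

test_that("rendering: background level, peak position, superposition", {
  teth <- bare_tether()
  blank <- render_kymograph(list(), teth, n_lines = 100,
                            background_counts = 10, seed = 1)
  expect_lt(abs(mean(blank$channels$eGFP) - 10), 0.2)  # Poisson mean
  # one bright static emitter: maximal mean column = its pixel
  tr <- simulate_trajectory(
    emitter_model("static", start_position_um = 5.05,
                  photons_per_line = 5000), teth, 100, seed = 2)
  k <- render_kymograph(list(tr), teth, n_lines = 100, seed = 3)
  expect_equal(which.max(colMeans(k$channels$eGFP)) - 1L, 50L)
  # two emitters 20 px apart: two local maxima in the mean profile
  tr2 <- simulate_trajectory(
    emitter_model("static", start_position_um = 3.05,
                  photons_per_line = 5000), teth, 100, seed = 4)
  k2 <- render_kymograph(list(tr, tr2), teth, n_lines = 100, seed = 5)
  prof <- colMeans(k2$channels$eGFP)
  peaks <- which(diff(sign(diff(prof))) == -2) + 1L
  peaks <- peaks[prof[peaks] > 10 + 5 * sqrt(10) / 10]
  expect_length(peaks, 2L)
  # truth table accompanies the image
  expect_s3_class(attr(k2, "truth"), "data.frame")
  expect_equal(nrow(attr(k2, "truth")), 200L)
})

test_that("simulate_fec reduces to the eWLC and accumulates rips", {
  p <- ewlc_params()
  grid <- seq(2, 40, 0.2)
  f0 <- simulate_fec(p, noise_sd_nm = 0, seed = 1)
  expect_equal(f0$distance_um * 1000, ewlc_length(grid, p),
               tolerance = 1e-9)
  f1 <- simulate_fec(p, rips = data.frame(force_pN = 15, delta_bp = 147),
                     noise_sd_nm = 0, seed = 1)
  truth <- attr(f1, "truth")
  expect_equal(max(truth$Lc_nm) - min(truth$Lc_nm), 147 * 0.34)
  f2 <- simulate_fec(p, rips = data.frame(force_pN = c(12, 20),
                                          delta_bp = c(73.5, 147)),
                     noise_sd_nm = 0, seed = 1)
  expect_equal(max(attr(f2, "truth")$Lc_nm),
               p$Lc_nm + (73.5 + 147) * 0.34)
  expect_error(simulate_fec(p, rips = data.frame(force_pN = 99,
                                                 delta_bp = 10)),
               "within the force grid")
})

test_that("dwell simulation: sample mean, censoring tail, empty case", {
  d <- simulate_dwells(27.2, 1e5, seed = 8)
  expect_lt(abs(mean(d$duration_s) / 27.2 - 1), 0.01)
  dc <- simulate_dwells(20, 2e4, observation_limit_s = 10, seed = 9)
  expect_lt(abs(mean(dc$censored) - exp(-0.5)), 0.02)
  expect_equal(nrow(simulate_dwells(27.2, 0, seed = 1)), 0L)
  # frame discretization rounds up to frame multiples
  df <- simulate_dwells(5, 100, frame_s = 0.25, seed = 10)
  expect_true(all(df$duration_s %% 0.25 == 0))
})

test_that("bleach staircase has the requested structure", {
  t0 <- simulate_bleach_trace(0, noise = FALSE, seed = 1)
  expect_equal(length(unique(t0$intensity)), 1L)
  t3 <- simulate_bleach_trace(3, noise = FALSE, seed = 2)
  drops <- which(diff(t3$intensity) < 0)
  expect_length(drops, 3L)
  expect_equal(unname(t3$intensity[nrow(t3)]), 20)  # background after all steps
  expect_equal(attr(t3, "truth")$n_steps, 3L)
})

test_that("nucleation is Poisson with the stated mean and supports bias", {
  counts <- vapply(1:2000, function(r)
    nrow(simulate_nucleation(0.277, 5.374, 60, seed = r)), numeric(1))
  lambda <- 0.277 * 5.374  # 1.489 per 60 s window
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.05)
  expect_equal(nrow(simulate_nucleation(0, 5.374, 60, seed = 1)), 0L)
  # junction weight concentrating mass in the outer 600 nt of each edge
  w <- function(nt) ifelse(nt < 600 | nt > 5374 - 600, 10, 1)
  ev <- simulate_nucleation(20, 5.374, 600, junction_weight = w, seed = 5)
  outer_frac <- mean(ev$position_nt < 600 | ev$position_nt > 5374 - 600)
  expect_gt(outer_frac, 0.5)
})
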