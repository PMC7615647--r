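# kinetics: event detection, order classes, dwell fits, rates,
# positional profiles, collisions, mobile fractions.

planted_kymo <- function(bind_times_s, positions_um, n_lines = 250,
                         dwell_lines = 30, photons = 200, seed = 9) {
  teth <- bare_tether()
  trajs <- lapply(seq_along(bind_times_s), function(i) {
    tr <- simulate_trajectory(
      emitter_model("static", start_position_um = positions_um[i],
                    bind_time_s = bind_times_s[i],
                    photons_per_line = photons),
      teth, n_lines = dwell_lines, seed = seed + i)
    attr(tr, "id") <- i
    tr
  })
  render_kymograph(trajs, teth, n_lines = n_lines, seed = seed)
}

test_that("detect_events finds planted events with accurate extents", {
  starts <- c(10, 20, 30, 40, 50)
  k <- planted_kymo(starts, positions_um = 1:5 + 0.3)
  ev <- detect_events(k)
  expect_equal(nrow(ev), 5L)
  expect_lt(max(abs(ev$start_s - starts)), 1.01)     # within closing reach
  expect_lt(max(abs(ev$end_s - (starts + 29 * 0.25))), 0.51)
  expect_lt(max(abs(sort(ev$position_um) - (1:5 + 0.3))), 0.1)
  # event alive at the final line is censored
  k2 <- planted_kymo(55, 3, n_lines = 250, dwell_lines = 100)
  ev2 <- detect_events(k2)
  expect_equal(nrow(ev2), 1L)
  expect_true(ev2$censored)
  # blank kymograph: no events
  blank <- render_kymograph(list(), bare_tether(), n_lines = 150, seed = 3)
  expect_equal(nrow(detect_events(blank)), 0L)
})

test_that("event order classes cover all four configurations", {
  evA <- data.frame(channel = "BRCA2",
                    start_s = c(0, 10, 40, 80),
                    end_s = c(8, 30, 60, 95),
                    position_um = c(1, 2, 3, 4))
  evB <- data.frame(channel = "RAD51",
                    start_s = c(0.1, 20, 35, 50),
                    end_s = c(8, 30, 60, 60),
                    position_um = c(1.05, 2.02, 3.03, 9))
  out <- classify_event_order(evA, evB)
  expect_equal(as.character(out$classes),
               c("co_complex", "first_alone_then_partner",
                 "on_preassembled_partner", "alone"))
  # symmetry: simultaneous arrivals are co_complex from either side
  out_ba <- classify_event_order(evB[1, ], evA[1, ])
  expect_identical(as.character(out_ba$classes), "co_complex")
})

test_that("order-class proportions are recovered from a simulated mix", {
  withr::with_seed(21, {
    n <- 100
    simultaneous <- runif(n) < 0.8
    startA <- runif(n, 0, 100)
    startB <- ifelse(simultaneous, startA, startA + runif(n, 2, 5))
    pos <- seq_len(n) * 1.0  # spaced far beyond the coloc radius
  })
  evA <- data.frame(channel = "BRCA2", start_s = startA,
                    end_s = startA + 20, position_um = pos)
  evB <- data.frame(channel = "RAD51", start_s = startB,
                    end_s = startB + 20, position_um = pos + 0.01)
  out <- classify_event_order(evA, evB)
  p_co <- unname(out$proportions["co_complex"])
  expect_lt(abs(p_co - 0.8), 2 * sqrt(0.8 * 0.2 / n) + 1e-9)
  expect_equal(unname(out$counts["first_alone_then_partner"]),
               sum(!simultaneous))
})

test_that("fit_dwell recovers tau and reports degenerate fits", {
  d1 <- simulate_dwells(27.2, 1e4, seed = 31)
  expect_lt(abs(fit_dwell(d1)$tau_s / 27.2 - 1), 0.05)
  d2 <- simulate_dwells(101.9, 1e4, seed = 32)
  expect_lt(abs(fit_dwell(d2)$tau_s / 101.9 - 1), 0.05)
  expect_error(fit_dwell(1:5), "at least 10")
  # censored dwells are excluded from the histogram but reported
  dc <- simulate_dwells(30, 500, observation_limit_s = 40, seed = 33)
  f <- fit_dwell(dc)
  expect_equal(f$n_events + f$n_censored, 500L)
  expect_equal(f$n_censored, sum(dc$censored))
  # all-equal durations: tau still returned, fit quality reported
  f2 <- fit_dwell(rep(14, 50))
  expect_true(is.finite(f2$tau_s))
  expect_true(is.finite(f2$r_squared))
})

test_that("nucleation_rate is pure arithmetic on the early window", {
  expect_equal(nucleation_rate(numeric(), 5.374)$rate_per_knt_min, 0)
  r <- nucleation_rate(c(5, 20, 55), 5.374, 60)
  expect_equal(r$rate_per_knt_min, 3 / 5.374, tolerance = 1e-12)
  # events after the window are not counted; positions are irrelevant
  r2 <- nucleation_rate(c(5, 20, 55, 70, 90), 5.374, 60)
  expect_equal(r2$count, 3L)
  # linear in event count
  r3 <- nucleation_rate(c(5, 6, 7, 8, 9, 10), 5.374, 60)
  expect_equal(r3$rate_per_knt_min, 2 * nucleation_rate(c(5, 6, 7), 5.374,
                                                        60)$rate_per_knt_min)
})

test_that("binding_frequency normalizes by span and time", {
  f <- binding_frequency(c(1, 2, 3, 4, 5, 6), span_um = 3,
                         observation_s = 120)
  expect_equal(f$per_um_min, 1.0)
  expect_equal(binding_frequency(numeric(), 3, 120)$per_um_min, 0)
  f2 <- binding_frequency(c(1, 2, 3, 4, 5, 6), 3, 240)
  expect_equal(f2$per_um_min, f$per_um_min / 2)
  f3 <- binding_frequency(rep(1, 6), 3, 120, span_knt = 5.374)
  expect_equal(f3$per_knt_min, 6 / (5.374 * 2))
})

test_that("position_profile: bin structure, normalization, edge cases", {
  # uniform synthetic signal over the gap: all 27 bins ~ 1/27
  kg <- Kymograph(list(RAD51 = matrix(100, 40, 100)), 100, 0.25)
  pr <- position_profile(kg, "RAD51", gap_span_um = c(2, 3.827))
  expect_equal(nrow(pr), 27L)
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-9)
  expect_lt(max(abs(pr$fraction - 1 / 27)), 1e-9)
  # all signal concentrated in the outer 600 nt at the right end
  img <- matrix(0, 40, 100)
  gap_cols <- 21:38  # ~ c(2, 3.827) um at 100 nm px
  img[, 37:38] <- 500
  kg2 <- Kymograph(list(RAD51 = img + 1), 100, 0.25)
  pr2 <- position_profile(kg2, "RAD51", gap_span_um = c(2, 3.827))
  expect_gt(sum(pr2$fraction[24:27]), 0.97)
  # fractions sum to 1 regardless of content (invariant)
  expect_equal(sum(pr2$fraction), 1, tolerance = 1e-9)
  expect_equal(nrow(position_profile(kg, "RAD51", c(2, 3.827),
                                     gap_nt = 5400)), 27L)
})

test_that("junction_stat groups bins and detects junction bias", {
  kg <- Kymograph(list(RAD51 = matrix(100, 40, 100)), 100, 0.25)
  pr <- position_profile(kg, "RAD51", gap_span_um = c(2, 3.827))
  js <- junction_stat(pr)
  expect_equal(js$n_middle_bins, 21L)
  expect_equal(unname(js$means["junction_3p"]), unname(js$means["middle"]),
               tolerance = 1e-9)
  # synthetic 5'-biased profiles, n = 11 molecules: p < 0.05
  withr::with_seed(8, {
    profs <- lapply(1:11, function(i) {
      f <- rep(1, 27) + rnorm(27, 0, 0.05)
      f[25:27] <- f[25:27] + 1.5  # 5' edge is the last bins by default
      p <- data.frame(bin = 1:27, nt_lo = 0:26 * 200,
                      nt_hi = 1:27 * 200, fraction = f / sum(f))
      attr(p, "orientation") <- "left_3prime"
      class(p) <- c("PositionProfile", "data.frame")
      p
    })
  })
  js2 <- junction_stat(profs)
  expect_lt(js2$p_5p_vs_middle, 0.05)
  expect_gt(js2$means["junction_5p"], js2$means["middle"])
  # orientation flips which physical end is which junction
  flipped <- lapply(profs, function(p) {
    attr(p, "orientation") <- "left_5prime"; p
  })
  js3 <- junction_stat(flipped)
  expect_equal(unname(js3$means["junction_3p"]),
               unname(js2$means["junction_5p"]))
})

test_that("collision outcomes: none, blocked, dissociated, bypass rate", {
  far <- Trajectory((0:49) * 0.25, rep(1, 50))
  expect_equal(sum(collision_outcomes(far, 5)$counts), 0L)
  # reflecting obstacle, bypass prob 0: collisions but no bypasses
  teth <- tether_model(total_bp = 40000, gap_start_nt = NULL,
                       obstacle_positions_um = 5, bead_margin_px = 0)
  n_coll <- 0
  for (r in 1:10) {
    tr <- simulate_trajectory(
      emitter_model("diffusive", D_um2_s = 0.08, start_position_um = 4.7),
      teth, 1000, seed = 400 + r)
    co <- collision_outcomes(tr, 5, approach_radius_um = 0.2)
    expect_equal(unname(co$counts["bypassed"]), 0L)
    n_coll <- n_coll + sum(co$counts)
  }
  expect_gt(n_coll, 0)
  # track ending inside the radius is a dissociation
  died <- Trajectory((0:9) * 0.25, seq(4, 4.95, length.out = 10))
  co2 <- collision_outcomes(died, 5, 0.2)
  expect_equal(unname(co2$counts["dissociated_at_obstacle"]), 1L)
  # with bypass probability, the bypass fraction is recovered
  tethb <- tether_model(total_bp = 40000, gap_start_nt = NULL,
                        obstacle_positions_um = 6.8, bypass_prob = 0.05,
                        bead_margin_px = 0)
  tot <- c(blocked = 0, bypassed = 0, dissociated_at_obstacle = 0)
  for (r in 1:40) {
    tr <- simulate_trajectory(
      emitter_model("diffusive", D_um2_s = 0.08, start_position_um = 6.5),
      tethb, 500, seed = 600 + r)
    tot <- tot + collision_outcomes(tr, 6.8, 0.2)$counts
  }
  n <- sum(tot)
  p_hat <- tot[["bypassed"]] / n
  expect_lt(abs(p_hat - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 0.02)
})

test_that("diffusive_fraction assigns regions by majority residence", {
  gap <- c(4, 6)
  mk_traj <- function(pos) Trajectory((0:19) * 0.25, rep(pos, 20))
  mk_fit <- function(cls) structure(list(D_um2_s = 0.04, alpha = 1,
                                         motion_class = cls),
                                    class = "DiffusionFit")
  trajs <- list(mk_traj(5), mk_traj(5.2), mk_traj(1), mk_traj(8))
  fits <- list(mk_fit("static"), mk_fit("static"),
               mk_fit("free"), mk_fit("free"))
  out <- diffusive_fraction(trajs, fits, gap)
  tab <- out$table
  expect_equal(tab$fraction_mobile[tab$region == "ssDNA"], 0)
  expect_equal(tab$fraction_mobile[tab$region == "dsDNA"], 1)
  expect_equal(tab$n, c(2L, 2L))
  # all static: fraction 0; constructed half-mobile: 0.5
  out2 <- diffusive_fraction(list(mk_traj(5), mk_traj(5)),
                             list(mk_fit("static"), mk_fit("free")), gap)
  expect_equal(out2$table$fraction_mobile[1], 0.5)
})
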