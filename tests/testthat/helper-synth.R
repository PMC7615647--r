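# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures.

# Ungapped tether without bead margins, convenient for event tests.
bare_tether <- function(total_bp = 20000, ...)
  tether_model(total_bp = total_bp, gap_start_nt = NULL,
               bead_margin_px = 0, ...)

# Render a kymograph with n static emitters at given positions.
static_kymo <- function(positions_um, n_lines = 200, photons = 200,
                        tether = bare_tether(), seed = 1, ...) {
  trajs <- lapply(seq_along(positions_um), function(i) {
    tr <- simulate_trajectory(
      emitter_model("static", start_position_um = positions_um[i],
                    photons_per_line = photons),
      tether, n_lines = n_lines, seed = seed + i)
    attr(tr, "id") <- i
    tr
  })
  render_kymograph(trajs, tether, n_lines = n_lines, seed = seed, ...)
}

# Independent brute-force O(N^2) time-averaged MSD oracle.
msd_oracle <- function(x) {
  N <- length(x)
  vapply(seq_len(N - 1L), function(n) {
    s <- 0
    for (i in seq_len(N - n)) s <- s + (x[i + n] - x[i])^2
    s / (N - n)
  }, numeric(1))
}

random_trajectory <- function(N, dt = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Trajectory((seq_len(N) - 1) * dt, cumsum(stats::rnorm(N, 0, 0.1)))
}
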