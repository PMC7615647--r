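# Extensible worm-like-chain (eWLC) mechanics: force-extension modelling,
# rupture ("rip") detection on the implied-contour-length trace, and
# conversion of contour-length changes to base pairs.

#' eWLC parameter set
#'
#' Parameters of the high-force extensible worm-like chain
#' `L(F) = Lc * (1 - 1/2 * sqrt(kBT / (F * Lp)) + F / S)`.
#' Defaults are the values used for lambda dsDNA in the source
#' experiments: Lp = 100 nm, S = 1000 pN, T = 297 K, 0.34 nm/bp (note the
#' textbook dsDNA Lp is ~50 nm; Lp is an ordinary field, not a constant).
#'
#' @param Lc_nm Contour length (nm); alternatively give `n_bp`.
#' @param n_bp Number of base pairs (Lc = n_bp * rise_per_bp).
#' @param Lp_nm Persistence length (nm).
#' @param S_pN Stretch modulus (pN).
#' @param T_K Absolute temperature (K).
#' @param rise_per_bp nm per base pair.
#' @return List of class `EWLCParams` with derived `kBT_pN_nm`
#'   (1.380649e-2 pN nm/K * T, ~4.100 pN nm at 297 K).
#' @export
ewlc_params <- function(Lc_nm = NULL, n_bp = 48502, Lp_nm = 100,
                        S_pN = 1000, T_K = 297, rise_per_bp = 0.34) {
  if (is.null(Lc_nm)) Lc_nm <- n_bp * rise_per_bp
  for (v in c(Lc_nm, Lp_nm, S_pN, T_K, rise_per_bp))
    stopifnot(is.finite(v), v > 0)
  structure(list(Lc_nm = Lc_nm, Lp_nm = Lp_nm, S_pN = S_pN, T_K = T_K,
                 rise_per_bp = rise_per_bp,
                 kBT_pN_nm = 1.380649e-2 * T_K),
            class = "EWLCParams")
}

#' eWLC extension at a given force
#'
#' Closed-form evaluation of
#' `L = Lc * (1 - 1/2 * sqrt(kBT/(F*Lp)) + F/S)`; monotone increasing in F
#' over the working range and linear in Lc.
#'
#' @param F_pN Force (pN), > 0 (vectorized).
#' @param p An [ewlc_params()].
#' @return Extension in nm.
#' @export
ewlc_length <- function(F_pN, p) {
  stopifnot(inherits(p, "EWLCParams"))
  if (any(F_pN <= 0)) stop("force must be positive")
  p$Lc_nm * (1 - 0.5 * sqrt(p$kBT_pN_nm / (F_pN * p$Lp_nm)) +
               F_pN / p$S_pN)
}

# Relative extension L/Lc at force F: the force-dependent factor g(F).
ewlc_rel_ext <- function(F_pN, p)
  1 - 0.5 * sqrt(p$kBT_pN_nm / (F_pN * p$Lp_nm)) + F_pN / p$S_pN

#' Fit the eWLC contour length to a force-extension curve
#'
#' Least squares over Lc only (Lp, S, T fixed); since the model is linear
#' in Lc the solution is closed-form. Samples are restricted to the given
#' force window (default 2-40 pN, the model's working range).
#'
#' @param curve A [ForceExtensionCurve].
#' @param p An [ewlc_params()] carrying the fixed Lp, S, T.
#' @param force_range_pN Window of forces used for the fit.
#' @return List: `Lc_nm`, `residual_rms_nm`, `n_samples`, `params`.
#' @export
fit_ewlc <- function(curve, p = ewlc_params(),
                     force_range_pN = c(2, 40)) {
  stopifnot(inherits(curve, "ForceExtensionCurve"))
  sel <- curve$force_pN >= force_range_pN[1] &
         curve$force_pN <= force_range_pN[2]
  if (sum(sel) < 5L) stop("need at least 5 samples in the force window")
  g <- ewlc_rel_ext(curve$force_pN[sel], p)
  d_nm <- curve$distance_um[sel] * 1000
  Lc <- sum(d_nm * g) / sum(g^2)
  resid <- d_nm - Lc * g
  list(Lc_nm = Lc, residual_rms_nm = sqrt(mean(resid^2)),
       n_samples = sum(sel), params = p)
}

#' Detect contour-length rips in a force-extension curve
#'
#' Converts each sample to its implied contour length
#' `Lc_i = distance_i / g(F_i)` (with `g` the eWLC relative extension),
#' then segments that sequence into piecewise-constant levels
#' ([segment_stepwise()]). Adjacent-segment increases of at least
#' `min_delta_Lc_nm` are emitted as rips, with the rupture force taken at
#' the segment boundary. Segmenting implied Lc rather than raw distance
#' makes the step height directly the released contour length,
#' independent of force.
#'
#' @param curve A [ForceExtensionCurve] from a monotone pull.
#' @param p An [ewlc_params()].
#' @param min_delta_Lc_nm Minimum contour-length release to report (nm).
#' @param force_range_pN Forces analysed (model validity window).
#' @param min_segment,penalty_factor Segmentation controls.
#' @return Data frame of class `RipEvent`: `force_pN`, `delta_Lc_nm`,
#'   `delta_bp`, plus attribute `segments` (per-segment Lc table).
#' @export
detect_rips <- function(curve, p = ewlc_params(), min_delta_Lc_nm = 10,
                        force_range_pN = c(2, 60), min_segment = 3L,
                        penalty_factor = 3) {
  stopifnot(inherits(curve, "ForceExtensionCurve"))
  sel <- which(curve$force_pN >= force_range_pN[1] &
               curve$force_pN <= force_range_pN[2])
  f <- curve$force_pN[sel]
  if (any(diff(f) < 0)) stop("pull must be monotone in force")
  lc <- curve$distance_um[sel] * 1000 / ewlc_rel_ext(f, p)
  cps <- segment_stepwise(lc, min_segment = min_segment,
                          penalty_factor = penalty_factor)
  bounds <- c(0L, cps, length(lc))
  seg <- data.frame(
    Lc_nm = vapply(seq_len(length(bounds) - 1L), function(i)
      mean(lc[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1)),
    f_lo = f[utils::head(bounds, -1) + 1L],
    f_hi = f[bounds[-1]])
  keep <- integer(0); dl <- numeric(0); rf <- numeric(0)
  if (length(cps)) {
    d <- diff(seg$Lc_nm)
    keep <- which(d >= min_delta_Lc_nm)
    dl <- d[keep]
    rf <- f[cps[keep]]
  }
  out <- data.frame(force_pN = rf, delta_Lc_nm = dl,
                    delta_bp = dl / p$rise_per_bp)
  attr(out, "segments") <- seg
  class(out) <- c("RipEvent", "data.frame")
  out
}

#' Convert a contour-length release to base pairs
#'
#' `delta_bp = delta_Lc_nm / rise_per_bp`; a full nucleosomal unwrap of
#' 147 bp corresponds to ~50 nm, a single wrap (73.5 bp) to ~25 nm.
#'
#' @param delta_Lc_nm Contour-length change (nm), or a `RipEvent` table.
#' @param rise_per_bp nm per base pair.
#' @return Base pairs released (numeric, vectorized).
#' @export
rip_to_bp <- function(delta_Lc_nm, rise_per_bp = 0.34) {
  if (is.data.frame(delta_Lc_nm)) delta_Lc_nm <- delta_Lc_nm$delta_Lc_nm
  delta_Lc_nm / rise_per_bp
}

#' Classify a tether as intact dsDNA or gapped
#'
#' Compares the measured force-extension curve with the all-dsDNA eWLC
#' prediction at the supplied parameters; if the RMS deviation over the
#' force window exceeds `residual_threshold_nm` the tether is called
#' `"gapped"` (an internal ssDNA segment makes the tether longer and
#' softer than pure dsDNA). This is a comparison against the dsDNA model,
#' not a composite ss+ds fit.
#'
#' @param curve A [ForceExtensionCurve].
#' @param p_ds [ewlc_params()] of the expected intact dsDNA tether.
#' @param residual_threshold_nm RMS deviation threshold (nm).
#' @param force_range_pN Comparison window (needs >= 5 pN of span).
#' @return List: `class` (`"intact_ds"` or `"gapped"`),
#'   `residual_rms_nm`, `threshold_nm`.
#' @export
classify_tether <- function(curve, p_ds = ewlc_params(),
                            residual_threshold_nm = 100,
                            force_range_pN = c(2, 40)) {
  stopifnot(inherits(curve, "ForceExtensionCurve"))
  sel <- curve$force_pN >= force_range_pN[1] &
         curve$force_pN <= force_range_pN[2]
  if (diff(range(curve$force_pN[sel])) < 5)
    stop("curve must span at least 5 pN within the comparison window")
  pred <- ewlc_length(curve$force_pN[sel], p_ds)
  rms <- sqrt(mean((curve$distance_um[sel] * 1000 - pred)^2))
  list(class = if (rms > residual_threshold_nm) "gapped" else "intact_ds",
       residual_rms_nm = rms, threshold_nm = residual_threshold_nm)
}
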