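---
title: "Models, estimators and design choices in kymoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in kymoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kymoquant` quantifies dual-trap confocal experiments on DNA tethers:
kymograph particle tracking, MSD/diffusion analysis, binding and
nucleation kinetics, photobleaching step counting, and extensible
worm-like-chain (eWLC) force-extension analysis. This vignette records
the models behind each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology was genuinely open. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The imaging model and the synthetic generator

A kymograph is a stack of confocal line scans along a stretched DNA
molecule: rows are scan lines (time), columns are position. The
generator (`simulate_trajectory()`, `render_kymograph()`) emulates:

- a tether mapped linearly from base pairs to micrometres at the dsDNA
  rise (0.34 nm/bp). The default substrate is a 48,502-bp λ molecule
  with a 5,374-nt internal ssDNA gap; nucleosomes are reflecting point
  obstacles with an optional bypass probability (default 0, matching the
  observed >90% blocking of sliding molecules);
- emitters that are **static**, **diffusive** (Gaussian increments of
  variance 2·D·Δt per line, reflecting at tether ends and obstacles;
  experimentally relevant D ≈ 0.01–0.1 µm²s⁻¹, mean ≈ 0.040), or
  **directed** (constant drift); trajectories truncate at the smaller of
  an exponential dwell and an exponential photobleaching draw;
- imaging at 100 nm/pixel and 0.25 s/line (1 s for nucleation runs),
  with each emitter contributing a pixel-integrated 1D Gaussian PSF
  (σ default 1.3 px) per line, constant mean background, and Poisson
  photon noise; bead contours are rendered as saturated edge columns.

**Photon budget.** The source experiments state no photon counts, so
brightness is a free parameter expressed as SNR — the pixel-integrated
PSF peak over the background Poisson SD. `photons_for_snr(5)` (~53
photons/line on a background of 10) is the default; this is the one
deliberately invented quantity in the generator and all recovery
claims are quoted at a stated SNR.

**What is *not* emulated:** blinking/triplet photophysics (only
single-exponential bleaching), tether elasticity fluctuations and bead
motion, chromatic offsets between channels, non-uniform background
(e.g. Sytox gradients), and intensity variation along a diffusing
trace. A green recovery test therefore establishes correctness of the
estimators under the stated statistical model, not robustness to every
instrumental artifact.

Every simulator takes an explicit integer seed, restores the caller's
RNG state, is bit-reproducible, and attaches its ground truth as an
attribute; recovery tests consume only the rendered data.

## 2. Tracking

The tracker reproduces the source procedure: the image is cropped at
the saturated bead contours (`crop_beads()`, coordinates preserved via
`origin_offset`), and the sub-pixel position in each scan line is
obtained by fitting a 1D Gaussian plus offset to the column profile
averaged over a centred 3-line moving window (`localize()`,
`window_frames = 3`).

Choices the source leaves open, and what we did:

- **Moving window interpretation.** "Fitting a three-frame moving
  window" is read as fitting the 3-line-averaged profile (noise
  reduction); `window_frames = 1` exposes the per-line alternative.
  The window matters: for a diffuser the 3-line average reports a
  motion-averaged position. Two consequences, both visible in the test
  suite: (i) instantaneous positions of fast diffusers
  (D ≈ 0.04 µm²s⁻¹ at 0.25 s lines, step SD ≈ 1.4 px) deviate from the
  window average by ~0.5 px, so frame-accurate sub-pixel recovery
  criteria are meaningful only for the static/slow population; (ii) the
  induced short-lag correlation biases the anomaly exponent α upward
  (the MSD acquires a negative offset). For MSD work on fast diffusers
  use `window_frames = 1`; the default stays 3 for fidelity to the
  source and for dim/static emitters, where it is clearly superior
  (at SNR 5 it is what makes localization possible at all).
- **Detection.** Candidate peaks must exceed a robust local background
  (median of the lowest intensity quartile) by 3 robust SDs (MAD of the
  profile). Accepted fits must additionally have width within
  `sigma_bounds_px` (0.7–3 px; the physical PSF is ~1.3 px, and narrow
  single-pixel noise spikes otherwise pass) and amplitude ≥ 5 profile
  SDs (`min_amplitude_sd`): detection at 3 SD finds candidates, but a
  *fitted* amplitude near the detection floor is overwhelmingly a noise
  fluctuation. With these gates a flat-background image yields zero
  localizations while SNR-5 emitters are retained at >95%.
- **Duplicate suppression.** Fits whose centres fall within 2 px
  (~1.5 PSF widths, unresolvable) are collapsed to the brightest;
  without this, duplicate fits of one emitter seed competing tracks
  that steal each other's future (observed as trajectory
  fragmentation).
- **Linking.** Greedy nearest-neighbour, gate 0.5 µm per line (≫ the
  ~0.14 µm per-line step at D = 0.04), up to 3 missed lines, minimum 10
  localizations, ties broken deterministically by smaller column.
  Global assignment (Hungarian) is unnecessary at the molecule
  densities of these experiments.
- **Overlap exclusion.** The source analyses "non-overlapping" parts of
  trajectories without defining overlap; frames where two tracks come
  within 3 px (configurable) are flagged `msd_eligible = FALSE`.
- **Smoothing.** Savitzky–Golay window 51, polynomial order 3 (order
  unstated in the source; order 3 is the common default and preserves
  cubic trends exactly). Trajectories not longer than the window are
  returned unsmoothed and flagged. Smoothing is applied for
  average-speed estimation, not before MSD fitting.

## 3. MSD and diffusion coefficients

`compute_msd()` implements the standard overlapping time average,
MSD(n) = Σᵢ₌₁^{N−n} (Xᵢ₊ₙ − Xᵢ)² / (N−n), n = 1…N−1, verified
exactly against an independent brute-force double loop. Sampling must
be uniform; linked tracks with gaps are split (`split_uniform()`).

`fit_msd()` does unweighted OLS of MSD against τ on the window
0.25 s < τ < 2 s (strict inequalities, following the source text; at
0.25-s lines this uses lags 0.5–1.75 s). The window excludes the
noise-dominated first lag and confinement effects of the finite tether
at long lags. Per-lag weighting is deliberately absent (the source
states none); pair counts are reported so weighted fits can be added.

**Slope convention.** The source prints the fit as "MSD = D·t + b",
making D the slope — a factor 2 from the physical 1D law MSD = 2Dτ.
Both are implemented: `convention = "paper"` (default, reproduces the
printed numbers) and `"physical"` (D = slope/2); every fit records
which was used. Which convention produced the printed D values cannot
be determined from the text.

The anomaly exponent α comes from log–log OLS on the same window; the
linear vs power-law description is chosen by r². Classification
(`classify_motion()`): static if D ≤ 0.01 µm²s⁻¹ (the first histogram
bin, as in the source's "corrected" analysis), directed if α > 1.2
(margin 0.2 above 1; the source states no margin), free otherwise.
`ensemble_D()` summarizes per-molecule fits (mean, t-based 95% CI,
0.01-wide histogram, static fraction) and can exclude the static bin —
it never alters individual fits. The condition-series regression
(`regress_condition()`, e.g. D vs [NaCl] or binding frequency vs force)
is weighted least squares on per-condition means with sample-size
weights; per-molecule values (not pooled MSDs) are the inputs, the
default reading of the source's salt regression.

## 4. Kinetics

- **Event detection** (`detect_events()`): the source scored events
  manually in Fiji; a reproducible rule is required. An event is an
  8-connected component of pixels above background + 3 robust SDs,
  after a 2-line × 2-px morphological closing that bridges blinking
  gaps. Components need ≥ 12 above-threshold pixels (rejects noise
  excursions); extent is delimited by lines holding ≥ 2 event pixels so
  a stray bridged pixel cannot stretch an event's timing. Events
  touching the last line are censored.
- **Order classes** (`classify_event_order()`): co-complex arrival if
  the two channels appear within 1 line and 2 px (diffraction-limited
  colocalization at 100 nm/px); otherwise classified by which channel
  was bound first; symmetric under channel relabelling for simultaneous
  arrivals.
- **Dwell times** (`fit_dwell()`): uncensored durations binned at 7 s,
  histogram fit with A·exp(−t/τ) at bin centres by least squares, as in
  the source. Binning does not bias τ (the expected bin contents decay
  geometrically with the same τ), and recovery at the source's sample
  sizes (n = 104, τ = 27.2 s; n = 62, τ = 101.9 s) is within 10% in
  median — both checked in the acceptance suite. Censored dwells are
  excluded (a histogram fit cannot use them) but counted, so a
  survival-based estimate can be compared later. Photobleaching is not
  corrected for.
- **Nucleation rate** (`nucleation_rate()`): count of nuclei appearing
  within the first 60 s (or 120 s) divided by gap length (knt) and
  window (min). The estimator is exactly linear in the count. For the
  *bias* acceptance check, replicate duration is chosen a priori by
  power analysis — ~25 expected events per replicate, so the pooled
  Monte-Carlo SE (1/√total events) is ≈0.6%, well under the 2% budget;
  at the 60-s window and 0.003 knt⁻¹min⁻¹ the MC noise alone would be
  ~25% and the check would measure noise, not bias. The 60-s/120-s
  windows remain the defaults for real data.
- **Positional profiles** (`position_profile()`): background-subtracted
  per-pixel intensity integrated over the analysis window, mapped
  linearly to nucleotides across the 5,374-nt gap, aggregated into
  200-nt bins. 5,374 = 26 × 200 + 174: the final partial bin is kept
  and rescaled to per-200-nt density before normalization, avoiding
  systematic under-weighting of one junction. Fractions sum to 1 within
  1e-9 (tested invariant). Which physical end is the 5′ junction cannot
  be inferred from the image; `orientation` is required metadata.
  `junction_stat()` compares the 3+3 junction bins against the 21
  middle bins across molecules with paired t tests.
- **Collisions** (`collision_outcomes()`): an approach episode is a
  maximal run of samples within 2 px of an obstacle; it ends as
  *bypassed* (exit on the far side), *dissociated at obstacle* (track
  ends inside), or *blocked*.

## 5. Photobleaching step counting

The source cites single-step photobleaching analysis without describing
the algorithm, so `count_steps()` uses deterministic penalized binary
segmentation under a piecewise-constant mean model: a split is accepted
when it lowers the RSS by more than `penalty_factor · σ̂² · log n`
(BIC-style), minimum segment 3 lines, minimum step 2 robust SDs.

Two numerical points:

- **Variance stabilization.** Photon noise is heteroscedastic
  (variance ≈ level), so a global σ̂ over- or under-penalizes depending
  on which level dominates the trace. Segmentation therefore runs on
  2·√(y − min(y) + 1) (an Anscombe-type transform, shifted for offset
  invariance), where Poisson noise has approximately constant SD; level
  means and step heights are then read off the raw trace. This is what
  makes the ≥90% exact-recovery criterion attainable; on the raw trace
  the bright-level fluctuations of a mostly-dark trace generate
  spurious steps.
- **Resolvability.** Coincident bleaching events are indistinguishable
  in principle, and the 3-line minimum segment sets a resolution floor.
  The generator (`simulate_bleach_trace()`) draws exponential event
  spacings but redraws until successive bleach frames are ≥ 5 lines
  apart and inside the trace — it emulates the *resolvable* staircases
  used for stoichiometry counting, and the recovery criterion tests the
  counter, not identifiability. This was decided before any recovery
  measurement.

An upward step is an arrival of new fluorophores; only the prefix
before the first arrival is analysed. `oligomer_distribution()`
tabulates counts per spot (the source observes monomers and dimers
predominating but prints no fractions, so no quantitative target
exists).

## 6. eWLC mechanics

`ewlc_length()` evaluates L(F) = L_c·(1 − ½·√(k_BT/(F·L_p)) + F/S),
the high-force extensible WLC. Defaults follow the source: L_p =
100 nm, S = 1000 pN, T = 297 K (k_BT ≈ 4.10 pN·nm), 0.34 nm/bp.
**Note** the textbook dsDNA persistence length is ~50 nm; 100 nm may be
a transcription slip in the source, so L_p is an ordinary config field
and every output records the parameters used. The model is valid above
~2 pN (the ½√· term exceeds 1 at very low force) and below
overstretching; fits default to 2–40 pN.

`fit_ewlc()` fits L_c only (the model is linear in L_c, so the LS
solution is closed-form). `detect_rips()` converts each sample to its
implied contour length L_c,i = dᵢ/g(Fᵢ) (g the relative extension) and
segments *that* sequence — step heights are then directly the released
contour length, force-independent — reusing the change-point machinery
of Section 5 (no variance stabilization: distance noise is
homoscedastic). Releases ≥ 10 nm become rips; ΔL_c/0.34 gives bp
(147 bp ↔ ~50 nm, single wrap 73.5 bp ↔ ~25 nm). `classify_tether()`
follows the source's procedure of *comparing* a curve against the
all-dsDNA model (RMS deviation over the window vs a 100-nm threshold)
rather than fitting a composite ss+ds model; a gapped tether reads
longer and softer than pure dsDNA.

The rip simulator adds stepwise contour length at each planted rupture
force plus Gaussian distance noise; in rare cases (<1% of samples at
the 1-nm default) noise would invert adjacent distances, and the
sample is nudged by 1e-9 µm to keep pulls strictly monotone.

## 7. I/O and reproducibility

TIFF support (uncompressed multi-page grayscale, little-endian float32
or uint16, JSON metadata sidecar) is implemented in the package because
the supported R stack ships no TIFF reader; conformance is
cross-checked in the test suite against an independent external reader.
Metadata (pixel size, line time, channel names) is always explicit —
the two imaging modes of the source (0.25 s vs 1 s lines) make
inference from data unsafe. CSVs are written at full double precision
and round-trip exactly. `run_pipeline()` snapshots the config, derives
per-stage seeds from the single run seed, logs per-stage counts, and
writes md5 checksums; identical snapshots reproduce identical
checksums.

λ-gap arithmetic: `locate_nick_sites()` / `nick_site_separation()`
implement SpCas9 nick geometry (blunt cut between protospacer positions
17 and 18, 3 bp 5′ of the NGG PAM) on both strands. They are verified
on synthetic sequences with planted protospacers; the real λ genome is
not bundled (it is an external reference the offline build cannot
fetch), so the acceptance check that reproduces the 5,374-nt gap from
the printed crRNA spacers fails with an explanatory message unless the
genome is supplied.

## 8. Known limitations

- The tracker is 1D by construction (kymographs); no drift correction,
  no intensity-weighted centroid fallback, no global assignment.
- D estimation uses OLS on the time-averaged MSD; covariance-based
  estimators (CVE/MLE) would have lower variance and are out of scope.
- Dwell fitting ignores censoring and photobleaching; τ estimates are
  biased low when bleaching competes with dissociation (the source
  notes the same limitation for its eGFP constructs).
- The eWLC omits the full Marko–Siggia interpolation and overstretching;
  gapped tethers are detected, not modelled (no freely-jointed-chain
  ssDNA term).
- Recovery guarantees are proven under the generator's model (Section
  1); instrument-specific artifacts are untested.
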