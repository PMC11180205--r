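# sen1kin

Single-molecule kinetic analysis of Sen1-dependent RNA polymerase II
transcription termination.

In two-color single-molecule fluorescence assays, a stalled Pol II
elongation complex (RNA labeled with Cy3, DNA or Sen1 with Cy5, under
alternating green/red laser excitation) is terminated by the Sen1
helicase. The observable record per molecule is a pair of intensity
traces from which FRET and protein-induced fluorescence enhancement
(PIFE) report the kinetic state: elongation, stalling, formation of the
Sen1–Pol II intermediate, RNA release, and the fate of the polymerase
afterwards. `sen1kin` implements the full analysis chain for such data —
and a ground-truth simulator of it — for researchers who want to fit
dwell-time kinetics of termination (or similar binding–catalysis
reactions) reproducibly:

* **Simulation** (`simulate_pathway()`, `render_trajectory()`,
  `simulate_dataset()`): a stochastic state machine draws per-molecule
  event times — Gaussian elongation, exponential Sen1 arrival at rate
  k₊·[Sen1], hypoexponential intermediate lifetime, branching polymerase
  fates, exponential post-termination dwells, exponential photobleaching —
  and renders them as noisy ALEX intensity traces with embedded truth.
* **Trace processing** (`compute_fret()`, `correct_fret()`,
  `pife_ratio()`, `segment_trace()`, `extract_dwells()`,
  `classify_pol2_fate()`, `termination_efficiency()`): proximity-ratio
  FRET, the PIFE-corrected FRET′ = FRET / (r·(1−FRET) + FRET),
  threshold/hysteresis segmentation into state segments, dwell tables
  with censoring flags, co-dissociation lag and fate classification.
* **Dwell-time models** (`pdf_single_exp()`, `pdf_exp_bleach()`,
  `pdf_smmm_bleach()`, `pdf_two_step()`): the waiting-time densities of
  the kinetic scheme. The single-molecule Michaelis–Menten density for a
  binding–catalysis cycle with binding rate k₊⁰ = k₊·S, reversal k₋ and
  turnover k_cat is

      f(τ) = (k₊⁰ k_cat / 2a) · [e^{(a+b)τ} − e^{(b−a)τ}] + B·e^{−τ/t₀},
      a = sqrt(¼(k₊⁰+k₋+k_cat)² − k₊⁰k_cat),  b = −½(k₊⁰+k₋+k_cat),

  which at k₋ = 0 reduces to the two-step hypoexponential
  f(τ) = k₁k₂/(k₂−k₁)·(e^{−k₁τ} − e^{−k₂τ}) with mean 1/k₁ + 1/k₂.
* **Fitting** (`fit_global_ls()`, `fit_mle()`, `fit_mle_global()`,
  `fit_mm_weighted()`, `fit_gaussian_peak()`, `fit_exp_rate()`,
  `fit_diffusion_models()`): global histogram least squares with held
  concentrations and shared rates, maximum likelihood with optional
  right-censoring, 1/SEM²-weighted classical Michaelis–Menten secondary
  fits k(S) = k_max·S/(K_m+S), and a 1D-vs-3D first-passage diffusion
  comparison (mean capture lifetime L²/2D with a constant capture
  fraction, against L²/6D with fraction ∝ 1/L) for post-termination
  polymerase sliding.

## Worked example

Fit the bundled per-ATP translocation-rate estimates with the weighted
Michaelis–Menten model, then estimate the helicase translocation rate
over the ~14 nt it covers before contacting the polymerase:

```r
library(sen1kin)

pts <- atp_titration_k1()          # ATP (uM), k (s^-1), sem, n
fit <- fit_mm_weighted(pts$atp_uM, pts$k, pts$sem)
fit
#> Fit (mm_curve)  reduced chi-square = 0.817, points = 4, free = 2
#>        estimate         se
#> k_max  5.862725  0.9109287
#> K_m   40.309730 13.2713558

translocation_rate(fit$estimates[["k_max"]], 14)
#> [1] 82.07816
```

The saturating stepping rate is k_max ≈ 5.9 s⁻¹ with K_m ≈ 40 µM, and
the implied translocation rate is ≈ 82 nt/s. A simulation-and-recovery
round trip for the two-step intermediate lifetime:

```r
k2 <- 8.69                          # shared catalytic release rate, s^-1
samples <- lapply(seq_len(nrow(pts)), function(i)
  sample_dwells("two_step", list(k1 = pts$k[i], k2 = k2), pts$n[i],
                seed = 20260931 + i))
fit_mle_global(samples, share = "k2")$estimates[["k2"]]
#> [1] 8.808877
```

## Analysis workflow

The `analysis/` scripts run the whole chain end to end and write their
tables under `results/` (bulky per-frame and per-dwell tables go to
`scratch/`):

1. `01_simulate.R` — simulate an ATP titration (4 × 200 molecules) with
   known ground truth.
2. `02_process.R` — segment traces, extract dwell tables, classify
   polymerase fates, compute the termination efficiency.
3. `03_fit_dwell_models.R` — global binding and two-step fits on
   simulated dwells; weighted Michaelis–Menten secondary fits; derived
   translocation/elongation rates.
4. `04_diffusion.R` — 1D-vs-3D diffusion comparison for post-termination
   sliding and the co-dissociation lag-zero extrapolation.

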