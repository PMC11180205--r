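#' Dwell-time densities and secondary-rate curves
#'
#' Closed-form waiting-time densities for the kinetic states of
#' Sen1-mediated Pol II transcription termination, plus the classical
#' Michaelis-Menten saturation curve and first-passage diffusion models
#' used as secondary fits.
#'
#' @name dwell_models
NULL

#' Known dwell-time model identifiers
#'
#' @return Character vector of model ids accepted by [sample_dwells()] and
#'   the fitting front-ends.
#' @export
dwell_model_ids <- function() {
  c("single_exp", "exp_bleach", "smmm", "smmm_bleach", "two_step",
    "mm_curve", "diffusion_1d", "diffusion_3d")
}

#' Single-exponential dwell density
#'
#' Waiting-time density for rate-limiting bimolecular binding at rate
#' `k_plus * S`: `A * exp(-k_plus * S * tau)`. The amplitude `A` is a free
#' fit parameter, not a normalization constant.
#'
#' @param tau Dwell time(s), seconds; must be non-negative.
#' @param A Amplitude (density units).
#' @param k_plus Second-order binding rate constant (M^-1 s^-1).
#' @param S Concentration of the binding species (M).
#' @return Density value(s), same length as `tau`.
#' @export
pdf_single_exp <- function(tau, A, k_plus, S) {
  stopifnot(all(tau >= 0), k_plus * S > 0)
  A * exp(-k_plus * S * tau)
}

#' Photobleaching-corrected single-exponential dwell density
#'
#' Adds an exponential photobleaching background of mean `t0` to the
#' binding exponential: `A*exp(-k_plus*S*tau) + B*exp(-tau/t0)`.
#'
#' @inheritParams pdf_single_exp
#' @param B Bleach-background amplitude.
#' @param t0 Mean photobleaching time of the reporter dye (s); held at its
#'   independently measured value during fits.
#' @return Density value(s).
#' @export
pdf_exp_bleach <- function(tau, A, k_plus, S, B, t0) {
  stopifnot(all(tau >= 0), t0 > 0)
  A * exp(-k_plus * S * tau) + B * exp(-tau / t0)
}

#' Single-molecule Michaelis-Menten dwell density with photobleaching
#'
#' Waiting-time density of one binding-catalysis turnover (binding at
#' `k_plus*S`, dissociation before catalysis at `k_minus`, turnover at
#' `k_cat`), plus an exponential bleaching background. The kinetic part
#' integrates to one. Writing `k0 = k_plus*S` and
#' `b = -(k0 + k_minus + k_cat)/2`,
#' `a = sqrt(b^2 - k0*k_cat)`, the density is
#' `k0*k_cat/(2a) * (exp((a+b)tau) - exp((b-a)tau)) + B*exp(-tau/t0)`.
#' The degenerate case `a = 0` (i.e. `k_minus = 0`, `k0 = k_cat`) is
#' evaluated through its analytic limit `k^2 * tau * exp(-k*tau)`.
#'
#' @inheritParams pdf_exp_bleach
#' @param k_minus Dissociation-before-catalysis rate (s^-1).
#' @param k_cat Catalytic turnover rate (s^-1).
#' @param B Bleach amplitude; set 0 for the pure kinetic density.
#' @return Density value(s).
#' @export
pdf_smmm_bleach <- function(tau, k_plus, S, k_minus, k_cat, B = 0, t0 = 237) {
  stopifnot(all(tau >= 0), k_minus >= 0, k_cat > 0, t0 > 0)
  k0 <- k_plus * S
  stopifnot(k0 > 0)
  b <- -(k0 + k_minus + k_cat) / 2
  a2 <- b^2 - k0 * k_cat
  # a2 >= (k0 - k_cat)^2/4 >= 0 for non-negative rates
  a <- sqrt(max(a2, 0))
  kinetic <- if (a < 1e-8 * abs(b)) {
    k <- -b
    k^2 * tau * exp(-k * tau)
  } else {
    (k0 * k_cat / (2 * a)) * (exp((a + b) * tau) - exp((b - a) * tau))
  }
  kinetic + B * exp(-tau / t0)
}

#' Hypoexponential (two-step) dwell density
#'
#' Density of the sum of two sequential exponential waits with rates `k1`
#' (ATP-dependent translocation) and `k2` (single-ATP catalytic release):
#' `k1*k2/(k2-k1) * (exp(-k1*tau) - exp(-k2*tau))`. Symmetric in (k1, k2);
#' the equal-rate limit `k^2*tau*exp(-k*tau)` is used when
#' `|k1 - k2| < 1e-8 * max(k1, k2)` to avoid catastrophic cancellation.
#'
#' @param tau Dwell time(s), seconds.
#' @param k1,k2 Step rates (s^-1), strictly positive.
#' @return Density value(s); integrates to one over `[0, Inf)`.
#' @export
pdf_two_step <- function(tau, k1, k2) {
  stopifnot(all(tau >= 0), k1 > 0, k2 > 0)
  if (abs(k1 - k2) < 1e-8 * max(k1, k2)) {
    k <- (k1 + k2) / 2
    k^2 * tau * exp(-k * tau)
  } else {
    (k1 * k2 / (k2 - k1)) * (exp(-k1 * tau) - exp(-k2 * tau))
  }
}

#' Mean of the hypoexponential two-step distribution
#'
#' @inheritParams pdf_two_step
#' @return `1/k1 + 1/k2`, seconds.
#' @export
hypoexp_mean <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  1 / k1 + 1 / k2
}

#' Classical Michaelis-Menten saturation curve
#'
#' @param S Substrate concentration (any unit, consistent with `K_m`).
#' @param k_max Saturating rate (s^-1).
#' @param K_m Michaelis constant (same unit as `S`).
#' @return Rate `k_max * S / (K_m + S)`.
#' @export
mm_curve <- function(S, k_max, K_m) {
  stopifnot(all(S >= 0), K_m > 0)
  k_max * S / (K_m + S)
}

#' Base pairs to micrometres for B-form DNA
#'
#' Fixed rise of 0.34 nm per base pair.
#'
#' @param bp Length in base pairs.
#' @return Length in micrometres.
#' @export
bp_to_um <- function(bp) bp * 0.34e-3

#' First-passage lifetime of post-termination polymerase diffusion
#'
#' Mean time for a polymerase released at the termination site to reach a
#' probe at distance `L`. Under 1D sliding the mean first-passage time is
#' `L^2 / (2 D)`; the 3D comparison model scales as `L^2 / (6 D)`.
#'
#' @param L Distance, micrometres (convert from bp with [bp_to_um()]).
#' @param D Diffusion coefficient (um^2 s^-1).
#' @param model `"1d"` (default) or `"3d"`.
#' @return Mean lifetime, seconds.
#' @export
diffusion_lifetime <- function(L, D, model = c("1d", "3d")) {
  model <- match.arg(model)
  stopifnot(all(L >= 0), D > 0)
  denom <- if (model == "1d") 2 else 6
  L^2 / (denom * D)
}

#' Capture fraction of post-termination polymerase diffusion
#'
#' Under 1D sliding the probability of reaching the probe before
#' dissociating is taken as a distance-independent constant `f_capture`;
#' the 3D alternative decays with distance as `c / L`.
#'
#' @inheritParams diffusion_lifetime
#' @param params Named list: `f_capture` for `"1d"`, `c` for `"3d"`.
#' @return Capture fraction(s).
#' @export
diffusion_fraction <- function(L, model = c("1d", "3d"), params) {
  model <- match.arg(model)
  if (model == "1d") {
    rep_len(params$f_capture, length(L))
  } else {
    pmin(params$c / pmax(L, .Machine$double.eps), 1)
  }
}

# Evaluate a registered dwell density for a parameter list; used by the
# samplers, the fitters and the model-registry round trips.
eval_dwell_pdf <- function(model_id, tau, pars) {
  switch(model_id,
    single_exp = pdf_single_exp(tau, A = pars$A %||% (pars$k_plus * pars$S),
                                k_plus = pars$k_plus, S = pars$S),
    exp_bleach = pdf_exp_bleach(tau, A = pars$A %||% (pars$k_plus * pars$S),
                                k_plus = pars$k_plus, S = pars$S,
                                B = pars$B %||% 0, t0 = pars$t0 %||% 237),
    smmm = ,
    smmm_bleach = pdf_smmm_bleach(tau, k_plus = pars$k_plus, S = pars$S,
                                  k_minus = pars$k_minus %||% 0,
                                  k_cat = pars$k_cat, B = pars$B %||% 0,
                                  t0 = pars$t0 %||% 237),
    two_step = pdf_two_step(tau, pars$k1, pars$k2),
    stop("unknown model_id: ", model_id)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
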