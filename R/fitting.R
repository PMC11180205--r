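#' Build a dwell-time histogram
#'
#' Fixed-width bins starting at zero. The default width is
#' `max(min_width, range/30)`, with `min_width` defaulting to one channel
#' frame period (40 ms).
#'
#' @param dwells A [dwell_sample()] (or numeric vector), n >= 10.
#' @param width Bin width in seconds; computed from the default rule if
#'   `NULL`.
#' @param min_width Lower bound on the default bin width.
#' @return A `dwell_histogram`: list with `bin_edges`, `mids`, `counts`,
#'   `density` (counts / (n * width)), `width`, `n`.
#' @export
build_histogram <- function(dwells, width = NULL, min_width = 0.04) {
  x <- if (inherits(dwells, "dwell_sample")) dwells$durations else dwells
  n <- length(x)
  if (n < 10) stop("need at least 10 dwells to histogram")
  if (is.null(width)) width <- max(min_width, diff(range(x)) / 30)
  edges <- seq(0, (ceiling(max(x) / width) + 1) * width, by = width)
  counts <- as.integer(table(cut(x, edges, include.lowest = TRUE,
                                 right = TRUE)))
  structure(list(bin_edges = edges, mids = utils::head(edges, -1) + width / 2,
                 counts = counts, density = counts / (n * width),
                 width = width, n = n),
            class = "dwell_histogram")
}

# Levenberg-Marquardt engine with box bounds and a deterministic
# multi-start spread; returns the best converged solution.
ls_engine <- function(resid_fn, start, lower, upper, n_starts = 5) {
  spreads <- exp(seq(-1, 1, length.out = n_starts))
  best <- NULL
  for (s in spreads) {
    st <- pmin(pmax(start * s, lower + 1e-12), ifelse(is.finite(upper),
                                                      upper, start * s))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

pick_start <- function(start, name, default) {
  if (!is.null(start) && name %in% names(start)) start[[name]] else default
}

fit_result <- function(model_id, estimates, ses, covariance, reduced_chisq,
                       n_points, n_free, converged, extra = list()) {
  structure(c(list(model_id = model_id, estimates = estimates, ses = ses,
                   covariance = covariance, reduced_chisq = reduced_chisq,
                   n_points = n_points, n_free = n_free,
                   converged = converged), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit (", x$model_id, ")  reduced chi-square = ",
      formatC(x$reduced_chisq, digits = 3), ", points = ", x$n_points,
      ", free = ", x$n_free, "\n", sep = "")
  est <- data.frame(estimate = x$estimates,
                    se = x$ses[names(x$estimates)])
  print(est, ...)
  invisible(x)
}

# covariance and SEs from an nls.lm fit, scaled by reduced chi-square;
# the hessian is equilibrated before inversion because rate and amplitude
# parameters can differ by many orders of magnitude
lm_covariance <- function(fit, n_points) {
  n_free <- length(fit$par)
  dof <- max(n_points - n_free, 1)
  redchi <- fit$deviance / dof
  cv <- tryCatch({
    h <- fit$hessian
    d <- sqrt(pmax(diag(h), .Machine$double.xmin))
    solve(h / (d %o% d)) / (d %o% d) * redchi
  }, error = function(e) matrix(NA_real_, n_free, n_free))
  list(cov = cv, ses = sqrt(pmax(diag(cv), 0)), reduced_chisq = redchi,
       dof = dof)
}

#' Global least-squares fit of dwell histograms with shared parameters
#'
#' Minimizes the Poisson-weighted sum of squares
#' `sum(((count - model * n * width) / sqrt(max(count, 1)))^2)` over all
#' conditions and bins. Kinetic rate parameters are shared across
#' conditions; per-condition amplitudes (and bleach amplitudes) are free;
#' concentrations and the photobleaching time are held.
#'
#' Supported models: `"single_exp"` (free `A` per condition,
#' shared `k_plus`, held `S`), `"exp_bleach"` (adds free `B` per condition
#' and held `t0`), `"smmm_bleach"` (single-molecule Michaelis-Menten with
#' free amplitude `A` and `B` per condition, shared `k_plus` and
#' optionally `k_minus`, held `k_cat`, `S`, `t0`), and `"two_step"`
#' (normalized hypoexponential scaled by `n * width`; one rate shared, the
#' other free per condition per `share`).
#'
#' @param histograms List of `dwell_histogram`, one per condition.
#' @param model_id Model identifier (see Details).
#' @param S Numeric vector of held concentrations (M), one per histogram
#'   (exponential and Michaelis-Menten models).
#' @param hold Named list of held parameters (`t0`, `k_cat`, `k_minus`).
#' @param share For `"two_step"`: which rate is shared across conditions,
#'   `"k2"` (default) or `"k1"`.
#' @param start Optional named numeric vector of starting values for the
#'   shared parameters.
#' @param weighting Bin-error model: `"pearson"` (default for the
#'   amplitude-carrying models) refits once with sigma taken from the
#'   previous pass's predicted counts, which removes the small-count bias
#'   of observed-count weights; `"neyman"` uses
#'   `sigma = sqrt(max(count, 1))` throughout (default for the
#'   amplitude-free two-step density, where predicted-count weights are
#'   degenerate).
#' @return A `fit_result`; `estimates` holds the shared parameter(s) and
#'   the per-condition free parameters (named `A.1`, `B.2`, `k1.3`, ...).
#' @export
fit_global_ls <- function(histograms, model_id, S = NULL, hold = list(),
                          share = c("k2", "k1"), start = NULL,
                          weighting = NULL) {
  share <- match.arg(share)
  if (is.null(weighting))
    weighting <- if (model_id == "two_step") "neyman" else "pearson"
  weighting <- match.arg(weighting, c("pearson", "neyman"))
  stopifnot(length(histograms) >= 1)
  nc <- length(histograms)
  counts <- lapply(histograms, `[[`, "counts")
  mids <- lapply(histograms, `[[`, "mids")
  widths <- vapply(histograms, `[[`, numeric(1), "width")
  ns <- vapply(histograms, `[[`, numeric(1), "n")
  sig <- lapply(counts, function(cc) sqrt(pmax(cc, 1)))
  n_points <- sum(lengths(counts))

  if (model_id %in% c("single_exp", "exp_bleach", "smmm_bleach")) {
    stopifnot(length(S) == nc)
    t0 <- hold$t0 %||% 237
  }

  build <- switch(model_id,
    single_exp = {
      # par = (k_plus, A_1..A_nc)
      A0 <- vapply(seq_len(nc), function(i) max(counts[[i]]) /
                     (ns[i] * widths[i]), numeric(1))
      k0 <- pick_start(start, "k_plus", 1 / (mean(unlist(mids)) * mean(S)))
      list(par = c(k_plus = unname(k0), A = A0),
           lower = rep(0, 1 + nc), upper = rep(Inf, 1 + nc),
           fn = function(p) {
             unlist(lapply(seq_len(nc), function(i) {
               pred <- pdf_single_exp(mids[[i]], p[1 + i], p[1], S[i]) *
                 ns[i] * widths[i]
               (counts[[i]] - pred) / sig[[i]]
             }))
           })
    },
    exp_bleach = {
      A0 <- vapply(seq_len(nc), function(i) max(counts[[i]]) /
                     (ns[i] * widths[i]), numeric(1))
      k0 <- pick_start(start, "k_plus", 1 / (mean(unlist(mids)) * mean(S)))
      # par = (k_plus, A_1..A_nc, B_1..B_nc)
      list(par = c(k_plus = unname(k0), A = A0, B = A0 / 10),
           lower = rep(0, 1 + 2 * nc), upper = rep(Inf, 1 + 2 * nc),
           fn = function(p) {
             unlist(lapply(seq_len(nc), function(i) {
               pred <- pdf_exp_bleach(mids[[i]], p[1 + i], p[1], S[i],
                                      p[1 + nc + i], t0) * ns[i] * widths[i]
               (counts[[i]] - pred) / sig[[i]]
             }))
           })
    },
    smmm_bleach = {
      k_cat <- hold$k_cat %||% stop("smmm_bleach requires held k_cat")
      k_minus <- hold$k_minus   # NULL means free (shared)
      free_km <- is.null(k_minus)
      A0 <- rep(1, nc)
      k0 <- pick_start(start, "k_plus", 1 / (mean(unlist(mids)) * mean(S)))
      par <- c(k_plus = unname(k0),
               if (free_km) c(k_minus = 0.01), A = A0, B = A0 / 50)
      np <- length(par)
      off <- 1L + free_km
      list(par = par, lower = rep(0, np), upper = rep(Inf, np),
           fn = function(p) {
             km <- if (free_km) p[2] else k_minus
             unlist(lapply(seq_len(nc), function(i) {
               kin <- pdf_smmm_bleach(mids[[i]], p[1], S[i], km, k_cat,
                                      B = 0, t0 = t0)
               pred <- (p[off + i] * kin +
                          p[off + nc + i] * exp(-mids[[i]] / t0)) *
                 ns[i] * widths[i]
               (counts[[i]] - pred) / sig[[i]]
             }))
           })
    },
    two_step = {
      held_shared <- hold[[share]]   # hold the shared rate instead of fitting
      shared0 <- pick_start(start, share, 2 / mean(unlist(mids)))
      free0 <- rep(1 / mean(unlist(mids)), nc)
      par <- if (is.null(held_shared))
        c(stats::setNames(unname(shared0), share), free = free0)
      else c(free = free0)
      off <- as.integer(is.null(held_shared))
      list(par = par, lower = rep(1e-6, length(par)),
           upper = rep(Inf, length(par)),
           fn = function(p) {
             sh <- if (is.null(held_shared)) p[1] else held_shared
             unlist(lapply(seq_len(nc), function(i) {
               k1 <- if (share == "k2") p[off + i] else sh
               k2 <- if (share == "k2") sh else p[off + i]
               pred <- pdf_two_step(mids[[i]], k1, k2) * ns[i] * widths[i]
               (counts[[i]] - pred) / sig[[i]]
             }))
           })
    },
    stop("unsupported model for global fit: ", model_id))

  fit <- ls_engine(build$fn, build$par, build$lower, build$upper)
  if (weighting == "pearson" && !is.null(fit)) {
    # second pass: sigma from the first pass's predicted counts
    res1 <- build$fn(fit$par)
    pos <- 1L
    for (i in seq_len(nc)) {
      nb <- length(counts[[i]])
      pred <- counts[[i]] - res1[pos:(pos + nb - 1)] * sig[[i]]
      sig[[i]] <- sqrt(pmax(pred, 1))
      pos <- pos + nb
    }
    fit2 <- ls_engine(build$fn, fit$par, build$lower, build$upper,
                      n_starts = 1)
    if (!is.null(fit2)) fit <- fit2
  }
  if (is.null(fit)) {
    return(fit_result(model_id, build$par, rep(NA_real_, length(build$par)),
                      NULL, NA_real_, n_points, length(build$par), FALSE))
  }
  est <- fit$par
  if (model_id == "two_step") {
    free_nm <- paste0(if (share == "k2") "k1" else "k2", ".", seq_len(nc))
    names(est) <- if (length(est) == nc) free_nm else c(share, free_nm)
  } else {
    base <- if (model_id == "smmm_bleach" && is.null(hold$k_minus))
      c("k_plus", "k_minus") else "k_plus"
    amp <- if (model_id == "single_exp") paste0("A.", seq_len(nc))
           else c(paste0("A.", seq_len(nc)), paste0("B.", seq_len(nc)))
    names(est) <- c(base, amp)
  }
  cv <- lm_covariance(fit, n_points)
  ses <- stats::setNames(cv$ses, names(est))
  fit_result(model_id, est, ses, cv$cov, cv$reduced_chisq, n_points,
             length(est), fit$info %in% 1:4,
             extra = list(share = if (model_id == "two_step") share else NULL))
}

#' Maximum-likelihood fit of a dwell sample
#'
#' Fits the normalized kinetic density (no amplitude, no bleach term) by
#' maximizing the log-likelihood, with optional right-censoring handled
#' through survival terms. For `single_exp` the uncensored MLE is the
#' closed form `rate = 1 / mean`; with censoring it is
#' `events / total time`. Standard errors come from the observed
#' information.
#'
#' @param dwells A [dwell_sample()].
#' @param model_id `"single_exp"` or `"two_step"`.
#' @param censoring Use the sample's censoring flags (default `FALSE`:
#'   censored dwells are dropped).
#' @return A `fit_result` with the rate estimate(s).
#' @export
fit_mle <- function(dwells, model_id = c("single_exp", "two_step"),
                    censoring = FALSE) {
  model_id <- match.arg(model_id)
  x <- dwells$durations
  cen <- dwells$censored
  if (!censoring) { x <- x[!cen]; cen <- rep(FALSE, length(x)) }
  n <- length(x)
  if (n < 10) stop("need at least 10 dwells")
  if (model_id == "single_exp") {
    k <- sum(!cen) / sum(x)
    se <- k / sqrt(sum(!cen))
    ll <- sum(log(k) * (!cen)) - k * sum(x)
    return(fit_result("single_exp", c(rate = k), c(rate = se),
                      matrix(se^2, dimnames = list("rate", "rate")),
                      NA_real_, n, 1, TRUE, extra = list(loglik = ll)))
  }
  surv_two_step <- function(t, k1, k2) {
    if (abs(k1 - k2) < 1e-8 * max(k1, k2)) {
      k <- (k1 + k2) / 2
      (1 + k * t) * exp(-k * t)
    } else {
      (k2 * exp(-k1 * t) - k1 * exp(-k2 * t)) / (k2 - k1)
    }
  }
  nll <- function(lp) {
    k1 <- exp(lp[1]); k2 <- exp(lp[2])
    d <- pdf_two_step(x[!cen], k1, k2)
    s <- if (any(cen)) surv_two_step(x[cen], k1, k2) else numeric(0)
    -(sum(log(pmax(d, 1e-300))) + sum(log(pmax(s, 1e-300))))
  }
  m <- mean(x)
  opt <- stats::optim(log(c(1.5 / m, 3 / m)), nll, method = "BFGS",
                      hessian = TRUE)
  k <- sort(exp(opt$par))  # report k1 <= k2 by convention
  ord <- order(exp(opt$par))
  # delta method: cov(k) = diag(k) H^-1 diag(k) on the log scale
  cv_log <- tryCatch(solve(opt$hessian),
                     error = function(e) matrix(NA_real_, 2, 2))
  cv <- diag(exp(opt$par)) %*% cv_log %*% diag(exp(opt$par))
  cv <- cv[ord, ord, drop = FALSE]
  est <- stats::setNames(k, c("k1", "k2"))
  dimnames(cv) <- list(names(est), names(est))
  fit_result("two_step", est, sqrt(pmax(diag(cv), 0)), cv, NA_real_, n, 2,
             opt$convergence == 0, extra = list(loglik = -opt$value))
}

#' Weighted classical Michaelis-Menten fit
#'
#' Least squares on `k(S) = k_max * S / (K_m + S)` with weights
#' `1 / sem^2`; standard errors from the chi-square-scaled covariance.
#'
#' @param S Substrate concentrations (>= 3 distinct values).
#' @param k Observed rates (s^-1).
#' @param sem Standard errors of `k` (> 0).
#' @return A `fit_result` with `k_max` and `K_m`.
#' @export
fit_mm_weighted <- function(S, k, sem) {
  stopifnot(length(S) >= 3, length(k) == length(S),
            length(sem) == length(S), all(sem > 0))
  if (length(unique(S)) < 3) stop("need at least 3 distinct S values")
  w <- 1 / sem^2
  fit <- stats::nls(k ~ k_max * S / (K_m + S),
                    start = list(k_max = max(k), K_m = stats::median(S)),
                    weights = w,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  sm <- summary(fit)
  co <- sm$coefficients
  est <- stats::setNames(co[, "Estimate"], rownames(co))
  ses <- stats::setNames(co[, "Std. Error"], rownames(co))
  dof <- length(S) - 2
  redchi <- sum(w * stats::residuals(fit)^2) / dof
  fit_result("mm_curve", est, ses, stats::vcov(fit), redchi, length(S), 2,
             fit$convInfo$isConv %||% TRUE)
}

#' Gaussian peak fit to binned durations
#'
#' Bins the durations and fits `A * exp(-(x - mu)^2 / (2 sd^2))` to the
#' counts; returns the peak location and its standard error. If the
#' nonlinear fit fails, the sample mean and its standard error are
#' returned with `converged = FALSE`.
#'
#' @param durations Numeric durations, n >= 30.
#' @param width Histogram bin width (default rule of [build_histogram()]).
#' @return A `fit_result` with `peak`, `sd`, `amplitude`.
#' @export
fit_gaussian_peak <- function(durations, width = NULL) {
  n <- length(durations)
  if (n < 30) stop("need at least 30 durations")
  h <- build_histogram(durations, width = width)
  x <- h$mids; y <- h$counts
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
               start = list(A = max(y), mu = mean(durations),
                            s = stats::sd(durations)),
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    m <- mean(durations)
    return(fit_result("gaussian_peak",
                      c(peak = m, sd = stats::sd(durations),
                        amplitude = max(y)),
                      c(peak = stats::sd(durations) / sqrt(n),
                        sd = NA_real_, amplitude = NA_real_),
                      NULL, NA_real_, length(y), 3, FALSE))
  }
  co <- summary(fit)$coefficients
  est <- c(peak = unname(co["mu", "Estimate"]),
           sd = abs(unname(co["s", "Estimate"])),
           amplitude = unname(co["A", "Estimate"]))
  ses <- c(peak = unname(co["mu", "Std. Error"]),
           sd = unname(co["s", "Std. Error"]),
           amplitude = unname(co["A", "Std. Error"]))
  rss <- sum(stats::residuals(fit)^2)
  fit_result("gaussian_peak", est, ses, stats::vcov(fit),
             rss / max(length(y) - 3, 1), length(y), 3, TRUE)
}

#' Single-exponential rate of a dwell sample
#'
#' Default maximum-likelihood route: `rate = 1 / mean`,
#' `SE = rate / sqrt(n)`. The `"ls"` route fits `A * exp(-k tau)` to the
#' histogram with Poisson weights.
#'
#' @param dwells A [dwell_sample()] (or numeric vector), n >= 10.
#' @param method `"mle"` (default) or `"ls"`.
#' @return A `fit_result` with `rate` (s^-1).
#' @export
fit_exp_rate <- function(dwells, method = c("mle", "ls")) {
  method <- match.arg(method)
  x <- if (inherits(dwells, "dwell_sample")) dwells$durations else dwells
  n <- length(x)
  if (n < 10) stop("need at least 10 dwells")
  if (method == "mle") {
    k <- 1 / mean(x)
    return(fit_result("single_exp", c(rate = k), c(rate = k / sqrt(n)),
                      matrix((k / sqrt(n))^2,
                             dimnames = list("rate", "rate")),
                      NA_real_, n, 1, TRUE))
  }
  h <- build_histogram(x)
  sig <- sqrt(pmax(h$counts, 1))
  fn <- function(p) (h$counts - p[1] * exp(-p[2] * h$mids)) / sig
  fit <- ls_engine(fn, c(A = max(h$counts), k = 1 / mean(x)),
                   lower = c(0, 1e-9), upper = c(Inf, Inf))
  cv <- lm_covariance(fit, length(h$counts))
  fit_result("single_exp",
             c(rate = unname(fit$par[2]), A = unname(fit$par[1])),
             c(rate = cv$ses[2], A = cv$ses[1]), cv$cov,
             cv$reduced_chisq, length(h$counts), 2, fit$info %in% 1:4)
}

#' Compare 1D and 3D diffusion models of post-termination sliding
#'
#' Jointly fits the mean capture lifetime and capture fraction versus
#' probe distance for (i) 1D sliding — lifetime `L^2/(2D)`, constant
#' fraction — and (ii) a 3D alternative — lifetime `L^2/(6D)`, fraction
#' `c/L` — by error-weighted least squares, and prefers the model with
#' the lower reduced chi-square.
#'
#' @param points Data frame with columns `L_um` (or `L_bp`),
#'   `mean_lifetime`, `lifetime_se`, `fraction`, `fraction_se`; >= 3 rows.
#' @return List: `fits` (named `fit_result` per model), `preferred`
#'   (`"1d"` or `"3d"`).
#' @export
fit_diffusion_models <- function(points) {
  if (nrow(points) < 3) stop("need at least 3 distances")
  L <- points$L_um %||% bp_to_um(points$L_bp)
  fit_one <- function(model) {
    denom <- if (model == "1d") 2 else 6
    fn <- function(p) {
      lt <- L^2 / (denom * p[1])
      fr <- if (model == "1d") rep(p[2], length(L)) else pmin(p[2] / L, 1)
      c((points$mean_lifetime - lt) / points$lifetime_se,
        (points$fraction - fr) / points$fraction_se)
    }
    start <- c(D = stats::median(L^2 / (denom * points$mean_lifetime)),
               p2 = if (model == "1d") mean(points$fraction)
                    else mean(points$fraction * L))
    fit <- ls_engine(fn, start, lower = c(1e-12, 0), upper = c(Inf, Inf))
    cv <- lm_covariance(fit, 2 * length(L))
    nm <- c("D", if (model == "1d") "f_capture" else "c")
    fit_result(paste0("diffusion_", model),
               stats::setNames(fit$par, nm), stats::setNames(cv$ses, nm),
               cv$cov, cv$reduced_chisq, 2 * length(L), 2,
               fit$info %in% 1:4)
  }
  fits <- list(`1d` = fit_one("1d"), `3d` = fit_one("3d"))
  preferred <- names(fits)[which.min(vapply(fits, `[[`, numeric(1),
                                            "reduced_chisq"))]
  list(fits = fits, preferred = preferred)
}

#' Derived kinetic quantities
#'
#' Simple arithmetic the kinetic analysis reports: helicase translocation
#' rate from a saturating stepping rate and a track length, polymerase
#' elongation rate from a transcribed length and its duration, and the
#' catalytic rate as the inverse mean intermediate lifetime.
#'
#' @param k_max Saturating rate, s^-1.
#' @param length_nt Track length, nt.
#' @return `translocation_rate()`: nt/s.
#' @export
translocation_rate <- function(k_max, length_nt) {
  stopifnot(k_max > 0, length_nt > 0)
  k_max * length_nt
}

#' @rdname translocation_rate
#' @param length_bp Transcribed length, bp.
#' @param duration_s Duration, s (> 0).
#' @return `elongation_rate()`: bp/s.
#' @export
elongation_rate <- function(length_bp, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  length_bp / duration_s
}

#' @rdname translocation_rate
#' @param mean_lifetime_s Mean intermediate lifetime, s (> 0).
#' @return `k_cat_from_mean()`: s^-1.
#' @export
k_cat_from_mean <- function(mean_lifetime_s) {
  if (mean_lifetime_s <= 0) stop("mean lifetime must be > 0")
  1 / mean_lifetime_s
}

#' Global maximum-likelihood fit of two-step dwell samples
#'
#' Jointly fits the normalized hypoexponential density to several
#' conditions with one rate shared across conditions and the other free
#' per condition — the default estimator for the amplitude-free two-step
#' model. Standard errors come from the observed information (delta method
#' on the log-rate scale).
#'
#' @param samples List of [dwell_sample()] objects (or numeric vectors),
#'   one per condition.
#' @param share Which rate is shared: `"k2"` (default) or `"k1"`.
#' @return A `fit_result` with the shared rate and per-condition free
#'   rates (named like `k1.1`, `k1.2`, ...).
#' @export
fit_mle_global <- function(samples, share = c("k2", "k1")) {
  share <- match.arg(share)
  xs <- lapply(samples, function(s)
    if (inherits(s, "dwell_sample")) s$durations[!s$censored] else s)
  nc <- length(xs)
  stopifnot(nc >= 1, all(lengths(xs) >= 10))
  nll <- function(lp) {
    sh <- exp(lp[1])
    -sum(vapply(seq_len(nc), function(i) {
      k1 <- if (share == "k2") exp(lp[1 + i]) else sh
      k2 <- if (share == "k2") sh else exp(lp[1 + i])
      sum(log(pmax(pdf_two_step(xs[[i]], k1, k2), 1e-300)))
    }, numeric(1)))
  }
  m <- mean(unlist(xs))
  # deterministic multi-start over the shared-rate scale
  best <- NULL
  for (f in c(1.5, 3, 6)) {
    st <- log(c(f / m, rep(1.5 / m, nc)))
    opt <- tryCatch(stats::optim(st, nll, method = "BFGS", hessian = TRUE,
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("global MLE failed to converge")
  k <- exp(best$par)
  cv_log <- tryCatch(solve(best$hessian),
                     error = function(e)
                       matrix(NA_real_, nc + 1, nc + 1))
  cv <- diag(k) %*% cv_log %*% diag(k)
  free_nm <- paste0(if (share == "k2") "k1" else "k2", ".", seq_len(nc))
  est <- stats::setNames(k, c(share, free_nm))
  dimnames(cv) <- list(names(est), names(est))
  fit_result("two_step", est, sqrt(pmax(diag(cv), 0)), cv, NA_real_,
             sum(lengths(xs)), nc + 1, best$convergence == 0,
             extra = list(loglik = -best$value, share = share))
}
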