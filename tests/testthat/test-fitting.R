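test_that("histogram construction: counts, density normalization, analytic bins", {
  set.seed(1)
  x <- runif(100, 0, 10)
  h <- build_histogram(x, width = 1)
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$density * h$width), 1, tolerance = 1e-12)
  expect_error(build_histogram(1:5), "at least 10")

  # first-bin density matches the bin-averaged exponential pdf
  rate <- 0.055
  set.seed(2)
  y <- rexp(1e4, rate)
  h <- build_histogram(y)
  p1 <- (pexp(h$bin_edges[2], rate) - pexp(0, rate))
  expected_density <- p1 / h$width
  se <- sqrt(p1 * (1 - p1) / 1e4) / h$width
  expect_lt(abs(h$density[1] - expected_density), 3 * se)
})

test_that("global exponential fit is exact on noise-free binned curves", {
  k_plus <- 5.5e6
  S <- c(3.5e-9, 5e-9, 10e-9)
  hists <- lapply(S, function(s) {
    edges <- seq(0, 200, by = 2)
    mids <- head(edges, -1) + 1
    A <- k_plus * s
    counts <- 500 * 2 * A * exp(-A * mids)   # n * width * density
    list(bin_edges = edges, mids = mids, counts = counts,
         density = counts / (500 * 2), width = 2, n = 500)
  })
  fit <- fit_global_ls(hists, "single_exp", S = S)
  expect_lt(abs(fit$estimates[["k_plus"]] - k_plus) / k_plus, 1e-3)
  expect_lt(fit$reduced_chisq, 1e-10)
})

test_that("global exponential fit recovers the binding constant from dwells", {
  k_plus <- 5.5e6
  des <- sen1_titration_design()
  hists <- vector("list", nrow(des))
  for (i in seq_len(nrow(des))) {
    d <- sample_dwells("single_exp",
                       list(k_plus = k_plus, S = des$sen1_M[i]),
                       des$n[i], seed = 40 + i)
    hists[[i]] <- build_histogram(d)
  }
  fit <- fit_global_ls(hists, "single_exp", S = des$sen1_M)
  expect_lt(abs(fit$estimates[["k_plus"]] - k_plus) / k_plus, 0.10)
  expect_true(fit$converged)
  expect_true(all(fit$ses >= 0, na.rm = TRUE))
})

test_that("global two-step fit recovers the shared catalytic rate", {
  pts <- atp_titration_k1()
  k2 <- 8.69
  hists <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- sample_dwells("two_step", list(k1 = pts$k[i], k2 = k2),
                       pts$n[i], seed = 50 + i)
    hists[[i]] <- build_histogram(d, width = 0.04)
  }
  fit <- fit_global_ls(hists, "two_step", share = "k2")
  expect_lt(abs(fit$estimates[["k2"]] - k2) / k2, 0.25)
})

test_that("reduced chi-square of a correctly specified fit is near one", {
  set.seed(7)
  redchis <- vapply(1:100, function(r) {
    d <- sample_dwells("single_exp", list(rate = 0.055), 400,
                       seed = 1000 + r)
    h <- build_histogram(d)
    fit <- fit_global_ls(list(h), "single_exp", S = 1e-8)
    fit$reduced_chisq
  }, numeric(1))
  expect_gt(mean(redchis), 0.7)
  expect_lt(mean(redchis), 1.4)
})

test_that("MLE: closed form for exponential, consistent recovery for two-step", {
  d <- dwell_sample(rexp(100, 2) + 1e-9)
  fit <- fit_mle(d, "single_exp")
  expect_equal(fit$estimates[["rate"]], 1 / mean(d$durations))

  d2 <- sample_dwells("two_step", list(k1 = 2.20, k2 = 8.69), 1e4,
                      seed = 61)
  fit2 <- fit_mle(d2, "two_step")
  expect_lt(abs(fit2$estimates[["k1"]] - 2.20), 3 * fit2$ses[["k1"]])
  expect_lt(abs(fit2$estimates[["k2"]] - 8.69), 3 * fit2$ses[["k2"]])

  # LS-histogram and MLE agree on the same large sample
  h <- build_histogram(d2, width = 0.04)
  fls <- fit_global_ls(list(h), "two_step", share = "k2")
  se_comb <- sqrt(fls$ses[["k2"]]^2 + fit2$ses[["k2"]]^2)
  expect_lt(abs(fls$estimates[["k2"]] - fit2$estimates[["k2"]]),
            2 * se_comb)
})

test_that("censored MLE uses survival terms", {
  set.seed(62)
  x <- rexp(2000, 0.5)
  cens <- rexp(2000, 0.1)
  obs <- pmin(x, cens)
  d <- dwell_sample(obs, censored = cens < x)
  fit <- fit_mle(d, "single_exp", censoring = TRUE)
  expect_lt(abs(fit$estimates[["rate"]] - 0.5), 3 * fit$ses[["rate"]])
  # dropping censored observations overestimates the rate
  fit_drop <- fit_mle(d, "single_exp", censoring = FALSE)
  expect_gt(fit_drop$estimates[["rate"]], fit$estimates[["rate"]])
})

test_that("weighted Michaelis-Menten fit is exact on noise-free data", {
  S <- c(10, 50, 200, 1000)
  k <- mm_curve(S, 5, 50)
  fit <- suppressWarnings(fit_mm_weighted(S, k, rep(1, 4)))
  expect_equal(fit$estimates[["k_max"]], 5, tolerance = 1e-6)
  expect_equal(fit$estimates[["K_m"]], 50, tolerance = 1e-6)
  expect_error(fit_mm_weighted(c(1, 2), c(1, 2), c(1, 1)))
})

test_that("weighted Michaelis-Menten fits reproduce the published titrations", {
  p1 <- atp_titration_k1()
  f1 <- fit_mm_weighted(p1$atp_uM, p1$k, p1$sem)
  expect_equal(f1$estimates[["k_max"]], 5.9, tolerance = 0.02)
  expect_equal(f1$estimates[["K_m"]], 40, tolerance = 0.03)

  p3 <- atp_titration_k3()
  f3 <- fit_mm_weighted(p3$atp_uM, p3$k, p3$sem)
  expect_equal(f3$estimates[["k_max"]], 5.33, tolerance = 0.01)
  expect_equal(f3$estimates[["K_m"]], 27, tolerance = 0.01)
})

test_that("Gaussian peak fit finds the elongation-duration peak", {
  set.seed(71)
  x <- rnorm(328, 2.9, 1.0)
  f <- fit_gaussian_peak(x)
  expect_lt(abs(f$estimates[["peak"]] - 2.9), 3 * f$ses[["peak"]])
  expect_lt(abs(f$estimates[["peak"]] - mean(x)),
            build_histogram(x)$width)
  set.seed(72)
  f2 <- fit_gaussian_peak(rnorm(328, 2.9, 1.0))
  se_comb <- sqrt(f$ses[["peak"]]^2 + f2$ses[["peak"]]^2)
  expect_lt(abs(f$estimates[["peak"]] - f2$estimates[["peak"]]),
            3 * se_comb)
  expect_error(fit_gaussian_peak(rnorm(10)), "at least 30")
})

test_that("single-exponential rate estimators", {
  set.seed(73)
  x <- rexp(116, 1.99)
  f <- fit_exp_rate(x)
  expect_equal(f$estimates[["rate"]], 1 / mean(x))
  expect_lt(abs(f$estimates[["rate"]] - 1.99), 3 * f$ses[["rate"]])
  set.seed(74)
  y <- rexp(5000, 0.8)
  fls <- fit_exp_rate(y, method = "ls")
  expect_lt(abs(fls$estimates[["rate"]] - 0.8) / 0.8, 0.1)
})

test_that("diffusion model comparison identifies the generating model", {
  D <- 1.3e-4; f_cap <- 0.26
  L_bp <- c(10, 19, 49, 61, 91)
  L <- bp_to_um(L_bp)
  lt <- diffusion_lifetime(L, D)
  pts <- data.frame(L_um = L, mean_lifetime = lt,
                    lifetime_se = pmax(0.1 * lt, 1e-3),
                    fraction = rep(f_cap, 5), fraction_se = 0.03)
  # noise-free: 1d preferred with ~zero chi-square
  res0 <- fit_diffusion_models(pts)
  expect_equal(res0$preferred, "1d")
  expect_lt(res0$fits[["1d"]]$reduced_chisq, 1e-6)

  set.seed(81)
  pts_noisy <- pts
  pts_noisy$mean_lifetime <- lt * (1 + rnorm(5, 0, 0.1))
  pts_noisy$fraction <- f_cap + rnorm(5, 0, 0.02)
  res <- fit_diffusion_models(pts_noisy)
  expect_equal(res$preferred, "1d")
  expect_lt(abs(res$fits[["1d"]]$estimates[["D"]] - D) / D, 0.30)

  # data generated by the 3d alternative select the 3d model
  set.seed(82)
  lt3 <- L^2 / (6 * D)
  pts3 <- data.frame(L_um = L, mean_lifetime = lt3 * (1 + rnorm(5, 0, 0.05)),
                     lifetime_se = pmax(0.05 * lt3, 1e-3),
                     fraction = pmin(0.005 / L, 1) + rnorm(5, 0, 0.005),
                     fraction_se = 0.01)
  res3 <- fit_diffusion_models(pts3)
  expect_equal(res3$preferred, "3d")
  expect_error(fit_diffusion_models(pts[1:2, ]))
})

test_that("derived rates: translocation, elongation, catalytic", {
  expect_equal(translocation_rate(5.9, 14), 82.6)
  expect_equal(round(translocation_rate(5.33, 16), 1), 85.3)
  expect_equal(round(elongation_rate(28, 2.9), 2), 9.66)
  expect_equal(round(elongation_rate(539, 47), 1), 11.5)
  expect_equal(k_cat_from_mean(0.25), 4)
  expect_error(elongation_rate(28, 0))
})

test_that("holding the shared rate propagates the MM/two-step identity", {
  # dwells from the binding-catalysis model with no pre-catalysis
  # dissociation: a two-step fit with k2 held at k_cat must recover the
  # same binding rate as the MM-form fit with k_minus held at 0
  k0 <- 0.0275; kc <- 4.04
  d <- sample_dwells("two_step", list(k1 = k0, k2 = kc), 3000, seed = 91)
  h <- build_histogram(d)
  f_mm <- fit_global_ls(list(h), "smmm_bleach", S = 1,
                        hold = list(k_minus = 0, k_cat = kc, t0 = 1e12))
  f_ts <- fit_global_ls(list(h), "two_step", share = "k2",
                        hold = list(k2 = kc))
  k_mm <- f_mm$estimates[["k_plus"]]
  k_ts <- f_ts$estimates[["k1.1"]]
  se <- sqrt(f_mm$ses[["k_plus"]]^2 + f_ts$ses[["k1.1"]]^2)
  expect_lt(abs(k_mm - k_ts), se)
  expect_lt(abs(k_mm - k0) / k0, 0.25)
})

test_that("parameter recovery holds across seeded replicates", {
  ok <- 0L
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    d <- sample_dwells("two_step", list(k1 = 2.20, k2 = 8.69), 229,
                       seed = 2000 + r)
    fit <- fit_mle(d, "two_step")
    in3 <- abs(fit$estimates[["k1"]] - 2.20) < 3 * fit$ses[["k1"]] &&
      abs(fit$estimates[["k2"]] - 8.69) < 3 * fit$ses[["k2"]]
    if (in3) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})
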