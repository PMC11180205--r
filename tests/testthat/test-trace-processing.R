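test_that("proximity ratio arithmetic and invalid-frame handling", {
  expect_equal(compute_fret(40, 60), 0.6)
  expect_equal(compute_fret(5, 0), 0)
  expect_true(is.na(compute_fret(0, 0)))
  expect_equal(compute_fret(c(40, 0), c(60, 0), floor = 10),
               c(0.6, NA_real_))
})

test_that("FRET correction matches the closed form and its fixed points", {
  expect_equal(correct_fret(0.8, 1.83), 0.8 / (1.83 * 0.2 + 0.8))
  expect_equal(round(correct_fret(0.8, 1.83), 4), 0.6861)
  expect_equal(round(correct_fret(0.6, 1.83), 4), 0.4505)
  f <- seq(0, 1, by = 0.05)
  for (r in c(0.5, 1, 1.35, 1.83, 1.98)) {
    out <- correct_fret(f, r)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(out[1], 0)
    expect_equal(out[length(out)], 1)
    expect_true(all(diff(out) > 0))   # strictly increasing
  }
  expect_equal(correct_fret(f, 1), f)
  expect_error(correct_fret(1.2, 1.83))
})

test_that("gamma factor from bleach-step intensities", {
  expect_equal(gamma_factor(100, 20, 40, 120), 1)
  expect_equal(gamma_factor(150, 30, 40, 100), 2)
  expect_error(gamma_factor(100, 20, 40, 40), "denominator")
})

test_that("window intensity ratio", {
  tr <- c(rep(200, 50), rep(100, 50))
  expect_equal(pife_ratio(tr, 1:50, 51:100), 2)
  expect_equal(pife_ratio(tr, 10:20, 10:20), 1)
  expect_error(pife_ratio(rep(0, 10), 1:5, 6:10), "zero mean")
  # rendered enhancement recovered in the presence of mild noise
  ev <- simulate_pathway(demo_scheme(), demo_condition(), seed = 41)
  tr2 <- render_trajectory(ev, demo_config(duration = 60, noise_sd = 2),
                           seed = 42)
  r <- tr2$frames[tr2$frames$laser == "red", ]
  el <- which(r$time_s + 0.03 < ev$t_elong_end)
  st <- which(r$time_s + 0.01 > ev$t_elong_end & r$time_s + 0.01 < ev$t_bind)
  ratio <- pife_ratio(r$i_aa, el, st)
  expect_lt(abs(ratio - 1.83), 0.15)
})

# which truth boundaries are resolvable at the 40 ms cycle resolution:
# every flanking dwell at least `m` seconds, no photobleach censoring, and
# the boundary safely inside the record
observable_boundaries <- function(ev, dur, m = 0.12) {
  stall_ok <- (ev$t_bind - ev$t_elong_end) >= m
  int_ok <- (ev$t_term - ev$t_bind) >= m
  pt_ok <- (ev$post_term_end - ev$t_term) >= m &&
    ev$bleach_acceptor > ev$post_term_end + m
  c(elongation_end = stall_ok && ev$bleach_donor > ev$t_bind &&
      ev$t_bind < dur - m,
    stall_end = stall_ok && int_ok && ev$bleach_donor > ev$t_term &&
      ev$t_term < dur - m,
    termination = stall_ok && int_ok && pt_ok &&
      ev$bleach_donor > ev$t_term && ev$t_term < dur - m,
    post_termination_end = stall_ok && int_ok && pt_ok &&
      ev$post_term_end < dur - m)
}

test_that("segmentation recovers observable noiseless changepoints exactly", {
  sc <- demo_scheme()
  checked <- 0L
  for (s in 1:30) {
    ev <- simulate_pathway(sc, demo_condition(), seed = 500 + s)
    tr <- render_trajectory(ev, demo_config(duration = 60), seed = 600 + s)
    seg <- segment_trace(tr)
    cp <- tr$truth$changepoints
    obs <- observable_boundaries(ev, 60)
    for (j in seq_len(nrow(cp))) {
      if (!obs[[cp$boundary[j]]]) next
      checked <- checked + 1L
      expect_true(cp$cycle[j] %in% seg$end_frame,
                  label = sprintf("seed %d boundary %s", s, cp$boundary[j]))
    }
  }
  expect_gt(checked, 40)  # the filter must leave a real test
})

test_that("segmentation tolerates noise: changepoints within one frame", {
  sc <- demo_scheme()
  cfg <- demo_config(duration = 60, noise_sd = 5)  # 5% of the 100-count scale
  hits <- 0L; total <- 0L; errs <- integer(0)
  for (s in 1:150) {
    ev <- simulate_pathway(sc, demo_condition(), seed = 700 + s)
    tr <- render_trajectory(ev, cfg, seed = 900 + s)
    seg <- segment_trace(tr)
    cp <- tr$truth$changepoints
    obs <- observable_boundaries(ev, 60)
    for (j in seq_len(nrow(cp))) {
      if (!obs[[cp$boundary[j]]]) next
      total <- total + 1L
      err <- min(abs(seg$end_frame - cp$cycle[j]))
      errs <- c(errs, err)
      if (err <= 1) hits <- hits + 1L
    }
  }
  expect_gt(total, 200)
  expect_gte(hits / total, 0.95)
  expect_lte(median(errs), 1)
})

test_that("single-state trace yields a single segment; unassignable gives empty", {
  cfg <- demo_config(duration = 10)
  n <- 500
  frames <- data.frame(molecule_id = "m", frame = 1:n,
                       time_s = (0:(n - 1)) * 0.02,
                       laser = rep(c("green", "red"), n / 2),
                       i_dd = NA_real_, i_da = NA_real_, i_aa = NA_real_)
  g <- frames$laser == "green"
  frames$i_dd[g] <- 80; frames$i_da[g] <- 20
  frames$i_aa[!g] <- 100
  tr <- structure(list(frames = frames, condition = NULL, config = cfg,
                       truth = NULL, molecule_id = "m"),
                  class = "trajectory")
  seg <- segment_trace(tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "stall")
  expect_equal(seg$start_frame, 1)
  expect_equal(seg$end_frame, n / 2)

  dark <- tr
  dark$frames$i_dd[g] <- 0; dark$frames$i_da[g] <- 0
  dark$frames$i_aa[!g] <- 0
  seg2 <- segment_trace(dark)
  expect_equal(nrow(seg2), 0)
  expect_equal(attr(seg2, "quality"), "empty")
})

test_that("dwell extraction converts frames to seconds and flags truncation", {
  seg <- data.frame(state = c("stall", "elongation", "stall", "stall"),
                    start_frame = c(1, 11, 31, 61),
                    end_frame = c(10, 30, 50, 90),
                    duration = c(10, 20, 20, 30) * 0.04)
  ds <- extract_dwells(seg, "stall", n_cycles = 100)
  expect_equal(sort(ds$durations), c(0.4, 0.8, 1.2))
  expect_false(any(ds$censored))
  ds2 <- extract_dwells(seg, "stall", n_cycles = 90)
  expect_true(ds2$censored[3])
  expect_equal(extract_dwells(seg, "intermediate")$n, 0)
})

test_that("extracted stall dwells agree with simulated exponential truth", {
  sc <- demo_scheme(k_plus = 5.5e6)
  design <- list(condition(sen1_conc = 10e-9, n_molecules = 150))
  tset <- simulate_dataset(design, sc, demo_config(duration = 120),
                           seed = 77)
  ds <- pool_dwells(tset, "stall")
  truth_waits <- tset$truth$stall_end_s - tset$truth$elongation_end_s
  expect_gt(ds$n, 50)
  se <- sd(ds$durations) / sqrt(ds$n)
  # extracted mean tracks the simulated sample (not just the ensemble) mean
  expect_lt(abs(mean(ds$durations) - mean(truth_waits[truth_waits < 100])),
            3 * se)
})

test_that("co-dissociation lags classify and partition", {
  expect_equal(classify_codissociation(100, 100)$category, "simultaneous")
  r <- classify_codissociation(103, 100)
  expect_equal(r$category, "delayed")
  expect_equal(r$lag, 3)
  expect_equal(classify_codissociation(99, 100)$category, "early")
  lags <- c(-2, 0, 0, 1, 4)
  cats <- vapply(lags, function(l)
    classify_codissociation(100 + l, 100)$category, character(1))
  expect_equal(sum(table(cats)), length(lags))
})

test_that("lag-zero extrapolation recovers the amplitude", {
  # noise-free discrete exponential (halving counts): the zero-lag
  # prediction equals the amplitude exactly
  lags <- rep(1:7, times = c(64, 32, 16, 8, 4, 2, 1))
  r0 <- suppressWarnings(lag_zero_extrapolation(lags))
  expect_equal(r0$predicted, 128, tolerance = 1e-8)
  expect_equal(r0$tau, 1 / log(2), tolerance = 1e-8)

  # Monte Carlo: hold out the zero bin, predict it
  set.seed(88)
  tau <- 1.8
  p <- exp(-(0:30) / tau); p <- p / sum(p)
  draws <- sample(0:30, 1000, TRUE, prob = p)
  held_out <- sum(draws == 0)
  res <- lag_zero_extrapolation(draws[draws >= 1])
  tol <- 3 * sqrt(res$se^2 + held_out)
  expect_lt(abs(res$predicted - held_out), tol)
  expect_error(lag_zero_extrapolation(c(1, 2)), "at least 3")
})

test_that("polymerase fate classification and retained-dissociation times", {
  rec <- data.frame(molecule_id = 1:4, rna_end_frame = c(100, 100, 100, 100),
                    pol2_end_frame = c(100, 150, 90, NA))
  out <- classify_pol2_fate(rec, frame_period = 0.04)
  expect_equal(unname(out$counts),
               c(before = 1, simultaneous = 1, after = 1, retained = 1),
               ignore_attr = TRUE)

  # exponential "after" lag means recover within 3 SE at published n
  for (par in list(c(mean = 36, n = 74), c(mean = 2.1, n = 120))) {
    set.seed(90 + par[["n"]])
    lag_s <- rexp(par[["n"]], 1 / par[["mean"]])
    rec <- data.frame(molecule_id = seq_along(lag_s), rna_end_frame = 0,
                      pol2_end_frame = round(lag_s / 0.04))
    out <- classify_pol2_fate(rec, frame_period = 0.04)
    expect_lt(abs(out$after_mean - par[["mean"]]), 3 * out$after_se)
  }
})

test_that("termination efficiency and its binomial error", {
  e <- termination_efficiency(170, 350)
  expect_equal(round(e$fraction, 4), 0.4857)
  expect_equal(e$se, sqrt(e$fraction * (1 - e$fraction) / 350))
  expect_equal(round(termination_efficiency(166, 406)$fraction, 4), 0.4089)
  z <- termination_efficiency(0, 10)
  expect_equal(z$fraction, 0)
  expect_equal(z$se, 0)
  expect_error(termination_efficiency(5, 0))
})
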