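#' Draw dwell times from a named kinetic model
#'
#' Samples i.i.d. dwell durations from one of the closed-form waiting-time
#' models. For `exp_bleach` and `smmm` the observed dwell is the minimum of
#' the kinetic wait and an exponential photobleach time of mean `t0`;
#' bleach-censored draws are flagged.
#'
#' @param model_id One of `"single_exp"`, `"exp_bleach"`, `"smmm"`,
#'   `"two_step"`.
#' @param params Named list of rates. `single_exp`/`exp_bleach`/`smmm` use
#'   `k_plus` (M^-1 s^-1) and `S` (M) — or a precomputed `rate` —, plus
#'   `t0` and, for `smmm`, `k_minus` and `k_cat`. `two_step` uses `k1`,
#'   `k2` (s^-1); `k1 == k2` is handled by the degenerate limit.
#' @param n Number of draws, >= 1.
#' @param seed Integer RNG seed.
#' @param condition Optional [condition()] attached to the sample.
#' @return A `dwell_sample`: list with `durations`, `censored`, `state`,
#'   `n`, `condition`, and the generating `params`.
#' @export
sample_dwells <- function(model_id, params, n, seed = NULL,
                          condition = NULL) {
  if (!model_id %in% c("single_exp", "exp_bleach", "smmm", "two_step"))
    stop("unknown model_id: ", model_id)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  censored <- rep(FALSE, n)
  if (model_id %in% c("single_exp", "exp_bleach", "smmm")) {
    rate <- params$rate %||% (params$k_plus * params$S)
    if (model_id == "smmm") {
      k0 <- rate; km <- params$k_minus %||% 0; kc <- params$k_cat
      if (k0 <= 0 || kc <= 0 || km < 0) stop("non-positive rates")
      dur <- vapply(seq_len(n), function(i) {
        t <- 0
        repeat {
          t <- t + stats::rexp(1, k0)          # binding wait
          t <- t + stats::rexp(1, km + kc)     # bound-intermediate lifetime
          if (stats::runif(1) < kc / (km + kc)) return(t)
        }
      }, numeric(1))
    } else {
      if (rate <= 0) stop("non-positive rate")
      dur <- stats::rexp(n, rate)
    }
    if (model_id != "single_exp") {
      t0 <- params$t0 %||% 237
      bleach <- stats::rexp(n, 1 / t0)
      censored <- bleach < dur
      dur <- pmin(dur, bleach)
    }
  } else { # two_step
    k1 <- params$k1; k2 <- params$k2
    if (k1 <= 0 || k2 <= 0) stop("non-positive rates")
    dur <- stats::rexp(n, k1) + stats::rexp(n, k2)
  }
  dwell_sample(dur, censored = censored, state = model_id,
               condition = condition, params = params)
}

#' Construct a dwell-time sample
#'
#' @param durations Positive dwell times, seconds.
#' @param censored Logical truncation flags (record end or photobleach).
#' @param state State label the dwells belong to.
#' @param condition Optional [condition()].
#' @param params Optional generating parameters (ground truth).
#' @return Object of class `dwell_sample`.
#' @export
dwell_sample <- function(durations, censored = rep(FALSE, length(durations)),
                         state = NA_character_, condition = NULL,
                         params = NULL) {
  if (length(durations) && any(durations <= 0))
    stop("durations must be > 0")
  stopifnot(length(censored) == length(durations))
  structure(list(durations = as.numeric(durations),
                 censored = as.logical(censored), state = state,
                 condition = condition, params = params,
                 n = length(durations)),
            class = "dwell_sample")
}

#' Simulate one molecule's termination pathway
#'
#' Runs the stochastic state machine for a single stalled polymerase
#' complex: Gaussian elongation, stall until Sen1 arrival (exponential at
#' `k_plus * S`), hypoexponential intermediate lifetime (`k1`, `k2`),
#' simultaneous Sen1/RNA departure at termination, a polymerase fate drawn
#' from `fate_fractions` (simultaneous release; retained with exponential
#' `k4` departure; retained throughout; 1D sliding with an exponential
#' capture time of mean `L^2/(2D)` thinned by `f_capture`), an exponential
#' post-termination Sen1-on-RNA dwell (`k3`), and independent exponential
#' photobleach clocks for both fluorophores.
#'
#' @param scheme A [kinetic_scheme()].
#' @param condition A [condition()]; supplies `sen1_conc` and, for the
#'   sliding fate, `probe_distance_bp`.
#' @param seed Integer RNG seed for this molecule.
#' @return A `pathway_events` list: event times (`t_elong_end`, `t_bind`,
#'   `t_term`, `pol2_end`, `post_term_end`, `bleach_donor`,
#'   `bleach_acceptor`, `capture_time`), the drawn `fate`, and a `segments`
#'   data frame of ideal state intervals.
#' @export
simulate_pathway <- function(scheme, condition, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), inherits(condition, "condition"))
  if (!is.null(seed)) set.seed(seed)
  t_elong <- max(stats::rnorm(1, scheme$elong_mean, scheme$elong_sd), 0.2)
  wait_bind <- stats::rexp(1, scheme$k_plus * condition$sen1_conc)
  t_bind <- t_elong + wait_bind
  t_int <- stats::rexp(1, scheme$k1) + stats::rexp(1, scheme$k2)
  t_term <- t_bind + t_int

  fate <- sample(names(scheme$fate_fractions), 1,
                 prob = scheme$fate_fractions)
  capture_time <- NA_real_
  pol2_end <- switch(fate,
    simultaneous = t_term,
    retained_then_dissociate = t_term + stats::rexp(1, scheme$k4),
    retained_throughout = Inf,
    sliding = Inf)
  if (fate == "sliding") {
    L <- bp_to_um(condition$probe_distance_bp %||% 91)
    mfpt <- diffusion_lifetime(L, scheme$D, "1d")
    if (stats::runif(1) < scheme$f_capture)
      capture_time <- t_term + stats::rexp(1, 1 / mfpt)
  }
  post_term_end <- t_term + stats::rexp(1, scheme$k3)
  bleach_donor <- stats::rexp(1, 1 / scheme$t0)
  bleach_acceptor <- stats::rexp(1, 1 / scheme$t0_acceptor)

  segments <- data.frame(
    state = c("elongation", "stall", "intermediate", "post_termination"),
    start_s = c(0, t_elong, t_bind, t_term),
    end_s = c(t_elong, t_bind, t_term, post_term_end))
  structure(list(t_elong_end = t_elong, t_bind = t_bind, t_term = t_term,
                 pol2_end = pol2_end, post_term_end = post_term_end,
                 capture_time = capture_time, fate = fate,
                 bleach_donor = bleach_donor,
                 bleach_acceptor = bleach_acceptor,
                 segments = segments, condition = condition),
            class = "pathway_events")
}

# Apparent (rendered) proximity-ratio level for each state. During
# elongation the acceptor quantum-yield enhancement inflates the apparent
# ratio from the true level E to pife*E / ((1-E) + pife*E) when
# pife_on_da is enabled.
state_fret_levels <- function(config,
                              true_levels = c(elongation = 0.7, stall = 0.2,
                                              intermediate = 0.85)) {
  lv <- true_levels
  if (isTRUE(config$pife_on_da)) {
    p <- config$pife_factor
    E <- lv[["elongation"]]
    lv[["elongation"]] <- p * E / ((1 - E) + p * E)
  }
  lv
}

#' Render a simulated pathway as an ALEX intensity trajectory
#'
#' Converts one molecule's event times into per-frame donor-excitation
#' (`i_dd`, `i_da`) and acceptor-excitation (`i_aa`) intensities under the
#' configured laser alternation. Donor-excitation frames split the total
#' donor-side emission according to the state's FRET level; acceptor
#' frames carry the acceptor baseline scaled by `pife_factor` while the
#' polymerase is elongating. Emission is zero after a fluorophore's bleach
#' or departure; Gaussian noise of sd `noise_sd` is added to live channels.
#' Ground truth (state changepoints in channel-frame units, bleach times,
#' fate) is embedded in the returned object.
#'
#' @param events A `pathway_events` from [simulate_pathway()].
#' @param config A [trajectory_config()].
#' @param molecule_id Identifier stored with the trajectory.
#' @param seed Integer RNG seed for the noise stream.
#' @return A `trajectory`: data frame `frames` (frame, time_s, laser, i_dd,
#'   i_da, i_aa), the `condition`, the `config`, and a `truth` list.
#' @export
render_trajectory <- function(events, config, molecule_id = "mol_1",
                              seed = NULL) {
  stopifnot(inherits(events, "pathway_events"),
            inherits(config, "trajectory_config"))
  if (!is.null(seed)) set.seed(seed)
  fp <- config$frame_period
  n_frames <- floor(config$duration / fp)
  if (n_frames < length(config$alex_pattern))
    stop("frame_period incompatible with alex_pattern length: record ",
         "shorter than one ALEX cycle")
  frame <- seq_len(n_frames)
  time_s <- (frame - 1) * fp
  mid <- time_s + fp / 2
  laser <- rep_len(config$alex_pattern, n_frames)

  lv <- state_fret_levels(config)
  # state of each frame by its midpoint
  state <- rep("dark", n_frames)
  state[mid < events$t_elong_end] <- "elongation"
  state[mid >= events$t_elong_end & mid < events$t_bind] <- "stall"
  state[mid >= events$t_bind & mid < events$t_term] <- "intermediate"
  state[mid >= events$t_term & mid < events$post_term_end] <- "post_termination"

  donor_total <- config$intensity_levels$donor_total
  acc <- config$intensity_levels$acceptor
  donor_alive <- mid < pmin(events$t_term, events$bleach_donor)
  tether <- events$condition$tether %||% "rna"
  acceptor_kin_end <- if (tether == "rna") events$post_term_end
                      else events$pol2_end
  acceptor_off <- pmin(acceptor_kin_end, events$bleach_acceptor)
  acceptor_alive <- mid < acceptor_off

  i_dd <- i_da <- i_aa <- rep(NA_real_, n_frames)
  g <- laser == "green"; r <- laser == "red"
  E <- ifelse(state %in% names(lv), lv[state], 0)
  i_dd[g] <- ifelse(donor_alive[g], donor_total * (1 - E[g]), 0)
  i_da[g] <- ifelse(donor_alive[g], donor_total * E[g], 0)
  pife <- ifelse(state == "elongation", config$pife_factor, 1)
  i_aa[r] <- ifelse(acceptor_alive[r], acc * pife[r], 0)

  if (config$noise_sd > 0) {
    i_dd[g] <- i_dd[g] + stats::rnorm(sum(g), 0, config$noise_sd)
    i_da[g] <- i_da[g] + stats::rnorm(sum(g), 0, config$noise_sd)
    i_aa[r] <- i_aa[r] + stats::rnorm(sum(r), 0, config$noise_sd)
  }

  cycle_len <- length(config$alex_pattern)
  cyc_period <- fp * cycle_len
  n_cycles <- floor(n_frames / cycle_len)
  # last cycle whose sampling-channel frame midpoint precedes the boundary
  off_of <- function(ch) (match(ch, config$alex_pattern) - 1) * fp + fp / 2
  last_cycle_before <- function(tt, off)
    pmin(pmax(floor((tt - off) / cyc_period) + 1, 0), n_cycles)
  bt <- c(events$t_elong_end, events$t_bind, events$t_term,
          events$post_term_end)
  # donor-read boundaries sample at the green frame, the acceptor-only
  # post-termination end at the red frame
  offs <- c(rep(off_of("green"), 3), off_of("red"))
  truth <- list(
    fate = events$fate,
    events = events,
    changepoints = data.frame(
      boundary = c("elongation_end", "stall_end", "termination",
                   "post_termination_end"),
      time_s = bt,
      cycle = mapply(last_cycle_before, bt, offs)),
    bleach_donor = events$bleach_donor,
    bleach_acceptor = events$bleach_acceptor)

  structure(list(frames = data.frame(molecule_id = molecule_id,
                                     frame = frame, time_s = time_s,
                                     laser = laser, i_dd = i_dd,
                                     i_da = i_da, i_aa = i_aa,
                                     stringsAsFactors = FALSE),
                 condition = events$condition, config = config,
                 truth = truth, molecule_id = molecule_id),
            class = "trajectory")
}

#' Simulate a multi-condition trajectory dataset
#'
#' Runs [simulate_pathway()] and [render_trajectory()] for every molecule
#' of every condition, using one derived RNG stream per molecule so any
#' subset is reproducible from the dataset seed.
#'
#' @param design List of [condition()] objects with distinct labels.
#' @param scheme A [kinetic_scheme()]; `k1` may be overridden per condition
#'   via a condition's `k1` field if present.
#' @param config A [trajectory_config()].
#' @param seed Integer master seed.
#' @return A `trajectory_set`: list with `trajectories` (list of
#'   `trajectory`), `truth` (long data frame of ground-truth event times),
#'   `design`, `scheme`, `config`, `seed`.
#' @export
simulate_dataset <- function(design, scheme, config, seed = 1) {
  stopifnot(length(design) >= 1)
  labels <- vapply(design, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  trajectories <- list()
  truth_rows <- list()
  idx <- 0L
  for (cond in design) {
    sch <- scheme
    if (!is.null(cond$k1)) sch$k1 <- cond$k1
    for (m in seq_len(cond$n_molecules)) {
      idx <- idx + 1L
      mol_id <- sprintf("%s_m%04d", cond$label, m)
      ms <- molecule_seed(seed, idx)
      ev <- simulate_pathway(sch, cond, seed = ms)
      tr <- render_trajectory(ev, config, molecule_id = mol_id,
                              seed = ms + 1L)
      trajectories[[mol_id]] <- tr
      truth_rows[[mol_id]] <- data.frame(
        molecule_id = mol_id, condition = cond$label,
        sen1_conc = cond$sen1_conc, atp_conc = cond$atp_conc,
        fate = ev$fate,
        elongation_end_s = ev$t_elong_end, stall_end_s = ev$t_bind,
        termination_s = ev$t_term, pol2_end_s = ev$pol2_end,
        post_termination_end_s = ev$post_term_end,
        bleach_donor_s = ev$bleach_donor,
        bleach_acceptor_s = ev$bleach_acceptor,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(trajectories = trajectories,
                 truth = do.call(rbind, c(truth_rows,
                                          make.row.names = FALSE)),
                 design = design, scheme = scheme, config = config,
                 seed = seed),
            class = "trajectory_set")
}

#' Write / read the long-format trajectory CSV
#'
#' One row per frame with columns `molecule_id, frame, time_s, laser,
#' i_dd, i_da, i_aa`; channels not read on a frame are empty.
#'
#' @param tset A `trajectory_set` (or list of `trajectory`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(tset, path) {
  trajs <- if (inherits(tset, "trajectory_set")) tset$trajectories else tset
  df <- do.call(rbind, c(lapply(trajs, `[[`, "frames"),
                         make.row.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @param frame_period,alex_pattern Timing metadata used to rebuild each
#'   trajectory's config on read.
#' @export
read_trajectories_csv <- function(path, frame_period = 0.02,
                                  alex_pattern = c("green", "red")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$molecule_id), function(d) {
    d <- d[order(d$frame), ]
    structure(list(frames = d, condition = NULL,
                   config = trajectory_config(
                     frame_period = frame_period,
                     alex_pattern = alex_pattern,
                     duration = max(d$time_s) + frame_period),
                   truth = NULL, molecule_id = d$molecule_id[1]),
              class = "trajectory")
  })
}

#' Write the ground-truth event table
#' @param tset A `trajectory_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(tset, path) {
  utils::write.csv(tset$truth, path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset manifest (conditions, scheme, config, seed) as YAML
#' @param tset A `trajectory_set`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(tset, path) {
  man <- list(
    seed = tset$seed,
    scheme = lapply(unclass(tset$scheme), function(x)
      if (is.numeric(x)) as.list(stats::setNames(as.numeric(x), names(x))) else x),
    config = unclass(tset$config),
    conditions = lapply(tset$design, unclass))
  yaml::write_yaml(man, path)
  invisible(path)
}
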