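#' FRET proximity ratio from donor-excitation intensities
#'
#' Element-wise `i_da / (i_dd + i_da)`. Frames whose total intensity is
#' below `floor` are returned as `NA` (invalid) rather than computed.
#'
#' @param i_dd Donor-excited donor emission.
#' @param i_da Donor-excited acceptor emission.
#' @param floor Minimum total intensity for a valid ratio.
#' @return Numeric series of proximity ratios with `NA` for invalid frames.
#' @export
compute_fret <- function(i_dd, i_da, floor = 0) {
  stopifnot(length(i_dd) == length(i_da))
  tot <- i_dd + i_da
  out <- ifelse(is.na(tot) | tot <= floor, NA_real_, i_da / tot)
  out
}

#' Correct the proximity ratio for acceptor quantum-yield enhancement
#'
#' When protein engagement enhances the acceptor quantum yield by
#' `pife_ratio`, the apparent proximity ratio overestimates FRET. The
#' corrected value is `FRET / (pife_ratio * (1 - FRET) + FRET)`; it is the
#' identity at `pife_ratio = 1`, maps 0 to 0 and 1 to 1, and is strictly
#' increasing in the input.
#'
#' @param fret Apparent proximity ratio(s) in `[0, 1]`.
#' @param pife_ratio Enhancement factor (> 0).
#' @return Corrected FRET value(s) in `[0, 1]`.
#' @export
correct_fret <- function(fret, pife_ratio) {
  ok <- is.na(fret) | (fret >= 0 & fret <= 1)
  if (!all(ok)) stop("fret must be in [0, 1]")
  stopifnot(pife_ratio > 0)
  fret / (pife_ratio * (1 - fret) + fret)
}

#' Detection-correction factor from an acceptor photobleaching step
#'
#' `gamma = (i_a_pre - i_a_post) / (i_d_post - i_d_pre)`, from donor and
#' acceptor intensities before and after acceptor photobleaching.
#'
#' @param i_a_pre,i_a_post Acceptor intensity before/after the bleach step.
#' @param i_d_pre,i_d_post Donor intensity before/after the bleach step.
#' @return Dimensionless gamma factor.
#' @export
gamma_factor <- function(i_a_pre, i_a_post, i_d_pre, i_d_post) {
  denom <- i_d_post - i_d_pre
  if (denom == 0) stop("zero denominator: donor intensity unchanged")
  (i_a_pre - i_a_post) / denom
}

#' Acceptor-enhancement (PIFE) ratio between two trace windows
#'
#' Mean intensity over `window_a` divided by mean over `window_b`
#' (typically the engaged/elongating region over the stalled region).
#'
#' @param trace Numeric intensity series.
#' @param window_a,window_b Integer frame index ranges within the trace.
#' @return Dimensionless ratio.
#' @export
pife_ratio <- function(trace, window_a, window_b) {
  stopifnot(length(window_a) > 0, length(window_b) > 0,
            max(window_a, window_b) <= length(trace), min(window_a, window_b) >= 1)
  mb <- mean(trace[window_b], na.rm = TRUE)
  if (mb == 0) stop("zero mean intensity in reference window")
  mean(trace[window_a], na.rm = TRUE) / mb
}

# Running median of width 3; preserves piecewise-constant plateaus and
# their boundaries exactly on noiseless data.
median3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  a <- x[1:(n - 2)]; b <- x[2:(n - 1)]; c <- x[3:n]
  out <- x
  out[2:(n - 1)] <- pmax(pmin(a, b), pmin(pmax(a, b), c))
  out
}

#' Segment an ALEX trajectory into kinetic states
#'
#' Assigns each ALEX cycle (one green + one red frame) a state label by
#' nearest-level classification of the median-filtered proximity ratio
#' against the configured apparent FRET bands, with temporal
#' disambiguation of the intermediate (high-FRET cycles after the first
#' stall run), acceptor-only detection of the post-termination state, and
#' an intensity floor for darkness. Runs shorter than `min_dwell` cycles
#' are absorbed into the preceding segment.
#'
#' @param traj A `trajectory`.
#' @param thresholds List: `floor` (counts, minimum live intensity),
#'   `min_dwell` (cycles), `levels` (named apparent FRET levels for
#'   `elongation`, `stall`, `intermediate`; defaults from the trajectory's
#'   config).
#' @return A data frame of class `state_segments` with columns `state`,
#'   `start_frame`, `end_frame` (inclusive, channel-frame/cycle units) and
#'   `duration` in seconds; attribute `quality` is `"ok"` or `"empty"`.
#' @export
segment_trace <- function(traj, thresholds = list()) {
  stopifnot(inherits(traj, "trajectory"))
  fl <- thresholds$floor %||% 25
  min_dwell <- thresholds$min_dwell %||% 2
  lv <- thresholds$levels %||% state_fret_levels(traj$config)
  fr <- traj$frames
  g <- fr[fr$laser == "green", ]
  r <- fr[fr$laser == "red", ]
  n_cyc <- min(nrow(g), nrow(r))
  if (n_cyc < min_dwell) {
    out <- data.frame(state = character(), start_frame = integer(),
                      end_frame = integer(), duration = numeric())
    attr(out, "quality") <- "empty"
    class(out) <- c("state_segments", class(out))
    return(out)
  }
  g <- g[seq_len(n_cyc), ]; r <- r[seq_len(n_cyc), ]
  cycle_period <- traj$config$frame_period * length(traj$config$alex_pattern)

  donor_tot <- g$i_dd + g$i_da
  donor_live <- donor_tot > fl
  acc_live <- r$i_aa > fl
  fret <- compute_fret(g$i_dd, g$i_da, floor = fl)
  fret[!is.na(fret)] <- median3(fret[!is.na(fret)])

  lev_names <- names(lv)
  raw <- character(n_cyc)
  for (i in seq_len(n_cyc)) {
    if (donor_live[i] && !is.na(fret[i])) {
      raw[i] <- lev_names[which.min(abs(lv - fret[i]))]
    } else if (isTRUE(acc_live[i])) {
      raw[i] <- "post_termination"
    } else {
      raw[i] <- "dark"
    }
  }
  # high-FRET band before any stall run is elongation, after it is the
  # intermediate (and vice versa for misassigned elongation cycles)
  first_stall <- match("stall", raw)
  if (!is.na(first_stall)) {
    hi <- raw %in% c("elongation", "intermediate")
    raw[hi & seq_len(n_cyc) < first_stall] <- "elongation"
    raw[hi & seq_len(n_cyc) > first_stall] <- "intermediate"
  } else {
    raw[raw == "intermediate"] <- "elongation"
  }

  if (all(raw == "dark")) {
    out <- data.frame(state = character(), start_frame = integer(),
                      end_frame = integer(), duration = numeric())
    attr(out, "quality") <- "empty"
    class(out) <- c("state_segments", class(out))
    return(out)
  }

  r_enc <- rle(raw)
  # absorb runs shorter than min_dwell into the previous run
  while (length(r_enc$lengths) > 1 && any(r_enc$lengths < min_dwell)) {
    i <- which(r_enc$lengths < min_dwell)[1]
    j <- if (i == 1) 2 else i - 1
    r_enc$lengths[j] <- r_enc$lengths[j] + r_enc$lengths[i]
    r_enc$lengths <- r_enc$lengths[-i]
    r_enc$values <- r_enc$values[-i]
    r_enc <- rle(inverse.rle(r_enc))
  }
  ends <- cumsum(r_enc$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- data.frame(state = r_enc$values, start_frame = starts,
                    end_frame = ends,
                    duration = (ends - starts + 1) * cycle_period,
                    stringsAsFactors = FALSE)
  attr(out, "quality") <- "ok"
  class(out) <- c("state_segments", class(out))
  out
}

#' Collect dwell times of one state from a segmentation
#'
#' Durations of all segments with the requested state label; a dwell whose
#' segment touches the record end (or is followed only by darkness that
#' began with a bleach) is flagged censored.
#'
#' @param segments A `state_segments` data frame from [segment_trace()].
#' @param state State label to collect.
#' @param condition Optional [condition()] attached to the sample.
#' @param n_cycles Total cycles in the record (for end-censoring); taken
#'   from the last segment if missing.
#' @return A [dwell_sample()].
#' @export
extract_dwells <- function(segments, state, condition = NULL,
                           n_cycles = NULL) {
  sel <- segments[segments$state == state, , drop = FALSE]
  if (nrow(sel) == 0)
    return(dwell_sample(numeric(0), logical(0), state = state,
                        condition = condition))
  if (is.null(n_cycles)) n_cycles <- max(segments$end_frame)
  censored <- sel$end_frame >= n_cycles
  dwell_sample(sel$duration, censored = censored, state = state,
               condition = condition)
}

#' Pool one state's dwells across a trajectory set
#'
#' Convenience wrapper: segment every trajectory, extract the named state,
#' and pool the uncensored durations.
#'
#' @param tset A `trajectory_set`.
#' @param state State label.
#' @param thresholds Passed to [segment_trace()].
#' @param drop_censored Drop censored dwells (default `TRUE`).
#' @return A [dwell_sample()].
#' @export
pool_dwells <- function(tset, state, thresholds = list(),
                        drop_censored = TRUE) {
  dur <- numeric(0); cen <- logical(0)
  for (tr in tset$trajectories) {
    seg <- segment_trace(tr, thresholds)
    ds <- extract_dwells(seg, state)
    dur <- c(dur, ds$durations); cen <- c(cen, ds$censored)
  }
  if (drop_censored) { dur <- dur[!cen]; cen <- cen[!cen] }
  dwell_sample(dur, cen, state = state)
}

#' Classify the Sen1/RNA co-dissociation lag of one molecule
#'
#' @param sen1_end_frame,rna_end_frame Last frame of each signal.
#' @param tol_frames Frames within which the two ends count as
#'   simultaneous (default 0, strict).
#' @return List with `lag` (frames, `sen1_end - rna_end`) and `category`
#'   in `{"simultaneous", "delayed", "early"}`.
#' @export
classify_codissociation <- function(sen1_end_frame, rna_end_frame,
                                    tol_frames = 0) {
  lag <- sen1_end_frame - rna_end_frame
  category <- if (abs(lag) <= tol_frames) "simultaneous"
              else if (lag > 0) "delayed" else "early"
  list(lag = lag, category = category)
}

#' Extrapolate the delayed-lag exponential to lag zero
#'
#' Fits `A * exp(-n / tau)` to the per-frame counts of delayed
#' co-dissociation events (lags >= 1 frame) and extrapolates the expected
#' number of events in the zero-lag bin, with the fitted amplitude's
#' standard error.
#'
#' @param delayed_lags Integer lags (frames >= 1) of delayed events.
#' @return List: `predicted` (count at frame 0), `se`, `tau` (frames),
#'   `fit` (the `nls` object).
#' @export
lag_zero_extrapolation <- function(delayed_lags) {
  if (length(delayed_lags) < 3) stop("need at least 3 delayed events")
  n <- seq_len(max(delayed_lags))
  counts <- tabulate(delayed_lags, nbins = max(delayed_lags))
  tau0 <- max(mean(delayed_lags), 0.5)
  fit <- stats::nls(counts ~ A * exp(-n / tau),
                    start = list(A = max(counts) * exp(1 / tau0), tau = tau0),
                    control = stats::nls.control(warnOnly = TRUE))
  co <- summary(fit)$coefficients
  list(predicted = unname(co["A", "Estimate"]),
       se = unname(co["A", "Std. Error"]),
       tau = unname(co["tau", "Estimate"]), fit = fit)
}

#' Classify post-termination polymerase fates
#'
#' Given per-molecule RNA (donor) and polymerase (acceptor) end frames,
#' classifies each molecule as the polymerase dissociating `before`,
#' `simultaneous` with, or `after` RNA release, or `retained` through the
#' record; fits a single-exponential mean to the `after` lags.
#'
#' @param records Data frame with columns `molecule_id`, `rna_end_frame`,
#'   `pol2_end_frame` (NA if retained to record end), optional logical
#'   `retained`.
#' @param frame_period Seconds per frame for the `after`-lag times.
#' @param tol_frames Simultaneity tolerance (frames).
#' @return List: `records` (with `category` and `lag_frames` columns),
#'   `counts` (named category counts), `after_mean` (s), `after_se`
#'   (mean/sqrt(n)), `after_n`.
#' @export
classify_pol2_fate <- function(records, frame_period = 0.04,
                               tol_frames = 0) {
  retained <- if (!is.null(records$retained)) records$retained
              else is.na(records$pol2_end_frame)
  lag <- records$pol2_end_frame - records$rna_end_frame
  category <- ifelse(retained, "retained",
              ifelse(abs(lag) <= tol_frames, "simultaneous",
              ifelse(lag > 0, "after", "before")))
  records$category <- category
  records$lag_frames <- ifelse(retained, NA_integer_, lag)
  counts <- table(factor(category,
                         levels = c("before", "simultaneous", "after",
                                    "retained")))
  after_lags <- lag[!retained & category == "after"] * frame_period
  after_mean <- if (length(after_lags)) mean(after_lags) else NA_real_
  after_se <- if (length(after_lags)) after_mean / sqrt(length(after_lags))
              else NA_real_
  list(records = records, counts = c(counts), after_mean = after_mean,
       after_se = after_se, after_n = length(after_lags))
}

#' Termination efficiency with binomial standard error
#'
#' Fraction of elongated-and-stalled complexes whose RNA is released
#' during the record.
#'
#' @param n_released Number of RNA-release events.
#' @param n_total Total complexes observed (>= 1).
#' @return List: `fraction`, `se` (`sqrt(p (1-p) / n)`), `n_released`,
#'   `n_total`.
#' @export
termination_efficiency <- function(n_released, n_total) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_released < 0 || n_released > n_total)
    stop("n_released must be in [0, n_total]")
  p <- n_released / n_total
  list(fraction = p, se = sqrt(p * (1 - p) / n_total),
       n_released = n_released, n_total = n_total)
}
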