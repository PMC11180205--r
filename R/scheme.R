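#' Ground-truth kinetic scheme for the termination simulator
#'
#' Bundles the rate constants and branch fractions that drive
#' [simulate_pathway()]: second-order Sen1 binding (`k_plus`), dissociation
#' before catalysis (`k_minus`), catalytic turnover (`k_cat`), the two-step
#' intermediate rates (`k1`, ATP-dependent translocation, per condition;
#' `k2`, single-ATP catalytic release, shared), post-termination Sen1-on-RNA
#' dissociation (`k3`), retained-polymerase dissociation (`k4`), the donor
#' photobleaching mean time `t0`, Gaussian elongation-duration parameters,
#' the four polymerase fate probabilities, and the 1D sliding parameters
#' (`D`, `f_capture`).
#'
#' @param k_plus Binding rate constant, M^-1 s^-1.
#' @param k_minus Dissociation-before-catalysis rate, s^-1.
#' @param k_cat Catalytic turnover rate, s^-1.
#' @param k1 ATP-dependent translocation rate of the intermediate, s^-1.
#' @param k2 Catalytic release rate, s^-1 (shared across ATP conditions).
#' @param k3 Post-termination Sen1-on-RNA dissociation rate, s^-1.
#' @param k4 Retained-polymerase dissociation rate, s^-1.
#' @param t0 Mean donor (Cy3) photobleaching time, s.
#' @param t0_acceptor Mean acceptor (Cy5) photobleaching time, s.
#' @param elong_mean,elong_sd Gaussian elongation duration, s.
#' @param fate_fractions Numeric length-4 probability vector, in order
#'   `simultaneous`, `retained_then_dissociate`, `retained_throughout`,
#'   `sliding`; must sum to 1.
#' @param D 1D diffusion coefficient of the released polymerase, um^2 s^-1.
#' @param f_capture Distance-independent end-capture fraction in `[0, 1]`.
#' @return An object of class `kinetic_scheme` (validated list).
#' @export
kinetic_scheme <- function(k_plus = 5.5e6, k_minus = 0, k_cat = 4.04,
                           k1 = 5.87, k2 = 8.69, k3 = 5.46, k4 = 1 / 36,
                           t0 = 237, t0_acceptor = 237,
                           elong_mean = 2.9, elong_sd = 1.0,
                           fate_fractions = c(simultaneous = 58,
                                              retained_then_dissociate = 74,
                                              retained_throughout = 34,
                                              sliding = 0) / 166,
                           D = 1.3e-4, f_capture = 0.26) {
  rates <- c(k_plus = k_plus, k_minus = k_minus, k_cat = k_cat, k1 = k1,
             k2 = k2, k3 = k3, k4 = k4)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (t0 <= 0 || t0_acceptor <= 0) stop("photobleaching times must be > 0")
  if (length(fate_fractions) != 4L)
    stop("fate_fractions must have length 4")
  if (any(fate_fractions < 0) || abs(sum(fate_fractions) - 1) > 1e-12)
    stop("fate_fractions must be a probability vector summing to 1")
  if (f_capture < 0 || f_capture > 1) stop("f_capture must be in [0, 1]")
  if (D <= 0) stop("D must be > 0")
  names(fate_fractions) <- c("simultaneous", "retained_then_dissociate",
                             "retained_throughout", "sliding")
  structure(list(k_plus = k_plus, k_minus = k_minus, k_cat = k_cat,
                 k1 = k1, k2 = k2, k3 = k3, k4 = k4, t0 = t0,
                 t0_acceptor = t0_acceptor, elong_mean = elong_mean,
                 elong_sd = elong_sd, fate_fractions = fate_fractions,
                 D = D, f_capture = f_capture),
            class = "kinetic_scheme")
}

#' Experimental condition descriptor
#'
#' @param sen1_conc Sen1 helicase-domain concentration, molar.
#' @param atp_conc ATP concentration, micromolar.
#' @param rna_ext_length RNA length (nt) extending from the polymerase RNA
#'   exit channel.
#' @param construct Free-text construct label.
#' @param n_molecules Number of molecules to simulate/collect.
#' @param label Optional short condition label (defaults to a composed one).
#' @param probe_distance_bp Distance (bp) from termination site to the
#'   acceptor probe; used by the sliding fate.
#' @param tether Which component is surface-tethered and hence what the
#'   acceptor channel reports after termination: `"rna"` (acceptor lives
#'   through the post-termination Sen1-on-RNA dwell) or `"pol2"`/`"dna"`
#'   (acceptor lives until the polymerase/DNA dissociates).
#' @param k1 Optional per-condition override of the scheme's ATP-dependent
#'   translocation rate (s^-1), e.g. from [mm_curve()] at this ATP level.
#' @return Object of class `condition`.
#' @export
condition <- function(sen1_conc = 10e-9, atp_conc = 1100,
                      rna_ext_length = 28, construct = "no_mismatch",
                      n_molecules = 200, label = NULL,
                      probe_distance_bp = 91, k1 = NULL,
                      tether = c("rna", "pol2", "dna")) {
  tether <- match.arg(tether)
  if (sen1_conc < 0 || atp_conc < 0) stop("concentrations must be >= 0")
  if (rna_ext_length < 0) stop("rna_ext_length must be >= 0")
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (is.null(label))
    label <- sprintf("sen1_%.3gnM_atp_%.4guM_%s", sen1_conc * 1e9,
                     atp_conc, construct)
  structure(list(sen1_conc = sen1_conc, atp_conc = atp_conc,
                 rna_ext_length = rna_ext_length, construct = construct,
                 n_molecules = as.integer(n_molecules), label = label,
                 probe_distance_bp = probe_distance_bp, k1 = k1,
                 tether = tether),
            class = "condition")
}

#' Trajectory rendering configuration
#'
#' ALEX timing and intensity model used by [render_trajectory()]. The
#' default alternates one 20 ms green (donor-excitation) frame with one
#' 20 ms red (acceptor-excitation) frame, so each channel is sampled at
#' 25 Hz.
#'
#' @param frame_period Seconds per camera frame (one laser slot).
#' @param alex_pattern Character vector of laser labels cycled over frames.
#' @param duration Total record length, seconds.
#' @param intensity_levels Named list: `donor_total` (total donor-excited
#'   emission while the donor is alive) and `acceptor` (acceptor-excited
#'   acceptor emission baseline).
#' @param noise_sd Additive Gaussian intensity noise, counts.
#' @param pife_factor Multiplicative acceptor enhancement while the
#'   polymerase engages DNA (>= 1).
#' @param pife_on_da Also scale donor-excited acceptor emission by
#'   `pife_factor` during engaged states (supports the FRET correction).
#' @return Object of class `trajectory_config`.
#' @export
trajectory_config <- function(frame_period = 0.02,
                              alex_pattern = c("green", "red"),
                              duration = 120,
                              intensity_levels = list(donor_total = 100,
                                                      acceptor = 100),
                              noise_sd = 0, pife_factor = 1.83,
                              pife_on_da = TRUE) {
  if (frame_period <= 0) stop("frame_period must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (pife_factor < 1) stop("pife_factor must be >= 1")
  if (!all(alex_pattern %in% c("green", "red")))
    stop("alex_pattern entries must be 'green' or 'red'")
  structure(list(frame_period = frame_period, alex_pattern = alex_pattern,
                 duration = duration, intensity_levels = intensity_levels,
                 noise_sd = noise_sd, pife_factor = pife_factor,
                 pife_on_da = pife_on_da),
            class = "trajectory_config")
}

# Derive a per-molecule 32-bit seed from a dataset seed so molecule streams
# are independent of how many molecules precede them.
molecule_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}
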