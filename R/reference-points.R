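#' Published per-condition rate estimates used as secondary-fit inputs
#'
#' Per-ATP rate estimates (with standard errors and event counts) from the
#' single-molecule ATP titrations of Sen1 helicase-domain action on stalled
#' Pol II elongation complexes. Each data frame has columns `atp_uM`, `k`
#' (s^-1), `sem` (s^-1), `n`. These points are the inputs to the classical
#' Michaelis-Menten secondary fits ([fit_mm_weighted()]).
#'
#' `atp_titration_k1()`: ATP-dependent translocation rate of the
#' Sen1-polymerase intermediate on the polymerase-tethered construct.
#' `atp_titration_k1_biornatether()`: same rate on the RNA-tethered
#' construct. `atp_titration_k3()`: post-termination Sen1-on-RNA
#' dissociation rate.
#'
#' @return A data frame (see Description).
#' @export
atp_titration_k1 <- function() {
  data.frame(atp_uM = c(20, 40, 200, 1100),
             k = c(2.20, 2.54, 5.12, 5.87),
             sem = c(0.32, 0.40, 0.98, 1.19),
             n = c(143L, 179L, 204L, 229L))
}

#' @rdname atp_titration_k1
#' @export
atp_titration_k1_biornatether <- function() {
  data.frame(atp_uM = c(20, 40, 200, 2000),
             k = c(0.84, 3.21, 4.59, 5.60),
             sem = c(0.19, 0.68, 1.15, 1.61),
             n = c(116L, 160L, 190L, 197L))
}

#' @rdname atp_titration_k1
#' @export
atp_titration_k3 <- function() {
  data.frame(atp_uM = c(20, 40, 200, 2000),
             k = c(1.99, 4.21, 4.25, 5.46),
             sem = c(0.30, 0.50, 0.45, 0.48),
             n = c(116L, 160L, 190L, 197L))
}

#' Study conditions of the Sen1 concentration titration
#'
#' Sen1 helicase-domain concentrations (M) and event counts of the
#' binding-rate titration on stalled complexes, used as the simulation
#' design for the global single-exponential recovery analysis; the
#' generating binding rate constant is 5.5e6 M^-1 s^-1.
#'
#' @return Data frame with `sen1_M`, `n`.
#' @export
sen1_titration_design <- function() {
  data.frame(sen1_M = c(3.5e-9, 5e-9, 10e-9),
             n = c(337L, 417L, 564L))
}
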