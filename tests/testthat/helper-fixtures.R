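# Shared fixtures: small schemes, conditions and datasets built in code.

demo_scheme <- function(...) {
  kinetic_scheme(...)
}

demo_condition <- function(n = 5, ...) {
  condition(n_molecules = n, ...)
}

demo_config <- function(duration = 60, noise_sd = 0, ...) {
  trajectory_config(duration = duration, noise_sd = noise_sd, ...)
}

# numeric CDF of a density by adaptive quadrature (vectorized over q)
numeric_cdf <- function(pdf, q) {
  vapply(q, function(u) {
    if (u <= 0) return(0)
    stats::integrate(pdf, 0, u, rel.tol = 1e-9,
                     subdivisions = 500L)$value
  }, numeric(1))
}

# Kolmogorov-Smirnov distance between a sample and a CDF function
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  F <- cdf(x)
  max(abs(F - (seq_len(n) - 1) / n), abs(F - seq_len(n) / n))
}
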