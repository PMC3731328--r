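# Independent oracles used to pin expected values.  These deliberately do
# not reuse the package's own code paths.

# Pointwise percent deviation, coded independently of percent_deviation().
oracle_percent_dev <- function(f_ref, f_calc) {
  abs(1 - f_calc / f_ref) * 100
}

# Closed-form integral of the squared hydrogen form factor over q^2:
# with c = (a0/2)^2, integral_0^U (1 + c u)^-4 du = (1 - (1 + c U)^-3)/(3 c),
# where u = q^2.
oracle_hydrogen_cumF2 <- function(q2, a0 = 0.52978) {
  cc <- (a0 / 2)^2
  (1 - (1 + cc * q2)^-3) / (3 * cc)
}

# Thomson polar-angle CDF: integral of (1 + cos^2) sin over [0, theta],
# normalized by 8/3.
oracle_thomson_cdf <- function(theta) {
  u <- cos(theta)
  ((1 - u) + (1 - u^3) / 3) / (8 / 3)
}

# Brute-force rectangle-rule integral of the coherent angular shape,
# 2 pi * int dcs(theta) sin(theta) dtheta, built from first principles.
oracle_total_shape <- function(energy_kev, f_of_q, n = 1e6,
                               hc = 12.398419) {
  lambda <- hc / energy_kev
  theta <- (seq_len(n) - 0.5) * pi / n
  q <- 4 * pi / lambda * sin(theta / 2)
  g <- (1 + cos(theta)^2) / 2 * f_of_q(q)^2 * sin(theta)
  2 * pi * sum(g) * pi / n
}

# A dense uniform hydrogen reference table.
oracle_hydrogen_table <- function(n = 5001, qmax = 50) {
  q <- seq(0, qmax, length.out = n)
  ff_table(1, q, (1 + (q * 0.52978 / 2)^2)^-2)
}
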