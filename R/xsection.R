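# Kinematics (q <-> theta at fixed photon energy), Thomson and Rayleigh
# angular shapes, and the cumulative integral of F^2 over q^2 that drives
# the inverse-CDF angle sampler.

#' Scattering kinematics at a fixed photon energy
#'
#' Precomputes the wavelength and the momentum-transfer scale for a photon
#' of the given energy.  The default convention is
#' `q = (4 pi / lambda) sin(theta / 2)`; the alternative
#' `"inverse_lambda"` convention drops the `4 pi` factor
#' (`q = sin(theta / 2) / lambda`), matching reference tabulations indexed
#' by `sin(theta/2)/lambda`.
#'
#' @param energy_kev Photon energy in keV, positive.
#' @param convention `"4pi"` (default) or `"inverse_lambda"`.
#' @return An object of class `scatter_kinematics`: list with `energy_kev`,
#'   `wavelength` (Angstrom), `k` (the prefactor of `sin(theta/2)`),
#'   `q_max` (momentum transfer at `theta = pi`), `convention`.
#' @examples
#' scatter_kinematics(10)$q_max  # about 10.13 1/Angstrom
#' @export
scatter_kinematics <- function(energy_kev, convention = c("4pi", "inverse_lambda")) {
  convention <- match.arg(convention)
  if (!is.numeric(energy_kev) || length(energy_kev) != 1L ||
      !is.finite(energy_kev) || energy_kev <= 0) {
    stop("`energy_kev` must be a single positive number", call. = FALSE)
  }
  lambda <- physical_constants()$hc / energy_kev
  k <- if (convention == "4pi") 4 * pi / lambda else 1 / lambda
  structure(list(energy_kev = energy_kev, wavelength = lambda, k = k,
                 q_max = k, convention = convention),
            class = "scatter_kinematics")
}

#' @export
print.scatter_kinematics <- function(x, ...) {
  cat(sprintf(
    "Kinematics: E = %g keV (%g MeV), lambda = %.5f A, q_max = %.4f 1/A [%s convention]\n",
    x$energy_kev, x$energy_kev / 1000, x$wavelength, x$q_max, x$convention))
  invisible(x)
}

#' Momentum transfer at a scattering angle
#'
#' @param theta Scattering angle in radians, in \[0, pi\]. Vectorized.
#' @param kin A [scatter_kinematics()] object.
#' @return Momentum transfer in 1/Angstrom; strictly increasing in `theta`.
#' @export
q_of_theta <- function(theta, kin) {
  .check_theta(theta)
  kin$k * sin(theta / 2)
}

#' Scattering angle at a momentum transfer (inverse of [q_of_theta()])
#'
#' @param q Momentum transfer in 1/Angstrom, in \[0, q_max\]. Vectorized.
#' @param kin A [scatter_kinematics()] object.
#' @return Angle in radians.
#' @export
theta_of_q <- function(q, kin) {
  if (any(q < 0 | q > kin$q_max * (1 + 1e-12))) {
    stop("`q` outside [0, q_max] for this energy", call. = FALSE)
  }
  2 * asin(pmin(q / kin$k, 1))
}

.check_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > pi)) {
    stop("`theta` must lie in [0, pi]", call. = FALSE)
  }
  invisible(theta)
}

#' Thomson angular shape
#'
#' The free-electron elastic-scattering angular factor `(1 + cos^2 theta)/2`,
#' normalized to 1 at `theta = 0`.
#'
#' @param theta Angle in radians, in \[0, pi\]. Vectorized.
#' @return Relative probability density, in \[1/2, 1\].
#' @export
thomson_angular <- function(theta) {
  .check_theta(theta)
  (1 + cos(theta)^2) / 2
}

# Turns an ff_params, ff_table (linear interpolation between nodes: LIT) or
# plain function into an evaluator f(q).  Tables must cover the requested q.
.ff_evaluator <- function(ff) {
  if (inherits(ff, "ff_params")) {
    function(q) suppressWarnings(empirical_ff(q, ff))
  } else if (inherits(ff, "ff_table")) {
    qmax_tab <- max(ff$q)
    qmin_tab <- min(ff$q)
    function(q) {
      if (any(q > qmax_tab * (1 + 1e-12)) || any(q < qmin_tab)) {
        stop(sprintf(
          "table covers q in [%g, %g] but evaluation needs q up to %g",
          qmin_tab, qmax_tab, max(q)), call. = FALSE)
      }
      stats::approx(ff$q, ff$f, xout = pmin(q, qmax_tab))$y
    }
  } else if (is.function(ff)) {
    ff
  } else {
    stop("`ff` must be an `ff_params`, an `ff_table`, or a function of q",
         call. = FALSE)
  }
}

#' Relative Rayleigh differential cross-section
#'
#' The coherent-scattering angular shape
#' `thomson_angular(theta) * F(q(theta))^2` (no classical-electron-radius
#' prefactor: the package samples angles, so only the shape matters).
#'
#' @inheritParams q_of_theta
#' @param ff Form factor: an `ff_params` object, an `ff_table` (evaluated by
#'   linear interpolation between nodes), or a function of `q`.
#' @return Relative differential cross-section values (dimensionless shape).
#' @examples
#' kin <- scatter_kinematics(10)
#' rayleigh_dcs(0, kin, get_params(14))  # about Z^2 = 196
#' @export
rayleigh_dcs <- function(theta, kin, ff) {
  f <- .ff_evaluator(ff)(q_of_theta(theta, kin))
  thomson_angular(theta) * f^2
}

#' Cumulative integral of F squared over q squared
#'
#' Builds the normalized running integral of `F(q)^2` with respect to `q^2`
#' on a uniform `q^2` grid from 0 to `q_max^2`, by the trapezoid rule.  This
#' is the distribution the Monte Carlo sampler inverts: in the small-angle /
#' low-energy regime the coherent cross-section is proportional to
#' `F^2 dq^2` up to the Thomson factor handled by rejection.
#'
#' @param kin A [scatter_kinematics()] object.
#' @param ff Form factor (see [rayleigh_dcs()]).
#' @param n_grid Number of grid points, >= 256 (default 1024).
#' @return An object of class `cumulative_f2`: list with `q2_grid`,
#'   `cumulative` (non-decreasing, 0 to 1), `total` (the unnormalized
#'   integral), `kin`.
#' @examples
#' cf <- build_cumulative_F2(scatter_kinematics(10), get_params(1))
#' utils::tail(cf$cumulative, 1)  # 1
#' @export
build_cumulative_F2 <- function(kin, ff, n_grid = 1024) {
  if (n_grid < 256) {
    stop("`n_grid` must be at least 256", call. = FALSE)
  }
  q2 <- seq(0, kin$q_max^2, length.out = n_grid)
  f2 <- .ff_evaluator(ff)(sqrt(q2))^2
  dq2 <- q2[2] - q2[1]
  cum <- c(0, cumsum((f2[-1] + f2[-n_grid]) / 2 * dq2))
  total <- cum[n_grid]
  if (total <= 0) {
    stop("integral of F^2 over q^2 is not positive", call. = FALSE)
  }
  structure(list(q2_grid = q2, cumulative = cum / total, total = total,
                 kin = kin),
            class = "cumulative_f2")
}

#' Relative total coherent-scattering shape integral
#'
#' `2 pi * integral of rayleigh_dcs(theta) sin(theta) dtheta` over \[0, pi\]
#' by composite Simpson quadrature.  Relative units (no `r_e^2`).
#'
#' @param energy_kev Photon energy in keV.
#' @param ff Form factor (see [rayleigh_dcs()]).
#' @param n_theta Number of quadrature nodes, >= 180 (default 721; forced
#'   odd for Simpson's rule).
#' @param convention q-convention passed to [scatter_kinematics()].
#' @return A single number, decreasing in energy for a fixed element.
#' @examples
#' total_coherent_shape(2.5, function(q) rep(1, length(q)))  # 8 pi / 3
#' @export
total_coherent_shape <- function(energy_kev, ff, n_theta = 721,
                                 convention = "4pi") {
  if (n_theta < 180) {
    stop("`n_theta` must be at least 180", call. = FALSE)
  }
  n <- as.integer(n_theta)
  if (n %% 2L == 0L) n <- n + 1L
  kin <- scatter_kinematics(energy_kev, convention)
  theta <- seq(0, pi, length.out = n)
  g <- rayleigh_dcs(theta, kin, ff) * sin(theta)
  h <- theta[2] - theta[1]
  w <- c(1, rep(c(4, 2), length.out = n - 2L), 1)
  2 * pi * sum(w * g) * h / 3
}
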