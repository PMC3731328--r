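# Closed-form and empirical atomic form factors, plus percent-deviation
# statistics against reference tabulations.

#' Closed-form hydrogen atomic form factor
#'
#' Evaluates the nonrelativistic hydrogen form factor
#' \deqn{F_H(q) = \left[1 + (q a_0 / 2)^2\right]^{-2}}
#' with the Bohr radius `a0 = 0.52978` Angstrom, where `q` is the momentum
#' transfer in inverse Angstrom (convention `q = 4 pi sin(theta/2) / lambda`).
#' Equals 1 at `q = 0` (one bound electron) and decreases strictly with `q`.
#'
#' @param q Momentum transfer in 1/Angstrom; non-negative, finite. Vectorized.
#' @return Dimensionless form-factor values in (0, 1].
#' @examples
#' hydrogen_ff(0)
#' hydrogen_ff(2 / physical_constants()$a0)  # exactly 0.25
#' @export
hydrogen_ff <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q))) {
    stop("`q` must be finite numeric", call. = FALSE)
  }
  if (any(q < 0)) {
    stop("`q` must be non-negative", call. = FALSE)
  }
  x <- q * physical_constants()$a0 / 2
  (1 + x^2)^-2
}

#' Seven-parameter empirical atomic form factor
#'
#' Evaluates the package's generalization of the hydrogen closed form,
#' \deqn{F(q, Z) = Z \left[\frac{a_1}{a_1 + b_1 x^2}\right]^{r}
#'   \cdot \frac{a_2}{a_2 + b_2 x^2} \cdot \frac{a_3}{a_3 + b_3 x^2},
#'   \qquad x = \frac{a_0 q}{2},}
#' a product of one hydrogen-like factor raised to the shape exponent `r`
#' and two wide Lorentzian correction factors.  With the hydrogen parameter
#' row (`r = 2`, `a1 = b1 = b2 = b3 = 1`, `a2 = a3 = 1E5`) the correction
#' factors are within 0.35% of unity over `q` in \[0, 50\] and the function
#' reduces to [hydrogen_ff()]; taking `a2 = a3 = 0` instead makes it reduce
#' exactly for `q > 0` while leaving the second and third factors 0/0 at
#' `q = 0`, which is why the large finite value is stored in the table.
#' At `q = 0` the function equals `Z` exactly for any positive parameters.
#'
#' For user-supplied degenerate parameters with some `a_i = 0` the 0/0 form
#' at `q = 0` is resolved by the mathematical limit from `q > 0` (the factor
#' is identically zero there, so the limit is 0).  No code path branches on
#' `Z`.
#'
#' @param q Momentum transfer in 1/Angstrom; non-negative, finite.
#'   Values above 50 are permitted but flagged with a warning as
#'   extrapolation beyond the calibrated range.  Vectorized.
#' @param params An `ff_params` object, e.g. from [get_params()] or
#'   [fit_parameters()].
#' @return Dimensionless form-factor values, finite and non-negative.
#' @examples
#' empirical_ff(c(0, 1, 10), get_params(14))
#' @export
empirical_ff <- function(q, params) {
  if (!inherits(params, "ff_params")) {
    stop("`params` must be an `ff_params` object", call. = FALSE)
  }
  if (!is.numeric(q) || any(!is.finite(q))) {
    stop("`q` must be finite numeric", call. = FALSE)
  }
  if (any(q < 0)) {
    stop("`q` must be non-negative", call. = FALSE)
  }
  if (any(q > .Q_FIT_MAX)) {
    warning(sprintf(
      "evaluating beyond the calibrated range q <= %g 1/Angstrom (extrapolation)",
      .Q_FIT_MAX), call. = FALSE)
  }
  x2 <- (q * physical_constants()$a0 / 2)^2
  params$Z *
    .lorentz_factor(params$a1, params$b1, x2)^params$r *
    .lorentz_factor(params$a2, params$b2, x2) *
    .lorentz_factor(params$a3, params$b3, x2)
}

# a / (a + b * x2) with the q -> 0 limit convention for a == 0: the factor is
# identically zero on q > 0, so its limit (and value) at x2 = 0 is taken as 0.
.lorentz_factor <- function(a, b, x2) {
  if (a == 0) {
    return(rep(0, length(x2)))
  }
  a / (a + b * x2)
}

#' Pointwise percent deviation between reference and calculated values
#'
#' \deqn{\Delta_i = \left|\frac{f_{ref} - f_{calc}}{f_{ref}}\right| \times 100}
#'
#' @param f_ref Reference (tabulated) values; must be nonzero.
#' @param f_calc Calculated values, same length or length 1.
#' @return Percent deviations, non-negative.
#' @examples
#' percent_deviation(2, 1)       # 50
#' percent_deviation(1, 1.003)   # 0.3
#' @export
percent_deviation <- function(f_ref, f_calc) {
  if (any(f_ref == 0)) {
    stop("percent deviation is undefined where `f_ref` is zero", call. = FALSE)
  }
  100 * abs((f_ref - f_calc) / f_ref)
}

#' Reference form-factor table
#'
#' Container for a tabulated form factor of one element: a strictly
#' ascending momentum-transfer grid and the matching dimensionless values.
#'
#' @param Z Atomic number the table describes.
#' @param q Momentum-transfer grid in 1/Angstrom, strictly ascending, >= 0.
#' @param f Form-factor values, same length, finite and non-negative.
#' @param comments Optional character vector of metadata lines (for tables
#'   read from disk).
#' @return An object of class `ff_table` with fields `Z`, `q`, `f`,
#'   `comments`.
#' @export
ff_table <- function(Z, q, f, comments = character()) {
  if (length(q) != length(f)) {
    stop("`q` and `f` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q < 0) || any(diff(q) <= 0)) {
    stop("`q` must be finite, non-negative and strictly ascending",
         call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("`f` must be finite and non-negative", call. = FALSE)
  }
  if (q[1] == 0 && abs(f[1] - Z) > 0.01 * Z) {
    stop(sprintf(
      "f at q = 0 is %g but should be within 1%% of Z = %d (form-factor normalization)",
      f[1], as.integer(Z)), call. = FALSE)
  }
  structure(list(Z = as.integer(Z), q = as.numeric(q), f = as.numeric(f),
                 comments = comments),
            class = "ff_table")
}

#' @export
print.ff_table <- function(x, ...) {
  cat(sprintf("Form-factor table: Z = %d, %d points, q in [%g, %g] 1/Angstrom\n",
              x$Z, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Deviation summary of the empirical function against a reference table
#'
#' Evaluates the empirical function on the reference grid, applies the
#' pointwise percent deviation, and summarizes it by maximum, mean and
#' population standard deviation (n in the denominator).
#'
#' @param ref An [ff_table()] of reference values; all `f` must be positive.
#' @param params An `ff_params` object with `params$Z == ref$Z`.
#' @return An object of class `deviation_summary`: list with `delta_max`,
#'   `delta_mean`, `delta_std` (percent) and `n_points`.
#' @examples
#' q <- seq(0, 50, length.out = 201)
#' ref <- ff_table(1, q, hydrogen_ff(q))
#' deviation_summary(ref, get_params(1))
#' @export
deviation_summary <- function(ref, params) {
  if (!inherits(ref, "ff_table")) {
    stop("`ref` must be an `ff_table`", call. = FALSE)
  }
  if (!inherits(params, "ff_params")) {
    stop("`params` must be an `ff_params` object", call. = FALSE)
  }
  if (ref$Z != params$Z) {
    stop(sprintf("element mismatch: table is Z = %d, parameters are Z = %d",
                 ref$Z, params$Z), call. = FALSE)
  }
  if (any(ref$f == 0)) {
    bad <- ref$q[which(ref$f == 0)[1]]
    stop(sprintf(
      "reference value is zero at q = %g: percent deviation undefined", bad),
      call. = FALSE)
  }
  calc <- suppressWarnings(empirical_ff(ref$q, params))
  dev <- percent_deviation(ref$f, calc)
  n <- length(dev)
  m <- mean(dev)
  out <- list(delta_max = max(dev), delta_mean = m,
              delta_std = sqrt(sum((dev - m)^2) / n), n_points = n)
  class(out) <- "deviation_summary"
  out
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat(sprintf(
    "Percent deviation over %d grid points: max %.5f, mean %.5f, sd %.5f\n",
    x$n_points, x$delta_max, x$delta_mean, x$delta_std))
  invisible(x)
}
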