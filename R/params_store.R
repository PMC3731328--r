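# Bit-exact storage and retrieval of the packaged element parameter table.
#
# The table is shipped as decimal strings in a CSV and parsed to double on
# load, so the file stays diffable against its printed source digits.  The
# special value 1E5 for a2, a3 of hydrogen is data, not code: nothing in the
# evaluators branches on Z.

.params_env <- new.env(parent = emptyenv())

.table_path <- function() {
  system.file("extdata", "table1_parameters.csv", package = "ffmc",
              mustWork = TRUE)
}

# Loads (once) and caches both the numeric table and the verbatim strings.
.load_table <- function() {
  if (!is.null(.params_env$table)) {
    return(.params_env$table)
  }
  path <- .table_path()
  raw <- utils::read.csv(path, colClasses = "character")
  num <- as.data.frame(lapply(raw, function(col) as.numeric(col)))
  num$Z <- as.integer(num$Z)
  stopifnot(identical(num$Z, seq.int(.Z_MIN, .Z_MAX)))
  .params_env$raw <- raw
  .params_env$table <- num
  num
}

.check_z <- function(Z) {
  if (length(Z) != 1L || !is.numeric(Z) || !is.finite(Z) || Z != round(Z)) {
    stop("`Z` must be a single integer atomic number", call. = FALSE)
  }
  Z <- as.integer(Z)
  if (Z < .Z_MIN || Z > .Z_MAX) {
    stop(sprintf(
      "Z = %d is outside the supported range %d..%d of the packaged parameter table",
      Z, .Z_MIN, .Z_MAX), call. = FALSE)
  }
  Z
}

#' Retrieve the packaged fit parameters for one element
#'
#' Looks up the seven-parameter row (r, a1, b1, a2, b2, a3, b3) for atomic
#' number `Z` exactly as stored in the packaged table, together with the
#' quoted percent-deviation statistics of the original fit.
#'
#' @param Z Atomic number, an integer in 1..30.
#' @return An object of class `ff_params`: a list with fields `Z`, `r`,
#'   `a1`, `b1`, `a2`, `b2`, `a3`, `b3`, `delta_max`, `delta_mean`,
#'   `delta_std`.
#' @examples
#' p <- get_params(14)
#' p$r
#' @seealso [list_supported()], [printed_deviation_stats()], [empirical_ff()]
#' @export
get_params <- function(Z) {
  Z <- .check_z(Z)
  tab <- .load_table()
  row <- tab[tab$Z == Z, , drop = FALSE]
  out <- as.list(row)
  out$Z <- as.integer(out$Z)
  class(out) <- "ff_params"
  out
}

#' Construct an `ff_params` object from explicit values
#'
#' Used by the refitting engine and by users exploring their own parameter
#' sets.  Values are validated for positivity of `r` and `a1`; the deviation
#' statistics are optional.
#'
#' @param Z Atomic number the parameters describe.
#' @param r,a1,b1,a2,b2,a3,b3 The seven free parameters.
#' @param delta_max,delta_mean,delta_std Optional percent-deviation
#'   statistics to carry along (for example from [deviation_summary()]).
#' @return An `ff_params` object.
#' @export
ff_params <- function(Z, r, a1, b1, a2, b2, a3, b3,
                      delta_max = NA_real_, delta_mean = NA_real_,
                      delta_std = NA_real_) {
  vals <- c(r = r, a1 = a1, b1 = b1, a2 = a2, b2 = b2, a3 = a3, b3 = b3)
  if (!all(is.finite(vals))) {
    stop("all seven parameters must be finite", call. = FALSE)
  }
  if (r <= 0 || a1 <= 0) {
    stop("`r` and `a1` must be positive", call. = FALSE)
  }
  out <- c(list(Z = as.integer(Z)), as.list(vals),
           list(delta_max = delta_max, delta_mean = delta_mean,
                delta_std = delta_std))
  class(out) <- "ff_params"
  out
}

#' @export
print.ff_params <- function(x, ...) {
  cat(sprintf("Empirical form-factor parameters (Z = %d)\n", x$Z))
  cat(sprintf("  r  = %g\n", x$r))
  cat(sprintf("  a  = (%g, %g, %g)\n", x$a1, x$a2, x$a3))
  cat(sprintf("  b  = (%g, %g, %g)\n", x$b1, x$b2, x$b3))
  if (is.finite(x$delta_max)) {
    cat(sprintf("  quoted deviation: max %g%%, mean %g%%, sd %g%%\n",
                x$delta_max, x$delta_mean, x$delta_std))
  }
  invisible(x)
}

#' List the atomic numbers covered by the packaged table
#'
#' @return Integer vector `1:30`, ascending.
#' @examples
#' list_supported()
#' @export
list_supported <- function() {
  .load_table()$Z
}

#' Quoted deviation statistics for one element
#'
#' Returns the three percent-deviation summaries (maximum, mean, standard
#' deviation of the pointwise percent deviation against the reference
#' tabulation) stored alongside the packaged parameters, for cross-checking
#' recomputed deviations.
#'
#' @inheritParams get_params
#' @return A named numeric vector `c(delta_max, delta_mean, delta_std)`, in
#'   percent.
#' @examples
#' printed_deviation_stats(1)
#' @export
printed_deviation_stats <- function(Z) {
  p <- get_params(Z)
  c(delta_max = p$delta_max, delta_mean = p$delta_mean,
    delta_std = p$delta_std)
}

# Verbatim string table, for round-trip / audit tests.
.raw_table <- function() {
  .load_table()
  .params_env$raw
}
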