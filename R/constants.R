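#' Physical constants used throughout ffmc
#'
#' Returns the two constants every kinematic and form-factor computation in
#' the package relies on.  The Bohr radius is deliberately the value the
#' bundled parameter table was calibrated with (0.52978 Angstrom), not the
#' CODATA value; changing it would silently invalidate the packaged fit.
#'
#' @return A list with components
#'   \describe{
#'     \item{a0}{Bohr radius in Angstrom (0.52978).}
#'     \item{hc}{Photon energy-wavelength conversion in keV * Angstrom
#'       (12.398419), so that \code{lambda = hc / E_keV}.}
#'   }
#' @examples
#' physical_constants()$a0
#' @export
physical_constants <- function() {
  list(a0 = 0.52978, hc = 12.398419)
}

# Range of momentum transfer (1/Angstrom) the empirical fit is designed for.
.Q_FIT_MAX <- 50

# Supported atomic numbers.
.Z_MIN <- 1L
.Z_MAX <- 30L
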