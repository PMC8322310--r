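#' Thermal energy in piconewton-nanometres
#'
#' `k_B T` at the given temperature, in the mechanical units used throughout
#' the package (forces in pN, lengths in nm). Uses the exact SI Boltzmann
#' constant, 1.380649e-2 pN nm / K; at the default 298 K this is 4.1143 pN nm.
#'
#' @param temperature Temperature in kelvin.
#' @return Thermal energy in pN nm.
#' @export
#' @examples
#' kBT(298)
kBT <- function(temperature = 298) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  1.380649e-2 * temperature
}

# Euler-Mascheroni constant, used by the closed-form mean rupture force
.euler_gamma <- 0.5772156649015329

#' Nominal loading rate of a constant-velocity pulling experiment
#'
#' The loading rate is the cantilever spring constant times the pulling
#' velocity.
#'
#' @param spring_constant Cantilever spring constant, pN/nm.
#' @param velocity Pulling velocity, nm/s.
#' @return Loading rate in pN/s.
#' @export
#' @examples
#' loading_rate(30, 2000) # 6e4 pN/s
#' Residue count behind a contour-length increment
#'
#' Each residue contributes about 0.38 nm to the contour of a fully
#' extended polypeptide, so an unfolding increment of `delta_lc` nm
#' corresponds to `round(delta_lc / 0.38)` residues.
#'
#' @param delta_lc Contour-length increment(s), nm.
#' @param rise_per_residue Contour gain per residue, nm.
#' @return Integer residue count(s).
#' @export
#' @examples
#' residues_from_increment(c(16, 24.5)) # 42, 64
residues_from_increment <- function(delta_lc, rise_per_residue = 0.38) {
  stopifnot(all(delta_lc > 0), rise_per_residue > 0)
  as.integer(round(delta_lc / rise_per_residue))
}

loading_rate <- function(spring_constant, velocity) {
  if (any(!is.finite(spring_constant)) || any(spring_constant <= 0)) {
    stop("`spring_constant` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(velocity)) || any(velocity <= 0)) {
    stop("`velocity` must be positive and finite", call. = FALSE)
  }
  spring_constant * velocity
}
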