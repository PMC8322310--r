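#' Default unfolding classes for the two pulling geometries
#'
#' Four contour-length-increment classes per pulling mode, with per-class
#' Bell kinetics (zero-force rate `k0 = 1/lifetime` and transition-state
#' distance `x_beta`) and the default sampling weight used when a construct
#' is assembled for simulation. HAP (handle-assisted pulling) favours the
#' long ~24.5/~33 nm increments and carries a long entropic spacer; PAP
#' (partner-assisted pulling) favours the short ~6.5 nm increment.
#'
#' @param mode `"HAP"` or `"PAP"`.
#' @return A tibble with columns `label`, `delta_lc`, `k0`, `x_beta`,
#'   `weight`.
#' @export
#' @examples
#' default_mode_classes("PAP")
default_mode_classes <- function(mode = c("HAP", "PAP")) {
  mode <- match.arg(mode)
  if (mode == "HAP") {
    tibble::tibble(
      label = c("dL6.4", "dL15.8", "dL24.5", "dL33.7"),
      delta_lc = c(6.4, 15.8, 24.5, 33.7),
      k0 = 1 / c(0.026, 0.010, 0.039, 0.030),
      x_beta = c(0.086, 0.071, 0.108, 0.088),
      weight = c(0.10, 0.20, 0.30, 0.40)
    )
  } else {
    tibble::tibble(
      label = c("dL6.5", "dL16.9", "dL24.6", "dL33.2"),
      delta_lc = c(6.5, 16.9, 24.6, 33.2),
      k0 = 1 / c(0.038, 0.027, 0.052, 0.061),
      x_beta = c(0.096, 0.054, 0.079, 0.074),
      weight = c(0.50, 0.20, 0.20, 0.10)
    )
  }
}

#' Assemble a random construct for one simulated pulling curve
#'
#' Draws `n_units` unfolding units i.i.d. from the per-class weights and
#' wraps them in a [protein_model()] with the mode's initial contour length
#' (the ~75 nm entropic spacer in HAP, the short ~6.5 nm initial segment in
#' PAP). Uses the current RNG state; seed externally for reproducibility.
#'
#' @param mode `"HAP"` or `"PAP"`.
#' @param n_units Number of unfoldable units in the construct.
#' @param classes Class table as from [default_mode_classes()]; must have
#'   columns `label`, `delta_lc`, `k0`, `x_beta`, `weight`.
#' @param initial_contour_length Contour length before any unfolding, nm;
#'   defaults to 75 (HAP) or 6.5 (PAP).
#' @param persistence_length Persistence length, nm.
#' @return A `protein_model`.
#' @export
sample_construct <- function(mode = c("HAP", "PAP"), n_units = 6,
                             classes = default_mode_classes(mode),
                             initial_contour_length = NULL,
                             persistence_length = 0.5) {
  mode <- match.arg(mode)
  if (is.null(initial_contour_length)) {
    initial_contour_length <- if (mode == "HAP") 75 else 6.5
  }
  w <- classes$weight / sum(classes$weight)
  draw <- sample.int(nrow(classes), n_units, replace = TRUE, prob = w)
  units <- classes[draw, c("label", "delta_lc", "k0", "x_beta")]
  units$count <- 1L
  protein_model(units, initial_contour_length, persistence_length,
                mode = mode, model_id = paste0(mode, "_construct"))
}
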