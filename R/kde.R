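#' Rule-of-thumb kernel bandwidth for force distributions
#'
#' Silverman-type bandwidth `H = 1.06 n^(-1/5) sigma` with the robust
#' spread `sigma = min(sigma_x, IQR / 1.34)`, where `sigma_x` is the sample
#' standard deviation (n-1 denominator) and the interquartile range uses
#' linearly interpolated quantiles (R type 7). A zero spread (constant
#' sample) falls back to `H = 1e-3 * (max - min + 1)` with a warning.
#'
#' @param sample Numeric vector, length >= 2.
#' @return Bandwidth in the units of `sample`.
#' @export
#' @examples
#' kde_bandwidth(1:5) # ~1.147
kde_bandwidth <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 2) stop("bandwidth needs at least 2 observations", call. = FALSE)
  sigma_x <- stats::sd(sample)
  iqr <- diff(stats::quantile(sample, c(0.25, 0.75), names = FALSE, type = 7))
  sigma <- min(sigma_x, iqr / 1.34)
  if (sigma <= 0) {
    warning("zero spread; falling back to a nominal bandwidth", call. = FALSE)
    return(1e-3 * (max(sample) - min(sample) + 1))
  }
  1.06 * n^(-1 / 5) * sigma
}

#' Most probable force by kernel density estimation
#'
#' Gaussian-kernel KDE of a rupture-force sample with the bandwidth rule of
#' [kde_bandwidth()], evaluated on a 512-point grid extending 4 bandwidths
#' beyond the sample range (so the density normalizes on the grid). The
#' most probable force `F_mp` is the grid argmax; exact ties break to the
#' lower force.
#'
#' @param forces Numeric vector of rupture forces, pN; length >= 5.
#' @param bandwidth Optional bandwidth override, pN.
#' @param n_grid Grid size.
#' @return A list of class `kde_result`: `f_mp`, `bandwidth`, `n`, `grid`,
#'   `density`.
#' @export
#' @examples
#' most_probable_force(rnorm(500, 60, 5))$f_mp
most_probable_force <- function(forces, bandwidth = NULL, n_grid = 512) {
  forces <- as.numeric(forces)
  n <- length(forces)
  if (n < 5) stop("need at least 5 force measurements", call. = FALSE)
  H <- bandwidth %||% kde_bandwidth(forces)
  lo <- min(forces) - 4 * H
  hi <- max(forces) + 4 * H
  d <- stats::density(forces, bw = H, kernel = "gaussian", n = n_grid,
                      from = lo, to = hi)
  # ties (densities equal within grid tolerance) break to the lower force
  imax <- which(d$y >= max(d$y) * (1 - 1e-9))[1]
  structure(
    list(f_mp = d$x[imax], bandwidth = H, n = n,
         grid = d$x, density = d$y),
    class = "kde_result"
  )
}

#' @export
print.kde_result <- function(x, ...) {
  cat(sprintf("<kde_result> n = %d, H = %.4g, F_mp = %.4g\n",
              x$n, x$bandwidth, x$f_mp))
  invisible(x)
}

#' Per-class, per-loading-rate force distributions
#'
#' Groups classified events by (mode, class, velocity), computes the
#' loading rate and the KDE most-probable force of each group. Groups
#' smaller than `min_n` are dropped.
#'
#' @param events Event tibble from [analyze_dataset()] (classified events
#'   with `peak_force_pN`).
#' @param min_n Minimum events per (mode, class, velocity) group.
#' @return Tibble: `mode`, `class`, `velocity_nm_per_s`,
#'   `loading_rate_pN_per_s`, `n`, `bandwidth_pN`, `f_mp_pN`,
#'   `f_se_pN` (standard error of the mean force, a scale for weighting).
#' @export
force_distributions <- function(events, min_n = 5) {
  ev <- dplyr::filter(events, !is.na(.data$class),
                      .data$class != "unclassified",
                      !.data$negative_increment)
  ev |>
    dplyr::group_by(.data$mode, .data$class, .data$velocity_nm_per_s,
                    .data$loading_rate_pN_per_s) |>
    dplyr::filter(dplyr::n() >= min_n) |>
    dplyr::summarise(
      n = dplyr::n(),
      bandwidth_pN = kde_bandwidth(.data$peak_force_pN),
      f_mp_pN = most_probable_force(.data$peak_force_pN)$f_mp,
      f_se_pN = stats::sd(.data$peak_force_pN) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
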