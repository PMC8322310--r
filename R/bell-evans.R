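#' Fit the Bell-Evans model to most-probable force vs loading rate
#'
#' The Bell-Evans relation
#' \deqn{F_{mp} = \frac{k_B T}{x_\beta}\,
#'   \ln\!\frac{LR \cdot x_\beta}{k_u^0 k_B T}}
#' is exactly linear in `ln(LR)`, so the fit is a linear regression of
#' `F_mp` on `ln(LR)`: slope `a = kBT / x_beta` and intercept `c` give
#' `x_beta = kBT / a` and `k_u0 = (1/a) exp(-c/a)`. Standard errors are
#' propagated from the regression covariance by the delta method. When
#' per-point standard errors are supplied, `1/SE^2` weighting is available
#' (off by default).
#'
#' @param points A data frame with columns `loading_rate_pN_per_s` and
#'   `f_mp_pN` (optionally `f_se_pN`, `n`); at least 2 rows, increasing
#'   force with loading rate. Output of [force_distributions()] works
#'   directly (fit per mode/class group before calling, e.g. with
#'   `dplyr::group_split()`).
#' @param temperature Temperature, K.
#' @param weighted Use `1 / f_se_pN^2` regression weights.
#' @return An object of class `bell_evans_fit`: `k_u0` (1/s), `tau`
#'   (= 1/k_u0, s), `x_beta` (nm), their standard errors, `temperature`,
#'   the underlying `lm` fit and the data.
#' @export
#' @examples
#' lr <- c(1.5e4, 3e4, 6e4, 9e4, 1.5e5)
#' f <- bell_evans_force(lr, k_u0 = 16.4, x_beta = 0.074)
#' fit_bell_evans(data.frame(loading_rate_pN_per_s = lr, f_mp_pN = f))
fit_bell_evans <- function(points, temperature = 298, weighted = FALSE) {
  stopifnot(is.data.frame(points))
  req <- c("loading_rate_pN_per_s", "f_mp_pN")
  if (!all(req %in% names(points))) {
    stop("`points` needs columns loading_rate_pN_per_s and f_mp_pN",
         call. = FALSE)
  }
  if (nrow(points) < 2) {
    stop("Bell-Evans fit needs at least 2 loading-rate points", call. = FALSE)
  }
  if (any(points$loading_rate_pN_per_s <= 0) || any(points$f_mp_pN <= 0)) {
    stop("loading rates and forces must be positive", call. = FALSE)
  }
  kbt <- kBT(temperature)
  dat <- data.frame(lnLR = log(points$loading_rate_pN_per_s),
                    F = points$f_mp_pN)
  w <- NULL
  if (weighted) {
    if (!"f_se_pN" %in% names(points) || any(!is.finite(points$f_se_pN)) ||
        any(points$f_se_pN <= 0)) {
      stop("weighted fit needs positive finite `f_se_pN`", call. = FALSE)
    }
    w <- 1 / points$f_se_pN^2
  }
  fit <- stats::lm(F ~ lnLR, data = dat, weights = w)
  a <- stats::coef(fit)[["lnLR"]]
  cc <- stats::coef(fit)[["(Intercept)"]]
  if (!is.finite(a) || a <= 0) {
    stop("Bell-Evans inapplicable: forces do not increase with loading rate",
         call. = FALSE)
  }
  x_beta <- kbt / a
  k_u0 <- (1 / a) * exp(-cc / a)

  # delta method on (a, c) -> (x_beta, k_u0)
  V <- stats::vcov(fit)[c("lnLR", "(Intercept)"), c("lnLR", "(Intercept)")]
  dxb <- c(-kbt / a^2, 0)
  dk0 <- c(k_u0 * (cc / a^2 - 1 / a), -k_u0 / a)
  x_beta_se <- sqrt(drop(t(dxb) %*% V %*% dxb))
  k_u0_se <- sqrt(drop(t(dk0) %*% V %*% dk0))

  structure(
    list(k_u0 = k_u0, tau = 1 / k_u0, x_beta = x_beta,
         k_u0_se = k_u0_se, tau_se = k_u0_se / k_u0^2,
         x_beta_se = x_beta_se, temperature = temperature,
         weighted = weighted, lm = fit, points = tibble::as_tibble(points)),
    class = "bell_evans_fit"
  )
}

#' Bell-Evans most-probable force at a loading rate
#'
#' Forward evaluation of the Bell-Evans relation (see [fit_bell_evans()]).
#'
#' @param loading_rate Loading rate(s), pN/s.
#' @param k_u0 Zero-force unfolding rate, 1/s.
#' @param x_beta Transition-state distance, nm.
#' @param temperature Temperature, K.
#' @return Most probable force, pN.
#' @export
bell_evans_force <- function(loading_rate, k_u0, x_beta, temperature = 298) {
  kbt <- kBT(temperature)
  (kbt / x_beta) * log(loading_rate * x_beta / (k_u0 * kbt))
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf(
    "<bell_evans_fit> k_u0 = %.4g 1/s (tau = %.4g s), x_beta = %.4g nm [%d points, T = %g K]\n",
    x$k_u0, x$tau, x$x_beta, nrow(x$points), x$temperature))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bell_evans_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_u0", "tau", "x_beta"),
    estimate = c(x$k_u0, x$tau, x$x_beta),
    std.error = c(x$k_u0_se, x$tau_se, x$x_beta_se),
    unit = c("1/s", "s", "nm")
  )
}

#' @export
glance.bell_evans_fit <- function(x, ...) {
  s <- summary(x$lm)
  tibble::tibble(
    n = nrow(x$points), r.squared = s$r.squared,
    sigma = s$sigma, temperature_K = x$temperature,
    weighted = x$weighted
  )
}

#' Arrhenius barrier height from the intrinsic unfolding rate
#'
#' `dG* = -ln(k_u0 / A)` in units of `k_B T`, with Arrhenius prefactor `A`
#' (default 1e9 1/s, the standard protein-dynamics attempt frequency).
#'
#' @param k_u0 Zero-force unfolding rate, 1/s; must not exceed `A`.
#' @param prefactor Arrhenius prefactor `A`, 1/s.
#' @return Barrier height as a multiple of `k_B T`.
#' @export
#' @examples
#' barrier_height(1 / 0.027) # ~17.1 kBT
barrier_height <- function(k_u0, prefactor = 1e9) {
  if (any(k_u0 <= 0)) stop("`k_u0` must be positive", call. = FALSE)
  if (any(k_u0 > prefactor)) {
    stop("`k_u0` exceeds the prefactor: negative barrier", call. = FALSE)
  }
  -log(k_u0 / prefactor)
}

#' Critical force that abolishes the unfolding barrier
#'
#' By default reproduces the printed-table numeric convention: the barrier
#' height expressed as its `k_B T` multiple divided by `x_beta` in nm,
#' labelled pN. That convention treats `k_B T` as numerically 1 pN nm; the
#' physically dimensioned force is obtained with `physical_units = TRUE`,
#' which multiplies by `k_B T` = 4.114 pN nm (at 298 K).
#'
#' @param dG_kBT Barrier height, `k_B T` multiples.
#' @param x_beta Transition-state distance, nm.
#' @param physical_units Multiply by `k_B T` to get a true pN value.
#' @param temperature Temperature, K (used only when `physical_units`).
#' @return Critical force (table convention, or pN when
#'   `physical_units = TRUE`).
#' @export
#' @examples
#' critical_force(17.5, 0.108) # 162.0
critical_force <- function(dG_kBT, x_beta, physical_units = FALSE,
                           temperature = 298) {
  if (any(dG_kBT <= 0) || any(x_beta <= 0)) {
    stop("`dG_kBT` and `x_beta` must be positive", call. = FALSE)
  }
  fc <- dG_kBT / x_beta
  if (physical_units) fc <- fc * kBT(temperature)
  fc
}

#' Kinetic summary table across modes and increment classes
#'
#' One row per (mode, class): mean increment, lifetime, transition-state
#' distance with standard errors, Arrhenius barrier height and critical
#' force — the machine twin of a printed kinetic-parameters table. Rows are
#' sorted by increment within mode.
#'
#' @param fits A tibble with one row per (mode, class) carrying columns
#'   `mode`, `class`, `delta_lc_nm`, `delta_lc_se_nm`, `lifetime_s`,
#'   `lifetime_se_s`, `x_beta_nm`, `x_beta_se_nm` (as assembled from
#'   [fit_bell_evans()] results; see the vignette pipeline).
#' @param prefactor Arrhenius prefactor, 1/s.
#' @param temperature Temperature, K.
#' @return The input tibble with `dG_kBT`, `Fc_table_convention` and
#'   `Fc_pN_physical` appended, sorted by `mode`, `delta_lc_nm`.
#' @export
kinetic_table <- function(fits, prefactor = 1e9, temperature = 298) {
  req <- c("mode", "class", "delta_lc_nm", "lifetime_s", "x_beta_nm")
  if (!all(req %in% names(fits))) {
    stop("`fits` must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  fits |>
    dplyr::mutate(
      dG_kBT = barrier_height(1 / .data$lifetime_s, prefactor),
      Fc_table_convention = critical_force(.data$dG_kBT, .data$x_beta_nm),
      Fc_pN_physical = critical_force(.data$dG_kBT, .data$x_beta_nm,
                                      physical_units = TRUE,
                                      temperature = temperature)
    ) |>
    dplyr::arrange(.data$mode, .data$delta_lc_nm)
}
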