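#' Fit the worm-like-chain model to one rising force segment
#'
#' Least-squares fit of the Marko-Siggia interpolation ([wlc_force()]) to
#' (extension, force) samples by Levenberg-Marquardt with box bounds:
#' persistence length constrained to `p_bounds` and contour length bounded
#' below just above the largest extension in the segment (the model
#' diverges there).
#'
#' @param extension,force Numeric vectors (nm, pN) of equal length, at
#'   least 8 samples.
#' @param temperature Temperature, K.
#' @param p_bounds Lower/upper persistence-length bounds, nm.
#' @param Lc_init Starting contour length, nm; defaults to 1.1 x the
#'   largest extension.
#' @param p_init Starting persistence length, nm.
#' @return A list: `Lc`, `p` (nm), `rmse` (pN), `converged` (logical),
#'   `p_at_bound` (TRUE when the persistence length is pinned at a bound,
#'   flagged because the contour length is then less trustworthy).
#' @export
#' @examples
#' x <- seq(5, 90, length.out = 50)
#' f <- wlc_force(x, Lc = 100, p = 0.5)
#' fit_wlc_segment(x, f)
fit_wlc_segment <- function(extension, force, temperature = 298,
                            p_bounds = c(0.1, 2), Lc_init = NULL,
                            p_init = 0.5) {
  stopifnot(length(extension) == length(force))
  if (length(extension) < 8) {
    stop("segment too short: need at least 8 samples", call. = FALSE)
  }
  xmax <- max(extension)
  if (is.null(Lc_init)) Lc_init <- 1.1 * xmax
  if (Lc_init <= xmax) {
    stop("`Lc_init` must exceed the largest extension", call. = FALSE)
  }
  lower <- c(Lc = xmax * 1.0001 + 1e-9, p = p_bounds[1])
  upper <- c(Lc = Inf, p = p_bounds[2])
  dat <- data.frame(x = extension, f = force)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ wlc_force(x, Lc, p, temperature),
      data = dat,
      start = c(Lc = Lc_init, p = min(max(p_init, p_bounds[1]), p_bounds[2])),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop("WLC fit did not converge: ", conditionMessage(fit), call. = FALSE)
  }
  co <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  p_at_bound <- co[["p"]] <= p_bounds[1] + 1e-8 || co[["p"]] >= p_bounds[2] - 1e-8
  if (p_at_bound) {
    warning(sprintf("fitted persistence length pinned at bound (p = %.3g nm)",
                    co[["p"]]), call. = FALSE)
  }
  list(Lc = unname(co["Lc"]), p = unname(co["p"]), rmse = rmse,
       converged = fit$convInfo$isConv %||% TRUE, p_at_bound = p_at_bound)
}
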