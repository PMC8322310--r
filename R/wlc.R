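#' Worm-like chain interpolation force
#'
#' Entropic restoring force of a worm-like chain at end-to-end extension `x`,
#' using the Marko-Siggia interpolation
#' \deqn{F(x) = \frac{k_B T}{p}\left[\frac{1}{4}\left(1 - x/L_c\right)^{-2}
#'   - \frac{1}{4} + \frac{x}{L_c}\right]}
#' with persistence length `p` and contour length `Lc`. The force is zero at
#' zero extension, strictly increasing in `x`, and diverges as `x`
#' approaches `Lc`.
#'
#' @param x Extension, nm. Vectorised; must satisfy `0 <= x < Lc`.
#' @param Lc Contour length, nm (> 0).
#' @param p Persistence length, nm (> 0).
#' @param temperature Temperature, K.
#' @return Force in pN, same length as `x`.
#' @export
#' @examples
#' wlc_force(50, Lc = 100, p = 0.5) # ~10.29 pN
wlc_force <- function(x, Lc, p, temperature = 298) {
  if (!is.numeric(Lc) || any(Lc <= 0)) stop("`Lc` must be positive", call. = FALSE)
  if (!is.numeric(p) || any(p <= 0)) stop("`p` must be positive", call. = FALSE)
  if (any(x < 0)) stop("extension `x` must be non-negative", call. = FALSE)
  if (any(x >= Lc)) {
    stop("extension `x` must be strictly below the contour length `Lc`",
         call. = FALSE)
  }
  t <- x / Lc
  (kBT(temperature) / p) * (0.25 * (1 - t)^-2 - 0.25 + t)
}

# derivative dF/dx of the interpolation formula, pN/nm (internal)
wlc_stiffness <- function(x, Lc, p, temperature = 298) {
  t <- x / Lc
  (kBT(temperature) / p) * (0.5 * (1 - t)^-3 + 1) / Lc
}

#' Force balance of a worm-like chain in series with a cantilever
#'
#' In constant-velocity pulling the piezo position `z` is shared between the
#' molecular extension `x` and the cantilever deflection `F / k_c`:
#' `x = z - F/k_c` with `F = wlc_force(x, ...)`. This solves for the unique
#' root by safeguarded Newton iteration; the WLC divergence at `Lc`
#' guarantees a solution with `x < Lc` for any finite `z`.
#'
#' @param z Piezo position, nm (>= 0). Scalar.
#' @param Lc,p Contour and persistence length, nm.
#' @param spring_constant Cantilever spring constant `k_c`, pN/nm (> 0).
#' @param temperature Temperature, K.
#' @param tol Absolute tolerance on the force residual, pN.
#' @param x_init Optional starting guess for the extension (warm start).
#' @return A list with elements `extension` (nm) and `force` (pN).
#' @export
#' @examples
#' solve_force_balance(90, Lc = 100, p = 0.5, spring_constant = 30)
solve_force_balance <- function(z, Lc, p, spring_constant, temperature = 298,
                                tol = 1e-9, x_init = NULL) {
  if (!is.numeric(z) || length(z) != 1 || z < 0) {
    stop("`z` must be a single non-negative number", call. = FALSE)
  }
  if (spring_constant <= 0) stop("`spring_constant` must be positive", call. = FALSE)
  if (Lc <= 0 || p <= 0) stop("`Lc` and `p` must be positive", call. = FALSE)
  if (z == 0) return(list(extension = 0, force = 0))

  hi <- min(z, Lc * (1 - 1e-12))
  x <- if (!is.null(x_init)) min(max(x_init, 0), hi) else min(0.9 * z, hi)
  lo <- 0
  # residual g(x) = F_wlc(x) - k_c (z - x); strictly increasing in x
  g <- function(x) wlc_force(x, Lc, p, temperature) - spring_constant * (z - x)
  for (iter in seq_len(100)) {
    gx <- g(x)
    if (abs(gx) < tol) break
    if (gx > 0) hi <- x else lo <- x
    step <- gx / (wlc_stiffness(x, Lc, p, temperature) + spring_constant)
    x_new <- x - step
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) x_new <- (lo + hi) / 2
    x <- x_new
  }
  if (abs(g(x)) >= max(tol, 1e-6)) {
    stop(sprintf(
      "force-balance solver did not converge (z=%.4g, Lc=%.4g, residual=%.3g pN)",
      z, Lc, g(x)
    ), call. = FALSE)
  }
  list(extension = x, force = spring_constant * (z - x))
}
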