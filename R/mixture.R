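#' Fit a sum of Gaussians to a histogram of contour-length increments
#'
#' Builds a histogram (Freedman-Diaconis bins by default) and fits the bin
#' counts with a sum of `K` Gaussian components
#' `A_k exp(-(x - mu_k)^2 / (2 s_k^2))` by bounded Levenberg-Marquardt
#' least squares — the "Gaussian fits to the histogram" convention rather
#' than raw-data EM. Components are returned sorted by mean, with standard
#' errors of the means from the fit covariance.
#'
#' @param values Numeric sample (nm); needs at least `10 * K` values.
#' @param K Number of components.
#' @param init_means Starting means, length `K` (required; e.g. the
#'   nominal class centres).
#' @param breaks Histogram breaks: `"FD"` (default) or a number/vector
#'   passed to [graphics::hist()].
#' @param init_sd Starting component SD, nm.
#' @return A list of class `increment_histogram`: `breaks`, `mids`,
#'   `counts`, and `components` (tibble: `mean_nm`, `sd_nm`, `amplitude`,
#'   `se_mean_nm`), plus `rmse`.
#' @export
#' @examples
#' x <- c(rnorm(300, 6.5, 1.5), rnorm(300, 16, 1.5))
#' fit_gaussian_mixture_hist(x, K = 2, init_means = c(6.5, 16))
fit_gaussian_mixture_hist <- function(values, K, init_means,
                                      breaks = "FD", init_sd = 1.5) {
  values <- values[is.finite(values)]
  if (length(values) < 10 * K) {
    stop("need at least 10 observations per component", call. = FALSE)
  }
  if (length(init_means) != K) {
    stop("`init_means` must have length K", call. = FALSE)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  bw <- mids[2] - mids[1]

  # parameter vector: (mu_1..K, log s_1..K handled via bounds, A_1..K)
  start <- list()
  lower <- c(); upper <- c()
  for (k in seq_len(K)) {
    start[[paste0("mu", k)]] <- init_means[k]
    near <- which.min(abs(mids - init_means[k]))
    start[[paste0("A", k)]] <- max(counts[near], 1)
    start[[paste0("s", k)]] <- init_sd
  }
  pars <- unlist(start)
  lower <- stats::setNames(rep(-Inf, length(pars)), names(pars))
  upper <- stats::setNames(rep(Inf, length(pars)), names(pars))
  lower[grep("^A", names(pars))] <- 0
  lower[grep("^s", names(pars))] <- bw / 10
  lower[grep("^mu", names(pars))] <- min(values)
  upper[grep("^mu", names(pars))] <- max(values)

  mix_fun <- function(par, x) {
    y <- 0
    for (k in seq_len(K)) {
      y <- y + par[[paste0("A", k)]] *
        exp(-(x - par[[paste0("mu", k)]])^2 / (2 * par[[paste0("s", k)]]^2))
    }
    y
  }
  resid_fun <- function(par) counts - mix_fun(as.list(par), mids)
  fit <- minpack.lm::nls.lm(par = pars, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info %in% c(0, 5)) {
    stop("Gaussian mixture fit did not converge (best RMSE ",
         signif(sqrt(mean(fit$fvec^2)), 4), ")", call. = FALSE)
  }
  est <- fit$par
  # SEs from the covariance of the least-squares fit
  se <- tryCatch({
    cv <- stats::vcov(fit)
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)

  comp <- tibble::tibble(
    mean_nm = vapply(seq_len(K), function(k) est[[paste0("mu", k)]], 1),
    sd_nm = vapply(seq_len(K), function(k) abs(est[[paste0("s", k)]]), 1),
    amplitude = vapply(seq_len(K), function(k) est[[paste0("A", k)]], 1),
    se_mean_nm = vapply(seq_len(K), function(k) se[[paste0("mu", k)]], 1)
  )
  if (any(comp$sd_nm < bw / 2)) {
    warning("a mixture component collapsed below half the bin width",
            call. = FALSE)
  }
  comp <- dplyr::arrange(comp, .data$mean_nm)
  structure(
    list(breaks = h$breaks, mids = mids, counts = counts,
         components = comp, rmse = sqrt(mean(fit$fvec^2))),
    class = "increment_histogram"
  )
}

#' @export
print.increment_histogram <- function(x, ...) {
  cat(sprintf("<increment_histogram> %d bins, %d components, fit RMSE %.3g\n",
              length(x$counts), nrow(x$components), x$rmse))
  print(x$components)
  invisible(x)
}
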