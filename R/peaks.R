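#' Detect unfolding peaks in a force-extension curve
#'
#' A rupture is a local maximum of the moving-mean-smoothed force, at or
#' above `min_peak_force`, followed within `drop_window` nm of extension by
#' a force drop of at least `min_drop` pN. The rupture index is then
#' refined on the raw trace as the sample preceding the largest single-step
#' force drop near the smoothed candidate (the unfolding discontinuity is
#' much larger than the noise). Each detected rupture closes a
#' `PeakSegment`: the stretch of samples from the end of the previous
#' rupture's drop to the rupture, which is the rising WLC branch fitted by
#' [fit_wlc_segment()].
#'
#' @param curve A `force_curve` tibble (needs `extension_nm`, `force_pN`).
#' @param min_drop Minimum force drop identifying a rupture, pN.
#' @param min_peak_force Minimum smoothed peak force, pN.
#' @param smooth_window Moving-mean window, samples (odd).
#' @param drop_window Extension window within which the drop must occur, nm.
#' @return A tibble of segments: `start`, `end` (half-open sample range of
#'   the rising stretch), `rupture` (index), `peak_force_smooth_pN`.
#' @export
detect_unfolding_peaks <- function(curve, min_drop = 20, min_peak_force = 20,
                                   smooth_window = 11, drop_window = 5) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0)
  if (min_drop <= 0) stop("`min_drop` must be > 0", call. = FALSE)
  n <- nrow(curve)
  if (smooth_window >= n) {
    stop("`smooth_window` must be smaller than the curve length", call. = FALSE)
  }
  f <- curve$force_pN
  x <- curve$extension_nm
  sm <- moving_mean(f, smooth_window)

  # local maxima of the smoothed force above threshold
  cand <- which(diff(sign(c(diff(sm), -1))) < 0)
  cand <- cand[sm[cand] >= min_peak_force]

  half <- smooth_window %/% 2
  segs <- list()
  pos <- 1L # start of the current rising stretch
  for (i in cand) {
    if (i <= pos) next
    # window of samples within drop_window nm of extension past the peak
    j <- i
    while (j < n && x[j + 1] - x[i] <= drop_window) j <- j + 1L
    if (j == i) next
    trough <- i + which.min(sm[(i + 1):j])
    if (sm[i] - sm[trough] < min_drop) next
    # refine on raw data: biggest single-step drop near the candidate
    lo <- max(pos, i - smooth_window)
    hi <- min(n - 1L, trough + half)
    d <- f[(lo + 1):(hi + 1)] - f[lo:hi]
    rupture <- lo + which.min(d) - 1L
    if (rupture - pos + 1L >= 2L) {
      segs[[length(segs) + 1L]] <- tibble::tibble(
        start = pos, end = rupture + 1L, rupture = rupture,
        peak_force_smooth_pN = sm[i]
      )
    }
    pos <- rupture + 1L
    # skip past the trough so the next rise starts clean
    pos <- max(pos, trough)
  }
  if (!length(segs)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          rupture = integer(),
                          peak_force_smooth_pN = double()))
  }
  dplyr::bind_rows(segs)
}

# centered moving mean with truncated windows at the edges
moving_mean <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
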