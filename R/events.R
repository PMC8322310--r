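#' Extract unfolding events from one force curve
#'
#' Runs peak detection ([detect_unfolding_peaks()]) and fits every detected
#' rising stretch with the worm-like-chain model ([fit_wlc_segment()]). The
#' per-event unfolding force is the fitted WLC force evaluated at the
#' rupture extension (forces are read off the model fit, not the noisy raw
#' maximum). Events whose fit fails are dropped with a message.
#'
#' @param curve A `force_curve` (simulated or read from disk).
#' @param curve_id Identifier copied into the output.
#' @param min_drop,min_peak_force,smooth_window,drop_window Peak-detection
#'   settings, see [detect_unfolding_peaks()].
#' @param p_bounds Persistence-length bounds for the WLC fits, nm.
#' @param min_segment_samples Segments shorter than this are skipped.
#' @return A tibble with one row per unfolding event: `curve_id`,
#'   `ordinal`, `rupture_index`, `rupture_extension_nm`, `peak_force_pN`,
#'   `Lc_nm`, `p_nm`, `rmse_pN`, `p_at_bound`, plus the curve metadata
#'   columns `mode`, `velocity_nm_per_s`, `spring_constant_pN_per_nm`,
#'   `temperature_K`.
#' @export
analyze_curve <- function(curve, curve_id = "curve",
                          min_drop = 20, min_peak_force = 20,
                          smooth_window = 11, drop_window = 5,
                          p_bounds = c(0.1, 2),
                          min_segment_samples = 8) {
  md <- attr(curve, "metadata") %||% list()
  temperature <- md$temperature_K %||% 298
  segs <- detect_unfolding_peaks(curve, min_drop = min_drop,
                                 min_peak_force = min_peak_force,
                                 smooth_window = smooth_window,
                                 drop_window = drop_window)
  if (nrow(segs) == 0) return(empty_events())

  rows <- purrr::pmap(segs, function(start, end, rupture, peak_force_smooth_pN) {
    idx <- start:(end - 1L)
    if (length(idx) < min_segment_samples) return(NULL)
    x <- curve$extension_nm[idx]
    f <- curve$force_pN[idx]
    fit <- tryCatch(
      suppressWarnings(fit_wlc_segment(x, f, temperature = temperature,
                                       p_bounds = p_bounds)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    x_rup <- curve$extension_nm[rupture]
    tibble::tibble(
      rupture_index = rupture,
      rupture_extension_nm = x_rup,
      peak_force_pN = wlc_force(x_rup, fit$Lc, fit$p, temperature),
      Lc_nm = fit$Lc, p_nm = fit$p, rmse_pN = fit$rmse,
      p_at_bound = fit$p_at_bound
    )
  })
  ev <- dplyr::bind_rows(rows)
  if (nrow(ev) == 0) return(empty_events())
  ev <- dplyr::arrange(ev, .data$rupture_index)
  tibble::tibble(
    curve_id = curve_id,
    ordinal = seq_len(nrow(ev)),
    ev,
    mode = md$mode %||% NA_character_,
    velocity_nm_per_s = md$velocity_nm_per_s %||% NA_real_,
    spring_constant_pN_per_nm = md$spring_constant_pN_per_nm %||% NA_real_,
    temperature_K = temperature
  )
}

empty_events <- function() {
  tibble::tibble(
    curve_id = character(), ordinal = integer(), rupture_index = integer(),
    rupture_extension_nm = double(), peak_force_pN = double(),
    Lc_nm = double(), p_nm = double(), rmse_pN = double(),
    p_at_bound = logical(), mode = character(),
    velocity_nm_per_s = double(), spring_constant_pN_per_nm = double(),
    temperature_K = double()
  )
}

#' Contour-length increments of an ordered event series
#'
#' `delta_lc[i] = Lc[i+1] - Lc[i]` for consecutive fitted peaks of one
#' curve; increment `i` is the contour length released by rupture `i`.
#' Negative increments (refolding or misordered fits) are retained but
#' flagged. Fewer than two events give an empty vector.
#'
#' @param Lc Ordered fitted contour lengths of one curve, nm.
#' @return A tibble with `delta_lc_nm` and `negative` flag (one row per
#'   increment, i.e. `length(Lc) - 1` rows).
#' @export
#' @examples
#' contour_length_increments(c(80, 113.7))
contour_length_increments <- function(Lc) {
  if (length(Lc) < 2) {
    return(tibble::tibble(delta_lc_nm = double(), negative = logical()))
  }
  d <- diff(Lc)
  tibble::tibble(delta_lc_nm = d, negative = d < 0)
}

#' Initial stretch of a curve
#'
#' Operationally defined as the fitted contour length of the first
#' unfolding peak (the entropic stretch preceding the first rupture). `NA`
#' when the curve has no events.
#'
#' @param Lc Ordered fitted contour lengths of one curve, nm.
#' @return A length-1 numeric (nm), `NA` if no events.
#' @export
initial_stretch <- function(Lc) {
  if (length(Lc) < 1) return(NA_real_)
  Lc[[1]]
}

#' Assign a contour-length increment to its nearest class
#'
#' Nearest-centre assignment with a tie rule (exact midpoints go to the
#' lower centre) and an outlier radius: increments farther than
#' `outlier_radius` from every centre are `"unclassified"`.
#'
#' @param delta_lc Increment(s), nm. Vectorised.
#' @param class_centers Sorted class centres, nm.
#' @param outlier_radius Maximum distance to the nearest centre, nm.
#' @return Character vector of class labels (`"dL<centre>"` or
#'   `"unclassified"`).
#' @export
#' @examples
#' classify_increment(c(6.5, 11.25, 50), c(6.5, 16, 24.5, 33))
classify_increment <- function(delta_lc, class_centers = c(6.5, 16, 24.5, 33),
                               outlier_radius = 5) {
  stopifnot(length(class_centers) > 0, !is.unsorted(class_centers))
  labels <- paste0("dL", format(class_centers, trim = TRUE))
  vapply(delta_lc, function(d) {
    if (!is.finite(d)) return(NA_character_)
    dist <- abs(d - class_centers)
    if (min(dist) > outlier_radius) return("unclassified")
    # ties break to the lower centre: which.min takes the first minimum
    labels[which.min(dist)]
  }, character(1))
}

#' Analyze every curve of a dataset into a classified event table
#'
#' Maps [analyze_curve()] over a dataset (a manifest tibble from
#' [read_manifest()], a directory of curve TSVs, or a list of in-memory
#' `force_curve`s), then derives per-curve contour-length increments,
#' initial stretches and class labels. Event `i` of a curve carries the
#' increment it releases (`delta_lc_nm = Lc[i+1] - Lc[i]`); the last event
#' of each curve has no following fit and stays unclassified (`NA`).
#'
#' @param dataset Manifest tibble, dataset directory, or named list of
#'   `force_curve` objects.
#' @param class_centers,outlier_radius See [classify_increment()].
#' @param ... Passed on to [analyze_curve()].
#' @return Event tibble: [analyze_curve()] columns plus `delta_lc_nm`,
#'   `negative_increment`, `class`, `initial_stretch_nm`,
#'   `loading_rate_pN_per_s`.
#' @export
analyze_dataset <- function(dataset, class_centers = c(6.5, 16, 24.5, 33),
                            outlier_radius = 5, ...) {
  curves <- as_curve_list(dataset)
  ev <- purrr::imap(curves, function(cv, id) analyze_curve(cv, curve_id = id, ...))
  ev <- dplyr::bind_rows(ev)
  if (nrow(ev) == 0) {
    return(dplyr::mutate(empty_events(), delta_lc_nm = double(),
                         negative_increment = logical(), class = character(),
                         initial_stretch_nm = double(),
                         loading_rate_pN_per_s = double()))
  }
  ev <- ev |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::mutate(
      delta_lc_nm = dplyr::lead(.data$Lc_nm) - .data$Lc_nm,
      negative_increment = !is.na(.data$delta_lc_nm) & .data$delta_lc_nm < 0,
      initial_stretch_nm = .data$Lc_nm[1]
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      class = ifelse(is.na(.data$delta_lc_nm), NA_character_,
                     classify_increment(.data$delta_lc_nm, class_centers,
                                        outlier_radius)),
      loading_rate_pN_per_s = .data$spring_constant_pN_per_nm *
        .data$velocity_nm_per_s
    )
  ev
}

as_curve_list <- function(dataset) {
  if (is.list(dataset) && !is.data.frame(dataset) &&
      all(vapply(dataset, inherits, logical(1), "force_curve"))) {
    if (is.null(names(dataset))) {
      names(dataset) <- sprintf("curve_%03d", seq_along(dataset))
    }
    return(dataset)
  }
  if (is.character(dataset) && length(dataset) == 1 && dir.exists(dataset)) {
    dataset <- read_manifest(dataset)
  }
  if (is.data.frame(dataset) && "path" %in% names(dataset)) {
    paths <- dataset$path
    curves <- purrr::map(paths, read_force_curve)
    names(curves) <- basename(paths)
    return(curves)
  }
  stop("`dataset` must be a manifest, a dataset directory, or a list of force_curve objects",
       call. = FALSE)
}

#' Per-mode relative class frequencies
#'
#' Relative frequency of each increment class among *classified* increments
#' (negative and unclassified increments excluded), reported per pulling
#' mode with counts. Frequencies sum to 1 within each mode.
#'
#' @param events Event tibble from [analyze_dataset()].
#' @param drop_negative Exclude flagged negative increments (default TRUE).
#' @return Tibble: `mode`, `class`, `n`, `frequency`.
#' @export
class_probabilities <- function(events, drop_negative = TRUE) {
  ev <- dplyr::filter(events, !is.na(.data$class),
                      .data$class != "unclassified")
  if (drop_negative) ev <- dplyr::filter(ev, !.data$negative_increment)
  if (nrow(ev) == 0) {
    stop("no classified increments in `events`", call. = FALSE)
  }
  ev |>
    dplyr::count(.data$mode, .data$class, name = "n") |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
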