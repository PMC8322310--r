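#' Write a force curve to a tab-separated text file
#'
#' The file starts with `#`-prefixed `key=value` header lines carrying the
#' acquisition metadata (mode, velocity, spring constant, sampling rate,
#' temperature, seed, model id), followed by a TSV table with columns
#' `time_s`, `piezo_nm`, `extension_nm`, `force_pN`. For synthetic curves
#' the ground-truth event log is embedded as a JSON-valued
#' `# truth_events=` header line so analysis recovery can be scored.
#'
#' @param curve A `force_curve` (see [simulate_curve()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  md <- attr(curve, "metadata")
  truth <- attr(curve, "truth_events")
  hdr <- vapply(names(md), function(k) {
    sprintf("# %s=%s", k, format(md[[k]], digits = 15, scientific = FALSE))
  }, character(1))
  if (!is.null(truth)) {
    hdr <- c(hdr, paste0("# truth_events=",
                         jsonlite::toJSON(truth, digits = NA)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("time_s", "piezo_nm", "extension_nm", "force_pN"),
                   collapse = "\t"), con)
  body <- sprintf("%.6g\t%.6g\t%.6g\t%.6g",
                  curve$time_s, curve$piezo_nm,
                  curve$extension_nm, curve$force_pN)
  writeLines(body, con)
  invisible(path)
}

#' Read a force curve written by [write_force_curve()]
#'
#' Also accepts plain extension/force tables (no header, `extension_nm` and
#' `force_pN` columns at minimum); missing metadata keys are `NULL`.
#'
#' @param path Curve file path.
#' @return A `force_curve` tibble with `metadata` and `truth_events`
#'   attributes.
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("no such curve file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  md <- list(); truth <- NULL
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    if (key == "truth_events") {
      truth <- tibble::as_tibble(jsonlite::fromJSON(val))
      if (nrow(truth) == 0) {
        truth <- tibble::tibble(time_s = double(), index = integer(),
                                force_pN = double(), label = character(),
                                delta_lc_nm = double())
      }
    } else {
      num <- suppressWarnings(as.numeric(val))
      md[[key]] <- if (is.na(num)) val else num
    }
  }
  dat <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("extension_nm", "force_pN") %in% names(dat))) {
    stop("curve file must have at least extension_nm and force_pN columns: ",
         path, call. = FALSE)
  }
  curve <- tibble::as_tibble(dat)
  attr(curve, "metadata") <- md
  attr(curve, "truth_events") <- truth
  class(curve) <- c("force_curve", class(curve))
  curve
}
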