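#' Unfolding-unit specification
#'
#' One class of cooperatively unfolding structure (a domain, linker or
#' intermediate) carrying Bell-model kinetics: zero-force unfolding rate
#' `k0`, transition-state distance `x_beta`, and the contour length
#' `delta_lc` released when it unfolds.
#'
#' @param label Class label (character).
#' @param delta_lc Contour-length gain on unfolding, nm (> 0).
#' @param k0 Zero-force unfolding rate, 1/s (> 0).
#' @param x_beta Distance to the transition state, nm (> 0).
#' @param count Number of copies of this unit in the construct.
#' @return A one-row tibble.
#' @export
#' @examples
#' unfolding_unit("domain", delta_lc = 33.2, k0 = 1 / 0.061, x_beta = 0.074)
unfolding_unit <- function(label, delta_lc, k0, x_beta, count = 1L) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.numeric(delta_lc) || delta_lc <= 0) stop("`delta_lc` must be > 0", call. = FALSE)
  if (!is.numeric(k0) || k0 <= 0) stop("`k0` must be > 0", call. = FALSE)
  if (!is.numeric(x_beta) || x_beta <= 0) stop("`x_beta` must be > 0", call. = FALSE)
  if (!is.numeric(count) || count < 0 || count != round(count)) {
    stop("`count` must be a non-negative integer", call. = FALSE)
  }
  tibble::tibble(label = label, delta_lc = delta_lc, k0 = k0,
                 x_beta = x_beta, count = as.integer(count))
}

#' Protein construct model for pulling simulations
#'
#' A construct is an ordered set of [unfolding_unit()] rows plus the elastic
#' backbone: all stretched polypeptide is modelled as a single worm-like
#' chain whose contour length starts at `initial_contour_length` (folded
#' construct plus any spacer/handle) and grows by `delta_lc` at every
#' unfolding event.
#'
#' @param units A tibble of unfolding units (rows from [unfolding_unit()],
#'   bound together); `count` columns are expanded so each physical copy is
#'   one row.
#' @param initial_contour_length Contour length before any unfolding, nm.
#' @param persistence_length Persistence length of the stretched chain, nm.
#' @param mode Pulling geometry, `"HAP"` (handle-assisted) or `"PAP"`
#'   (partner-assisted); metadata only.
#' @param model_id Identifier carried into curve metadata.
#' @return An object of class `protein_model`.
#' @export
#' @examples
#' protein_model(unfolding_unit("EC", 33.2, 16.4, 0.074, count = 3),
#'               initial_contour_length = 30)
protein_model <- function(units, initial_contour_length,
                          persistence_length = 0.5,
                          mode = c("HAP", "PAP"),
                          model_id = "model") {
  mode <- match.arg(mode)
  units <- tibble::as_tibble(units)
  req <- c("label", "delta_lc", "k0", "x_beta")
  if (!all(req %in% names(units))) {
    stop("`units` must have columns label, delta_lc, k0, x_beta", call. = FALSE)
  }
  if (!"count" %in% names(units)) units$count <- 1L
  units <- units[rep(seq_len(nrow(units)), units$count),
                 c("label", "delta_lc", "k0", "x_beta")]
  if (nrow(units) < 1) stop("model needs at least one unfolding unit", call. = FALSE)
  if (initial_contour_length <= 0) stop("`initial_contour_length` must be > 0", call. = FALSE)
  if (persistence_length <= 0) stop("`persistence_length` must be > 0", call. = FALSE)
  structure(
    list(units = units,
         initial_contour_length = initial_contour_length,
         persistence_length = persistence_length,
         mode = mode, model_id = model_id),
    class = "protein_model"
  )
}

#' Pulling protocol for a constant-velocity AFM retraction
#'
#' @param velocity Retraction velocity, nm/s.
#' @param spring_constant Cantilever spring constant, pN/nm.
#' @param sampling_rate Force sampling rate, Hz.
#' @param temperature Temperature, K.
#' @param max_piezo Piezo travel; the trace ends when the piezo reaches it, nm.
#' @param force_noise_sd Gaussian noise SD added to the recorded force, pN.
#' @param seed Integer seed making the simulated curve reproducible.
#' @return An object of class `pulling_protocol` (a named list).
#' @export
pulling_protocol <- function(velocity, spring_constant = 30,
                             sampling_rate = 1e4, temperature = 298,
                             max_piezo = 300, force_noise_sd = 5,
                             seed = 1L) {
  vals <- c(velocity = velocity, spring_constant = spring_constant,
            sampling_rate = sampling_rate, temperature = temperature,
            max_piezo = max_piezo)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all protocol parameters must be positive and finite", call. = FALSE)
  }
  if (force_noise_sd < 0) stop("`force_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(velocity = velocity, spring_constant = spring_constant,
         sampling_rate = sampling_rate, temperature = temperature,
         max_piezo = max_piezo, force_noise_sd = force_noise_sd,
         seed = as.integer(seed)),
    class = "pulling_protocol"
  )
}

#' Simulate one constant-velocity pulling curve
#'
#' Monte-Carlo kinetic simulation of a sawtooth force-extension curve. Per
#' time step `dt = 1/sampling_rate` the piezo advances `v dt`; the chain
#' extension and true force come from the WLC/cantilever force balance
#' ([solve_force_balance()]); every still-folded unit then unfolds with
#' probability `1 - exp(-k(F) dt)` where `k(F) = k0 exp(F x_beta / kBT)`
#' (Bell kinetics, force held constant within the step). An unfolding event
#' adds that unit's `delta_lc` to the chain contour length. Recorded force
#' is the true force plus i.i.d. Gaussian noise.
#'
#' If the expected per-step unfolding probability exceeds 0.1 anywhere along
#' the trace, a warning flags the time step as too coarse for the kinetics.
#'
#' @param model A [protein_model()].
#' @param protocol A [pulling_protocol()]; its `seed` makes the curve
#'   deterministic.
#' @return A `force_curve`: a tibble with columns `time_s`, `piezo_nm`,
#'   `extension_nm`, `force_pN`, carrying attributes `metadata` (protocol +
#'   model info) and `truth_events` (tibble of every unfolding: `time_s`,
#'   `index`, `force_pN`, `label`, `delta_lc_nm`).
#' @export
#' @examples
#' m <- protein_model(unfolding_unit("EC", 33.2, 16.4, 0.074, count = 3), 30)
#' fc <- simulate_curve(m, pulling_protocol(2000, max_piezo = 140, seed = 7))
simulate_curve <- function(model, protocol) {
  stopifnot(inherits(model, "protein_model"), inherits(protocol, "pulling_protocol"))
  withr::with_seed(protocol$seed, simulate_curve_impl(model, protocol))
}

simulate_curve_impl <- function(model, protocol) {
  dt <- 1 / protocol$sampling_rate
  v <- protocol$velocity
  kc <- protocol$spring_constant
  Tk <- protocol$temperature
  p <- model$persistence_length
  kbt <- kBT(Tk)
  n_steps <- floor(protocol$max_piezo / (v * dt))
  units <- model$units
  folded <- rep(TRUE, nrow(units))
  Lc <- model$initial_contour_length

  time <- seq_len(n_steps) * dt
  piezo <- seq_len(n_steps) * (v * dt)
  ext <- numeric(n_steps)
  force <- numeric(n_steps)
  ev_idx <- integer(0); ev_force <- numeric(0); ev_label <- character(0)
  ev_dlc <- numeric(0)
  x_prev <- 0
  max_step_prob <- 0

  c1 <- kbt / p
  for (i in seq_len(n_steps)) {
    # inline safeguarded Newton on the WLC/cantilever force balance,
    # warm-started from the previous step's extension
    z <- piezo[i]
    hi <- min(z, Lc * (1 - 1e-12)); lo <- 0
    x <- min(x_prev, hi)
    for (it in seq_len(100)) {
      tt <- x / Lc
      g <- c1 * (0.25 * (1 - tt)^-2 - 0.25 + tt) - kc * (z - x)
      if (abs(g) < 1e-8) break
      if (g > 0) hi <- x else lo <- x
      xn <- x - g / (c1 * (0.5 * (1 - tt)^-3 + 1) / Lc + kc)
      if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- 0.5 * (lo + hi)
      x <- xn
    }
    x_prev <- x
    f_true <- kc * (z - x)
    ext[i] <- x
    force[i] <- f_true
    if (any(folded)) {
      k <- units$k0[folded] * exp(f_true * units$x_beta[folded] / kbt)
      p_unf <- -expm1(-k * dt)
      max_step_prob <- max(max_step_prob, p_unf)
      hit <- which(stats::runif(length(p_unf)) < p_unf)
      if (length(hit)) {
        idx <- which(folded)[hit]
        folded[idx] <- FALSE
        Lc <- Lc + sum(units$delta_lc[idx])
        ev_idx <- c(ev_idx, rep(i, length(idx)))
        ev_force <- c(ev_force, rep(f_true, length(idx)))
        ev_label <- c(ev_label, units$label[idx])
        ev_dlc <- c(ev_dlc, units$delta_lc[idx])
      }
    }
  }
  if (max_step_prob > 0.1) {
    warning(sprintf(
      "per-step unfolding probability reached %.2f (> 0.1): time step too coarse for the kinetics; increase sampling_rate",
      max_step_prob
    ), call. = FALSE)
  }
  noise <- if (protocol$force_noise_sd > 0) {
    stats::rnorm(n_steps, 0, protocol$force_noise_sd)
  } else 0

  curve <- tibble::tibble(
    time_s = time, piezo_nm = piezo, extension_nm = ext,
    force_pN = force + noise
  )
  attr(curve, "metadata") <- list(
    mode = model$mode, model_id = model$model_id,
    velocity_nm_per_s = v, spring_constant_pN_per_nm = kc,
    sampling_rate_hz = protocol$sampling_rate, temperature_K = Tk,
    force_noise_sd_pN = protocol$force_noise_sd, seed = protocol$seed,
    persistence_length_nm = p,
    initial_contour_length_nm = model$initial_contour_length
  )
  attr(curve, "truth_events") <- tibble::tibble(
    time_s = time[ev_idx], index = ev_idx, force_pN = ev_force,
    label = ev_label, delta_lc_nm = ev_dlc
  )
  class(curve) <- c("force_curve", class(curve))
  curve
}

#' @export
print.force_curve <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<force_curve> %s, %g nm/s, %d samples, %d true unfolding events\n",
              md$mode, md$velocity_nm_per_s, nrow(x),
              nrow(attr(x, "truth_events"))))
  NextMethod()
}
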