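#' Thermal damage model parameters
#'
#' First-order Arrhenius kinetics for liver tissue (frequency factor
#' A = 7.39e39 1/s, activation energy Ea = 2.577e5 J/mol) and the
#' critical-temperature threshold (60 degrees C).
#'
#' @param frequency_factor Arrhenius frequency factor A (1/s).
#' @param activation_energy activation energy Ea (J/mol).
#' @param gas_constant universal gas constant (J/(mol K)).
#' @param omega_threshold damage-integral threshold for necrosis; Omega = 1
#'   corresponds to 63% of the damage process completed.
#' @param critical_temperature critical temperature (degrees C).
#' @param critical_mode which temperature statistic the critical-temperature
#'   mask thresholds: the running maximum (`"max_over_time"`, necrosis is
#'   irreversible) or the final snapshot (`"final_time"`, end-time isoline).
#' @return an object of class `damage_params`.
#' @export
damage_params <- function(frequency_factor = 7.39e39,
                          activation_energy = 2.577e5,
                          gas_constant = 8.3145,
                          omega_threshold = 1.0,
                          critical_temperature = 60,
                          critical_mode = c("max_over_time", "final_time")) {
  stopifnot(frequency_factor > 0, activation_energy > 0, omega_threshold > 0)
  structure(list(frequency_factor = frequency_factor,
                 activation_energy = activation_energy,
                 gas_constant = gas_constant,
                 omega_threshold = omega_threshold,
                 critical_temperature = critical_temperature,
                 critical_mode = match.arg(critical_mode)),
            class = "damage_params")
}

#' Arrhenius thermal-damage integral
#'
#' Omega(T) = integral of A exp(-Ea / (R (T(t) + 273.15))) dt with the
#' temperature in degrees C (equivalently, absolute temperature in the
#' exponent), accumulated per cell by trapezoidal integration over the stored
#' snapshots.
#'
#' @param history a [run_transient()] result (snapshots in K).
#' @param params a [damage_params()].
#' @return an object of class `damage_field` with per-cell `omega` and the
#'   completed damage fraction `fraction = 1 - exp(-omega)`.
#' @export
arrhenius_integral <- function(history, params = damage_params()) {
  stopifnot(inherits(history, "temperature_history"))
  t <- history$times
  if (length(t) == 0) stop("empty history", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("snapshot times must be strictly increasing", call. = FALSE)
  A <- params$frequency_factor; Ea <- params$activation_energy
  R <- params$gas_constant
  integrand <- function(TK) A * exp(-Ea / (R * TK))
  omega <- history$fields[[1]] * 0
  if (length(t) > 1) {
    f_prev <- integrand(history$fields[[1]])
    for (k in 2:length(t)) {
      f_k <- integrand(history$fields[[k]])
      omega <- omega + (t[k] - t[k - 1]) / 2 * (f_prev + f_k)
      f_prev <- f_k
    }
  }
  structure(list(omega = omega, fraction = 1 - exp(-omega),
                 grid = history$grid, params = params),
            class = "damage_field")
}

#' @export
print.damage_field <- function(x, ...) {
  cat(sprintf("<damage_field> max Omega = %.3g, necrotic cells (Omega > %g): %d\n",
              max(x$omega, na.rm = TRUE), x$params$omega_threshold,
              sum(x$omega > x$params$omega_threshold, na.rm = TRUE)))
  invisible(x)
}

#' Completed fraction of the thermal damage process
#'
#' @param omega Arrhenius damage integral value(s), >= 0.
#' @return 1 - exp(-omega), in \[0, 1); Omega = 1 gives 0.632 (63%).
#' @examples
#' round(100 * damage_fraction(1))  # 63
#' @export
damage_fraction <- function(omega) {
  if (any(omega < 0, na.rm = TRUE))
    stop("omega must be >= 0", call. = FALSE)
  1 - exp(-omega)
}

# shared constructor for 2D necrosis masks
zone_mask <- function(mask, grid, model) {
  structure(list(mask = mask, grid = grid, model = model), class = "zone_mask")
}

#' @export
print.zone_mask <- function(x, ...) {
  area <- sum(x$grid$dr[row(x$mask)[x$mask]] * x$grid$dz[col(x$mask)[x$mask]])
  cat(sprintf("<zone_mask> model %s: %d necrotic cells, half-plane area %.1f mm^2\n",
              x$model, sum(x$mask), 1e6 * area))
  invisible(x)
}

#' Binary necrosis mask from the Arrhenius damage integral
#'
#' A cell is necrotic iff Omega strictly exceeds the threshold (default 1,
#' i.e. 63% of the damage process completed).
#'
#' @param damage an [arrhenius_integral()] result.
#' @param params a [damage_params()].
#' @return an object of class `zone_mask` (2D logical matrix plus grid).
#' @export
arrhenius_mask <- function(damage, params = damage_params()) {
  stopifnot(inherits(damage, "damage_field"))
  m <- damage$omega > params$omega_threshold
  m[is.na(m)] <- FALSE
  zone_mask(m, damage$grid, "arrhenius")
}

#' Binary necrosis mask from the critical-temperature model
#'
#' A cell is necrotic iff the selected temperature statistic (running maximum
#' or final snapshot, per `critical_mode`) reaches the critical temperature
#' (>=, default 60 degrees C).
#'
#' @param history a [run_transient()] result.
#' @param params a [damage_params()].
#' @return an object of class `zone_mask`.
#' @export
critical_temp_mask <- function(history, params = damage_params()) {
  stopifnot(inherits(history, "temperature_history"))
  if (length(history$fields) == 0) stop("empty history", call. = FALSE)
  stat <- if (params$critical_mode == "max_over_time") history$max_field else
    history$fields[[length(history$fields)]]
  m <- stat >= params$critical_temperature + 273.15
  m[is.na(m)] <- FALSE
  zone_mask(m, history$grid, "critical_temp")
}

#' Half-plane area of a necrosis mask
#'
#' @param mask a `zone_mask`.
#' @return area of the necrotic region in the (r, z) plane (m^2).
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "zone_mask"))
  sum(outer(mask$grid$dr, mask$grid$dz)[mask$mask])
}
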