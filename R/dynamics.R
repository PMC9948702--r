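# Numerical dynamics: logistic well phase (fixed-step RK4) and exponential
# pool phase (exact closed form).

#' Integrate the within-well logistic system
#'
#' Integrates `dx_i/dt = x_i * r_i * (1 - sum_k x_k / K)` for duration `t`
#' with a fixed-step 4th-order Runge-Kutta scheme. All strains share the
#' carrying capacity `K`; strains at zero density stay at zero. Non-viable
#' wells use the same equation with every `r_i` equal to the death rate
#' (the logistic bracket then damps the decay); set `bracket = FALSE` for
#' pure exponential decay instead.
#'
#' @param x Non-negative per-strain densities (length 4 in the standard
#'   model, but any length is accepted).
#' @param rates Per-strain growth rates, same length as `x`.
#' @param K Carrying capacity (> 0).
#' @param t Duration (> 0).
#' @param dt Step size (> 0, default 0.01 time units).
#' @param bracket Apply the logistic saturation term (default `TRUE`).
#' @return Numeric vector of densities after time `t`.
#' @seealso [integrate_pool()] for the unstructured phase.
#' @export
integrate_well <- function(x, rates, K, t, dt = 0.01, bracket = TRUE) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("`x` must be non-negative densities", call. = FALSE)
  }
  if (length(rates) != length(x)) {
    stop("`rates` must match `x` in length", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t <= 0) {
    stop("`t` must be > 0", call. = FALSE)
  }
  nm <- names(x)
  out <- wells_rk4(matrix(as.numeric(x), nrow = 1L),
                   matrix(as.numeric(rates), nrow = 1L),
                   K, t, dt, as.logical(bracket))
  setNames(drop(out), nm)
}

#' Integrate the pool (exponential) phase
#'
#' In the unstructured pool the strains grow exponentially,
#' `y_i(t) = y_i(0) * exp(r_i * t)`, computed in closed form.
#'
#' @param y Non-negative per-strain densities.
#' @param rates Per-strain pool growth rates.
#' @param t Duration (>= 0; `t = 0` is the identity).
#' @return Numeric vector of densities after time `t`.
#' @export
integrate_pool <- function(y, rates, t) {
  if (!is.numeric(y) || anyNA(y) || any(y < 0)) {
    stop("`y` must be non-negative densities", call. = FALSE)
  }
  if (length(rates) != length(y)) {
    stop("`rates` must match `y` in length", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("`t` must be >= 0", call. = FALSE)
  }
  setNames(y * exp(rates * t), names(y))
}

#' Strain frequencies from densities
#'
#' @param y Non-negative per-strain densities.
#' @return `y / sum(y)` when the total is positive, otherwise all zeros
#'   (the extinct pool).
#' @export
pool_frequencies <- function(y) {
  tot <- sum(y)
  if (tot > 0) y / tot else y * 0
}

# clamp denormal-range densities to zero between phases
clamp_densities <- function(x, eps = 1e-12) {
  x[x < eps] <- 0
  x
}
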