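#' Gamma-variate vascular input function parameters
#'
#' The arterial (vascular) input of hyperpolarized pyruvate is modeled as a
#' gamma-variate bolus: zero before arrival at `t0`, then
#' `amplitude * ((t - t0)/rate)^shape * exp(-(t - t0)/rate)`.
#' The defaults (arrival 15 s after the start of acquisition, shape 2.8,
#' time constant 4.5 s) place the bolus peak near 27.6 s and deposit more
#' than 99% of the input AUC within 100 s of injection, matching the signal
#' lifetime of a clinical hyperpolarized pyruvate study.
#'
#' @param t0 Bolus arrival time (s) after acquisition start.
#' @param amplitude Peak-scaling constant (arbitrary units).
#' @param shape Gamma-variate shape exponent (dimensionless, > 0).
#' @param rate Gamma-variate time constant (s, > 0).
#' @return An object of class `vif_params`.
#' @export
vif_params <- function(t0 = 15, amplitude = 1, shape = 2.8, rate = 4.5) {
  check_number(t0, "t0", lo = 0)
  check_number(amplitude, "amplitude", lo = 0)
  check_number(shape, "shape", lo = 0, closed_lo = FALSE)
  check_number(rate, "rate", lo = 0, closed_lo = FALSE)
  structure(list(t0 = t0, amplitude = amplitude, shape = shape, rate = rate),
            class = "vif_params")
}

#' Evaluate a gamma-variate vascular input function
#'
#' @param vifp A [vif_params()] object.
#' @param times Numeric vector of times (s).
#' @return VIF concentration at `times` (same length), zero before `t0`.
#' @export
#' @examples
#' t <- seq(0, 120, by = 3)
#' plot(t, gamma_variate_vif(vif_params(), t), type = "l")
gamma_variate_vif <- function(vifp, times) {
  stopifnot(inherits(vifp, "vif_params"), is.numeric(times))
  tau <- (times - vifp$t0) / vifp$rate
  out <- numeric(length(times))
  pos <- which(tau > 0)
  out[pos] <- vifp$amplitude * tau[pos]^vifp$shape * exp(-tau[pos])
  out
}

# Coerce VIF specifications to an evaluator function of time.
vif_function <- function(vif_source) {
  if (inherits(vif_source, "vif_params"))
    return(function(t) gamma_variate_vif(vif_source, t))
  if (is.function(vif_source)) return(vif_source)
  stop_invalid("vif_source must be a vif_params object or a function of time")
}
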