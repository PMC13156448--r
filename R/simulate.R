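# Forward simulation of the compartmental models.
#
# Both models are linear time-invariant (LTI) systems x' = A x + b u(t)
# driven by the (analytic) vascular input u. They are solved by exact
# exponential-integrator stepping: within each internal step the homogeneous
# propagator exp(A h) is exact and the forcing convolution is evaluated by
# 4-point Gauss-Legendre quadrature, so accuracy is limited only by the
# quadrature of the smooth input (well below 1e-8 relative at the default
# step). The internal step is decoupled from the acquisition TR.

# Matrix exponential via scaling-and-squaring with a Taylor core; matrices
# here are at most 4 x 4 and well scaled.
expm_small <- function(A) {
  n <- nrow(A)
  nrm <- max(colSums(abs(A)))
  j <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0L
  As <- A / 2^j
  E <- diag(n)
  term <- diag(n)
  for (k in 1:24) {
    term <- term %*% As / k
    E <- E + term
  }
  for (i in seq_len(j)) E <- E %*% E
  E
}

.gauss4_nodes <- c(0.069431844202974, 0.330009478207572,
                   0.669990521792428, 0.930568155797026)
.gauss4_weights <- c(0.173927422568727, 0.326072577431273,
                     0.326072577431273, 0.173927422568727)

# Solve x' = A x + b u(t), x(0) = 0, on the uniform grid 0, h, ..., N h.
# Returns an (N + 1) x k matrix of states.
lti_solve <- function(A, b, ufun, h, n_steps) {
  k <- nrow(A)
  E <- expm_small(A * h)
  # forcing contribution vectors for each Gauss node
  M <- vapply(seq_along(.gauss4_nodes), function(i) {
    drop(expm_small(A * h * (1 - .gauss4_nodes[i])) %*% b) *
      (.gauss4_weights[i] * h)
  }, numeric(k))                               # k x 4
  t_nodes <- outer(.gauss4_nodes * h, (0:(n_steps - 1)) * h, `+`)  # 4 x N
  G <- M %*% matrix(ufun(as.vector(t_nodes)), nrow = 4)            # k x N
  X <- matrix(0, n_steps + 1, k)
  x <- numeric(k)
  for (n in seq_len(n_steps)) {
    x <- E %*% x + G[, n]
    X[n + 1L, ] <- x
  }
  X
}

# Fast exact solver for the simplified model's lower-triangular 3-state
# system with input entering the first state only. The matrix exponential of
# a triangular matrix is evaluated in divided-difference (Opitz) form and the
# time stepping reduces to three scalar first-order recursions, handled by
# stats::filter at C speed. Returns NULL when eigenvalues nearly coincide
# (divided differences would cancel); callers then fall back to the generic
# propagator path.
lti_solve_tri3 <- function(A, b, U_raw, h, n_steps) {
  l1 <- A[1, 1]; l2 <- A[2, 2]; l3 <- A[3, 3]
  scale <- max(abs(c(l1, l2, l3)), 1e-3)
  if (min(abs(c(l1 - l2, l1 - l3, l2 - l3))) < 1e-6 * scale) return(NULL)
  ex <- function(tau) {
    e1 <- exp(l1 * tau); e2 <- exp(l2 * tau); e3 <- exp(l3 * tau)
    list(e1 = e1, e2 = e2, e3 = e3,
         dd12 = (e1 - e2) / (l1 - l2),
         dd123 = e1 / ((l1 - l2) * (l1 - l3)) +
           e2 / ((l2 - l1) * (l2 - l3)) + e3 / ((l3 - l1) * (l3 - l2)))
  }
  Eh <- ex(h)
  E11 <- Eh$e1; E22 <- Eh$e2; E33 <- Eh$e3
  E21 <- A[2, 1] * Eh$dd12
  E32 <- A[3, 2] * ((Eh$e2 - Eh$e3) / (l2 - l3))
  E31 <- A[2, 1] * A[3, 2] * Eh$dd123
  tau <- h * (1 - .gauss4_nodes)
  Et <- ex(tau)
  w <- .gauss4_weights * h * b[1]
  M <- rbind(w * Et$e1, w * A[2, 1] * Et$dd12,
             w * A[2, 1] * A[3, 2] * Et$dd123)       # 3 x 4
  G <- M %*% U_raw
  x1 <- stats::filter(G[1, ], E11, method = "recursive")
  x1p <- c(0, x1[-n_steps])
  x2 <- stats::filter(E21 * x1p + G[2, ], E22, method = "recursive")
  x2p <- c(0, x2[-n_steps])
  x3 <- stats::filter(E31 * x1p + E32 * x2p + G[3, ], E33,
                      method = "recursive")
  rbind(0, cbind(as.numeric(x1), as.numeric(x2), as.numeric(x3)))
}

# System matrix and input vector of the simplified (3PCs) model;
# states: Pyr_ee, Pyr_c, Lac_c.
system_3pcs <- function(params, acq) {
  a <- effective_rates(params, acq)
  A <- matrix(0, 3, 3)
  A[1, 1] <- a$alphaPee
  A[2, 1] <- params$kecP / params$vc
  A[2, 2] <- a$alphaPc
  A[3, 2] <- params$kPL
  A[3, 3] <- a$alphaLc
  list(A = A, b = c(params$kve / params$vee, 0, 0))
}

# Full (3PC) model; states: Pyr_ee, Pyr_c, Lac_c, Lac_ee. Lactate is absent
# from the arterial input, so no intravascular lactate state is carried;
# lactate crossing the endothelium (intravasation, rate kve/vee) is washed
# out by flowing blood and leaves the visible system. This loss channel is
# what the simplified model's heuristic betaL stands in for.
system_3pc <- function(params, acq) {
  R1P <- 1 / acq$T1Pyr
  R1L <- 1 / acq$T1Lac
  rfP <- rf_loss_rate(acq$thetaPyr, acq$TR)
  rfL <- rf_loss_rate(acq$thetaLac, acq$TR)
  A <- matrix(0, 4, 4)
  A[1, 1] <- -(params$kve / params$vee + params$kecP / params$vee + R1P + rfP)
  A[1, 2] <- params$kecP / params$vee
  A[2, 1] <- params$kecP / params$vc
  A[2, 2] <- -(params$kecP / params$vc + params$kPL + R1P + rfP)
  A[2, 3] <- params$kLP
  A[3, 2] <- params$kPL
  A[3, 3] <- -(params$kLP + params$kecL / params$vc + R1L + rfL)
  A[3, 4] <- params$kecL / params$vc
  A[4, 3] <- params$kecL / params$vee
  A[4, 4] <- -(params$kecL / params$vee + params$kve / params$vee + R1L + rfL)
  list(A = A, b = c(params$kve / params$vee, 0, 0, 0))
}

#' Construct a dynamic signal time course
#'
#' Container for sampled metabolite signal curves: acquisition times, total
#' pyruvate and lactate signal per frame, the VIF concentration, and
#' optionally the per-compartment signals.
#'
#' @param times Sample times (s), strictly increasing.
#' @param pyr,lac Total pyruvate and lactate signal per frame (a.u.).
#' @param vif Optional VIF concentration per frame.
#' @param compartments Optional data frame of per-compartment signals.
#' @param meta Optional list of provenance metadata (model, seed, sigma, ...).
#' @return An object of class `signal_timecourse`.
#' @export
signal_timecourse <- function(times, pyr, lac, vif = NULL,
                              compartments = NULL, meta = list()) {
  stopifnot(is.numeric(times), is.numeric(pyr), is.numeric(lac))
  if (length(pyr) != length(times) || length(lac) != length(times))
    stop_invalid("times, pyr, and lac must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing")
  if (!is.null(vif) && length(vif) != length(times))
    stop_invalid("vif must have the same length as times")
  structure(list(times = as.numeric(times), pyr = as.numeric(pyr),
                 lac = as.numeric(lac), vif = vif,
                 compartments = compartments, meta = meta),
            class = "signal_timecourse")
}

#' @export
print.signal_timecourse <- function(x, ...) {
  cat(sprintf("<signal_timecourse> %d frames, t = %g..%g s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  peak pyr %.4g, peak lac %.4g%s\n", max(x$pyr), max(x$lac),
              if (!is.null(x$meta$sigma))
                sprintf(", noise sigma %.4g", x$meta$sigma) else ""))
  invisible(x)
}

simulate_model <- function(sys, params, acq, vifp, times, dt, per_compartment,
                           model_name) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(vifp, "vif_params"))
  if (is.null(times)) times <- (seq_len(acq$n_frames) - 1L) * acq$TR
  if (length(times) < 2 || times[1] != 0)
    stop_invalid("times must start at 0 and contain at least two frames")
  sp <- diff(times)
  if (max(abs(sp - sp[1])) > 1e-9 * sp[1])
    stop_invalid("times must be uniformly spaced")
  sp <- sp[1]
  m <- max(1L, ceiling(sp / dt - 1e-9))
  h <- sp / m
  n_steps <- (length(times) - 1L) * m
  ufun <- function(t) params$vif_scale * gamma_variate_vif(vifp, t)
  X <- lti_solve(sys$A, sys$b, ufun, h, n_steps)
  idx <- seq(1L, n_steps + 1L, by = m)
  piv <- ufun(times)
  sP <- sin(deg2rad(acq$thetaPyr))
  sL <- sin(deg2rad(acq$thetaLac))
  w_iv <- params$vb * sP * exp(-acq$TE / acq$T2Pv)
  w_ee <- params$vee * sP * exp(-acq$TE / acq$T2Pe)
  w_c <- params$vc * sP * exp(-acq$TE / acq$T2Pc)
  w_lc <- params$vc * sL * exp(-acq$TE / acq$T2Lc)
  comp <- data.frame(pyr_iv = w_iv * piv,
                     pyr_ee = w_ee * X[idx, 1],
                     pyr_c = w_c * X[idx, 2],
                     lac_c = w_lc * X[idx, 3])
  if (ncol(X) >= 4) {
    # extravascular/extracellular lactate shares the intracellular lactate T2*
    comp$lac_ee <- params$vee * sL * exp(-acq$TE / acq$T2Lc) * X[idx, 4]
  }
  lac <- comp$lac_c + if (!is.null(comp$lac_ee)) comp$lac_ee else 0
  signal_timecourse(times = times,
                    pyr = comp$pyr_iv + comp$pyr_ee + comp$pyr_c,
                    lac = lac,
                    vif = gamma_variate_vif(vifp, times),
                    compartments = if (per_compartment) comp else NULL,
                    meta = list(model = model_name, dt = h,
                                params = params, acq = acq, vifp = vifp))
}

#' Simulate the simplified three-compartment (3PCs) model
#'
#' Solves the decoupled linear system for extravascular/extracellular
#' pyruvate, intracellular pyruvate, and intracellular lactate driven by
#' `vif_scale * VIF(t)`, then forms per-frame signals as volume-weighted
#' magnetizations attenuated by `sin(theta) * exp(-TE/T2*)`. RF excitation
#' loss is modeled as the continuous rate `(1 - cos(theta))/TR`, consistent
#' with the closed-form AUC identities.
#'
#' @inheritParams effective_rates
#' @param vifp A [vif_params()] object.
#' @param times Output times (s); default the acquisition grid
#'   `0, TR, ..., (n_frames - 1) TR`. Must be uniform and start at 0.
#' @param dt Upper bound on the internal integration step (s).
#' @param per_compartment If `TRUE`, include per-pool signals in the result.
#' @return A [signal_timecourse()].
#' @export
#' @examples
#' tc <- simulate_3pcs(table1_params("3pcs_c"), acquisition_params(),
#'                     vif_params())
#' integrated_auc_ratio(tc)
simulate_3pcs <- function(params, acq, vifp, times = NULL, dt = 0.5,
                          per_compartment = FALSE) {
  stopifnot(inherits(params, "kinetic_params_3pcs"))
  simulate_model(system_3pcs(params, acq), params, acq, vifp, times, dt,
                 per_compartment, "3pcs")
}

#' Simulate the full three-compartment (3PC) model
#'
#' As [simulate_3pcs()], but with reversible intracellular exchange (`kLP`),
#' bidirectional membrane transport for both metabolites, and lactate
#' washout by intravasation; lactate signal sums the intracellular and
#' extravascular/extracellular pools. With `kLP = kecL = kecP = 0` the
#' solution coincides exactly with the simplified model at `betaL = 0`
#' (at `kecP > 0` the models differ through pyruvate efflux from the cell,
#' which the simplified model neglects).
#'
#' @param params A [kinetic_params_3pc()] object.
#' @inheritParams simulate_3pcs
#' @return A [signal_timecourse()].
#' @export
simulate_3pc <- function(params, acq, vifp, times = NULL, dt = 0.5,
                         per_compartment = FALSE) {
  stopifnot(inherits(params, "kinetic_params_3pc"))
  simulate_model(system_3pc(params, acq), params, acq, vifp, times, dt,
                 per_compartment, "3pc")
}

# Discrete-pulse cross-check simulator for the simplified model: longitudinal
# magnetization evolves without the continuous RF-loss rate between frames and
# is depleted by cos(theta) at each excitation; the sampled signal uses the
# pre-pulse magnetization. Used only to verify that the continuous RF-loss
# approximation in the model equations is adequate.
#' @noRd
simulate_3pcs_discrete <- function(params, acq, vifp, dt = 0.05) {
  a <- effective_rates(params, acq)
  rfP <- rf_loss_rate(acq$thetaPyr, acq$TR)
  rfL <- rf_loss_rate(acq$thetaLac, acq$TR)
  A <- matrix(0, 3, 3)
  A[1, 1] <- a$alphaPee + rfP
  A[2, 1] <- params$kecP / params$vc
  A[2, 2] <- a$alphaPc + rfP
  A[3, 2] <- params$kPL
  A[3, 3] <- a$alphaLc + rfL
  b <- c(params$kve / params$vee, 0, 0)
  ufun <- function(t) params$vif_scale * gamma_variate_vif(vifp, t)
  m <- max(1L, ceiling(acq$TR / dt))
  h <- acq$TR / m
  E <- expm_small(A * h)
  M <- vapply(seq_along(.gauss4_nodes), function(i) {
    drop(expm_small(A * h * (1 - .gauss4_nodes[i])) %*% b) *
      (.gauss4_weights[i] * h)
  }, numeric(3))
  times <- (seq_len(acq$n_frames) - 1L) * acq$TR
  cP <- cos(deg2rad(acq$thetaPyr))
  cL <- cos(deg2rad(acq$thetaLac))
  sP <- sin(deg2rad(acq$thetaPyr))
  sL <- sin(deg2rad(acq$thetaLac))
  x <- numeric(3)
  pyr <- lac <- numeric(acq$n_frames)
  for (n in seq_len(acq$n_frames)) {
    t_n <- times[n]
    pyr[n] <- (params$vb * ufun(t_n) * exp(-acq$TE / acq$T2Pv) +
                 params$vee * x[1] * exp(-acq$TE / acq$T2Pe) +
                 params$vc * x[2] * exp(-acq$TE / acq$T2Pc)) * sP
    lac[n] <- params$vc * x[3] * sL * exp(-acq$TE / acq$T2Lc)
    x <- x * c(cP, cP, cL)
    if (n < acq$n_frames) {
      for (j in seq_len(m)) {
        tj <- t_n + (j - 1) * h
        g <- M %*% ufun(tj + .gauss4_nodes * h)
        x <- E %*% x + g
      }
      x <- as.numeric(x)
    }
  }
  signal_timecourse(times, pyr, lac, vif = gamma_variate_vif(vifp, times),
                    meta = list(model = "3pcs_discrete"))
}

#' Noise specification calibrated to peak pyruvate SNR
#'
#' Zero-mean Gaussian noise whose standard deviation is set from the target
#' peak pyruvate signal-to-noise ratio:
#' `sigma = max(pyr) / target_peak_snr`.
#'
#' @param target_peak_snr Target peak pyruvate SNR (> 0).
#' @param seed Optional RNG seed for reproducible noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(target_peak_snr, seed = NULL) {
  check_number(target_peak_snr, "target_peak_snr", lo = 0, closed_lo = FALSE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(target_peak_snr = target_peak_snr, seed = seed),
            class = "noise_spec")
}

#' Add calibrated Gaussian noise to a signal time course
#'
#' Adds i.i.d. zero-mean Gaussian noise independently to the pyruvate and
#' lactate channels at every frame, with standard deviation
#' `max(pyr)/target_peak_snr`. The caller's RNG state is left untouched when
#' a seed is supplied.
#'
#' @param curves A noiseless [signal_timecourse()].
#' @param noise A [noise_spec()].
#' @return A [signal_timecourse()] with noisy `pyr` and `lac`; the realized
#'   `sigma`, seed, and target SNR are recorded in `meta`.
#' @export
add_noise <- function(curves, noise) {
  stopifnot(inherits(curves, "signal_timecourse"), inherits(noise, "noise_spec"))
  sigma <- max(curves$pyr) / noise$target_peak_snr
  n <- length(curves$times)
  eps <- with_seed(noise$seed, stats::rnorm(2L * n, sd = sigma))
  out <- curves
  out$pyr <- curves$pyr + eps[seq_len(n)]
  out$lac <- curves$lac + eps[n + seq_len(n)]
  out$meta$sigma <- sigma
  out$meta$target_peak_snr <- noise$target_peak_snr
  out$meta$noise_seed <- noise$seed
  out
}

#' Estimate peak pyruvate SNR from dynamic data
#'
#' Peak pyruvate signal divided by the noise standard deviation, with the
#' noise level estimated from frames acquired after the hyperpolarized
#' magnetization has decayed away.
#'
#' @param curves A [signal_timecourse()].
#' @param noise_window Integer frame indices of the noise-only window;
#'   defaults to the final quarter of the acquisition.
#' @return Estimated peak SNR (may be `Inf` for noiseless input, with a
#'   warning).
#' @export
peak_snr <- function(curves, noise_window = NULL) {
  stopifnot(inherits(curves, "signal_timecourse"))
  n <- length(curves$times)
  if (is.null(noise_window))
    noise_window <- seq.int(max(1L, floor(0.75 * n) + 1L), n)
  noise_window <- as.integer(noise_window)
  if (length(noise_window) < 2 || any(noise_window < 1 | noise_window > n))
    stop_invalid("noise_window must contain at least two valid frame indices")
  pk <- max(curves$pyr)
  if (max(abs(curves$pyr[noise_window])) > 0.2 * pk)
    warning("noise window overlaps the signal support; SNR may be biased")
  s <- stats::sd(curves$pyr[noise_window])
  if (s == 0) {
    warning("zero noise standard deviation in window; returning Inf")
    return(Inf)
  }
  pk / s
}

#' Integrated (traditional) lactate/pyruvate AUC ratio
#'
#' Sums the sampled lactate and pyruvate curves and returns their ratio, the
#' conventional semi-quantitative metric. By default the curves are truncated
#' to the frames where pyruvate signal is appreciable -- from the first frame
#' exceeding 2% of the pyruvate maximum through the last frame exceeding 1% --
#' to limit the noise included in the sums.
#'
#' @param curves A [signal_timecourse()].
#' @param truncation `"support"` (default) for the threshold rule above or
#'   `"none"` to sum over all frames.
#' @return A single number, `sum(lac)/sum(pyr)` over the retained frames.
#' @export
integrated_auc_ratio <- function(curves, truncation = c("support", "none")) {
  stopifnot(inherits(curves, "signal_timecourse"))
  truncation <- match.arg(truncation)
  keep <- seq_along(curves$times)
  if (truncation == "support") {
    pk <- max(curves$pyr)
    above_lo <- which(curves$pyr > 0.02 * pk)
    above_hi <- which(curves$pyr > 0.01 * pk)
    keep <- seq.int(min(above_lo), max(above_hi))
  }
  denom <- sum(curves$pyr[keep])
  if (denom <= 0) stop_invalid("pyruvate sum is non-positive over the window")
  sum(curves$lac[keep]) / denom
}
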