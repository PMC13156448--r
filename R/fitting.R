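# Parameter estimation by multi-start bounded nonlinear least squares.

param_names_3pcs <- c("kPL", "kecP", "kve", "betaL", "vb", "vee", "vc",
                      "vif_scale")
param_names_3pc <- c("kPL", "kLP", "kecP", "kecL", "kve", "vb", "vee", "vc",
                     "vif_scale")
rate_names <- c("kPL", "kLP", "kecP", "kecL", "kve", "betaL")

#' Specification of a model fit
#'
#' Describes which parameters are free, the values of the fixed ones, the box
#' bounds, the multi-start protocol, and the optional L2 penalty. Initial
#' values for each restart are drawn uniformly at random over \[0, 1\]
#' (clipped into the bounds), and the best of `n_restarts` local fits is
#' returned, guarding against local minima of the residual.
#'
#' Volume fractions, when fitted, are parameterized by two stick-breaking
#' simplex coordinates `vfrac1`, `vfrac2` (with `vb = vfrac1`,
#' `vee = (1 - vfrac1) * vfrac2`, `vc` the remainder) so that
#' `vb + vee + vc = 1` holds by construction.
#'
#' @param free_params Character vector of free parameter names. Use
#'   `"vfrac1"`, `"vfrac2"` to fit the three volume fractions.
#' @param fixed_params Named list (or kinetic parameter object) supplying
#'   values for all non-free parameters.
#' @param bounds Optional named list of `c(lo, hi)` per free parameter.
#'   Defaults: \[0, 1\] s^-1 for rate constants and `betaL`, \[0, 10\] for
#'   `vif_scale`, \[0.001, 0.999\] for simplex coordinates.
#' @param n_restarts Number of random restarts (default 500; use fewer for
#'   quick exploratory fits).
#' @param seed RNG seed controlling the restart draws.
#' @param reg_lambda L2 penalty weight on the kinetic rate constants
#'   (`vif_scale` and volume fractions are never penalized); 0 gives plain
#'   least squares.
#' @param ftol,ptol,maxiter Levenberg-Marquardt stopping controls (relative
#'   objective reduction, relative parameter change, iteration cap). Tighten
#'   `ftol`/`ptol` for noiseless benchmark fits; the defaults suit noisy
#'   data.
#' @param start_power Exponent applied to the uniform restart draws
#'   (`start = runif()^start_power`). 1 gives plain uniform starts; 2
#'   concentrates starts toward small parameter values, recovering with few
#'   restarts the small-rate basins that a large uniform multi-start would
#'   reach, which matters when slow-transport physiologies are plausible.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free_params = c("kPL", "kecP", "kve", "betaL",
                                     "vif_scale"),
                     fixed_params = list(), bounds = NULL,
                     n_restarts = 500, seed = 1, reg_lambda = 0,
                     ftol = 1e-9, ptol = 1e-8, maxiter = 150,
                     start_power = 1) {
  stopifnot(is.character(free_params), length(free_params) > 0)
  check_number(n_restarts, "n_restarts", lo = 1)
  check_number(reg_lambda, "reg_lambda", lo = 0)
  check_number(seed, "seed")
  if (inherits(fixed_params, "kinetic_params"))
    fixed_params <- unclass(fixed_params)
  check_number(start_power, "start_power", lo = 0, closed_lo = FALSE)
  structure(list(free_params = free_params, fixed_params = fixed_params,
                 bounds = bounds, n_restarts = as.integer(n_restarts),
                 seed = seed, reg_lambda = reg_lambda,
                 ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
                 start_power = start_power),
            class = "fit_spec")
}

default_bounds <- function(name) {
  if (name %in% rate_names) return(c(0, 1))
  if (name == "vif_scale") return(c(0, 10))
  if (name %in% c("vfrac1", "vfrac2")) return(c(0.001, 0.999))
  if (name %in% c("vb", "vee", "vc")) return(c(0.001, 0.999))
  stop_invalid("no default bounds for parameter '%s'", name)
}

resolve_bounds <- function(spec) {
  t(vapply(spec$free_params, function(nm) {
    b <- spec$bounds[[nm]]
    if (is.null(b)) b <- default_bounds(nm)
    if (length(b) != 2 || b[1] > b[2])
      stop_invalid("invalid bounds for '%s'", nm)
    b
  }, numeric(2)))
}

# Assemble the full parameter list (plain named list) from free values +
# fixed values, expanding simplex coordinates into volume fractions.
assemble_params <- function(theta, spec, model) {
  all_names <- if (model == "3pcs") param_names_3pcs else param_names_3pc
  p <- as.list(theta)
  names(p) <- spec$free_params
  uses_simplex <- all(c("vfrac1", "vfrac2") %in% spec$free_params)
  if (uses_simplex) {
    p$vb <- p$vfrac1
    p$vee <- (1 - p$vfrac1) * p$vfrac2
    p$vc <- 1 - p$vb - p$vee
    p$vfrac1 <- NULL
    p$vfrac2 <- NULL
  }
  for (nm in setdiff(all_names, names(p))) {
    v <- spec$fixed_params[[nm]]
    if (is.null(v))
      stop_invalid("parameter '%s' is neither free nor fixed", nm)
    p[[nm]] <- v
  }
  p[all_names]
}

validate_fit_spec <- function(spec, model) {
  all_names <- if (model == "3pcs") param_names_3pcs else param_names_3pc
  free <- spec$free_params
  uses_simplex <- any(c("vfrac1", "vfrac2") %in% free)
  if (uses_simplex && !all(c("vfrac1", "vfrac2") %in% free))
    stop_invalid("both simplex coordinates vfrac1 and vfrac2 must be free")
  covered <- setdiff(free, c("vfrac1", "vfrac2"))
  if (uses_simplex) covered <- c(covered, "vb", "vee", "vc")
  unknown <- setdiff(covered, all_names)
  if (length(unknown) > 0)
    stop_invalid("unknown free parameter(s) for the %s model: %s", model,
                 paste(unknown, collapse = ", "))
  missing <- setdiff(all_names, union(covered, names(spec$fixed_params)))
  if (length(missing) > 0)
    stop_invalid("parameter(s) neither free nor fixed: %s",
                 paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Max-normalized residual between observed and modeled curves
#'
#' Concatenates the per-frame differences for pyruvate and lactate, each
#' divided by the maximum of the corresponding observed curve so that the two
#' metabolites are weighted equally in the objective.
#'
#' @param observed,model [signal_timecourse()] objects on the same time grid.
#' @return Numeric vector of length `2 * n_frames`.
#' @export
residual_curves <- function(observed, model) {
  stopifnot(inherits(observed, "signal_timecourse"),
            inherits(model, "signal_timecourse"))
  if (length(observed$times) != length(model$times) ||
      max(abs(observed$times - model$times)) > 1e-9)
    stop_invalid("observed and model curves must share the same time grid")
  mp <- max(observed$pyr)
  ml <- max(observed$lac)
  if (mp <= 0 || ml <= 0)
    stop_invalid("observed maxima must be positive for normalization")
  c((observed$pyr - model$pyr) / mp, (observed$lac - model$lac) / ml)
}

# Fast inner evaluator: precomputes the Gauss-node VIF samples and grid
# layout once per fit; each objective evaluation rebuilds only the (cheap)
# propagators for the current parameters.
make_model_evaluator <- function(times, acq, vif_source, model, dt) {
  sp <- diff(times)
  if (times[1] != 0 || any(sp <= 0) || max(abs(sp - sp[1])) > 1e-9 * sp[1])
    stop_invalid("data times must be uniform and start at 0")
  sp <- sp[1]
  m <- max(1L, ceiling(sp / dt - 1e-9))
  h <- sp / m
  n_steps <- (length(times) - 1L) * m
  ufun <- vif_function(vif_source)
  t_nodes <- outer(.gauss4_nodes * h, (0:(n_steps - 1)) * h, `+`)
  U_raw <- matrix(ufun(as.vector(t_nodes)), nrow = 4)
  u_frames_raw <- ufun(times)
  idx <- seq(1L, n_steps + 1L, by = m)
  sP <- sin(deg2rad(acq$thetaPyr))
  sL <- sin(deg2rad(acq$thetaLac))
  eP <- c(exp(-acq$TE / acq$T2Pv), exp(-acq$TE / acq$T2Pe),
          exp(-acq$TE / acq$T2Pc))
  eL <- exp(-acq$TE / acq$T2Lc)
  k <- if (model == "3pcs") 3L else 4L
  pclass <- c(sprintf("kinetic_params_%s", model), "kinetic_params")
  function(p) {
    class(p) <- pclass
    sys <- if (model == "3pcs") system_3pcs(p, acq) else system_3pc(p, acq)
    X <- if (k == 3L) lti_solve_tri3(sys$A, sys$b, U_raw, h, n_steps)
         else NULL
    if (is.null(X)) {
      E <- expm_small(sys$A * h)
      M <- vapply(seq_along(.gauss4_nodes), function(i) {
        drop(expm_small(sys$A * h * (1 - .gauss4_nodes[i])) %*% sys$b) *
          (.gauss4_weights[i] * h)
      }, numeric(k))
      G <- M %*% U_raw
      X <- matrix(0, n_steps + 1L, k)
      x <- numeric(k)
      for (n in seq_len(n_steps)) {
        x <- E %*% x + G[, n]
        X[n + 1L, ] <- x
      }
    }
    piv <- u_frames_raw
    pyr <- p$vif_scale * (p$vb * eP[1] * piv + p$vee * eP[2] * X[idx, 1] +
                            p$vc * eP[3] * X[idx, 2]) * sP
    lac <- p$vif_scale * p$vc * eL * X[idx, 3] * sL
    if (k == 4L) lac <- lac + p$vif_scale * p$vee * eL * X[idx, 4] * sL
    list(pyr = pyr, lac = lac)
  }
}

fit_engine <- function(data, vif_source, model, spec, acq, dt) {
  stopifnot(inherits(data, "signal_timecourse"), inherits(spec, "fit_spec"))
  model <- match.arg(model, c("3pcs", "3pc"))
  validate_fit_spec(spec, model)
  bounds <- resolve_bounds(spec)
  evaluator <- make_model_evaluator(data$times, acq, vif_source, model, dt)
  mp <- max(data$pyr)
  ml <- max(data$lac)
  if (mp <= 0 || ml <= 0)
    stop_invalid("observed maxima must be positive for normalization")
  penal_idx <- which(spec$free_params %in% rate_names)
  penal_vols <- all(c("vfrac1", "vfrac2") %in% spec$free_params)
  sqrt_lambda <- sqrt(spec$reg_lambda)
  resid_fun <- function(theta) {
    p <- assemble_params(theta, spec, model)
    mod <- evaluator(p)
    r <- c((data$pyr - mod$pyr) / mp, (data$lac - mod$lac) / ml)
    if (spec$reg_lambda > 0) {
      # penalize all free physiological parameters (rates and volume
      # fractions); vif_scale is a signal-calibration constant, not
      # physiology, and stays unpenalized
      pen <- theta[penal_idx]
      if (penal_vols) pen <- c(pen, p$vb, p$vee, p$vc)
      r <- c(r, sqrt_lambda * pen)
    }
    r
  }
  n_free <- length(spec$free_params)
  # row-wise fill: restart r consumes the same draws for any n_restarts, so
  # enlarging the restart budget can only improve the best objective
  sp_pow <- if (is.null(spec$start_power)) 1 else spec$start_power
  starts <- with_seed(spec$seed,
                      matrix(stats::runif(spec$n_restarts * n_free)^sp_pow,
                             nrow = spec$n_restarts, byrow = TRUE))
  starts <- pmin(pmax(starts, matrix(bounds[, 1], spec$n_restarts, n_free,
                                     byrow = TRUE)),
                 matrix(bounds[, 2], spec$n_restarts, n_free, byrow = TRUE))
  per_restart <- rep(NA_real_, spec$n_restarts)
  solutions <- vector("list", spec$n_restarts)
  converged <- logical(spec$n_restarts)
  ctrl <- minpack.lm::nls.lm.control(maxiter = spec$maxiter,
                                     ftol = spec$ftol, ptol = spec$ptol)
  for (r in seq_len(spec$n_restarts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[r, ], lower = bounds[, 1],
                         upper = bounds[, 2], fn = resid_fun, control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    per_restart[r] <- res$deviance
    solutions[[r]] <- res$par
    converged[r] <- res$info %in% 1:4
  }
  ok <- which(converged & !is.na(per_restart))
  if (length(ok) == 0)
    stop_invalid("no restart converged (%d attempted)", spec$n_restarts)
  best_obj <- min(per_restart[ok])
  # discard boundary-pinned restarts that are far worse than the best basin
  pinned <- vapply(ok, function(r) {
    th <- solutions[[r]]
    any(abs(th - bounds[, 1]) < 1e-9 | abs(th - bounds[, 2]) < 1e-9)
  }, logical(1))
  keep <- ok[!(pinned & per_restart[ok] > 10 * best_obj)]
  if (length(keep) == 0) keep <- ok
  best <- keep[which.min(per_restart[keep])]
  theta <- solutions[[best]]
  names(theta) <- spec$free_params
  plist <- assemble_params(theta, spec, model)
  params <- kinetic_params_from_list(c(plist, list(model = model)))
  structure(list(params = params, free = theta,
                 objective = per_restart[best],
                 n_converged = sum(per_restart[ok] <=
                                     best_obj * (1 + 1e-3) + 1e-15),
                 per_restart = per_restart,
                 n_failed = sum(!converged),
                 model = model, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, objective %.4g (%d/%d restarts in best basin)\n",
              x$model, x$objective, x$n_converged, length(x$per_restart)))
  print(round(x$free, 5))
  invisible(x)
}

#' Multi-start bounded least-squares fit of a kinetic model
#'
#' Fits the selected model to observed pyruvate and lactate curves by
#' repeated bounded Levenberg-Marquardt minimization of the max-normalized
#' residual ([residual_curves()]), from random initial values, returning the
#' best restart. Deterministic for a fixed `spec$seed`.
#'
#' @param data Observed [signal_timecourse()] on the acquisition grid
#'   (uniform times starting at 0).
#' @param vif_source A [vif_params()] object or a function of time giving the
#'   arterial input concentration.
#' @param model `"3pcs"` (simplified) or `"3pc"` (full).
#' @param spec A [fit_spec()].
#' @param acq An [acquisition_params()]; defaults to the one recorded in
#'   `data$meta$acq` when present.
#' @param dt Internal integration step bound (s) for model evaluation.
#' @return A `fit_result`: fitted parameters (`params`), free-parameter
#'   vector (`free`), final objective, per-restart objectives, and counts of
#'   converged/failed restarts.
#' @export
#' @examples
#' truth <- table1_params("3pcs_c")
#' tc <- simulate_3pcs(truth, acquisition_params(), vif_params())
#' spec <- fit_spec(n_restarts = 5, fixed_params = truth)
#' fit_multistart(tc, vif_params(), "3pcs", spec)
fit_multistart <- function(data, vif_source, model = c("3pcs", "3pc"), spec,
                           acq = data$meta$acq, dt = 0.5) {
  model <- match.arg(model)
  if (is.null(acq))
    stop_invalid("no acquisition parameters supplied or recorded in data")
  fit_engine(data, vif_source, model, spec, acq, dt)
}

#' L2-regularized multi-start least-squares fit
#'
#' As [fit_multistart()], but the objective adds an L2 penalty
#' `reg_lambda * sum(k^2)` over the free kinetic rate constants (`kPL`,
#' `kecP`, `kve`, `betaL`, and, for the full model, `kLP`, `kecL`);
#' `vif_scale` and volume fractions are never penalized. Shrinking otherwise
#' poorly determined rates stabilizes downstream quantities -- pool fractions
#' and the model-derived AUC ratio -- on noisy data. With `reg_lambda = 0`
#' this reduces exactly to [fit_multistart()].
#'
#' @inheritParams fit_multistart
#' @return A `fit_result`.
#' @export
fit_regularized <- function(data, vif_source, model = c("3pcs", "3pc"), spec,
                            acq = data$meta$acq, dt = 0.5) {
  model <- match.arg(model)
  if (is.null(acq))
    stop_invalid("no acquisition parameters supplied or recorded in data")
  fit_engine(data, vif_source, model, spec, acq, dt)
}

#' Monte-Carlo precision of fitted parameters versus SNR
#'
#' Generates noiseless simplified-model curves from a known truth, then, for
#' each SNR level, repeatedly adds calibrated Gaussian noise, refits the free
#' parameters, and tabulates the mean, standard deviation, and coefficient of
#' variation (CoV = sd/mean) of each fitted parameter. The precision of
#' `kPL` depends strongly on which compartment dominates the pyruvate signal:
#' only intracellular dominance permits a reproducible `kPL` estimate at
#' modest SNR.
#'
#' @param truth A [kinetic_params_3pcs()] generating parameter set.
#' @param acq An [acquisition_params()].
#' @param vifp A [vif_params()].
#' @param snr_levels Numeric vector of target peak pyruvate SNRs.
#' @param n_reps Noise realizations per SNR level (>= 2).
#' @param spec A [fit_spec()]; defaults to fitting `kPL`, `kecP`, `kve`, and
#'   `vif_scale` with everything else fixed at the truth.
#' @param seed Master seed; per-replicate noise seeds are derived from it.
#' @param dt Internal integration step bound (s).
#' @return A data frame with columns `snr`, `param`, `mean`, `sd`, `cov`,
#'   `n_fail`, `n_reps`.
#' @export
cov_experiment <- function(truth, acq, vifp, snr_levels = c(10, 20, 40, 80),
                           n_reps = 100, spec = NULL, seed = 1, dt = 0.5) {
  stopifnot(inherits(truth, "kinetic_params_3pcs"), n_reps >= 2)
  if (is.null(spec))
    spec <- fit_spec(free_params = c("kPL", "kecP", "kve", "vif_scale"),
                     fixed_params = truth, n_restarts = 10, seed = seed)
  clean <- simulate_3pcs(truth, acq, vifp, dt = dt)
  seeds <- matrix(derive_seeds(seed, length(snr_levels) * n_reps),
                  nrow = n_reps)
  out <- list()
  for (j in seq_along(snr_levels)) {
    fits <- matrix(NA_real_, n_reps, length(spec$free_params),
                   dimnames = list(NULL, spec$free_params))
    n_fail <- 0L
    for (r in seq_len(n_reps)) {
      noisy <- add_noise(clean, noise_spec(snr_levels[j], seeds[r, j]))
      rspec <- spec
      rspec$seed <- seeds[r, j] + 1
      fit <- tryCatch(
        fit_multistart(noisy, vifp, "3pcs", rspec, acq = acq, dt = dt),
        error = function(e) NULL)
      if (is.null(fit)) n_fail <- n_fail + 1L else fits[r, ] <- fit$free
    }
    ok <- stats::complete.cases(fits)
    for (nm in spec$free_params) {
      m <- mean(fits[ok, nm])
      s <- stats::sd(fits[ok, nm])
      out[[length(out) + 1L]] <- data.frame(
        snr = snr_levels[j], param = nm, mean = m, sd = s, cov = s / m,
        n_fail = n_fail, n_reps = n_reps)
    }
  }
  do.call(rbind, out)
}
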