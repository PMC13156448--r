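#' Per-compartment signal AUC factors of the simplified model
#'
#' Laplace-domain identities for the simplified three-compartment model give
#' each compartment's signal area-under-the-curve as a multiple of the VIF
#' concentration AUC. The factors combine the steady-state (s = 0) Laplace
#' solution with the per-pool signal weighting `sin(theta) * exp(-TE/T2*)`.
#' Because every factor is proportional to the VIF AUC, ratios of factors --
#' pool fractions and the AUC ratio -- are independent of the input function.
#'
#' @inheritParams effective_rates
#' @return A list with elements `A_iv`, `A_ee`, `A_c` (pyruvate pools) and
#'   `A_lac` (intracellular lactate), all non-negative, expressed per unit of
#'   VIF concentration AUC.
#' @export
compartment_auc_factors <- function(params, acq) {
  a <- effective_rates(params, acq)
  if (any(abs(unlist(a)) < .Machine$double.eps))
    stop_invalid("degenerate effective rates: all alpha values must be nonzero")
  sP <- sin(deg2rad(acq$thetaPyr))
  sL <- sin(deg2rad(acq$thetaLac))
  # Laplace s = 0 solutions per unit VIF AUC
  pee <- -params$kve / (a$alphaPee * params$vee)
  pc <- (params$kecP * params$kve) /
    (a$alphaPc * params$vc * a$alphaPee * params$vee)
  lc <- -(params$kPL * params$kecP * params$kve) /
    (a$alphaLc * a$alphaPc * params$vc * a$alphaPee * params$vee)
  list(A_iv = params$vb * sP * exp(-acq$TE / acq$T2Pv),
       A_ee = params$vee * pee * sP * exp(-acq$TE / acq$T2Pe),
       A_c = params$vc * pc * sP * exp(-acq$TE / acq$T2Pc),
       A_lac = params$vc * lc * sL * exp(-acq$TE / acq$T2Lc))
}

#' Pool fractions: compartmental shares of the total pyruvate signal AUC
#'
#' The fraction of total pyruvate signal AUC contributed by spins in each
#' physical compartment. The dominant pool determines which kinetic rate
#' constant the lactate/pyruvate AUC ratio chiefly reflects.
#'
#' @inheritParams effective_rates
#' @return A list with elements `f_iv`, `f_ee`, `f_c`, each in \[0, 1\] and
#'   summing to 1.
#' @export
#' @examples
#' pool_fractions(table1_params("3pcs_iv"), acquisition_params(TE = 0))
pool_fractions <- function(params, acq) {
  A <- compartment_auc_factors(params, acq)
  tot <- A$A_iv + A$A_ee + A$A_c
  if (tot <= 0)
    stop_invalid("degenerate parameters: total pyruvate AUC factor is zero")
  list(f_iv = A$A_iv / tot, f_ee = A$A_ee / tot, f_c = A$A_c / tot)
}

#' Closed-form (parameterized) lactate/pyruvate AUC ratio
#'
#' Evaluates the model-derived AUC ratio: the intracellular lactate signal AUC
#' divided by the summed pyruvate signal AUC over all three compartments. The
#' expression involves only kinetic parameters, volume fractions, and
#' acquisition parameters -- not the vascular input function.
#'
#' @inheritParams effective_rates
#' @return A single non-negative number.
#' @export
#' @examples
#' auc_ratio_parameterized(table1_params("3pcs_c"), acquisition_params(TE = 0))
auc_ratio_parameterized <- function(params, acq) {
  A <- compartment_auc_factors(params, acq)
  tot <- A$A_iv + A$A_ee + A$A_c
  if (tot <= 0)
    stop_invalid("degenerate parameters: total pyruvate AUC factor is zero")
  A$A_lac / tot
}

#' Limiting-regime closed forms of the AUC ratio
#'
#' When one pyruvate pool carries essentially all of the pyruvate signal, the
#' parameterized AUC ratio collapses to a simpler expression (TE/T2* effects
#' neglected). With `Theta = sin(thetaLac)/sin(thetaPyr)`:
#' \describe{
#'   \item{intracellular}{`Theta * (-kPL / alphaLc)` -- the ratio is
#'     proportional to intracellular metabolism.}
#'   \item{extracellular}{`Theta * kecP / (vee * alphaPc) * kPL / alphaLc` --
#'     membrane transport becomes rate-limiting.}
#'   \item{intravascular}{`Theta * (-kve / (vb * alphaPee)) * kecP /
#'     (vee * alphaPc) * kPL / alphaLc` -- extravasation enters as well.}
#' }
#'
#' @inheritParams effective_rates
#' @param regime One of `"intracellular"`, `"extracellular"`,
#'   `"intravascular"`.
#' @return A single non-negative number.
#' @export
auc_ratio_limit <- function(params, acq,
                            regime = c("intracellular", "extracellular",
                                       "intravascular")) {
  regime <- match.arg(regime)
  a <- effective_rates(params, acq)
  Theta <- sin(deg2rad(acq$thetaLac)) / sin(deg2rad(acq$thetaPyr))
  lac_term <- -params$kPL / a$alphaLc
  switch(regime,
    intracellular = Theta * lac_term,
    extracellular = Theta * (params$kecP / (params$vee * a$alphaPc)) *
      (params$kPL / a$alphaLc),
    intravascular = Theta * (-params$kve / (params$vb * a$alphaPee)) *
      (params$kecP / (params$vee * a$alphaPc)) * (params$kPL / a$alphaLc))
}

#' Classify the dominant hyperpolarized pyruvate pool
#'
#' Labels a parameter set by the compartment contributing the largest share of
#' total pyruvate signal AUC. Ties within 1e-12 are resolved in favor of the
#' more upstream compartment (intravascular over extravascular/extracellular
#' over intracellular), giving a deterministic, conservative attribution.
#'
#' @inheritParams effective_rates
#' @return One of `"intravascular"`, `"extravascular_extracellular"`,
#'   `"intracellular"`.
#' @export
#' @examples
#' classify_dominant_pool(table1_params("3pcs_ee"), acquisition_params())
classify_dominant_pool <- function(params, acq) {
  f <- pool_fractions(params, acq)
  v <- c(intravascular = f$f_iv,
         extravascular_extracellular = f$f_ee,
         intracellular = f$f_c)
  best <- max(v)
  names(v)[which(v >= best - 1e-12)][1]
}

#' Recalculate the AUC ratio under reference acquisition parameters
#'
#' Corrects a model-derived AUC ratio for acquisition effects (typically echo
#' time) by re-evaluating the closed form with a reference acquisition. The
#' kinetic parameters are usually obtained by fitting data measured with
#' `acq_measured`; the corrected ratio depends only on `acq_reference`, so
#' measurements made at different echo times become directly comparable.
#'
#' @param params Fitted or known [kinetic_params_3pcs()].
#' @param acq_measured Acquisition used for the measurement (kept for
#'   provenance; the corrected value does not depend on its TE).
#' @param acq_reference Acquisition at which the ratio is to be expressed.
#' @return A single non-negative number.
#' @export
recalculate_auc_ratio <- function(params, acq_measured, acq_reference) {
  stopifnot(inherits(acq_measured, "acquisition_params"))
  auc_ratio_parameterized(params, acq_reference)
}
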