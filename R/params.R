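#' Kinetic parameters of the simplified three-compartment (3PCs) model
#'
#' The simplified model tracks hyperpolarized pyruvate through intravascular,
#' extravascular/extracellular, and intracellular spaces, with unidirectional
#' extravasation (`kve`), cell-membrane transport (`kecP`), and intracellular
#' conversion to lactate (`kPL`). Lactate efflux and back-conversion are
#' absorbed into a single heuristic intracellular lactate loss rate `betaL`.
#'
#' @param kPL Apparent pyruvate-to-lactate conversion rate (s^-1).
#' @param kecP Pyruvate cell-membrane transport rate (s^-1).
#' @param kve Pyruvate extravasation rate (s^-1).
#' @param betaL Heuristic intracellular lactate signal loss rate (s^-1).
#' @param vb,vee,vc Intravascular, extravascular/extracellular, and
#'   intracellular volume fractions. Must be in (0, 1) and sum to 1;
#'   `vee` and `vc` must be strictly positive because the model equations
#'   normalize fluxes by them.
#' @param vif_scale Dimensionless amplitude scaling of the vascular input
#'   function (VIF).
#'
#' @return An object of class `kinetic_params_3pcs` (a named list).
#' @seealso [kinetic_params_3pc()] for the full model,
#'   [effective_rates()], [pool_fractions()], [auc_ratio_parameterized()].
#' @export
#' @examples
#' p <- kinetic_params_3pcs(kPL = 0.2061, kecP = 0.1211, kve = 0.1656,
#'                          betaL = 0.078, vb = 0.02, vee = 0.196, vc = 0.784)
#' pool_fractions(p, acquisition_params(TE = 0))
kinetic_params_3pcs <- function(kPL, kecP, kve, betaL, vb, vee, vc,
                                vif_scale = 1) {
  for (nm in c("kPL", "kecP", "kve", "betaL"))
    check_number(get(nm), nm, lo = 0)
  check_number(vif_scale, "vif_scale", lo = 0)
  check_volume_fractions(vb, vee, vc)
  structure(list(kPL = kPL, kecP = kecP, kve = kve, betaL = betaL,
                 vb = vb, vee = vee, vc = vc, vif_scale = vif_scale),
            class = c("kinetic_params_3pcs", "kinetic_params"))
}

#' Kinetic parameters of the full three-compartment (3PC) model
#'
#' The full model adds reversible intracellular exchange (`kLP`) and
#' bidirectional lactate membrane transport (`kecL`); no intravascular lactate
#' is modeled because none is present in the arterial input.
#'
#' @inheritParams kinetic_params_3pcs
#' @param kLP Lactate-to-pyruvate conversion rate (s^-1).
#' @param kecL Lactate cell-membrane transport rate (s^-1).
#' @return An object of class `kinetic_params_3pc`.
#' @export
kinetic_params_3pc <- function(kPL, kLP, kecP, kecL, kve, vb, vee, vc,
                               vif_scale = 1) {
  for (nm in c("kPL", "kLP", "kecP", "kecL", "kve"))
    check_number(get(nm), nm, lo = 0)
  check_number(vif_scale, "vif_scale", lo = 0)
  check_volume_fractions(vb, vee, vc)
  structure(list(kPL = kPL, kLP = kLP, kecP = kecP, kecL = kecL, kve = kve,
                 vb = vb, vee = vee, vc = vc, vif_scale = vif_scale),
            class = c("kinetic_params_3pc", "kinetic_params"))
}

check_volume_fractions <- function(vb, vee, vc) {
  check_number(vb, "vb", lo = 0, hi = 1, closed_lo = FALSE, closed_hi = FALSE)
  check_number(vee, "vee", lo = 0, hi = 1, closed_lo = FALSE, closed_hi = FALSE)
  check_number(vc, "vc", lo = 0, hi = 1, closed_lo = FALSE, closed_hi = FALSE)
  if (abs(vb + vee + vc - 1) > 1e-9)
    stop_invalid("volume fractions must sum to 1 (got %.12g)", vb + vee + vc)
  invisible(TRUE)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 10), " ",
             format(vals, digits = 5), collapse = "\n"), "\n")
  invisible(x)
}

#' Acquisition parameters for a dynamic hyperpolarized 13C acquisition
#'
#' Defaults follow a typical clinical spectral-spatial EPI protocol: TR 3 s,
#' 60 frames (3-minute acquisition), constant flip angles of 20 deg for
#' pyruvate and 30 deg for lactate, T1 of 43 s (pyruvate) and 33 s (lactate),
#' and apparent T2* of 100 ms for intravascular pyruvate, 55 ms for
#' extravascular/extracellular and intracellular pyruvate, and 33 ms for
#' intracellular lactate. Acquisition starts before the bolus arrives
#' (`t_bolus`, seconds after the first frame).
#'
#' @param TR Repetition time (s).
#' @param TE Echo time (s).
#' @param thetaPyr,thetaLac Flip angles (degrees), in (0, 90).
#' @param T1Pyr,T1Lac Longitudinal relaxation times (s).
#' @param T2Pv,T2Pe,T2Pc,T2Lc Apparent transverse relaxation times (s) of
#'   intravascular, extravascular/extracellular, and intracellular pyruvate,
#'   and of intracellular lactate.
#' @param n_frames Number of acquired frames.
#' @param t_bolus Bolus arrival time after acquisition start (s).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(TR = 3, TE = 0, thetaPyr = 20, thetaLac = 30,
                               T1Pyr = 43, T1Lac = 33,
                               T2Pv = 0.100, T2Pe = 0.055, T2Pc = 0.055,
                               T2Lc = 0.033,
                               n_frames = 60, t_bolus = 15) {
  check_number(TR, "TR", lo = 0, closed_lo = FALSE)
  check_number(TE, "TE", lo = 0)
  check_number(thetaPyr, "thetaPyr", lo = 0, hi = 90,
               closed_lo = FALSE, closed_hi = FALSE)
  check_number(thetaLac, "thetaLac", lo = 0, hi = 90,
               closed_lo = FALSE, closed_hi = FALSE)
  for (nm in c("T1Pyr", "T1Lac", "T2Pv", "T2Pe", "T2Pc", "T2Lc"))
    check_number(get(nm), nm, lo = 0, closed_lo = FALSE)
  check_number(n_frames, "n_frames", lo = 1)
  check_number(t_bolus, "t_bolus", lo = 0)
  structure(list(TR = TR, TE = TE, thetaPyr = thetaPyr, thetaLac = thetaLac,
                 T1Pyr = T1Pyr, T1Lac = T1Lac,
                 T2Pv = T2Pv, T2Pe = T2Pe, T2Pc = T2Pc, T2Lc = T2Lc,
                 n_frames = as.integer(n_frames), t_bolus = t_bolus),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat("<acquisition_params>\n")
  cat(sprintf("  TR %g s, TE %g ms, flips %g/%g deg, %d frames, bolus at %g s\n",
              x$TR, 1000 * x$TE, x$thetaPyr, x$thetaLac, x$n_frames, x$t_bolus))
  cat(sprintf("  T1 %g/%g s; T2* (Pv/Pe/Pc/Lc) %g/%g/%g/%g ms\n",
              x$T1Pyr, x$T1Lac, 1000 * x$T2Pv, 1000 * x$T2Pe, 1000 * x$T2Pc,
              1000 * x$T2Lc))
  invisible(x)
}

# RF excitation loss modeled as the continuous rate (1 - cos(theta)) / TR.
rf_loss_rate <- function(theta_deg, TR) (1 - cos(deg2rad(theta_deg))) / TR

#' Effective per-compartment signal decay rates
#'
#' Aggregates exchange, longitudinal relaxation, and (continuous-rate) RF
#' excitation losses into one effective decay rate per model state:
#' `alphaPee` for extravascular/extracellular pyruvate, `alphaPc` for
#' intracellular pyruvate, and `alphaLc` for intracellular lactate. All three
#' are strictly negative for valid parameters.
#'
#' @param params A [kinetic_params_3pcs()] object.
#' @param acq An [acquisition_params()] object.
#' @return A list with elements `alphaPee`, `alphaPc`, `alphaLc` (s^-1).
#' @export
#' @examples
#' p <- table1_params("3pcs_c")
#' effective_rates(p, acquisition_params())
effective_rates <- function(params, acq) {
  stopifnot(inherits(params, "kinetic_params_3pcs"),
            inherits(acq, "acquisition_params"))
  R1P <- 1 / acq$T1Pyr
  R1L <- 1 / acq$T1Lac
  rfP <- rf_loss_rate(acq$thetaPyr, acq$TR)
  rfL <- rf_loss_rate(acq$thetaLac, acq$TR)
  list(alphaPee = -(params$kve / params$vee + params$kecP / params$vee +
                      R1P + rfP),
       alphaPc = -(params$kPL + R1P + rfP),
       alphaLc = -(R1L + rfL + params$betaL))
}
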