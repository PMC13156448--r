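# Readers, writers, the bundled parameter registry, and per-voxel analysis.

#' Reference kinetic parameter sets
#'
#' The package ships six reference parameter sets representing physiological
#' conditions in which the hyperpolarized pyruvate signal is dominated by the
#' intravascular (`iv`), extravascular/extracellular (`ee`), or intracellular
#' (`c`) compartment -- one trio for the full model (`"3pc_*"`) and one for
#' the simplified model (`"3pcs_*"`). The simplified-model sets are the
#' least-squares counterparts of the full-model sets.
#'
#' @param name One of `"3pc_iv"`, `"3pc_ee"`, `"3pc_c"`, `"3pcs_iv"`,
#'   `"3pcs_ee"`, `"3pcs_c"`. Omit to list available names.
#' @return A [kinetic_params_3pcs()] or [kinetic_params_3pc()] object, or a
#'   character vector of names when `name` is missing.
#' @export
#' @examples
#' table1_params()
#' table1_params("3pcs_c")
table1_params <- function(name) {
  path <- system.file("extdata", "table1_params.json", package = "hpauc",
                      mustWork = TRUE)
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (missing(name)) return(names(reg))
  if (!name %in% names(reg))
    stop_invalid("unknown parameter set '%s'; available: %s", name,
                 paste(names(reg), collapse = ", "))
  kinetic_params_from_list(reg[[name]])
}

#' Build kinetic parameters from a plain named list
#'
#' Reconstructs a kinetic parameter object from a named list or JSON record.
#' The model variant is taken from a `model` element (`"3pcs"` or `"3pc"`) or
#' inferred from the fields present (`betaL` implies the simplified model).
#'
#' @param x A named list of parameter values.
#' @return A kinetic parameter object.
#' @export
kinetic_params_from_list <- function(x) {
  model <- x$model
  if (is.null(model)) model <- if (!is.null(x$betaL)) "3pcs" else "3pc"
  vs <- if (is.null(x$vif_scale)) 1 else x$vif_scale
  if (model == "3pcs")
    kinetic_params_3pcs(kPL = x$kPL, kecP = x$kecP, kve = x$kve,
                        betaL = x$betaL, vb = x$vb, vee = x$vee, vc = x$vc,
                        vif_scale = vs)
  else
    kinetic_params_3pc(kPL = x$kPL, kLP = x$kLP, kecP = x$kecP,
                       kecL = x$kecL, kve = x$kve, vb = x$vb, vee = x$vee,
                       vc = x$vc, vif_scale = vs)
}

#' Read dynamic signal time courses from CSV
#'
#' Expects columns `time_s`, `pyr`, `lac`, optionally `vif` and `voxel_id`.
#' Rows are sorted by time within each voxel; rows with missing or
#' non-numeric required fields are rejected with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A named list of [signal_timecourse()] objects, one per voxel
#'   (single unnamed voxel files yield one element named `"voxel1"`).
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "pyr", "lac")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_invalid("missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(df[required]) |
                 !vapply(seq_len(nrow(df)), function(i)
                   all(vapply(df[i, required], is.numeric, logical(1))),
                   logical(1)))
  if (length(bad) > 0)
    stop_invalid("malformed rows at line(s): %s",
                 paste(bad + 1L, collapse = ", "))
  if (!"voxel_id" %in% names(df)) df$voxel_id <- "voxel1"
  out <- lapply(split(df, df$voxel_id), function(d) {
    d <- d[order(d$time_s), ]
    if (anyDuplicated(d$time_s))
      stop_invalid("non-monotone (duplicated) time values in voxel '%s'",
                   d$voxel_id[1])
    signal_timecourse(times = d$time_s, pyr = d$pyr, lac = d$lac,
                      vif = if ("vif" %in% names(d)) d$vif else NULL,
                      meta = list(voxel_id = d$voxel_id[1]))
  })
  out[unique(df$voxel_id)]
}

#' Write signal time courses to CSV
#'
#' Long-format companion to [read_timecourses()]: columns `voxel_id`,
#' `time_s`, `pyr`, `lac`, and `vif` (when present).
#'
#' @param timecourses A [signal_timecourse()] or a named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(timecourses, path) {
  if (inherits(timecourses, "signal_timecourse"))
    timecourses <- list(voxel1 = timecourses)
  rows <- lapply(names(timecourses), function(id) {
    tc <- timecourses[[id]]
    d <- data.frame(voxel_id = id, time_s = tc$times, pyr = tc$pyr,
                    lac = tc$lac)
    if (!is.null(tc$vif)) d$vif <- tc$vif
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Per-voxel kinetic analysis of dynamic hyperpolarized pyruvate data
#'
#' Mirrors a clinical per-voxel workflow: voxels passing peak-SNR and tumor
#' fraction thresholds are fit with the L2-regularized multi-start least
#' squares (free parameters: `kPL`, `kecP`, `kve`, `betaL`, the three volume
#' fractions via two simplex coordinates, and `vif_scale`), then summarized
#' by their integrated AUC ratio, model-derived AUC ratio, and dominant
#' pyruvate pool.
#'
#' @param records Named list of [signal_timecourse()] objects (e.g. from
#'   [read_timecourses()]).
#' @param vif_source The arterial input: a [vif_params()] object, a function
#'   of time, or the name of a record whose `vif` column (or pyruvate curve)
#'   is the measured input, interpolated linearly.
#' @param fitspec A [fit_spec()]; its `free_params` should include the
#'   simplex coordinates `vfrac1`, `vfrac2` when volume fractions are fitted.
#' @param acq An [acquisition_params()].
#' @param thresholds List with elements `snr` (minimum peak SNR, default 10)
#'   and `tumor_frac` (minimum tumor fraction, default 0.3; voxels without a
#'   `tumor_frac` in `meta` are not filtered on it).
#' @param noise_window Optional frame indices for noise estimation, passed to
#'   [peak_snr()].
#' @return A list with `voxels` (per-voxel results: fit, peak SNR, integrated
#'   and model-derived AUC ratios, dominant-pool label), `excluded` (names
#'   and reasons), and `summary` (label counts).
#' @export
analyze_voxels <- function(records, vif_source, fitspec, acq,
                           thresholds = list(snr = 10, tumor_frac = 0.3),
                           noise_window = NULL) {
  stopifnot(is.list(records), length(records) > 0)
  if (is.character(vif_source)) {
    if (!vif_source %in% names(records))
      stop_invalid("no record named '%s' to use as the arterial input",
                   vif_source)
    ref <- records[[vif_source]]
    curve <- if (!is.null(ref$vif)) ref$vif else ref$pyr
    vfun <- stats::approxfun(ref$times, curve, rule = 1, yleft = 0, yright = 0)
    vif_source <- function(t) pmax(0, vfun(t))
  }
  snr_min <- if (is.null(thresholds$snr)) 10 else thresholds$snr
  tf_min <- if (is.null(thresholds$tumor_frac)) 0.3 else thresholds$tumor_frac
  voxels <- list()
  excluded <- list()
  for (id in names(records)) {
    tc <- records[[id]]
    snr <- peak_snr(tc, noise_window)
    tf <- tc$meta$tumor_frac
    if (!is.null(tf) && !is.na(tf) && tf < tf_min) {
      excluded[[id]] <- sprintf("tumor fraction %.2f below %.2f", tf, tf_min)
      next
    }
    if (is.finite(snr) && snr < snr_min) {
      excluded[[id]] <- sprintf("peak SNR %.1f below %.1f", snr, snr_min)
      next
    }
    fit <- fit_regularized(tc, vif_source, model = "3pcs", spec = fitspec,
                           acq = acq)
    voxels[[id]] <- list(
      voxel_id = id,
      peak_snr = snr,
      tumor_frac = tf,
      fit = fit,
      integrated_ratio = integrated_auc_ratio(tc),
      model_ratio = auc_ratio_parameterized(fit$params, acq),
      dominant_pool = classify_dominant_pool(fit$params, acq))
  }
  labels <- vapply(voxels, `[[`, character(1), "dominant_pool")
  list(voxels = voxels, excluded = excluded,
       summary = list(n_analyzed = length(voxels),
                      n_excluded = length(excluded),
                      label_counts = table(factor(labels, levels = c(
                        "intravascular", "extravascular_extracellular",
                        "intracellular")))))
}
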