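test_that("parameter constructors enforce physical invariants", {
  expect_error(kinetic_params_3pcs(kPL = -0.1, kecP = 0.1, kve = 0.1,
                                   betaL = 0.1, vb = 0.2, vee = 0.4,
                                   vc = 0.4),
               "kPL")
  expect_error(kinetic_params_3pcs(kPL = 0.1, kecP = 0.1, kve = 0.1,
                                   betaL = 0.1, vb = 0.2, vee = 0.4,
                                   vc = 0.5),
               "sum to 1")
  # vee = 0 rejected: the model equations normalize fluxes by it
  expect_error(kinetic_params_3pcs(kPL = 0.1, kecP = 0.1, kve = 0.1,
                                   betaL = 0.1, vb = 0.5, vee = 0,
                                   vc = 0.5),
               "vee")
  expect_error(acquisition_params(TR = 0), "TR")
  expect_error(acquisition_params(thetaPyr = 95), "thetaPyr")
  expect_error(acquisition_params(T1Pyr = -1), "T1Pyr")
})

test_that("effective decay rates match their closed-form definition", {
  a <- effective_rates(params3pcs("c"), acq0())
  # frozen from direct arithmetic on the rate definitions
  expect_equal(a$alphaPee, -1.5061134, tolerance = 1e-6)
  expect_equal(a$alphaPc, -0.2494583, tolerance = 1e-6)
  expect_equal(a$alphaLc, -0.1529612, tolerance = 1e-6)
  expect_true(all(unlist(a) < 0))

  # with betaL = 0 the lactate rate reduces to relaxation + RF loss only
  p0 <- kinetic_params_3pcs(kPL = 0.2, kecP = 0.1, kve = 0.1, betaL = 0,
                            vb = 0.1, vee = 0.4, vc = 0.5)
  acq <- acq0()
  a0 <- effective_rates(p0, acq)
  expect_equal(a0$alphaLc,
               -(1 / acq$T1Lac + (1 - cos(30 * pi / 180)) / acq$TR))

  # all loss mechanisms off: rates -> 0
  pz <- kinetic_params_3pcs(kPL = 0, kecP = 0, kve = 0, betaL = 0,
                            vb = 0.1, vee = 0.4, vc = 0.5)
  az <- effective_rates(pz, acquisition_params(thetaPyr = 1e-6,
                                               thetaLac = 1e-6,
                                               T1Pyr = 1e12, T1Lac = 1e12))
  expect_true(all(abs(unlist(az)) < 1e-11))
})

test_that("pool fractions reproduce the printed reference percentages", {
  for (cl in c("iv", "ee", "c")) {
    f <- pool_fractions(params3pcs(cl), acq0())
    got <- 100 * c(f$f_iv, f$f_ee, f$f_c)
    expect_equal(got, table1b_percent[[cl]], tolerance = 0.1 / 60)
    expect_equal(sum(got), 100, tolerance = 1e-9)
  }
})

test_that("compartment AUC factors vanish with their upstream rates", {
  acq <- acq0()
  base <- unclass(params3pcs("c"))
  no_kve <- kinetic_params_from_list(modifyList(base, list(kve = 0,
                                                           model = "3pcs")))
  A <- compartment_auc_factors(no_kve, acq)
  expect_equal(c(A$A_ee, A$A_c, A$A_lac), c(0, 0, 0))
  expect_gt(A$A_iv, 0)

  no_kpl <- kinetic_params_from_list(modifyList(base, list(kPL = 0,
                                                           model = "3pcs")))
  A2 <- compartment_auc_factors(no_kpl, acq)
  Afull <- compartment_auc_factors(params3pcs("c"), acq)
  expect_equal(A2$A_lac, 0)
  expect_equal(A2$A_iv, Afull$A_iv)
  expect_equal(A2$A_ee, Afull$A_ee)
  expect_equal(auc_ratio_parameterized(no_kpl, acq), 0)

  no_kecp <- kinetic_params_from_list(modifyList(base, list(kecP = 0,
                                                            model = "3pcs")))
  expect_equal(pool_fractions(no_kecp, acq)$f_c, 0)
})

test_that("parameterized AUC ratio and limiting forms match frozen values", {
  acq <- acq0()
  pc <- params3pcs("c")
  expect_equal(auc_ratio_parameterized(pc, acq), 1.3334573,
               tolerance = 1e-6)
  expect_equal(auc_ratio_limit(pc, acq, "intracellular"), 1.9697674,
               tolerance = 1e-6)
  expect_error(auc_ratio_limit(pc, acq, "nonsense"))
})

test_that("AUC ratio is monotone in kPL (up) and betaL (down)", {
  acq <- acq0()
  base <- unclass(params3pcs("c"))
  ratios_kpl <- vapply(seq(0.05, 0.5, length.out = 8), function(k) {
    auc_ratio_parameterized(kinetic_params_from_list(
      modifyList(base, list(kPL = k, model = "3pcs"))), acq)
  }, numeric(1))
  expect_true(all(diff(ratios_kpl) > 0))
  ratios_bl <- vapply(seq(0, 0.3, length.out = 8), function(b) {
    auc_ratio_parameterized(kinetic_params_from_list(
      modifyList(base, list(betaL = b, model = "3pcs"))), acq)
  }, numeric(1))
  expect_true(all(diff(ratios_bl) < 0))
})

test_that("limiting forms are reached as one pool approaches dominance", {
  acq <- acq0()
  # intracellular: fast delivery, tiny vascular/interstitial volumes
  p_c <- kinetic_params_3pcs(kPL = 0.2, kecP = 5, kve = 5, betaL = 0.05,
                             vb = 0.002, vee = 0.008, vc = 0.99)
  expect_gt(pool_fractions(p_c, acq)$f_c, 0.99)
  expect_equal(auc_ratio_parameterized(p_c, acq),
               auc_ratio_limit(p_c, acq, "intracellular"), tolerance = 0.01)
  # extravascular/extracellular: fast extravasation, slow uptake
  p_ee <- kinetic_params_3pcs(kPL = 0.2, kecP = 0.001, kve = 10,
                              betaL = 0.05, vb = 0.002, vee = 0.98,
                              vc = 0.018)
  expect_gt(pool_fractions(p_ee, acq)$f_ee, 0.99)
  expect_equal(auc_ratio_parameterized(p_ee, acq),
               auc_ratio_limit(p_ee, acq, "extracellular"), tolerance = 0.01)
  # intravascular: little extravasation, blood-dominated volume
  p_iv <- kinetic_params_3pcs(kPL = 0.2, kecP = 0.001, kve = 0.001,
                              betaL = 0.05, vb = 0.99, vee = 0.008,
                              vc = 0.002)
  expect_gt(pool_fractions(p_iv, acq)$f_iv, 0.99)
  expect_equal(auc_ratio_parameterized(p_iv, acq),
               auc_ratio_limit(p_iv, acq, "intravascular"), tolerance = 0.01)
})

test_that("dominant-pool classification labels the reference sets", {
  acq <- acq0()
  expect_identical(classify_dominant_pool(params3pcs("iv"), acq),
                   "intravascular")
  expect_identical(classify_dominant_pool(params3pcs("ee"), acq),
                   "extravascular_extracellular")
  expect_identical(classify_dominant_pool(params3pcs("c"), acq),
                   "intracellular")
})

test_that("echo-time recalculation corrects the ratio to a reference TE", {
  pc <- params3pcs("c")
  acq_meas <- acquisition_params(TE = 0.060)
  acq_ref <- acquisition_params(TE = 0.020)
  # identity when measured and reference TE coincide
  expect_equal(recalculate_auc_ratio(pc, acq_meas, acq_meas),
               auc_ratio_parameterized(pc, acq_meas))
  # lactate T2* is shortest, so the ratio falls with TE and the corrected
  # value at a shorter reference TE exceeds the raw long-TE value
  expect_gt(recalculate_auc_ratio(pc, acq_meas, acq_ref),
            auc_ratio_parameterized(pc, acq_meas))
  te_grid <- seq(0, 0.06, by = 0.01)
  ratios <- vapply(te_grid, function(te)
    auc_ratio_parameterized(pc, acquisition_params(TE = te)), numeric(1))
  expect_true(all(diff(ratios) < 0))
  # TE = 0 reference reproduces the TE-free closed form
  expect_equal(recalculate_auc_ratio(pc, acq_meas, acq0()), 1.3334573,
               tolerance = 1e-6)
})
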