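test_that("gamma-variate input is causal with the expected peak and support", {
  vifp <- vif0()
  t <- seq(0, 200, by = 0.01)
  v <- gamma_variate_vif(vifp, t)
  expect_true(all(v[t < vifp$t0] == 0))
  expect_true(all(v >= 0))
  # analytic peak location: t0 + shape * rate
  expect_equal(t[which.max(v)], vifp$t0 + vifp$shape * vifp$rate,
               tolerance = 1e-3)
  expect_equal(t[which.max(v)], 27.6, tolerance = 1e-3)
  # bolus essentially complete by 100 s, matching the signal lifetime
  expect_gt(sum(v[t <= 100]) / sum(v), 0.99)
})

test_that("simplified-model solver matches an adaptive ODE oracle", {
  library(deSolve)
  acq <- acquisition_params()
  vifp <- vif0()
  pc <- params3pcs("c")
  tc <- simulate_3pcs(pc, acq, vifp, per_compartment = TRUE)
  a <- effective_rates(pc, acq)
  rhs <- function(t, y, parms) {
    u <- pc$vif_scale * gamma_variate_vif(vifp, t)
    list(c(a$alphaPee * y[1] + pc$kve / pc$vee * u,
           pc$kecP / pc$vc * y[1] + a$alphaPc * y[2],
           pc$kPL * y[2] + a$alphaLc * y[3]))
  }
  ref <- deSolve::ode(c(0, 0, 0), times = tc$times, func = rhs, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  sP <- sin(acq$thetaPyr * pi / 180)
  sL <- sin(acq$thetaLac * pi / 180)
  expect_lt(max(abs(tc$compartments$pyr_ee - pc$vee * sP * ref[, 2])) /
              max(pc$vee * sP * ref[, 2]), 1e-8)
  expect_lt(max(abs(tc$compartments$lac_c - pc$vc * sL * ref[, 4])) /
              max(pc$vc * sL * ref[, 4]), 1e-8)
})

test_that("simulation degenerates correctly without input or transport", {
  acq <- acquisition_params()
  zero_vif <- vif_params(amplitude = 0)
  tc <- simulate_3pcs(params3pcs("c"), acq, zero_vif)
  expect_true(all(tc$pyr == 0) && all(tc$lac == 0))
  tc3 <- simulate_3pc(params3pc("c"), acq, zero_vif)
  expect_true(all(tc3$pyr == 0) && all(tc3$lac == 0))

  base <- unclass(params3pcs("c"))
  no_uptake <- kinetic_params_from_list(modifyList(base, list(kecP = 0,
                                                              model = "3pcs")))
  tcu <- simulate_3pcs(no_uptake, acq, vif0())
  expect_true(all(tcu$lac == 0))
  expect_gt(max(tcu$pyr), 0)
})

test_that("signals are linear in the input amplitude and vif_scale", {
  acq <- acquisition_params()
  pc <- params3pcs("ee")
  tc1 <- simulate_3pcs(pc, acq, vif0())
  tc2 <- simulate_3pcs(pc, acq, vif_params(amplitude = 3))
  expect_equal(tc2$pyr, 3 * tc1$pyr, tolerance = 1e-12)
  expect_equal(tc2$lac, 3 * tc1$lac, tolerance = 1e-12)
  scaled <- kinetic_params_from_list(modifyList(unclass(pc),
                                                list(vif_scale = 2,
                                                     model = "3pcs")))
  tc3 <- simulate_3pcs(scaled, acq, vif0())
  expect_equal(tc3$pyr, 2 * tc1$pyr, tolerance = 1e-12)
})

test_that("full model nests the simplified model", {
  # with reverse exchange off, the only remaining structural difference is
  # the full model's pyruvate efflux from the cell (kecP is bidirectional
  # there, unidirectional in the simplified model), so the models coincide
  # exactly at kecP = 0 and converge as kecP -> 0
  acq <- acquisition_params()
  vifp <- vif0()
  mk <- function(kecP) {
    p3 <- kinetic_params_3pc(kPL = 0.2, kLP = 0, kecP = kecP, kecL = 0,
                             kve = 0.08, vb = 0.02, vee = 0.196, vc = 0.784)
    ps <- kinetic_params_3pcs(kPL = 0.2, kecP = kecP, kve = 0.08, betaL = 0,
                              vb = 0.02, vee = 0.196, vc = 0.784)
    list(full = simulate_3pc(p3, acq, vifp),
         simp = simulate_3pcs(ps, acq, vifp))
  }
  exact <- mk(0)
  expect_lt(max(abs(exact$full$pyr - exact$simp$pyr)) / max(exact$simp$pyr),
            1e-8)
  expect_true(all(exact$full$lac == 0) && all(exact$simp$lac == 0))
  near <- mk(1e-3)
  expect_lt(max(abs(near$full$pyr - near$simp$pyr)) / max(near$simp$pyr),
            1e-3)
  expect_lt(max(abs(near$full$lac - near$simp$lac)) / max(near$simp$lac),
            5e-3)
})

test_that("closed-form AUC identities agree with dense numerical integration", {
  acq <- acquisition_params()
  # VIF-independence: two very different boluses give the same ratio
  vifs <- list(vif0(), vif_params(t0 = 5, amplitude = 4, shape = 1.5,
                                  rate = 9))
  for (cl in c("iv", "ee", "c")) {
    p <- params3pcs(cl)
    closed <- auc_ratio_parameterized(p, acq)
    for (vf in vifs) {
      d <- dense_sim(p, acq, vf)
      num <- trapz(d$lac, d$times) / trapz(d$pyr, d$times)
      expect_equal(num, closed, tolerance = 0.005)
    }
    # pool fractions from integrated per-compartment signals
    d <- dense_sim(p, acq, vifs[[1]])
    shares <- vapply(c("pyr_iv", "pyr_ee", "pyr_c"), function(nm)
      trapz(d$compartments[[nm]], d$times), numeric(1))
    shares <- shares / sum(shares)
    f <- pool_fractions(p, acq)
    expect_equal(unname(shares), c(f$f_iv, f$f_ee, f$f_c), tolerance = 0.005)
  }
  # full model: integrated pyruvate shares against the steady-state
  # (Laplace s = 0) linear solve, an independent closed-form oracle
  for (cl in c("iv", "ee", "c")) {
    p <- params3pc(cl)
    d <- dense_sim(p, acq, vifs[[1]])
    shares <- vapply(c("pyr_iv", "pyr_ee", "pyr_c"), function(nm)
      trapz(d$compartments[[nm]], d$times), numeric(1))
    shares <- shares / sum(shares)
    sys <- hpauc:::system_3pc(p, acq)
    xbar <- solve(sys$A, -sys$b)
    ref <- c(p$vb, p$vee * xbar[1], p$vc * xbar[2])
    ref <- ref / sum(ref)
    expect_equal(unname(shares), unname(ref), tolerance = 0.005)
  }
})

test_that("discrete-pulse RF bookkeeping corroborates the continuous rate", {
  acq <- acquisition_params()
  for (cl in c("iv", "c")) {
    p <- params3pcs(cl)
    cont <- simulate_3pcs(p, acq, vif0())
    disc <- hpauc:::simulate_3pcs_discrete(p, acq, vif0())
    expect_equal(integrated_auc_ratio(disc), integrated_auc_ratio(cont),
                 tolerance = 0.05)
  }
})

test_that("noise is calibrated to the target peak SNR and reproducible", {
  acq <- acquisition_params()
  tc <- simulate_3pcs(params3pcs("c"), acq, vif0())
  ns <- noise_spec(20, seed = 123)
  noisy1 <- add_noise(tc, ns)
  noisy2 <- add_noise(tc, ns)
  expect_identical(noisy1$pyr, noisy2$pyr)
  expect_identical(noisy1$lac, noisy2$lac)
  expect_equal(noisy1$meta$sigma, max(tc$pyr) / 20)
  expect_error(noise_spec(0), "target_peak_snr")

  # long noise-only tail: realized noise sd within sampling error of the
  # calibrated sigma, and the peak-SNR estimate close to target (the noisy
  # maximum biases it upward slightly)
  n <- 10000
  flat <- signal_timecourse(times = seq(0, n - 1), pyr = c(1, rep(0, n - 1)),
                            lac = rep(0, n))
  noisy <- add_noise(flat, noise_spec(20, seed = 7))
  expect_equal(stats::sd(noisy$pyr[101:n]), 0.05, tolerance = 0.03)
  expect_equal(peak_snr(noisy, noise_window = 101:n), 20, tolerance = 0.2)
})

test_that("peak SNR estimation flags degenerate and overlapping windows", {
  acq <- acquisition_params()
  # exactly noiseless tail: zero standard deviation is flagged
  flat <- signal_timecourse(times = 0:9, pyr = c(1, rep(0, 9)),
                            lac = rep(0, 10))
  expect_warning(expect_identical(peak_snr(flat, noise_window = 5:10), Inf),
                 "zero noise")
  tc <- simulate_3pcs(params3pcs("c"), acq, vif0())
  # noiseless simulation: residual tail is numerically tiny, SNR effectively
  # unbounded
  expect_gt(peak_snr(tc), 1e6)
  noisy <- add_noise(tc, noise_spec(20, seed = 1))
  expect_warning(peak_snr(noisy, noise_window = 5:15), "overlaps")
  est <- peak_snr(noisy)
  expect_gt(est, 10)
  expect_lt(est, 40)
  # ratio invariance under joint scaling
  scaled <- noisy
  scaled$pyr <- 10 * noisy$pyr
  scaled$lac <- 10 * noisy$lac
  expect_equal(peak_snr(scaled), est)
})

test_that("integrated AUC ratio is scale invariant and truncates noise", {
  acq <- acquisition_params()
  tc <- simulate_3pcs(params3pcs("c"), acq, vif0())
  r <- integrated_auc_ratio(tc)
  doubled <- tc
  doubled$pyr <- 2 * tc$pyr
  doubled$lac <- 2 * tc$lac
  expect_equal(integrated_auc_ratio(doubled), r)
  zero_lac <- tc
  zero_lac$lac <- rep(0, length(tc$times))
  expect_equal(integrated_auc_ratio(zero_lac), 0)
  # truncation drops pre-bolus frames and a sliver of the lactate tail, so
  # the two ratios agree only to a few percent on noiseless data
  expect_equal(r, integrated_auc_ratio(tc, truncation = "none"),
               tolerance = 0.05)
})
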