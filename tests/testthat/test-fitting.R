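# Nonlinear fitting: exact recovery, goodness of fit, saturation rule,
# model ranking and the single-step Arrhenius estimation.

fine_grid <- c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15, 20, 25, 30)

test_that("noiseless curves return the generating parameters exactly", {
  cases <- list(
    list(model = "weibull", params = list(alpha = 4.52, beta = 0.6)),
    list(model = "peleg", params = list(K1 = 0.02, K2 = 1 / 138.9)),
    list(model = "exponential", params = list(K = 0.35, n = 0.6)),
    list(model = "first_order", params = list(H = 0.25)),
    list(model = "fick", params = list(D_eff = 6.533e-8, G = 6.53)))
  for (cs in cases) {
    cv <- sim_rehydration_curves(cs$model, cs$params, E_a = 14,
                                 temperatures = 353.15, times = fine_grid,
                                 noise_sd = 0, seed = 1)[[1]]
    fit <- fit_kinetics(cv, cs$model, M_e = 150, M_o = 11.1)
    for (nm in names(cs$params))
      expect_equal(coef(fit)[[nm]], cs$params[[nm]], tolerance = 1e-6,
                   label = sprintf("%s:%s", cs$model, nm))
    # refitting the model to its own predictions is a fixed point
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("goodness-of-fit statistics match their definitions", {
  g <- goodness_of_fit(c(0, 0.5, 1), c(0, 0.5, 1), 1)
  expect_equal(g$R2, 1); expect_equal(g$RMSE, 0); expect_equal(g$chi2, 0)
  # SSE = SST when predicting the mean
  expect_equal(goodness_of_fit(c(0, 1), c(0.5, 0.5), 1)$R2, 0)
  # constant shift e on every point gives RMSE |e|
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3) + 0.2, 1)$RMSE, 0.2)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 1, 0.9), 1), "undefined")
  expect_error(goodness_of_fit(1:3, 1:2, 1), "differ")
})

test_that("saturation time applies the consecutive-difference rule", {
  cv <- rehydration_curve(c(0, 60, 120, 180), c(10, 12, 12.04, 12.06),
                          dry_mass = 9, temperature = 353.15)
  out <- estimate_rehydration_time(cv)
  expect_equal(out$time, 120)
  expect_true(out$saturated)
  const <- rehydration_curve(c(0, 60, 120), c(12, 12, 12), dry_mass = 9,
                             temperature = 353.15)
  expect_equal(estimate_rehydration_time(const)$time, 0)
  fast <- rehydration_curve(c(0, 60, 120), c(10, 12, 14), dry_mass = 9,
                            temperature = 353.15)
  out <- estimate_rehydration_time(fast)
  expect_false(out$saturated)
  expect_equal(out$time, 120)
})

test_that("model ranking prefers the generating model", {
  cv <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.5),
                               temperatures = 353.15,
                               times = fine_grid, noise_sd = 0,
                               seed = 2)[[1]]
  fw <- fit_kinetics(cv, "weibull", M_e = 150, M_o = 11.1)
  ff <- fit_kinetics(cv, "first_order", M_e = 150, M_o = 11.1)
  fe <- fit_kinetics(cv, "exponential", M_e = 150, M_o = 11.1)
  tab <- compare_models(list(ff, fw, fe))
  expect_equal(tab$model[tab$rank == 1], "weibull")
  # Weibull and its exponential reparameterization share the fit quality
  expect_equal(tab$R2[tab$model == "weibull"],
               tab$R2[tab$model == "exponential"], tolerance = 1e-9)
  # refusing to rank fits on different data
  cv2 <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.5),
                                temperatures = 363.15, times = fine_grid,
                                noise_sd = 0, seed = 2)[[1]]
  f2 <- fit_kinetics(cv2, "weibull", M_e = 150, M_o = 11.1)
  expect_error(compare_models(list(fw, f2)), "same curve")
})

test_that("fits are invariant to time-unit rescaling", {
  cv_min <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                   temperatures = 353.15,
                                   times = seq(0, 360, 12), noise_sd = 0,
                                   seed = 3)[[1]]
  cv_h <- rehydration_curve(cv_min$time / 60, moisture = cv_min$moisture,
                            dry_mass = 10, temperature = 353.15)
  f_min <- fit_kinetics(cv_min, "weibull", M_e = 150, M_o = 11.1)
  f_h <- fit_kinetics(cv_h, "weibull", M_e = 150, M_o = 11.1)
  expect_equal(coef(f_min)[["alpha"]] / 60, coef(f_h)[["alpha"]],
               tolerance = 1e-6)
  expect_equal(coef(f_min)[["beta"]], coef(f_h)[["beta"]], tolerance = 1e-6)
})

test_that("degenerate curves are rejected with clear errors", {
  flat <- rehydration_curve(c(0, 10, 20, 30, 40), rep(12, 5), dry_mass = 9,
                            temperature = 353.15)
  expect_error(fit_kinetics(flat, "weibull"), "degenerate")
  short <- rehydration_curve(c(0, 10, 20), c(10, 11, 12), dry_mass = 9,
                             temperature = 353.15)
  expect_error(fit_kinetics(short, "weibull"), "at least")
})

test_that("single-step Arrhenius recovers E_a exactly on noiseless data", {
  cvs <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                E_a = 14, times = seq(0, 360, 12),
                                noise_sd = 0, seed = 4)
  fit <- fit_arrhenius(cvs, "weibull", M_e = 150, M_o = 11.1)
  expect_equal(coef(fit)[["E_a"]], 14, tolerance = 1e-4)
  expect_equal(coef(fit)[["alpha_ref"]], 60, tolerance = 1e-4)
  expect_equal(coef(fit)[["beta"]], 0.7, tolerance = 1e-4)
  # the implied constant at T_ref is k_ref itself
  expect_equal(predict(fit, list(time = 60, temperature = 353.15)),
               weibull_rr(60, 60, 0.7), tolerance = 1e-6)
})

test_that("two-step and single-step estimates coincide without noise", {
  cvs <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                E_a = 14, times = seq(0, 360, 12),
                                noise_sd = 0, seed = 5)
  ss <- fit_arrhenius(cvs, "weibull", M_e = 150, M_o = 11.1)
  ts <- fit_arrhenius(cvs, "weibull", M_e = 150, M_o = 11.1,
                      method = "two_step")
  expect_equal(coef(ss)[["E_a"]], coef(ts)[["E_a"]], tolerance = 1e-6)
  expect_equal(coef(ss)[["alpha_ref"]], coef(ts)[["alpha_ref"]],
               tolerance = 1e-6)
})

test_that("zero activation energy gives identical rates at all temperatures", {
  cvs <- sim_rehydration_curves("first_order", list(H = 0.02), E_a = 0,
                                times = seq(0, 360, 12), noise_sd = 0,
                                seed = 6)
  rates <- vapply(cvs, function(cv)
    coef(fit_kinetics(cv, "first_order", M_e = 150, M_o = 11.1))[["H"]], 0)
  expect_lt(diff(range(rates)) / mean(rates), 1e-6)
  fit <- fit_arrhenius(cvs, "first_order", M_e = 150, M_o = 11.1)
  expect_equal(coef(fit)[["E_a"]], 0, tolerance = 1e-4)
})

test_that("a single temperature is refused with guidance", {
  cvs <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                temperatures = 353.15, noise_sd = 0, seed = 7)
  expect_error(fit_arrhenius(cvs, "weibull"), "fit_kinetics")
})

test_that("parameter bias shrinks with the noise level", {
  noise <- c(2, 0.5, 0.05)    # %db on a 138.9 %db span
  bias <- vapply(noise, function(ns) {
    a <- vapply(1:12, function(s) {
      cv <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                   temperatures = 353.15,
                                   times = seq(0, 360, 12),
                                   noise_sd = ns, seed = 100 + s)[[1]]
      coef(fit_kinetics(cv, "weibull", M_e = 150, M_o = 11.1))[["alpha"]]
    }, 0)
    abs(mean(a) / 60 - 1)
  }, 0)
  expect_lt(bias[3], 0.02)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("standard errors are finite and positive under noise", {
  cvs <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                E_a = 14, times = seq(0, 360, 12),
                                noise_sd = 0.5, seed = 8)
  fit <- fit_arrhenius(cvs, "weibull", M_e = 150, M_o = 11.1)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.arrhenius_fit")
})
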