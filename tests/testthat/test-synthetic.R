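# Synthetic generators: seeded determinism, noiseless generative identities,
# calibrated noise, and round trips through the fitting layer.

test_that("rehydration generator is deterministic under a seed", {
  a <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.6),
                              seed = 42)
  b <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.6),
                              seed = 42)
  expect_identical(a, b)
  c <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.6),
                              seed = 43)
  expect_false(identical(a, c))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  invisible(sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.6),
                                   seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("noiseless generation reproduces the model exactly", {
  cv <- sim_rehydration_curves("weibull", list(alpha = 10, beta = 0.6),
                               temperatures = 353.15,
                               times = c(0, 5, 10, 20, 40), M_o = 0,
                               M_e = 100, noise_sd = 0, seed = 1)[[1]]
  # RR at t = alpha is 1 - exp(-1)
  expect_equal(cv$moisture[3] / 100, 1 - exp(-1), tolerance = 1e-12)
  expect_true(all(diff(cv$weight) >= 0))
})

test_that("additive noise has the configured standard deviation", {
  times <- seq(0, 398, by = 2)                  # 200 points
  noisy <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                  temperatures = 353.15, times = times,
                                  noise_sd = 0.5, seed = 7)[[1]]
  clean <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
                                  temperatures = 353.15, times = times,
                                  noise_sd = 0, seed = 7)[[1]]
  res_sd <- sd(noisy$moisture - clean$moisture)
  expect_gte(res_sd, 0.375)
  expect_lte(res_sd, 0.625)
})

test_that("invalid generator inputs are rejected", {
  expect_error(sim_rehydration_curves("weibull", list(alpha = -1, beta = 0.6)),
               "positive")
  expect_error(sim_rehydration_curves("weibull", list(alpha = 1, beta = 0.6),
                                      M_o = 150, M_e = 100), "M_e")
  expect_error(sim_rehydration_curves("weibull", list(alpha = 1, beta = 0.6),
                                      noise_sd = -1), "noise_sd")
  expect_error(sim_rehydration_curves("weibull", list(alpha = 1, beta = 0.6),
                                      times = c(5, 10)), "start at 0")
  expect_error(sim_rehydration_curves("nonsense", list(a = 1)))
})

test_that("every model round-trips through fitting at zero noise", {
  cases <- list(weibull = list(alpha = 20, beta = 0.8),
                peleg = list(K1 = 0.1, K2 = 1 / 138.9),
                exponential = list(K = 0.09, n = 0.8),
                first_order = list(H = 0.05),
                fick = list(D_eff = 2e-8, G = 6))
  for (model in names(cases)) {
    cv <- sim_rehydration_curves(model, cases[[model]],
                                 temperatures = 353.15,
                                 times = c(0, 1, 2, 4, 6, 9, 12, 16, 20, 25,
                                           30, 40, 50, 70, 90, 120),
                                 noise_sd = 0, seed = 11)[[1]]
    fit <- fit_kinetics(cv, model, M_e = 150, M_o = 11.1)
    for (nm in names(cases[[model]]))
      expect_equal(coef(fit)[[nm]], cases[[model]][[nm]], tolerance = 1e-6,
                   label = sprintf("%s:%s", model, nm))
  }
})

test_that("replicate generator honours means, sds and seed", {
  exact <- sim_replicates(c(L = 24.4, a = 18.3), sds = 0, n = 4, seed = 1)
  expect_true(all(exact[, "L"] == 24.4) && all(exact[, "a"] == 18.3))
  reps <- sim_replicates(c(x = 10), sds = 2, n = 200, seed = 2)
  expect_lt(abs(mean(reps) - 10), 3 * 2 / sqrt(200))
  expect_identical(sim_replicates(c(x = 1), 1, 5, seed = 3),
                   sim_replicates(c(x = 1), 1, 5, seed = 3))
  expect_error(sim_replicates(c(x = 1), 1, n = 1), "n >= 2")
  expect_error(sim_replicates(c(x = 1), -1, n = 3), "sds")
})

test_that("replicate colour draws reproduce the nominal colour differences", {
  col <- bean_quality_nominals$color
  ctrl <- sim_replicates(c(L = col$L[1], a = col$a[1], b = col$b[1]),
                         c(col$L_sd[1], col$a_sd[1], col$b_sd[1]),
                         n = 6, seed = 31)
  for (i in 2:4) {
    reps <- sim_replicates(c(L = col$L[i], a = col$a[i], b = col$b[i]),
                           c(col$L_sd[i], col$a_sd[i], col$b_sd[i]),
                           n = 6, seed = 31 + i)
    expect_equal(delta_e(colMeans(reps), colMeans(ctrl)),
                 col$delta_e_printed[i], tolerance = 0.5,
                 label = col$treatment[i])
  }
})

test_that("peak-table generator plants the configured log-mean shift", {
  pt <- sim_peak_table(n_per_class = 200, n_variables = 10,
                       discriminant = list(1L, 2L, 3L, 4L),
                       effect_size = 3, noise_cv = 0.3, seed = 5)
  expect_true(all(pt$areas > 0))
  sdlog <- sqrt(log(1 + 0.3^2))
  lg <- log(pt$areas[, 1])
  in_cls <- pt$class == "cooked"
  expect_equal(mean(lg[in_cls]) - mean(lg[!in_cls]), 3 * sdlog,
               tolerance = 0.1)
  expect_identical(sim_peak_table(seed = 9), sim_peak_table(seed = 9))
  expect_error(sim_peak_table(effect_size = -1), "effect_size")
  expect_error(sim_peak_table(n_per_class = 2), "replicates")
  # empty discriminant sets give a legal null table
  null_pt <- sim_peak_table(discriminant = rep(list(integer()), 4), seed = 1)
  expect_s3_class(null_pt, "peak_table")
})
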