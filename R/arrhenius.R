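# Single-step Arrhenius estimation: the Arrhenius law is substituted for the
# model's temperature-dependent time constant and all curves recorded at
# different rehydration temperatures are fitted jointly, estimating the
# reference rate constant (or diffusivity) and the activation energy in one
# least-squares problem.

# which parameter carries the temperature dependence, and its orientation:
# sign +1 -> the parameter is a rate (grows with T), -1 -> a time constant
.arr_models <- function() {
  list(
    peleg       = list(arr = "K1", ref_name = "K1_ref", sign = -1,
                       shared = "K2"),
    weibull     = list(arr = "alpha", ref_name = "alpha_ref", sign = -1,
                       shared = "beta"),
    exponential = list(arr = "K", ref_name = "K_ref", sign = +1,
                       shared = "n"),
    first_order = list(arr = "H", ref_name = "H_ref", sign = +1,
                       shared = NULL),
    fick        = list(arr = "D_eff", ref_name = "D_eff0", sign = +1,
                       shared = "G")
  )
}

.arr_value <- function(ref, E_a, temperature, T_ref, sign) {
  if (sign > 0) arrhenius_k(temperature, ref, E_a, T_ref)
  else ref * exp(-(E_a * 1000 / 8.314) * (1 / T_ref - 1 / temperature))
}

#' Global single-step Arrhenius fit across rehydration temperatures
#'
#' Substitutes the Arrhenius law for the temperature-dependent parameter of
#' a kinetic model (Peleg's `K1`, Weibull's `alpha`, the exponential and
#' first-order rate constants, or the effective diffusivity) and fits all
#' curves of one drying method, recorded at two or more temperatures,
#' in a single joint least-squares problem. The estimates are the value of
#' the constant at the reference temperature (default 353.15 K, i.e. 80
#' degrees C, the middle of a 70-100 degrees C range) and the activation
#' energy `E_a` in kJ/mol; any remaining model parameter (`K2`, `beta`,
#' `n`, `G`) is shared across temperatures.
#'
#' `method = "two_step"` instead fits each curve separately and regresses
#' the log rate constants on inverse temperature; on noiseless data the two
#' routes coincide, and the two-step result is used internally to start the
#' joint optimisation.
#'
#' @param curves list of [rehydration_curve] objects, all from the same
#'   drying method, at two or more distinct temperatures.
#' @inheritParams fit_kinetics
#' @param T_ref reference temperature in kelvin.
#' @param M_o initial moisture (%db) override applied to every curve (see
#'   [fit_kinetics]).
#' @param method `"single_step"` (joint fit) or `"two_step"`.
#' @return Object of class `"arrhenius_fit"`: coefficients (reference
#'   constant, `E_a`, shared parameter), standard errors, covariance,
#'   pooled goodness of fit, fitted values and residuals per observation,
#'   and convergence metadata.
#' @examples
#' tt <- seq(0, 300, 15)
#' cvs <- lapply(c(343.15, 353.15, 363.15, 373.15), function(Tk) {
#'   a <- 60 * exp((14 * 1000 / 8.314) * (1 / Tk - 1 / 353.15))
#'   rehydration_curve(tt, moisture = 10 + 140 * weibull_rr(tt, a, 0.7),
#'                     dry_mass = 10, temperature = Tk)
#' })
#' fit <- fit_arrhenius(cvs, "weibull")
#' coef(fit)["E_a"]
#' @export
fit_arrhenius <- function(curves, model = c("peleg", "weibull", "exponential",
                                            "first_order", "fick"),
                          T_ref = 353.15, geometry = c("slab", "sphere"),
                          L = NULL, M_e = NULL, M_o = NULL, n_starts = 5L,
                          method = c("single_step", "two_step")) {
  model <- match.arg(model)
  geometry <- match.arg(geometry)
  method <- match.arg(method)
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, TRUE, "rehydration_curve")))
  temps <- vapply(curves, `[[`, 0, "temperature")
  if (length(unique(round(temps, 6))) < 2L)
    stop("need curves at >= 2 distinct temperatures; ",
         "use fit_kinetics() for a single curve")
  methods_ <- unique(vapply(curves, `[[`, "", "method"))
  if (length(methods_) > 1L)
    stop("curves mix drying methods: ", paste(methods_, collapse = ", "))

  reg <- .kin_models()[[model]]
  arr <- .arr_models()[[model]]

  # per-curve response and context
  obs <- lapply(curves, function(cv) {
    M <- cv$moisture
    Mo_i <- if (is.null(M_o)) M[1L] else M_o
    Me_i <- if (is.null(M_e)) M[length(M)] else M_e
    if (Me_i <= Mo_i) stop("degenerate curve: no moisture gain")
    rr <- rehydration_ratio(M, Mo_i, Me_i)
    y <- if (reg$response == "MR") 1 - rr else rr
    Li <- if (is.null(L)) cv$half_thickness else L
    if (model == "fick" && is.null(Li))
      stop("the diffusion model needs L for every curve")
    list(t = cv$time, y = y, temperature = cv$temperature,
         ctx = list(dM = Me_i - Mo_i, geometry = geometry, L = Li))
  })
  y_all <- unlist(lapply(obs, `[[`, "y"))
  curve_index <- rep(seq_along(obs), vapply(obs, function(o) length(o$y), 0L))

  # two-step route (also the initialiser for the joint fit)
  two_step <- .arrhenius_two_step(curves, model, T_ref, geometry, L, M_e,
                                  M_o, n_starts, reg, arr)
  if (method == "two_step") {
    fit <- two_step
  } else {
    par_names <- c(arr$ref_name, "E_a", arr$shared)
    p0 <- two_step$coefficients[par_names]
    lower <- c(unname(reg$lower[arr$arr]), -Inf,
               if (!is.null(arr$shared)) unname(reg$lower[arr$shared]))
    upper <- c(unname(reg$upper[arr$arr]), Inf,
               if (!is.null(arr$shared)) unname(reg$upper[arr$shared]))
    predict_all <- function(p) {
      p <- stats::setNames(p, par_names)
      unlist(lapply(obs, function(o) {
        kT <- .arr_value(p[[arr$ref_name]], p[["E_a"]], o$temperature,
                         T_ref, arr$sign)
        pp <- stats::setNames(numeric(length(reg$params)), reg$params)
        pp[arr$arr] <- kT
        if (!is.null(arr$shared)) pp[arr$shared] <- p[[arr$shared]]
        reg$predict(o$t, pp, o$ctx)
      }))
    }
    resid_fn <- function(p) y_all - predict_all(p)
    best <- .lm_multistart(resid_fn, p0, lower, upper, n_starts)
    est <- stats::setNames(best$par, par_names)
    pred <- predict_all(est)
    gof <- goodness_of_fit(y_all, pred, length(est))
    ses <- .lm_se(best, par_names)
    fit <- list(coefficients = est, se = ses$se, vcov = ses$vcov,
                fitted = pred, residuals = y_all - pred, gof = gof,
                convergence = list(code = best$info, message = best$message,
                                   iterations = best$niter,
                                   deviance = best$deviance))
  }

  structure(c(fit,
              list(model = model, method = method, T_ref = T_ref,
                   geometry = geometry,
                   temperatures = temps, curve_index = curve_index,
                   observed = y_all, response = reg$response,
                   curves = curves, n_obs = length(y_all),
                   per_curve = if (method == "two_step") two_step$per_curve
                               else NULL)),
            class = "arrhenius_fit")
}

# fit each temperature separately, then log-linear regression of the rate
# on (1/T_ref - 1/T); slope = E_a / R
.arrhenius_two_step <- function(curves, model, T_ref, geometry, L, M_e,
                                M_o, n_starts, reg, arr) {
  single <- lapply(curves, fit_kinetics, model = model, M_e = M_e, M_o = M_o,
                   geometry = geometry, L = L, n_starts = n_starts)
  temps <- vapply(curves, `[[`, 0, "temperature")
  k_hat <- vapply(single, function(f) unname(coef(f)[arr$arr]), 0)
  rate <- if (arr$sign > 0) k_hat else 1 / k_hat
  x <- 1 / T_ref - 1 / temps
  lmfit <- stats::lm(log(rate) ~ x)
  sm <- stats::coef(suppressWarnings(summary(lmfit)))
  E_a <- sm["x", "Estimate"] * 8.314 / 1000
  E_a_se <- sm["x", "Std. Error"] * 8.314 / 1000
  k_ref_rate <- exp(sm["(Intercept)", "Estimate"])
  ref <- if (arr$sign > 0) k_ref_rate else 1 / k_ref_rate
  ref_se <- ref * sm["(Intercept)", "Std. Error"]   # delta method on log scale
  est <- stats::setNames(c(ref, E_a), c(arr$ref_name, "E_a"))
  se <- stats::setNames(c(ref_se, E_a_se), c(arr$ref_name, "E_a"))
  if (!is.null(arr$shared)) {
    sh <- vapply(single, function(f) unname(coef(f)[arr$shared]), 0)
    est[arr$shared] <- mean(sh)
    se[arr$shared] <- stats::sd(sh) / sqrt(length(sh))
  }
  pred <- unlist(lapply(single, fitted))
  yall <- unlist(lapply(single, `[[`, "observed"))
  gof <- goodness_of_fit(yall, pred, length(est))
  list(coefficients = est, se = se,
       vcov = matrix(NA_real_, length(est), length(est),
                     dimnames = list(names(est), names(est))),
       fitted = pred, residuals = yall - pred, gof = gof,
       per_curve = single,
       convergence = list(code = 0L, message = "two-step (per-curve + log-linear)",
                          iterations = NA_integer_, deviance = sum((yall - pred)^2)))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.arrhenius_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Arrhenius %s fit: %s model, %d curves (T = %s K), T_ref = %.2f K\n",
              gsub("_", "-", x$method), x$model, length(x$curves),
              paste(format(x$temperatures), collapse = ", "), x$T_ref))
  print(signif(x$coefficients, digits))
  cat(sprintf("pooled R2 = %.4f, RMSE = %.4g\n", x$gof$R2, x$gof$RMSE))
  invisible(x)
}

#' @export
summary.arrhenius_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(model = object$model, method = object$method,
                 coefficients = tab, gof = object$gof,
                 temperatures = object$temperatures, T_ref = object$T_ref,
                 n_obs = object$n_obs),
            class = "summary.arrhenius_fit")
}

#' @export
print.summary.arrhenius_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Arrhenius %s estimation, %s model\n",
              gsub("_", "-", x$method), x$model))
  cat(sprintf("Temperatures (K): %s; T_ref = %.2f K; %d observations\n\n",
              paste(format(x$temperatures), collapse = ", "), x$T_ref, x$n_obs))
  print(signif(x$coefficients, digits))
  cat(sprintf("\npooled R2 = %.5f   RMSE = %.4g   chi2 = %.4g\n",
              x$gof$R2, x$gof$RMSE, x$gof$chi2))
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) object$coefficients

#' @export
vcov.arrhenius_fit <- function(object, ...) object$vcov

#' @export
fitted.arrhenius_fit <- function(object, ...) object$fitted

#' @export
residuals.arrhenius_fit <- function(object, ...) object$residuals

#' Predict uptake at arbitrary time and temperature
#'
#' Evaluates the jointly fitted model at new times and a new temperature,
#' using the Arrhenius law for the temperature-dependent constant.
#'
#' @param object an `arrhenius_fit`.
#' @param newdata list or data frame with elements `time` (min) and
#'   `temperature` (K, single value).
#' @param dM moisture gain `M_e - M_o` (%db) for the Peleg model; defaults
#'   to the first fitted curve's.
#' @param L half-thickness / radius (m) for the diffusion model; defaults
#'   to the first fitted curve's.
#' @param ... unused.
#' @return Predicted response (RR, or MR for the diffusion model).
#' @export
predict.arrhenius_fit <- function(object, newdata, dM = NULL, L = NULL, ...) {
  reg <- .kin_models()[[object$model]]
  arr <- .arr_models()[[object$model]]
  p <- object$coefficients
  t <- as.numeric(newdata$time)
  Tk <- as.numeric(newdata$temperature)[1L]
  kT <- .arr_value(p[[arr$ref_name]], p[["E_a"]], Tk, object$T_ref, arr$sign)
  pp <- stats::setNames(numeric(length(reg$params)), reg$params)
  pp[arr$arr] <- kT
  if (!is.null(arr$shared)) pp[arr$shared] <- p[[arr$shared]]
  cv1 <- object$curves[[1L]]
  M <- cv1$moisture
  ctx <- list(dM = if (is.null(dM)) M[length(M)] - M[1L] else dM,
              geometry = if (is.null(object$geometry)) "slab" else object$geometry,
              L = if (is.null(L)) cv1$half_thickness else L)
  reg$predict(t, pp, ctx)
}

#' @export
plot.arrhenius_fit <- function(x, n_grid = 150, ...) {
  cols <- grDevices::hcl.colors(length(x$curves), "Zissou 1")
  tmax <- max(vapply(x$curves, function(cv) max(cv$time), 0))
  idx <- x$curve_index
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, 1.05),
                 xlab = "time (min)", ylab = x$response,
                 main = sprintf("%s model, single-step Arrhenius", x$model), ...)
  for (i in seq_along(x$curves)) {
    cv <- x$curves[[i]]
    graphics::points(cv$time, x$observed[idx == i], col = cols[i], pch = 16)
    tg <- seq(0, max(cv$time), length.out = n_grid)
    graphics::lines(tg, predict(x, list(time = tg,
                                        temperature = cv$temperature),
                                L = cv$half_thickness),
                    col = cols[i])
  }
  graphics::legend("right", legend = sprintf("%.0f K", x$temperatures),
                   col = cols, lty = 1, bty = "n")
  invisible(x)
}
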