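# Model registry -------------------------------------------------------------
# Each kinetic model is described by: free parameter names, box bounds,
# a predictor on the observed response scale (RR, or MR for the diffusion
# model), and a data-driven initialiser. dM = M_e - M_o is fixed from the
# curve, not estimated.

.kin_models <- function() {
  list(
    peleg = list(
      params = c("K1", "K2"),
      response = "RR",
      lower = c(K1 = 1e-10, K2 = 1e-10),
      upper = c(K1 = Inf, K2 = Inf),
      predict = function(t, p, ctx) peleg_rr(t, p[["K1"]], p[["K2"]], ctx$dM),
      init = function(t, rr, ctx) {
        # linearisation: t/RR = dM*K1 + dM*K2*t
        ok <- t > 0 & rr > 1e-6
        if (sum(ok) >= 2L) {
          cf <- stats::coef(stats::lm(I(t[ok] / rr[ok]) ~ t[ok]))
          K1 <- cf[[1L]] / ctx$dM; K2 <- cf[[2L]] / ctx$dM
          if (is.finite(K1) && K1 > 0 && is.finite(K2) && K2 > 0)
            return(c(K1 = K1, K2 = K2))
        }
        c(K1 = unname(t[length(t)] / 10 / ctx$dM), K2 = unname(1 / ctx$dM))
      }),
    weibull = list(
      params = c("alpha", "beta"),
      response = "RR",
      lower = c(alpha = 1e-10, beta = 1e-6),
      upper = c(alpha = Inf, beta = 2),
      predict = function(t, p, ctx) weibull_rr(t, p[["alpha"]], p[["beta"]]),
      init = function(t, rr, ctx)
        c(alpha = .time_to_fraction(t, rr, 1 - exp(-1)), beta = 1)),
    exponential = list(
      params = c("K", "n"),
      response = "RR",
      lower = c(K = 1e-12, n = 1e-6),
      upper = c(K = Inf, n = 2),
      predict = function(t, p, ctx) exponential_rr(t, p[["K"]], p[["n"]]),
      init = function(t, rr, ctx)
        c(K = 1 / .time_to_fraction(t, rr, 1 - exp(-1)), n = 1)),
    first_order = list(
      params = "H",
      response = "RR",
      lower = c(H = 1e-12),
      upper = c(H = Inf),
      predict = function(t, p, ctx) first_order_rr(t, p[["H"]]),
      init = function(t, rr, ctx)
        c(H = 1 / .time_to_fraction(t, rr, 1 - exp(-1)))),
    fick = list(
      params = c("D_eff", "G"),
      response = "MR",
      lower = c(D_eff = 1e-16, G = 1),
      upper = c(D_eff = Inf, G = 10),
      predict = function(t, p, ctx)
        fick_mr(t * 60, p[["D_eff"]], ctx$L, p[["G"]], geometry = ctx$geometry),
      init = function(t, mr, ctx) {
        # log MR tail is linear with slope -m^2 pi^2 D / L^2 (m = 1)
        ok <- t > 0 & mr > 1e-8 & mr < 0.8
        G0 <- if (ctx$geometry == "slab") 8 else 6
        if (sum(ok) >= 2L) {
          sl <- stats::coef(stats::lm(log(mr[ok]) ~ t[ok]))[[2L]]
          D <- -sl * ctx$L^2 / pi^2 / 60
          if (is.finite(D) && D > 0)
            return(c(D_eff = D, G = min(G0, 9.9)))
        }
        c(D_eff = ctx$L^2 / (60 * max(t[-1L])), G = min(G0, 9.9))
      })
  )
}

# interpolated time at which RR first reaches `frac`; fallback mid-range
.time_to_fraction <- function(t, rr, frac) {
  i <- which(rr >= frac)[1L]
  if (is.na(i) || i == 1L) return(max(t) / 2)
  t0 <- t[i - 1L]; t1 <- t[i]; r0 <- rr[i - 1L]; r1 <- rr[i]
  if (r1 <= r0) return(t1)
  t0 + (frac - r0) / (r1 - r0) * (t1 - t0)
}

# deterministic multiplicative jitters used by the multi-start strategy
.start_jitters <- function(n_params, n_starts) {
  base <- c(1, 1 / 3, 3, 1 / 10, 10, 1 / 30, 30)
  lapply(seq_len(n_starts), function(i) rep(base[((i - 1L) %% length(base)) + 1L],
                                            n_params))
}

.clip_box <- function(p, lower, upper) pmin(pmax(p, lower * 1.0000001),
                                            ifelse(is.finite(upper),
                                                   upper * 0.9999999, upper))

# shared Levenberg-Marquardt driver with deterministic multi-start
.lm_multistart <- function(resid_fn, start, lower, upper, n_starts = 5L) {
  best <- NULL
  jitters <- .start_jitters(length(start), n_starts)
  for (j in jitters) {
    p0 <- .clip_box(start * j, lower, upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance - 1e-14) best <- fit
    if (!is.null(best) && best$deviance < 1e-20) break
  }
  if (is.null(best))
    stop("nonlinear least-squares failed from every starting point")
  best
}

# asymptotic covariance at the optimum from the Jacobian-based summary
.lm_se <- function(fit, param_names) {
  out <- tryCatch({
    sm <- summary(fit)
    cf <- sm$coefficients
    list(se = stats::setNames(cf[, "Std. Error"], param_names),
         vcov = {
           v <- tryCatch(sm$sigma^2 * solve(fit$hessian / 2),
                         error = function(e) matrix(NA_real_,
                                                    length(param_names),
                                                    length(param_names)))
           dimnames(v) <- list(param_names, param_names)
           v
         })
  }, error = function(e)
    list(se = stats::setNames(rep(NA_real_, length(param_names)), param_names),
         vcov = matrix(NA_real_, length(param_names), length(param_names),
                       dimnames = list(param_names, param_names))))
  out
}

#' Fit a rehydration model to one curve
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints and a
#' deterministic multi-start strategy) of one kinetic model to a single
#' rehydration curve. The response is the rehydration ratio RR computed from
#' the curve's initial moisture and its equilibrium moisture (by default the
#' last observed moisture, following the gravimetric saturation criterion);
#' the diffusion model is fitted on the moisture ratio MR = 1 - RR instead.
#'
#' Parameter starting values are data-driven (Peleg via its linearised form,
#' Weibull/exponential/first-order from the interpolated time to 63%
#' completion, diffusivity from the slope of the log-MR tail) and jittered
#' deterministically across restarts. Standard errors come from the
#' Jacobian-based asymptotic covariance at the optimum.
#'
#' @param curve a [rehydration_curve].
#' @param model one of `"peleg"`, `"weibull"`, `"exponential"`,
#'   `"first_order"`, `"fick"`.
#' @param M_e equilibrium moisture (%db) override; default last observed.
#' @param M_o initial moisture (%db) override; default the first observed
#'   moisture. Supplying the independently measured dried-sample moisture
#'   matters for the diffusion model, whose geometric factor is identified
#'   by the intercept `MR(0) = G/8` (slab) or `G/6` (sphere): with
#'   `M_o = M(0)` the observed intercept is forced to 1.
#' @param geometry for `model = "fick"`: `"slab"` (half-thickness `L`) or
#'   `"sphere"` (`L` is the radius).
#' @param L for `model = "fick"`: half-thickness / radius in metres;
#'   defaults to the curve's `half_thickness`.
#' @param start optional named vector of starting values.
#' @param n_starts number of deterministic multi-start attempts.
#' @return An object of class `"kinetic_fit"` with components
#'   `coefficients`, `se`, `vcov`, `fitted`, `residuals`, `observed`,
#'   `response` (`"RR"` or `"MR"`), `gof` (R2, RMSE, chi2), `curve`,
#'   and convergence metadata. Supports `print`, `summary`, `coef`, `vcov`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' tt <- seq(0, 300, by = 10)
#' cv <- rehydration_curve(tt, moisture = 10 + 140 * weibull_rr(tt, 60, 0.8),
#'                         dry_mass = 10, temperature = 353.15)
#' fit <- fit_kinetics(cv, "weibull")
#' coef(fit)
#' @export
fit_kinetics <- function(curve, model = c("peleg", "weibull", "exponential",
                                          "first_order", "fick"),
                         M_e = NULL, M_o = NULL,
                         geometry = c("slab", "sphere"), L = NULL,
                         start = NULL, n_starts = 5L) {
  stopifnot(inherits(curve, "rehydration_curve"))
  model <- match.arg(model)
  geometry <- match.arg(geometry)
  reg <- .kin_models()[[model]]

  M <- curve$moisture
  if (is.null(M_o)) M_o <- M[1L]
  if (is.null(M_e)) M_e <- M[length(M)]
  if (M_e <= M_o)
    stop("degenerate curve: equilibrium moisture does not exceed the initial")
  if (stats::var(M) == 0) stop("degenerate curve: constant moisture")
  n_par <- length(reg$params)
  if (length(curve$time) < n_par + 2L)
    stop(sprintf("need at least %d observations to fit %d parameters",
                 n_par + 2L, n_par))

  rr <- rehydration_ratio(M, M_o, M_e)
  ctx <- list(dM = M_e - M_o, geometry = geometry,
              L = if (is.null(L)) curve$half_thickness else L)
  if (model == "fick" && is.null(ctx$L))
    stop("the diffusion model needs the half-thickness / radius L (in m)")
  y <- if (reg$response == "MR") 1 - rr else rr
  t <- curve$time

  p0 <- if (is.null(start)) reg$init(t, y, ctx) else start[reg$params]
  p0 <- .clip_box(p0, reg$lower, reg$upper)
  resid_fn <- function(p) y - reg$predict(t, stats::setNames(p, reg$params), ctx)
  best <- .lm_multistart(resid_fn, p0, reg$lower, reg$upper, n_starts)

  est <- stats::setNames(best$par, reg$params)
  pred <- reg$predict(t, est, ctx)
  gof <- goodness_of_fit(y, pred, n_par)
  ses <- .lm_se(best, reg$params)

  structure(list(model = model, coefficients = est, se = ses$se,
                 vcov = ses$vcov, fitted = pred, residuals = y - pred,
                 observed = y, response = reg$response, time = t,
                 M_o = M_o, M_e = M_e, context = ctx, curve = curve,
                 gof = gof, n_obs = length(y), n_params = n_par,
                 convergence = list(code = best$info,
                                    message = best$message,
                                    iterations = best$niter,
                                    deviance = best$deviance)),
            class = "kinetic_fit")
}

#' Goodness-of-fit statistics
#'
#' Concordance measures between observed and model-predicted values:
#' `R2 = 1 - SSE/SST`, `RMSE = sqrt(SSE/N)` and the reduced residual
#' chi-square `chi2 = SSE/(N - n_params)`.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param n_params number of fitted parameters, `< length(observed)`.
#' @return Named list with `R2`, `RMSE`, `chi2`.
#' @examples
#' goodness_of_fit(c(0, 1), c(0.5, 0.5), 1)
#' @export
goodness_of_fit <- function(observed, predicted, n_params) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  n <- length(observed)
  if (n <= n_params) stop("more parameters than residual degrees of freedom")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero total variance: R2 is undefined")
  sse <- sum((observed - predicted)^2)
  list(R2 = 1 - sse / sst, RMSE = sqrt(sse / n), chi2 = sse / (n - n_params))
}

# Wald-Wolfowitz runs test on residual signs (normal approximation);
# a small |z| indicates randomly distributed residuals
.runs_test <- function(r) {
  s <- r > 0
  s <- s[r != 0]
  n1 <- sum(s); n2 <- sum(!s); n <- n1 + n2
  if (n1 == 0L || n2 == 0L || n < 3L)
    return(list(z = NA_real_, p = NA_real_))
  runs <- 1L + sum(diff(as.integer(s)) != 0L)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Rank competing kinetic fits on the same data
#'
#' Orders a set of [fit_kinetics] results fitted to the same observations by
#' goodness of fit (highest R2, then lowest RMSE, then lowest chi-square)
#' and reports a Wald-Wolfowitz runs test on the residual signs as a summary
#' of how randomly the errors scatter about each fitted curve.
#'
#' @param fits list of `kinetic_fit` objects on identical observations.
#' @return Data frame with one row per fit, ordered best first; columns
#'   `model`, `R2`, `RMSE`, `chi2`, `runs_z`, `runs_p`, `rank`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L, all(vapply(fits, inherits, TRUE, "kinetic_fit")))
  base_t <- fits[[1L]]$time
  base_m <- fits[[1L]]$curve$moisture
  for (f in fits[-1L]) {
    if (length(f$time) != length(base_t) ||
        any(abs(f$time - base_t) > 1e-9) ||
        any(abs(f$curve$moisture - base_m) > 1e-9))
      stop("fits were not computed on the same curve")
  }
  rows <- lapply(fits, function(f) {
    rt <- .runs_test(f$residuals)
    data.frame(model = f$model, R2 = f$gof$R2, RMSE = f$gof$RMSE,
               chi2 = f$gof$chi2, runs_z = rt$z, runs_p = rt$p)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$R2, tab$RMSE, tab$chi2)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

# ---- methods ---------------------------------------------------------------

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic fit: %s model on %s (%d obs)\n",
              x$model, x$response, x$n_obs))
  print(signif(x$coefficients, digits))
  cat(sprintf("R2 = %.4f, RMSE = %.4g, chi2 = %.4g\n",
              x$gof$R2, x$gof$RMSE, x$gof$chi2))
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(model = object$model, coefficients = tab, gof = object$gof,
                 convergence = object$convergence, n_obs = object$n_obs),
            class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Kinetic model: %s (%d observations)\n\n", x$model, x$n_obs))
  print(signif(x$coefficients, digits))
  cat(sprintf("\nR2 = %.5f   RMSE = %.4g   chi2 = %.4g\n",
              x$gof$R2, x$gof$RMSE, x$gof$chi2))
  cat(sprintf("Converged in %d iterations (%s)\n",
              x$convergence$iterations, x$convergence$message))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
vcov.kinetic_fit <- function(object, ...) object$vcov

#' @export
fitted.kinetic_fit <- function(object, ...) object$fitted

#' @export
residuals.kinetic_fit <- function(object, ...) object$residuals

#' Predict from a fitted kinetic model
#'
#' @param object a `kinetic_fit`.
#' @param newdata numeric vector of times (minutes); defaults to the times
#'   of the fitted curve.
#' @param type response scale: the model's own (`"RR"` for the empirical
#'   models, `"MR"` for the diffusion model) or the other one.
#' @param ... unused.
#' @return Predicted ratio at each time.
#' @export
predict.kinetic_fit <- function(object, newdata = NULL,
                                type = c("response", "RR", "MR"), ...) {
  type <- match.arg(type)
  t <- if (is.null(newdata)) object$time else as.numeric(newdata)
  reg <- .kin_models()[[object$model]]
  y <- reg$predict(t, object$coefficients, object$context)
  if (type == "response" || type == object$response) return(y)
  1 - y
}

#' @export
plot.kinetic_fit <- function(x, n_grid = 200, ...) {
  tg <- seq(0, max(x$time), length.out = n_grid)
  yg <- predict(x, tg)
  graphics::plot(x$time, x$observed, xlab = "time (min)",
                 ylab = x$response,
                 main = sprintf("%s model fit", x$model), ...)
  graphics::lines(tg, yg, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate response curves from a fitted kinetic model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around
#' the fitted curve; useful for parametric-bootstrap checks.
#'
#' @param object a `kinetic_fit`.
#' @param nsim number of simulated curves.
#' @param seed optional integer seed (global RNG state is restored).
#' @param ... unused.
#' @return Matrix with `nsim` columns, one simulated response per column.
#' @export
simulate.kinetic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  sigma <- sqrt(object$convergence$deviance /
                  max(1L, object$n_obs - object$n_params))
  matrix(object$fitted + stats::rnorm(object$n_obs * nsim, 0, sigma),
         ncol = nsim)
}
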