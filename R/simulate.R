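# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes -- saturating monotone uptake curves with Arrhenius
# temperature dependence and additive balance-reading noise; replicate
# quality measurements as Gaussian draws around group means; aligned peak
# tables as log-normal areas with class-specific log-mean shifts on planted
# discriminant variables -- so that every downstream stage can be exercised
# and calibrated without laboratory data.

# run `expr` under `seed`, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Simulate rehydration curves across temperatures
#'
#' Generates one uptake curve per rehydration temperature from a chosen
#' kinetic model whose temperature-dependent constant follows the Arrhenius
#' law, then adds additive Gaussian noise on the dry-basis moisture,
#' truncated so that weights never fall below the dry mass -- the simplest
#' model consistent with a balance-reading error. With `noise_sd = 0` the
#' curves reproduce the generating model exactly (and are monotone
#' non-decreasing), which is what makes exact-recovery tests of the fitting
#' layer possible.
#'
#' Defaults mirror the bench conditions of a rehydration study on
#' pre-cooked dried beans: 70-100 degrees C water baths, about 10 g of
#' dried sample at roughly 11 %db initial moisture saturating near
#' 150 %db, weighed at regular intervals; the default `noise_sd` of
#' 0.5 %db corresponds to a 0.05 g balance resolution on a 10 g dry mass.
#'
#' @param model kinetic model name (see [fit_kinetics]).
#' @param params named list of the model's true parameters **at `T_ref`**
#'   (e.g. `list(alpha = 60, beta = 0.7)`; for `"fick"`,
#'   `list(D_eff = 5e-10, G = 6)`).
#' @param E_a activation energy (kJ/mol) of the temperature-dependent
#'   constant; 0 makes all temperatures identical.
#' @param T_ref reference temperature (K).
#' @param temperatures rehydration temperatures (K), one curve each.
#' @param times sampling grid in minutes, strictly increasing from 0.
#' @param M_o,M_e initial and equilibrium moisture (%db), `M_e > M_o`.
#' @param noise_sd standard deviation of the additive moisture noise
#'   (%db), `>= 0`.
#' @param dry_mass dry solids mass (g) used to reconstruct weights.
#' @param method drying-method label stamped on the curves.
#' @param L half-thickness / radius (m), needed for `"fick"`.
#' @param geometry `"slab"` or `"sphere"`, for `"fick"`.
#' @param seed integer seed; one global seed drives all curves, so equal
#'   seeds give byte-identical output.
#' @return List of [rehydration_curve] objects, one per temperature.
#' @examples
#' cvs <- sim_rehydration_curves("weibull", list(alpha = 60, beta = 0.7),
#'                               E_a = 14, noise_sd = 0, seed = 1)
#' length(cvs)
#' @export
sim_rehydration_curves <- function(model = c("peleg", "weibull", "exponential",
                                             "first_order", "fick"),
                                   params,
                                   E_a = 14, T_ref = 353.15,
                                   temperatures = c(343.15, 353.15,
                                                    363.15, 373.15),
                                   times = seq(0, 360, by = 12),
                                   M_o = 11.1, M_e = 150,
                                   noise_sd = 0.5, dry_mass = 10,
                                   method = "other", L = 5e-3,
                                   geometry = c("slab", "sphere"),
                                   seed = NULL) {
  model <- match.arg(model)
  geometry <- match.arg(geometry)
  reg <- .kin_models()[[model]]
  arr <- .arr_models()[[model]]
  if (!all(reg$params %in% names(params)))
    stop("params must name: ", paste(reg$params, collapse = ", "))
  p_ref <- vapply(reg$params, function(nm) as.numeric(params[[nm]]), 0)
  if (any(p_ref <= 0)) stop("non-physical parameters: all must be positive")
  if (any(temperatures <= 273.15)) stop("temperatures must be in kelvin, > 273.15")
  if (times[1L] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (M_e <= M_o) stop("M_e must exceed M_o")

  ctx <- list(dM = M_e - M_o, geometry = geometry, L = L)
  .with_seed(seed, {
    lapply(seq_along(temperatures), function(i) {
      Tk <- temperatures[i]
      pT <- p_ref
      pT[arr$arr] <- .arr_value(p_ref[[arr$arr]], E_a, Tk, T_ref, arr$sign)
      y <- reg$predict(times, pT, ctx)
      rr <- if (reg$response == "MR") 1 - y else y
      M <- M_o + ctx$dM * rr
      if (noise_sd > 0) {
        M <- M + stats::rnorm(length(M), 0, noise_sd)
        M <- pmax(M, 0)                      # weights never below dry mass
      }
      rehydration_curve(times, moisture = M, dry_mass = dry_mass,
                        temperature = Tk,
                        sample_id = sprintf("%s_T%03.0fK", method, Tk),
                        method = method, half_thickness = L)
    })
  })
}

#' Simulate an aligned volatile peak table
#'
#' Draws log-normal peak areas (GC-MS areas are positive and right-skewed,
#' so noise is multiplicative) with a fixed log-mean per variable and a
#' class-specific upward log-mean shift on each class's planted
#' discriminant variables. `effect_size` is expressed in units of the
#' log-scale noise standard deviation, so `effect_size = 3` plants a
#' 3-sigma separation.
#'
#' @param n_classes number of treatment classes (default 4: a cooked
#'   control plus three drying methods).
#' @param n_per_class replicates per class, `>= 3` (6 mirrors typical
#'   headspace repetition counts).
#' @param n_variables number of aligned volatile variables.
#' @param discriminant list of integer vectors, one per class: indices of
#'   the variables planted as discriminant for that class. `NULL` plants
#'   two distinct variables per class; use empty vectors for a null table.
#' @param effect_size log-mean shift in units of the log-noise sd, `>= 0`.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param classes class labels.
#' @param seed integer seed (single global seed, reproducible).
#' @return A [peak_table] with evenly spaced synthetic retention times and
#'   attributes `discriminant` (the planted index sets) recorded for
#'   calibration studies.
#' @examples
#' pt <- sim_peak_table(effect_size = 3, seed = 42)
#' pt
#' @export
sim_peak_table <- function(n_classes = 4L, n_per_class = 6L,
                           n_variables = 30L, discriminant = NULL,
                           effect_size = 3, noise_cv = 0.3,
                           classes = c("cooked", "AD", "VD", "FD"),
                           seed = NULL) {
  if (n_per_class < 3L) stop("need at least 3 replicates per class")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_cv <= 0) stop("noise_cv must be positive")
  classes <- if (length(classes) >= n_classes) classes[seq_len(n_classes)]
             else sprintf("class%d", seq_len(n_classes))
  if (is.null(discriminant))
    discriminant <- lapply(seq_len(n_classes),
                           function(k) ((k - 1L) * 2L + 1L):((k - 1L) * 2L + 2L))
  stopifnot(length(discriminant) == n_classes)
  if (any(unlist(discriminant) > n_variables))
    stop("discriminant indices outside 1..n_variables")

  sdlog <- sqrt(log(1 + noise_cv^2))
  mu <- seq(log(1e4), log(1e6), length.out = n_variables)  # baseline log-means
  n <- n_classes * n_per_class
  cls <- rep(classes, each = n_per_class)
  shift <- matrix(0, n, n_variables)
  for (k in seq_len(n_classes)) {
    idx <- discriminant[[k]]
    if (length(idx))
      shift[cls == classes[k], idx] <- effect_size * sdlog
  }
  areas <- .with_seed(seed, {
    exp(matrix(mu, n, n_variables, byrow = TRUE) + shift +
          matrix(stats::rnorm(n * n_variables, 0, sdlog), n, n_variables))
  })
  rownames(areas) <- sprintf("%s_%02d", cls, sequence(rep(n_per_class, n_classes)))
  colnames(areas) <- sprintf("v%03d", seq_len(n_variables))
  pt <- peak_table(areas, class = cls,
                   rt = seq(5, 40, length.out = n_variables))
  attr(pt, "discriminant") <- stats::setNames(discriminant, classes)
  pt
}

#' Simulate replicate quality measurements
#'
#' Gaussian replicates around nominal group means -- the generative
#' counterpart of a "mean +/- standard deviation" quality table row, used
#' to exercise colour, enthalpy and hardness comparisons.
#'
#' @param means named numeric vector of nominal means (one column each).
#' @param sds standard deviations, recycled to `length(means)`, `>= 0`.
#' @param n number of replicates, `>= 2` (downstream tests need variance).
#' @param seed integer seed.
#' @return Numeric matrix `n x length(means)` with the names of `means`
#'   as column names.
#' @examples
#' sim_replicates(c(L = 24.4, a = 18.3, b = 8.7), sds = 0.5, n = 6, seed = 7)
#' @export
sim_replicates <- function(means, sds, n, seed = NULL) {
  if (n < 2L) stop("need n >= 2 replicates")
  sds <- rep_len(sds, length(means))
  if (any(sds < 0)) stop("sds must be >= 0")
  out <- .with_seed(seed, {
    vapply(seq_along(means),
           function(j) stats::rnorm(n, means[j], sds[j]),
           numeric(n))
  })
  colnames(out) <- names(means)
  out
}
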