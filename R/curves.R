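#' Rehydration curve
#'
#' Container for one time course of water uptake by a dried sample held at a
#' fixed rehydration temperature: the weights (and/or dry-basis moistures)
#' recorded at increasing times until saturation.
#'
#' Moisture is carried on a dry basis (%db, g water per 100 g dry solids).
#' When only weights are supplied the moisture track is computed from the dry
#' mass; when only moistures are supplied and a dry mass is given, weights are
#' reconstructed as `dry_mass * (1 + M/100)`.
#'
#' @param time numeric vector of sampling times in minutes, strictly
#'   increasing and starting at 0.
#' @param weight numeric vector of sample weights (g), same length as `time`.
#' @param moisture numeric vector of dry-basis moisture contents (%db).
#'   At least one of `weight`, `moisture` must be given.
#' @param dry_mass dry solids mass (g); required when only weights are given.
#' @param temperature rehydration temperature in kelvin (> 273.15 K).
#' @param sample_id character label for the sample.
#' @param method drying method label, conventionally one of `"AD"`, `"VD"`,
#'   `"FD"` (air, vacuum, freeze drying) or `"other"`.
#' @param half_thickness half-thickness (slab) or radius (sphere) of the
#'   piece in metres; needed only for diffusion-model fitting.
#'
#' @return An object of class `"rehydration_curve"`: a list with elements
#'   `time`, `weight`, `moisture`, `dry_mass`, `temperature`, `sample_id`,
#'   `method`, `half_thickness`.
#' @examples
#' cv <- rehydration_curve(time = c(0, 30, 60, 120),
#'                         weight = c(10, 14, 16, 17),
#'                         dry_mass = 9, temperature = 353.15)
#' cv$moisture
#' @export
rehydration_curve <- function(time, weight = NULL, moisture = NULL,
                              dry_mass = NULL, temperature,
                              sample_id = "sample", method = "other",
                              half_thickness = NULL) {
  time <- as.numeric(time)
  if (length(time) < 2L)
    stop("a rehydration curve needs at least two time points")
  if (time[1L] != 0)
    stop("time grid must start at 0 min")
  if (any(diff(time) <= 0))
    stop("time grid must be strictly increasing")
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      temperature <= 273.15)
    stop("temperature must be a single value in kelvin above 273.15")
  if (is.null(weight) && is.null(moisture))
    stop("supply weights, moistures, or both")
  if (!is.null(weight)) {
    weight <- as.numeric(weight)
    if (length(weight) != length(time))
      stop("weight and time lengths differ")
    if (is.null(dry_mass))
      stop("dry_mass is required to convert weights to dry-basis moisture")
  }
  if (!is.null(dry_mass) && (!is.numeric(dry_mass) || dry_mass <= 0))
    stop("dry_mass must be a positive mass in g")
  if (!is.null(weight) && any(weight < dry_mass - 1e-9))
    stop("weights below the dry mass are not physical")
  if (is.null(moisture)) {
    moisture <- moisture_db(weight, dry_mass)
  } else {
    moisture <- as.numeric(moisture)
    if (length(moisture) != length(time))
      stop("moisture and time lengths differ")
    if (any(moisture < 0))
      stop("dry-basis moisture cannot be negative")
    if (is.null(weight) && !is.null(dry_mass))
      weight <- dry_mass * (1 + moisture / 100)
  }
  structure(list(time = time, weight = weight, moisture = moisture,
                 dry_mass = dry_mass, temperature = temperature,
                 sample_id = as.character(sample_id),
                 method = as.character(method),
                 half_thickness = half_thickness),
            class = "rehydration_curve")
}

#' @export
print.rehydration_curve <- function(x, ...) {
  cat(sprintf("Rehydration curve '%s' (%s), %.2f K\n",
              x$sample_id, x$method, x$temperature))
  cat(sprintf("  %d observations over %.1f min; moisture %.1f -> %.1f %%db\n",
              length(x$time), max(x$time),
              x$moisture[1L], x$moisture[length(x$moisture)]))
  invisible(x)
}

#' Dry-basis moisture from weight
#'
#' `moisture_db()` converts a sample weight and its dry solids mass into a
#' dry-basis moisture content, `100 * (weight - dry_mass) / dry_mass` (%db).
#' `wb_to_db()` and `db_to_wb()` convert between wet-basis and dry-basis
#' percentages.
#'
#' @param weight sample weight (g), `>= dry_mass`.
#' @param dry_mass dry solids mass (g), positive.
#' @return Moisture content in %db (resp. %wb for `db_to_wb`).
#' @examples
#' moisture_db(23, 9)   # 155.6 %db
#' wb_to_db(10)         # 11.11 %db
#' @export
moisture_db <- function(weight, dry_mass) {
  if (any(dry_mass <= 0)) stop("dry_mass must be positive")
  if (any(weight < dry_mass - 1e-9))
    stop("weight below dry mass: not a physical moisture content")
  100 * (weight - dry_mass) / dry_mass
}

#' @rdname moisture_db
#' @param wb wet-basis moisture (% of total weight), `< 100`.
#' @export
wb_to_db <- function(wb) {
  if (any(wb < 0) || any(wb >= 100)) stop("wet-basis moisture must be in [0, 100)")
  100 * wb / (100 - wb)
}

#' @rdname moisture_db
#' @param db dry-basis moisture (%db), `>= 0`.
#' @export
db_to_wb <- function(db) {
  if (any(db < 0)) stop("dry-basis moisture must be non-negative")
  100 * db / (100 + db)
}

#' Rehydration ratio and moisture ratio
#'
#' Normalised progress of water uptake between the initial moisture `M_o` of
#' the dried sample and its equilibrium (saturation) moisture `M_e`:
#' `RR = (M_t - M_o) / (M_e - M_o)`, and `MR = 1 - RR`. `RR` runs from 0 at
#' the start to 1 at saturation; `MR` is the fraction of the total uptake
#' still to happen, the quantity described by the diffusion series solution.
#'
#' A literal transcription of the ratio sometimes seen in print,
#' `(M_t - M_e) / (M_e - M_o)`, equals `RR - 1` and so starts at -1 rather
#' than 0; it is available behind `as_printed = TRUE` for audit, but every
#' model in this package uses the `RR(0) = 0` orientation.
#'
#' @param M_t moisture at time t (%db), vectorised.
#' @param M_o initial moisture of the dried sample (%db).
#' @param M_e equilibrium moisture (%db), `> M_o`.
#' @param as_printed if `TRUE`, return `(M_t - M_e)/(M_e - M_o)` instead.
#' @return `rehydration_ratio`: RR (dimensionless); `moisture_ratio`: 1 - RR.
#' @examples
#' rehydration_ratio(80, M_o = 10, M_e = 150)
#' moisture_ratio(80, M_o = 10, M_e = 150)
#' @export
rehydration_ratio <- function(M_t, M_o, M_e, as_printed = FALSE) {
  if (M_e <= M_o)
    stop("degenerate moisture range: M_e must exceed M_o")
  if (isTRUE(as_printed)) (M_t - M_e) / (M_e - M_o)
  else (M_t - M_o) / (M_e - M_o)
}

#' @rdname rehydration_ratio
#' @export
moisture_ratio <- function(M_t, M_o, M_e) {
  1 - rehydration_ratio(M_t, M_o, M_e)
}

#' Rehydration yield and relative rehydration moisture
#'
#' `rehydration_yield()` is the ratio of the saturated weight to the initial
#' (dry) weight, `Y = W_e / W_0`; a rehydrated product has `Y >= 1`.
#' `relative_rehydration_moisture()` compares the equilibrium moisture of the
#' rehydrated sample with the moisture of the freshly cooked reference,
#' `RRM = M_e / M_c`; values near 1 indicate the drying step did not reduce
#' the water-holding capacity.
#'
#' @param W_e weight at saturation (g).
#' @param W_0 initial weight before rehydration (g), positive.
#' @return Dimensionless ratio.
#' @examples
#' rehydration_yield(25.6, 10)            # 2.56
#' relative_rehydration_moisture(150, 156)
#' @export
rehydration_yield <- function(W_e, W_0) {
  if (any(W_0 <= 0)) stop("initial weight must be positive")
  W_e / W_0
}

#' @rdname rehydration_yield
#' @param M_e equilibrium moisture of the rehydrated sample (%db).
#' @param M_c moisture of the freshly cooked reference (%db), positive.
#' @export
relative_rehydration_moisture <- function(M_e, M_c) {
  if (any(M_c <= 0)) stop("cooked reference moisture must be positive")
  M_e / M_c
}

#' Saturation time of a rehydration curve
#'
#' Applies the gravimetric saturation rule used when recording the curves:
#' the sample is saturated from the first time point after which every
#' consecutive weight difference stays within `weight_tol` (default 0.05 g).
#' If the rule is never met the last observed time is returned with
#' `saturated = FALSE`.
#'
#' @param curve a [rehydration_curve].
#' @param weight_tol largest weight change (g) between consecutive readings
#'   still considered insignificant.
#' @return List with `time` (minutes) and logical `saturated`.
#' @examples
#' cv <- rehydration_curve(c(0, 60, 120, 180), c(10, 12, 12.04, 12.06),
#'                         dry_mass = 9, temperature = 353.15)
#' estimate_rehydration_time(cv)$time  # 120
#' @export
estimate_rehydration_time <- function(curve, weight_tol = 0.05) {
  stopifnot(inherits(curve, "rehydration_curve"))
  w <- curve$weight
  if (is.null(w))
    stop("curve carries no weights; saturation is a gravimetric criterion")
  dw <- abs(diff(w))
  small <- dw <= weight_tol
  last_big <- max(c(0L, which(!small)))
  if (last_big == length(small))
    return(list(time = curve$time[length(curve$time)], saturated = FALSE))
  if (last_big == 0L)                       # never changed significantly
    return(list(time = 0, saturated = TRUE))
  # saturation is reached at the end of the first insignificant interval
  # that follows the last significant one
  list(time = curve$time[last_big + 2L], saturated = TRUE)
}
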