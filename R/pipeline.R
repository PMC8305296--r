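#' Pipeline configuration
#'
#' Assembles and validates the settings for [run_pipeline]. All temperature
#' inputs are in degrees Celsius at this boundary and converted to kelvin
#' internally; thicknesses are supplied in mm and converted to metres.
#' When `rehydration_csv` / `peak_csv` are `NULL` the pipeline simulates
#' its inputs from the nominal bean values ([bean_nominals]) under `seed`,
#' so a full run is reproducible end to end without external data.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer master seed; every stochastic stage derives its
#'   sub-seed deterministically from it.
#' @param rehydration_csv optional tidy rehydration CSV
#'   (see [read_rehydration_csv]).
#' @param peak_csv optional aligned peak-table CSV (see [read_peak_csv]).
#' @param models kinetic models to fit.
#' @param temperatures_C rehydration temperatures for simulated curves.
#' @param T_ref_C Arrhenius reference temperature (degrees C).
#' @param weight_tol saturation criterion (g) for rehydration times.
#' @param vid_threshold absolute VID above which a volatile is discriminant.
#' @param n_lv number of PLS-DA latent variables.
#' @param M_c moisture of the freshly cooked reference (%db), used for the
#'   relative rehydration moisture.
#' @param beta Weibull shape factor of the simulated curves.
#' @param noise_sd additive moisture noise (%db) of the simulated curves.
#' @param half_thickness_mm bean half-thickness for the diffusion model.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            rehydration_csv = NULL, peak_csv = NULL,
                            models = c("peleg", "weibull", "exponential",
                                       "first_order", "fick"),
                            temperatures_C = c(70, 80, 90, 100),
                            T_ref_C = 80, weight_tol = 0.05,
                            vid_threshold = 0.8, n_lv = 3L,
                            M_c = 160, beta = 0.65, noise_sd = 0.5,
                            half_thickness_mm = 5) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(weight_tol > 0, vid_threshold > 0, n_lv >= 1L, M_c > 0,
            half_thickness_mm > 0, noise_sd >= 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 rehydration_csv = rehydration_csv, peak_csv = peak_csv,
                 models = models, temperatures_C = temperatures_C,
                 T_ref = T_ref_C + 273.15, weight_tol = weight_tol,
                 vid_threshold = vid_threshold, n_lv = as.integer(n_lv),
                 M_c = M_c, beta = beta, noise_sd = noise_sd,
                 L = half_thickness_mm / 1000),
            class = "pipeline_config")
}

# dense-early grid matching how uptake curves are actually sampled
.pipeline_time_grid <- function() {
  c(0, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12, 15, 20, 25, 30, 40, 50, 60)
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis end to end and writes a report bundle to
#' `config$out_dir`:
#'
#' 1. **kinetics** -- per-curve fits of the configured models and the
#'    single-step Arrhenius fit per drying method
#'    (`table1_kinetics.csv`), plus saturation-rule rehydration times;
#' 2. **quality** -- colour difference (both from group means and averaged
#'    over replicate pairs), hardness, degree of starch retrogradation,
#'    yield and relative rehydration moisture with ANOVA letters
#'    (`table2_quality.csv`);
#' 3. **volatiles** -- total-peak-area comparison, NIPALS PLS-DA, VID
#'    coefficients and the discriminant-compound table with retention
#'    indices (`table3_discriminants.csv`);
#' 4. `summary.json` (machine-readable key results) and `pipeline.log`
#'    (every stage, parameter and warning; no timestamps, so identical
#'    configurations give byte-identical bundles).
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the fitted objects and tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # fail on missing inputs before any computation
  for (p in c(config$rehydration_csv, config$peak_csv))
    if (!is.null(p) && !file.exists(p))
      stop("configured input does not exist: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  run_stage <- function(name, expr) {
    note("stage %s: start", name)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        note("stage %s: warning: %s", name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    note("stage %s: done", name)
    res
  }
  note("pipeline seed %d", config$seed)
  note("models: %s", paste(config$models, collapse = ", "))
  note("T_ref %.2f K; weight_tol %.3g g; VID threshold %.2f; %d LVs",
       config$T_ref, config$weight_tol, config$vid_threshold, config$n_lv)

  nom <- bean_kinetic_nominals
  qn <- bean_quality_nominals

  ## stage 1: rehydration curves -------------------------------------------
  curves_by_method <- run_stage("load_curves", {
    if (!is.null(config$rehydration_csv)) {
      cvs <- read_rehydration_csv(config$rehydration_csv)
      split(cvs, vapply(cvs, `[[`, "", "method"))
    } else {
      Me <- stats::setNames(qn$rehydration$RRM * config$M_c,
                            qn$rehydration$treatment)
      out <- list()
      for (i in seq_len(nrow(nom))) {
        m <- nom$method[i]
        out[[m]] <- sim_rehydration_curves(
          "weibull",
          params = list(alpha = nom$alpha_ref[i], beta = config$beta),
          E_a = nom$E_a_weibull[i], T_ref = config$T_ref,
          temperatures = config$temperatures_C + 273.15,
          times = .pipeline_time_grid(),
          M_o = 11.1, M_e = unname(Me[m]),
          noise_sd = config$noise_sd, method = m, L = config$L,
          seed = config$seed + i)
        note("simulated %d curves for %s (alpha_ref %.3g min, E_a %.3g kJ/mol)",
             length(out[[m]]), m, nom$alpha_ref[i], nom$E_a_weibull[i])
      }
      out
    }
  })

  ## stage 2: kinetic fits --------------------------------------------------
  kinetics <- run_stage("kinetics", {
    rows <- list(); arr_fits <- list()
    for (m in names(curves_by_method)) {
      cvs <- curves_by_method[[m]]
      for (mod in config$models) {
        af <- fit_arrhenius(cvs, mod, T_ref = config$T_ref, L = config$L)
        arr_fits[[paste(m, mod, sep = ".")]] <- af
        cf <- coef(af); se <- af$se
        ref_name <- .arr_models()[[mod]]$ref_name
        shared <- .arr_models()[[mod]]$shared
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, model = mod,
          E_a = unname(cf["E_a"]), E_a_se = unname(se["E_a"]),
          k_ref_name = ref_name, k_ref = unname(cf[ref_name]),
          k_ref_se = unname(se[ref_name]),
          shared_name = if (is.null(shared)) NA_character_ else shared,
          shared = if (is.null(shared)) NA_real_ else unname(cf[shared]),
          shared_se = if (is.null(shared)) NA_real_ else unname(se[shared]),
          R2 = af$gof$R2, RMSE = af$gof$RMSE, chi2 = af$gof$chi2)
      }
    }
    rehyd_time <- lapply(curves_by_method, function(cvs)
      vapply(cvs, function(cv)
        estimate_rehydration_time(cv, config$weight_tol)$time, 0))
    list(table = do.call(rbind, rows), fits = arr_fits,
         rehydration_time_min = rehyd_time)
  })

  ## stage 3: quality --------------------------------------------------------
  quality <- run_stage("quality", {
    col <- qn$color
    color_reps <- lapply(seq_len(nrow(col)), function(i)
      sim_replicates(c(L = col$L[i], a = col$a[i], b = col$b[i]),
                     sds = c(col$L_sd[i], col$a_sd[i], col$b_sd[i]),
                     n = 6, seed = config$seed + 100L + i))
    names(color_reps) <- col$treatment
    ctrl <- color_reps$control
    de_means <- vapply(setdiff(col$treatment, "control"), function(tr)
      delta_e(colMeans(color_reps[[tr]]), colMeans(ctrl)), 0)
    de_reps <- vapply(setdiff(col$treatment, "control"), function(tr)
      mean(delta_e(color_reps[[tr]], ctrl)), 0)

    hr <- qn$hardness
    hardness <- sim_replicates(stats::setNames(hr$hardness_N, hr$treatment),
                               hr$hardness_sd, n = 20,
                               seed = config$seed + 120L)
    hard_cmp <- group_compare(as.vector(hardness),
                              rep(hr$treatment, each = 20))

    th <- qn$thermal[qn$thermal$treatment != "control", ]
    dHG <- sim_replicates(c(dHG = 3.0), 0.1, n = 6,
                          seed = config$seed + 130L)
    dHR <- sim_replicates(stats::setNames(th$DR_pct / 100 * 3.0, th$treatment),
                          th$DR_sd / 100 * 3.0, n = 6,
                          seed = config$seed + 131L)
    DR <- degree_retrogradation(dHR, mean(dHG))
    dr_cmp <- group_compare(as.vector(DR), rep(th$treatment, each = 6))

    rh <- qn$rehydration
    Yreps <- sim_replicates(stats::setNames(rh$Y, rh$treatment), rh$Y_sd,
                            n = 6, seed = config$seed + 140L)
    RRMreps <- sim_replicates(stats::setNames(rh$RRM, rh$treatment),
                              rh$RRM_sd, n = 6, seed = config$seed + 141L)
    y_cmp <- group_compare(as.vector(Yreps), rep(rh$treatment, each = 6))
    rrm_cmp <- group_compare(as.vector(RRMreps), rep(rh$treatment, each = 6))
    note("delta E* (of means): %s",
         paste(sprintf("%s %.2f", names(de_means), de_means), collapse = ", "))

    list(delta_e_of_means = de_means, delta_e_mean_of_reps = de_reps,
         hardness = hard_cmp, DR = dr_cmp, Y = y_cmp, RRM = rrm_cmp)
  })

  ## stage 4: volatiles -------------------------------------------------------
  volatiles <- run_stage("volatiles", {
    pt <- if (!is.null(config$peak_csv)) read_peak_csv(config$peak_csv)
          else sim_peak_table(seed = config$seed + 200L)
    tot <- total_peak_area(pt, compare = TRUE)
    nlv <- min(config$n_lv, nrow(pt$areas) - 1L, ncol(pt$areas))
    model <- plsda(pt, ncomp = nlv)
    vid <- vid_coefficients(model)
    disc <- select_discriminants(vid, config$vid_threshold)
    if (nrow(disc) && !is.null(pt$rt)) {
      ladder_rt <- seq(min(pt$rt) - 1, max(pt$rt) + 1, length.out = 15L)
      disc$RI <- round(retention_index(pt$rt[disc$variable], 8:22, ladder_rt))
    }
    note("PLS-DA with %d LVs; %d discriminant variables at |VID| > %.2f",
         nlv, nrow(disc), config$vid_threshold)
    list(peak_table = pt, totals = tot, model = model, vid = vid,
         discriminants = disc)
  })

  ## outputs ------------------------------------------------------------------
  run_stage("write_outputs", {
    utils::write.csv(kinetics$table,
                     file.path(config$out_dir, "table1_kinetics.csv"),
                     row.names = FALSE)
    q <- quality
    fmt <- function(cmp) format_mean_sd(cmp, digits = 4)
    t2row <- function(metric, vals) {
      out <- data.frame(metric = metric, control = NA_character_,
                        AD = NA_character_, VD = NA_character_,
                        FD = NA_character_, stringsAsFactors = FALSE)
      for (nm in names(vals)) out[[nm]] <- as.character(vals[[nm]])
      out
    }
    t2 <- rbind(
      t2row("delta_E_of_means", round(q$delta_e_of_means, 2)),
      t2row("delta_E_mean_of_reps", round(q$delta_e_mean_of_reps, 2)),
      t2row("hardness_N", fmt(q$hardness)),
      t2row("DR_pct", fmt(q$DR)),
      t2row("Y", fmt(q$Y)),
      t2row("RRM", fmt(q$RRM)))
    utils::write.csv(t2, file.path(config$out_dir, "table2_quality.csv"),
                     row.names = FALSE)
    utils::write.csv(volatiles$discriminants,
                     file.path(config$out_dir, "table3_discriminants.csv"),
                     row.names = FALSE)
    summary_obj <- list(
      seed = config$seed,
      kinetics = kinetics$table,
      rehydration_time_min = kinetics$rehydration_time_min,
      delta_e_of_means = as.list(round(quality$delta_e_of_means, 4)),
      delta_e_mean_of_reps = as.list(round(quality$delta_e_mean_of_reps, 4)),
      total_peak_area_anova_p = volatiles$totals$comparison$anova$p,
      n_discriminants = nrow(volatiles$discriminants),
      plsda_R2Y = volatiles$model$R2Y)
    jsonlite::write_json(summary_obj,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
    NULL
  })

  invisible(list(config = config, curves = curves_by_method,
                 kinetics = kinetics, quality = quality,
                 volatiles = volatiles, log = log_lines))
}
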