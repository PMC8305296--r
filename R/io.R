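#' Read rehydration curves from a tidy CSV
#'
#' Long-format reader: one row per weighing, columns `sample_id`, `method`,
#' `temperature_C`, `time_min`, `weight_g`, `dry_mass_g` and optionally
#' `moisture_pct_db` and `half_thickness_mm`. Temperatures are accepted in
#' degrees Celsius at this boundary only and stored in kelvin; thicknesses
#' in mm are converted to metres. Validation failures (missing columns,
#' non-monotone times, duplicate time points, weights below the dry mass)
#' raise errors naming the offending row of the file.
#'
#' @param path CSV file path.
#' @return Named list of [rehydration_curve] objects, one per `sample_id`.
#' @export
read_rehydration_csv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "method", "temperature_C", "time_min",
            "weight_g", "dry_mass_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$.row <- seq_len(nrow(df)) + 1L          # file row (after the header)
  out <- list()
  for (sid in unique(df$sample_id)) {
    d <- df[df$sample_id == sid, , drop = FALSE]
    if (anyDuplicated(d$time_min)) {
      dup <- d$.row[duplicated(d$time_min)][1L]
      stop(sprintf("duplicate (sample, time) pair for '%s' at file row %d",
                   sid, dup))
    }
    if (any(diff(d$time_min) <= 0)) {
      bad <- d$.row[which(diff(d$time_min) <= 0)[1L] + 1L]
      stop(sprintf("time not increasing for '%s' at file row %d", sid, bad))
    }
    low <- d$weight_g < d$dry_mass_g - 1e-9
    if (any(low))
      stop(sprintf("weight below dry mass for '%s' at file row %d",
                   sid, d$.row[which(low)[1L]]))
    out[[sid]] <- rehydration_curve(
      time = d$time_min, weight = d$weight_g,
      moisture = if ("moisture_pct_db" %in% names(d)) d$moisture_pct_db,
      dry_mass = d$dry_mass_g[1L],
      temperature = d$temperature_C[1L] + 273.15,
      sample_id = sid, method = d$method[1L],
      half_thickness = if ("half_thickness_mm" %in% names(d))
        d$half_thickness_mm[1L] / 1000)
  }
  out
}

#' Write rehydration curves to the tidy CSV schema
#'
#' Inverse of [read_rehydration_csv]; a write-then-read round trip
#' reproduces the curves.
#'
#' @param curves list of [rehydration_curve] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rehydration_csv <- function(curves, path) {
  if (inherits(curves, "rehydration_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, method = cv$method,
               temperature_C = cv$temperature - 273.15,
               time_min = cv$time, weight_g = cv$weight,
               dry_mass_g = cv$dry_mass,
               moisture_pct_db = cv$moisture,
               half_thickness_mm = if (is.null(cv$half_thickness)) NA
                                   else cv$half_thickness * 1000)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read an aligned peak table from CSV
#'
#' Wide format: one row per sample, a `sample_id` column, a `class` column,
#' and one numeric column per volatile variable.
#'
#' @param path CSV file path.
#' @param internal_standard optional internal-standard column name.
#' @return A [peak_table].
#' @export
read_peak_csv <- function(path, internal_standard = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    stop("peak CSV needs 'sample_id' and 'class' columns")
  m <- as.matrix(df[, setdiff(names(df), c("sample_id", "class")),
                    drop = FALSE])
  rownames(m) <- df$sample_id
  peak_table(m, class = df$class, internal_standard = internal_standard)
}

#' @rdname read_peak_csv
#' @param table a [peak_table] to write.
#' @export
write_peak_csv <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = rownames(table$areas),
                   class = as.character(table$class),
                   table$areas, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
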