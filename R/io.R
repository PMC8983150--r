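#' Default run configuration
#'
#' Nested list mirroring the YAML configuration schema: `chip` (geometry),
#' `fluid`, `measurement` (tilt calibration), `transport` (gradient
#' solve), `experiment` (synthetic generation / analysis) and `seed`.
#' Lengths are in micrometres, times in seconds, flows in mL/min.
#'
#' @return Named list.
#' @export
default_config <- function() {
  geom <- chip_geometry()
  list(
    chip = as.list(geom),
    fluid = list(viscosity_pa_s = 8.9e-4, density_kg_m3 = 1000,
                 gravity_m_s2 = 9.81),
    measurement = list(tilt_deg = 45, separation_mm = 30),
    transport = list(diffusivity_tmz_m2_s = 5e-10, diffusivity_bay_m2_s = 5e-10,
                     inlet_tmz_uM = 600, inlet_bay_uM = 10,
                     dosing_flow_mL_min = 2.198e-4, cell_size_um = 50),
    experiment = list(cell_line = "SYN", control_viability = 0.92,
                      noise_sd = 0.10, replicates = 5,
                      days = c(4L, 7L), day_scale = c(0.5, 1.0), kappa = 0,
                      hill_tmz = list(emax = 0.4, ec50_uM = 250, hill_n = 1.5),
                      hill_bay = list(emax = 0.28, ec50_uM = 0.1, hill_n = 0.8)),
    seed = 1L
  )
}

merge_validate <- function(user, dflt, path = "") {
  bad <- setdiff(names(user), names(dflt))
  if (length(bad))
    stop("read_chip_config: unknown key(s)", if (nzchar(path)) paste0(" in '", path, "'"),
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in names(user)) {
    if (is.list(dflt[[nm]]) && !is.null(names(dflt[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("read_chip_config: '", paste0(path, nm), "' must be a mapping", call. = FALSE)
      dflt[[nm]] <- merge_validate(user[[nm]], dflt[[nm]],
                                   paste0(path, nm, "/"))
    } else {
      dflt[[nm]] <- user[[nm]]
    }
  }
  dflt
}

#' Read and validate a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema of
#' [default_config()] (unknown keys anywhere are rejected) and fills
#' missing entries with the defaults.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_chip_config <- function(path) {
  if (!file.exists(path)) stop("read_chip_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_validate(user, default_config())
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; used in run logs so a report
#' can be traced to the exact configuration that produced it.
#'
#' @param config configuration list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Read a replicate-level viability CSV
#'
#' Expected header: `cell_line,column,day,replicate` and either
#' `viability` (fraction) or `viability_pct`. Values on the percent scale
#' (any value above 1 when the column is named `viability`) are detected
#' and converted to fractions with a notice. Rows with an unknown column
#' label, viabilities outside \[0, 100\] or duplicate
#' (cell_line, column, day, replicate) keys are rejected with the
#' offending row number.
#'
#' @param path CSV file path.
#' @param allowed_columns permitted column labels (default `A`-`G`).
#' @return data.frame with `viability` as a fraction in \[0, 1\].
#' @export
read_viability_csv <- function(path, allowed_columns = LETTERS[1:7]) {
  if (!file.exists(path)) stop("read_viability_csv: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "column", "day", "replicate")
  if (!all(need %in% names(df)))
    stop("read_viability_csv: header must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  vcol <- intersect(c("viability", "viability_pct"), names(df))
  if (length(vcol) == 0)
    stop("read_viability_csv: need a 'viability' or 'viability_pct' column",
         call. = FALSE)
  v <- df[[vcol[1]]]
  bad <- which(!df$column %in% allowed_columns)
  if (length(bad))
    stop("read_viability_csv: unknown column label '", df$column[bad[1]],
         "' in row ", bad[1], call. = FALSE)
  bad <- which(!is.finite(v) | v < 0 | v > 100)
  if (length(bad))
    stop("read_viability_csv: viability outside [0, 100] in row ", bad[1],
         call. = FALSE)
  if (vcol[1] == "viability_pct" || any(v > 1)) {
    if (vcol[1] == "viability") message("read_viability_csv: values > 1 detected; ",
                                        "treating as percent and dividing by 100")
    v <- v / 100
  }
  key <- paste(df$cell_line, df$column, df$day, df$replicate)
  if (anyDuplicated(key))
    stop("read_viability_csv: duplicate (cell_line, column, day, replicate) key ",
         "in row ", which(duplicated(key))[1], call. = FALSE)
  out <- data.frame(cell_line = as.character(df$cell_line),
                    column = as.character(df$column),
                    day = as.integer(df$day),
                    replicate = as.integer(df$replicate),
                    viability = v, stringsAsFactors = FALSE)
  out[order(out$cell_line, out$day, out$column, out$replicate), , drop = FALSE]
}

#' Write a replicate-level viability CSV
#'
#' Deterministic output: rows sorted by (cell_line, day, column,
#' replicate), viability written as percent with fixed 4-decimal
#' formatting.
#'
#' @param table viability data.frame (fractional `viability`).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_viability_csv <- function(table, path) {
  tb <- table[order(table$cell_line, table$day, table$column, table$replicate), ]
  out <- data.frame(cell_line = tb$cell_line, column = tb$column, day = tb$day,
                    replicate = tb$replicate,
                    viability_pct = sprintf("%.4f", 100 * tb$viability))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-column dose map CSV
#'
#' @param dose_map a `column_dose_map`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_column_doses <- function(dose_map, path) {
  out <- data.frame(column = dose_map$column,
                    frac_tmz = sprintf("%.6f", dose_map$frac_tmz),
                    dose_tmz_uM = sprintf("%.6f", dose_map$dose_tmz_uM),
                    frac_bay = sprintf("%.6f", dose_map$frac_bay),
                    dose_bay_uM = sprintf("%.6f", dose_map$dose_bay_uM))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-column dose map CSV
#'
#' @param path CSV written by [write_column_doses()].
#' @return A `column_dose_map` data.frame.
#' @export
read_column_doses <- function(path) {
  if (!file.exists(path)) stop("read_column_doses: no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("column", "frac_tmz", "dose_tmz_uM", "frac_bay", "dose_bay_uM")
  if (!all(need %in% names(df)))
    stop("read_column_doses: header must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$frac_tmz < 0 | df$frac_tmz > 1 | df$frac_bay < 0 | df$frac_bay > 1))
    stop("read_column_doses: fractions must lie in [0, 1]", call. = FALSE)
  df <- df[, need]
  class(df) <- c("column_dose_map", "data.frame")
  df
}

#' Write a synergy report CSV
#'
#' @param report a `synergy_report` (optionally with a `day` column added).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_synergy_report <- function(report, path) {
  out <- as.data.frame(report)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.6g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
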