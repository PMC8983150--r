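#' Specification of a synthetic chip viability experiment
#'
#' Ground-truth generative model for the seven-column, two-day, n = 5
#' replicate viability design. Per day `d` and column `k`, the single-drug
#' effects are the Hill effects at the column's doses scaled by the day
#' effect (drug action accumulates over the week, so the day-7 scale
#' exceeds the day-4 scale), the combined true effect is
#' \deqn{e_{true} = e_{Bliss} + \kappa\, e_A e_B (1 - e_{Bliss})}
#' (`kappa = 0` is exact Bliss independence, positive `kappa` adds
#' synergy), and replicate viabilities are Gaussian around
#' `control_viability * (1 - e_true)` with standard deviation `noise_sd`,
#' truncated to \[0, 1\]. The default noise of 0.10 viability fraction gives
#' column SEMs around 4.5 points at n = 5, in the middle of the 2-7 point
#' range typical of live/dead spheroid assays.
#'
#' Default Hill curves are anchored to published single-drug anchors for
#' this assay: TMZ at 600 uM produces roughly a third loss of viability
#' (emax 0.4, ec50 250 uM, slope 1.5); BAY 11-7082 at 10 uM about a
#' quarter (emax 0.28, ec50 0.1 uM, shallow slope 0.8).
#'
#' @param hill_tmz,hill_bay ground-truth single-drug [hill_params()]
#'   (their `v0` is ignored; the control level is `control_viability`).
#' @param kappa interaction strength in \[-1, 1\]; 0 = Bliss-consistent.
#' @param control_viability untreated viability fraction.
#' @param noise_sd replicate noise SD in viability fraction (>= 0).
#' @param replicates replicates per column and day (>= 2).
#' @param days assay days after drug administration.
#' @param day_scale effect scale per day (same length as `days`).
#' @param seed default RNG seed for [simulate_viability_experiment()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(hill_tmz = hill_params(1, 0.4, 250, 1.5),
                           hill_bay = hill_params(1, 0.28, 0.1, 0.8),
                           kappa = 0, control_viability = 0.92,
                           noise_sd = 0.10, replicates = 5,
                           days = c(4L, 7L), day_scale = c(0.5, 1.0),
                           seed = 1L) {
  stopifnot(inherits(hill_tmz, "hill_params"), inherits(hill_bay, "hill_params"))
  if (!is.finite(kappa) || kappa < -1 || kappa > 1)
    stop("synthetic_spec: kappa must lie in [-1, 1]", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("synthetic_spec: noise_sd must be >= 0", call. = FALSE)
  if (replicates < 2) stop("synthetic_spec: replicates must be >= 2", call. = FALSE)
  if (!(control_viability > 0 && control_viability <= 1))
    stop("synthetic_spec: control_viability must be in (0, 1]", call. = FALSE)
  if (length(day_scale) != length(days))
    stop("synthetic_spec: day_scale must match days", call. = FALSE)
  if (any(day_scale < 0) || any(day_scale > 1))
    stop("synthetic_spec: day_scale entries must lie in [0, 1]", call. = FALSE)
  structure(list(hill_tmz = hill_tmz, hill_bay = hill_bay, kappa = kappa,
                 control_viability = control_viability, noise_sd = noise_sd,
                 replicates = as.integer(replicates), days = as.integer(days),
                 day_scale = day_scale, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a chip viability experiment with known ground truth
#'
#' Draws replicate viabilities for every column and day of the design from
#' the generative model in [synthetic_spec()], along with a matching
#' untreated control table, and returns the exact per-column ground truth
#' so that downstream estimates (effects, Bliss excess, best column) can be
#' scored against it. Deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param dose_map a `column_dose_map` giving each column's two doses.
#' @param cell_line label written into the tables.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A list of class `viability_experiment`: `treated` and `control`
#'   replicate tables (`cell_line`, `column`, `day`, `replicate`,
#'   `viability` fraction) and `truth` (per day and column: single-drug
#'   effects, Bliss effect, true combined effect and viability, plus the
#'   true best column per day).
#' @export
simulate_viability_experiment <- function(spec, dose_map,
                                          cell_line = "SYN", seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!all(c("column", "dose_tmz_uM", "dose_bay_uM") %in% names(dose_map)))
    stop("simulate_viability_experiment: dose_map must have column, ",
         "dose_tmz_uM, dose_bay_uM", call. = FALSE)
  set.seed(seed)
  labs <- dose_map$column
  truth <- do.call(rbind, lapply(seq_along(spec$days), function(di) {
    s <- spec$day_scale[di]
    ea <- pmin(s * hill_effect(dose_map$dose_tmz_uM, spec$hill_tmz), 1)
    eb <- pmin(s * hill_effect(dose_map$dose_bay_uM, spec$hill_bay), 1)
    ebl <- bliss_effect(ea, eb)
    et <- pmin(pmax(ebl + spec$kappa * ea * eb * (1 - ebl), 0), 1)
    data.frame(day = spec$days[di], column = labs,
               dose_tmz_uM = dose_map$dose_tmz_uM,
               dose_bay_uM = dose_map$dose_bay_uM,
               e_tmz = ea, e_bay = eb, e_bliss = ebl, e_true = et,
               viability_true = spec$control_viability * (1 - et),
               stringsAsFactors = FALSE)
  }))
  nrep <- spec$replicates
  draw <- function(mu) pmin(pmax(stats::rnorm(nrep, mu, spec$noise_sd), 0), 1)
  rows <- function(day, column, viab) {
    data.frame(cell_line = cell_line, column = column, day = day,
               replicate = seq_len(nrep), viability = viab,
               stringsAsFactors = FALSE)
  }
  treated <- do.call(rbind, lapply(seq_len(nrow(truth)), function(r)
    rows(truth$day[r], truth$column[r], draw(truth$viability_true[r]))))
  control <- do.call(rbind, lapply(seq_len(nrow(truth)), function(r)
    rows(truth$day[r], truth$column[r], draw(spec$control_viability))))
  best <- vapply(split(truth, truth$day),
                 function(d) d$column[which.max(d$e_true)], "")
  structure(list(treated = treated, control = control,
                 truth = truth, best_column = best, spec = spec, seed = seed),
            class = "viability_experiment")
}

#' @export
print.viability_experiment <- function(x, ...) {
  cat("viability_experiment: ", length(unique(x$truth$column)), " columns x ",
      length(x$spec$days), " days x ", x$spec$replicates,
      " replicates (kappa = ", x$spec$kappa, ", noise_sd = ", x$spec$noise_sd,
      ", seed = ", x$seed, ")\n", sep = "")
  cat("true best column per day:",
      paste(names(x$best_column), x$best_column, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate perfusion measurements of fabricated chips
#'
#' Synthetic counterpart of the tilt-perfusion calibration: for each true
#' gap depth the measured rate is the forward model [predict_perfusion()]
#' plus Gaussian measurement noise, floored at zero. Deterministic given
#' the seed.
#'
#' @param geometry a [chip_geometry()].
#' @param depths_um true laminar gap depths in micrometres (>= 0).
#' @param noise_sd_mL_min measurement noise SD in mL/min.
#' @param seed RNG seed.
#' @param exposure_s optional UV exposure times to attach to the records.
#' @param fluid,tilt_deg,separation_m forwarded to [predict_perfusion()].
#' @return data.frame with `exposure_s`, `gap_depth_um` (true) and
#'   `perfusion_mL_min` (noisy measurement).
#' @export
simulate_perfusion_measurements <- function(geometry, depths_um,
                                            noise_sd_mL_min = 0, seed = 1L,
                                            exposure_s = NA_real_,
                                            fluid = fluid_properties(),
                                            tilt_deg = 45, separation_m = 0.03) {
  if (any(depths_um < 0))
    stop("simulate_perfusion_measurements: depths must be >= 0", call. = FALSE)
  set.seed(seed)
  q <- vapply(depths_um, function(h)
    predict_perfusion(geometry, h, fluid, tilt_deg = tilt_deg,
                      separation_m = separation_m), 0)
  meas <- pmax(q + stats::rnorm(length(q), 0, noise_sd_mL_min), 0)
  data.frame(exposure_s = exposure_s, gap_depth_um = depths_um,
             perfusion_mL_min = meas)
}
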