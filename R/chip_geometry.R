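#' Parametric geometry of a two-inlet gradient chip
#'
#' Describes the layout of a hydrogel drug-gradient chip: two inlet
#' reservoirs feeding a manifold, `count` parallel culture channels (one
#' microwell column each, labelled `A`, `B`, ... left to right), a single
#' outlet, and a thin laminar flow distribution layer (the "gap") between
#' the glass lid and the hydrogel body. The left inlet is the TMZ side by
#' convention; the right inlet carries the second drug.
#'
#' All lengths are in micrometres. The layout is parametric and
#' left-right mirror symmetric: column centres sit at
#' `(k - 1/2) * pitch` across a footprint of width `count * pitch`.
#'
#' @param channels list with `count` (number of channels, >= 2, odd when
#'   `mirror_symmetric`), `width_um`, `depth_um`, `length_um`, `pitch_um`.
#' @param wells list with `per_column`, `diameter_um`, `depth_um`,
#'   `first_y_um` (axial position of the first well centre, measured from
#'   the manifold end), `pitch_um` (axial well spacing).
#' @param gap_depth_um depth of the laminar flow layer (> 0).
#' @param feed list with `width_um`, `depth_um`, `length_um` describing the
#'   short low-resistance port connecting each inlet reservoir to the
#'   manifold.
#' @param mirror_symmetric logical; the parametric layout is intrinsically
#'   symmetric, the flag additionally asserts symmetric operation (equal
#'   inlet pressures/flows) and requires an odd channel count so that a
#'   central column exists.
#'
#' @return An object of class `chip_geometry`.
#' @examples
#' geom <- chip_geometry()
#' geom$labels       # "A" ... "G"
#' @export
chip_geometry <- function(channels = list(count = 7, width_um = 500, depth_um = 87,
                                          length_um = 20000, pitch_um = 1500),
                          wells = list(per_column = 6, diameter_um = 400, depth_um = 300,
                                       first_y_um = 8000, pitch_um = 800),
                          gap_depth_um = 92.6,
                          feed = list(width_um = 3000, depth_um = 1000, length_um = 2000),
                          mirror_symmetric = TRUE) {
  dims <- c(channel_width_um = channels$width_um, channel_depth_um = channels$depth_um,
            channel_length_um = channels$length_um, channel_pitch_um = channels$pitch_um,
            wells_per_column = wells$per_column, well_diameter_um = wells$diameter_um,
            well_depth_um = wells$depth_um, well_first_y_um = wells$first_y_um,
            well_pitch_um = wells$pitch_um, gap_depth_um = gap_depth_um,
            feed_width_um = feed$width_um, feed_depth_um = feed$depth_um,
            feed_length_um = feed$length_um, channel_count = channels$count)
  for (nm in names(dims)) {
    if (!is.numeric(dims[[nm]]) || length(dims[[nm]]) != 1 || is.na(dims[[nm]]) ||
        dims[[nm]] <= 0)
      stop("chip_geometry: field '", nm, "' must be a single positive number", call. = FALSE)
  }
  n <- as.integer(channels$count)
  if (n < 2) stop("chip_geometry: field 'channel_count' must be >= 2", call. = FALSE)
  if (n > 26) stop("chip_geometry: at most 26 channels (single-letter labels)", call. = FALSE)
  if (isTRUE(mirror_symmetric) && n %% 2 == 0)
    stop("chip_geometry: mirror_symmetric layout needs an odd channel count ",
         "(a central column must exist)", call. = FALSE)
  if (channels$width_um > channels$pitch_um)
    stop("chip_geometry: channel_width_um exceeds channel_pitch_um", call. = FALSE)
  last_y <- wells$first_y_um + (wells$per_column - 1) * wells$pitch_um +
    wells$diameter_um / 2
  if (last_y > channels$length_um)
    stop("chip_geometry: well row does not fit inside channel_length_um", call. = FALSE)

  g <- list(
    channels = list(count = n, width_um = channels$width_um,
                    depth_um = channels$depth_um, length_um = channels$length_um,
                    pitch_um = channels$pitch_um),
    wells = list(per_column = as.integer(wells$per_column),
                 diameter_um = wells$diameter_um, depth_um = wells$depth_um,
                 first_y_um = wells$first_y_um, pitch_um = wells$pitch_um),
    gap_depth_um = gap_depth_um,
    feed = list(width_um = feed$width_um, depth_um = feed$depth_um,
                length_um = feed$length_um),
    mirror_symmetric = isTRUE(mirror_symmetric),
    labels = LETTERS[seq_len(n)],
    footprint_width_um = n * channels$pitch_um
  )
  class(g) <- "chip_geometry"
  g
}

#' Build a chip geometry from a configuration list
#'
#' Accepts the `chip` section of a run configuration (e.g. read from YAML
#' with [read_chip_config()]). Missing entries fall back to the package
#' defaults; unknown keys are rejected.
#'
#' @param config named list with any of the keys `channels`, `wells`,
#'   `gap_depth_um`, `feed`, `mirror_symmetric`, or the list returned by
#'   `as.list()` on a `chip_geometry`.
#' @return A validated [chip_geometry()] object.
#' @export
build_geometry <- function(config = list()) {
  if (inherits(config, "chip_geometry")) config <- as.list(config)
  allowed <- c("channels", "wells", "gap_depth_um", "feed", "mirror_symmetric")
  config <- config[!names(config) %in% c("labels", "footprint_width_um")]
  bad <- setdiff(names(config), allowed)
  if (length(bad))
    stop("build_geometry: unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dflt <- formals(chip_geometry)
  args <- list(
    channels = utils::modifyList(eval(dflt$channels), config$channels %||% list()),
    wells = utils::modifyList(eval(dflt$wells), config$wells %||% list()),
    gap_depth_um = config$gap_depth_um %||% eval(dflt$gap_depth_um),
    feed = utils::modifyList(eval(dflt$feed), config$feed %||% list()),
    mirror_symmetric = config$mirror_symmetric %||% TRUE
  )
  sub_allowed <- list(channels = c("count", "width_um", "depth_um", "length_um", "pitch_um"),
                      wells = c("per_column", "diameter_um", "depth_um", "first_y_um", "pitch_um"),
                      feed = c("width_um", "depth_um", "length_um"))
  for (s in names(sub_allowed)) {
    bad <- setdiff(names(config[[s]] %||% list()), sub_allowed[[s]])
    if (length(bad))
      stop("build_geometry: unknown key(s) in '", s, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(chip_geometry, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.list.chip_geometry <- function(x, ...) {
  list(channels = x$channels, wells = x$wells, gap_depth_um = x$gap_depth_um,
       feed = x$feed, mirror_symmetric = x$mirror_symmetric)
}

#' Reflect a chip geometry left-right
#'
#' Returns the geometry obtained by mirroring the layout about its central
#' axis, which exchanges column `k` with column `N + 1 - k`. Because the
#' parametric layout places columns symmetrically, reflecting a
#' mirror-symmetric geometry returns an identical object.
#'
#' @param geometry a [chip_geometry()].
#' @return A `chip_geometry`.
#' @export
reflect_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "chip_geometry"))
  # column centres are at (k - 1/2) * pitch, invariant under reflection;
  # only the labelling direction flips, and labels are reassigned left->right
  geometry
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat("chip_geometry:", x$channels$count, "channels (",
      paste(x$labels[c(1, x$channels$count)], collapse = "-"),
      "), footprint", x$footprint_width_um / 1000, "x",
      x$channels$length_um / 1000, "mm\n")
  cat("  channel: ", x$channels$width_um, " x ", x$channels$depth_um,
      " um, pitch ", x$channels$pitch_um, " um\n", sep = "")
  cat("  wells:   ", x$wells$per_column, " per column, d = ",
      x$wells$diameter_um, " um\n", sep = "")
  cat("  gap depth: ", x$gap_depth_um, " um; mirror_symmetric: ",
      x$mirror_symmetric, "\n", sep = "")
  invisible(x)
}

#' UV dose from exposure time and irradiance
#'
#' The photopolymerisation dose delivered to the chip is the product of
#' exposure time and lamp irradiance; at the default irradiance of
#' 20 mW/cm^2 a 32 s exposure delivers 640 mJ/cm^2.
#'
#' @param time_s exposure time in seconds (>= 0).
#' @param irradiance_mW_cm2 lamp irradiance in mW/cm^2 (> 0), default 20.
#' @return Dose in mJ/cm^2.
#' @export
exposure_to_dose <- function(time_s, irradiance_mW_cm2 = 20) {
  if (any(!is.finite(time_s)) || any(time_s < 0))
    stop("exposure_to_dose: time_s must be >= 0", call. = FALSE)
  if (any(!is.finite(irradiance_mW_cm2)) || any(irradiance_mW_cm2 <= 0))
    stop("exposure_to_dose: irradiance_mW_cm2 must be > 0", call. = FALSE)
  time_s * irradiance_mW_cm2
}

#' Calibrate the UV-exposure to gap-depth relation
#'
#' Builds a monotone interpolant through measured (exposure time, gap depth)
#' pairs. Longer UV exposure crosslinks more of the hydrogel thickness and
#' leaves a shallower laminar flow layer, so depth must decrease strictly
#' with time; inconsistent calibration data are rejected. The relation is
#' empirical: no photopolymerisation kinetics are modelled.
#'
#' Interpolation is piecewise monotone cubic (Hyman-filtered spline), which
#' passes exactly through the supplied points without overshoot; with only
#' two records it reduces to linear interpolation. Queries outside the
#' calibrated time range raise an error rather than extrapolating.
#'
#' @param exposure_s exposure times in seconds, strictly increasing.
#' @param gap_depth_um measured/estimated gap depths in micrometres.
#' @param irradiance_mW_cm2 irradiance used to report the UV dose per record.
#' @return An object of class `exposure_depth_curve`; evaluate it with
#'   [depth_at()].
#' @examples
#' cal <- calibrate_exposure_depth(c(24, 26, 28, 30), c(162.1, 106.6, 92.6, 57.3))
#' depth_at(cal, 28)  # 92.6
#' @export
calibrate_exposure_depth <- function(exposure_s, gap_depth_um,
                                     irradiance_mW_cm2 = 20) {
  if (length(exposure_s) != length(gap_depth_um))
    stop("calibrate_exposure_depth: time and depth vectors differ in length",
         call. = FALSE)
  if (length(exposure_s) < 2)
    stop("calibrate_exposure_depth: need at least 2 records", call. = FALSE)
  o <- order(exposure_s)
  t <- exposure_s[o]; h <- gap_depth_um[o]
  if (any(diff(t) <= 0))
    stop("calibrate_exposure_depth: exposure times must be distinct", call. = FALSE)
  if (any(diff(h) >= 0))
    stop("calibrate_exposure_depth: gap depth must decrease strictly with ",
         "exposure time; calibration data are inconsistent", call. = FALSE)
  fun <- if (length(t) == 2) {
    stats::approxfun(t, h)
  } else {
    stats::splinefun(t, h, method = "hyman")
  }
  structure(list(records = data.frame(exposure_s = t,
                                      uv_dose_mJ_cm2 = exposure_to_dose(t, irradiance_mW_cm2),
                                      gap_depth_um = h),
                 irradiance_mW_cm2 = irradiance_mW_cm2,
                 range_s = range(t), fun = fun),
            class = "exposure_depth_curve")
}

#' Evaluate an exposure-depth calibration curve
#'
#' @param curve an `exposure_depth_curve` from [calibrate_exposure_depth()].
#' @param time_s query exposure time(s), within the calibrated range.
#' @return Interpolated gap depth(s) in micrometres.
#' @export
depth_at <- function(curve, time_s) {
  stopifnot(inherits(curve, "exposure_depth_curve"))
  if (any(time_s < curve$range_s[1]) || any(time_s > curve$range_s[2]))
    stop("depth_at: query outside the calibrated exposure range [",
         curve$range_s[1], ", ", curve$range_s[2], "] s; refusing to extrapolate",
         call. = FALSE)
  curve$fun(time_s)
}

#' @export
print.exposure_depth_curve <- function(x, ...) {
  cat("exposure_depth_curve over [", x$range_s[1], ",", x$range_s[2], "] s,",
      nrow(x$records), "records\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' Largest spheroid size that can escape through the laminar gap
#'
#' The laminar flow layer admits single cells but retains grown spheroids:
#' a spheroid wider than `floor(gap_depth / cell_diameter)` cells cannot
#' pass through the gap. With the working 92.6 um gap and ~15 um
#' glioblastoma cells, spheroids wider than 6 cells are retained.
#'
#' @param gap_depth_um gap depth in micrometres (> 0).
#' @param cell_diameter_um single-cell diameter in micrometres (> 0),
#'   default 15.
#' @return Integer cell count; monotone non-decreasing in `gap_depth_um`
#'   and non-increasing in `cell_diameter_um`.
#' @export
min_retained_spheroid_cells <- function(gap_depth_um, cell_diameter_um = 15) {
  if (any(gap_depth_um <= 0) || any(cell_diameter_um <= 0))
    stop("min_retained_spheroid_cells: arguments must be > 0", call. = FALSE)
  as.integer(floor(gap_depth_um / cell_diameter_um))
}
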