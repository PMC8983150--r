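#' Rasterize the chip footprint onto a uniform 2D grid
#'
#' Discretises the depth-averaged chip footprint (width
#' `count * pitch`, length `channel_length`) into square cells of side
#' `cell_size_um`. Each cell is classified as `gap` (laminar layer only),
#' `channel` (over a culture channel strip) or `well` (over a microwell);
#' wells also record which column they belong to. The inlet edge (y = 0) is
#' split at the centreline into the left (drug A / TMZ) and right (drug B)
#' inlet segments; the opposite edge is the outlet. Internally indexing is
#' 0-based with half-open cell extents `[i*dx, (i+1)*dx)`; the exported
#' coordinates are cell centres.
#'
#' @param geometry a [chip_geometry()].
#' @param cell_size_um grid spacing in micrometres; must not exceed the
#'   channel width and must divide the footprint width and length, the
#'   channel pitch and the well diameter and pitch to within 5%.
#' @return An object of class `chip_grid` with elements `cell_size_um`,
#'   `nx`, `ny`, `x_um`, `y_um` (cell-centre coordinates), `mask`
#'   (nx x ny integer matrix: 1 gap, 2 channel, 3 well), `well_column`
#'   (nx x ny integer matrix, 0 outside wells), `inlet_left` (logical per
#'   x-index) and `geometry`.
#' @export
rasterize <- function(geometry, cell_size_um = 50) {
  stopifnot(inherits(geometry, "chip_geometry"))
  dx <- cell_size_um
  if (dx <= 0) stop("rasterize: cell_size_um must be > 0", call. = FALSE)
  if (dx > geometry$channels$width_um)
    stop("rasterize: cell_size_um exceeds the channel width", call. = FALSE)
  key <- c(footprint_width = geometry$footprint_width_um,
           channel_length = geometry$channels$length_um,
           channel_pitch = geometry$channels$pitch_um,
           well_diameter = geometry$wells$diameter_um,
           well_pitch = geometry$wells$pitch_um)
  for (nm in names(key)) {
    m <- key[[nm]] / dx
    if (abs(m - round(m)) * dx > 0.05 * key[[nm]])
      stop("rasterize: cell_size_um does not divide ", nm, " (= ", key[[nm]],
           " um) within 5%", call. = FALSE)
  }
  nx <- round(geometry$footprint_width_um / dx)
  ny <- round(geometry$channels$length_um / dx)
  x <- (seq_len(nx) - 0.5) * dx
  y <- (seq_len(ny) - 0.5) * dx
  mask <- matrix(1L, nx, ny)
  wellcol <- matrix(0L, nx, ny)
  xcol <- (seq_len(geometry$channels$count) - 0.5) * geometry$channels$pitch_um
  for (k in seq_along(xcol)) {
    in_strip <- abs(x - xcol[k]) <= geometry$channels$width_um / 2
    mask[in_strip, ] <- 2L
  }
  ywell <- geometry$wells$first_y_um +
    (seq_len(geometry$wells$per_column) - 1L) * geometry$wells$pitch_um
  r2 <- (geometry$wells$diameter_um / 2)^2
  for (k in seq_along(xcol)) for (yw in ywell) {
    dx2 <- (x - xcol[k])^2
    sel_x <- which(dx2 <= r2)
    for (i in sel_x) {
      sel_y <- which(dx2[i] + (y - yw)^2 <= r2)
      if (length(sel_y)) { mask[i, sel_y] <- 3L; wellcol[i, sel_y] <- k }
    }
  }
  # fraction of each inlet-edge cell lying left of the centreline, so that
  # a cell straddling the centreline (odd nx) splits its boundary
  # concentration between the two inlet streams
  half <- geometry$footprint_width_um / 2
  cover_left <- pmin(pmax((half - (x - dx / 2)) / dx, 0), 1)
  structure(list(cell_size_um = dx, nx = nx, ny = ny, x_um = x, y_um = y,
                 mask = mask, well_column = wellcol,
                 inlet_left = cover_left,
                 geometry = geometry),
            class = "chip_grid")
}

#' @export
print.chip_grid <- function(x, ...) {
  cat("chip_grid: ", x$nx, " x ", x$ny, " cells of ", x$cell_size_um,
      " um (", x$nx * x$ny, " cells); ", sum(x$mask == 3L), " well cells in ",
      x$geometry$channels$count, " columns\n", sep = "")
  invisible(x)
}

#' Depth-averaged velocity field on the chip grid
#'
#' Builds the face-flux field of the dosing flow through the laminar layer.
#' For the rectangular depth-averaged footprint with a full-width inlet edge
#' and a full-width outlet edge and uniform gap depth, the exact Hele-Shaw
#' solution is uniform plug flow down the chip axis; the face fluxes are
#' constructed accordingly and are exactly divergence-free. The total flow
#' is taken from a [solve_flow()] solution (its outlet flow) or may be given
#' directly in mL/min.
#'
#' Unequal inlet flows are not representable by this symmetric plug profile;
#' a flow solution with left/right inlet flows differing by more than 1%
#' raises an error.
#'
#' @param flow a `flow_solution` or a single total flow rate in mL/min.
#' @param grid a [rasterize()]d `chip_grid`.
#' @param geometry chip geometry; defaults to the grid's.
#' @return An object of class `velocity_field` with face fluxes `qx`
#'   ((nx+1) x ny) and `qy` (nx x (ny+1)), in m^2/s per unit depth
#'   (positive toward +x / +y, i.e. toward the outlet), the cell velocity
#'   `v_m_s`, and the total flow `Q_m3_s`.
#' @export
velocity_field <- function(flow, grid, geometry = grid$geometry) {
  stopifnot(inherits(grid, "chip_grid"))
  if (inherits(flow, "flow_solution")) {
    inl <- -flow$node_net_flux_m3_s[c("inlet_left", "inlet_right")]
    if (all(is.finite(inl)) && sum(abs(inl)) > 0 &&
        abs(inl[1] - inl[2]) > 0.01 * max(abs(inl)))
      stop("velocity_field: unequal inlet flows (",
           paste(signif(inl * 6e7, 3), collapse = " vs "),
           " mL/min); the plug-flow field assumes symmetric operation",
           call. = FALSE)
    Q <- flow$node_net_flux_m3_s[["outlet"]]
  } else if (is.numeric(flow) && length(flow) == 1) {
    Q <- flow / 6e7
  } else stop("velocity_field: 'flow' must be a flow_solution or mL/min scalar",
              call. = FALSE)
  if (Q < 0) stop("velocity_field: negative total flow", call. = FALSE)
  W <- geometry$footprint_width_um * 1e-6
  h <- geometry$gap_depth_um * 1e-6
  dx <- grid$cell_size_um * 1e-6
  v <- Q / (W * h)              # depth-averaged axial speed, m/s
  q <- v * dx                   # advective flux per face per unit depth, m^2/s
  structure(list(qx = matrix(0, grid$nx + 1, grid$ny),
                 qy = matrix(q, grid$nx, grid$ny + 1),
                 v_m_s = v, Q_m3_s = Q, cell_size_um = grid$cell_size_um),
            class = "velocity_field")
}

#' Maximum discrete divergence of a velocity field
#'
#' Net face flux out of each cell, relative to the mean face flux
#' magnitude; exactly zero for the plug-flow construction.
#'
#' @param velocity a [velocity_field()].
#' @return Maximum relative cell divergence (dimensionless).
#' @export
max_divergence <- function(velocity) {
  nx <- nrow(velocity$qx) - 1; ny <- ncol(velocity$qx)
  div <- velocity$qx[-1, , drop = FALSE] - velocity$qx[-(nx + 1), , drop = FALSE] +
    velocity$qy[, -1, drop = FALSE] - velocity$qy[, -(ny + 1), drop = FALSE]
  scale <- mean(abs(velocity$qy))
  if (scale == 0) return(max(abs(div)))
  max(abs(div)) / scale
}
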