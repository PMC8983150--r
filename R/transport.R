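#' Transport parameters for the two-drug gradient solve
#'
#' Defaults describe the dosing configuration: TMZ at 600 uM on the left
#' inlet, BAY 11-7082 at 10 uM on the right inlet, equal small-molecule
#' diffusivities of 5e-10 m^2/s, and a slow dosing flow. The default flow,
#' 2.198e-4 mL/min, is the package's one-time Peclet calibration: it sets
#' the advection-diffusion balance so that the lateral interface spread at
#' the well rows is about 1.15 mm, which reproduces the published
#' seven-column gradient shape (99.9% of the inlet concentration at the
#' column nearest the drug's own inlet, ~50% at the central column).
#'
#' @param diffusivity_tmz_m2_s,diffusivity_bay_m2_s drug diffusivities.
#' @param inlet_tmz_uM,inlet_bay_uM inlet concentrations in micromolar.
#' @param dosing_flow_mL_min total flow during drug administration.
#' @param cell_size_um default grid spacing for [solve_gradient()].
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(diffusivity_tmz_m2_s = 5e-10,
                             diffusivity_bay_m2_s = 5e-10,
                             inlet_tmz_uM = 600, inlet_bay_uM = 10,
                             dosing_flow_mL_min = 2.198e-4,
                             cell_size_um = 50) {
  if (diffusivity_tmz_m2_s <= 0 || diffusivity_bay_m2_s <= 0)
    stop("transport_params: diffusivities must be > 0", call. = FALSE)
  if (inlet_tmz_uM < 0 || inlet_bay_uM < 0)
    stop("transport_params: inlet concentrations must be >= 0", call. = FALSE)
  if (dosing_flow_mL_min <= 0)
    stop("transport_params: dosing_flow_mL_min must be > 0", call. = FALSE)
  structure(list(diffusivity_tmz_m2_s = diffusivity_tmz_m2_s,
                 diffusivity_bay_m2_s = diffusivity_bay_m2_s,
                 inlet_tmz_uM = inlet_tmz_uM, inlet_bay_uM = inlet_bay_uM,
                 dosing_flow_mL_min = dosing_flow_mL_min,
                 cell_size_um = cell_size_um),
            class = "transport_params")
}

#' Steady-state advection-diffusion solve for one drug
#'
#' Finite-volume discretisation of the depth-averaged steady transport
#' equation on the chip grid: first-order upwind advection on the face
#' fluxes plus central diffusion, assembled as one sparse linear system and
#' solved directly. The inlet edge carries the drug at fraction 1 on its own
#' inlet segment and 0 on the other (Dirichlet through a ghost-cell
#' half-step); the outlet is a zero-diffusive-gradient outflow; the side
#' walls are no-flux. The upwind scheme is monotone, so the solution obeys
#' the discrete maximum principle: fractions stay in \[0, 1\] to round-off.
#'
#' @param grid a [rasterize()]d `chip_grid`.
#' @param velocity a [velocity_field()] on the same grid.
#' @param diffusivity_m2_s drug diffusivity.
#' @param inlet_side `"left"` or `"right"`: which inlet segment carries this
#'   drug at fraction 1.
#' @param drug label stored with the result.
#' @return An object of class `concentration_field` with the fraction
#'   matrix `frac` (nx x ny, dimensionless in \[0, 1\]), the inlet boundary
#'   fractions `cbc`, and the relative residual of the linear solve.
#' @export
solve_steady_transport <- function(grid, velocity, diffusivity_m2_s = 5e-10,
                                   inlet_side = c("left", "right"),
                                   drug = inlet_side[1]) {
  stopifnot(inherits(grid, "chip_grid"), inherits(velocity, "velocity_field"))
  inlet_side <- match.arg(inlet_side)
  nx <- grid$nx; ny <- grid$ny; n <- nx * ny
  D <- diffusivity_m2_s
  qx <- velocity$qx; qy <- velocity$qy
  cbc <- if (inlet_side == "left") as.numeric(grid$inlet_left) else
    1 - as.numeric(grid$inlet_left)

  idx <- function(i, j) (j - 1L) * nx + i
  ii <- vector("list", 8); jj <- vector("list", 8); xx <- vector("list", 8)
  put <- local({k <- 0L; function(r, c, v) {k <<- k + 1L
    ii[[k]] <<- r; jj[[k]] <<- c; xx[[k]] <<- v}})

  # vertical interior faces between (i-1, j) and (i, j)
  I <- rep(2:nx, ny); J <- rep(seq_len(ny), each = nx - 1L)
  a <- idx(I - 1L, J); b <- idx(I, J)
  q <- qx[cbind(I, J)]
  qp <- pmax(q, 0); qm <- pmax(-q, 0)
  put(c(a, a, b, b), c(a, b, b, a), c(qp + D, -(qm + D), qm + D, -(qp + D)))

  # horizontal interior faces between (i, j-1) and (i, j)
  I <- rep(seq_len(nx), ny - 1L); J <- rep(2:ny, each = nx)
  a <- idx(I, J - 1L); b <- idx(I, J)
  q <- qy[cbind(I, J)]
  qp <- pmax(q, 0); qm <- pmax(-q, 0)
  put(c(a, a, b, b), c(a, b, b, a), c(qp + D, -(qm + D), qm + D, -(qp + D)))

  b_rhs <- numeric(n)
  # inlet boundary faces (j = 1)
  top <- idx(seq_len(nx), 1L)
  qin <- qy[, 1L]
  put(top, top, 2 * D + pmax(-qin, 0))
  b_rhs[top] <- b_rhs[top] + (pmax(qin, 0) + 2 * D) * cbc
  # outlet boundary faces (j = ny): advective outflow, zero diffusive gradient
  bot <- idx(seq_len(nx), ny)
  qout <- qy[, ny + 1L]
  put(bot, bot, pmax(qout, 0))

  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  cvec <- tryCatch(as.numeric(Matrix::solve(A, b_rhs)),
                   error = function(e) stop("solve_steady_transport: singular ",
                                            "system (no outlet path?): ",
                                            conditionMessage(e), call. = FALSE))
  res <- max(abs(A %*% cvec - b_rhs)) / max(abs(b_rhs))
  if (res > 1e-10)
    warning("solve_steady_transport: relative residual ", signif(res, 3),
            " exceeds 1e-10")
  if (min(cvec) < -1e-9 || max(cvec) > 1 + 1e-9)
    warning("solve_steady_transport: maximum principle violated: range [",
            signif(min(cvec), 4), ", ", signif(max(cvec), 4), "]")
  structure(list(frac = matrix(cvec, nx, ny), drug = drug,
                 inlet_side = inlet_side, cbc = cbc,
                 diffusivity_m2_s = D, residual_rel = res,
                 cell_size_um = grid$cell_size_um),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("concentration_field (", x$drug, ", inlet ", x$inlet_side, "): ",
      nrow(x$frac), " x ", ncol(x$frac), " cells, range [",
      signif(min(x$frac), 4), ", ", signif(max(x$frac), 4),
      "], residual ", signif(x$residual_rel, 2), "\n", sep = "")
  invisible(x)
}

#' Tracer conservation check for a solved field
#'
#' Relative imbalance between the advective tracer flux entering at the
#' inlet edge and the advective flux leaving at the outlet edge; the side
#' walls are no-flux by construction so they cannot leak. A converged
#' steady solve balances to round-off; values above 1e-3 indicate an
#' unconverged or corrupted field.
#'
#' @param field a `concentration_field`.
#' @param velocity the [velocity_field()] used for the solve.
#' @param grid the `chip_grid` used for the solve.
#' @return Relative flux imbalance (dimensionless, >= 0).
#' @export
check_conservation <- function(field, velocity, grid) {
  stopifnot(inherits(field, "concentration_field"))
  influx <- sum(pmax(velocity$qy[, 1L], 0) * field$cbc)
  outflux <- sum(pmax(velocity$qy[, grid$ny + 1L], 0) * field$frac[, grid$ny])
  if (influx == 0) return(abs(outflux))
  abs(influx - outflux) / influx
}

#' Reduce concentration fields to a per-column dose map
#'
#' Each microwell column's drug fraction is the mean fraction over that
#' column's well cells (dead-end wells equilibrate diffusively with the
#' channel above them at steady state); absolute doses scale the fractions
#' by the inlet concentrations.
#'
#' @param fields list with `concentration_field`s `tmz` and `bay`.
#' @param grid the `chip_grid` the fields were solved on.
#' @param params a [transport_params()] supplying inlet concentrations.
#' @return A data.frame of class `column_dose_map` with columns `column`,
#'   `frac_tmz`, `dose_tmz_uM`, `frac_bay`, `dose_bay_uM`, one row per
#'   microwell column A, B, ... left to right.
#' @export
extract_column_doses <- function(fields, grid, params = transport_params()) {
  stopifnot(inherits(grid, "chip_grid"))
  labs <- grid$geometry$labels
  nwell <- tabulate(grid$well_column[grid$well_column > 0L],
                    nbins = length(labs))
  if (any(nwell == 0))
    stop("extract_column_doses: column(s) without well cells: ",
         paste(labs[nwell == 0], collapse = ", "), call. = FALSE)
  colmean <- function(field) {
    v <- tapply(field$frac[grid$well_column > 0L],
                grid$well_column[grid$well_column > 0L], mean)
    as.numeric(v[as.character(seq_along(labs))])
  }
  out <- data.frame(column = labs,
                    frac_tmz = colmean(fields$tmz),
                    dose_tmz_uM = NA_real_,
                    frac_bay = colmean(fields$bay),
                    dose_bay_uM = NA_real_,
                    stringsAsFactors = FALSE)
  out$dose_tmz_uM <- out$frac_tmz * params$inlet_tmz_uM
  out$dose_bay_uM <- out$frac_bay * params$inlet_bay_uM
  class(out) <- c("column_dose_map", "data.frame")
  out
}

#' Simulate the two-drug column gradient of the chip
#'
#' Convenience wrapper running the full transport chain: rasterize the
#' geometry, build the plug dosing flow, solve the steady advection-
#' diffusion equation for each drug (TMZ from the left inlet, BAY 11-7082
#' from the right) and reduce to the per-column dose map.
#'
#' @param geometry a [chip_geometry()].
#' @param params a [transport_params()].
#' @param cell_size_um grid spacing; defaults to `params$cell_size_um`.
#' @return An object of class `gradient_solution`: list with `grid`,
#'   `velocity`, `fields` (tmz, bay), `dose_map`, `peclet` (advective over
#'   diffusive transport across one column pitch) and conservation
#'   imbalances per drug.
#' @examples
#' \donttest{
#' sol <- solve_gradient(chip_geometry(), cell_size_um = 100)
#' sol$dose_map
#' }
#' @export
solve_gradient <- function(geometry, params = transport_params(),
                           cell_size_um = params$cell_size_um) {
  grid <- rasterize(geometry, cell_size_um)
  vel <- velocity_field(params$dosing_flow_mL_min, grid, geometry)
  f_tmz <- solve_steady_transport(grid, vel, params$diffusivity_tmz_m2_s,
                                  "left", drug = "tmz")
  f_bay <- solve_steady_transport(grid, vel, params$diffusivity_bay_m2_s,
                                  "right", drug = "bay")
  fields <- list(tmz = f_tmz, bay = f_bay)
  structure(list(grid = grid, velocity = vel, fields = fields,
                 dose_map = extract_column_doses(fields, grid, params),
                 peclet = vel$v_m_s * geometry$channels$pitch_um * 1e-6 /
                   min(params$diffusivity_tmz_m2_s, params$diffusivity_bay_m2_s),
                 conservation = c(tmz = check_conservation(f_tmz, vel, grid),
                                  bay = check_conservation(f_bay, vel, grid)),
                 params = params),
            class = "gradient_solution")
}

#' @export
print.gradient_solution <- function(x, ...) {
  cat("gradient_solution on a ", x$grid$nx, " x ", x$grid$ny,
      " grid (cell ", x$grid$cell_size_um, " um), Peclet ",
      signif(x$peclet, 4), "\n", sep = "")
  dm <- x$dose_map
  dm$frac_tmz <- round(100 * dm$frac_tmz, 2)
  dm$frac_bay <- round(100 * dm$frac_bay, 2)
  names(dm)[names(dm) == "frac_tmz"] <- "tmz_pct"
  names(dm)[names(dm) == "frac_bay"] <- "bay_pct"
  print(dm, row.names = FALSE, digits = 4)
  invisible(x)
}
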