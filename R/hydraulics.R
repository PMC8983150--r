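#' Fluid properties of the perfusion medium
#'
#' Culture medium is treated as water at room temperature.
#'
#' @param viscosity_pa_s dynamic viscosity in Pa s (default 8.9e-4).
#' @param density_kg_m3 density in kg/m^3 (default 1000).
#' @param gravity_m_s2 gravitational acceleration (default 9.81).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity_pa_s = 8.9e-4, density_kg_m3 = 1000,
                             gravity_m_s2 = 9.81) {
  vals <- c(viscosity_pa_s = viscosity_pa_s, density_kg_m3 = density_kg_m3,
            gravity_m_s2 = gravity_m_s2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("fluid_properties: all properties must be positive", call. = FALSE)
  structure(as.list(vals), class = "fluid_properties")
}

#' Poiseuille resistance of a rectangular microchannel
#'
#' First-order wide-duct approximation for laminar flow in a rectangular
#' channel of width `w`, depth `h` (h <= w) and length `L`:
#' \deqn{R = \frac{12 \mu L}{w h^3 (1 - 0.63\, h/w)}}
#' accurate to a few percent for aspect ratios h/w below ~0.7 and exact in
#' the infinite-slit limit \eqn{12 \mu L / (w h^3)} as h/w -> 0.
#'
#' @param width_m channel width in metres (the longer transverse side).
#' @param depth_m channel depth in metres; must not exceed `width_m`.
#' @param length_m channel length in metres.
#' @param viscosity_pa_s dynamic viscosity in Pa s.
#' @return Hydraulic resistance in Pa s / m^3.
#' @export
rect_channel_resistance <- function(width_m, depth_m, length_m,
                                    viscosity_pa_s = 8.9e-4) {
  if (any(width_m <= 0) || any(depth_m <= 0) || any(length_m <= 0))
    stop("rect_channel_resistance: dimensions must be > 0", call. = FALSE)
  if (any(depth_m > width_m))
    stop("rect_channel_resistance: depth exceeds width; the approximation ",
         "requires h <= w - swap the axes so that width is the longer side",
         call. = FALSE)
  12 * viscosity_pa_s * length_m / (width_m * depth_m^3 * (1 - 0.63 * depth_m / width_m))
}

#' Hydrostatic driving pressure of a tilted chip
#'
#' When the chip is tilted with the inlets above the outlet, the pressure
#' head is \eqn{\Delta P = \rho g \,\Delta\ell \sin\theta} where
#' `separation_m` is the in-plane inlet-to-outlet separation. Reservoir
#' draw-down during the measurement is neglected (quasi-static).
#'
#' @param separation_m in-plane inlet to outlet separation in metres.
#' @param fluid a [fluid_properties()].
#' @param tilt_deg tilt angle in degrees, between 0 and 90.
#' @return Pressure difference in Pa.
#' @export
hydrostatic_pressure <- function(separation_m, fluid = fluid_properties(),
                                 tilt_deg = 45) {
  if (any(tilt_deg < 0) || any(tilt_deg > 90))
    stop("hydrostatic_pressure: tilt_deg must lie in [0, 90]", call. = FALSE)
  if (any(separation_m < 0))
    stop("hydrostatic_pressure: separation_m must be >= 0", call. = FALSE)
  fluid$density_kg_m3 * fluid$gravity_m_s2 * separation_m * sin(tilt_deg * pi / 180)
}

#' Construct a hydraulic resistance network
#'
#' @param nodes data.frame with columns `id` (character) and `pressure_pa`
#'   (numeric; `NA` for interior junction nodes, fixed values for boundary
#'   reservoirs).
#' @param edges data.frame with columns `from`, `to` (node ids), `kind`
#'   (free-text, e.g. `"rectangular_channel"` or `"slit_gap"`) and
#'   `resistance` (Pa s / m^3, > 0).
#' @return An object of class `hydraulic_network`.
#' @export
hydraulic_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (anyDuplicated(nodes$id)) stop("hydraulic_network: duplicate node ids", call. = FALSE)
  if (!all(c(edges$from, edges$to) %in% nodes$id))
    stop("hydraulic_network: edge endpoint not among nodes", call. = FALSE)
  if (any(!is.finite(edges$resistance)) || any(edges$resistance <= 0))
    stop("hydraulic_network: every edge resistance must be > 0", call. = FALSE)
  # connectivity: every node must reach a boundary node through the edge graph
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  seen <- nodes$id[!is.na(nodes$pressure_pa)]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (!setequal(seen, nodes$id))
    stop("hydraulic_network: node(s) not connected to any boundary reservoir: ",
         paste(setdiff(nodes$id, seen), collapse = ", "), call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "hydraulic_network")
}

#' Solve the flow in a hydraulic network
#'
#' Solves Kirchhoff's node conservation equations with per-edge Poiseuille
#' law \eqn{Q = \Delta P / R}: interior node pressures are obtained from the
#' conductance Laplacian, then signed edge flows and per-node net fluxes are
#' reported. Interior node imbalance is checked against 1e-12 of the total
#' boundary inflow.
#'
#' @param network a [hydraulic_network()] with fixed pressures on at least
#'   two reservoir nodes.
#' @return An object of class `flow_solution` with elements `edges`
#'   (the edge table plus `flow_m3_s`, positive from -> to),
#'   `node_pressure_pa`, `node_net_flux_m3_s` and `total_inflow_m3_s`.
#' @export
solve_flow <- function(network) {
  stopifnot(inherits(network, "hydraulic_network"))
  nodes <- network$nodes; edges <- network$edges
  bset <- !is.na(nodes$pressure_pa)
  if (sum(bset) < 2)
    stop("solve_flow: boundary pressures required on at least 2 reservoirs",
         call. = FALSE)
  id <- nodes$id
  g <- 1 / edges$resistance
  n <- length(id)
  G <- matrix(0, n, n, dimnames = list(id, id))
  for (e in seq_len(nrow(edges))) {
    i <- edges$from[e]; j <- edges$to[e]
    G[i, j] <- G[i, j] - g[e]; G[j, i] <- G[j, i] - g[e]
    G[i, i] <- G[i, i] + g[e]; G[j, j] <- G[j, j] + g[e]
  }
  # solve in potentials shifted by the largest boundary pressure: edge
  # pressure drops that are tiny compared to the absolute head (e.g. across
  # low-resistance feed ports) would otherwise lose ~5 digits to cancellation
  shift <- max(nodes$pressure_pa[bset])
  phi <- nodes$pressure_pa - shift
  names(phi) <- id
  int <- id[!bset]
  if (length(int)) {
    rhs <- -G[int, id[bset], drop = FALSE] %*% phi[id[bset]]
    sol <- tryCatch(solve(G[int, int, drop = FALSE], rhs),
                    error = function(e) stop("solve_flow: singular system - ",
                                             "disconnected boundary?", call. = FALSE))
    phi[int] <- as.numeric(sol)
  }
  p <- phi + shift
  edges$flow_m3_s <- (phi[edges$from] - phi[edges$to]) / edges$resistance
  net <- stats::setNames(numeric(n), id)
  for (e in seq_len(nrow(edges))) {
    net[edges$from[e]] <- net[edges$from[e]] - edges$flow_m3_s[e]
    net[edges$to[e]] <- net[edges$to[e]] + edges$flow_m3_s[e]
  }
  inflow <- sum(pmax(net[bset], 0))
  imb <- if (length(int)) max(abs(net[int])) else 0
  if (inflow > 0 && imb > 1e-12 * inflow)
    warning("solve_flow: interior node imbalance ", signif(imb / inflow, 3),
            " of total inflow exceeds 1e-12")
  structure(list(edges = edges, node_pressure_pa = p, node_net_flux_m3_s = net,
                 total_inflow_m3_s = inflow,
                 rel_imbalance = if (inflow > 0) imb / inflow else 0),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("flow_solution:", nrow(x$edges), "edges, total inflow",
      signif(x$total_inflow_m3_s * 6e7, 4), "mL/min, rel. imbalance",
      signif(x$rel_imbalance, 2), "\n")
  invisible(x)
}

#' Hydraulic network of the gradient chip
#'
#' Both inlet reservoirs connect through short wide feed ports to a common
#' manifold; the culture channels run in parallel from the manifold to the
#' outlet, and the laminar gap layer - which overlies the whole hydrogel -
#' is modelled as one wide slit in parallel with the channels.
#'
#' @param geometry a [chip_geometry()].
#' @param fluid a [fluid_properties()].
#' @param delta_p_pa boundary pressure at the inlets relative to the outlet.
#' @param gap_depth_um gap depth override in micrometres; `0` removes the
#'   slit path (fully crosslinked chip). Defaults to the geometry's value.
#' @return A [hydraulic_network()].
#' @export
chip_network <- function(geometry, fluid = fluid_properties(), delta_p_pa,
                         gap_depth_um = geometry$gap_depth_um) {
  stopifnot(inherits(geometry, "chip_geometry"))
  if (gap_depth_um < 0) stop("chip_network: gap_depth_um must be >= 0", call. = FALSE)
  um <- 1e-6
  mu <- fluid$viscosity_pa_s
  r_feed <- rect_channel_resistance(geometry$feed$width_um * um,
                                    geometry$feed$depth_um * um,
                                    geometry$feed$length_um * um, mu)
  r_chan <- rect_channel_resistance(geometry$channels$width_um * um,
                                    geometry$channels$depth_um * um,
                                    geometry$channels$length_um * um, mu)
  nodes <- data.frame(id = c("inlet_left", "inlet_right", "manifold", "outlet"),
                      pressure_pa = c(delta_p_pa, delta_p_pa, NA, 0))
  edges <- data.frame(from = c("inlet_left", "inlet_right",
                               rep("manifold", geometry$channels$count)),
                      to = c("manifold", "manifold",
                             rep("outlet", geometry$channels$count)),
                      kind = c("rectangular_channel", "rectangular_channel",
                               rep("rectangular_channel", geometry$channels$count)),
                      resistance = c(r_feed, r_feed,
                                     rep(r_chan, geometry$channels$count)))
  if (gap_depth_um > 0) {
    r_gap <- rect_channel_resistance(geometry$footprint_width_um * um,
                                     gap_depth_um * um,
                                     geometry$channels$length_um * um, mu)
    edges <- rbind(edges, data.frame(from = "manifold", to = "outlet",
                                     kind = "slit_gap", resistance = r_gap))
  }
  hydraulic_network(nodes, edges)
}

#' Predict the chip perfusion rate
#'
#' Forward model: builds the chip's hydraulic network for a given laminar
#' gap depth and returns the total outlet flow under the hydrostatic head of
#' the tilted chip. Strictly increasing in `gap_depth_um`; at zero gap depth
#' it returns the channel-only baseline (about 0.12 mL/min for the default
#' geometry, whose channel depth is calibrated to that measured anchor).
#'
#' @param geometry a [chip_geometry()].
#' @param gap_depth_um laminar gap depth in micrometres (>= 0).
#' @param fluid a [fluid_properties()].
#' @param delta_p_pa driving pressure; if `NULL`, computed from
#'   `tilt_deg` and `separation_m` via [hydrostatic_pressure()].
#' @param tilt_deg,separation_m tilt measurement configuration (45 degrees,
#'   30 mm in-plane separation by default).
#' @return Perfusion rate in mL/min.
#' @export
predict_perfusion <- function(geometry, gap_depth_um = geometry$gap_depth_um,
                              fluid = fluid_properties(), delta_p_pa = NULL,
                              tilt_deg = 45, separation_m = 0.03) {
  if (gap_depth_um < 0) stop("predict_perfusion: gap_depth_um must be >= 0", call. = FALSE)
  if (is.null(delta_p_pa))
    delta_p_pa <- hydrostatic_pressure(separation_m, fluid, tilt_deg)
  sol <- solve_flow(chip_network(geometry, fluid, delta_p_pa, gap_depth_um))
  out <- sol$node_net_flux_m3_s[["outlet"]]
  out * 6e7   # m^3/s -> mL/min
}

#' Estimate the laminar gap depth from a measured perfusion rate
#'
#' Inverts the forward model [predict_perfusion()] by monotone root
#' bracketing: the perfusion rate increases strictly with gap depth, so the
#' measured rate determines the depth uniquely. A measurement at or below
#' the channel-only baseline returns 0 (with a warning when strictly
#' below); a measurement above the rate predicted at `h_max_um` cannot be
#' bracketed and raises an error.
#'
#' @param measured_mL_min measured perfusion rate in mL/min.
#' @param geometry a [chip_geometry()].
#' @param fluid a [fluid_properties()].
#' @param delta_p_pa,tilt_deg,separation_m as in [predict_perfusion()].
#' @param h_max_um upper end of the search bracket (default 500 um).
#' @param tol_um root tolerance in micrometres (default 1e-4).
#' @return Estimated gap depth in micrometres.
#' @examples
#' geom <- chip_geometry()
#' q <- predict_perfusion(geom, 92.6)
#' estimate_gap_depth(q, geom)  # 92.6 within 1e-3
#' @export
estimate_gap_depth <- function(measured_mL_min, geometry,
                               fluid = fluid_properties(), delta_p_pa = NULL,
                               tilt_deg = 45, separation_m = 0.03,
                               h_max_um = 500, tol_um = 1e-4) {
  if (is.null(delta_p_pa))
    delta_p_pa <- hydrostatic_pressure(separation_m, fluid, tilt_deg)
  f <- function(h) predict_perfusion(geometry, h, fluid, delta_p_pa) - measured_mL_min
  f0 <- f(0)
  if (f0 >= 0) {
    if (f0 > 0)
      warning("estimate_gap_depth: measured perfusion below the channel-only ",
              "baseline; returning 0")
    return(0)
  }
  if (f(h_max_um) < 0)
    stop("estimate_gap_depth: measured perfusion exceeds the forward model at ",
         "h_max_um = ", h_max_um, " um; root not bracketable (raise h_max_um)",
         call. = FALSE)
  stats::uniroot(f, c(0, h_max_um), tol = tol_um)$root
}
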