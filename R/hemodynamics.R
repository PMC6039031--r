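# Unit conversions at the interface: pressures are mmHg, internal pressure
# unit is dyn/cm^2; viscosities are cP, internal unit Poise.
MMHG_TO_DYN_CM2 <- 1333.22
CP_TO_POISE <- 0.01

#' Diameter-dependent apparent blood viscosity
#'
#' Empirical in-vitro law for the apparent viscosity of blood in narrow tubes
#' at a fixed hematocrit of 45% (the Fahraeus-Lindqvist effect):
#' `mu(d) = 220 exp(-1.3 d) + 3.2 - 2.44 exp(-0.06 d^0.645)` centipoise,
#' with the diameter `d` in micrometres. Viscosity falls towards a minimum
#' near capillary diameters and approaches the bulk value 3.2 cP in wide
#' tubes.
#'
#' @param d_um Vessel diameter in micrometres (> 0), vectorized.
#' @return Apparent viscosity in cP.
#' @examples
#' blood_viscosity(10) # ~ 1.33 cP
#' @export
blood_viscosity <- function(d_um) {
  if (!all(d_um > 0)) stop("diameter must be positive")
  220 * exp(-1.3 * d_um) + 3.2 - 2.44 * exp(-0.06 * d_um^0.645)
}

#' Hagen-Poiseuille hydraulic conductance of a vessel
#'
#' Laminar flow in a straight cylinder obeys `dP = 8 mu L Q / (pi r^4)`, so
#' the flow per unit pressure drop is `pi r^4 / (8 mu L)`.
#'
#' @param length_cm Vessel length (cm).
#' @param radius_cm Vessel radius (cm).
#' @param viscosity_cP Apparent viscosity (cP).
#' @return Conductance in cm^3 s^-1 per dyn cm^-2. Multiply by a pressure
#'   drop in dyn/cm^2 (mmHg x 1333.22) to get a flow in cm^3/s.
#' @export
poiseuille_conductance <- function(length_cm, radius_cm, viscosity_cP) {
  if (!all(length_cm > 0) || !all(radius_cm > 0) || !all(viscosity_cP > 0))
    stop("length, radius and viscosity must be positive")
  pi * radius_cm^4 / (8 * viscosity_cP * CP_TO_POISE * length_cm)
}

edge_conductances <- function(graph) {
  e <- graph$edges
  mu <- blood_viscosity(2 * e$radius_cm * 1e4)
  poiseuille_conductance(e$length_cm, e$radius_cm, mu)
}

#' Solve nodal blood pressures by Kirchhoff balance
#'
#' Entrance nodes are held at `delta_P` mmHg and exit nodes at 0; every
#' interior node satisfies conservation of flow with Hagen-Poiseuille edge
#' conductances, each vessel's viscosity evaluated at its own diameter. The
#' lateral surfaces carry no prescribed flux: no-flow boundaries arise
#' naturally from the graph. The interior system is symmetric positive
#' definite and solved by a sparse Cholesky factorization.
#'
#' @param graph A `vessel_graph`.
#' @param delta_P Pressure drop across the network (mmHg).
#' @return Tibble `node`, `pressure_mmHg`.
#' @export
solve_pressures <- function(graph, delta_P) {
  stopifnot(inherits(graph, "vessel_graph"), delta_P >= 0)
  nodes <- graph$nodes
  edges <- graph$edges
  nn <- nrow(nodes)
  g <- edge_conductances(graph)
  entr <- nodes$id[nodes$role == "entrance"]
  exit <- nodes$id[nodes$role == "exit"]
  if (length(entr) == 0 || length(exit) == 0)
    stop("graph has no entrance or exit nodes")
  fixed <- c(entr, exit)
  p_fixed <- c(rep(delta_P, length(entr)), rep(0, length(exit)))
  free <- setdiff(seq_len(nn), fixed)

  # Weighted graph Laplacian, assembled sparse.
  L <- Matrix::sparseMatrix(
    i = c(edges$u, edges$v, edges$u, edges$v),
    j = c(edges$v, edges$u, edges$u, edges$v),
    x = c(-g, -g, g, g),
    dims = c(nn, nn)
  )
  p <- numeric(nn)
  p[fixed] <- p_fixed
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    # A disconnected interior component never touches a boundary node and
    # makes A singular; name it rather than failing opaquely.
    b <- -L[free, fixed, drop = FALSE] %*% p_fixed
    sol <- tryCatch(Matrix::solve(A, b), error = function(e) {
      comp <- igraph::components(igraph::graph_from_edgelist(
        cbind(edges$u, edges$v), directed = FALSE))
      bad <- setdiff(unique(comp$membership[free]), comp$membership[fixed])
      stop("pressure system is singular; component(s) without boundary nodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    })
    p[free] <- as.numeric(sol)
  }
  tibble::tibble(node = nodes$id, pressure_mmHg = p)
}

#' Orient edge flows from a pressure solution
#'
#' Computes each vessel's volumetric flow `Q = g * dp` from the pressure drop
#' along it, orients edges from high to low pressure, derives the transit
#' rate `f = Q / (pi r^2 L)` (reciprocal transit time), and flags stagnant
#' vessels whose flow magnitude falls below `stagnant_tol * max |Q|` (these
#' get `f = 0` and are excluded from parent relations).
#'
#' @param graph A `vessel_graph`.
#' @param pressures Output of [solve_pressures()].
#' @param delta_P The pressure drop used (mmHg), stored for reporting.
#' @param stagnant_tol Relative flow tolerance below which a vessel is
#'   treated as stagnant.
#' @return A `flow_solution`: list with the `graph`, the `pressures` tibble,
#'   an `edges` tibble (`edge, up_node, down_node, flow_cm3_s, transit_rate_s,
#'   stagnant`), and `total_flow_mL_min`.
#' @export
edge_flows <- function(graph, pressures, delta_P = NA_real_,
                       stagnant_tol = 1e-12) {
  stopifnot(inherits(graph, "vessel_graph"))
  e <- graph$edges
  p <- pressures$pressure_mmHg[order(pressures$node)]
  g <- edge_conductances(graph)
  dp <- p[e$u] - p[e$v]
  q <- g * abs(dp) * MMHG_TO_DYN_CM2
  up <- ifelse(dp >= 0, e$u, e$v)
  down <- ifelse(dp >= 0, e$v, e$u)
  stagnant <- q <= stagnant_tol * max(q)
  vol <- vessel_volumes(graph)
  f <- ifelse(stagnant, 0, q / vol)
  q[stagnant] <- 0
  fe <- tibble::tibble(
    edge = e$edge, up_node = up, down_node = down,
    flow_cm3_s = q, transit_rate_s = f, volume_cm3 = vol,
    stagnant = stagnant
  )
  sol <- structure(list(graph = graph, pressures = pressures, edges = fe,
                        delta_P = delta_P),
                   class = "flow_solution")
  sol$total_flow_mL_min <- total_flow(sol)
  sol
}

#' Solve the full flow problem on a vessel graph
#'
#' Convenience wrapper: [solve_pressures()] then [edge_flows()].
#'
#' @inheritParams solve_pressures
#' @inheritParams edge_flows
#' @return A `flow_solution`.
#' @export
solve_flow <- function(graph, delta_P, stagnant_tol = 1e-12) {
  p <- solve_pressures(graph, delta_P)
  edge_flows(graph, p, delta_P = delta_P, stagnant_tol = stagnant_tol)
}

#' Total network perfusion
#'
#' Sum of the outflows from all entrance nodes, in mL/min. By conservation
#' this equals the total inflow into the exit nodes.
#'
#' @param flow A `flow_solution`.
#' @return Perfusion in mL min^-1.
#' @export
total_flow <- function(flow) {
  stopifnot(inherits(flow, "flow_solution"))
  entr <- flow$graph$nodes$id[flow$graph$nodes$role == "entrance"]
  fe <- flow$edges
  out <- sum(fe$flow_cm3_s[fe$up_node %in% entr]) -
    sum(fe$flow_cm3_s[fe$down_node %in% entr])
  out * 60
}

# Signed net flow imbalance (cm^3/s) at every node; ~0 at interior nodes.
node_residuals <- function(flow) {
  fe <- flow$edges
  nn <- nrow(flow$graph$nodes)
  infl <- tapply(fe$flow_cm3_s, factor(fe$down_node, levels = seq_len(nn)), sum,
                 default = 0)
  outf <- tapply(fe$flow_cm3_s, factor(fe$up_node, levels = seq_len(nn)), sum,
                 default = 0)
  as.numeric(infl) - as.numeric(outf)
}

#' Kirchhoff residual of a flow solution
#'
#' Maximum absolute net flow imbalance over interior nodes, relative to the
#' total network inflow. Solver quality metric; should be at machine-
#' precision level (<= 1e-10).
#'
#' @param flow A `flow_solution`.
#' @return Dimensionless relative residual.
#' @export
kirchhoff_residual <- function(flow) {
  res <- node_residuals(flow)
  interior <- flow$graph$nodes$role == "interior"
  total_in <- flow$total_flow_mL_min / 60
  max(abs(res[interior])) / total_in
}

#' Tidy a flow solution into its per-edge table
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return The per-edge tibble with radii and lengths joined on.
#' @export
tidy.flow_solution <- function(x, ...) {
  x$edges |>
    dplyr::left_join(x$graph$edges[, c("edge", "length_cm", "radius_cm")],
                     by = "edge")
}

#' One-row summary of a flow solution
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return Tibble with pressure drop, perfusion, stagnant count, residual.
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(
    delta_P_mmHg = x$delta_P,
    total_flow_mL_min = x$total_flow_mL_min,
    n_edges = nrow(x$edges),
    n_stagnant = sum(x$edges$stagnant),
    kirchhoff_residual = kirchhoff_residual(x)
  )
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %d vessels, dP = %g mmHg, Q = %.4g mL/min, %d stagnant\n",
    nrow(x$edges), x$delta_P, x$total_flow_mL_min, sum(x$edges$stagnant)))
  invisible(x)
}

# Parent sets: for each edge, the indices (into the edge table) of the
# non-stagnant edges whose flow enters its upstream node. Also marks edges
# fed directly from an entrance node.
flow_parents <- function(flow) {
  fe <- flow$edges
  entr <- flow$graph$nodes$id[flow$graph$nodes$role == "entrance"]
  active <- which(!fe$stagnant)
  by_down <- split(active, fe$down_node[active])
  parents <- lapply(seq_len(nrow(fe)), function(i) {
    if (fe$stagnant[i]) return(integer(0))
    p <- by_down[[as.character(fe$up_node[i])]]
    if (is.null(p)) integer(0) else p
  })
  list(parents = parents, entrance_fed = fe$up_node %in% entr & !fe$stagnant)
}
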