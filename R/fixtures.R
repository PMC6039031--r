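#' Deterministic small test networks with oracle solutions
#'
#' Named tiny vessel graphs used for cross-module validation, each packaged
#' with independently computed reference quantities:
#'
#' * `"single"` — one vessel from an entrance to an exit; the oracle flow is
#'   the closed-form Hagen-Poiseuille flow.
#' * `"chain2"` — two equal vessels in series; by symmetry the middle node
#'   sits at half the applied pressure drop.
#' * `"g1_uniform"` — the `n = 1` lattice with all radii equal and two
#'   entrance / two exit corners; oracle pressures come from a dense solve
#'   of the 4-unknown interior system assembled here from first principles.
#' * `"g2_seeded"` — the `n = 2` lattice with seeded Gamma radii; intended
#'   for steady-state cross-checks against time integration.
#'
#' @param name Fixture id.
#' @param delta_P Pressure drop (mmHg) used for the stored oracles.
#' @return List with `graph`, `delta_P` and fixture-specific oracle fields
#'   (`oracle_pressures`, `oracle_flow_cm3_s`, ...).
#' @export
make_fixture <- function(name = c("single", "chain2", "g1_uniform", "g2_seeded"),
                         delta_P = 100) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture; available: single, chain2, g1_uniform, g2_seeded"))
  switch(name,
    single = fixture_single(delta_P),
    chain2 = fixture_chain2(delta_P),
    g1_uniform = fixture_g1_uniform(delta_P),
    g2_seeded = fixture_g2_seeded(delta_P)
  )
}

fixture_single <- function(delta_P) {
  r <- 3.9e-4; L <- 1
  nodes <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                          role = c("entrance", "exit"))
  edges <- tibble::tibble(edge = 1L, u = 1L, v = 2L, length_cm = L,
                          radius_cm = r)
  graph <- vessel_graph(nodes, edges, side = 1)
  mu <- blood_viscosity(2 * r * 1e4)
  q <- pi * r^4 * delta_P * 1333.22 / (8 * mu * 0.01 * L)
  list(graph = graph, delta_P = delta_P, oracle_flow_cm3_s = q,
       oracle_transit_rate_s = q / (pi * r^2 * L))
}

fixture_chain2 <- function(delta_P) {
  r <- 5e-4
  nodes <- tibble::tibble(id = 1:3, x = c(0, 0.5, 1), y = 0, z = 0,
                          role = c("entrance", "interior", "exit"))
  edges <- tibble::tibble(edge = 1:2, u = c(1L, 2L), v = c(2L, 3L),
                          length_cm = 0.5, radius_cm = r)
  graph <- vessel_graph(nodes, edges, side = 1)
  list(graph = graph, delta_P = delta_P,
       oracle_pressures = c(delta_P, delta_P / 2, 0))
}

# n = 1 cube, equal radii, entrances {(0,0,0),(0,1,1)}, exits {(1,0,1),(1,1,0)}.
# The 4 remaining corners are interior unknowns; with unit conductances the
# balance at an interior node with neighbours N is 3 p - sum(p_N) = 0. The
# oracle assembles and solves that dense 4x4 system directly.
fixture_g1_uniform <- function(delta_P) {
  n <- 1
  nodes <- lattice_nodes(n, 1)
  edges <- lattice_edges(n)
  edges$length_cm <- 1
  edges$radius_cm <- 4e-4
  nodes$role <- "interior"
  idx <- function(ix, iy, iz) node_index(ix, iy, iz, n)
  nodes$role[c(idx(0, 0, 0), idx(0, 1, 1))] <- "entrance"
  nodes$role[c(idx(1, 0, 1), idx(1, 1, 0))] <- "exit"
  graph <- vessel_graph(nodes, edges, side = 1, n = n)

  free <- which(nodes$role == "interior")
  fixed_p <- ifelse(nodes$role == "entrance", delta_P, 0)
  A <- matrix(0, length(free), length(free))
  b <- numeric(length(free))
  for (k in seq_along(free)) {
    node <- free[k]
    nb <- c(edges$v[edges$u == node], edges$u[edges$v == node])
    A[k, k] <- length(nb)
    for (nbh in nb) {
      pos <- match(nbh, free)
      if (is.na(pos)) b[k] <- b[k] + fixed_p[nbh] else A[k, pos] <- A[k, pos] - 1
    }
  }
  p <- fixed_p
  p[free] <- solve(A, b)
  list(graph = graph, delta_P = delta_P, oracle_pressures = p)
}

fixture_g2_seeded <- function(delta_P) {
  graph <- build_lattice(lattice_spec(2, seed = 42L))
  list(graph = graph, delta_P = delta_P)
}
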