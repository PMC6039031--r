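#' Calibrated mean vessel radius for a lattice level
#'
#' The lattice `G_n` subdivides a cube of side `side` cm into `n^3` sub-cubes
#' and carries `3n(n+1)^2` vessels of length `side/n`. Requiring the total
#' nominal vessel volume to be a fixed fraction `1/B` of the tissue volume,
#' `3(n+1)^2 * pi * rbar^2 = 1/B`, pins the mean radius to
#'
#' \deqn{\bar r = \frac{1}{(n+1)\sqrt{3\pi B}}}
#'
#' which for the default tissue:vessel volume ratio `B = 30` is
#' `1/((n+1) sqrt(90 pi))`. At `n = 149` this gives the anatomical
#' capillary-scale mean radius of about 3.9 um.
#'
#' @param n Subdivision level (positive integer).
#' @param volume_ratio_B Tissue:vessel volume ratio (dimensionless, > 0).
#' @param side Cube edge length in cm.
#' @return Mean radius in cm.
#' @examples
#' mean_radius(149) * 1e4 # ~ 3.9 um
#' @export
mean_radius <- function(n, volume_ratio_B = 30, side = 1) {
  stopifnot(is.numeric(n), all(n >= 1), is.numeric(volume_ratio_B),
            all(volume_ratio_B > 0), side > 0)
  side / ((n + 1) * sqrt(3 * pi * volume_ratio_B))
}

#' Gamma radius model for a lattice level
#'
#' Vessel radii are drawn from a Gamma distribution with shape `alpha` and
#' rate `beta = alpha / rbar`, so that the expectation equals the calibrated
#' [mean_radius()]. The default shape `alpha = 5` matches the right-skewed
#' radius histograms reported for human cortical microvasculature
#' (skewness `2/sqrt(alpha) ~ 0.89`).
#'
#' @param n Subdivision level.
#' @param alpha Gamma shape parameter.
#' @inheritParams mean_radius
#' @return A list with class `radius_model`: `alpha`, `beta` (1/cm),
#'   `mean_radius` (cm).
#' @export
radius_model <- function(n, alpha = 5, volume_ratio_B = 30, side = 1) {
  stopifnot(alpha > 0)
  rbar <- mean_radius(n, volume_ratio_B, side)
  structure(list(alpha = alpha, beta = alpha / rbar, mean_radius = rbar),
            class = "radius_model")
}

#' Sample vessel radii from a radius model
#'
#' @param count Number of radii to draw.
#' @param model A [radius_model()].
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return Numeric vector of radii in cm.
#' @export
sample_radii <- function(count, model, seed = NULL) {
  stopifnot(is.numeric(count), count >= 1, inherits(model, "radius_model"))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  stats::rgamma(count, shape = model$alpha, rate = model$beta)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Nominal vessel exchange area of a lattice level
#'
#' Lateral cylinder area of all `3n(n+1)^2` vessels of length `side/n` at the
#' calibrated mean radius; for `B = 30`, `side = 1` this simplifies to
#' `6 (n+1) sqrt(pi/90)` cm^2. This is the blood-tissue interface through
#' which carrier transport acts, and the abscissa of the scaling analysis.
#'
#' @inheritParams mean_radius
#' @return Area in cm^2.
#' @export
exchange_area_nominal <- function(n, volume_ratio_B = 30, side = 1) {
  stopifnot(all(n >= 1))
  3 * n * (n + 1)^2 * 2 * pi * mean_radius(n, volume_ratio_B, side) * (side / n)
}

#' Lattice specification
#'
#' Bundles the parameters that define one lattice realization.
#'
#' @param n Subdivision level (>= 1).
#' @param side Cube edge length (cm).
#' @param alpha Gamma shape for the radius distribution.
#' @param volume_ratio_B Tissue:vessel volume ratio.
#' @param entrance_fraction Fraction of each flow face's nodes designated
#'   entrances (on `x = 0`) and exits (on `x = side`).
#' @param entrance_mode `"checkerboard"` (deterministic parity rule) or
#'   `"random"` (seeded).
#' @param seed Integer seed for radius sampling (and random boundary mode).
#' @return A list with class `lattice_spec`.
#' @export
lattice_spec <- function(n, side = 1, alpha = 5, volume_ratio_B = 30,
                         entrance_fraction = 0.5,
                         entrance_mode = c("checkerboard", "random"),
                         seed = 1L) {
  entrance_mode <- match.arg(entrance_mode)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == floor(n),
            side > 0, alpha > 0, volume_ratio_B > 0,
            entrance_fraction > 0, entrance_fraction <= 1)
  structure(list(n = as.integer(n), side = side, alpha = alpha,
                 volume_ratio_B = volume_ratio_B,
                 entrance_fraction = entrance_fraction,
                 entrance_mode = entrance_mode, seed = as.integer(seed)),
            class = "lattice_spec")
}

# Node table of the bare lattice: ids are 1-based, lexicographic in (ix,iy,iz).
lattice_nodes <- function(n, side) {
  g <- expand.grid(iz = 0:n, iy = 0:n, ix = 0:n)
  tibble::tibble(
    id = seq_len((n + 1)^3),
    ix = g$ix, iy = g$iy, iz = g$iz,
    x = g$ix * side / n, y = g$iy * side / n, z = g$iz * side / n
  )
}

node_index <- function(ix, iy, iz, n) {
  ix * (n + 1)^2 + iy * (n + 1) + iz + 1L
}

# Edge table: all axis-aligned unit steps, deterministic order (x-, y-, z-
# direction blocks, each lexicographic in the lower endpoint).
lattice_edges <- function(n) {
  step <- function(dx, dy, dz) {
    g <- expand.grid(iz = 0:(n - dz), iy = 0:(n - dy), ix = 0:(n - dx))
    tibble::tibble(
      u = node_index(g$ix, g$iy, g$iz, n),
      v = node_index(g$ix + dx, g$iy + dy, g$iz + dz, n)
    )
  }
  e <- dplyr::bind_rows(step(1, 0, 0), step(0, 1, 0), step(0, 0, 1))
  e$edge <- seq_len(nrow(e))
  e[, c("edge", "u", "v")]
}

#' Designate entrance and exit nodes on the flow faces
#'
#' Marks `floor(fraction * (n+1)^2)` nodes on the face `x = 0` as entrances
#' and the same count on `x = side` as exits. The default checkerboard mode
#' takes nodes of even `(iy + iz)` parity first (ordered lexicographically),
#' a deterministic rule; `"random"` draws a seeded sample.
#'
#' @param graph A `vessel_graph`.
#' @param fraction Fraction of face nodes to select, in (0, 1].
#' @param mode `"checkerboard"` or `"random"`.
#' @param seed Seed for random mode.
#' @return The graph with updated `role` column (`entrance`, `exit`,
#'   `interior`) in its node table.
#' @export
select_boundary_nodes <- function(graph, fraction = 0.5,
                                  mode = c("checkerboard", "random"),
                                  seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "vessel_graph"), fraction > 0, fraction <= 1)
  nodes <- graph$nodes
  side <- graph$side
  pick_face <- function(face_nodes, count, which_seed) {
    if (mode == "checkerboard") {
      ord <- order((face_nodes$iy + face_nodes$iz) %% 2, face_nodes$iy,
                   face_nodes$iz)
      face_nodes$id[ord][seq_len(count)]
    } else {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(which_seed)
      sample(face_nodes$id, count)
    }
  }
  entr_face <- nodes[nodes$x == 0, ]
  exit_face <- nodes[nodes$x == side, ]
  count <- floor(fraction * nrow(entr_face))
  if (count < 1) stop("entrance fraction selects no nodes")
  entrances <- pick_face(entr_face, count, seed)
  exits <- pick_face(exit_face, count, seed + 1L)
  nodes$role <- "interior"
  nodes$role[nodes$id %in% entrances] <- "entrance"
  nodes$role[nodes$id %in% exits] <- "exit"
  graph$nodes <- nodes
  graph
}

#' Reassign radii so that boundary-near vessels are wider
#'
#' Capillary beds taper away from feeding and draining vessels, so vessels
#' further from any entrance or exit node should have smaller radii. Each
#' edge's boundary distance is the minimum hop count from either endpoint to
#' the nearest entrance-or-exit node; the sampled radii are then reassigned
#' by rank: sorted descending and handed out in order of increasing boundary
#' distance (ties broken by edge index). The multiset of radii is unchanged,
#' so the Gamma marginal distribution is preserved exactly.
#'
#' @param graph A `vessel_graph` with radii sampled and roles assigned.
#' @return The graph with permuted `radius_cm` and a `boundary_dist` column.
#' @export
enforce_radius_monotonicity <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  nodes <- graph$nodes
  edges <- graph$edges
  boundary <- nodes$id[nodes$role %in% c("entrance", "exit")]
  if (length(boundary) == 0) stop("no entrance/exit nodes designated")
  nd <- node_hop_distances(edges, nrow(nodes), boundary)
  edist <- pmin(nd[edges$u], nd[edges$v])
  ord <- order(edist, edges$edge)
  new_r <- numeric(nrow(edges))
  new_r[ord] <- sort(edges$radius_cm, decreasing = TRUE)
  edges$radius_cm <- new_r
  edges$boundary_dist <- edist
  graph$edges <- edges
  graph
}

# Multi-source unweighted hop distance from `sources` to every node, via a
# super-source BFS in igraph.
node_hop_distances <- function(edges, n_nodes, sources) {
  super <- n_nodes + 1L
  el <- rbind(cbind(edges$u, edges$v), cbind(rep(super, length(sources)), sources))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  d <- igraph::distances(g, v = super, weights = NA)[1, ]
  as.numeric(d[seq_len(n_nodes)]) - 1
}

#' Build a calibrated cubic-lattice vessel graph
#'
#' Constructs `G_n`: `(n+1)^3` nodes on the regular grid of a cube of side
#' `side` cm, `3n(n+1)^2` axis-aligned vessels of length `side/n`, radii
#' drawn from the calibrated Gamma model and reordered by
#' [enforce_radius_monotonicity()], with entrance/exit nodes designated on
#' the faces `x = 0` and `x = side` by [select_boundary_nodes()].
#'
#' @param spec A [lattice_spec()], or a level `n` (other arguments default).
#' @param ... Passed to [lattice_spec()] when `spec` is given as a number.
#' @return A `vessel_graph`: list with tibbles `nodes`
#'   (`id, ix, iy, iz, x, y, z, role`) and `edges`
#'   (`edge, u, v, length_cm, radius_cm, boundary_dist`), plus `side`, `n`,
#'   and the originating `spec`.
#' @examples
#' g <- build_lattice(2, seed = 1)
#' nrow(g$nodes) # 27
#' nrow(g$edges) # 54
#' @export
build_lattice <- function(spec, ...) {
  if (!inherits(spec, "lattice_spec")) spec <- lattice_spec(spec, ...)
  n <- spec$n
  nodes <- lattice_nodes(n, spec$side)
  edges <- lattice_edges(n)
  edges$length_cm <- spec$side / n
  model <- radius_model(n, spec$alpha, spec$volume_ratio_B, spec$side)
  edges$radius_cm <- sample_radii(nrow(edges), model, seed = spec$seed)
  nodes$role <- "interior"
  graph <- structure(list(nodes = nodes, edges = edges, side = spec$side,
                          n = n, spec = spec),
                     class = "vessel_graph")
  graph <- select_boundary_nodes(graph, spec$entrance_fraction,
                                 spec$entrance_mode, seed = spec$seed + 7L)
  enforce_radius_monotonicity(graph)
}

#' Assemble a vessel graph from node and edge tables
#'
#' For user-supplied (non-lattice) networks. Validates positivity of lengths
#' and radii, presence of boundary roles, and connectivity.
#'
#' @param nodes Tibble with at least `id`, `x`, `y`, `z`, `role`.
#' @param edges Tibble with at least `u`, `v`, `length_cm`, `radius_cm`.
#' @param side Physical extent (cm), used for slice profiles.
#' @param n Lattice level if applicable, else `NA`.
#' @return A `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges, side = 1, n = NA_integer_) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  required_n <- c("id", "x", "y", "z", "role")
  required_e <- c("u", "v", "length_cm", "radius_cm")
  miss <- setdiff(required_n, names(nodes))
  if (length(miss)) stop("node table missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(required_e, names(edges))
  if (length(miss)) stop("edge table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(edges$length_cm > 0)) stop("all edge lengths must be positive")
  if (!all(edges$radius_cm > 0)) stop("all edge radii must be positive")
  if (!any(nodes$role == "entrance") || !any(nodes$role == "exit"))
    stop("graph must designate entrance and exit nodes")
  if (!"edge" %in% names(edges)) edges$edge <- seq_len(nrow(edges))
  g <- igraph::graph_from_edgelist(cbind(edges$u, edges$v), directed = FALSE)
  if (igraph::components(g)$no > 1) stop("vessel graph is not connected")
  structure(list(nodes = nodes, edges = edges, side = side,
                 n = if (is.na(n)) NA_integer_ else as.integer(n), spec = NULL),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  ne <- sum(x$nodes$role == "entrance")
  nx <- sum(x$nodes$role == "exit")
  cat(sprintf(
    "<vessel_graph> %d nodes, %d edges%s; %d entrances / %d exits; side %g cm\n",
    nrow(x$nodes), nrow(x$edges),
    if (!is.na(x$n)) sprintf(" (lattice n = %d)", x$n) else "", ne, nx, x$side))
  cat(sprintf("  mean radius %.3g um, total vessel volume %.4g cm^3\n",
              mean(x$edges$radius_cm) * 1e4, sum(vessel_volumes(x))))
  invisible(x)
}

#' Per-vessel blood volumes
#'
#' Cylinder volumes `pi r^2 L` per edge.
#'
#' @param graph A `vessel_graph`.
#' @return Numeric vector (cm^3) aligned with the edge table.
#' @export
vessel_volumes <- function(graph) {
  with(graph$edges, pi * radius_cm^2 * length_cm)
}

#' Tidy a vessel graph into its edge table
#'
#' @param x A `vessel_graph`.
#' @param ... Unused.
#' @return The edge tibble with endpoint coordinates joined on.
#' @export
tidy.vessel_graph <- function(x, ...) {
  nd <- x$nodes[, c("id", "x", "y", "z")]
  x$edges |>
    dplyr::left_join(dplyr::rename(nd, u = "id", x0 = "x", y0 = "y", z0 = "z"),
                     by = "u") |>
    dplyr::left_join(dplyr::rename(nd, v = "id", x1 = "x", y1 = "y", z1 = "z"),
                     by = "v")
}
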