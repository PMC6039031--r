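#' Carrier transport parameters
#'
#' Parameters of the saturable blood-brain-barrier transport and clearance
#' model. Defaults are mid-range literature values for L-Dopa carried by the
#' LAT1 transporter: maximal transport rate `k1` (uM/s), half-saturation
#' concentration `K` (uM), tissue clearance/metabolism rate `k2` (1/s),
#' tissue:vessel volume ratio `B`, and entrance blood concentration `v0`
#' (uM). `target_set` optionally restricts the aggregate tissue amount to a
#' vessel subset (edge indices); `NULL` means all vessels.
#'
#' @param k1 Maximal transport rate, uM s^-1 (>= 0).
#' @param K Half-saturation concentration, uM (> 0).
#' @param k2 Clearance rate, s^-1 (>= 0).
#' @param B Tissue:vessel volume ratio (> 0).
#' @param v0 Entrance blood concentration, uM (> 0).
#' @param target_set Optional integer vector of edge indices.
#' @param flow_weighted_mixing Use flow-weighted instead of volume-weighted
#'   parent averaging at confluences (sensitivity analysis only; the model's
#'   stated mixing rule is volume-weighted).
#' @return A list with class `transport_params`.
#' @export
transport_params <- function(k1 = 0.3, K = 101, k2 = 3.25e-2, B = 30, v0 = 5,
                             target_set = NULL, flow_weighted_mixing = FALSE) {
  stopifnot(k1 >= 0, K > 0, k2 >= 0, B > 0, v0 > 0)
  structure(list(k1 = k1, K = K, k2 = k2, B = B, v0 = v0,
                 target_set = target_set,
                 flow_weighted_mixing = isTRUE(flow_weighted_mixing)),
            class = "transport_params")
}

# Mixing weights for parent averaging: vessel volumes (the model's rule) or
# flows (optional sensitivity variant).
mixing_weights <- function(flow, params) {
  if (params$flow_weighted_mixing) flow$edges$flow_cm3_s
  else flow$edges$volume_cm3
}

#' Right-hand side of the per-vessel transport ODE system
#'
#' For vessel `i` with blood concentration `v_i` and tissue concentration
#' `w_i`:
#' \deqn{dv_i/dt = -f_i v_i - k_1 v_i/(K + v_i) + f_i c_{in,i}}
#' \deqn{B\, dw_i/dt = k_1 v_i/(K + v_i) - k_2 w_i}
#' where `f_i` is the transit rate and the inflow concentration `c_in` is
#' the volume-weighted average of the parent vessels' blood concentrations,
#' or the constant entrance concentration `v0` for vessels fed directly from
#' an entrance node. Stagnant vessels have `f = 0`.
#'
#' @param v,w Numeric vectors of blood and tissue concentrations (uM), one
#'   per vessel.
#' @param flow A `flow_solution`.
#' @param params A [transport_params()].
#' @param structure Optional precomputed [flow_parents()] output (internal
#'   speed-up for repeated evaluation).
#' @return List with `dv` and `dw` (uM/s).
#' @export
transport_rhs <- function(v, w, flow, params, structure = NULL) {
  m <- nrow(flow$edges)
  if (length(v) != m || length(w) != m)
    stop("state dimensions do not match the number of vessels")
  if (is.null(structure)) structure <- flow_parents(flow)
  f <- flow$edges$transit_rate_s
  wt <- mixing_weights(flow, params)
  c_in <- vapply(seq_len(m), function(i) {
    if (structure$entrance_fed[i]) return(params$v0)
    p <- structure$parents[[i]]
    if (length(p) == 0) return(0)
    sum(wt[p] * v[p]) / sum(wt[p])
  }, numeric(1))
  uptake <- params$k1 * v / (params$K + v)
  list(dv = -f * v - uptake + f * c_in,
       dw = (uptake - params$k2 * w) / params$B)
}

# Edge processing order for the sweep: decreasing upstream-node pressure.
# Pressure strictly decreases along flow, so every (non-stagnant) parent of
# an edge precedes it. Stagnant edges are excluded.
sweep_order <- function(flow) {
  p <- flow$pressures$pressure_mmHg[order(flow$pressures$node)]
  active <- which(!flow$edges$stagnant)
  active[order(-p[flow$edges$up_node[active]], active)]
}

#' Steady state by topological sweep
#'
#' The flow orientation is acyclic, so the steady state of the transport
#' system can be found in one pass over the vessels in flow order. For each
#' vessel, the inflow concentration `c_in` is the (volume-weighted) parent
#' average, or `v0` for entrance-fed vessels; the blood concentration solves
#' the flow/uptake balance `f (c_in - v) = k1 v/(K + v)`, i.e. the unique
#' nonnegative root of `v^2 + (K + k1/f - c_in) v - K c_in = 0`, and the
#' tissue concentration follows as `w = k1 v / (k2 (K + v))`. Stagnant
#' vessels carry no drug at equilibrium (`v = w = 0`) and are excluded from
#' parent averages.
#'
#' @inheritParams transport_rhs
#' @return A `steady_state`: list with a per-vessel tibble `vessels`
#'   (`edge, v_uM, w_uM, volume_cm3, stagnant`), the aggregate tissue amount
#'   `W` (uM cm^3), the `params` and the `flow`.
#' @export
steady_state_sweep <- function(flow, params = transport_params()) {
  stopifnot(inherits(flow, "flow_solution"), inherits(params, "transport_params"))
  fe <- flow$edges
  m <- nrow(fe)
  structure_ <- flow_parents(flow)
  parents <- structure_$parents
  entrance_fed <- structure_$entrance_fed
  f <- fe$transit_rate_s
  wt <- mixing_weights(flow, params)
  k1 <- params$k1; K <- params$K; k2 <- params$k2; v0 <- params$v0
  v <- numeric(m)
  for (i in sweep_order(flow)) {
    p <- parents[[i]]
    c_in <- if (entrance_fed[i]) v0
            else if (length(p) == 0) 0
            else sum(wt[p] * v[p]) / sum(wt[p])
    if (c_in <= 0) next
    if (k1 == 0) { v[i] <- c_in; next }
    b <- K + k1 / f[i] - c_in
    v[i] <- (-b + sqrt(b * b + 4 * K * c_in)) / 2
  }
  w <- if (k2 > 0) k1 * v / (k2 * (K + v)) else rep(0, m)
  new_steady_state(v, w, flow, params)
}

new_steady_state <- function(v, w, flow, params) {
  vessels <- tibble::tibble(
    edge = flow$edges$edge, v_uM = v, w_uM = w,
    volume_cm3 = flow$edges$volume_cm3, stagnant = flow$edges$stagnant
  )
  st <- structure(list(vessels = vessels, params = params, flow = flow),
                  class = "steady_state")
  st$W <- aggregate_w(st)
  st
}

#' Aggregate tissue drug amount
#'
#' `W = B * sum_{i in T} V_i w_i` (uM cm^3) over the target vessel set `T`
#' (default: all vessels). Under the `B = 30` volume calibration the served
#' tissue volume is the whole cube, so for a 1 cm^3 cube `W` is numerically
#' the mean tissue concentration in uM.
#'
#' @param state A `steady_state` (or any object with a `vessels` tibble
#'   holding `w_uM` and `volume_cm3`).
#' @param target_set Optional integer vector of edge indices overriding the
#'   one in the state's params.
#' @return Amount in uM cm^3.
#' @export
aggregate_w <- function(state, target_set = NULL) {
  vs <- state$vessels
  if (is.null(target_set)) target_set <- state$params$target_set
  if (!is.null(target_set)) {
    unknown <- setdiff(target_set, vs$edge)
    if (length(unknown))
      stop("target set contains unknown vessel(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    vs <- vs[vs$edge %in% target_set, ]
  }
  state$params$B * sum(vs$volume_cm3 * vs$w_uM)
}

#' Steady state by damped Newton iteration
#'
#' Solves the full coupled steady-state system with Newton's method on the
#' assembled sparse Jacobian, starting from `initial` (zero by default).
#' This is the cross-validation path for [steady_state_sweep()] — the two
#' must agree to high relative accuracy — and remains applicable should a
#' flow orientation ever fail to be acyclic.
#'
#' @inheritParams transport_rhs
#' @param initial Optional list with `v` and `w` starting vectors.
#' @param tol Relative residual tolerance; the infinity norm of the
#'   right-hand side must fall below `tol * max(1, max(f) * v0)`, the
#'   natural scale of the flow terms.
#' @param max_iter Maximum Newton iterations.
#' @return A `steady_state`.
#' @export
steady_state_newton <- function(flow, params = transport_params(),
                                initial = NULL, tol = 1e-14, max_iter = 50) {
  stopifnot(inherits(flow, "flow_solution"))
  fe <- flow$edges
  m <- nrow(fe)
  structure_ <- flow_parents(flow)
  f <- fe$transit_rate_s
  wt <- mixing_weights(flow, params)
  k1 <- params$k1; K <- params$K; k2 <- params$k2; B <- params$B

  # Sparse inflow operator M: (M v)_i = volume-weighted parent average.
  ii <- jj <- xx <- list()
  for (i in seq_len(m)) {
    p <- structure_$parents[[i]]
    if (length(p)) {
      ii[[length(ii) + 1]] <- rep(i, length(p))
      jj[[length(jj) + 1]] <- p
      xx[[length(xx) + 1]] <- wt[p] / sum(wt[p])
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(c(ii, list(integer(0)))),
                            j = unlist(c(jj, list(integer(0)))),
                            x = unlist(c(xx, list(numeric(0)))),
                            dims = c(m, m))
  e_fed <- as.numeric(structure_$entrance_fed)

  resid <- function(v, w) {
    uptake <- k1 * v / (K + v)
    c_in <- as.numeric(M %*% v) + e_fed * params$v0
    list(rv = -f * v - uptake + f * c_in,
         rw = (uptake - k2 * w) / B)
  }
  v <- if (is.null(initial)) numeric(m) else initial$v
  w <- if (is.null(initial)) numeric(m) else initial$w
  scale <- tol * max(1, max(f) * params$v0)
  for (iter in seq_len(max_iter)) {
    r <- resid(v, w)
    rn <- max(abs(c(r$rv, r$rw)))
    if (rn <= scale) break
    du <- k1 * K / (K + v)^2                     # d uptake / d v
    Jvv <- Matrix::Diagonal(m, -f - du) + Matrix::Diagonal(m, f) %*% M
    Jwv <- Matrix::Diagonal(m, du / B)
    Jww <- Matrix::Diagonal(m, -k2 / B)
    J <- rbind(cbind(Jvv, Matrix::Matrix(0, m, m, sparse = TRUE)),
               cbind(Jwv, Jww))
    step <- as.numeric(Matrix::solve(J, -c(r$rv, r$rw)))
    # Damped update: backtrack until the residual norm does not increase.
    lambda <- 1
    repeat {
      v_new <- pmax(v + lambda * step[seq_len(m)], 0)
      w_new <- w + lambda * step[m + seq_len(m)]
      r_new <- resid(v_new, w_new)
      if (max(abs(c(r_new$rv, r_new$rw))) < rn || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    stalled <- max(abs(c(r_new$rv, r_new$rw))) >= rn
    v <- v_new; w <- w_new
    if (stalled) break
  }
  r <- resid(v, w)
  rn <- max(abs(c(r$rv, r$rw)))
  if (rn > scale)
    stop(sprintf(
      "Newton iteration did not converge in %d iterations (residual %.3g)",
      max_iter, rn))
  # Stagnant vessels decouple (f = 0): steady state has v = 0 there, and we
  # also zero w for k2 = 0 degeneracy.
  v[fe$stagnant] <- 0
  w[fe$stagnant] <- 0
  new_steady_state(v, w, flow, params)
}

#' Integrate the transport system in time
#'
#' Stiff-capable integration of the full ODE system (validation tool; the
#' model's predictions are steady states). Uses `deSolve::ode` with lsoda.
#' Note that the tissue pool is slow: its time constant is `B/k2` (the
#' volume-ratio factor buffers the tissue), so the default horizon is
#' `15 B / k2`, long enough to relax the trajectory to well below 1e-6 of
#' the entrance concentration.
#'
#' @param initial List with `v` and `w` start vectors (default all zero).
#' @param times Numeric vector of output times (s).
#' @inheritParams transport_rhs
#' @param rtol,atol Integration tolerances.
#' @return Tibble with columns `time` and the trajectory matrices nested as
#'   list-columns `v` and `w` per row.
#' @export
integrate_transport <- function(flow, params = transport_params(),
                                initial = NULL, times = NULL,
                                rtol = 1e-8, atol = 1e-10) {
  m <- nrow(flow$edges)
  if (is.null(initial)) initial <- list(v = numeric(m), w = numeric(m))
  if (is.null(times))
    times <- seq(0, 15 * params$B / max(params$k2, 1e-6), length.out = 11)
  structure_ <- flow_parents(flow)
  deriv <- function(t, y, parms) {
    r <- transport_rhs(y[seq_len(m)], y[m + seq_len(m)], flow, params,
                       structure = structure_)
    list(c(r$dv, r$dw))
  }
  out <- deSolve::ode(y = c(initial$v, initial$w), times = times, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("time integration failed; see deSolve diagnostics")
  tibble::tibble(
    time = out[, 1],
    v = lapply(seq_len(nrow(out)), function(r) unname(out[r, 1 + seq_len(m)])),
    w = lapply(seq_len(nrow(out)), function(r) unname(out[r, 1 + m + seq_len(m)]))
  )
}

#' Axial slice profile of tissue drug amount
#'
#' Bins vessels into `n` slabs along a coordinate axis by edge midpoint and
#' computes the aggregate tissue amount per slab. Reproduces the downstream
#' depletion profile: drug enters at `x = 0` and is progressively extracted,
#' so the profile decreases along the flow axis.
#'
#' @param state A `steady_state` on a lattice-built graph.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Tibble `slice`, `mid` (slab midpoint coordinate, cm), `W`
#'   (uM cm^3), `n_vessels`.
#' @export
slice_profile <- function(state, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  graph <- state$flow$graph
  if (is.na(graph$n)) stop("slice profiles require a lattice-built graph")
  n <- graph$n
  nd <- graph$nodes
  coord <- nd[[axis]]
  mid <- (coord[graph$edges$u] + coord[graph$edges$v]) / 2
  slice <- pmin(pmax(ceiling(mid * n / graph$side), 1L), n)
  B <- state$params$B
  state$vessels |>
    dplyr::mutate(slice = slice) |>
    dplyr::group_by(slice) |>
    dplyr::summarise(W = B * sum(.data$volume_cm3 * .data$w_uM),
                     n_vessels = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(mid = (.data$slice - 0.5) * graph$side / n) |>
    dplyr::select("slice", "mid", "W", "n_vessels")
}

#' Tidy a steady state into its per-vessel table
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return The per-vessel tibble with transit rates joined on.
#' @export
tidy.steady_state <- function(x, ...) {
  x$vessels |>
    dplyr::left_join(x$flow$edges[, c("edge", "transit_rate_s")], by = "edge")
}

#' One-row summary of a steady state
#'
#' @param x A `steady_state`.
#' @param ... Unused.
#' @return Tibble with the aggregate amount, concentration ranges and the
#'   tissue:plasma ratio implied by the entrance concentration.
#' @export
glance.steady_state <- function(x, ...) {
  perf <- !x$vessels$stagnant
  tibble::tibble(
    W_uM_cm3 = x$W,
    v_min = min(x$vessels$v_uM[perf]), v_max = max(x$vessels$v_uM[perf]),
    w_min = min(x$vessels$w_uM[perf]), w_max = max(x$vessels$w_uM[perf]),
    partition = x$W / x$params$v0,
    n_stagnant = sum(!perf)
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %d vessels, W = %.4g uM cm^3 (v0 = %g uM)\n",
              nrow(x$vessels), x$W, x$params$v0))
  invisible(x)
}
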