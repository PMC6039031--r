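# Shared small networks, built once per test run.
G2 <- build_lattice(lattice_spec(2, seed = 11L))
G3 <- build_lattice(lattice_spec(3, seed = 12L))
G5 <- build_lattice(lattice_spec(5, seed = 13L))

FLOW_G2 <- solve_flow(G2, 100)
FLOW_G3 <- solve_flow(G3, 100)
FLOW_G5 <- solve_flow(G5, 100)

# Independent transport RHS, written directly from the model equations with
# explicit loops; deliberately separate from the package's vectorized path.
naive_rhs <- function(v, w, flow, params) {
  fe <- flow$edges
  entr <- flow$graph$nodes$id[flow$graph$nodes$role == "entrance"]
  m <- nrow(fe)
  dv <- numeric(m); dw <- numeric(m)
  for (i in seq_len(m)) {
    f <- fe$transit_rate_s[i]
    upt <- params$k1 * v[i] / (params$K + v[i])
    if (fe$stagnant[i]) {
      dv[i] <- -upt
    } else if (fe$up_node[i] %in% entr) {
      dv[i] <- -f * v[i] - upt + f * params$v0
    } else {
      par <- which(!fe$stagnant & fe$down_node == fe$up_node[i])
      c_in <- if (length(par) == 0) 0 else
        sum(fe$volume_cm3[par] * v[par]) / sum(fe$volume_cm3[par])
      dv[i] <- -f * v[i] - upt + f * c_in
    }
    dw[i] <- (upt - params$k2 * w[i]) / params$B
  }
  list(dv = dv, dw = dw)
}

# Maximum relative disagreement between two steady states, on the scale of
# the entrance concentration (avoids 0/0 on fully depleted vessels).
max_rel_diff <- function(a, b, scale) {
  max(abs(c(a$vessels$v_uM - b$vessels$v_uM,
            a$vessels$w_uM - b$vessels$w_uM))) / scale
}
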