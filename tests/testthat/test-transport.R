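test_that("transport RHS matches an independently coded evaluation", {
  params <- transport_params()
  m <- nrow(FLOW_G2$edges)
  set.seed(31)
  v <- runif(m, 0, params$v0)
  w <- runif(m, 0, 5)
  got <- transport_rhs(v, w, FLOW_G2, params)
  want <- naive_rhs(v, w, FLOW_G2, params)
  expect_equal(got$dv, want$dv, tolerance = 1e-12)
  expect_equal(got$dw, want$dw, tolerance = 1e-12)
  expect_error(transport_rhs(v[-1], w, FLOW_G2, params), "dimensions")
})

test_that("transport RHS limits behave as the equations dictate", {
  params <- transport_params(v0 = 5)
  m <- nrow(FLOW_G2$edges)
  # empty network: only entrance-fed vessels see inflow
  r0 <- transport_rhs(numeric(m), numeric(m), FLOW_G2, params)
  entr <- FLOW_G2$graph$nodes$id[FLOW_G2$graph$nodes$role == "entrance"]
  fed <- FLOW_G2$edges$up_node %in% entr & !FLOW_G2$edges$stagnant
  expect_equal(r0$dv[fed], FLOW_G2$edges$transit_rate_s[fed] * 5)
  expect_true(all(r0$dv[!fed] == 0))
  # transport switched off and blood at the inflow level: equilibrium in v
  p0 <- transport_params(k1 = 0, v0 = 5)
  r1 <- transport_rhs(rep(5, m), numeric(m), FLOW_G2, p0)
  expect_equal(max(abs(r1$dv)), 0, tolerance = 1e-12)
})

test_that("sweep steady state solves the per-vessel balance exactly", {
  params <- transport_params()
  st <- steady_state_sweep(FLOW_G3, params)
  r <- transport_rhs(st$vessels$v_uM, st$vessels$w_uM, FLOW_G3, params)
  expect_lt(max(abs(c(r$dv, r$dw))), 1e-9)
  # bounds: blood below entrance level, tissue below k1/k2
  perf <- !st$vessels$stagnant
  expect_true(all(st$vessels$v_uM[perf] > 0 &
                    st$vessels$v_uM[perf] <= params$v0 + 1e-12))
  expect_true(all(st$vessels$w_uM[perf] <= params$k1 / params$k2 + 1e-12))
})

test_that("sweep handles the no-uptake degenerate case", {
  st <- steady_state_sweep(FLOW_G2, transport_params(k1 = 0, v0 = 7))
  perf <- !st$vessels$stagnant
  expect_equal(st$vessels$v_uM[perf], rep(7, sum(perf)), tolerance = 1e-12)
  expect_true(all(st$vessels$w_uM == 0))
})

test_that("Newton and sweep solvers agree to tight relative accuracy", {
  for (fl in list(FLOW_G2, FLOW_G3)) {
    params <- transport_params(k1 = 0.8, K = 45, v0 = 3)
    sw <- steady_state_sweep(fl, params)
    nt <- steady_state_newton(fl, params)
    expect_lt(max_rel_diff(sw, nt, params$v0), 1e-8)
  }
})

test_that("Newton initialized at the sweep root converges immediately", {
  params <- transport_params()
  sw <- steady_state_sweep(FLOW_G2, params)
  nt <- steady_state_newton(FLOW_G2, params,
                            initial = list(v = sw$vessels$v_uM,
                                           w = sw$vessels$w_uM),
                            max_iter = 1)
  expect_lt(max_rel_diff(sw, nt, params$v0), 1e-10)
})

test_that("time integration relaxes onto the sweep steady state", {
  # the tissue pool relaxes at rate k2/B, so the horizon must span B/k2
  params <- transport_params()
  sw <- steady_state_sweep(FLOW_G2, params)
  tr <- integrate_transport(FLOW_G2, params,
                            times = c(0, 15 * params$B / params$k2))
  end_v <- tr$v[[nrow(tr)]]
  end_w <- tr$w[[nrow(tr)]]
  expect_lt(max(abs(end_v - sw$vessels$v_uM)) / params$v0, 1e-6)
  expect_lt(max(abs(end_w - sw$vessels$w_uM)) / params$v0, 1e-6)
  # starting at the steady state stays there
  tr0 <- integrate_transport(FLOW_G2, params,
                             initial = list(v = sw$vessels$v_uM,
                                            w = sw$vessels$w_uM),
                             times = c(0, 1000))
  expect_lt(max(abs(tr0$v[[2]] - sw$vessels$v_uM)) / params$v0, 1e-6)
})

test_that("pure washout fills every perfused vessel to the inflow level", {
  params <- transport_params(k1 = 0, k2 = 0, v0 = 2)
  tr <- integrate_transport(FLOW_G2, params, times = c(0, 1e4),
                            rtol = 1e-10)
  perf <- !FLOW_G2$edges$stagnant
  expect_equal(max(abs(tr$v[[2]][perf] - 2)), 0, tolerance = 1e-6)
})

test_that("aggregate tissue amount factorizes and is additive over targets", {
  params <- transport_params()
  st <- steady_state_sweep(FLOW_G3, params)
  zero <- st; zero$vessels$w_uM <- 0
  expect_equal(aggregate_w(zero), 0)
  const <- st; const$vessels$w_uM <- 2.5
  expect_equal(aggregate_w(const),
               2.5 * params$B * sum(st$vessels$volume_cm3))
  half <- st$vessels$edge[seq_len(nrow(st$vessels)) %% 2 == 0]
  rest <- setdiff(st$vessels$edge, half)
  expect_equal(aggregate_w(st, half) + aggregate_w(st, rest), st$W)
  expect_error(aggregate_w(st, c(1L, 99999L)), "unknown")
})

test_that("axial slice profile partitions W and shows downstream depletion", {
  g <- build_lattice(10, seed = 3)
  st <- steady_state_sweep(solve_flow(g, 100))
  pr <- slice_profile(st, "x")
  expect_equal(nrow(pr), 10)
  expect_equal(sum(pr$W), st$W, tolerance = 1e-12)
  expect_equal(sum(pr$n_vessels), nrow(g$edges))
  # drug is depleted along the flow axis: the outflow-side slab holds less
  # than the inflow-side slab
  expect_lt(pr$W[nrow(pr)], pr$W[1])
  # uniform tissue concentration spreads W in proportion to slab volume
  unif <- st; unif$vessels$w_uM <- 1
  pru <- slice_profile(unif, "x")
  vol <- tapply(st$vessels$volume_cm3,
                pmin(pmax(ceiling(((g$nodes$x[g$edges$u] +
                                      g$nodes$x[g$edges$v]) / 2) * 10), 1), 10),
                sum)
  expect_equal(pru$W, as.numeric(vol) * st$params$B, tolerance = 1e-12)
})
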