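test_that("calibrated mean radius follows the volume-ratio closed form", {
  # 1/((n+1) sqrt(90 pi)) for B = 30; frozen values evaluated independently
  expect_equal(mean_radius(5), 9.9119e-3, tolerance = 1e-4)
  expect_equal(mean_radius(149) * 1e4, 3.9648, tolerance = 1e-4)
  # refinement halves the mean radius when n -> 2n + 1
  for (n in c(1, 7, 30)) {
    expect_equal(mean_radius(n) / mean_radius(2 * n + 1), 2)
  }
  # generalized volume ratio
  expect_equal(mean_radius(5, volume_ratio_B = 10),
               1 / (6 * sqrt(30 * pi)))
  expect_error(mean_radius(0))
  expect_error(mean_radius(5, volume_ratio_B = -1))
})

test_that("total nominal vessel volume is side^3/B at every level", {
  for (n in c(1, 5, 18, 149)) {
    vol <- 3 * n * (n + 1)^2 * pi * mean_radius(n)^2 * (1 / n)
    expect_equal(vol, 1 / 30, tolerance = 1e-12)
  }
})

test_that("radius sampling is reproducible and matches the Gamma moments", {
  model <- radius_model(5)
  expect_identical(sample_radii(100, model, seed = 9),
                   sample_radii(100, model, seed = 9))
  r <- sample_radii(1e5, model, seed = 1)
  se <- model$mean_radius / sqrt(model$alpha) / sqrt(1e5)
  expect_lt(abs(mean(r) - model$mean_radius), 3 * se)
  skew <- mean(((r - mean(r)) / sd(r))^3)
  expect_equal(skew, 2 / sqrt(5), tolerance = 0.05)
})

test_that("lattice graphs have the predicted vertex and edge counts", {
  g1 <- build_lattice(1, seed = 1)
  expect_equal(nrow(g1$nodes), 8)
  expect_equal(nrow(g1$edges), 12)
  g6 <- build_lattice(6, seed = 1)
  expect_equal(nrow(g6$nodes), 343)
  expect_equal(nrow(g6$edges), 882)
  expect_true(all(g6$edges$length_cm == 1 / 6))
  expect_true(all(g6$edges$radius_cm > 0))
})

test_that("boundary node selection is deterministic, sized and disjoint", {
  expect_equal(sum(G5$nodes$role == "entrance"), 18) # half of 36 face nodes
  expect_equal(sum(G5$nodes$role == "exit"), 18)
  expect_true(all(G5$nodes$x[G5$nodes$role == "entrance"] == 0))
  expect_true(all(G5$nodes$x[G5$nodes$role == "exit"] == G5$side))

  twice <- select_boundary_nodes(G5, 0.5, mode = "checkerboard")
  expect_identical(twice$nodes$role, G5$nodes$role)

  all_face <- select_boundary_nodes(G5, 1)
  expect_equal(sum(all_face$nodes$role == "entrance"), 36)

  r1 <- select_boundary_nodes(G5, 0.5, mode = "random", seed = 3)
  r2 <- select_boundary_nodes(G5, 0.5, mode = "random", seed = 3)
  expect_identical(r1$nodes$role, r2$nodes$role)
  expect_error(select_boundary_nodes(G5, 1e-9), "no nodes")
})

test_that("radius monotonicity reassignment permutes and orders radii", {
  set.seed(21)
  g <- G3
  shuffled <- g
  shuffled$edges$radius_cm <- sample(g$edges$radius_cm)
  fixed <- enforce_radius_monotonicity(shuffled)
  expect_equal(sort(fixed$edges$radius_cm), sort(g$edges$radius_cm))
  # exhaustive pairwise property: nearer the boundary means at least as wide
  d <- fixed$edges$boundary_dist
  r <- fixed$edges$radius_cm
  for (k in sort(unique(d))[-1]) {
    expect_gte(min(r[d < k]), max(r[d == k]))
  }
  expect_gte(min(r[d == 0]), max(r[d == max(d)]))
})

test_that("nominal exchange area matches its closed form", {
  for (n in c(3, 18, 149)) {
    expect_equal(exchange_area_nominal(n), 6 * (n + 1) * sqrt(pi / 90),
                 tolerance = 1e-12)
  }
  expect_equal(exchange_area_nominal(18), 21.30, tolerance = 1e-3)
  expect_equal(exchange_area_nominal(149), 168.1, tolerance = 1e-3)
})

test_that("vessel_graph validates its inputs", {
  nodes <- tibble::tibble(id = 1:2, x = c(0, 1), y = 0, z = 0,
                          role = c("entrance", "exit"))
  edges <- tibble::tibble(u = 1L, v = 2L, length_cm = 1, radius_cm = 1e-3)
  expect_s3_class(vessel_graph(nodes, edges), "vessel_graph")
  expect_error(vessel_graph(nodes, dplyr::mutate(edges, radius_cm = -1)),
               "positive")
  expect_error(vessel_graph(dplyr::mutate(nodes, role = "interior"), edges),
               "entrance")
  bad <- dplyr::select(edges, -radius_cm)
  expect_error(vessel_graph(nodes, bad), "radius_cm")
})
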