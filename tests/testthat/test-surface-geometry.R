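test_that("mesh constructor validates its invariants", {
  v <- diag(3)
  expect_s3_class(surface_mesh(v, rbind(c(1, 2, 3))), "surface_mesh")
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "face indices")
  expect_error(surface_mesh(v, rbind(c(1, 1, 2))), "degenerate")
  expect_error(surface_mesh(v[, 1:2], rbind(c(1, 2, 3))), "N x 3")
})

test_that("icosphere has the subdivision counts and Euler characteristic of a closed sphere", {
  for (s in 0:3) {
    m <- make_icosphere(s, radius_mm = 1)
    expect_equal(n_vertices(m), 10 * 4^s + 2)
    expect_equal(n_faces(m), 20 * 4^s)
    ne <- nrow(mesh_edges(m)$edges)
    expect_equal(n_vertices(m) - ne + n_faces(m), 2) # V - E + F
    expect_equal(unname(sqrt(rowSums(m$vertices^2))),
                 rep(1, n_vertices(m)), tolerance = 1e-12)
  }
})

test_that("geodesic distances on a flat sheet are straight lines up to the documented bound", {
  m <- grid_mesh(6, 5, h = 2)
  d <- geodesic_distance_matrix(m)
  expect_equal(unname(diag(d)), rep(0, n_vertices(m)))
  expect_equal(unclass(d), t(unclass(d)))
  de <- euclidean_distance_matrix(m)
  # straight lines along directions the refined graph represents are exact
  # (axis rows/columns and the triangulation diagonal) ...
  id <- function(i, j) (j - 1) * 6 + i
  for (pair in list(c(id(1, 1), id(6, 1)), c(id(2, 1), c(id(2, 5))),
                    c(id(1, 1), id(5, 5)), c(id(3, 2), id(6, 2)))) {
    expect_equal(d[pair[1], pair[2]], de[pair[1], pair[2]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # ... and every pair is within the worst-case direction factor of the
  # axis + diagonal direction set on a right-triangle grid: a straight
  # line of slope t in the unshared quadrant costs (1-t) + t*sqrt(2) per
  # unit x, maximized over t at t = sqrt(2)-1, giving sqrt(4 - 2*sqrt(2))
  bound <- sqrt(4 - 2 * sqrt(2))
  off <- upper.tri(de)
  ratio <- unclass(d)[off] / unclass(de)[off]
  expect_true(all(ratio >= 1 - 1e-9))
  expect_true(all(ratio <= bound + 1e-9))
})

test_that("geodesic on the unit icosphere approaches the great-circle arc", {
  m <- make_icosphere(4, radius_mm = 1)
  d <- geodesic_distance_matrix(m, sources = 1L)
  anti <- which.min(rowSums(sweep(m$vertices, 2, -m$vertices[1, ])^2))
  expect_lt(abs(d[1, anti] - pi) / pi, 0.02)
})

test_that("geodesic approximation is bracketed by Euclidean and edge-graph Dijkstra", {
  m <- bumpy_sphere(2, seed = 4)
  d <- geodesic_distance_matrix(m)
  de <- euclidean_distance_matrix(m)
  dg <- dijkstra_oracle(m)
  expect_true(all(unclass(de) <= unclass(d) + 1e-9))
  expect_true(all(unclass(d) <= dg + 1e-9))
})

test_that("geodesic output agrees with a hand-rolled Dijkstra bound on tiny meshes", {
  m <- torus_mesh(6, 5)
  d <- geodesic_distance_matrix(m)
  for (src in c(1L, 7L)) {
    hand <- dijkstra_by_hand(m, src)
    expect_true(all(d[src, ] <= hand + 1e-9))
    # refined shortcuts cannot undercut the straight-line bound
    eu <- sqrt(rowSums(sweep(m$vertices, 2, m$vertices[src, ])^2))
    expect_true(all(d[src, ] >= eu - 1e-9))
  }
})

test_that("triangle inequality holds on sampled vertex triples", {
  m <- bumpy_sphere(2, seed = 9)
  d <- unclass(geodesic_distance_matrix(m))
  set.seed(11)
  n <- nrow(d)
  a <- sample.int(n, 2000, replace = TRUE)
  b <- sample.int(n, 2000, replace = TRUE)
  cc <- sample.int(n, 2000, replace = TRUE)
  expect_true(all(d[cbind(a, cc)] <= d[cbind(a, b)] + d[cbind(b, cc)] + 1e-9))
})

test_that("scaling coordinates scales distances; normalization is scale invariant", {
  m <- bumpy_sphere(1, seed = 3)
  m2 <- m
  m2$vertices <- m$vertices * 3.7
  d1 <- geodesic_distance_matrix(m)
  d2 <- geodesic_distance_matrix(m2)
  expect_equal(unclass(d2), 3.7 * unclass(d1), tolerance = 1e-12)
  expect_equal(unclass(normalize_distances(d1)),
               unclass(normalize_distances(d2)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("disconnected meshes are rejected with the component count", {
  v <- rbind(diag(3), diag(3) + 10)
  f <- rbind(c(1, 2, 3), c(4, 5, 6))
  m <- surface_mesh(v, f)
  expect_error(geodesic_distance_matrix(m), "2 components")
})

test_that("euclidean distances follow Pythagoras and never exceed geodesic", {
  v <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 4, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3)))
  de <- euclidean_distance_matrix(m)
  expect_equal(de[1, 2], 5)
  expect_equal(unname(diag(de)), c(0, 0, 0))
  mb <- bumpy_sphere(2, seed = 21)
  expect_true(all(unclass(euclidean_distance_matrix(mb)) <=
                    unclass(geodesic_distance_matrix(mb)) + 1e-9))
})

test_that("multi-source distance is the min over single-source maps and zero on seeds", {
  m <- bumpy_sphere(1, seed = 5)
  d <- geodesic_distance_matrix(m)
  seeds <- c(3L, 17L)
  ms <- multi_source_distance(m, seeds, dist_matrix = d)
  expect_equal(map_values(ms), pmin(d[3, ], d[17, ]))
  expect_equal(map_values(ms)[seeds], c(0, 0))
  # single-vertex seed reduces to that row
  one <- multi_source_distance(m, 5L, dist_matrix = d)
  expect_equal(map_values(one), unclass(d)[5, ])
  # without a precomputed matrix the same map comes out
  ms2 <- multi_source_distance(m, seeds)
  expect_equal(map_values(ms2), map_values(ms), tolerance = 1e-12)
  expect_error(multi_source_distance(m, integer()), "nonempty")
})

test_that("min-max normalization maps the off-diagonal range onto [0,1] and round-trips", {
  vals <- matrix(c(0, 10, 60, 10, 0, 110, 60, 110, 0), 3, 3)
  d <- geodca:::new_surf_dist(vals, metric = "geodesic")
  nd <- normalize_distances(d)
  expect_equal(nd[1, 3], 0.5)
  off <- unclass(nd)[upper.tri(nd)]
  expect_equal(range(off), c(0, 1))
  expect_equal(unname(diag(nd)), c(0, 0, 0))
  expect_true(attr(nd, "normalized"))
  back <- denormalize_distances(nd)
  expect_equal(unclass(back), vals, tolerance = 1e-9, ignore_attr = TRUE)
  # constant off-diagonal is undefined
  cst <- geodca:::new_surf_dist(matrix(1, 3, 3) - diag(3), metric = "geodesic")
  expect_error(normalize_distances(cst), "constant")
})
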