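test_that("DCA matches its definition on a written-out 5-vertex example", {
  dist5 <- matrix(0, 5, 5)
  dist5[1, ] <- c(0, 1, 2, 3, 4)
  dist5 <- dist5 + t(dist5)
  dist5[2:5, 2:5] <- dist5[2:5, 2:5] + (1 - diag(4)) # make it a valid-ish metric table
  conn5 <- diag(5)
  conn5[1, ] <- c(1, 0.1, 0.2, 0.8, 0.9)
  conn5 <- (conn5 + t(conn5)) / 2
  diag(conn5) <- 1
  d <- geodca:::new_surf_dist(dist5, metric = "geodesic")
  cm <- geodca:::new_conn_matrix(conn5)
  # k = round(0.5 * 4) = 2; v1's two strongest are v4, v5 -> (3 + 4) / 2
  map <- distance_to_connected_areas(cm, d, percent = 50)
  expect_equal(map_values(map)[1], 3.5)
})

test_that("DCA equals the naive double-loop implementation exactly", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(20:120, 1)
    cm <- correlation_matrix(matrix(rnorm(n * 40), n, 40))
    dm <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
    d <- geodca:::new_surf_dist(dm, metric = "euclidean")
    p <- sample(c(2, 5, 10, 30, 100), 1)
    expect_identical(map_values(distance_to_connected_areas(cm, d, p)),
                     naive_dca(unclass(cm), dm, p))
  }
})

test_that("at percent = 100 the DCA map is pure geometry", {
  m <- bumpy_sphere(1, seed = 6)
  d <- geodesic_distance_matrix(m)
  n <- n_vertices(m)
  cm1 <- correlation_matrix(matrix(rnorm(n * 30), n, 30))
  cm2 <- correlation_matrix(matrix(rnorm(n * 30), n, 30))
  m1 <- distance_to_connected_areas(cm1, d, 100)
  m2 <- distance_to_connected_areas(cm2, d, 100)
  expect_equal(map_values(m1), map_values(m2)) # connectivity-independent
  expect_equal(map_values(m1), rowSums(unclass(d)) / (n - 1))
})

test_that("DCA with nearest-neighbour connectivity equals mean of k smallest distances", {
  m <- bumpy_sphere(1, seed = 8)
  d <- geodesic_distance_matrix(m)
  n <- n_vertices(m)
  conn <- geodca:::new_conn_matrix(1 - unclass(d) / max(d)) # rank = proximity
  p <- 10
  k <- geodca:::top_k_count(p, n)
  oracle <- sapply(seq_len(n), function(v) mean(sort(unclass(d)[v, -v])[1:k]))
  expect_equal(map_values(distance_to_connected_areas(conn, d, p)), oracle)
})

test_that("group averaging is the vertexwise mean and enforces aligned units", {
  set.seed(12)
  maps <- lapply(1:10, function(i) vertex_map(rnorm(50), units = "mm"))
  avg <- group_average(maps)
  oracle <- Reduce(`+`, lapply(maps, map_values)) / 10
  expect_equal(map_values(avg), oracle)
  expect_equal(map_values(group_average(maps[1])), map_values(maps[[1]]))
  two <- group_average(list(maps[[1]],
                            vertex_map(2 * map_values(maps[[1]]), units = "mm")))
  expect_equal(map_values(two), 1.5 * map_values(maps[[1]]))
  expect_error(group_average(list(maps[[1]], vertex_map(rnorm(50), "normalized"))),
               "units")
  expect_error(group_average(list()), "nonempty")
})

test_that("mm rescaling inverts a single subject's normalization and uses mean min/range", {
  vals <- matrix(runif(36, 5, 80), 6, 6)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  d <- geodca:::new_surf_dist(vals, metric = "geodesic")
  nd <- normalize_distances(d)
  prov <- tibble::tibble(min = attr(nd, "norm_min"), range = attr(nd, "norm_range"))
  cm <- correlation_matrix(matrix(rnorm(6 * 20), 6, 20))
  map_norm <- distance_to_connected_areas(cm, nd, 50)
  map_mm <- distance_to_connected_areas(cm, d, 50)
  expect_equal(map_values(rescale_to_mm(map_norm, prov)), map_values(map_mm),
               tolerance = 1e-12)
  # endpoints of the normalized scale
  z <- vertex_map(c(0, 1), units = "normalized")
  prov2 <- tibble::tibble(min = c(10, 20), range = c(100, 60))
  expect_equal(map_values(rescale_to_mm(z, prov2)), c(15, 15 + 80))
  expect_error(rescale_to_mm(z, tibble::tibble(min = NA_real_, range = 1)),
               "provenance")
  expect_error(rescale_to_mm(vertex_map(1:3, units = "mm"), prov2), "normalized")
})

test_that("geodesic-minus-Euclidean difference maps behave vertexwise", {
  a <- vertex_map(c(1, 2, 3), units = "mm")
  expect_equal(map_values(metric_difference_map(a, a)), c(0, 0, 0))
  b <- vertex_map(c(1, 2, 2.5), units = "mm")
  expect_equal(map_values(metric_difference_map(a, b)), c(0, 0, 0.5))
  expect_error(metric_difference_map(a, vertex_map(1:3, units = "normalized")),
               "units")
  # at percent = 100, geodesic >= Euclidean vertexwise on any mesh
  m <- bumpy_sphere(1, seed = 13)
  dg <- geodesic_distance_matrix(m)
  de <- euclidean_distance_matrix(m)
  cm <- correlation_matrix(matrix(rnorm(n_vertices(m) * 20), n_vertices(m), 20))
  diff <- metric_difference_map(distance_to_connected_areas(cm, dg, 100),
                                distance_to_connected_areas(cm, de, 100))
  expect_true(all(map_values(diff) >= -1e-9))
})

test_that("ICC(2,1) matches an aov mean-squares oracle on a small table", {
  # 3 subjects x 2 runs, one vertex
  y <- c(9, 8, 6, 5, 12, 11)
  df <- data.frame(y = y,
                   subject = factor(rep(1:3, each = 2)),
                   run = factor(rep(1:2, 3)))
  ms <- summary(stats::aov(y ~ subject + run, data = df))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 3; k <- 2
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  arr <- array(rep(y[c(1, 3, 5, 2, 4, 6)], each = 2), c(2, 3, 2))
  got <- icc_map(arr)
  expect_equal(map_values(got), rep(icc_oracle, 2), tolerance = 1e-12)
})

test_that("ICC approaches 1 with huge subject effects and 0 for pure noise", {
  set.seed(14)
  nv <- 40; ns <- 200; nr <- 2
  subj <- matrix(rnorm(nv * ns, sd = 10), nv, ns)
  arr1 <- array(NA_real_, c(nv, ns, nr))
  arr0 <- array(rnorm(nv * ns * nr), c(nv, ns, nr))
  for (r in 1:nr) arr1[, , r] <- subj + rnorm(nv * ns, sd = 0.01)
  expect_true(all(map_values(icc_map(arr1)) > 0.99))
  expect_lt(mean(abs(map_values(icc_map(arr0)))), 0.1)
  expect_error(icc_map(arr0[, , 1, drop = FALSE]), "at least 2")
})

test_that("icc_map accepts a tidy subject x run table of maps", {
  set.seed(15)
  grid <- expand.grid(subject = 1:3, run = 1:2)
  grid$map <- lapply(seq_len(nrow(grid)), function(i) vertex_map(rnorm(20)))
  tab <- tibble::as_tibble(grid)
  got <- icc_map(tab)
  arr <- array(NA_real_, c(20, 3, 2))
  for (i in seq_len(nrow(tab))) {
    arr[, tab$subject[i], tab$run[i]] <- map_values(tab$map[[i]])
  }
  expect_equal(map_values(got), map_values(icc_map(arr)))
})

test_that("threshold sweep returns one map per percent, consistent with single calls", {
  m <- bumpy_sphere(1, seed = 16)
  d <- geodesic_distance_matrix(m)
  n <- n_vertices(m)
  cm <- correlation_matrix(matrix(rnorm(n * 50), n, 50))
  sw <- threshold_sweep(cm, d, percents = c(30, 10, 2))
  expect_equal(nrow(sw), 3)
  expect_equal(map_values(sw$map[[2]]),
               map_values(distance_to_connected_areas(cm, d, 10)))
  one <- threshold_sweep(cm, d, percents = 100)
  expect_equal(map_values(one$map[[1]]),
               map_values(distance_to_connected_areas(cm, d, 100)))
})
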