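test_that("spatial correlation recovers identity, inversion, and a hand-ranked example", {
  x <- vertex_map(c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5, 7, 8, 0.2, 6))
  same <- spatial_correlation(x, x)
  expect_equal(same$spearman_r, 1)
  expect_equal(same$slope, 1)
  neg <- vertex_map(-map_values(x))
  expect_equal(spatial_correlation(neg, x)$spearman_r, -1)
  # midrank hand computation with one tie, padded to the 10-vertex minimum
  a <- c(1, 2, 2, 3, 5, 4, 7, 6, 9, 8, 10, 11)
  b <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 11, 12)
  ra <- rank(a); rb <- rank(b) # midranks
  hand_r <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spatial_correlation(vertex_map(a), vertex_map(b))$spearman_r,
               hand_r)
})

test_that("spatial correlation applies exclusions and rejects degenerate input", {
  set.seed(20)
  a <- rnorm(30); b <- a + rnorm(30)
  excl <- c(rep(TRUE, 5), rep(FALSE, 25))
  got <- spatial_correlation(vertex_map(a), vertex_map(b), exclude = excl)
  expect_equal(got$n_vertices_used, 25)
  ref <- cor(a[-(1:5)], b[-(1:5)], method = "spearman")
  expect_equal(got$spearman_r, ref)
  # integer indices behave like the mask
  got2 <- spatial_correlation(vertex_map(a), vertex_map(b), exclude = 1:5)
  expect_equal(got2$spearman_r, ref)
  expect_error(spatial_correlation(vertex_map(a[1:12]), vertex_map(b[1:12]),
                                   exclude = 1:8), "fewer than 10")
  expect_error(spatial_correlation(vertex_map(rep(1, 15)), vertex_map(rnorm(15))),
               "constant")
})

test_that("patch extraction finds connected components per network with a size filter", {
  m <- grid_mesh(10, 6)
  labels <- integer(60)
  labels[1:30] <- 1L # rows 1-3: one connected block
  # network 2 split into two islands: 20 and 8 vertices, separated by row 4 (=0)
  labels[41:60] <- 2L
  labels[31:38] <- 0L
  labels[39:40] <- 2L
  p0 <- extract_patches(parcellation(labels), m, min_size = 0)
  # oracle via igraph components on each network's induced subgraph
  for (net in 1:2) {
    vs <- which(labels == net)
    ed <- geodca:::mesh_edges(m)$edges
    keep <- ed[, 1] %in% vs & ed[, 2] %in% vs
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed[keep, 1], to = ed[keep, 2]), directed = FALSE,
      vertices = data.frame(name = vs))
    expect_equal(sum(p0$network == net), igraph::components(g)$no)
  }
  expect_equal(sum(p0$size), sum(labels > 0)) # conservation at min_size 0
  # only components strictly larger than min_size survive
  p25 <- extract_patches(parcellation(labels), m, min_size = 19)
  expect_equal(p25$size[p25$network == 2], 22)
  expect_true(all(p0$size[p0$network == 2] %in% c(22, 8) |
                    p0$network != 2))
})

test_that("single connected network yields one patch; sizes sort descending within network", {
  m <- bumpy_sphere(1, seed = 22)
  labels <- rep(1L, n_vertices(m))
  p <- extract_patches(parcellation(labels), m)
  expect_equal(nrow(p), 1)
  expect_equal(p$size, n_vertices(m))
})

test_that("random layouts conserve template sizes exactly and are seed-deterministic", {
  m <- make_icosphere(2, radius_mm = 70)
  cfg <- generator_config(mesh_subdivisions = 2, rng_seed = 3)
  tp <- make_tiered_parcellation(m, cfg)
  tpl <- extract_patches(tp$parc, m, 0)
  lay <- random_patch_layout(m, tpl, rng_seed = 11)
  po <- attr(lay, "patch_of")
  expect_equal(sort(as.integer(table(po[po > 0]))), sort(tpl$size))
  # per-network vertex counts conserved
  expect_equal(table(parc_labels(lay))[as.character(unique(tpl$network))],
               table(parc_labels(tp$parc))[as.character(unique(tpl$network))])
  expect_identical(parc_labels(random_patch_layout(m, tpl, rng_seed = 11)),
                   parc_labels(lay))
  expect_false(identical(parc_labels(random_patch_layout(m, tpl, rng_seed = 12)),
                         parc_labels(lay)))
  # every grown patch is spatially connected
  adj <- geodca:::mesh_adjacency(m)
  for (pid in unique(po[po > 0])) {
    vs <- which(po == pid)
    g <- igraph::graph_from_data_frame(
      do.call(rbind, lapply(vs, function(v) {
        nb <- adj[[v]][adj[[v]] %in% vs]
        if (length(nb)) data.frame(from = v, to = nb) else NULL
      })), directed = FALSE, vertices = data.frame(name = vs))
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("a single template of size N reproduces full coverage for any seed", {
  m <- bumpy_sphere(1, seed = 23)
  tpl <- tibble::tibble(network = 1L, patch = 1L, size = n_vertices(m),
                        vertices = list(seq_len(n_vertices(m))))
  for (s in c(1, 99)) {
    lay <- random_patch_layout(m, tpl, rng_seed = s)
    expect_true(all(parc_labels(lay) == 1L))
  }
})

test_that("templates with slack leave uncovered vertices unassigned", {
  m <- make_icosphere(2, radius_mm = 70)
  tpl <- tibble::tibble(network = c(1L, 2L), patch = 1:2, size = c(40L, 25L),
                        vertices = list(integer(), integer()))
  lay <- random_patch_layout(m, tpl, rng_seed = 4)
  labs <- parc_labels(lay)
  expect_equal(sum(labs == 1L), 40)
  expect_equal(sum(labs == 2L), 25)
  expect_equal(sum(labs == 0L), n_vertices(m) - 65)
})

test_that("the binary model map is the mean within-network distance (hand example)", {
  dm <- matrix(c(0, 2, 5, 6,
                 2, 0, 4, 7,
                 5, 4, 0, 3,
                 6, 7, 3, 0), 4, 4)
  d <- geodca:::new_surf_dist(dm, metric = "geodesic")
  parc <- parcellation(c(1L, 1L, 2L, 2L))
  mm <- model_distance_map(parc, d)
  expect_equal(map_values(mm), c(2, 2, 3, 3))
  # unassigned vertices come back NA
  parc0 <- parcellation(c(1L, 1L, 2L, 2L, 0L)[1:4])
  expect_error(model_distance_map(parcellation(c(1L, 1L, 2L, 3L)), d), "single vertex")
})

test_that("one all-covering network reduces the model map to the percent-100 geometry map", {
  m <- bumpy_sphere(1, seed = 24)
  d <- geodesic_distance_matrix(m)
  n <- n_vertices(m)
  mm <- model_distance_map(parcellation(rep(1L, n)), d)
  cm <- correlation_matrix(matrix(rnorm(n * 20), n, 20))
  expect_equal(map_values(mm),
               map_values(distance_to_connected_areas(cm, d, 100)))
})

test_that("compact patches have shorter model distances than split networks", {
  m <- make_icosphere(2, radius_mm = 70)
  d <- geodesic_distance_matrix(m)
  adj <- geodca:::mesh_adjacency(m)
  n <- n_vertices(m)
  # compact cap of 30 around vertex 1 vs. two caps of 15 at antipodes
  grow_from <- function(start, size) {
    got <- start
    while (length(got) < size) {
      cand <- setdiff(unique(unlist(adj[got])), got)
      got <- c(got, cand[seq_len(min(length(cand), size - length(got)))])
    }
    got
  }
  anti <- which.min(rowSums(sweep(m$vertices, 2, -m$vertices[1, ])^2))
  compact <- grow_from(1L, 30)
  split <- c(grow_from(1L, 15), grow_from(anti, 15))
  lab1 <- integer(n); lab1[compact] <- 1L; lab1[setdiff(seq_len(n), compact)] <- 2L
  lab2 <- integer(n); lab2[split] <- 1L; lab2[setdiff(seq_len(n), split)] <- 2L
  m1 <- map_values(model_distance_map(parcellation(lab1), d))
  m2 <- map_values(model_distance_map(parcellation(lab2), d))
  expect_lt(mean(m1[compact]), mean(m2[split]))
})

test_that("the add-one permutation p-value lands on its grid and bounds", {
  m <- make_icosphere(2, radius_mm = 70)
  d <- geodesic_distance_matrix(m)
  cfg <- generator_config(mesh_subdivisions = 2, rng_seed = 6)
  tp <- make_tiered_parcellation(m, cfg, dist = d)
  nt <- topography_null_test(NULL, tp$seeds, tp$parc, m, d,
                             n_iter = 9, rng_seed = 31, min_patch_size = 0)
  expect_equal(nt$p_value, (1 + sum(nt$r_null >= nt$observed_r)) / 10)
  expect_gte(nt$p_value, 1 / 10)
  expect_lte(nt$p_value, 1)
  expect_length(nt$r_null, 9)
  g <- glance(nt)
  expect_equal(g$p_value, nt$p_value)
  expect_equal(nrow(tidy(nt)), 9)
  # n_iter = 1 with null below observed gives the textbook 1/2
  if (nt$r_null[1] < nt$observed_r) {
    one <- topography_null_test(NULL, tp$seeds, tp$parc, m, d,
                                n_iter = 1, rng_seed = 31, min_patch_size = 0)
    expect_equal(one$p_value, 1 / 2)
  }
})

test_that("the null distribution is invariant to relabeling non-primary networks", {
  m <- make_icosphere(2, radius_mm = 70)
  d <- geodesic_distance_matrix(m)
  cfg <- generator_config(mesh_subdivisions = 2, rng_seed = 8)
  tp <- make_tiered_parcellation(m, cfg, dist = d)
  labels <- parc_labels(tp$parc)
  # swap two non-primary network ids (both intermediate tier)
  relab <- labels
  relab[labels == 4L] <- 5L
  relab[labels == 5L] <- 4L
  nt1 <- topography_null_test(NULL, tp$seeds, tp$parc, m, d,
                              n_iter = 5, rng_seed = 77, min_patch_size = 0)
  nt2 <- topography_null_test(NULL, tp$seeds, parcellation(relab), m, d,
                              n_iter = 5, rng_seed = 77, min_patch_size = 0)
  expect_equal(nt1$r_null, nt2$r_null, tolerance = 1e-12)
  expect_equal(nt1$observed_r, nt2$observed_r, tolerance = 1e-12)
})
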