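#' Synthetic-cortex generator configuration
#'
#' The generator emulates the statistical structure the analysis assumes on
#' real cortex: a sphere-like hemisphere mesh, a tiered network
#' parcellation whose primary-tier networks are compact patches around
#' anchor landmarks, and Gaussian time series whose correlation decays with
#' geodesic distance plus elevated long-range correlation within
#' distributed-tier networks.  Defaults give a desk-scale but geometrically
#' nontrivial cortex: a subdivision-4 icosphere (2,562 vertices, 70 mm
#' radius), 8 networks (2 primary, 3 intermediate, 3 distributed), local
#' correlation decay length 10 mm, long-range within-network correlation
#' 0.35, 600 timepoints, measurement noise SD 0.5.
#'
#' @param mesh_subdivisions icosphere subdivision level.
#' @param radius_mm sphere radius (mm).
#' @param n_networks total number of networks.
#' @param tier_of_network character vector of length `n_networks` with
#'   values `"primary"`, `"intermediate"`, `"distributed"` (>= 1 primary,
#'   at most 2).
#' @param lambda_local correlation decay length (mm): local coupling is
#'   `exp(-d_geodesic / lambda_local)`.
#' @param rho_network extra correlation in `[0, 1)` between vertices of the
#'   same distributed-tier network lying in different patches.
#' @param rho_intermediate cross-patch correlation for intermediate-tier
#'   networks (default `rho_network / 2`); their moderately distant
#'   coupling is what places them between the locally wired primary tier
#'   and the long-range distributed tier.
#' @param noise_sd SD of independent measurement noise added to the latent
#'   signal (unit-variance); it attenuates sample correlations by
#'   `1 / (1 + noise_sd^2)` uniformly, which leaves node-wise connectivity
#'   ranks -- and hence DCA -- unchanged.
#' @param T timepoints per run.
#' @param n_subjects,n_runs replication structure.
#' @param rng_seed integer seed controlling every random element.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(mesh_subdivisions = 4, radius_mm = 70,
                             n_networks = 8,
                             tier_of_network = c("primary", "primary",
                                                 "intermediate", "intermediate",
                                                 "intermediate", "distributed",
                                                 "distributed", "distributed"),
                             lambda_local = 10, rho_network = 0.35,
                             rho_intermediate = rho_network / 2,
                             noise_sd = 0.5, T = 600,
                             n_subjects = 1, n_runs = 1, rng_seed = 1) {
  stopifnot(n_networks >= 3, length(tier_of_network) == n_networks,
            all(tier_of_network %in% c("primary", "intermediate", "distributed")),
            rho_network >= 0, rho_network < 1, lambda_local > 0,
            rho_intermediate >= 0, rho_intermediate < 1,
            T >= 3, noise_sd >= 0)
  np <- sum(tier_of_network == "primary")
  if (np < 1 || np > 2) stop("need 1 or 2 primary-tier networks")
  structure(
    list(mesh_subdivisions = mesh_subdivisions, radius_mm = radius_mm,
         n_networks = n_networks, tier_of_network = tier_of_network,
         lambda_local = lambda_local, rho_network = rho_network,
         rho_intermediate = rho_intermediate,
         noise_sd = noise_sd, T = T, n_subjects = n_subjects,
         n_runs = n_runs, rng_seed = rng_seed),
    class = "generator_config"
  )
}

#' Tiered synthetic parcellation with primary anchors
#'
#' Tiles the mesh completely with region-grown networks arranged by
#' geodesic distance from two antipodal anchor vertices drawn along a
#' random axis: primary-tier networks are compact single caps around the
#' anchors; intermediate-tier networks occupy the middle distance band
#' (longitude sectors, paired across hemispheres); distributed-tier
#' networks split the far (equatorial) band into alternating longitude
#' sectors so each comprises >= 2 patches placed far from the anchors.  The
#' union of primary-tier vertices is returned as the seed region standing
#' in for primary-cortex landmarks.
#'
#' @param mesh a [surface_mesh()] (sphere-like; the generator's icosphere).
#' @param config a [generator_config()].
#' @param dist optional precomputed `surf_dist` (unnormalized, mm) to avoid
#'   recomputing anchor distances.
#' @return a list: `parc` ([parcellation()]), `seeds` (integer vertex ids),
#'   `tiers` (tibble `network`, `tier`), `anchors` (the two anchor
#'   vertices).
#' @export
make_tiered_parcellation <- function(mesh, config = generator_config(),
                                     dist = NULL) {
  v <- mesh$vertices
  n <- nrow(v)
  tiers <- config$tier_of_network
  set.seed(as.integer((config$rng_seed + 77) %% .Machine$integer.max))
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  proj <- as.vector(v %*% u)
  a1 <- which.max(proj); a2 <- which.min(proj)
  if (!is.null(dist)) {
    danch <- unclass(dist)[c(a1, a2), , drop = FALSE]
  } else {
    danch <- unclass(geodesic_distance_matrix(mesh, sources = c(a1, a2)))
  }
  dmin <- pmin(danch[1, ], danch[2, ])
  nearer1 <- danch[1, ] <= danch[2, ]

  n_p <- sum(tiers == "primary")
  n_i <- sum(tiers == "intermediate")
  n_d <- sum(tiers == "distributed")
  ids_p <- which(tiers == "primary")
  ids_i <- which(tiers == "intermediate")
  ids_d <- which(tiers == "distributed")
  q <- stats::quantile(dmin, c(n_p, n_p + n_i) / config$n_networks)

  # longitude about the anchor axis, with a random sector offset
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  phi <- (atan2(v %*% e2, v %*% e1) + stats::runif(1, 0, 2 * pi)) %% (2 * pi)

  labels <- integer(n)
  prim <- dmin <= q[1]
  labels[prim] <- if (n_p == 2) ifelse(nearer1[prim], ids_p[1], ids_p[2]) else ids_p[1]
  inter <- !prim & dmin <= q[2]
  sec_i <- pmin(n_i, 1L + floor(phi[inter] / (2 * pi) * n_i))
  labels[inter] <- ids_i[sec_i]
  distb <- dmin > q[2]
  sec_d <- pmin(2L * n_d, 1L + floor(phi[distb] / (2 * pi) * (2 * n_d)))
  labels[distb] <- ids_d[1L + (sec_d - 1L) %% n_d]

  labels <- absorb_small_islands(labels, mesh, min_keep = 6L)
  parc <- parcellation(labels)
  list(parc = parc, seeds = which(labels %in% ids_p),
       tiers = tibble::tibble(network = seq_len(config$n_networks), tier = tiers),
       anchors = c(a1, a2))
}

# Reassign tiny disconnected islands (discretization slivers at band or
# sector boundaries) to the majority label among their neighbours, so every
# patch of the generated parcellation is a meaningful spatial unit.
absorb_small_islands <- function(labels, mesh, min_keep = 6L) {
  adj <- mesh_adjacency(mesh)
  for (pass in 1:10) {
    patches <- extract_patches(parcellation(labels), mesh, min_size = 0)
    small <- patches[patches$size < min_keep, ]
    if (nrow(small) == 0L) break
    for (i in seq_len(nrow(small))) {
      vs <- small$vertices[[i]]
      nb_labels <- unlist(lapply(vs, function(x) labels[adj[[x]]]))
      nb_labels <- nb_labels[!(nb_labels %in% labels[vs[1]])]
      if (length(nb_labels) == 0L) next
      labels[vs] <- as.integer(names(which.max(table(nb_labels))))
    }
  }
  labels
}

# Structural (noiseless) target correlation: local geodesic decay plus
# long-range coupling within distributed-tier networks (different patches),
# clipped and repaired to the nearest valid correlation structure by
# clipping eigenvalues at a small positive floor and renormalizing to unit
# diagonal.
structural_correlation <- function(mesh, parc, dist, config, repair = TRUE) {
  dm <- unclass(dist)
  C <- exp(-dm / config$lambda_local)
  rho_of_tier <- c(distributed = config$rho_network,
                   intermediate = config$rho_intermediate %||% 0)
  if (any(rho_of_tier > 0)) {
    patches <- extract_patches(parc, mesh, min_size = 0)
    labels <- parc_labels(parc)
    for (tier in names(rho_of_tier)) {
      rho <- rho_of_tier[[tier]]
      if (rho <= 0) next
      tier_nets <- which(config$tier_of_network == tier)
      for (net in intersect(tier_nets, unique(labels))) {
        vs <- which(labels == net)
        pid <- integer(length(vs))
        prows <- patches[patches$network == net, ]
        for (p in seq_len(nrow(prows))) {
          pid[match(prows$vertices[[p]], vs)] <- p
        }
        add <- rho * outer(pid, pid, "!=")
        C[vs, vs] <- C[vs, vs] + add
      }
    }
  }
  C[C > 0.99] <- 0.99
  diag(C) <- 1
  if (repair) C <- repair_correlation(C)$C
  C
}

# Eigenvalue clipping repair; returns the repaired correlation and a factor
# F with F %*% t(F) = C (rows unit norm) for exact Gaussian sampling.
repair_correlation <- function(C, floor_frac = 1e-8) {
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, floor_frac * max(eg$values))
  fac <- eg$vectors %*% diag(sqrt(lam))
  s <- sqrt(rowSums(fac^2))
  fac <- fac / s
  list(C = tcrossprod(fac), F = fac)
}

#' Simulate distance-coupled vertex time series
#'
#' Draws, for every subject and run, `T` samples of a zero-mean Gaussian
#' whose correlation is the structural target
#' `clip[exp(-d_geo/lambda_local) + rho_tier * same-network,
#' different-patch]` (with `rho_tier` = `rho_network` for distributed-tier
#' and `rho_intermediate` for intermediate-tier networks), repaired to a
#' valid correlation structure, plus
#' independent measurement noise of SD `noise_sd`.  Fully reproducible from
#' `config$rng_seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param parc the [parcellation()] from [make_tiered_parcellation()].
#' @param config a [generator_config()].
#' @param dist a `surf_dist` for `mesh` (unnormalized, mm).
#' @return a tibble with columns `subject`, `run`, `ts` (list-column of
#'   `N x T` matrices); attribute `target_correlation` holds the repaired
#'   structural correlation the samples converge to (up to uniform noise
#'   attenuation `1/(1+noise_sd^2)`).
#' @export
simulate_timeseries <- function(mesh, parc, config = generator_config(), dist) {
  C <- structural_correlation(mesh, parc, dist, config, repair = FALSE)
  rep <- repair_correlation(C)
  fac <- rep$F
  n <- nrow(fac)
  grid <- tidyr::expand_grid(subject = seq_len(config$n_subjects),
                             run = seq_len(config$n_runs))
  ts <- purrr::pmap(grid, function(subject, run) {
    set.seed(as.integer((config$rng_seed + 1000 * subject + run) %%
                          .Machine$integer.max))
    z <- matrix(stats::rnorm(n * config$T), n, config$T)
    x <- fac %*% z
    if (config$noise_sd > 0) {
      x <- x + config$noise_sd * matrix(stats::rnorm(n * config$T), n, config$T)
    }
    x
  })
  out <- dplyr::mutate(grid, ts = ts)
  attr(out, "target_correlation") <- rep$C
  out
}

#' Noiseless ground-truth DCA map
#'
#' The distance-to-connected-areas map computed from the repaired
#' structural correlation target instead of sample correlations; the
#' estimate from [simulate_timeseries()] converges to it as `T` grows
#' (noise attenuation is uniform across pairs and so never changes a
#' node's connectivity ranking).
#'
#' @inheritParams simulate_timeseries
#' @param percent node-wise threshold, as in
#'   [distance_to_connected_areas()].
#' @return a [vertex_map()].
#' @export
ground_truth_dca <- function(parc, dist, config = generator_config(),
                             percent = 2, mesh = NULL) {
  if (is.null(mesh)) stop("`mesh` is required (patch structure of the parcellation)")
  C <- structural_correlation(mesh, parc, dist, config, repair = TRUE)
  distance_to_connected_areas(new_conn_matrix(C), dist, percent = percent)
}
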