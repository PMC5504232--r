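# Mesh fixtures built in code: planar grids, tori and bumpy icospheres, plus
# an independent edge-graph Dijkstra oracle for geodesic checks.

# Right-triangle planar grid mesh on [0, (nx-1)*h] x [0, (ny-1)*h], z = 0.
grid_mesh <- function(nx = 6, ny = 6, h = 1, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xy <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1)
  v <- cbind(xy$x * h, xy$y * h, 0)
  if (jitter > 0) {
    interior <- xy$x > 0 & xy$x < nx - 1 & xy$y > 0 & xy$y < ny - 1
    v[interior, 1:2] <- v[interior, 1:2] +
      matrix(stats::runif(2 * sum(interior), -jitter, jitter), ncol = 2)
  }
  id <- function(i, j) (j - 1) * nx + i
  f <- NULL
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      f <- rbind(f,
                 c(id(i, j), id(i + 1, j), id(i, j + 1)),
                 c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  surface_mesh(v, f)
}

# Torus grid mesh (closed surface, nontrivial curvature).
torus_mesh <- function(nu = 10, nv = 8, R = 3, r = 1) {
  uu <- 2 * pi * (seq_len(nu) - 1) / nu
  vv <- 2 * pi * (seq_len(nv) - 1) / nv
  g <- expand.grid(u = uu, v = vv)
  vtx <- cbind((R + r * cos(g$v)) * cos(g$u),
               (R + r * cos(g$v)) * sin(g$u),
               r * sin(g$v))
  id <- function(i, j) ((j - 1) %% nv) * nu + ((i - 1) %% nu) + 1
  f <- NULL
  for (j in seq_len(nv)) {
    for (i in seq_len(nu)) {
      f <- rbind(f,
                 c(id(i, j), id(i + 1, j), id(i, j + 1)),
                 c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
    }
  }
  surface_mesh(vtx, f)
}

# Icosphere with random radial bumps (bumpy closed surface, <= 500 vertices
# at subdivisions <= 2).
bumpy_sphere <- function(subdivisions = 2, radius = 10, bump = 0.15,
                         seed = 1) {
  set.seed(seed)
  m <- make_icosphere(subdivisions, radius_mm = radius)
  scale <- 1 + stats::runif(n_vertices(m), -bump, bump)
  m$vertices <- m$vertices * scale
  m
}

# A small pool of varied test meshes (all <= 500 vertices), keyed by seed.
random_test_mesh <- function(seed) {
  set.seed(seed)
  kind <- seed %% 3
  if (kind == 0) {
    grid_mesh(nx = 5 + seed %% 4, ny = 5 + (seed + 1) %% 4,
              jitter = 0.2, seed = seed)
  } else if (kind == 1) {
    torus_mesh(nu = 8 + seed %% 5, nv = 6 + seed %% 4)
  } else {
    bumpy_sphere(2, radius = 5 + seed %% 10, bump = 0.2, seed = seed)
  }
}

# Independent oracle: Dijkstra on the raw vertex-edge graph, built through
# igraph directly from the face list (separate code path from the package's
# refined-graph machinery).
dijkstra_oracle <- function(mesh, sources = NULL) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  n <- nrow(mesh$vertices)
  if (is.null(sources)) sources <- seq_len(n)
  d <- igraph::distances(g, v = sources, to = seq_len(n))
  dimnames(d) <- NULL
  d
}

# Hand-rolled O(V^2) Dijkstra, fully independent of igraph; for tiny meshes.
dijkstra_by_hand <- function(mesh, source) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  n <- nrow(mesh$vertices)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- logical(n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    inc <- which(e[, 1] == u | e[, 2] == u)
    for (k in inc) {
      v <- if (e[k, 1] == u) e[k, 2] else e[k, 1]
      if (dist[u] + w[k] < dist[v]) dist[v] <- dist[u] + w[k]
    }
  }
  dist
}

# Naive double-loop DCA, the definition written out directly.
naive_dca <- function(conn, dist, percent) {
  n <- nrow(conn)
  k <- max(1, round(percent / 100 * (n - 1)))
  out <- numeric(n)
  for (v in seq_len(n)) {
    r <- conn[v, ]
    r[v] <- -Inf
    ord <- order(-r, seq_len(n))
    sel <- ord[seq_len(k)]
    out[v] <- mean(dist[v, sel])
  }
  out
}
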