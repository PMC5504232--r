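#' Triangular surface mesh
#'
#' Container for a triangulated surface: an `N x 3` matrix of vertex
#' coordinates (millimetres) and an `M x 3` matrix of 1-based vertex indices,
#' one row per triangle.  All distances in the package are computed on one
#' such mesh (one cortical hemisphere); no cross-mesh distance exists.
#'
#' @param vertices numeric `N x 3` matrix of coordinates (mm).
#' @param faces integer `M x 3` matrix of 1-based vertex indices; every row
#'   must name three distinct vertices.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @examples
#' m <- make_icosphere(1, radius_mm = 70)
#' m
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("`faces` must be an M x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices must lie in [1, ", n, "]")
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
    faces[, 2] == faces[, 3]
  if (any(degen)) {
    stop("degenerate faces (repeated vertex) at rows: ",
         paste(utils::head(which(degen), 5), collapse = ", "))
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh a [surface_mesh()].
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Undirected unique edge list (two columns, v1 < v2) with Euclidean lengths.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  list(edges = e, lengths = sqrt(rowSums(d * d)))
}

# Weighted igraph of the vertex-edge graph.
mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- ed$lengths
  g
}

# Adjacency list: for each vertex, the integer vector of its neighbours.
mesh_adjacency <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  n <- n_vertices(mesh)
  adj <- split(c(ed[, 2], ed[, 1]), factor(c(ed[, 1], ed[, 2]), levels = seq_len(n)))
  lapply(adj, as.integer)
}

# Number of connected components of the vertex-edge graph.
mesh_components <- function(mesh) {
  igraph::components(mesh_graph(mesh))$no
}

# One round of flat midpoint subdivision: every edge gains its midpoint,
# every triangle splits into four.  Midpoints lie on the original faces, so
# the polyhedral surface itself is unchanged -- only the graph is refined.
# Returns the refined mesh plus the ids of the original vertices in it.
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  ed <- mesh_edges(mesh)$edges
  mid_id <- n + seq_len(nrow(ed))
  # lookup: edge (a,b), a<b  ->  midpoint vertex id
  key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  idx <- structure(mid_id, names = key(ed[, 1], ed[, 2]))
  mids <- (v[ed[, 1], , drop = FALSE] + v[ed[, 2], , drop = FALSE]) / 2
  m12 <- idx[as.character(key(f[, 1], f[, 2]))]
  m23 <- idx[as.character(key(f[, 2], f[, 3]))]
  m13 <- idx[as.character(key(f[, 1], f[, 3]))]
  new_f <- rbind(
    cbind(f[, 1], m12, m13),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m13, m23),
    cbind(m12, m23, m13)
  )
  list(mesh = surface_mesh(rbind(v, mids), new_f), original = seq_len(n))
}

#' Icosphere mesh generator
#'
#' Builds a geodesic sphere by repeatedly subdividing an icosahedron and
#' projecting new vertices back to the sphere.  With `subdivisions = s` the
#' mesh has `10 * 4^s + 2` vertices and `20 * 4^s` faces; the default radius
#' of 70 mm is comparable to a human cortical hemisphere.
#'
#' @param subdivisions non-negative integer; 0 gives the bare icosahedron
#'   (12 vertices, 20 faces).
#' @param radius_mm sphere radius in millimetres.
#' @return a [surface_mesh()].
#' @examples
#' make_icosphere(2)
#' @export
make_icosphere <- function(subdivisions = 4, radius_mm = 70) {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  mesh <- surface_mesh(v, f)
  for (i in seq_len(subdivisions)) {
    mesh <- subdivide_midpoint(mesh)$mesh
  }
  r <- sqrt(rowSums(mesh$vertices^2))
  mesh$vertices <- mesh$vertices / r * radius_mm
  mesh
}
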