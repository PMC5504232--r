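#' Vertexwise functional connectivity
#'
#' Functional connectivity between two vertices is the Pearson
#' product-moment correlation of their time series.  `correlation_matrix()`
#' turns one run's vertices-by-timepoints matrix into the node-by-node
#' connectivity matrix of its hemisphere; matrices from several runs are
#' combined with [average_matrices()].  Correlation is invariant to per-row
#' affine rescaling, so upstream mean-centering / variance normalization of
#' the time series needs no separate step here.
#'
#' @param ts numeric `N x T` matrix, vertices in rows, timepoints in columns
#'   (`T >= 3`).  Any missing vertices must be repaired first with
#'   [fill_missing_vertices()].
#' @return a `conn_matrix`: symmetric `N x N` matrix in `[-1, 1]` with unit
#'   diagonal and attribute `n_runs` (number of runs combined).
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts, 1, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0L) {
    stop("zero-variance (or missing) time series at vertices: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  }
  r <- stats::cor(t(ts))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- NULL
  new_conn_matrix(r, n_runs = 1L)
}

new_conn_matrix <- function(values, n_runs = 1L) {
  structure(values, class = c("conn_matrix", "matrix", "array"),
            n_runs = as.integer(n_runs))
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d x %d, %d run(s) combined\n",
              nrow(x), ncol(x), attr(x, "n_runs")))
  invisible(x)
}

#' Combine connectivity matrices across runs
#'
#' Runs are combined by entrywise arithmetic averaging of the raw
#' correlation values.  A Fisher z alternative (average `atanh(r)`, then
#' `tanh` back) is available but off by default.
#'
#' @param mats list of `conn_matrix` objects of identical dimension.
#' @param fisher_z average on the Fisher z scale instead of raw r.
#' @return a `conn_matrix` with `n_runs` equal to `length(mats)`.
#' @export
average_matrices <- function(mats, fisher_z = FALSE) {
  if (!is.list(mats) || length(mats) == 0L) {
    stop("`mats` must be a nonempty list of connectivity matrices")
  }
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) stop("all matrices must have the same shape")
  n <- length(mats)
  if (fisher_z) {
    acc <- Reduce(`+`, lapply(mats, function(m) {
      z <- unclass(m); z[z > 0.999999] <- 0.999999; z[z < -0.999999] <- -0.999999
      atanh(z)
    })) / n
    avg <- tanh(acc)
  } else {
    avg <- Reduce(`+`, lapply(mats, unclass)) / n
  }
  diag(avg) <- 1
  new_conn_matrix(avg, n_runs = sum(vapply(mats, function(m) {
    as.integer(attr(m, "n_runs") %||% 1L)
  }, integer(1))))
}

#' Repair vertices without data by neighbourhood interpolation
#'
#' Vertices with no sampled time series (e.g. occipital-pole vertices that
#' fell outside the functional field of view) are filled by iteratively
#' averaging the time series of their immediate mesh neighbours that already
#' carry data; rounds repeat until no missing vertex remains.  Valid vertices
#' are never touched, so the operation is idempotent.
#'
#' @param ts numeric `N x T` matrix.
#' @param missing logical vector (length `N`) or integer indices of the
#'   vertices to fill.
#' @param mesh the [surface_mesh()] the rows of `ts` live on.
#' @return the repaired `N x T` matrix.
#' @export
fill_missing_vertices <- function(ts, missing, mesh) {
  ts <- as.matrix(ts)
  n <- nrow(ts)
  stopifnot(n == n_vertices(mesh))
  if (is.logical(missing)) missing <- which(missing)
  missing <- unique(as.integer(missing))
  if (length(missing) == 0L) return(ts)
  if (length(missing) >= n) stop("all vertices missing; nothing to interpolate from")
  adj <- mesh_adjacency(mesh)
  valid <- rep(TRUE, n); valid[missing] <- FALSE
  while (length(missing) > 0L) {
    can_fill <- missing[vapply(missing, function(v) any(valid[adj[[v]]]), logical(1))]
    if (length(can_fill) == 0L) {
      stop("missing vertices disconnected from any data: ",
           paste(utils::head(missing, 10), collapse = ", "))
    }
    filled <- lapply(can_fill, function(v) {
      nb <- adj[[v]][valid[adj[[v]]]]
      colMeans(ts[nb, , drop = FALSE])
    })
    for (i in seq_along(can_fill)) ts[can_fill[i], ] <- filled[[i]]
    valid[can_fill] <- TRUE
    missing <- setdiff(missing, can_fill)
  }
  ts
}

#' Node-wise top-percentile connectivity threshold
#'
#' Selects, for one seed vertex, the `k` vertices with the highest
#' correlation to it, where `k = max(1, round(percent/100 * (N - 1)))`.  The
#' seed itself is excluded; ties at the cutoff are broken towards the lower
#' vertex index so the set is deterministic.  Negative correlations simply
#' rank low (no absolute-value ranking).
#'
#' @param conn a `conn_matrix`.
#' @param seed seed vertex index.
#' @param percent threshold level in `(0, 100]` (2 reproduces the default
#'   analysis; the set at a smaller percent is nested in the set at a larger
#'   one).
#' @return integer vector of the selected vertex indices.
#' @export
top_percent_neighbors <- function(conn, seed, percent) {
  if (!is.numeric(percent) || length(percent) != 1L ||
      percent <= 0 || percent > 100) {
    stop("`percent` must be a single value in (0, 100]")
  }
  n <- nrow(conn)
  seed <- as.integer(seed)
  stopifnot(seed >= 1L, seed <= n)
  k <- top_k_count(percent, n)
  r <- unclass(conn)[seed, ]
  r[seed] <- -Inf
  ord <- order(-r, seq_len(n))
  ord[seq_len(k)]
}

# k(percent, N) = max(1, round(percent/100 * (N-1))); round() is base R's
# banker's rounding -- documented and applied consistently everywhere.
top_k_count <- function(percent, n) {
  max(1L, as.integer(round(percent / 100 * (n - 1))))
}
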