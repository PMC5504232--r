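#' Distance-to-connected-areas (DCA)
#'
#' The core statistic: for every vertex, its connectivity row is thresholded
#' to the top `percent` most correlated vertices
#' ([top_percent_neighbors()]) and the vertex's surface distances to those
#' vertices are averaged.  Short values mark vertices whose strong
#' functional connections are local (typical of primary sensorimotor
#' cortex); long values mark vertices participating in distributed,
#' long-range networks (association cortex).  At `percent = 100` the map
#' degenerates to pure geometry: each vertex's mean distance to every other
#' vertex.
#'
#' @param conn a `conn_matrix` (see [correlation_matrix()]).
#' @param dist a `surf_dist` on the same mesh (see
#'   [geodesic_distance_matrix()]).
#' @param percent node-wise connectivity threshold in `(0, 100]`; the
#'   standard analysis uses 2.
#' @return a [vertex_map()] in the units of `dist` (mm, or normalized).
#' @examples
#' mesh <- make_icosphere(2, radius_mm = 70)
#' d <- geodesic_distance_matrix(mesh)
#' set.seed(1)
#' ts <- matrix(rnorm(n_vertices(mesh) * 50), n_vertices(mesh))
#' dca <- distance_to_connected_areas(correlation_matrix(ts), d, percent = 10)
#' @export
distance_to_connected_areas <- function(conn, dist, percent = 2) {
  n <- nrow(conn)
  if (nrow(dist) != n || ncol(dist) != n || ncol(conn) != n) {
    stop("connectivity (", nrow(conn), "x", ncol(conn), ") and distance (",
         nrow(dist), "x", ncol(dist), ") matrices must be square and aligned")
  }
  if (!is.numeric(percent) || percent <= 0 || percent > 100) {
    stop("`percent` must be in (0, 100]")
  }
  k <- top_k_count(percent, n)
  cm <- unclass(conn)
  dm <- unclass(dist)
  idx <- seq_len(n)
  vals <- vapply(idx, function(v) {
    r <- cm[v, ]
    r[v] <- -Inf
    sel <- order(-r, idx)[seq_len(k)]
    mean(dm[v, sel])
  }, numeric(1))
  units <- if (isTRUE(attr(dist, "normalized"))) "normalized" else "mm"
  vertex_map(vals, units = units, percent = percent,
             metric = attr(dist, "metric") %||% NA_character_)
}

#' Vertexwise group average of aligned maps
#'
#' @param maps list of [vertex_map()]s (or numeric vectors) on the same
#'   mesh and in the same units, one per subject (or run).
#' @return the vertexwise mean as a [vertex_map()].
#' @export
group_average <- function(maps) {
  if (!is.list(maps) || length(maps) == 0L) stop("`maps` must be a nonempty list")
  maps <- lapply(maps, as_vertex_map)
  units <- unique(vapply(maps, map_units, character(1)))
  if (length(units) != 1L) {
    stop("maps mix units (", paste(units, collapse = ", "),
         "); convert before averaging")
  }
  vals <- lapply(maps, map_values)
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) stop("maps differ in length")
  out <- Reduce(`+`, vals) / length(vals)
  vertex_map(out, units = units,
             percent = attr(maps[[1]], "percent") %||% NA_real_,
             metric = attr(maps[[1]], "metric") %||% NA_character_)
}

#' Rescale a normalized group map back to millimetres
#'
#' Subject distance matrices are min-max normalized before group analysis to
#' adjust for brain size; this undoes that for readability.  A normalized
#' value `x` maps to `x * mean(range) + mean(min)` over the subjects' stored
#' normalization parameters -- for a single subject this is the exact
#' inverse of its own normalization.
#'
#' @param map a normalized [vertex_map()].
#' @param subject_ranges data frame (or tibble) with numeric columns `min`
#'   and `range`, one row per subject, recorded by [normalize_distances()]
#'   (attributes `norm_min`, `norm_range`).
#' @return a [vertex_map()] in mm.
#' @export
rescale_to_mm <- function(map, subject_ranges) {
  map <- as_vertex_map(map, units = "normalized")
  if (map_units(map) != "normalized") stop("`map` must be in normalized units")
  if (is.null(subject_ranges) || !all(c("min", "range") %in% names(subject_ranges)) ||
      nrow(as.data.frame(subject_ranges)) == 0L ||
      any(!is.finite(subject_ranges$min)) || any(!is.finite(subject_ranges$range))) {
    stop("normalization provenance missing: need finite `min` and `range` per subject")
  }
  vals <- map_values(map) * mean(subject_ranges$range) + mean(subject_ranges$min)
  vertex_map(vals, units = "mm", percent = attr(map, "percent") %||% NA_real_,
             metric = attr(map, "metric") %||% NA_character_)
}

#' Geodesic-minus-Euclidean difference map
#'
#' Subtracting the Euclidean-based map from the geodesic-based one
#' highlights regions (e.g. across sulci or between opposing banks) where
#' straight-line distance underestimates distance along the sheet.
#'
#' @param geo,euc aligned [vertex_map()]s in the same units.
#' @return a [vertex_map()] of `geo - euc`, units `"unitless"` if inputs
#'   were normalized, else mm.
#' @export
metric_difference_map <- function(geo, euc) {
  geo <- as_vertex_map(geo); euc <- as_vertex_map(euc)
  if (map_units(geo) != map_units(euc)) stop("maps differ in units")
  g <- map_values(geo); e <- map_values(euc)
  if (length(g) != length(e)) stop("maps differ in length")
  vertex_map(g - e, units = map_units(geo),
             percent = attr(geo, "percent") %||% NA_real_,
             metric = "difference")
}

#' Test-retest reliability map (intraclass correlation)
#'
#' Per-vertex intraclass correlation coefficient of subject-by-run DCA
#' values.  The default variant is ICC(2,1): two-way random effects,
#' absolute agreement, single measurement,
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with `n` subjects (rows), `k` runs (columns).  ICC(3,1) (consistency,
#' runs fixed) is available as an option.  Values are clipped to `[-1, 1]`
#' for reporting.
#'
#' @param maps_by_run a tibble/data frame with columns `subject`, `run` and
#'   a list-column `map` of aligned [vertex_map()]s (every subject must have
#'   every run), or a 3-d array `vertices x subjects x runs`.
#' @param variant `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return a [vertex_map()] of ICC values, units `"unitless"`.
#' @export
icc_map <- function(maps_by_run, variant = c("ICC2_1", "ICC3_1")) {
  variant <- match.arg(variant)
  arr <- icc_input_array(maps_by_run)
  n <- dim(arr)[2]; k <- dim(arr)[3]
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 runs")
  mu <- apply(arr, 1, mean)
  row_m <- apply(arr, c(1, 2), mean) # vertices x subjects
  col_m <- apply(arr, c(1, 3), mean) # vertices x runs
  ss_rows <- k * rowSums((row_m - mu)^2)
  ss_cols <- n * rowSums((col_m - mu)^2)
  ss_tot <- apply(arr, 1, function(x) sum((x - mean(x))^2))
  ss_err <- pmax(ss_tot - ss_rows - ss_cols, 0)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- if (variant == "ICC2_1") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  icc[!is.finite(icc)] <- 0
  vertex_map(pmin(1, pmax(-1, icc)), units = "unitless")
}

icc_input_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopifnot(is.data.frame(x), all(c("subject", "run", "map") %in% names(x)))
  subs <- sort(unique(x$subject)); runs <- sort(unique(x$run))
  if (nrow(x) != length(subs) * length(runs)) {
    stop("need a complete subject x run table of maps")
  }
  nv <- length(map_values(x$map[[1]]))
  arr <- array(NA_real_, c(nv, length(subs), length(runs)))
  for (i in seq_len(nrow(x))) {
    arr[, match(x$subject[i], subs), match(x$run[i], runs)] <-
      map_values(x$map[[i]])
  }
  if (anyNA(arr)) stop("maps differ in length or table incomplete")
  arr
}

#' DCA across a range of connectivity thresholds
#'
#' Recomputes the map at each threshold so results are not specific to one
#' arbitrary choice; under distance-decaying connectivity, distances
#' decrease with stricter thresholds.
#'
#' @inheritParams distance_to_connected_areas
#' @param percents numeric vector of thresholds, e.g.
#'   `c(30, 25, 20, 15, 10, 5, 2)`.
#' @return a tibble with one row per threshold: `percent`, `map`
#'   (list-column of [vertex_map()]s), `median` (vertexwise median of the
#'   map).
#' @export
threshold_sweep <- function(conn, dist, percents = c(30, 25, 20, 15, 10, 5, 2)) {
  maps <- purrr::map(percents, ~distance_to_connected_areas(conn, dist, .x))
  tibble::tibble(
    percent = percents,
    map = maps,
    median = purrr::map_dbl(maps, ~stats::median(map_values(.x)))
  )
}
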