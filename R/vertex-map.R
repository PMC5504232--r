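#' Per-vertex scalar maps
#'
#' A vertex map holds one scalar per mesh vertex (a distance-to-connected-areas
#' map, a distance-from-primary map, an ICC map, ...).  It is a tibble with
#' columns `vertex` and `value` so it drops straight into dplyr/ggplot2
#' pipelines; measurement metadata travel as attributes.
#'
#' @param values numeric vector, one value per vertex (NA allowed only for
#'   vertices explicitly flagged absent, e.g. unassigned vertices of a model
#'   map).
#' @param units one of `"mm"`, `"normalized"`, `"unitless"`.
#' @param percent,metric optional provenance: connectivity threshold (per
#'   cent) and distance metric (`"geodesic"`/`"euclidean"`) the map was
#'   computed with.
#' @return a tibble of class `vertex_map` with columns `vertex`, `value`.
#' @export
vertex_map <- function(values, units = c("mm", "normalized", "unitless"),
                       percent = NA_real_, metric = NA_character_) {
  units <- match.arg(units)
  out <- tibble::tibble(vertex = seq_along(values), value = as.double(values))
  class(out) <- c("vertex_map", class(out))
  attr(out, "units") <- units
  attr(out, "percent") <- percent
  attr(out, "metric") <- metric
  out
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("<vertex_map> %d vertices, units = %s", nrow(x), map_units(x)))
  if (!is.na(attr(x, "percent"))) cat(sprintf(", percent = %g", attr(x, "percent")))
  if (!is.na(attr(x, "metric") %||% NA)) cat(sprintf(", metric = %s", attr(x, "metric")))
  cat("\n")
  NextMethod()
}

#' @rdname vertex_map
#' @param x a `vertex_map`, or any numeric vector of per-vertex values.
#' @export
map_values <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot("value" %in% names(x))
    x$value[order(x$vertex)]
  } else {
    as.double(x)
  }
}

#' @rdname vertex_map
#' @export
map_units <- function(x) attr(x, "units") %||% "unitless"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce numeric vectors to vertex_map, pass vertex_maps through.
as_vertex_map <- function(x, units = "unitless") {
  if (inherits(x, "vertex_map")) x else vertex_map(x, units = units)
}
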