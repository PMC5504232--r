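# Readers/writers for the surface-analysis formats the pipeline consumes:
# FreeSurfer binary surface / curv / annot, GIFTI (surface, shape, label,
# time series), OFF for fixtures, CSV for maps and time series, a small
# binary container for pairwise distance matrices, and JSON for null
# results.  All numeric payloads round-trip exactly at their storage
# precision (float32 for FreeSurfer/GIFTI, float64 elsewhere).

# ---- OFF ------------------------------------------------------------------

#' Read / write meshes in OFF format
#'
#' Plain-text Object File Format; handy for fixtures and interchange.
#'
#' @param path file path.
#' @param mesh a [surface_mesh()].
#' @return `read_off()` returns a [surface_mesh()]; `write_off()` its input,
#'   invisibly.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]][1:3])
  }))
  fac <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- as.integer(strsplit(l, "\\s+")[[1]])
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  surface_mesh(vtx, fac)
}

#' @rdname read_off
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_faces(mesh)), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(mesh)
}

# ---- FreeSurfer binary surface -------------------------------------------

fs_read_int3 <- function(con) {
  b <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  b[1] * 65536L + b[2] * 256L + b[3]
}

fs_write_int3 <- function(con, value) {
  writeBin(as.raw(c(value %/% 65536 %% 256, value %/% 256 %% 256, value %% 256)),
           con)
}

#' Read / write FreeSurfer binary surfaces
#'
#' The triangle-file format used by `lh.white`, `lh.pial` etc. (magic
#' 0xFFFFFE, big-endian float32 coordinates, int32 0-based faces).
#'
#' @param path file path.
#' @param mesh a [surface_mesh()].
#' @param comment comment string stored in the header.
#' @return `read_fs_surface()` returns a [surface_mesh()].
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- fs_read_int3(con)
  if (magic != 16777214L) stop("not a FreeSurfer triangle surface: ", path)
  # comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated surface file")
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  vtx <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "big"),
                ncol = 3, byrow = TRUE)
  fac <- matrix(readBin(con, "integer", nf * 3, size = 4, endian = "big"),
                ncol = 3, byrow = TRUE) + 1L
  surface_mesh(vtx, fac)
}

#' @rdname read_fs_surface
#' @export
write_fs_surface <- function(mesh, path, comment = "created by geodca") {
  con <- file(path, "wb")
  on.exit(close(con))
  fs_write_int3(con, 16777214L)
  writeBin(charToRaw(paste0(comment, "\n\n")), con)
  writeBin(n_vertices(mesh), con, size = 4, endian = "big")
  writeBin(n_faces(mesh), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4, endian = "big")
  invisible(mesh)
}

#' Read / write FreeSurfer curvature (morph) files
#'
#' Per-vertex scalar maps in the "new" curv format (magic 0xFFFFFF,
#' big-endian float32); values are stored at float32 precision.
#'
#' @param path file path.
#' @param map a [vertex_map()] or numeric vector.
#' @param units units recorded on the returned map.
#' @return `read_fs_curv()` returns a [vertex_map()].
#' @export
read_fs_curv <- function(path, units = "unitless") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- fs_read_int3(con)
  if (magic != 16777215L) stop("not a new-format curv file: ", path)
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "big") # fnum, vals_per_vertex
  vals <- readBin(con, "numeric", nv, size = 4, endian = "big")
  vertex_map(vals, units = units)
}

#' @rdname read_fs_curv
#' @export
write_fs_curv <- function(map, path) {
  vals <- map_values(as_vertex_map(map))
  con <- file(path, "wb")
  on.exit(close(con))
  fs_write_int3(con, 16777215L)
  writeBin(length(vals), con, size = 4, endian = "big")
  writeBin(0L, con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")
  writeBin(as.numeric(vals), con, size = 4, endian = "big")
  invisible(map)
}

# ---- FreeSurfer annot -----------------------------------------------------

#' Read / write FreeSurfer annotation files
#'
#' Per-vertex integer labels with a colour table (version-2 colortable).
#' Network ids are encoded through the colour lookup exactly as FreeSurfer
#' does (`code = r + g*2^8 + b*2^16`); unassigned vertices get code 0.
#'
#' @param path file path.
#' @param parc a [parcellation()].
#' @param names optional character vector of structure names, one per
#'   network id present.
#' @return `read_fs_annot()` returns a [parcellation()].
#' @export
read_fs_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  dat <- readBin(con, "integer", 2 * n, size = 4, endian = "big")
  vert <- dat[seq(1, 2 * n, by = 2)] + 1L
  code <- dat[seq(2, 2 * n, by = 2)]
  tag <- readBin(con, "integer", 1, size = 4, endian = "big")
  labels <- integer(max(vert))
  if (length(tag) == 1L && tag == 1L) {
    version <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (version != -2L) stop("only version-2 colortables are supported")
    readBin(con, "integer", 1, size = 4, endian = "big") # max structure id
    fn_len <- readBin(con, "integer", 1, size = 4, endian = "big")
    readBin(con, "raw", fn_len)
    n_entries <- readBin(con, "integer", 1, size = 4, endian = "big")
    ids <- integer(n_entries); codes <- integer(n_entries)
    nms <- character(n_entries)
    for (i in seq_len(n_entries)) {
      ids[i] <- readBin(con, "integer", 1, size = 4, endian = "big") + 1L
      nm_len <- readBin(con, "integer", 1, size = 4, endian = "big")
      nms[i] <- rawToChar(readBin(con, "raw", nm_len)[seq_len(max(0, nm_len - 1))])
      rgba <- readBin(con, "integer", 4, size = 4, endian = "big")
      codes[i] <- rgba[1] + rgba[2] * 256L + rgba[3] * 65536L
    }
    labels[vert] <- ids[match(code, codes)]
    labels[is.na(labels)] <- 0L
    nm_tbl <- tibble::tibble(network = ids, name = nms)
    return(parcellation(labels, network_names = nm_tbl))
  }
  labels[vert] <- code
  parcellation(labels)
}

#' @rdname read_fs_annot
#' @export
write_fs_annot <- function(parc, path, names = NULL) {
  labels <- parc_labels(parc)
  nets <- sort(unique(labels[labels > 0L]))
  if (is.null(names)) names <- sprintf("network_%d", nets)
  stopifnot(length(names) == length(nets))
  # distinct colours -> codes; id 0 stays code 0
  r <- (nets * 37L) %% 256L
  g <- (nets * 101L) %% 256L
  b <- (nets * 197L + 1L) %% 256L
  codes <- r + g * 256L + b * 65536L
  if (anyDuplicated(codes)) stop("colour collision; too many networks")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(labels)
  writeBin(n, con, size = 4, endian = "big")
  code_of <- c(0L, codes)[match(labels, c(0L, nets))]
  interleaved <- integer(2 * n)
  interleaved[seq(1, 2 * n, by = 2)] <- seq_len(n) - 1L
  interleaved[seq(2, 2 * n, by = 2)] <- code_of
  writeBin(interleaved, con, size = 4, endian = "big")
  writeBin(1L, con, size = 4, endian = "big")   # tag: colortable present
  writeBin(-2L, con, size = 4, endian = "big")  # version 2
  writeBin(max(nets), con, size = 4, endian = "big")
  fn <- c(charToRaw("geodca.ctab"), as.raw(0))
  writeBin(length(fn), con, size = 4, endian = "big")
  writeBin(fn, con)
  writeBin(length(nets), con, size = 4, endian = "big")
  for (i in seq_along(nets)) {
    writeBin(nets[i] - 1L, con, size = 4, endian = "big")
    nm <- c(charToRaw(names[i]), as.raw(0))
    writeBin(length(nm), con, size = 4, endian = "big")
    writeBin(nm, con)
    writeBin(c(r[i], g[i], b[i], 0L), con, size = 4, endian = "big")
  }
  invisible(parc)
}

# ---- GIFTI ----------------------------------------------------------------

gifti_dtype <- function(x) {
  switch(x,
         NIFTI_TYPE_FLOAT32 = list(what = "numeric", size = 4),
         NIFTI_TYPE_FLOAT64 = list(what = "numeric", size = 8),
         NIFTI_TYPE_INT32 = list(what = "integer", size = 4),
         stop("unsupported GIFTI data type: ", x))
}

gifti_read_darray <- function(node) {
  at <- xml2::xml_attrs(node)
  dims <- as.integer(at[grep("^Dim[0-9]$", names(at))])
  dt <- gifti_dtype(at[["DataType"]])
  enc <- at[["Encoding"]]
  txt <- xml2::xml_text(xml2::xml_find_first(node, ".//*[local-name()='Data']"))
  vals <- if (enc == "ASCII") {
    v <- as.numeric(strsplit(trimws(txt), "\\s+")[[1]])
    if (dt$what == "integer") as.integer(v) else v
  } else if (enc %in% c("Base64Binary", "GZipBase64Binary")) {
    raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
    if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
    endian <- if (identical(at[["Endian"]], "BigEndian")) "big" else "little"
    readBin(raw, dt$what, n = prod(dims), size = dt$size, endian = endian)
  } else {
    stop("unsupported GIFTI encoding: ", enc)
  }
  if (length(dims) > 1L) {
    # stored row-major; return as R (column-major) matrix
    vals <- t(matrix(vals, nrow = dims[2], ncol = dims[1]))
  }
  list(intent = at[["Intent"]], values = vals, dims = dims)
}

read_gifti_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name()='DataArray']")
  lapply(nodes, gifti_read_darray)
}

gifti_format_data <- function(values, type) {
  if (type == "NIFTI_TYPE_INT32") {
    paste(as.integer(values), collapse = " ")
  } else {
    paste(format(values, digits = 9, trim = TRUE, scientific = TRUE),
          collapse = " ")
  }
}

write_gifti_arrays <- function(arrays, path, label_table = NULL) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  if (!is.null(label_table)) {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (i in seq_len(nrow(label_table))) {
      lb <- xml2::xml_add_child(lt, "Label", Key = as.character(label_table$network[i]))
      xml2::xml_text(lb) <- label_table$name[i]
    }
  }
  for (a in arrays) {
    values <- a$values
    if (is.matrix(values)) {
      dims <- dim(values)
      flat <- as.vector(t(values)) # row-major on disk
    } else {
      dims <- length(values)
      flat <- values
    }
    attrs <- c(Intent = a$intent, DataType = a$type,
               ArrayIndexingOrder = "RowMajorOrder",
               Dimensionality = as.character(length(dims)))
    for (i in seq_along(dims)) {
      attrs[paste0("Dim", i - 1)] <- as.character(dims[i])
    }
    attrs <- c(attrs, Encoding = "ASCII", Endian = "LittleEndian",
               ExternalFileName = "", ExternalFileOffset = "")
    da <- xml2::xml_add_child(doc, "DataArray")
    for (nm in names(attrs)) xml2::xml_set_attr(da, nm, attrs[[nm]])
    dn <- xml2::xml_add_child(da, "Data")
    xml2::xml_text(dn) <- gifti_format_data(flat, a$type)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write GIFTI files
#'
#' Minimal GIFTI-1 codec for the four array kinds the pipeline uses:
#' surfaces (`.surf.gii`: POINTSET + TRIANGLE), per-vertex shape maps
#' (`.shape.gii`), label maps (`.label.gii` with a label table) and
#' time-series stacks (`.func.gii`, one data array per timepoint).  Writing
#' uses ASCII encoding; reading also accepts Base64Binary and
#' GZipBase64Binary.
#'
#' @param path file path.
#' @param mesh,map,parc,ts object to write.
#' @param units units recorded on maps read back.
#' @param names optional network names for label files.
#' @return readers return the corresponding package object.
#' @export
read_gifti_surface <- function(path) {
  arrs <- read_gifti_arrays(path)
  intents <- vapply(arrs, `[[`, character(1), "intent")
  pt <- arrs[[match("NIFTI_INTENT_POINTSET", intents)]]
  tr <- arrs[[match("NIFTI_INTENT_TRIANGLE", intents)]]
  surface_mesh(pt$values, tr$values + 1L)
}

#' @rdname read_gifti_surface
#' @export
write_gifti_surface <- function(mesh, path) {
  write_gifti_arrays(list(
    list(intent = "NIFTI_INTENT_POINTSET", type = "NIFTI_TYPE_FLOAT32",
         values = mesh$vertices),
    list(intent = "NIFTI_INTENT_TRIANGLE", type = "NIFTI_TYPE_INT32",
         values = mesh$faces - 1L)
  ), path)
  invisible(mesh)
}

#' @rdname read_gifti_surface
#' @export
read_gifti_map <- function(path, units = "unitless") {
  arrs <- read_gifti_arrays(path)
  vertex_map(arrs[[1]]$values, units = units)
}

#' @rdname read_gifti_surface
#' @export
write_gifti_map <- function(map, path) {
  write_gifti_arrays(list(
    list(intent = "NIFTI_INTENT_SHAPE", type = "NIFTI_TYPE_FLOAT32",
         values = map_values(as_vertex_map(map)))
  ), path)
  invisible(map)
}

#' @rdname read_gifti_surface
#' @export
read_gifti_labels <- function(path) {
  doc <- xml2::read_xml(path)
  arrs <- read_gifti_arrays(path)
  labs <- xml2::xml_find_all(doc, "//*[local-name()='Label']")
  nm <- NULL
  if (length(labs) > 0) {
    nm <- tibble::tibble(
      network = as.integer(xml2::xml_attr(labs, "Key")),
      name = xml2::xml_text(labs)
    )
  }
  parcellation(as.integer(arrs[[1]]$values), network_names = nm)
}

#' @rdname read_gifti_surface
#' @export
write_gifti_labels <- function(parc, path, names = NULL) {
  labels <- parc_labels(parc)
  nets <- sort(unique(labels[labels > 0L]))
  nm <- attr(parc, "network_names")
  if (is.null(nm)) {
    if (is.null(names)) names <- sprintf("network_%d", nets)
    nm <- tibble::tibble(network = nets, name = names)
  }
  write_gifti_arrays(list(
    list(intent = "NIFTI_INTENT_LABEL", type = "NIFTI_TYPE_INT32",
         values = labels)
  ), path, label_table = nm)
  invisible(parc)
}

#' @rdname read_gifti_surface
#' @export
read_gifti_timeseries <- function(path) {
  arrs <- read_gifti_arrays(path)
  do.call(cbind, lapply(arrs, `[[`, "values"))
}

#' @rdname read_gifti_surface
#' @export
write_gifti_timeseries <- function(ts, path) {
  ts <- as.matrix(ts)
  arrays <- lapply(seq_len(ncol(ts)), function(j) {
    list(intent = "NIFTI_INTENT_TIME_SERIES", type = "NIFTI_TYPE_FLOAT32",
         values = ts[, j])
  })
  write_gifti_arrays(arrays, path)
  invisible(ts)
}

# ---- CSV and containers ---------------------------------------------------

#' CSV import/export for maps and time series
#'
#' Vertex maps go to two-column CSV (`vertex`, `value`); time-series
#' matrices to plain CSV, one row per vertex.
#'
#' @param map a [vertex_map()]; `ts` a matrix; `path` a file path.
#' @param units units recorded on read maps.
#' @param ts vertices-by-timepoints matrix.
#' @return readers return the corresponding object.
#' @export
write_map_csv <- function(map, path) {
  readr::write_csv(tibble::as_tibble(as_vertex_map(map)), path)
  invisible(map)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path, units = "unitless") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  vertex_map(df$value[order(df$vertex)], units = units)
}

#' @rdname write_map_csv
#' @export
write_timeseries_csv <- function(ts, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(as.matrix(ts)),
                                     .name_repair = "minimal"), path)
  invisible(ts)
}

#' @rdname write_map_csv
#' @export
read_timeseries_csv <- function(path) {
  as.matrix(readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "d")))
}

#' Binary container for pairwise distance matrices
#'
#' A dense `N x N` float64 payload preceded by a one-line JSON header
#' recording the metric, normalization state and the normalization
#' parameters, so [rescale_to_mm()] stays well defined after a round trip.
#'
#' @param dist a `surf_dist`.
#' @param path file path.
#' @return `read_dist_matrix()` returns a `surf_dist`.
#' @export
write_dist_matrix <- function(dist, path) {
  stopifnot(inherits(dist, "surf_dist"))
  header <- jsonlite::toJSON(list(
    format = "geodca-dist-1", n = nrow(dist),
    metric = attr(dist, "metric"),
    normalized = isTRUE(attr(dist, "normalized")),
    norm_min = attr(dist, "norm_min"), norm_range = attr(dist, "norm_range")
  ), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, "\n")), con)
  writeBin(as.vector(unclass(dist)), con, size = 8, endian = "little")
  invisible(dist)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header_raw <- raw()
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0 || b == as.raw(10)) break
    header_raw <- c(header_raw, b)
  }
  h <- jsonlite::fromJSON(rawToChar(header_raw))
  if (!identical(h$format, "geodca-dist-1")) stop("not a geodca distance file")
  vals <- matrix(readBin(con, "numeric", h$n * h$n, size = 8,
                         endian = "little"), h$n, h$n)
  new_surf_dist(vals, metric = h$metric, normalized = isTRUE(h$normalized),
                norm_min = h$norm_min %||% NA_real_,
                norm_range = h$norm_range %||% NA_real_)
}

#' Export a permutation-null result
#'
#' Writes the full null distribution, observed statistic, p-value and seed
#' as JSON (and, optionally, the per-iteration correlations as CSV).
#'
#' @param x a `topography_null`.
#' @param path JSON output path.
#' @param csv_path optional CSV path for `tidy(x)`.
#' @return `x`, invisibly.
#' @export
write_null_json <- function(x, path, csv_path = NULL) {
  stopifnot(inherits(x, "topography_null"))
  jsonlite::write_json(
    list(observed_r = x$observed_r, p_value = x$p_value,
         model_fit_r = x$model_fit_r, n_iter = x$n_iter,
         rng_seed = x$rng_seed, n_redraws = x$n_redraws,
         r_values = x$r_null),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) readr::write_csv(tidy(x), csv_path)
  invisible(x)
}
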