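#' Per-vertex network parcellation
#'
#' A parcellation assigns each mesh vertex an integer network id; 0 means
#' unassigned.  Stored as a tibble (`vertex`, `network`) so it composes with
#' dplyr; an optional id-to-name table travels as the `network_names`
#' attribute.
#'
#' @param labels integer vector, one network id (>= 0) per vertex.
#' @param network_names optional data frame with columns `network`, `name`.
#' @return a tibble of class `parcellation`.
#' @export
parcellation <- function(labels, network_names = NULL) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be nonnegative integers (0 = unassigned)")
  }
  out <- tibble::tibble(vertex = seq_along(labels), network = labels)
  class(out) <- c("parcellation", class(out))
  attr(out, "network_names") <- network_names
  out
}

#' @rdname parcellation
#' @param parc a `parcellation` (or bare integer label vector).
#' @export
parc_labels <- function(parc) {
  if (inherits(parc, "data.frame")) {
    as.integer(parc$network[order(parc$vertex)])
  } else {
    as.integer(parc)
  }
}

#' Spatial correlation between two vertex maps
#'
#' Spearman rank correlation (midranks for ties), the ordinary
#' least-squares slope of `map_a` on `map_b` (raw values), and the naive
#' two-sided p-value across included vertices.  The naive p treats vertices
#' as independent -- spatially smooth maps violate that, which is exactly
#' why [topography_null_test()] exists.
#'
#' @param map_a,map_b aligned [vertex_map()]s (or numeric vectors).
#' @param exclude optional logical mask or integer indices of vertices to
#'   drop (e.g. prefrontal vertices deviating from the global trend).
#'   Vertices where either map is `NA` are always dropped.
#' @return a one-row tibble: `spearman_r`, `slope`, `naive_p`,
#'   `n_vertices_used`.
#' @export
spatial_correlation <- function(map_a, map_b, exclude = NULL) {
  a <- map_values(as_vertex_map(map_a))
  b <- map_values(as_vertex_map(map_b))
  if (length(a) != length(b)) stop("maps differ in length")
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- keep & !exclude
    else keep[as.integer(exclude)] <- FALSE
  }
  if (sum(keep) < 10L) stop("fewer than 10 vertices left after exclusion")
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant map after exclusion; correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    spearman_r = unname(ct$estimate),
    slope = stats::cov(a, b) / stats::var(b),
    naive_p = ct$p.value,
    n_vertices_used = sum(keep)
  )
}

#' Spatially connected patches of a parcellation
#'
#' For each network id, finds the connected components of its vertex set
#' under mesh edge adjacency; components larger than `min_size` are
#' retained.  The standard 17-network cortical template yields 42 such
#' patches at `min_size = 25` on a 10k-vertex hemisphere.
#'
#' @param parc a [parcellation()].
#' @param mesh the [surface_mesh()] the labels live on.
#' @param min_size retain components with strictly more than this many
#'   vertices (0 keeps everything).
#' @return a tibble sorted by (`network`, decreasing `size`): columns
#'   `network`, `patch` (running id), `size`, `vertices` (list-column of
#'   integer vertex sets).
#' @export
extract_patches <- function(parc, mesh, min_size = 0) {
  labels <- parc_labels(parc)
  stopifnot(length(labels) == n_vertices(mesh))
  ed <- mesh_edges(mesh)$edges
  out <- list()
  for (net in sort(unique(labels[labels > 0L]))) {
    vs <- which(labels == net)
    keep <- labels[ed[, 1]] == net & labels[ed[, 2]] == net
    sub <- ed[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(sub, vs), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(vs) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (cid in seq_len(max(comp))) {
      members <- vs[comp == cid]
      if (length(members) > min_size) {
        out[[length(out) + 1L]] <- tibble::tibble(
          network = net, size = length(members), vertices = list(members))
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(network = integer(), patch = integer(),
                          size = integer(), vertices = list()))
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), network, dplyr::desc(size))
  res$patch <- seq_len(nrow(res))
  res[, c("network", "patch", "size", "vertices")]
}

#' Random network topography: size-matched random patches
#'
#' Re-places every template patch at a random mesh location while keeping
#' its exact vertex count: each patch is seeded at a uniformly drawn
#' unassigned vertex and grown by breadth-first accretion, choosing
#' uniformly among unassigned boundary vertices, until the target size is
#' reached.  Patches are placed in descending size order and are pairwise
#' disjoint; a patch that runs out of free boundary is restarted (bounded
#' retries), and the whole layout restarts if placement keeps failing.
#'
#' @param mesh a [surface_mesh()].
#' @param template_patches tibble as from [extract_patches()] (columns
#'   `network`, `size` used).
#' @param rng_seed integer seed; the layout is reproducible from it.
#' @param max_retries per-patch restarts before the layout itself restarts.
#' @param max_restarts full-layout restarts before giving up.
#' @return a [parcellation()]: each random patch carries its template's
#'   network id; vertices not covered stay 0.  The attribute `patch_of`
#'   records which template patch each vertex was grown for (same-network
#'   patches are not constrained apart, so touching ones would merge in
#'   [extract_patches()]).
#' @export
random_patch_layout <- function(mesh, template_patches, rng_seed,
                                max_retries = 50L, max_restarts = 25L) {
  # canonical placement order: descending size, ties resolved by a
  # label-free ranking of each network's size multiset.  Placement then
  # consumes randomness in a way that depends only on sizes and their
  # grouping, so relabeling networks leaves the null layouts intact
  ord0 <- canonical_template_order(template_patches)
  sizes <- template_patches$size[ord0]
  nets <- template_patches$network[ord0]
  n <- n_vertices(mesh)
  if (sum(sizes) > n) stop("template sizes exceed vertex count")
  adj <- mesh_adjacency(mesh)
  set.seed(as.integer(rng_seed %% .Machine$integer.max))
  if (sum(sizes) == n) {
    # Templates tile the whole mesh: sequential growth cannot leave a
    # perfectly fillable remainder, so patches are grown competitively to
    # their size caps, leftover enclosed pockets are flooded from adjacent
    # patches, and sizes are then matched exactly by transferring boundary
    # vertices (only moves that keep the donor patch connected).
    for (restart in seq_len(max_restarts)) {
      res <- tile_layout(adj, sizes, n)
      if (is.null(res)) next
      labels <- rebalance_sizes(adj, res$labels, res$count, sizes,
                                max_moves = 50L * n)
      if (!is.null(labels)) {
        out <- parcellation(nets[labels])
        attr(out, "patch_of") <- ord0[labels]
        return(out)
      }
    }
  } else {
    # Slack exists: grow patches one at a time in descending size order by
    # uniform boundary accretion; vertices left over stay unassigned.
    for (restart in seq_len(max_restarts)) {
      labels <- integer(n)
      patch_of <- integer(n)
      ok <- TRUE
      for (i in seq_along(sizes)) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          patch <- grow_patch(adj, labels, sizes[i])
          if (!is.null(patch)) {
            labels[patch] <- nets[i]
            patch_of[patch] <- ord0[i]
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) {
        out <- parcellation(labels)
        attr(out, "patch_of") <- patch_of
        return(out)
      }
    }
  }
  stop("could not place all random patches after ", max_restarts,
       " restarts; try a different rng_seed")
}

# Order template patches by descending size; break ties by ranking each
# network's full size multiset (largest-first lexicographic), then by the
# patch's rank within its network.  The key never looks at network ids, so
# relabeling networks cannot change which geometric slot a grouping gets.
canonical_template_order <- function(template_patches) {
  sz <- template_patches$size
  net <- template_patches$network
  multiset_key <- vapply(net, function(g) {
    paste(formatC(sort(sz[net == g], decreasing = TRUE), width = 9,
                  flag = "0"), collapse = ",")
  }, character(1))
  group_rank <- match(multiset_key, sort(unique(multiset_key), decreasing = TRUE))
  within_rank <- stats::ave(-sz, net, FUN = rank)
  order(-sz, group_rank, within_rank)
}

# Competitive capped growth from random starts, then flood-fill of enclosed
# free pockets (overshooting some patches by exactly the total undershoot of
# others).  Returns patch-index labels (1..k) and counts, or NULL.
tile_layout <- function(adj, sizes, n) {
  k <- length(sizes)
  labels <- integer(n)
  starts <- sample.int(n, k)
  labels[starts] <- seq_len(k)
  count <- rep(1L, k)
  bnd <- vector("list", k)
  for (i in seq_len(k)) {
    nb <- adj[[starts[i]]]
    bnd[[i]] <- nb[labels[nb] == 0L]
  }
  active <- which(count < sizes)
  while (length(active) > 0L) {
    i <- if (length(active) == 1L) active else sample(active, 1L)
    b <- bnd[[i]]
    b <- b[labels[b] == 0L]
    if (length(b) == 0L) {
      bnd[[i]] <- b
      active <- setdiff(active, i)
      next
    }
    v <- if (length(b) == 1L) b else sample(b, 1L)
    labels[v] <- i
    count[i] <- count[i] + 1L
    nb <- adj[[v]]
    bnd[[i]] <- unique(c(b[b != v], nb[labels[nb] == 0L]))
    if (count[i] >= sizes[i]) active <- setdiff(active, i)
  }
  free <- which(labels == 0L)
  while (length(free) > 0L) {
    progress <- FALSE
    for (v in free) {
      nb <- labels[adj[[v]]]
      nb <- nb[nb > 0L]
      if (length(nb) > 0L) {
        i <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
        labels[v] <- i
        count[i] <- count[i] + 1L
        progress <- TRUE
      }
    }
    free <- which(labels == 0L)
    if (!progress && length(free) > 0L) return(NULL)
  }
  list(labels = labels, count = count)
}

# Match patch sizes exactly by moving single boundary vertices from
# better-supplied neighbours into the currently most undersized patch; a
# move is legal only if the donor patch stays connected and nonempty.
rebalance_sizes <- function(adj, labels, count, sizes, max_moves) {
  repeat {
    deficit <- sizes - count
    under <- which(deficit > 0L)
    if (length(under) == 0L) return(labels)
    q <- if (length(under) == 1L) under else sample(under, 1L)
    vq <- which(labels == q)
    ext <- unique(unlist(adj[vq], use.names = FALSE))
    ext <- ext[labels[ext] != q]
    if (length(ext) == 0L) return(NULL)
    surplus <- count - sizes
    ord <- order(-surplus[labels[ext]], sample.int(length(ext)))
    moved <- FALSE
    for (v in ext[ord]) {
      p <- labels[v]
      if (count[p] <= 1L) next
      if (removal_keeps_connected(adj, labels, v, p)) {
        labels[v] <- q
        count[p] <- count[p] - 1L
        count[q] <- count[q] + 1L
        moved <- TRUE
        break
      }
    }
    if (!moved) return(NULL)
    max_moves <- max_moves - 1L
    if (max_moves <= 0L) return(NULL)
  }
}

removal_keeps_connected <- function(adj, labels, v, p) {
  nb_p <- adj[[v]][labels[adj[[v]]] == p]
  if (length(nb_p) <= 1L) return(length(nb_p) == 1L)
  seen <- logical(length(labels))
  seen[v] <- TRUE # excluded from traversal
  start <- nb_p[1]
  seen[start] <- TRUE
  stack <- start
  while (length(stack) > 0L) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- adj[[x]]
    nb <- nb[labels[nb] == p & !seen[nb]]
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen[nb_p])
}

# Grow one connected patch of `size` unassigned vertices by uniform boundary
# accretion; NULL if the patch dead-ends before reaching the target size.
grow_patch <- function(adj, labels, size) {
  free <- which(labels == 0L)
  if (length(free) < size) return(NULL)
  start <- free[sample.int(length(free), 1L)]
  in_patch <- logical(length(labels))
  in_patch[start] <- TRUE
  patch <- integer(size)
  patch[1L] <- start
  boundary <- adj[[start]][labels[adj[[start]]] == 0L]
  count <- 1L
  while (count < size) {
    boundary <- boundary[!in_patch[boundary]]
    if (length(boundary) == 0L) return(NULL)
    pick <- boundary[sample.int(length(boundary), 1L)]
    count <- count + 1L
    patch[count] <- pick
    in_patch[pick] <- TRUE
    nb <- adj[[pick]]
    boundary <- unique(c(boundary[boundary != pick],
                         nb[labels[nb] == 0L & !in_patch[nb]]))
  }
  patch
}

#' Binary within-network connectivity model
#'
#' Models connectivity of a network arrangement as a binary graph linking
#' all vertex pairs within, but never between, networks; the
#' distance-to-connected-areas of a labeled vertex is then simply its mean
#' surface distance to every other vertex of its network (across all of the
#' network's patches).  Unassigned vertices get `NA`.
#'
#' @param parc a [parcellation()].
#' @param dist a `surf_dist` aligned to the parcellation.
#' @return a [vertex_map()] (NA on unassigned vertices).
#' @export
model_distance_map <- function(parc, dist) {
  labels <- parc_labels(parc)
  n <- length(labels)
  stopifnot(nrow(dist) == n)
  singles <- names(which(table(labels[labels > 0L]) == 1L))
  if (length(singles) > 0L) {
    stop("network(s) with a single vertex (mean over empty set): ",
         paste(singles, collapse = ", "))
  }
  dm <- unclass(dist)
  vals <- rep(NA_real_, n)
  for (net in unique(labels[labels > 0L])) {
    vs <- which(labels == net)
    vals[vs] <- rowSums(dm[vs, vs, drop = FALSE]) / (length(vs) - 1L)
  }
  units <- if (isTRUE(attr(dist, "normalized"))) "normalized" else "mm"
  vertex_map(vals, units = units, metric = attr(dist, "metric") %||% NA_character_)
}

#' Permutation test against random network topography
#'
#' Tests whether the observed anchoring of connectivity distance in primary
#' cortex could arise from a randomly arranged network topography.  Each
#' iteration re-places all template patches at random ([random_patch_layout()]),
#' recomputes the binary-model distance map ([model_distance_map()]) and the
#' distance from the new locations of the primary-network patches, and
#' records their Spearman correlation.  The observed statistic is the same
#' model-based correlation on the original parcellation; the one-sided
#' empirical p-value uses the add-one rule
#' `p = (1 + #\{r_null >= r_obs\}) / (n_iter + 1)`.
#'
#' @param observed_map the data-derived DCA [vertex_map()] (used to report
#'   how well the binary model captures it, `model_fit_r`).
#' @param primary_seeds integer vertex ids of the primary-cortex seed
#'   region on the original parcellation.
#' @param parc the original [parcellation()].
#' @param mesh the [surface_mesh()].
#' @param dist a `surf_dist` for `mesh`.
#' @param n_iter number of random topographies (1000 is a typical choice;
#'   the add-one p-value can then reach 1/1001).
#' @param rng_seed integer seed; iteration i uses a sub-seed derived from it.
#' @param min_patch_size template patches must exceed this size (default 25).
#' @param templates optional template-patch tibble (as from
#'   [extract_patches()]); defaults to the patches of `parc`.  Supplying a
#'   fixed set makes repeated tests over re-drawn "observed" layouts
#'   exactly exchangeable with their nulls.
#' @return an object of class `topography_null` with elements `observed_r`,
#'   `r_null`, `p_value`, `model_fit_r`, `n_iter`, `rng_seed`, `n_redraws`.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
topography_null_test <- function(observed_map, primary_seeds, parc, mesh,
                                 dist, n_iter = 1000, rng_seed = 1,
                                 min_patch_size = 25, templates = NULL) {
  stopifnot(n_iter >= 1)
  labels <- parc_labels(parc)
  primary_seeds <- unique(as.integer(primary_seeds))
  primary_nets <- sort(unique(labels[primary_seeds]))
  primary_nets <- primary_nets[primary_nets > 0L]
  if (length(primary_nets) == 0L) {
    stop("primary seeds fall on unassigned vertices only")
  }
  if (is.null(templates)) {
    templates <- extract_patches(parc, mesh, min_size = min_patch_size)
  }
  if (nrow(templates) == 0L) stop("no template patches exceed min_patch_size")

  model_obs <- model_distance_map(parc, dist)
  dfp_obs <- multi_source_distance(mesh, primary_seeds, dist_matrix = dist)
  observed_r <- spatial_correlation(model_obs, dfp_obs)$spearman_r
  model_fit_r <- if (!is.null(observed_map)) {
    spatial_correlation(as_vertex_map(observed_map), model_obs)$spearman_r
  } else {
    NA_real_
  }

  r_null <- numeric(n_iter)
  n_redraws <- 0L
  for (i in seq_len(n_iter)) {
    attempt <- 0L
    repeat {
      sub_seed <- (as.double(rng_seed) + i * 9973 + attempt * 7919211) %%
        .Machine$integer.max
      layout <- tryCatch(
        random_patch_layout(mesh, templates, rng_seed = sub_seed),
        error = function(e) NULL
      )
      if (!is.null(layout)) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (attempt > 50L) stop("patch placement kept failing; try a new rng_seed")
    }
    lay_labels <- parc_labels(layout)
    model_i <- model_distance_map(layout, dist)
    new_primary <- which(lay_labels %in% primary_nets)
    dfp_i <- multi_source_distance(mesh, new_primary, dist_matrix = dist)
    r_null[i] <- spatial_correlation(model_i, dfp_i)$spearman_r
  }
  p <- (1 + sum(r_null >= observed_r)) / (n_iter + 1)
  structure(
    list(observed_r = observed_r, r_null = r_null, p_value = p,
         model_fit_r = model_fit_r, n_iter = as.integer(n_iter),
         rng_seed = rng_seed, n_redraws = n_redraws),
    class = "topography_null"
  )
}

#' @export
print.topography_null <- function(x, ...) {
  cat(sprintf(
    "<topography_null> observed r = %.3f, null range [%.3f, %.3f], p = %.4g (%d iterations)\n",
    x$observed_r, min(x$r_null), max(x$r_null), x$p_value, x$n_iter))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for topography-null results
#' @param x a `topography_null` object.
#' @param ... unused.
#' @return `tidy()`: one row per permutation (`iteration`, `r`); `glance()`:
#'   a one-row summary.
#' @export
tidy.topography_null <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$r_null), r = x$r_null)
}

#' @rdname tidy.topography_null
#' @export
glance.topography_null <- function(x, ...) {
  tibble::tibble(
    observed_r = x$observed_r, p_value = x$p_value,
    model_fit_r = x$model_fit_r,
    null_mean = mean(x$r_null), null_sd = stats::sd(x$r_null),
    null_min = min(x$r_null), null_max = max(x$r_null),
    n_iter = x$n_iter, n_redraws = x$n_redraws
  )
}
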