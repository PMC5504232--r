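#' Network-specific distance distributions
#'
#' Samples the DCA map within the spatial extent of each network and
#' returns one distribution per network, sorted by increasing mean -- the
#' ordering that suggested the sensorimotor / attention / higher-order
#' grouping in cortical data.
#'
#' @param map a [vertex_map()] (or numeric vector).
#' @param parc a [parcellation()] aligned to the map.
#' @return a tibble sorted by increasing `mean`: columns `network`, `n`,
#'   `mean`, `samples` (list-column of the map values at that network's
#'   vertices).
#' @export
sample_network_distributions <- function(map, parc) {
  vals <- map_values(as_vertex_map(map))
  labels <- parc_labels(parc)
  if (length(vals) != length(labels)) stop("map and parcellation differ in length")
  nets <- sort(unique(labels[labels > 0L]))
  if (length(nets) == 0L) stop("parcellation has no labeled vertices")
  rows <- purrr::map(nets, function(net) {
    s <- vals[labels == net]
    s <- s[!is.na(s)]
    if (length(s) == 0L) stop("network ", net, " has no sampled values")
    tibble::tibble(network = net, n = length(s), mean = mean(s), samples = list(s))
  })
  dplyr::arrange(dplyr::bind_rows(rows), mean)
}

#' Jensen-Shannon divergence between two sample sets
#'
#' Both sample sets are histogrammed on shared equal-width bins spanning
#' their pooled range (or explicit `breaks`); the divergence is
#' \deqn{JSD(P, Q) = \tfrac12 KL(P \| M) + \tfrac12 KL(Q \| M), \quad
#'   M = \tfrac12 (P + Q)}
#' with natural logarithms and the `0 log 0 = 0` convention, so it is
#' symmetric, nonnegative and bounded by `log(2)` (attained for disjoint
#' supports).
#'
#' @param p_samples,q_samples nonempty numeric vectors.
#' @param n_bins number of equal-width bins (>= 2; default 64).
#' @param breaks optional explicit bin breaks (overrides `n_bins`), e.g. the
#'   shared binning of [divergence_matrix()].
#' @param log_base base of the logarithm (default `exp(1)`: nats, bound
#'   `log(2)`; use 2 for bits, bound 1).
#' @return a single nonnegative number, at most `log(2, log_base)`.
#' @examples
#' js_divergence(rnorm(500), rnorm(500, 5)) # near log(2)
#' @export
js_divergence <- function(p_samples, q_samples, n_bins = 64, breaks = NULL,
                          log_base = exp(1)) {
  if (length(p_samples) == 0L || length(q_samples) == 0L) {
    stop("sample sets must be nonempty")
  }
  if (is.null(breaks)) {
    if (n_bins < 2) stop("`n_bins` must be at least 2")
    breaks <- shared_breaks(c(p_samples, q_samples), n_bins)
  }
  p <- bin_probs(p_samples, breaks)
  q <- bin_probs(q_samples, breaks)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2 / log(log_base)
}

shared_breaks <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) { # all-constant pooled samples: one degenerate bin suffices
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  seq(lo, hi, length.out = n_bins + 1)
}

bin_probs <- function(x, breaks) {
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE),
                  nbins = length(breaks) - 1L)
  cnt / sum(cnt)
}

#' Pairwise divergence between network distributions
#'
#' Jensen-Shannon divergences between all pairs of network distributions,
#' histogrammed on one shared equal-width binning spanning the pooled range
#' of *all* networks (so entries are comparable across pairs).
#'
#' @param dists tibble from [sample_network_distributions()] (>= 2 rows).
#' @param n_bins shared bin count (default 64).
#' @param log_base logarithm base, as in [js_divergence()].
#' @return a `divergence_matrix`: symmetric `K x K` matrix, zero diagonal,
#'   entries in `[0, log(2)]`, with attribute `networks` (the row/column
#'   network ids, in the input order).
#' @export
divergence_matrix <- function(dists, n_bins = 64, log_base = exp(1)) {
  if (nrow(dists) < 2L) stop("need at least two networks")
  breaks <- shared_breaks(unlist(dists$samples), n_bins)
  k <- nrow(dists)
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- js_divergence(
        dists$samples[[i]], dists$samples[[j]], breaks = breaks,
        log_base = log_base)
    }
  }
  structure(m, class = c("divergence_matrix", "matrix", "array"),
            networks = dists$network)
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d networks, max JSD = %.3f (bound log 2 = %.3f)\n",
              nrow(x), max(x), log(2)))
  invisible(x)
}

#' Group networks by their divergence profiles
#'
#' k-means on the rows of the divergence matrix (each network's divergence
#' profile is its feature vector), best of `nstart` restarts by
#' within-cluster sum of squares, deterministic for a given `rng_seed`.
#' With k = 3 this reproduces the sensorimotor / attention / higher-order
#' grouping on cortical data and the planted tiers on synthetic data.
#'
#' @param div a `divergence_matrix`.
#' @param k number of clusters (default 3; must not exceed the number of
#'   networks).
#' @param rng_seed integer seed.
#' @param nstart random restarts (>= 10 recommended).
#' @return a tibble of class `network_clustering`: columns `network`,
#'   `cluster`; attributes `k`, `rng_seed`, `tot_withinss`.
#' @export
cluster_networks <- function(div, k = 3, rng_seed = 1, nstart = 10) {
  kn <- nrow(div)
  if (k < 1 || k > kn) stop("`k` must be in [1, ", kn, "]")
  if (k == kn) {
    # every network its own cluster: the optimum with zero scatter
    clusters <- seq_len(kn)
    tot_withinss <- 0
  } else {
    set.seed(as.integer(rng_seed %% .Machine$integer.max))
    km <- stats::kmeans(unclass(div), centers = k, nstart = max(10, nstart))
    clusters <- as.integer(km$cluster)
    tot_withinss <- km$tot.withinss
  }
  out <- tibble::tibble(
    network = attr(div, "networks") %||% seq_len(kn),
    cluster = clusters
  )
  class(out) <- c("network_clustering", class(out))
  attr(out, "k") <- as.integer(k)
  attr(out, "rng_seed") <- rng_seed
  attr(out, "tot_withinss") <- tot_withinss
  out
}
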