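# ---- cortical parcellation from a connection-incidence matrix ----

#' Louvain community partition of an incidence matrix
#'
#' Groups effectively connected cortical areas into larger interconnected
#' regions by modularity maximisation (Louvain, resolution 2.0 by
#' default) on the inter-areal connection-incidence matrix. Directional
#' matrices are symmetrised by arithmetic mean. Areas in
#' `forced_separate` (e.g. amygdala and hippocampus) are removed before
#' clustering and re-attached as singleton regions regardless of their
#' connectivity. Louvain is order-dependent, so the best of `restarts`
#' seeded runs (by modularity at the stated resolution) is kept;
#' deterministic under a fixed seed.
#'
#' @param incidence square nonnegative areas-x-areas matrix with dimnames.
#' @param resolution Louvain resolution parameter (default 2.0).
#' @param forced_separate character vector of areas kept as their own
#'   singleton regions.
#' @param seed integer seed.
#' @param restarts number of seeded Louvain restarts.
#' @return list of class `region_partition`: `membership` (named integer
#'   vector), `modularity`, `resolution`, `forced_separate`, `seed`.
#' @export
louvain_partition <- function(incidence, resolution = 2.0,
                              forced_separate = character(), seed = 1,
                              restarts = 20) {
  stopifnot(is.matrix(incidence), nrow(incidence) == ncol(incidence))
  areas <- rownames(incidence)
  if (is.null(areas)) {
    areas <- paste0("area", seq_len(nrow(incidence)))
    dimnames(incidence) <- list(areas, areas)
  }
  m <- (incidence + t(incidence)) / 2
  diag(m) <- 0
  if (any(m < 0)) stop("incidence must be nonnegative", call. = FALSE)
  keep <- setdiff(areas, forced_separate)
  membership <- stats::setNames(integer(length(areas)), areas)
  mod <- NA_real_
  if (all(m[keep, keep] == 0)) {
    warning("all-zero incidence: returning a single trivial community")
    membership[keep] <- 1L
  } else {
    g <- igraph::graph_from_adjacency_matrix(m[keep, keep, drop = FALSE],
                                             mode = "undirected",
                                             weighted = TRUE)
    best <- NULL; best_mod <- -Inf
    for (r in seq_len(restarts)) {
      cl <- .with_seed(seed + r,
                       igraph::cluster_louvain(g, resolution = resolution))
      q <- igraph::modularity(g, igraph::membership(cl),
                              weights = igraph::E(g)$weight,
                              resolution = resolution)
      if (q > best_mod) { best_mod <- q; best <- cl }
    }
    membership[keep] <- as.integer(igraph::membership(best))
    mod <- best_mod
  }
  nxt <- max(membership) + 1L
  for (a in intersect(forced_separate, areas)) {
    membership[a] <- nxt
    nxt <- nxt + 1L
  }
  structure(list(membership = membership, modularity = mod,
                 resolution = resolution,
                 forced_separate = intersect(forced_separate, areas),
                 seed = seed),
            class = "region_partition")
}

#' Within-region signaling-latency threshold
#'
#' The short/long-latency boundary is the 95th percentile
#' (linear-interpolation quantile) of the pooled distribution of signaling
#' latencies observed within brain regions. With fewer than `min_n`
#' observations the configured default (65 ms) is returned with a warning.
#'
#' @param latencies_ms numeric vector of within-region latencies (ms).
#' @param default_ms fallback threshold (default 65 ms).
#' @param min_n minimal number of observations (default 20).
#' @param percentile percentile to use (default 95).
#' @return threshold in ms.
#' @export
latency_threshold <- function(latencies_ms, default_ms = 65, min_n = 20,
                              percentile = 95) {
  latencies_ms <- latencies_ms[is.finite(latencies_ms)]
  if (length(latencies_ms) < min_n) {
    warning("fewer than ", min_n,
            " latency observations; falling back to default ",
            default_ms, " ms")
    return(default_ms)
  }
  quantile(latencies_ms, percentile / 100, names = FALSE, type = 7)
}
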