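#' Hotspot coverage map
#'
#' For each gene (motif), the set `HS(g)` of hotspot ids covered by at least
#' one hit of that gene's motif. `|HS(g)|` equals the gene's `HM` cell in the
#' enrichment table.
#'
#' @param hits A hit table from [scan_regions()] over hotspot sequences
#'   (multiple motifs may be concatenated with `rbind`), or a named list of
#'   hotspot-id vectors.
#' @return Named list (gene -> character vector of hotspot ids) of class
#'   `coverage_map`.
#' @export
coverage_map <- function(hits) {
  if (is.data.frame(hits)) {
    cov <- lapply(split(hits$region_id, hits$motif), unique)
  } else cov <- lapply(hits, unique)
  structure(cov, class = "coverage_map")
}

#' Meet/min coverage similarity between two hotspot sets
#'
#' `|A intersect B| / min(|A|, |B|)`: 1 when one set contains the other,
#' 0 when disjoint.
#'
#' @param hs_i,hs_j Character vectors of hotspot ids (non-empty).
#' @return Weight in `[0, 1]`.
#' @export
meet_min_weight <- function(hs_i, hs_j) {
  if (!length(hs_i) || !length(hs_j))
    stop_config("meet/min weight undefined for an empty hotspot set")
  length(intersect(hs_i, hs_j)) / min(length(unique(hs_i)),
                                      length(unique(hs_j)))
}

#' Build the hotspot coverage graph
#'
#' Complete weighted graph over genes, edge weights the meet/min similarity
#' of the genes' covered-hotspot sets.
#'
#' @param coverage A [coverage_map()] (every gene must cover >= 1 hotspot).
#' @return An object of class `coverage_graph`: symmetric weight matrix with
#'   unit diagonal, gene names as dimnames, and the coverage map as
#'   attribute `coverage`.
#' @export
build_coverage_graph <- function(coverage) {
  genes <- names(coverage)
  if (!length(genes)) stop_config("empty gene list")
  if (any(vapply(coverage, length, integer(1)) == 0))
    stop_config("every gene must cover at least one hotspot")
  n <- length(genes)
  w <- diag(1, n)
  dimnames(w) <- list(genes, genes)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      w[i, j] <- w[j, i] <- meet_min_weight(coverage[[i]], coverage[[j]])
    }
  }
  structure(w, coverage = coverage, class = c("coverage_graph", "matrix"))
}

#' @export
print.coverage_graph <- function(x, ...) {
  cat(sprintf("<coverage_graph> %d genes\n", nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

# Order a cluster list: descending size, then by lexicographically smallest
# member; genes sorted within each cluster.
order_clusters <- function(clusters) {
  clusters <- lapply(clusters, sort)
  first <- vapply(clusters, `[`, character(1), 1)
  unname(clusters[order(-vapply(clusters, length, integer(1)), first)])
}

#' Threshold clustering of the coverage graph
#'
#' Keeps edges with weight `>= w_t` and returns the connected components as
#' gene clusters (a partition of the genes), reported in order of
#' descending size then lexicographic first member.
#'
#' @param graph A [build_coverage_graph()] result.
#' @param w_t Weight threshold; edges at exactly `w_t` are kept. Meaningful
#'   values lie in `[0, 1]`; any `w_t > 1` removes every edge and yields all
#'   singletons.
#' @return List of character vectors (clusters).
#' @export
threshold_clusters <- function(graph, w_t) {
  if (w_t < 0) stop_config("w_t must be non-negative")
  adj <- (unclass(graph) >= w_t) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  order_clusters(split(rownames(graph), comp$membership))
}

#' Hierarchical clustering of the coverage graph
#'
#' Agglomerative clustering on distance `1 - w` (average linkage by
#' default), cut at `k` clusters.
#'
#' @param graph A [build_coverage_graph()] result.
#' @param k Number of clusters, `1 <= k <=` number of genes.
#' @param method Linkage: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @return List of character vectors (clusters), ordered as in
#'   [threshold_clusters()].
#' @export
hierarchical_clusters <- function(graph, k,
                                  method = c("average", "single", "complete")) {
  method <- match.arg(method)
  n <- nrow(graph)
  if (k < 1 || k > n) stop_config("k must be in [1, number of genes]")
  if (n == 1) return(list(rownames(graph)))
  d <- stats::as.dist(1 - unclass(graph))
  hc <- stats::hclust(d, method = method)
  memb <- stats::cutree(hc, k = k)
  order_clusters(split(rownames(graph), memb))
}

#' Summarise hotspot coverage of gene clusters
#'
#' For each cluster, the size of the union of its genes' covered hotspots;
#' plus all pairwise cluster intersections, the full Venn-region
#' decomposition, the overall union and (when `n_hotspots` is given) the
#' number of hotspots not covered by any cluster.
#'
#' @param clusters List of character vectors partitioning the graph's genes.
#' @param coverage The [coverage_map()].
#' @param n_hotspots Optional total number of hotspots.
#' @return List with `cluster_sizes` (genes per cluster), `cluster_union`
#'   (hotspots per cluster), `pairwise_intersections` (matrix),
#'   `venn_regions` (named vector: counts of hotspots covered by exactly
#'   each non-empty cluster subset, names like `"1"`, `"1&2"`),
#'   `overall_union`, and `uncovered` (`NA` without `n_hotspots`).
#' @export
coverage_summary <- function(clusters, coverage, n_hotspots = NULL) {
  genes <- unlist(clusters)
  if (anyDuplicated(genes))
    stop_config("clusters must not share genes")
  miss <- setdiff(genes, names(coverage))
  if (length(miss)) stop_config("no coverage for gene(s): ", miss[1])
  unions <- lapply(clusters, function(cl) unique(unlist(coverage[cl])))
  k <- length(clusters)
  pair <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    pair[i, j] <- length(intersect(unions[[i]], unions[[j]]))
  all_hs <- unique(unlist(unions))
  membership <- vapply(all_hs, function(h)
    paste(which(vapply(unions, function(u) h %in% u, logical(1))),
          collapse = "&"), character(1))
  venn <- table(membership)
  list(cluster_sizes = vapply(clusters, length, integer(1)),
       cluster_union = vapply(unions, length, integer(1)),
       pairwise_intersections = pair,
       venn_regions = stats::setNames(as.integer(venn), names(venn)),
       overall_union = length(all_hs),
       uncovered = if (is.null(n_hotspots)) NA_integer_
                   else n_hotspots - length(all_hs))
}
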