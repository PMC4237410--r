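#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity for a weighted undirected graph:
#' Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j),
#' where 2m is the total weight over ordered pairs, A the weight matrix and
#' k the weighted degrees. Evaluated directly from the weight matrix, so it
#' serves as an independent check on any optimizer's reported score.
#'
#' @param graph a `corr_graph`, or a symmetric weight matrix.
#' @param membership vector of cluster labels, one per node.
#' @return modularity Q, a number in [-1, 1].
#' @export
modularity_q <- function(graph, membership) {
  w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
  p <- nrow(w)
  if (length(membership) != p)
    stop("membership length does not match node count")
  two_m <- sum(w)
  if (two_m <= 0) stop("modularity undefined for an empty graph (m = 0)")
  k <- rowSums(w)
  same <- outer(membership, membership, `==`)
  sum((w - outer(k, k) / two_m) * same) / two_m
}

#' Initial membership by fast-greedy modularity optimization
#'
#' Agglomerative heuristic: starting from singletons, repeatedly merge the
#' community pair with the largest modularity gain and return the partition
#' at the maximum Q encountered. Delegates to [igraph::cluster_fast_greedy()];
#' nodes with no surviving edges stay singletons.
#'
#' @param graph a `corr_graph` or symmetric weight matrix.
#' @return factor of cluster labels, one per node, named by node label; the
#'   achieved Q is attached as `attr(, "Q")` (`NA` for an edgeless graph).
#' @export
fast_greedy <- function(graph) {
  w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(w)))
  if (sum(w) <= 0) {
    memb <- factor(seq_len(nrow(w)))
    names(memb) <- labels
    attr(memb, "Q") <- NA_real_
    return(memb)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  # walk the merge path ourselves: igraph cuts at its recorded maximum, but
  # on flat stretches (ties, e.g. a single clique) we prefer the coarsest
  # partition with the same Q
  p <- nrow(w)
  best_q <- -Inf
  best <- igraph::membership(cl)
  ncomp <- igraph::components(g)$no   # cuts below this are impossible
  for (k in seq(ncomp, p)) {
    mk <- try(suppressWarnings(igraph::cut_at(cl, no = k)), silent = TRUE)
    if (inherits(mk, "try-error")) next
    qk <- modularity_q(w, mk)
    if (qk > best_q + 1e-12) {
      best_q <- qk
      best <- mk
    }
  }
  memb <- factor(best)
  names(memb) <- labels
  attr(memb, "Q") <- modularity_q(w, as.integer(memb))
  memb
}
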