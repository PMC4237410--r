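#' Fit community structure to a topology-constrained correlation network
#'
#' The main entry point. From an n x (p*d) sample matrix it (1) computes
#' per-dimension Pearson correlations, (2) zeroes entries that fail a Fisher
#' z-test at `alpha`, (3) combines dimensions into correlation-vector
#' magnitudes, (4) masks non-contact pairs when a contact/adjacency matrix is
#' given, (5) obtains an initial membership by fast-greedy modularity
#' optimization, (6) optionally repairs over-fragmentation with the
#' discriminant confidence-ellipse collision filter ([lda_refine()]), and
#' (7) merges any remaining statistically unsupported bipartitions with a
#' permutation test ([significance_refine()]).
#'
#' Topology constraints sparsify the graph and are known to fragment
#' modularity optima into spuriously many modules; stage (6) is the corrective
#' step and stage (7) the final significance guard.
#'
#' @param x numeric sample matrix, n observations by p*d variables (columns
#'   ordered point-within-dimension), or a `tccn_sim`.
#' @param dims number of coordinate dimensions per point (1 for scalar data
#'   such as votes; 2-3 for shapes). Ignored when `x` is a `tccn_sim`.
#' @param contacts optional symmetric logical p x p contact matrix; `NULL`
#'   fits the unconstrained network.
#' @param alpha significance level for both the Fisher edge filter and the
#'   bipartition permutation test (default 0.05).
#' @param lda apply the discriminant-ellipse filter (default `TRUE`).
#' @param significance apply the permutation refinement (default `TRUE`).
#' @param level confidence level of the ellipses (default 0.95).
#' @param n_perm permutations per bipartition test (default 999).
#' @param seed optional seed for the permutation tests.
#' @param p_adjust multiplicity correction for the Fisher filter
#'   (default `"none"`).
#' @return object of class `"tccn"`: list with `graph` (the `corr_graph`),
#'   `membership` (final factor), `stages` (memberships after each stage),
#'   `Q` (modularity of each stage), `n_clusters`, and the call.
#' @examples
#' tpl <- double_h_template()
#' sim <- simulate_dataset(tpl, n_samples = 200, corr_a = 0.5, corr_b = 0.5,
#'                         seed = 7)
#' fit <- tccn(sim, contacts = infer_contacts(tpl), seed = 7, n_perm = 199)
#' fit
#' table(fit$membership, tpl$truth)
#' @export
tccn <- function(x, dims = 1L, contacts = NULL, alpha = 0.05,
                 lda = TRUE, significance = TRUE, level = 0.95,
                 n_perm = 999L, seed = NULL, p_adjust = "none") {
  cl <- match.call()
  if (inherits(x, "tccn_sim")) dims <- x$dims
  graph <- correlation_graph(x, dims, contacts, alpha, p_adjust)
  initial <- fast_greedy(graph)
  stages <- list(initial = initial)
  current <- initial
  if (lda && nlevels(droplevels(factor(current))) >= 2L) {
    # the discriminant filter sees the unconstrained magnitude matrix: it
    # deliberately has no information about the topology constraint
    current <- lda_refine(graph$magnitudes, current, level)
    stages$lda <- current
  }
  if (significance && nlevels(droplevels(factor(current))) >= 2L) {
    current <- significance_refine(graph, current, alpha, n_perm, seed)
    stages$significance <- current
  }
  names(current) <- graph$labels
  has_edges <- sum(graph$weights) > 0
  q <- vapply(stages, function(m)
    if (has_edges) modularity_q(graph, as.character(m)) else NA_real_,
    0)
  structure(list(graph = graph, membership = current, stages = stages,
                 Q = q, n_clusters = nlevels(droplevels(factor(current))),
                 alpha = alpha, lda = lda, level = level, call = cl),
            class = "tccn")
}

#' Simulate one structured replicate and fit it
#'
#' Convenience wrapper for the benchmark: generates one Cholesky-structured
#' replicate on the template, infers its contact matrix, and runs [tccn()]
#' on the contact-constrained graph. The same `seed` drives the simulation
#' draws and the permutation tests.
#'
#' @param template shape template.
#' @param corr_a,corr_b,n_samples,inter_range,noise_sd simulation settings,
#'   see [simulate_dataset()].
#' @param alpha,lda,level,n_perm,seed fitting settings, see [tccn()].
#' @param contacts optional precomputed contact matrix (saves recomputation
#'   across replicates).
#' @return a `tccn` fit; the simulation is attached as `$sim`.
#' @export
tccn_simulated <- function(template = double_h_template(),
                           corr_a = 0.5, corr_b = 0.5, n_samples = 500L,
                           inter_range = c(0, 0.1), noise_sd = 0.1,
                           alpha = 0.05, lda = TRUE, level = 0.95,
                           n_perm = 999L, seed = NULL, contacts = NULL) {
  sim <- simulate_dataset(template, n_samples, corr_a, corr_b,
                          inter_range, noise_sd, seed = seed)
  if (is.null(contacts)) contacts <- infer_contacts(template, noise_sd)
  fit <- tccn(sim, contacts = contacts, alpha = alpha, lda = lda,
              level = level, n_perm = n_perm, seed = seed)
  fit$sim <- sim
  fit
}

#' @export
print.tccn <- function(x, ...) {
  cat("Topology-constrained correlation network communities\n")
  print(x$graph)
  cat(sprintf("Clusters: %d  (Q = %.4f)\n", x$n_clusters,
              x$Q[[length(x$Q)]]))
  cat("Sizes:", paste(table(droplevels(factor(x$membership))),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tccn <- function(object, ...) {
  stages <- vapply(names(object$stages), function(s)
    nlevels(droplevels(factor(object$stages[[s]]))), 0L)
  out <- list(n_nodes = length(object$membership),
              n_edges = sum(object$graph$weights[
                upper.tri(object$graph$weights)] > 0),
              constrained = object$graph$constrained,
              stage_clusters = stages, Q = object$Q,
              sizes = table(droplevels(factor(object$membership))))
  class(out) <- "summary.tccn"
  out
}

#' @export
print.summary.tccn <- function(x, ...) {
  cat(sprintf("Nodes: %d   Edges: %d%s\n", x$n_nodes, x$n_edges,
              if (x$constrained) "   (topology-constrained)" else ""))
  cat("Clusters by stage:\n")
  for (s in names(x$stage_clusters))
    cat(sprintf("  %-12s %3d  (Q = %.4f)\n", s, x$stage_clusters[[s]],
                x$Q[[s]]))
  cat("Final cluster sizes:\n")
  print(x$sizes)
  invisible(x)
}

#' Plot discriminant scores and confidence ellipses of a fit
#'
#' Refits the discriminant projection on the final membership and draws the
#' node scores on the first two discriminants, coloured by cluster, with each
#' cluster's confidence ellipse outline. With fewer than three clusters only
#' one discriminant exists and scores are plotted against node index.
#'
#' @param x a `tccn` fit.
#' @param level ellipse confidence level (defaults to the fit's).
#' @param ... passed to [graphics::plot()].
#' @export
plot.tccn <- function(x, level = x$level, ...) {
  memb <- droplevels(factor(x$membership))
  if (nlevels(memb) < 2L) {
    graphics::plot(seq_along(memb), rep(0, length(memb)),
                   xlab = "node", ylab = "", main = "single cluster", ...)
    return(invisible(x))
  }
  fit <- fit_lda(x$graph$weights, memb)
  sc <- fit$scores
  if (ncol(sc) == 1L) sc <- cbind(sc, seq_len(nrow(sc)))
  cols <- as.integer(fit$membership)
  graphics::plot(sc[, 1], sc[, 2], col = cols, pch = 19,
                 xlab = "LD1", ylab = if (fit$q == 2L) "LD2" else "node", ...)
  if (fit$q == 2L) {
    for (lev in levels(fit$membership)) {
      e <- confidence_ellipse(fit$scores[fit$membership == lev, ,
                                         drop = FALSE], level)
      theta <- seq(0, 2 * pi, length.out = 181)
      u <- e$a * cos(theta); v <- e$b * sin(theta)
      graphics::lines(e$center[1] + cos(e$angle) * u - sin(e$angle) * v,
                      e$center[2] + sin(e$angle) * u + cos(e$angle) * v,
                      col = which(levels(fit$membership) == lev))
    }
  }
  invisible(x)
}
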