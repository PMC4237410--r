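#' Permutation test of one module bipartition
#'
#' Tests whether two modules are genuinely separated: the observed statistic
#' is the Welch t-contrast between the mean within-module edge weight and the
#' mean cross-pair edge weight over the two modules' induced (union)
#' subgraph, absent edges counting as weight 0. The null distribution is
#' built by randomly reassigning the union's nodes into two groups of the
#' original sizes; the one-sided p-value is (1 + #{null >= observed}) /
#' (n_perm + 1). A large p means the bipartition is no better than a random
#' split of the union, i.e. the modules should be merged.
#'
#' @param graph a `corr_graph` or symmetric weight matrix.
#' @param membership cluster labels, one per node.
#' @param pair length-2 vector naming the two modules to test.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutation draws.
#' @return list of class `"bipartition_test"`: `module_pair`, `statistic`,
#'   `p_value`, `n_perm`.
#' @export
permutation_bipartition_test <- function(graph, membership, pair,
                                         n_perm = 999L, seed = NULL) {
  w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
  stopifnot(length(pair) == 2L)
  memb <- as.character(membership)
  idx1 <- which(memb == as.character(pair[1]))
  idx2 <- which(memb == as.character(pair[2]))
  if (!length(idx1) || !length(idx2)) stop("both modules must be non-empty")
  out <- list(module_pair = pair, statistic = NA_real_, p_value = 1,
              n_perm = as.integer(n_perm))
  class(out) <- "bipartition_test"
  union_idx <- c(idx1, idx2)
  nu <- length(union_idx)
  if (nu < 3L) return(out)  # test undefined; merge
  if (!is.null(seed)) set.seed(seed)
  sub <- w[union_idx, union_idx, drop = FALSE]
  n1 <- length(idx1)
  grp <- rep(c(TRUE, FALSE), c(n1, nu - n1))
  tstat <- function(lab) {
    same <- outer(lab, lab, `==`)
    ut <- upper.tri(sub)
    wi <- sub[ut & same]
    cr <- sub[ut & !same]
    if (length(wi) < 2L || length(cr) < 2L) return(0)
    denom <- sqrt(stats::var(wi) / length(wi) + stats::var(cr) / length(cr))
    if (!is.finite(denom) || denom <= 0) return(0)
    (mean(wi) - mean(cr)) / denom
  }
  obs <- tstat(grp)
  null <- vapply(seq_len(n_perm), function(i) tstat(sample(grp)), 0)
  out$statistic <- obs
  out$p_value <- (1 + sum(null >= obs)) / (n_perm + 1)
  out
}

#' @export
print.bipartition_test <- function(x, ...) {
  cat(sprintf("Bipartition %s | %s: t = %.3f, p = %.4f (%d permutations)\n",
              x$module_pair[1], x$module_pair[2], x$statistic, x$p_value,
              x$n_perm))
  invisible(x)
}

#' Merge statistically unsupported module bipartitions
#'
#' Final refinement stage: every pair of modules is tested with
#' [permutation_bipartition_test()]; while any pair fails at level `alpha`,
#' the pair with the largest p-value is merged and the tests involving the
#' merged module are recomputed. Terminates after at most g - 1 merges; the
#' output is a coarsening of the input.
#'
#' Module pairs with no connecting edge are never merged: joining two
#' disconnected communities strictly decreases modularity and a bipartition
#' with no cross connectivity cannot fail a separation test in any meaningful
#' way (the permutation test is also powerless on very small unions, e.g.
#' two 2-node modules admit only three distinct splits). Such pairs are
#' reported with `p_value = NA` in the test table.
#'
#' @param graph a `corr_graph` or weight matrix.
#' @param membership factor of cluster labels.
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations per test.
#' @param seed optional base seed (advanced deterministically across tests).
#' @return factor of refined labels; attribute `"tests"` holds a data frame
#'   of all pairwise tests from the final round.
#' @export
significance_refine <- function(graph, membership, alpha = 0.05,
                                n_perm = 999L, seed = NULL) {
  memb <- droplevels(factor(membership))
  nm <- names(membership)
  counter <- 0L
  next_seed <- function() {
    if (is.null(seed)) return(NULL)
    counter <<- counter + 1L
    seed + counter
  }
  repeat {
    groups <- levels(memb)
    g <- length(groups)
    if (g < 2L) break
    pairs <- utils::combn(groups, 2)
    w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
    pvals <- apply(pairs, 2, function(pr) {
      idx1 <- memb == pr[1]; idx2 <- memb == pr[2]
      if (all(w[idx1, idx2] <= 0)) return(NA_real_)  # disconnected: keep
      permutation_bipartition_test(graph, memb, pr, n_perm,
                                   next_seed())$p_value
    })
    tests <- data.frame(module1 = pairs[1, ], module2 = pairs[2, ],
                        p_value = pvals)
    if (all(is.na(pvals) | pvals < alpha)) {
      attr(memb, "tests") <- tests
      break
    }
    worst <- which.max(pvals)
    keep <- pairs[1, worst]; drop <- pairs[2, worst]
    levels(memb)[levels(memb) == drop] <- keep
    memb <- droplevels(memb)
    attr(memb, "tests") <- tests
  }
  names(memb) <- nm
  memb
}
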