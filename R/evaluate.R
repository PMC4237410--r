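#' Pair-level confusion counts between two partitions
#'
#' Counts unordered node pairs by co-membership: `tp` pairs co-clustered in
#' both truth and prediction, `fn` co-clustered in truth only, `fp` in
#' prediction only. This pair basis makes the counts well defined when the
#' two partitions have different numbers of clusters.
#'
#' @param truth,predicted label vectors over the same nodes.
#' @return list of class `"pair_confusion"` with integer `tp`, `fp`, `fn`.
#' @export
pair_confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must label the same nodes")
  ut <- upper.tri(diag(length(truth)))
  same_t <- outer(truth, truth, `==`)[ut]
  same_p <- outer(predicted, predicted, `==`)[ut]
  structure(list(tp = sum(same_t & same_p),
                 fp = sum(!same_t & same_p),
                 fn = sum(same_t & !same_p)),
            class = "pair_confusion")
}

#' Pair F-score of a clustering against ground truth
#'
#' Harmonic mean F = 2*sn*sp/(sn + sp) of sensitivity sn = tp/(tp + fn) and
#' the precision-form "specificity" sp = tp/(tp + fp), computed over
#' co-clustered node pairs. F = 0 when tp = 0.
#'
#' @param conf a `pair_confusion`, or the truth labels if `predicted` given.
#' @param predicted optional predicted labels (then `conf` is truth).
#' @return F-score in [0, 1].
#' @examples
#' f_score(list(tp = 2, fp = 1, fn = 1))  # sn = sp = 2/3 -> F = 2/3
#' @export
f_score <- function(conf, predicted = NULL) {
  if (!is.null(predicted)) conf <- pair_confusion(conf, predicted)
  tp <- conf$tp; fp <- conf$fp; fn <- conf$fn
  if (tp + fn == 0) stop("truth has no co-clustered pairs; F-score undefined")
  if (tp == 0) return(0)
  sn <- tp / (tp + fn)
  sp <- tp / (tp + fp)
  2 * sn * sp / (sn + sp)
}

#' Benchmark grid of structured simulations
#'
#' Runs the full pipeline (simulate, build the contact-constrained graph,
#' fast-greedy, optional discriminant-ellipse filter, permutation
#' refinement) for each requested intra-correlation cell, `replicates` times
#' with seeds `base_seed + replicate`, and scores each run with the pair
#' F-score against the template's true two-letter clustering.
#'
#' @param cells two-column matrix or data frame of (corr_a, corr_b) values.
#' @param replicates simulated replicates per cell (benchmark tables use 20).
#' @param lda logical: apply [lda_refine()] between the optimizer and the
#'   permutation refinement.
#' @param n_samples samples per replicate (default 500).
#' @param inter_range inter-cluster correlation range, default U(0, 0.1).
#' @param noise_sd simulation noise (default 0.1).
#' @param alpha Fisher-filter and bipartition-test level.
#' @param n_perm permutations per bipartition test.
#' @param base_seed replicate r of a cell uses seed `base_seed + r`.
#' @param template shape template (default [double_h_template()]).
#' @return data frame with one row per cell: `corr_a`, `corr_b`, `mean_f`,
#'   `sd_f`, `n_rep`; per-replicate scores in `attr(, "scores")` (cells in
#'   rows).
#' @export
run_grid <- function(cells, replicates = 20L, lda = TRUE,
                     n_samples = 500L, inter_range = c(0, 0.1),
                     noise_sd = 0.1, alpha = 0.05, n_perm = 999L,
                     base_seed = 42L, template = double_h_template()) {
  cells <- as.matrix(cells)
  stopifnot(ncol(cells) == 2L)
  contacts <- infer_contacts(template, noise_sd)
  scores <- matrix(NA_real_, nrow(cells), replicates)
  for (i in seq_len(nrow(cells))) {
    for (r in seq_len(replicates)) {
      fit <- tccn_simulated(template,
                            corr_a = cells[i, 1], corr_b = cells[i, 2],
                            n_samples = n_samples, inter_range = inter_range,
                            noise_sd = noise_sd, alpha = alpha, lda = lda,
                            n_perm = n_perm, seed = base_seed + r,
                            contacts = contacts)
      scores[i, r] <- f_score(as.character(template$truth),
                              as.character(fit$membership))
    }
  }
  out <- data.frame(corr_a = cells[, 1], corr_b = cells[, 2],
                    mean_f = rowMeans(scores),
                    sd_f = apply(scores, 1, stats::sd),
                    n_rep = replicates)
  attr(out, "scores") <- scores
  out
}

#' Per-cell Mann-Whitney comparison of two benchmark grids
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per grid cell on the
#' retained per-replicate F-scores of two [run_grid()] results, typically the
#' filtered vs unfiltered arms run on the same seeds.
#'
#' @param grid_a,grid_b `run_grid()` results over the same cells.
#' @return `grid_a`'s cell columns plus `mean_a`, `mean_b`, `p_value`.
#' @export
compare_grids <- function(grid_a, grid_b) {
  sa <- attr(grid_a, "scores"); sb <- attr(grid_b, "scores")
  if (is.null(sa) || is.null(sb) || nrow(sa) != nrow(sb))
    stop("grids must carry per-replicate scores over the same cells")
  p <- vapply(seq_len(nrow(sa)), function(i) {
    if (all(sa[i, ] == sb[i, ])) return(1)  # degenerate all-tied cell
    pv <- suppressWarnings(stats::wilcox.test(sa[i, ], sb[i, ],
                                              exact = FALSE)$p.value)
    if (is.finite(pv)) pv else 1
  }, 0)
  data.frame(corr_a = grid_a$corr_a, corr_b = grid_a$corr_b,
             mean_a = grid_a$mean_f, mean_b = grid_b$mean_f, p_value = p)
}
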