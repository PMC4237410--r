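#' Per-dimension Pearson correlation matrices
#'
#' Splits an n x (p*d) sample matrix into its d dimension blocks (columns
#' ordered point-within-dimension: the first p columns are dimension 1, and
#' so on) and returns one p x p Pearson correlation matrix per dimension.
#' Missing values are handled pairwise-complete; the per-pair sample counts
#' are attached as `attr(, "n_pairs")` so the Fisher test downstream can use
#' the correct standard error for each entry. Zero-variance columns yield
#' zero correlations (with a warning) rather than NaN.
#'
#' @param x numeric matrix (or `tccn_sim`), n samples by p*d variables.
#' @param dims number of spatial dimensions d (1, 2 or 3).
#' @return list of d correlation matrices, each with an `"n_pairs"` attribute.
#' @export
per_dimension_correlations <- function(x, dims = 1L) {
  if (inherits(x, "tccn_sim")) {
    dims <- x$dims
    x <- x$data
  }
  x <- as.matrix(x)
  if (nrow(x) < 4L) stop("need at least 4 samples")
  if (ncol(x) %% dims != 0L)
    stop("column count ", ncol(x), " is not divisible by dims = ", dims)
  p <- ncol(x) %/% dims
  lapply(seq_len(dims), function(k) {
    block <- x[, (k - 1L) * p + seq_len(p), drop = FALSE]
    obs <- !is.na(block)
    n_pairs <- crossprod(obs)
    r <- suppressWarnings(stats::cor(block, use = "pairwise.complete.obs"))
    bad <- !is.finite(r)
    if (any(bad)) {
      warning("zero-variance or empty-overlap columns: ",
              sum(bad & upper.tri(bad)), " correlation(s) set to 0")
      r[bad] <- 0
    }
    diag(r) <- 1
    attr(r, "n_pairs") <- n_pairs
    r
  })
}

#' Fisher z-test filter for correlations
#'
#' Tests each correlation against zero with the Fisher z-transformation:
#' z = atanh(r) is approximately normal with standard error 1/sqrt(n - 3).
#' Entries whose two-sided test does not reject at level `alpha` are set to
#' zero; significant entries pass through unchanged. An optional
#' multiple-testing correction over the off-diagonal entries is available but
#' off by default.
#'
#' @param r correlation matrix (or scalar/vector).
#' @param n sample count: a scalar, or a matrix of per-entry counts such as
#'   the `"n_pairs"` attribute of [per_dimension_correlations()]. All counts
#'   must exceed 3.
#' @param alpha two-sided significance level (default 0.05).
#' @param p_adjust method passed to [stats::p.adjust()] (`"none"`,
#'   `"bonferroni"`, `"BH"`, ...).
#' @return object shaped like `r` with non-significant entries zeroed
#'   (diagonal of a matrix is kept at its input value).
#' @examples
#' fisher_filter(0.15, n = 500)  # retained: |atanh(r)|*sqrt(497) = 3.37
#' fisher_filter(0.05, n = 500)  # zeroed:   1.12 < 1.96
#' @export
fisher_filter <- function(r, n, alpha = 0.05, p_adjust = "none") {
  if (any(n <= 3)) stop("Fisher z-test requires n > 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  rc <- pmin(pmax(r, -1), 1)
  z <- atanh(rc * (abs(rc) < 1)) # |r| == 1 handled below
  se <- 1 / sqrt(n - 3)
  pval <- 2 * stats::pnorm(-abs(z) / se)
  pval[abs(rc) >= 1] <- 0
  if (is.matrix(r) && nrow(r) == ncol(r)) {
    ut <- upper.tri(r)
    pval[ut] <- stats::p.adjust(pval[ut], method = p_adjust)
    pval[lower.tri(pval)] <- t(pval)[lower.tri(pval)]
    out <- ifelse(pval < alpha, r, 0)
    diag(out) <- diag(r)
    dimnames(out) <- dimnames(r)
  } else {
    pval <- stats::p.adjust(pval, method = p_adjust)
    out <- ifelse(pval < alpha, r, 0)
  }
  out
}

#' Correlation-vector magnitude matrix
#'
#' Combines d per-dimension correlation matrices into one non-negative
#' magnitude per pair: the Euclidean norm sqrt(sum over dimensions of r^2).
#' For d = 1 this is the absolute correlation.
#'
#' @param r_list list of p x p (filtered) correlation matrices.
#' @return p x p matrix of magnitudes; each entry is at most sqrt(d).
#' @export
magnitude_matrix <- function(r_list) {
  if (is.matrix(r_list)) r_list <- list(r_list)
  dims <- dim(r_list[[1]])
  if (!all(vapply(r_list, function(m) identical(dim(m), dims), logical(1))))
    stop("all per-dimension matrices must have the same shape")
  out <- sqrt(Reduce(`+`, lapply(r_list, function(m) unclass(m)^2)))
  attributes(out) <- attributes(out)["dim"]
  dimnames(out) <- dimnames(r_list[[1]])
  out
}

#' Build a (topology-constrained) correlation graph
#'
#' Assembles the weighted undirected graph the community analysis runs on.
#' An edge i--j is present with weight `magnitudes[i, j]` when that magnitude
#' is positive (some dimension's correlation survived the significance
#' filter) and, if a contact matrix is supplied, when i and j are in contact.
#' The diagonal is always zero.
#'
#' @param magnitudes symmetric non-negative p x p matrix, e.g. from
#'   [magnitude_matrix()].
#' @param contacts optional symmetric logical p x p contact/adjacency matrix;
#'   `NULL` builds the unconstrained graph.
#' @return object of class `"corr_graph"`: list with `weights` (p x p),
#'   `labels`, `constrained`.
#' @export
build_graph <- function(magnitudes, contacts = NULL) {
  magnitudes <- as.matrix(magnitudes)
  p <- nrow(magnitudes)
  if (ncol(magnitudes) != p || any(abs(magnitudes - t(magnitudes)) > 1e-10))
    stop("magnitude matrix must be square and symmetric")
  if (any(magnitudes < 0)) stop("magnitudes must be non-negative")
  w <- (magnitudes + t(magnitudes)) / 2
  diag(w) <- 0
  constrained <- !is.null(contacts)
  if (constrained) {
    contacts <- as.matrix(contacts)
    if (!identical(dim(contacts), dim(w)))
      stop("contact matrix shape does not match")
    storage.mode(contacts) <- "logical"
    if (!isTRUE(all(contacts == t(contacts))))
      stop("contact matrix must be symmetric")
    w[!contacts] <- 0
  }
  labels <- rownames(magnitudes)
  if (is.null(labels)) labels <- paste0("v", seq_len(p))
  dimnames(w) <- list(labels, labels)
  # keep the natural diagonal (self-magnitude sqrt(d)) here: these are the
  # discriminant-filter features, not adjacencies
  mag <- (magnitudes + t(magnitudes)) / 2
  dimnames(mag) <- list(labels, labels)
  structure(list(weights = w, magnitudes = mag, labels = labels,
                 constrained = constrained),
            class = "corr_graph")
}

#' @export
print.corr_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Correlation graph: %d nodes, %d edges%s\n",
              nrow(x$weights), ne,
              if (x$constrained) " (topology-constrained)" else ""))
  invisible(x)
}

#' Correlation graph straight from samples
#'
#' Convenience wrapper chaining [per_dimension_correlations()],
#' [fisher_filter()] (per dimension, with per-pair sample counts),
#' [magnitude_matrix()] and [build_graph()].
#'
#' @param x sample matrix or `tccn_sim`.
#' @param dims spatial dimensions.
#' @param contacts optional contact matrix.
#' @param alpha Fisher-test level.
#' @param p_adjust multiplicity correction (default none).
#' @return a `corr_graph`.
#' @export
correlation_graph <- function(x, dims = 1L, contacts = NULL, alpha = 0.05,
                              p_adjust = "none") {
  rl <- per_dimension_correlations(x, dims)
  filt <- lapply(rl, function(r)
    fisher_filter(r, attr(r, "n_pairs"), alpha, p_adjust))
  build_graph(magnitude_matrix(filt), contacts)
}
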