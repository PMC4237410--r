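#' Linear discriminant scores of nodes given a grouping
#'
#' Fits a linear discriminant projection of the node feature matrix (the
#' significance-filtered correlation-magnitude matrix, the same matrix that
#' defines the graph) onto the grouping: directions maximizing between-group
#' scatter relative to within-group scatter. The classical sphering
#' construction is used: variables are scaled by their pooled within-group
#' standard deviation, the within-class covariance is whitened through a
#' tolerance-truncated SVD (directions with no appreciable within-group
#' variance are dropped, not amplified), and the discriminants are the
#' leading right singular vectors of the whitened group means. Variables
#' that are constant within groups (for example the all-zero feature columns
#' of isolated nodes) are dropped rather than raising an error. The first
#' q = min(2, groups - 1) discriminants are returned.
#'
#' @param features numeric matrix, nodes in rows.
#' @param membership factor (or coercible) of group labels, one per row.
#' @param tol relative tolerance for the within-class rank truncation
#'   (default 1e-4, the conventional value).
#' @return `NULL` when fewer than two groups are present (nothing to
#'   discriminate); otherwise a list of class `"lda_scores"` with `scores`
#'   (p x q), `membership` (factor, unused levels dropped), `q`, and the
#'   kept-variable projection `directions`.
#' @export
fit_lda <- function(features, membership, tol = 1e-4) {
  x <- as.matrix(features)
  memb <- droplevels(factor(membership))
  if (nrow(x) != length(memb)) stop("one membership label per row required")
  g <- nlevels(memb)
  if (g < 2L) return(NULL)
  q <- min(2L, g - 1L)
  n <- nrow(x)
  counts <- tabulate(memb)
  gmeans <- apply(x, 2, function(col) tapply(col, memb, mean))
  gmeans <- matrix(gmeans, nrow = g)  # g x nf, robust to nf = 1
  xw <- x - gmeans[as.integer(memb), , drop = FALSE]
  degenerate <- function() {
    scores <- matrix(0, n, q, dimnames = list(rownames(x),
                                              paste0("LD", seq_len(q))))
    structure(list(scores = scores, membership = memb,
                   directions = NULL, q = q),
              class = "lda_scores")
  }
  if (n <= g) return(degenerate())
  f1 <- sqrt(colSums(xw^2) / (n - g))
  keep <- f1 > tol * max(f1, 0)
  if (!any(keep)) return(degenerate())
  sc1 <- 1 / f1[keep]
  xs <- sqrt(1 / (n - g)) * xw[, keep, drop = FALSE] *
    rep(sc1, each = n)
  sv <- svd(xs, nu = 0)
  rank <- sum(sv$d > tol * sv$d[1])
  scaling <- (sv$v[, seq_len(rank), drop = FALSE] *
                rep(sc1, times = rank)) %*%
    diag(1 / sv$d[seq_len(rank)], rank)
  prior <- counts / n
  xbar <- colSums(prior * gmeans)
  mb <- sqrt(n * prior / (g - 1)) *
    sweep(gmeans[, keep, drop = FALSE], 2, xbar[keep])
  sv2 <- svd(mb %*% scaling, nu = 0)
  rank2 <- max(1L, sum(sv2$d > tol * sv2$d[1]))
  directions <- scaling %*% sv2$v[, seq_len(min(q, rank2)), drop = FALSE]
  scores <- sweep(x[, keep, drop = FALSE], 2, xbar[keep]) %*% directions
  if (ncol(scores) < q)  # fewer usable discriminants than requested
    scores <- cbind(scores, matrix(0, n, q - ncol(scores)))
  colnames(scores) <- paste0("LD", seq_len(q))
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, membership = memb,
                 directions = directions, q = q),
            class = "lda_scores")
}

#' Confidence ellipse of a group's discriminant scores
#'
#' Normal-theory data ellipse of one group's scores on the first two linear
#' discriminants: centred at the group mean, axes from the eigendecomposition
#' of the 2 x 2 score covariance scaled by sqrt of the chi-squared(2 df)
#' quantile at `level`. A singleton group yields a point ellipse. One-column
#' scores (two-group fits have a single discriminant) yield a degenerate
#' ellipse: the chi-squared(1 df) confidence interval on LD1, represented
#' with semi-minor axis 0.
#'
#' @param scores numeric matrix (m x 1 or m x 2) of one group's scores.
#' @param level confidence level, default 0.95.
#' @param scaling `"f"` (default) for the small-sample normal-theory radius,
#'   `sqrt(2 (m-1)/(m-2) F(level; 2, m-2))`, which accounts for the group
#'   covariance being estimated from few nodes; `"chisq"` for the asymptotic
#'   `sqrt(chisq(level, 2))` radius.
#' @return object of class `"conf_ellipse"`: list with `center` (length 2),
#'   `a` and `b` (semi-major/minor axes, `a >= b >= 0`), `angle` (major-axis
#'   orientation, radians) and `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95,
                               scaling = c("f", "chisq")) {
  stopifnot(level > 0, level < 1)
  scaling <- match.arg(scaling)
  scores <- as.matrix(scores)
  m <- nrow(scores)
  if (ncol(scores) == 1L) scores <- cbind(scores, 0)
  center <- colMeans(scores)
  if (m < 2L) {
    ell <- list(center = center, a = 0, b = 0, angle = 0, level = level)
    class(ell) <- "conf_ellipse"
    return(ell)
  }
  s <- stats::cov(scores)
  radius2 <- function(df) {
    if (scaling == "chisq" || m - df < 1L)
      stats::qchisq(level, df)
    else
      df * (m - 1) / (m - df) * stats::qf(level, df, m - df)
  }
  if (all(abs(scores[, 2]) < 1e-300)) {
    # single discriminant: the analogous 1-D interval on LD1
    a <- sqrt(radius2(1) * s[1, 1])
    ell <- list(center = center, a = a, b = 0, angle = 0, level = level)
    class(ell) <- "conf_ellipse"
    return(ell)
  }
  eg <- eigen(s, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  r <- sqrt(radius2(2))
  ell <- list(center = center,
              a = r * sqrt(vals[1]), b = r * sqrt(vals[2]),
              angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
              level = level)
  class(ell) <- "conf_ellipse"
  ell
}

#' Test whether a point lies inside (or on) a confidence ellipse
#'
#' The membership inequality ((x-h)^2/a^2 + (y-k)^2/b^2 <= 1) is applied in
#' the ellipse's principal-axes frame: the point is translated to the centre
#' and rotated by minus the orientation angle before the quadratic form is
#' evaluated. Degenerate axes (point or interval ellipses) are compared with
#' an absolute tolerance of 1e-12.
#'
#' @param point numeric length-2 (x, y).
#' @param ellipse a `conf_ellipse`.
#' @param tol tolerance for degenerate axes.
#' @return logical.
#' @export
point_in_ellipse <- function(point, ellipse, tol = 1e-12) {
  d <- point - ellipse$center
  co <- cos(ellipse$angle); si <- sin(ellipse$angle)
  u <- co * d[1] + si * d[2]
  v <- -si * d[1] + co * d[2]
  a <- ellipse$a; b <- ellipse$b
  if (a <= tol && b <= tol) return(abs(u) <= tol && abs(v) <= tol)
  if (b <= tol) return(abs(v) <= tol && abs(u) <= a * (1 + 1e-9))
  (u / a)^2 + (v / b)^2 <= 1 + 1e-9
}

#' Collision test between two confidence ellipses
#'
#' Two ellipses collide when they overlap or one contains the other. The test
#' checks each centre against the other ellipse (containment) and then 360
#' uniformly spaced boundary points of each ellipse against the other
#' (boundary crossing).
#'
#' @param e1,e2 `conf_ellipse` objects.
#' @param n_points boundary points sampled per ellipse.
#' @return logical.
#' @export
ellipses_collide <- function(e1, e2, n_points = 360L) {
  if (point_in_ellipse(e1$center, e2) || point_in_ellipse(e2$center, e1))
    return(TRUE)
  boundary <- function(e) {
    theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    u <- e$a * cos(theta); v <- e$b * sin(theta)
    co <- cos(e$angle); si <- sin(e$angle)
    cbind(e$center[1] + co * u - si * v,
          e$center[2] + si * u + co * v)
  }
  b1 <- boundary(e1)
  for (i in seq_len(nrow(b1)))
    if (point_in_ellipse(b1[i, ], e2)) return(TRUE)
  b2 <- boundary(e2)
  for (i in seq_len(nrow(b2)))
    if (point_in_ellipse(b2[i, ], e1)) return(TRUE)
  FALSE
}

#' Refine a membership vector by discriminant-ellipse collisions
#'
#' The over-fragmentation filter. Iterates: fit the discriminant projection
#' of the feature matrix on the current grouping, compute each group's 95%
#' confidence ellipse on the first two discriminants, test all group pairs
#' for ellipse collisions, and merge every connected component of the
#' collision graph into one group. Stops when no ellipses collide, one group
#' remains, or `max_iter` iterations have run. The output is always a
#' coarsening of the input partition: groups are only ever merged.
#'
#' @param features node feature matrix (rows = nodes), typically
#'   `graph$weights` of a [build_graph()] result.
#' @param membership factor of initial cluster labels.
#' @param level ellipse confidence level (default 0.95).
#' @param max_iter iteration cap; defaults to the initial group count, the
#'   maximum number of merging rounds possible.
#' @param scaling ellipse radius rule, see [confidence_ellipse()].
#' @return factor of refined labels (named as input), with attributes
#'   `"iterations"` (collision rounds performed).
#' @export
lda_refine <- function(features, membership, level = 0.95, max_iter = NULL,
                       scaling = c("f", "chisq")) {
  scaling <- match.arg(scaling)
  memb <- droplevels(factor(membership))
  nm <- names(membership)
  if (is.null(nm) && !is.null(rownames(features))) nm <- rownames(features)
  if (is.null(max_iter)) max_iter <- nlevels(memb)
  features <- as.matrix(features)
  if (nrow(features) == ncol(features)) {
    # a node's self-magnitude carries no grouping information but acts as a
    # high-leverage outlier in its own column; replace it with the mean of
    # the node's retained correlations so the self-entry sits at the node's
    # typical similarity scale
    off <- features; diag(off) <- NA
    diag(features) <- apply(off, 1, function(z) {
      z <- z[!is.na(z) & z > 0]
      if (length(z)) mean(z) else 0
    })
  }
  iter <- 0L
  while (nlevels(memb) >= 2L && iter < max_iter) {
    fit <- fit_lda(features, memb)
    groups <- levels(fit$membership)
    ells <- lapply(groups, function(lev)
      confidence_ellipse(fit$scores[fit$membership == lev, , drop = FALSE],
                         level, scaling))
    g <- length(groups)
    collide <- diag(TRUE, g)
    for (i in seq_len(g - 1L)) for (j in seq(i + 1L, g)) {
      collide[i, j] <- collide[j, i] <- ellipses_collide(ells[[i]], ells[[j]])
    }
    if (!any(collide[upper.tri(collide)])) break
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      collide, mode = "undirected", diag = FALSE))$membership
    # name each merged component after its first original label
    new_lab <- vapply(comp, function(k) groups[which(comp == k)[1]], "")
    memb <- droplevels(factor(new_lab[match(memb, groups)]))
    iter <- iter + 1L
  }
  names(memb) <- nm
  attr(memb, "iterations") <- iter
  memb
}
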