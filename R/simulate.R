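#' Two-letter "H" shape template on a unit grid
#'
#' Builds the benchmark shape used by the structured simulations: two
#' contiguous capital-H glyphs drawn on a unit grid. Each letter consists of
#' two vertical 5-point bars (x = 0 and x = 2 within the letter) plus a single
#' crossbar point at (1, 2); the second letter is translated along x by
#' `offset` grid units. The crossbars are deliberate chokepoints: they leave
#' each letter's bars weakly connected, which makes the contact-constrained
#' clustering problem hard.
#'
#' @param offset horizontal translation (grid units) of the second letter.
#'   Must be at least 3, otherwise the glyphs overlap; at exactly 3 the facing
#'   bars sit at unit distance and the letters touch.
#' @return an object of class `"shape_template"`: a list with `coords`
#'   (p x 2 matrix of grid coordinates), `truth` (factor of length p with
#'   levels `"A"`/`"B"`), and `labels` (point names).
#' @examples
#' tpl <- double_h_template()
#' nrow(tpl$coords)   # 22 points, 11 per letter
#' table(tpl$truth)
#' @export
double_h_template <- function(offset = 3L) {
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 3L)
    stop("offset must be >= 3 grid units; smaller values overlap the letters")
  h_glyph <- rbind(
    cbind(0, 0:4),    # left bar
    cbind(2, 0:4),    # right bar
    c(1, 2)           # crossbar chokepoint
  )
  coords <- rbind(h_glyph, sweep(h_glyph, 2, c(offset, 0), "+"))
  p <- nrow(coords)
  truth <- factor(rep(c("A", "B"), each = nrow(h_glyph)))
  labels <- paste0(rep(c("A", "B"), each = nrow(h_glyph)),
                   seq_len(nrow(h_glyph)))
  dimnames(coords) <- list(labels, c("x", "y"))
  structure(list(coords = coords, truth = truth, labels = labels),
            class = "shape_template")
}

#' Block target correlation matrix for a shape template
#'
#' Constructs the p x p correlation matrix the simulator factorizes: unit
#' diagonal, constant intra-cluster correlation within each true cluster, and
#' independent uniform draws on `inter_range` for every cross-cluster pair
#' (symmetrized). If the result is not positive definite the cross-cluster
#' entries are redrawn (up to `max_retries` times) and, as a last resort, a
#' small diagonal jitter (1e-8) is added.
#'
#' @param template a `shape_template`.
#' @param corr_a,corr_b intra-cluster correlation of clusters A and B, in
#'   (0, 1); the benchmark grid uses 0.15 to 0.95.
#' @param inter_range length-2 numeric, the support of the uniform
#'   inter-cluster correlation (default `c(0, 0.1)`).
#' @param max_retries redraw attempts before jittering.
#' @return p x p positive-definite correlation matrix.
#' @export
target_correlation <- function(template, corr_a, corr_b,
                               inter_range = c(0, 0.1), max_retries = 10L) {
  stopifnot(inherits(template, "shape_template"),
            corr_a >= 0, corr_a < 1, corr_b >= 0, corr_b < 1,
            length(inter_range) == 2L,
            inter_range[1] >= 0, inter_range[2] < 1,
            inter_range[1] <= inter_range[2])
  in_a <- template$truth == levels(template$truth)[1]
  p <- nrow(template$coords)
  block <- matrix(0, p, p)
  block[in_a, in_a] <- corr_a
  block[!in_a, !in_a] <- corr_b
  n_cross <- sum(in_a) * sum(!in_a)
  for (try in seq_len(max_retries + 1L)) {
    rho <- block
    cross <- stats::runif(n_cross, inter_range[1], inter_range[2])
    rho[in_a, !in_a] <- cross
    rho[!in_a, in_a] <- t(rho[in_a, !in_a, drop = FALSE])
    diag(rho) <- 1
    ok <- !inherits(try(chol(rho), silent = TRUE), "try-error")
    if (ok) return(rho)
  }
  # high intra-correlation blocks leave little eigenvalue margin and random
  # cross blocks can push the matrix indefinite for every redraw; repair by
  # shrinking the cross block toward zero until the factorization succeeds,
  # which preserves the uniform character of the inter-cluster correlations
  # (scaled down) and leaves the intra-cluster blocks exact
  for (shrink in 0.9^seq_len(60)) {
    rho2 <- block
    rho2[in_a, !in_a] <- shrink * rho[in_a, !in_a]
    rho2[!in_a, in_a] <- t(rho2[in_a, !in_a, drop = FALSE])
    diag(rho2) <- 1
    if (!inherits(try(chol(rho2), silent = TRUE), "try-error")) return(rho2)
  }
  stop("target correlation matrix is not positive definite after repair")
}

#' Simulate a correlated sample anchored to a shape
#'
#' Cholesky-based structured simulation. For each spatial dimension an
#' n x p standard-normal matrix is drawn, right-multiplied by the upper
#' Cholesky factor of the target correlation (so its columns acquire the
#' target correlation structure), scaled by `noise_sd`, and added to the
#' replicated template coordinates. The same target correlation matrix is
#' shared by all dimensions; the noise draws are independent per dimension.
#'
#' @param template a `shape_template`.
#' @param n_samples number of rows (specimens); at least 4 so the Fisher
#'   z-test downstream is defined. Default 500.
#' @param corr_a,corr_b,inter_range passed to [target_correlation()], unless
#'   `rho` is supplied.
#' @param noise_sd standard deviation of the positional noise, in grid units
#'   (default 0.1). Purely a spatial scale: column correlations do not depend
#'   on it, but the contact rule threshold `1 + noise_sd` does.
#' @param seed optional integer seed, applied with [set.seed()] before any
#'   draw (the uniform cross-correlations included).
#' @param rho optional pre-built p x p target correlation, overriding
#'   `corr_a`/`corr_b`/`inter_range`.
#' @return object of class `"tccn_sim"`: list with `data` (n x 2p matrix,
#'   columns ordered point-within-dimension: all x's then all y's), `dims`,
#'   `template`, `rho`, `noise_sd`.
#' @examples
#' sim <- simulate_dataset(double_h_template(), n_samples = 100,
#'                         corr_a = 0.5, corr_b = 0.5, seed = 1)
#' dim(sim$data)
#' @export
simulate_dataset <- function(template, n_samples = 500L,
                             corr_a = 0.5, corr_b = 0.5,
                             inter_range = c(0, 0.1),
                             noise_sd = 0.1, seed = NULL, rho = NULL) {
  stopifnot(inherits(template, "shape_template"), n_samples >= 4L,
            noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho))
    rho <- target_correlation(template, corr_a, corr_b, inter_range)
  p <- nrow(template$coords)
  d <- ncol(template$coords)
  L <- chol(rho)  # upper triangular, rho = t(L) %*% L
  dat <- matrix(NA_real_, n_samples, p * d)
  for (k in seq_len(d)) {
    z <- matrix(stats::rnorm(n_samples * p), n_samples, p)
    noise <- noise_sd * (z %*% L)
    dat[, (k - 1L) * p + seq_len(p)] <-
      matrix(template$coords[, k], n_samples, p, byrow = TRUE) + noise
  }
  colnames(dat) <- rep(template$labels, d)  # node identity, repeated per dim
  structure(list(data = dat, dims = d, template = template, rho = rho,
                 noise_sd = noise_sd),
            class = "tccn_sim")
}

#' Contact matrix of a shape template
#'
#' Two points are in contact when the Euclidean distance between their
#' template coordinates is at most one grid unit plus the simulation noise
#' standard deviation. Contacts are a property of the template alone and are
#' unaffected by sample noise.
#'
#' @param template a `shape_template`.
#' @param noise_sd noise standard deviation added to the unit threshold
#'   (default 0.1, giving threshold 1.1: grid neighbours only).
#' @return symmetric logical p x p matrix with zero diagonal.
#' @export
infer_contacts <- function(template, noise_sd = 0.1) {
  stopifnot(inherits(template, "shape_template"), noise_sd >= 0)
  dmat <- as.matrix(stats::dist(template$coords))
  contacts <- dmat <= 1 + noise_sd
  diag(contacts) <- FALSE
  dimnames(contacts) <- list(template$labels, template$labels)
  contacts
}
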