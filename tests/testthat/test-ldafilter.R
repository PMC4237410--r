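test_that("discriminant fit matches MASS::lda on a well-conditioned problem", {
  skip_if_not_installed("MASS")
  set.seed(21)
  n <- 30
  grp <- rep(1:3, each = 10)
  x <- matrix(rnorm(n * 4), n, 4)
  x[grp == 2, 1] <- x[grp == 2, 1] + 4
  x[grp == 3, 2] <- x[grp == 3, 2] + 4
  fit <- fit_lda(x, grp)
  ref <- predict(MASS::lda(x, grouping = grp))$x
  expect_equal(fit$q, 2L)
  expect_gt(abs(cor(fit$scores[, 1], ref[, 1])), 0.9999)
  expect_gt(abs(cor(fit$scores[, 2], ref[, 2])), 0.9999)
})

test_that("LD1 separates groups at least as well as any single feature", {
  set.seed(22)
  n <- 40
  grp <- rep(1:2, each = 20)
  x <- matrix(rnorm(n * 3), n, 3)
  x[grp == 2, ] <- x[grp == 2, ] + 2
  fit <- fit_lda(x, grp)
  std_sep <- function(v) {
    abs(mean(v[grp == 1]) - mean(v[grp == 2])) /
      sqrt((var(v[grp == 1]) + var(v[grp == 2])) / 2)
  }
  expect_gte(std_sep(fit$scores[, 1]) + 1e-9, max(apply(x, 2, std_sep)))
})

test_that("degenerate discriminant inputs stay defined", {
  x <- matrix(1, 10, 4)          # identical rows
  fit <- fit_lda(x, rep(1:2, 5))
  expect_true(all(fit$scores == fit$scores[1, 1]))
  expect_null(fit_lda(x, rep(1, 10)))  # single group: nothing to do

  # constant-within-group (all-zero) columns are tolerated, not fatal
  set.seed(23)
  y <- cbind(matrix(rnorm(20), 10, 2), 0)
  y[1:5, 1] <- y[1:5, 1] + 3
  expect_s3_class(fit_lda(y, rep(1:2, each = 5)), "lda_scores")
})

test_that("whole-block label permutation leaves scores unchanged up to sign", {
  set.seed(24)
  x <- matrix(rnorm(60), 20, 3)
  x[11:20, ] <- x[11:20, ] + 3
  grp <- rep(c("a", "b"), each = 10)
  f1 <- fit_lda(x, grp)
  f2 <- fit_lda(x, rep(c("b", "a"), each = 10))
  expect_equal(abs(cor(f1$scores[, 1], f2$scores[, 1])), 1, tolerance = 1e-9)
})

test_that("confidence ellipse axes follow the known quantile arithmetic", {
  # four points with exactly identity sample covariance
  s <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- confidence_ellipse(s, scaling = "chisq")
  expect_equal(e$center, c(0, 0), ignore_attr = TRUE)
  expect_equal(e$a, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(e$b, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)

  # doubling the covariance scales both axes by sqrt(2)
  e2 <- confidence_ellipse(sqrt(2) * s, scaling = "chisq")
  expect_equal(e2$a / e$a, sqrt(2), tolerance = 1e-9)

  # small-sample scaling inflates the radius beyond chi-squared
  ef <- confidence_ellipse(s, scaling = "f")
  expect_gt(ef$a, e$a)

  # singleton group: point ellipse at the score
  p <- confidence_ellipse(matrix(c(2, 3), 1, 2))
  expect_equal(c(p$center, p$a, p$b), c(2, 3, 0, 0), ignore_attr = TRUE)
})

test_that("point membership agrees with the rotated quadratic form", {
  set.seed(25)
  for (i in 1:50) {
    ell <- structure(list(center = runif(2, -3, 3), a = runif(1, 0.5, 3),
                          b = runif(1, 0.1, 0.5), angle = runif(1, -pi, pi),
                          level = 0.95), class = "conf_ellipse")
    pt <- runif(2, -4, 4)
    d <- pt - ell$center
    uv <- c(cos(ell$angle) * d[1] + sin(ell$angle) * d[2],
            -sin(ell$angle) * d[1] + cos(ell$angle) * d[2])
    oracle <- (uv[1] / ell$a)^2 + (uv[2] / ell$b)^2 <= 1 + 1e-9
    expect_identical(point_in_ellipse(pt, ell), oracle)
  }
  circ <- structure(list(center = c(1, 1), a = 2, b = 2, angle = 0.3,
                         level = 0.95), class = "conf_ellipse")
  expect_true(point_in_ellipse(c(1, 1), circ))
  vert <- circ$center + 2 * c(cos(0.3), sin(0.3))
  expect_true(point_in_ellipse(vert, circ))            # vertex: on the edge
  expect_false(point_in_ellipse(circ$center + c(4.1, 0), circ))
})

test_that("ellipse collisions capture overlap, containment and separation", {
  mk <- function(cx, cy, a, b, ang = 0)
    structure(list(center = c(cx, cy), a = a, b = b, angle = ang,
                   level = 0.95), class = "conf_ellipse")
  expect_true(ellipses_collide(mk(0, 0, 1, 1), mk(0, 0, 1, 1)))
  expect_false(ellipses_collide(mk(0, 0, 1, 1), mk(10, 0, 1, 1)))
  expect_true(ellipses_collide(mk(0, 0, 1, 1), mk(1.5, 0, 1, 1)))
  # containment: tiny ellipse strictly inside a big one
  expect_true(ellipses_collide(mk(0, 0, 5, 5), mk(1, 0, 0.2, 0.1)))
  # rotated thin ellipses crossing
  expect_true(ellipses_collide(mk(0, 0, 3, 0.1, pi / 4),
                               mk(0, 0, 3, 0.1, -pi / 4)))
  # degenerate (interval) ellipses on a shared axis
  expect_true(ellipses_collide(mk(0, 0, 2, 0), mk(3, 0, 2, 0)))
  expect_false(ellipses_collide(mk(0, 0, 2, 0), mk(5, 0, 2, 0)))
})

test_that("collision refinement merges indistinguishable groups only", {
  set.seed(26)
  # two groups drawn from one cloud: merged
  x <- matrix(rnorm(20 * 5), 20, 5)
  merged <- lda_refine(x, rep(1:2, each = 10))
  expect_equal(nlevels(merged), 1L)

  # far-separated supports (>= 10 pooled SDs): untouched
  y <- matrix(rnorm(20 * 5, sd = 0.5), 20, 5)
  y[11:20, ] <- y[11:20, ] + 20
  kept <- lda_refine(y, rep(1:2, each = 10))
  expect_equal(nlevels(kept), 2L)

  # idempotence: the refinement output is a fixed point
  again <- lda_refine(y, kept)
  expect_equal(as.integer(again), as.integer(kept))
})

test_that("refinement only ever coarsens and terminates quickly", {
  set.seed(27)
  for (trial in 1:10) {
    p <- 18
    x <- matrix(rnorm(p * p), p, p)
    memb <- factor(sample(1:4, p, replace = TRUE))
    out <- lda_refine(x, memb)
    expect_lte(nlevels(out), nlevels(droplevels(memb)))
    expect_lte(attr(out, "iterations"), nlevels(droplevels(memb)))
    # coarsening: nodes together before stay together
    for (lv in levels(droplevels(memb))) {
      inside <- memb == lv
      expect_equal(length(unique(out[inside])), 1L)
    }
  }
})

test_that("structureless near-complete graphs collapse under the filter", {
  # i.i.d. edge weights carry no community signal: the filter should merge
  # modularity's arbitrary fragments in nearly every run, often all the way
  # to a single group
  merged_any <- 0
  merged_all <- 0
  for (s in 1:50) {
    set.seed(s)
    w <- random_complete_graph(8)
    g <- build_graph(w)
    init <- fast_greedy(g)
    if (nlevels(init) < 2) {
      merged_any <- merged_any + 1
      merged_all <- merged_all + 1
      next
    }
    out <- lda_refine(g$magnitudes, init)
    if (nlevels(out) < nlevels(init)) merged_any <- merged_any + 1
    if (nlevels(out) == 1) merged_all <- merged_all + 1
  }
  expect_gte(merged_any / 50, 0.7)
  expect_gte(merged_all / 50, 0.5)
})
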