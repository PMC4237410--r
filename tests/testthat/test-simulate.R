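test_that("double-H template has the expected grid geometry", {
  tpl <- double_h_template()
  expect_equal(nrow(tpl$coords), 22L)
  expect_equal(unname(table(tpl$truth)), c(11L, 11L), ignore_attr = TRUE)

  dmat <- as.matrix(dist(tpl$coords))
  cross <- dmat[tpl$truth == "A", tpl$truth == "B"]
  expect_equal(min(cross), 1)   # contiguous letters touch at unit distance

  far <- double_h_template(offset = 10)
  dfar <- as.matrix(dist(far$coords))
  expect_equal(min(dfar[far$truth == "A", far$truth == "B"]), 8)
  cfar <- infer_contacts(far, noise_sd = 0.1)
  expect_false(any(cfar[far$truth == "A", far$truth == "B"]))

  # within-letter nearest neighbours sit at one grid unit
  for (lv in c("A", "B")) {
    dl <- dmat[tpl$truth == lv, tpl$truth == lv]
    diag(dl) <- Inf
    expect_equal(unname(apply(dl, 1, min)), rep(1, 11))
  }

  expect_error(double_h_template(offset = 2), "offset")
})

test_that("crossbar chokepoints have exactly two within-letter contacts", {
  for (off in c(3L, 5L, 10L)) {
    tpl <- double_h_template(offset = off)
    contacts <- infer_contacts(tpl, noise_sd = 0.1)
    for (lv in c("A", "B")) {
      idx <- which(tpl$truth == lv)
      crossbar <- idx[11]   # 11th point of each glyph is the crossbar
      expect_equal(sum(contacts[crossbar, idx]), 2L)
    }
  }
})

test_that("target correlation matrix has exact block structure", {
  tpl <- double_h_template()
  set.seed(1)
  rho <- target_correlation(tpl, 0.5, 0.5, inter_range = c(0, 0))
  in_a <- tpl$truth == "A"
  expect_equal(unname(diag(rho)), rep(1, 22))
  expect_equal(unname(rho[in_a, in_a][upper.tri(diag(11))]), rep(0.5, 55))
  expect_equal(unname(rho[in_a, !in_a]), matrix(0, 11, 11), ignore_attr = TRUE)
  expect_silent(chol(rho))

  rho2 <- target_correlation(tpl, 0.15, 0.95, inter_range = c(0, 0.1))
  cross <- rho2[in_a, !in_a]
  expect_true(all(cross >= 0 & cross <= 0.1))
  expect_equal(unname(rho2[!in_a, !in_a][upper.tri(diag(11))]), rep(0.95, 55))

  ident <- target_correlation(tpl, 0, 0, inter_range = c(0, 0))
  expect_equal(ident, diag(22), ignore_attr = TRUE)
})

test_that("target correlation is positive definite across the benchmark grid", {
  tpl <- double_h_template()
  set.seed(42)
  for (cc in c(0.15, 0.55, 0.95)) {
    rho <- target_correlation(tpl, cc, cc, inter_range = c(0, 0.1))
    expect_silent(chol(rho))
    in_a <- tpl$truth == "A"
    expect_equal(unname(rho[in_a, in_a][upper.tri(diag(11))]), rep(cc, 55))
  }
})

test_that("simulated samples are anchored to the shape", {
  tpl <- double_h_template()
  sim0 <- simulate_dataset(tpl, n_samples = 10, corr_a = 0.5, corr_b = 0.5,
                           noise_sd = 0, seed = 1)
  target <- rep(unname(c(tpl$coords[, 1], tpl$coords[, 2])), each = 10)
  expect_equal(as.vector(sim0$data), target)

  n <- 500
  sim <- simulate_dataset(tpl, n_samples = n, corr_a = 0.5, corr_b = 0.5,
                          inter_range = c(0, 0), noise_sd = 0.1, seed = 2)
  # CLT bound on the column means
  mu <- c(tpl$coords[, 1], tpl$coords[, 2])
  expect_true(max(abs(colMeans(sim$data) - mu)) < 4 * 0.1 / sqrt(n))
})

test_that("empirical correlations converge to the target", {
  tpl <- double_h_template()
  sim <- simulate_dataset(tpl, n_samples = 500, corr_a = 0.5, corr_b = 0.5,
                          inter_range = c(0, 0), seed = 3)
  in_a <- tpl$truth == "A"
  rx <- cor(sim$data[, 1:22])
  within <- c(rx[in_a, in_a][upper.tri(diag(11))],
              rx[!in_a, !in_a][upper.tri(diag(11))])
  expect_lt(abs(mean(within) - 0.5), 0.08)

  # large-sample: nearly all entries within 3 Fisher-z standard errors
  big <- simulate_dataset(tpl, n_samples = 10000, corr_a = 0.4, corr_b = 0.7,
                          inter_range = c(0, 0.05), seed = 4)
  se3 <- 3 / sqrt(10000 - 3)
  ok <- 0; tot <- 0
  for (k in 1:2) {
    r <- cor(big$data[, (k - 1) * 22 + 1:22])
    dev <- abs(atanh(pmin(pmax(r, -0.999), 0.999)) - atanh(big$rho))
    ut <- upper.tri(r)
    ok <- ok + sum(dev[ut] <= se3)
    tot <- tot + sum(ut)
  }
  expect_gte(ok / tot, 0.99)
})

test_that("contact rule is one grid unit plus the noise sd", {
  tpl <- double_h_template()
  c1 <- infer_contacts(tpl, noise_sd = 0.1)
  expect_true(isSymmetric(c1))
  expect_false(any(diag(c1)))
  # grid neighbours at distance 1 are contacts; diagonals at sqrt(2) are not
  expect_true(c1["A1", "A2"])
  expect_false(c1["A1", "A7"])  # (0,0) vs (2,1): sqrt(5)
  d <- as.matrix(dist(tpl$coords))
  expect_false(any(c1[abs(d - sqrt(2)) < 1e-9]))
  c5 <- infer_contacts(tpl, noise_sd = 0.5)
  expect_true(all(c5[abs(d - sqrt(2)) < 1e-9]))
  # contacts depend on the template only, never on sample noise
  expect_identical(c1, infer_contacts(double_h_template(), noise_sd = 0.1))
})

test_that("contact graph restricted to one letter is connected", {
  tpl <- double_h_template()
  contacts <- infer_contacts(tpl, 0.1)
  for (lv in c("A", "B")) {
    sub <- contacts[tpl$truth == lv, tpl$truth == lv]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
  }
})
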