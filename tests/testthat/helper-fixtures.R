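# Shared fixtures, all generated in code.

# symmetric weight matrix with i.i.d. uniform weights on every pair
random_complete_graph <- function(p, lo = 0, hi = 1) {
  w <- matrix(0, p, p)
  w[upper.tri(w)] <- stats::runif(p * (p - 1) / 2, lo, hi)
  w + t(w)
}

# two internally-heavy blocks joined (optionally) by weak cross weights
block_weight_matrix <- function(sizes, within, cross = 0) {
  p <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  w <- matrix(cross, p, p)
  for (b in seq_along(sizes)) w[lab == b, lab == b] <- within[b]
  diag(w) <- 0
  w
}

# brute-force Newman-Girvan modularity: literal double sum over ordered pairs
modularity_bruteforce <- function(w, membership) {
  p <- nrow(w)
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (membership[i] == membership[j])
      q <- q + w[i, j] - k[i] * k[j] / two_m
  }
  q / two_m
}

# all set partitions of 1..n (for exhaustive modularity search)
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (sub in all_partitions(n - 1L)) {
    for (b in seq_along(sub)) {
      nxt <- sub
      nxt[[b]] <- c(nxt[[b]], n)
      out[[length(out) + 1L]] <- nxt
    }
    out[[length(out) + 1L]] <- c(sub, list(n))
  }
  out
}

partition_to_labels <- function(partition, n) {
  lab <- integer(n)
  for (b in seq_along(partition)) lab[partition[[b]]] <- b
  lab
}

# pair-confusion oracle: literal enumeration over all unordered pairs
pair_confusion_oracle <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) tp <- tp + 1L
    if (!st && sp) fp <- fp + 1L
    if (st && !sp) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# synthetic stand-in for a polarized two-party senate over the bundled real
# US state adjacency (the genuine roll-call table is not distributed here):
# party-line voting plus a per-motion regional pull, one noise-voting
# maverick, ~2% missing votes
synthetic_senate <- function(n_motions = 400, seed = 3) {
  set.seed(seed)
  adj <- read_adjacency(system.file("extdata", "us_state_adjacency.tsv",
                                    package = "tccn"))
  states <- rownames(adj)
  regions <- list(
    NE = c("ME", "NH", "VT", "MA", "RI", "CT", "NY", "NJ", "PA", "MD", "DE"),
    S  = c("VA", "WV", "KY", "TN", "NC", "SC", "GA", "FL", "AL", "MS", "LA",
           "AR", "TX", "OK"),
    MW = c("OH", "IN", "IL", "MI", "WI", "MN", "IA", "MO", "ND", "SD", "NE",
           "KS"),
    W  = c("MT", "WY", "CO", "NM", "AZ", "UT", "ID", "NV", "WA", "OR", "CA",
           "AK", "HI"))
  reg <- rep(NA_character_, length(states))
  names(reg) <- states
  for (r in names(regions)) reg[regions[[r]]] <- r
  dem <- c("CA", "OR", "WA", "NY", "MA", "RI", "CT", "VT", "NJ", "MD", "DE",
           "IL", "MI", "WI", "MN", "IA", "HI", "WV", "AR", "MT", "ND", "SD")
  party <- ifelse(states %in% dem, -1, 1)
  sen_states <- rep(states, each = 2)
  sen_party <- rep(party, each = 2)
  p <- length(sen_states)
  reg_idx <- match(reg[sen_states], names(regions))
  votes <- matrix(NA_real_, p, n_motions)
  for (m in seq_len(n_motions)) {
    d <- sample(c(-1, 1), 1)
    regional <- stats::rnorm(length(regions))
    util <- 1.6 * sen_party * d + 1.1 * regional[reg_idx] +
      stats::rnorm(p)
    votes[, m] <- ifelse(util > 0, 1, -1)
  }
  maverick <- which(sen_states == "FL")[1]
  votes[maverick, ] <- sample(c(-1, 1), n_motions, replace = TRUE)
  votes[matrix(stats::runif(p * n_motions) < 0.02, p, n_motions)] <- NA
  rownames(votes) <- paste0(sen_states, "_", rep(1:2, length(states)))
  list(votes = votes, states = sen_states, adjacency = adj,
       maverick = maverick)
}
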