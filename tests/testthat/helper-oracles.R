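# Independent oracles used to check the streaming implementations.

# Naive weighted-KS enrichment: materialize the full running sum.
naive_es <- function(scores, hit, weight_p = 1) {
  stopifnot(length(scores) == length(hit))
  n <- length(scores)
  w <- abs(scores)^weight_p * hit
  if (sum(w) == 0) w <- hit / sum(hit) else w <- w / sum(w)
  miss <- (1 - hit) / (n - sum(hit))
  rs <- cumsum(w - miss)
  maxdev <- max(rs, 0)
  mindev <- min(rs, 0)
  if (maxdev >= -mindev - 1e-9) maxdev else mindev
}

# Exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled values to the first group.
perm_wilcox_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(pool)
  m <- length(x)
  ranks <- rank(pool)
  obs <- sum(ranks[seq_len(m)])
  combos <- utils::combn(n, m)
  stats <- apply(combos, 2, function(i) sum(ranks[i]))
  mu <- m * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Step-up Benjamini-Hochberg from its definition: sort, p * m / i, cummin
# from the right, restore order.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Random ranked signature over n genes.
random_signature <- function(n, prefix = "g") {
  s <- rnorm(n)
  names(s) <- sprintf("%s%04d", prefix, seq_len(n))
  rank_genes(s)
}

# Small cohort config used by fast module tests.
small_config <- function(seed, ...) {
  sim_config(n_genes = 300, n_samples = 60, n_tf_targets = 30,
             compendium_size = 20, seed = seed, ...)
}
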