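# Independent brute-force reference implementations used to cross-check the
# package's statistics on small instances. These deliberately follow the
# textbook formulas step by step and share no code with the package.

# Kruskal-Wallis H with tie correction, from first principles.
oracle_kruskal_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n <- length(values)
  r <- rank(values)
  off <- 0
  h <- 0
  for (g in groups) {
    rg <- r[seq_along(g) + off]
    off <- off + length(g)
    h <- h + sum(rg)^2 / length(g)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Wilcoxon signed-rank V: sum of the ranks of |d| over positive d, zeros
# dropped, mid-ranks for ties.
oracle_signed_rank_v <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}

# Holm step-down adjustment by direct application of the rule.
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Kendall's W evaluated symbol by symbol from the defining formula.
oracle_kendall_w <- function(rank_matrix) {
  m <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  Ri <- colSums(rank_matrix)
  S <- sum((Ri - mean(Ri))^2)
  12 * S / (m^2 * (n^3 - n))
}

# Path length by an explicit loop.
oracle_path_length <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  total
}

# Transition counting by scanning every sequence position.
oracle_transition_counts <- function(labels_list, order) {
  states <- c("UFZ", "CFZ", "LFZ")
  ctx <- if (order == 1) states else {
    as.vector(t(outer(states, states, paste, sep = ",")))
  }
  counts <- matrix(0, length(ctx), 3, dimnames = list(ctx, states))
  for (l in labels_list) {
    if (length(l) <= order) next
    for (t in seq.int(order + 1, length(l))) {
      key <- paste(l[(t - order):(t - 1)], collapse = ",")
      counts[key, l[t]] <- counts[key, l[t]] + 1
    }
  }
  counts
}
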