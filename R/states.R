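# Canonical facial zones, ordered top-to-bottom on the face.
aoi_states <- function() c("UFZ", "CFZ", "LFZ")

# Label for a conditioning context: the k most recent zones, oldest first.
context_labels <- function(order, states = aoi_states()) {
  if (order == 1L) return(states)
  grid <- expand.grid(prev1 = states, prev2 = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste(grid$prev2, grid$prev1, sep = ",")
}

# Map (oldest, ..., newest) state indices to a context row index.
# Contexts are enumerated with the most recent state varying fastest is NOT
# what context_labels() does, so keep the two in lockstep: row index =
# (idx_oldest - 1) * 3 + idx_newest for order 2.
context_index <- function(idx_mat) {
  if (ncol(idx_mat) == 1L) return(idx_mat[, 1L])
  (idx_mat[, 1L] - 1L) * 3L + idx_mat[, 2L]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Stationary distribution of a row-stochastic matrix (left eigenvector of the
# dominant eigenvalue, normalized to sum to 1).
stationary_distribution <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1", call. = FALSE)
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("no valid stationary distribution found", call. = FALSE)
  v <- pmax(v, 0)
  stats::setNames(v / sum(v), rownames(P))
}
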