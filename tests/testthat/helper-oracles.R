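# Independent naive oracles: direct double-loop evaluation of the influence
# measures from their defining sums, written without any package internals.

oracle_counts <- function(x, y, subset) {
  keys <- apply(x[, subset, drop = FALSE], 1, paste, collapse = "-")
  cells <- unique(keys)
  nj <- integer(length(cells))
  n1 <- integer(length(cells))
  for (ci in seq_along(cells)) {
    for (i in seq_len(nrow(x))) {
      if (keys[i] == cells[ci]) {
        nj[ci] <- nj[ci] + 1L
        if (y[i] == 1L) n1[ci] <- n1[ci] + 1L
      }
    }
  }
  list(nj = nj, n1 = n1)
}

oracle_i_score <- function(x, y, subset) {
  cc <- oracle_counts(x, y, subset)
  pi1 <- mean(y)
  tot <- 0
  for (j in seq_along(cc$nj))
    tot <- tot + (cc$n1[j] - cc$nj[j] * pi1)^2
  tot
}

# base-2 logs on purpose: also exercises the base invariance of the ratio
oracle_mgr <- function(x, y, subset) {
  cc <- oracle_counts(x, y, subset)
  n <- nrow(x)
  pi1 <- mean(y)
  l2 <- function(v) if (v > 0) log2(v) else 0
  info_y <- -(pi1 * l2(pi1) + (1 - pi1) * l2(1 - pi1))
  info_cond <- 0
  split_info <- 0
  for (j in seq_along(cc$nj)) {
    nj <- cc$nj[j]
    n1 <- cc$n1[j]
    info_cond <- info_cond -
      (n1 / n) * l2(n1 / nj) - ((nj - n1) / n) * l2((nj - n1) / nj)
    split_info <- split_info - (nj / n) * l2(nj / n)
  }
  if (split_info <= 0) return(0)
  max(info_y - info_cond, 0) / split_info
}

# exhaustive best-subset score of an initial set (oracle for backward_drop)
oracle_best_subset <- function(dm, initial, measure) {
  best <- -Inf
  k <- length(initial)
  for (s in seq_len(k)) {
    combs <- utils::combn(initial, s)
    for (c in seq_len(ncol(combs))) {
      pt <- build_partition(dm, combs[, c])
      v <- if (measure == "mgr") mgr(pt) else i_score(pt)
      if (v > best) best <- v
    }
  }
  best
}

# the heavy null-bias experiment is shared across test files
.bias_cache <- new.env(parent = emptyenv())
cached_bias_experiment <- function() {
  if (is.null(.bias_cache$ex))
    .bias_cache$ex <- experiment_bias_vs_order(n = 10000, sizes = 1:9,
                                               reps = 2000, seed = 11)
  .bias_cache$ex
}

# module-2 replicate distribution (criterion-scale, shared)
.rep_cache <- new.env(parent = emptyenv())
cached_module2_replicates <- function(reps = 1000) {
  if (is.null(.rep_cache$df)) {
    gr1 <- numeric(reps)
    m23 <- numeric(reps)
    top1 <- logical(reps)
    for (r in seq_len(reps)) {
      dm <- gen_module2(n = 200, p = 10, seed = 5000 + r)
      rk <- gr_ranking(dm)
      top1[r] <- rk$index[1] == 1L
      gr1[r] <- rk$gr[match(1L, rk$index)]
      m23[r] <- mgr(dm, subset = c(2, 3))
    }
    .rep_cache$df <- data.frame(gr1 = gr1, m23 = m23, top1 = top1)
  }
  .rep_cache$df
}

random_binary_dm <- function(n, p, seed) {
  set.seed(seed)
  discrete_matrix(matrix(sample(0:1, n * p, replace = TRUE), n, p),
                  sample(0:1, n, replace = TRUE))
}
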