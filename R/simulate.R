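#' Simulated two-pathway interaction model
#'
#' Generates the benchmark dataset used throughout the package's examples and
#' tests: \eqn{n} samples of \eqn{p} iid uniform binary predictors, with the
#' outcome following the first variable with probability \code{mix_prob} and
#' the XOR (sum mod 2) of variables 2 and 3 otherwise,
#' \deqn{Y = X_1 \bmod 2 \textrm{ w.p. } q, \qquad
#'       Y = (X_2 + X_3) \bmod 2 \textrm{ w.p. } 1 - q.}
#' At the default \code{mix_prob = 0.5} the marginal Gain Ratio of \eqn{X_1}
#' has expectation \eqn{1 - H(3/4) \approx 0.1887} and the pair
#' \eqn{\{X_2, X_3\}} carries the same information jointly
#' (\eqn{MGR \approx 0.0944}) while each of \eqn{X_2, X_3} is marginally
#' uninformative — the canonical case a single-variable ranking misses.
#'
#' @param n sample count (default 200).
#' @param p number of predictors, \eqn{\ge 3} (default 10).
#' @param mix_prob probability that the outcome follows \eqn{X_1}.
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return a \code{\link{discrete_matrix}}.
#' @examples
#' dm <- gen_module2(seed = 7)
#' gr_ranking(dm)[1:3, ]
#' @export
gen_module2 <- function(n = 200, p = 10, mix_prob = 0.5, seed = NULL) {
  stopifnot(n >= 1, p >= 3, mix_prob >= 0, mix_prob <= 1)
  local_seed(seed, {
    x <- matrix(sample(0:1, n * p, replace = TRUE), n, p)
    use_x1 <- stats::runif(n) < mix_prob
    y <- ifelse(use_x1, x[, 1] %% 2L, (x[, 2] + x[, 3]) %% 2L)
    discrete_matrix(x, y)
  })
}

#' Null model: independent uniform binary data
#'
#' Predictors and outcome all iid uniform on \{0, 1\}; no subset carries real
#' information, so any non-zero influence measure is pure estimation bias.
#' Used to characterize how the measures inflate with subset size.
#'
#' @param n,p dimensions.
#' @param seed optional integer seed.
#' @return a \code{\link{discrete_matrix}}.
#' @export
gen_null <- function(n, p, seed = NULL) {
  stopifnot(n >= 1, p >= 1)
  local_seed(seed, {
    x <- matrix(sample(0:1, n * p, replace = TRUE), n, p)
    y <- sample(0:1, n, replace = TRUE)
    discrete_matrix(x, y)
  })
}

#' Null-bias of the influence measures versus subset size
#'
#' For each subset size, repeatedly generates fresh independent binary data
#' and scores a size-\code{k} subset with both measures. Under the null both
#' measures grow with subset size — the I-score concavely (log-like, fast
#' early growth that flattens) and MGR convexly (exponential-like, slow early
#' growth that accelerates) — which is why MGR is preferred when the true
#' interaction involves few variables.
#'
#' @param n samples per replicate (default 10000).
#' @param sizes subset sizes to profile.
#' @param reps replicates per size (default 2000; a desk-scale default — the
#'   shape of the curves is stable well below the tens of thousands of
#'   replicates one would use for publication-quality quantiles).
#' @param seed optional integer seed.
#' @return list with \code{draws} (long data frame: size, rep, i_score, mgr)
#'   and \code{summary} (per-size quartiles of both measures).
#' @export
experiment_bias_vs_order <- function(n = 10000, sizes = 1:9, reps = 2000,
                                     seed = NULL) {
  stopifnot(reps >= 1, all(sizes >= 1))
  local_seed(seed, {
    rows <- vector("list", length(sizes))
    for (si in seq_along(sizes)) {
      k <- sizes[si]
      iv <- numeric(reps)
      mv <- numeric(reps)
      for (r in seq_len(reps)) {
        x <- matrix(sample(0:1, n * k, replace = TRUE), n, k)
        y <- sample(0:1, n, replace = TRUE)
        key <- if (k == 1L) x[, 1] else as.vector(x %*% 2^(seq_len(k) - 1))
        cc <- .cell_counts(key, y)
        pi1 <- mean(y)
        iv[r] <- .i_score_counts(cc$nj, cc$n1, pi1)
        mv[r] <- .mgr_counts(cc$nj, cc$n1, n, pi1)
      }
      rows[[si]] <- data.frame(size = k, rep = seq_len(reps),
                               i_score = iv, mgr = mv)
    }
    draws <- do.call(rbind, rows)
    qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    summ <- do.call(rbind, lapply(split(draws, draws$size), function(d) {
      data.frame(size = d$size[1],
                 i_q1 = qs(d$i_score)[1], i_median = qs(d$i_score)[2],
                 i_q3 = qs(d$i_score)[3],
                 mgr_q1 = qs(d$mgr)[1], mgr_median = qs(d$mgr)[2],
                 mgr_q3 = qs(d$mgr)[3])
    }))
    rownames(summ) <- NULL
    list(draws = draws, summary = summ)
  })
}

#' Co-growth of the I-score and MGR on random subsets
#'
#' Samples random variable subsets of each requested size from \code{dm} and
#' records the two influence measures as paired values, to check that they
#' agree on what counts as an informative subset (positive rank correlation)
#' even though their scales and size-biases differ.
#'
#' @param dm a \code{\link{discrete_matrix}} with at least \code{max(sizes)}
#'   variables.
#' @param sizes subset sizes to sample.
#' @param draws subsets drawn per size.
#' @param seed optional integer seed.
#' @return data frame with columns \code{size}, \code{draw}, \code{i_score},
#'   \code{mgr}.
#' @export
experiment_correlation <- function(dm, sizes = 1:9, draws = 500, seed = NULL) {
  dm <- as_discrete_matrix(dm)
  stopifnot(draws >= 1, max(sizes) <= dm$p)
  local_seed(seed, {
    out <- vector("list", length(sizes))
    for (si in seq_along(sizes)) {
      k <- sizes[si]
      iv <- numeric(draws)
      mv <- numeric(draws)
      for (d in seq_len(draws)) {
        s <- sort(sample.int(dm$p, k))
        cc <- .cell_counts(.subset_keys(dm$x, s), dm$y)
        iv[d] <- .i_score_counts(cc$nj, cc$n1, dm$pi1)
        mv[d] <- .mgr_counts(cc$nj, cc$n1, dm$n, dm$pi1)
      }
      out[[si]] <- data.frame(size = k, draw = seq_len(draws),
                              i_score = iv, mgr = mv)
    }
    do.call(rbind, out)
  })
}
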