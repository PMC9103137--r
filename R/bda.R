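#' @title Backward Dropping Algorithm and return-set filtering
#' @description The interaction search: random initial subsets of size
#' \eqn{k} are each reduced greedily — repeatedly dropping the variable
#' whose removal maximizes the influence measure — and the best intermediate
#' subset (the \emph{return set}) is kept. Sizing calculators give the
#' admissible initial size from the sample count and the number of
#' repetitions needed to cover all order-\eqn{z} interactions; overlap
#' filtering and forward adding then reduce the pool of return sets to a
#' disjoint list of final interactions.
#' @name bda
NULL

#' Admissible initial subset size
#'
#' Two sizing rules for the initial subset of the backward-dropping search
#' on \eqn{n} samples of variables with \code{categories} codes each:
#' \itemize{
#'   \item Poisson-approximation rule: the largest \eqn{k} with
#'     \eqn{n^2 / (2 m_{k-1}) \ge 1}, where \eqn{m_{k-1}} is the number of
#'     partition cells induced by \eqn{k - 1} variables;
#'   \item adequacy rule: the largest \eqn{k} keeping at least 4
#'     observations per partition cell on average (\eqn{n / m_k \ge 4}).
#' }
#' Both bounds are reported; any initial size between them is admissible in
#' practice.
#'
#' @param n training sample count.
#' @param categories codes per variable (2 after binary discretization).
#' @return list with \code{poisson_bound}, \code{adequacy_bound} and
#'   \code{recommended} (the sorted pair).
#' @examples
#' initial_size_bounds(72)  # 12 and 4
#' @export
initial_size_bounds <- function(n, categories = 2) {
  stopifnot(n >= 1, categories >= 2)
  # n^2 / (2 c^(k-1)) >= 1  <=>  k <= log_c(n^2/2) + 1
  pois <- if (n^2 / 2 < 1) 0L
          else as.integer(floor(log(n^2 / 2) / log(categories)) + 1)
  adeq <- if (n / 4 < 1) 0L
          else as.integer(floor(log(n / 4) / log(categories)))
  if (pois == 0L || adeq == 0L)
    warning("sample size too small for a meaningful initial subset")
  list(poisson_bound = pois, adequacy_bound = adeq,
       recommended = sort(c(adeq, pois)))
}

#' Number of backward-dropping repetitions
#'
#' Coupon-collector style estimate of how many random size-\eqn{k} initial
#' subsets are needed so that every interaction of \eqn{z} variables among
#' \eqn{p} appears in at least one draw:
#' \deqn{\hat B = \lceil [C(p,z)/C(k,z)] \log C(p,z) \rceil,}
#' with \eqn{2\hat B} a practical upper bound covering all key variables.
#'
#' @param p number of candidate variables.
#' @param k initial subset size.
#' @param z interaction order to cover (\eqn{z \le k \le p}).
#' @return list with \code{B_hat} and \code{upper_bound} (\eqn{= 2\hat B}).
#' @examples
#' bda_repetitions(p = 30, k = 6, z = 4)  # B_hat = 18670
#' @export
bda_repetitions <- function(p, k, z) {
  if (!(z >= 1 && z <= k && k <= p))
    stop("need 1 <= z <= k <= p (got z=", z, ", k=", k, ", p=", p, ")")
  npz <- choose(p, z)
  b_hat <- max(1, ceiling(npz / choose(k, z) * log(npz)))
  list(B_hat = b_hat, upper_bound = 2 * b_hat)
}

#' One backward-dropping pass
#'
#' Starting from \code{initial_subset}, repeatedly drops the variable whose
#' removal gives the highest influence measure, recording each retained
#' pending combination (sizes \eqn{k} down to 1, the initial subset
#' included), and returns the pending combination with the maximum measure.
#' Ties in the drop choice are broken by dropping the smallest variable
#' index; ties across pending combinations go to the smaller subset, then
#' lexicographically.
#'
#' @param dm a \code{\link{discrete_matrix}}.
#' @param initial_subset integer vector of distinct variable indices.
#' @param measure \code{"mgr"} or \code{"i_score"}.
#' @return list of class \code{"return_set"}: \code{variables} (sorted
#'   indices), \code{score}, and \code{path} (data frame of pending subset
#'   sizes and scores).
#' @export
backward_drop <- function(dm, initial_subset, measure = c("mgr", "i_score")) {
  dm <- as_discrete_matrix(dm)
  measure <- match.arg(measure)
  current <- .check_subset(dm, initial_subset)
  pending <- list(current)
  pending_scores <- .score_subset(dm, current, measure)
  while (length(current) > 1L) {
    drop_scores <- vapply(seq_along(current), function(i) {
      .score_subset(dm, current[-i], measure)
    }, numeric(1))
    best <- which(drop_scores == max(drop_scores))[1L]  # ties: current is
    # sorted ascending, so the first argmax drops the smallest index
    current <- current[-best]
    pending[[length(pending) + 1L]] <- current
    pending_scores <- c(pending_scores, max(drop_scores))
  }
  sizes <- lengths(pending)
  o <- order(-pending_scores, sizes, lex_order(pending))
  best <- o[1L]
  structure(list(variables = pending[[best]],
                 score = pending_scores[best],
                 path = data.frame(size = sizes, score = pending_scores)),
            class = "return_set")
}

#' @export
print.return_set <- function(x, ...) {
  cat("Return set {", paste(x$variables, collapse = ", "), "}  score = ",
      format(x$score, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Run the full backward-dropping search
#'
#' Draws \code{B} initial subsets of size \code{k} uniformly (without
#' replacement within a draw, independently across draws), runs
#' \code{\link{backward_drop}} on each, and collapses duplicate return sets
#' (same variable set), keeping the highest score.
#'
#' @param dm a \code{\link{discrete_matrix}} with \eqn{p \ge k}.
#' @param k initial subset size.
#' @param B number of repetitions (see \code{\link{bda_repetitions}}).
#' @param measure \code{"mgr"} or \code{"i_score"}.
#' @param seed optional integer seed; results are reproducible given it.
#' @return list of unique \code{"return_set"} objects sorted by decreasing
#'   score (ties: smaller subset, then lexicographic).
#' @examples
#' dm <- gen_module2(seed = 11)
#' rs <- run_bda(dm, k = 4, B = 50, seed = 11)
#' rs[[1]]
#' @export
run_bda <- function(dm, k, B, measure = c("mgr", "i_score"), seed = NULL) {
  dm <- as_discrete_matrix(dm)
  measure <- match.arg(measure)
  stopifnot(B >= 1, k >= 1)
  if (dm$p < k) stop("initial size k = ", k, " exceeds p = ", dm$p)
  local_seed(seed, {
    out <- new.env(parent = emptyenv())
    for (b in seq_len(B)) {
      init <- sort(sample.int(dm$p, k))
      rs <- backward_drop(dm, init, measure)
      keyname <- paste(rs$variables, collapse = ",")
      prev <- out[[keyname]]
      if (is.null(prev) || rs$score > prev$score) {
        rs$origin <- b
        out[[keyname]] <- rs
      }
    }
    sets <- as.list(out)
    scores <- vapply(sets, `[[`, numeric(1), "score")
    sizes <- vapply(sets, function(s) length(s$variables), integer(1))
    o <- order(-scores, sizes,
               lex_order(lapply(sets, `[[`, "variables")))
    unname(sets[o])
  })
}

#' Remove overlapping return sets
#'
#' Sorts return sets by decreasing score and greedily keeps a set only when
#' it shares no variable with any already-kept set, so the final
#' interactions are disjoint. Score ties are broken toward the
#' lexicographically smaller variable set.
#'
#' @param return_sets list of \code{"return_set"} objects.
#' @return the filtered list, in kept order.
#' @export
filter_overlaps <- function(return_sets) {
  if (length(return_sets) == 0L) return(return_sets)
  scores <- vapply(return_sets, `[[`, numeric(1), "score")
  o <- order(-scores, lex_order(lapply(return_sets, `[[`, "variables")))
  kept <- list()
  used <- integer(0)
  for (i in o) {
    v <- return_sets[[i]]$variables
    if (!any(v %in% used)) {
      kept[[length(kept) + 1L]] <- return_sets[[i]]
      used <- c(used, v)
    }
  }
  kept
}

#' Forward adding: rebuild return sets to remove false positives
#'
#' Each return set is rebuilt variable by variable. Members are ordered by
#' decreasing marginal contribution — the drop in the measure when the
#' variable is left out of the full set — and re-admitted one at a time in
#' that order, each staying only if adding it increases the measure by more
#' than \code{tol}. Variables dragged along by the greedy backward pass but
#' carrying no signal are dropped here; the top-contributing variable seeds
#' the rebuild and is always kept, so no set can become empty.
#'
#' @param dm a \code{\link{discrete_matrix}}.
#' @param return_sets list of (overlap-filtered) \code{"return_set"}s.
#' @param measure \code{"mgr"} or \code{"i_score"}.
#' @param tol strict-increase tolerance (default 1e-9).
#' @return list of \code{"return_set"} objects with rebuilt variable sets
#'   and recomputed scores.
#' @export
forward_add <- function(dm, return_sets, measure = c("mgr", "i_score"),
                        tol = 1e-9) {
  dm <- as_discrete_matrix(dm)
  measure <- match.arg(measure)
  lapply(return_sets, function(rs) {
    v <- rs$variables
    if (length(v) == 1L) {
      rs$score <- .score_subset(dm, v, measure)
      return(rs)
    }
    full <- .score_subset(dm, v, measure)
    contrib <- vapply(seq_along(v), function(i) {
      full - .score_subset(dm, v[-i], measure)
    }, numeric(1))
    ord <- v[order(-contrib, v)]
    current <- ord[1L]
    cur_score <- .score_subset(dm, current, measure)
    for (j in ord[-1L]) {
      trial <- .score_subset(dm, sort(c(current, j)), measure)
      if (trial > cur_score + tol) {
        current <- sort(c(current, j))
        cur_score <- trial
      }
    }
    rs$variables <- current
    rs$score <- cur_score
    rs
  })
}
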