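#' @title Influence measures for variable subsets
#' @description
#' A subset \eqn{S_b} of \eqn{k} discrete predictor variables partitions the
#' samples into cells, one per observed combination of category codes. Two
#' scalar influence measures score how strongly that partition separates the
#' two outcome classes:
#' \itemize{
#'   \item the \emph{I-score}
#'     \eqn{I(S_b) = \sum_j [n_1(j) - n_j \pi_1]^2}, the squared deviation of
#'     per-cell case counts from their expectation under no association;
#'   \item the \emph{Multivariate Gain Ratio}
#'     \eqn{MGR(S_b) = [Info(Y) - Info_{S_b}(Y)] / SplitInfo(S_b)}, the
#'     information gained about \eqn{Y} by the partition, normalized by the
#'     partition's self-information to correct the bias toward subsets that
#'     induce many cells. For a single variable this is the classical Gain
#'     Ratio.
#' }
#' @name influence-measures
NULL

# ---- internal fast path -----------------------------------------------------

# integer cell keys for the samples on a column subset (mixed-radix encoding;
# falls back to string keys if the radix product would lose integer precision)
.subset_keys <- function(x, cols) {
  if (length(cols) == 1L) return(x[, cols])
  radix <- apply(x[, cols, drop = FALSE], 2, max) + 1
  if (prod(as.numeric(radix)) < 2^52) {
    key <- numeric(nrow(x))
    mult <- 1
    for (j in seq_along(cols)) {
      key <- key + as.numeric(x[, cols[j]]) * mult
      mult <- mult * radix[j]
    }
    key
  } else {
    do.call(paste, c(as.data.frame(x[, cols, drop = FALSE]), sep = "\r"))
  }
}

# occupied-cell totals and case counts for a key vector
.cell_counts <- function(key, y) {
  idx <- match(key, unique(key))
  nj <- tabulate(idx)
  n1 <- tabulate(idx[y == 1L], nbins = length(nj))
  list(nj = nj, n1 = n1)
}

.i_score_counts <- function(nj, n1, pi1) sum((n1 - nj * pi1)^2)

.entropy_counts <- function(nj, n1, n, pi1, base = exp(1)) {
  lb <- log(base)
  info_y <- -(xlogx(pi1) + xlogx(1 - pi1)) / lb
  q <- n1 / nj
  info_cond <- -sum((nj / n) * (xlogx(q) + xlogx(1 - q))) / lb
  split_info <- -sum(xlogx(nj / n)) / lb
  c(info_y = info_y, info_cond = info_cond, split_info = split_info)
}

.mgr_counts <- function(nj, n1, n, pi1) {
  e <- .entropy_counts(nj, n1, n, pi1)
  if (e[["split_info"]] <= 0) return(0)
  max(e[["info_y"]] - e[["info_cond"]], 0) / e[["split_info"]]
}

# score a column subset directly (hot loop for BDA / triple screening)
.score_subset <- function(dm, cols, measure = c("mgr", "i_score")) {
  measure <- match.arg(measure)
  cc <- .cell_counts(.subset_keys(dm$x, cols), dm$y)
  if (measure == "mgr") .mgr_counts(cc$nj, cc$n1, dm$n, dm$pi1)
  else .i_score_counts(cc$nj, cc$n1, dm$pi1)
}

.check_subset <- function(dm, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must contain at least one variable")
  if (anyDuplicated(subset)) stop("subset indices must be distinct")
  if (any(subset < 1L) || any(subset > dm$p))
    stop("subset index out of range [1, ", dm$p, "]")
  sort(subset)
}

# ---- partition table --------------------------------------------------------

#' Partition induced by a variable subset
#'
#' Groups the samples by their tuple of category codes on \code{subset} and
#' tallies, for each occupied cell \eqn{j}, the cell total \eqn{n_j} and the
#' number of class-1 samples \eqn{n_1(j)}. Only occupied cells are stored.
#'
#' @param dm a \code{\link{discrete_matrix}}.
#' @param subset integer vector of distinct variable indices (1-based).
#' @return An object of class \code{"partition_table"}: list with
#'   \code{cells} (matrix of cell code tuples, one row per occupied cell),
#'   \code{nj}, \code{n1} (integer vectors aligned with the cell rows),
#'   \code{n}, \code{pi1} and \code{subset}.
#' @examples
#' dm <- discrete_matrix(matrix(c(0, 0, 1, 1), 4, 1), c(1, 0, 1, 1))
#' build_partition(dm, 1)
#' @export
build_partition <- function(dm, subset) {
  dm <- as_discrete_matrix(dm)
  subset <- .check_subset(dm, subset)
  key <- .subset_keys(dm$x, subset)
  uk <- unique(key)
  idx <- match(key, uk)
  nj <- tabulate(idx)
  n1 <- tabulate(idx[dm$y == 1L], nbins = length(uk))
  first <- match(seq_along(uk), idx)
  cells <- dm$x[first, subset, drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, nj = nj, n1 = n1, n = dm$n, pi1 = dm$pi1,
                 subset = subset),
            class = "partition_table")
}

#' @export
print.partition_table <- function(x, ...) {
  cat("Partition on variables {", paste(x$subset, collapse = ", "), "}: ",
      length(x$nj), " occupied cells, n = ", x$n, "\n", sep = "")
  df <- cbind(as.data.frame(x$cells), n_j = x$nj, n1_j = x$n1)
  print(utils::head(df, 16L), row.names = FALSE)
  if (nrow(df) > 16L) cat("... (", nrow(df) - 16L, " more cells)\n", sep = "")
  invisible(x)
}

# ---- measures ---------------------------------------------------------------

#' @rdname influence-measures
#' @param x a \code{"partition_table"} or a \code{\link{discrete_matrix}}.
#' @param subset when \code{x} is a discrete matrix, the variable subset to
#'   score (built into a partition internally).
#' @param ... passed between methods.
#' @return \code{i_score} and \code{mgr} return a single non-negative number.
#'   A partition with a single occupied cell (zero split information) has
#'   \code{mgr = 0} by convention, as does single-class data
#'   (\eqn{\pi_1 \in \{0, 1\}}).
#' @examples
#' dm <- gen_module2(n = 200, seed = 1)
#' mgr(dm, subset = c(2, 3))
#' i_score(dm, subset = c(2, 3))
#' @export
i_score <- function(x, ...) UseMethod("i_score")

#' @rdname influence-measures
#' @export
i_score.partition_table <- function(x, ...) {
  .i_score_counts(x$nj, x$n1, x$pi1)
}

#' @rdname influence-measures
#' @export
i_score.discrete_matrix <- function(x, subset, ...) {
  i_score(build_partition(x, subset))
}

#' @rdname influence-measures
#' @export
mgr <- function(x, ...) UseMethod("mgr")

#' @rdname influence-measures
#' @export
mgr.partition_table <- function(x, ...) {
  .mgr_counts(x$nj, x$n1, x$n, x$pi1)
}

#' @rdname influence-measures
#' @export
mgr.discrete_matrix <- function(x, subset, ...) {
  mgr(build_partition(x, subset))
}

#' Entropy components of the multivariate gain ratio
#'
#' Returns the three sums entering the MGR: the outcome entropy
#' \eqn{Info(Y)}, the conditional outcome entropy given the partition
#' \eqn{Info_{S_b}(Y)}, and the partition self-information
#' \eqn{SplitInfo(S_b)}. Terms with a zero count contribute zero
#' (\eqn{0 \log 0 := 0}).
#'
#' @param partition a \code{"partition_table"}.
#' @param base logarithm base; natural log by default. MGR itself is
#'   base-invariant.
#' @return named numeric vector \code{(info_y, info_cond, split_info)}, all
#'   non-negative.
#' @export
entropy_terms <- function(partition, base = exp(1)) {
  stopifnot(inherits(partition, "partition_table"))
  .entropy_counts(partition$nj, partition$n1, partition$n, partition$pi1,
                  base = base)
}

#' Gain-ratio ranking of single variables
#'
#' Computes the Gain Ratio of every variable (the single-variable case of
#' \code{\link{mgr}}) and ranks them from most to least informative. Ties are
#' broken by ascending variable index.
#'
#' @param dm a \code{\link{discrete_matrix}}.
#' @return data frame with columns \code{variable}, \code{index}, \code{gr},
#'   sorted by decreasing \code{gr}.
#' @examples
#' gr_ranking(gen_module2(n = 200, seed = 1))
#' @export
gr_ranking <- function(dm) {
  dm <- as_discrete_matrix(dm)
  gr <- vapply(seq_len(dm$p), function(j) .score_subset(dm, j, "mgr"),
               numeric(1))
  o <- order(-gr, seq_len(dm$p))
  data.frame(variable = dm$variable_names[o], index = o, gr = gr[o],
             row.names = NULL, stringsAsFactors = FALSE)
}
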