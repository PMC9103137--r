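#' @title Triple screening: dimension reduction by 3-way interactions
#' @description When thousands of variables survive preprocessing, the
#' subset search is preceded by a screen built on 3-way interactions: every
#' triple is scored with the chosen influence measure, an elbow in the
#' decay of (strided) triple scores fixes how many top triples to keep, and
#' an elbow in the decay of per-variable retention frequencies within those
#' triples fixes which variables go forward.
#' @name triple-screening
NULL

#' Score every variable triple
#'
#' Computes the influence measure of all \eqn{C(p,3)} triples and sorts them
#' from high to low; ties are broken lexicographically by variable indices.
#'
#' @param dm a \code{\link{discrete_matrix}} with \eqn{p \ge 3}.
#' @param measure \code{"mgr"} or \code{"i_score"}.
#' @param max_triples guard against runaway inputs: error if \eqn{C(p,3)}
#'   exceeds it (default 5e7).
#' @param progress_every log a progress message every this many triples
#'   (0 = silent).
#' @return data frame with columns \code{v1}, \code{v2}, \code{v3},
#'   \code{score}, sorted by decreasing score.
#' @export
score_all_triples <- function(dm, measure = c("mgr", "i_score"),
                              max_triples = 5e7, progress_every = 0) {
  dm <- as_discrete_matrix(dm)
  measure <- match.arg(measure)
  if (dm$p < 3L) stop("triple screening needs p >= 3")
  if (choose(dm$p, 3) > max_triples)
    stop("C(p,3) = ", choose(dm$p, 3), " exceeds max_triples")
  trip <- utils::combn(dm$p, 3L)
  nt <- ncol(trip)
  score <- numeric(nt)
  for (t in seq_len(nt)) {
    score[t] <- .score_subset(dm, trip[, t], measure)
    if (progress_every > 0 && t %% progress_every == 0L)
      message("scored ", t, " / ", nt, " triples")
  }
  o <- order(-score, trip[1L, ], trip[2L, ], trip[3L, ])
  data.frame(v1 = trip[1L, o], v2 = trip[2L, o], v3 = trip[3L, o],
             score = score[o])
}

#' Retain top triples by the second-difference elbow
#'
#' Takes every \code{stride}-th score from the sorted triple list, computes
#' second differences of that subsequence, and cuts where the second
#' difference first comes near zero (within \code{epsilon_frac} of its
#' maximum magnitude) — the point where the score decay has stabilized. When
#' fewer than \code{3 * stride} triples exist the stride shrinks
#' automatically to a tenth of the triple count.
#'
#' @param scores data frame from \code{\link{score_all_triples}}.
#' @param stride spacing of the probed score sequence (default 1000).
#' @param epsilon_frac "near zero" tolerance as a fraction of the maximum
#'   absolute second difference (default 0.01).
#' @return list with \code{triple_cutoff} (number of retained triples),
#'   \code{retained} (data frame of retained triples),
#'   \code{thousandth_scores}, \code{second_diffs}, \code{stride}.
#' @export
select_top_triples <- function(scores, stride = 1000, epsilon_frac = 0.01) {
  nt <- nrow(scores)
  stopifnot(nt >= 1L)
  if (nt < 3L * stride) {
    stride <- max(1L, nt %/% 10L)
    message("fewer than 3 strided points; stride shrunk to ", stride)
  }
  probe_ranks <- seq(stride, nt, by = stride)
  t_seq <- scores$score[probe_ranks]
  if (length(t_seq) < 3L) {
    warning("fewer than 3 strided scores; keeping all triples")
    return(list(triple_cutoff = nt, retained = scores,
                thousandth_scores = t_seq, second_diffs = numeric(0),
                stride = stride))
  }
  d2 <- diff(t_seq, differences = 2L)
  thr <- epsilon_frac * max(abs(d2))
  hit <- which(abs(d2) <= thr)
  i <- if (length(hit)) hit[1L] else length(d2)
  cutoff <- min(i * stride, nt)
  list(triple_cutoff = cutoff,
       retained = scores[seq_len(cutoff), , drop = FALSE],
       thousandth_scores = t_seq, second_diffs = d2, stride = stride)
}

#' Retain top variables by the retention-frequency elbow
#'
#' Counts how often each variable occurs among the retained triples, sorts
#' frequencies from high to low, and cuts where the first differences have
#' stabilized near zero for good: index \eqn{i} qualifies when every
#' remaining drop \eqn{|\Delta f_j|, j \ge i} is at most the larger of
#' \code{epsilon_frac} times the maximum drop and the median remaining drop
#' (the "sustained" requirement — a flat stretch ahead of a still-pending
#' cliff does not trigger the cut). When all frequencies are equal there is
#' no elbow and every variable is kept with a warning.
#'
#' @param retained data frame of retained triples (columns v1, v2, v3).
#' @param epsilon_frac tolerance fraction (default 0.01).
#' @return list with \code{variable_cutoff}, \code{retained_variables}
#'   (integer indices), \code{retention_freq} (named, sorted non-increasing),
#'   \code{first_diffs}.
#' @export
select_top_variables <- function(retained, epsilon_frac = 0.01) {
  stopifnot(nrow(retained) >= 1L)
  occ <- c(retained$v1, retained$v2, retained$v3)
  tab <- table(occ)
  vars <- as.integer(names(tab))
  freq <- as.integer(tab)
  o <- order(-freq, vars)
  vars <- vars[o]
  freq <- freq[o]
  names(freq) <- vars
  if (length(freq) <= 1L)
    return(list(variable_cutoff = length(vars), retained_variables = vars,
                retention_freq = freq, first_diffs = numeric(0)))
  d1 <- diff(freq)
  if (max(abs(d1)) == 0) {
    warning("all retention frequencies equal; no elbow, keeping all variables")
    return(list(variable_cutoff = length(vars), retained_variables = vars,
                retention_freq = freq, first_diffs = d1))
  }
  thr <- epsilon_frac * max(abs(d1))
  cutoff <- length(vars)
  for (i in seq_along(d1)) {
    tail_abs <- abs(d1[i:length(d1)])
    if (max(tail_abs) <= max(thr, stats::median(tail_abs))) {
      cutoff <- i
      break
    }
  }
  list(variable_cutoff = cutoff,
       retained_variables = sort(vars[seq_len(cutoff)]),
       retention_freq = freq, first_diffs = d1)
}

#' Full triple-screening stage
#'
#' Runs \code{\link{score_all_triples}}, \code{\link{select_top_triples}}
#' and \code{\link{select_top_variables}} and collects every intermediate
#' quantity into one report.
#'
#' @inheritParams score_all_triples
#' @inheritParams select_top_triples
#' @return object of class \code{"screen_report"}.
#' @examples
#' dm <- gen_module2(n = 300, p = 8, seed = 3)
#' screen_triples(dm)$retained_variables
#' @export
screen_triples <- function(dm, measure = c("mgr", "i_score"), stride = 1000,
                           epsilon_frac = 0.01, max_triples = 5e7) {
  measure <- match.arg(measure)
  scores <- score_all_triples(dm, measure, max_triples = max_triples)
  top_t <- select_top_triples(scores, stride = stride,
                              epsilon_frac = epsilon_frac)
  top_v <- select_top_variables(top_t$retained, epsilon_frac = epsilon_frac)
  structure(list(measure = measure,
                 triple_scores = scores,
                 thousandth_scores = top_t$thousandth_scores,
                 second_diffs = top_t$second_diffs,
                 stride = top_t$stride,
                 triple_cutoff = top_t$triple_cutoff,
                 retention_freq = top_v$retention_freq,
                 first_diffs = top_v$first_diffs,
                 variable_cutoff = top_v$variable_cutoff,
                 retained_variables = top_v$retained_variables),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Triple screen (", x$measure, "): ", nrow(x$triple_scores),
      " triples scored\n", sep = "")
  cat("Retained triples: ", x$triple_cutoff, " (stride ", x$stride, ")\n",
      sep = "")
  cat("Retained variables (", x$variable_cutoff, "): ",
      paste(x$retained_variables, collapse = ", "), "\n", sep = "")
  invisible(x)
}
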