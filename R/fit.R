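#' Fit an interaction-selection classifier
#'
#' The package's central fitting function. Given a discretized design matrix
#' and binary outcome it (i) optionally screens variables through 3-way
#' interaction scores when \eqn{p} is large, (ii) searches for influential
#' variable subsets with the backward-dropping algorithm under the chosen
#' influence measure, (iii) reduces the return sets to disjoint interactions
#' by overlap filtering and forward adding, and (iv) builds one ridge
#' sub-classifier per interaction (with all product terms) and combines them
#' by boosting.
#'
#' @param x a \code{\link{discrete_matrix}}, or an integer-coded matrix /
#'   data frame (then \code{y} is required). A formula method is also
#'   provided: \code{mgr_fit(status ~ ., data = df)}.
#' @param y binary outcome vector when \code{x} is a plain matrix.
#' @param measure influence measure driving the search: \code{"mgr"}
#'   (default; preferred when true interactions involve few variables) or
#'   \code{"i_score"}.
#' @param k initial subset size for the backward-dropping search; default is
#'   the adequacy bound of \code{\link{initial_size_bounds}} (at least 4
#'   samples per partition cell), clipped to \eqn{[2, p]}.
#' @param B number of search repetitions; default is \eqn{\hat B} from
#'   \code{\link{bda_repetitions}}, capped at \code{B_max}.
#' @param z interaction order the repetitions should cover (default
#'   \code{min(k, 3)}).
#' @param B_max cap on the automatic \code{B} (default 2000); an explicit
#'   \code{B} is never capped.
#' @param screening run triple screening first? Default (\code{NULL}):
#'   only when \eqn{p} exceeds \code{screening_threshold}.
#' @param screening_threshold automatic screening trigger (default 100).
#' @param stride,epsilon_frac screening elbow parameters, see
#'   \code{\link{select_top_triples}}.
#' @param forward_tol strict-increase tolerance of
#'   \code{\link{forward_add}}.
#' @param cv_folds internal CV folds for the ridge penalty.
#' @param seed integer root seed; every stage draws from a seed derived
#'   from it, so the fit is fully reproducible.
#' @param ... unused.
#' @return object of class \code{"mgr_fit"} with components
#'   \code{interactions} (list of integer vectors, original column
#'   indexing), \code{interaction_scores}, \code{ensemble}, \code{screen}
#'   (screen report or NULL), \code{measure}, \code{config}, \code{data}
#'   (training summary), \code{call}.
#' @examples
#' dm <- gen_module2(seed = 42)
#' fit <- mgr_fit(dm, k = 4, B = 50, seed = 42)
#' fit
#' summary(fit)
#' @export
mgr_fit <- function(x, ...) UseMethod("mgr_fit")

#' @rdname mgr_fit
#' @export
mgr_fit.default <- function(x, y = NULL, measure = c("mgr", "i_score"),
                            k = NULL, B = NULL, z = NULL, B_max = 2000,
                            screening = NULL, screening_threshold = 100,
                            stride = 1000, epsilon_frac = 0.01,
                            forward_tol = 1e-9, cv_folds = 5, seed = NULL,
                            ...) {
  cl <- match.call()
  measure <- match.arg(measure)
  dm <- as_discrete_matrix(x, y)

  if (is.null(screening)) screening <- dm$p > screening_threshold
  screen <- NULL
  vars <- seq_len(dm$p)
  if (isTRUE(screening)) {
    screen <- screen_triples(dm, measure = measure, stride = stride,
                             epsilon_frac = epsilon_frac)
    vars <- screen$retained_variables
  }
  dm_s <- if (length(vars) < dm$p) {
    discrete_matrix(dm$x[, vars, drop = FALSE], dm$y)
  } else dm

  bounds <- initial_size_bounds(dm$n)
  if (is.null(k)) k <- max(2L, min(bounds$adequacy_bound, dm_s$p))
  k <- min(k, dm_s$p)
  if (is.null(z)) z <- min(k, 3L)
  if (is.null(B)) B <- min(bda_repetitions(dm_s$p, k, z)$B_hat, B_max)

  rs <- run_bda(dm_s, k = k, B = B, measure = measure,
                seed = derive_seed(seed, "bda"))
  rs <- filter_overlaps(rs)
  rs <- forward_add(dm_s, rs, measure = measure, tol = forward_tol)
  # map back to original column indices
  interactions <- lapply(rs, function(s) sort(vars[s$variables]))
  scores <- vapply(rs, `[[`, numeric(1), "score")
  if (length(interactions) == 0L)
    stop("the search produced no interactions")

  ensemble <- boost_combine(dm, interactions, cv_folds = cv_folds,
                            seed = derive_seed(seed, "boost"))
  fitted_scores <- predict(ensemble, dm, type = "score")
  structure(list(interactions = interactions,
                 interaction_scores = scores,
                 ensemble = ensemble,
                 screen = screen,
                 measure = measure,
                 config = list(k = k, B = B, z = z, screening = screening,
                               stride = stride, epsilon_frac = epsilon_frac,
                               forward_tol = forward_tol,
                               cv_folds = cv_folds, seed = seed,
                               bounds = bounds),
                 data = list(n = dm$n, p = dm$p, pi1 = dm$pi1,
                             variable_names = dm$variable_names, y = dm$y),
                 fitted_scores = fitted_scores,
                 call = cl),
            class = "mgr_fit")
}

#' @rdname mgr_fit
#' @param formula model formula; the left-hand side names the binary
#'   outcome column, the right-hand side selects predictors (\code{.} for
#'   all others).
#' @param data data frame of integer codes plus the outcome column.
#' @export
mgr_fit.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.factor(y) || is.character(y)) {
    vals <- sort(unique(as.character(y)))
    if (length(vals) != 2L) stop("outcome must have exactly 2 levels")
    y <- as.integer(as.character(y) == vals[2L])
  }
  x <- as.matrix(mf[, -1L, drop = FALSE])
  fit <- mgr_fit.default(x, y, ...)
  fit$call <- match.call()
  fit
}

.interaction_label <- function(fit, idx) {
  paste0("{", paste(fit$data$variable_names[idx], collapse = ", "), "}")
}

#' @export
print.mgr_fit <- function(x, ...) {
  cat("Interaction-selection classifier (measure: ", x$measure, ")\n",
      sep = "")
  cat("Training data: n = ", x$data$n, ", p = ", x$data$p,
      ", pi1 = ", format(x$data$pi1, digits = 3), "\n", sep = "")
  if (!is.null(x$screen))
    cat("Screening kept ", x$screen$variable_cutoff, " of ", x$data$p,
        " variables\n", sep = "")
  cat("Search: k = ", x$config$k, ", B = ", x$config$B, "\n", sep = "")
  cat("Selected interactions (", length(x$interactions), "):\n", sep = "")
  for (i in seq_along(x$interactions))
    cat("  ", .interaction_label(x, x$interactions[[i]]), "  ", x$measure,
        " = ", format(x$interaction_scores[i], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mgr_fit <- function(object, ...) {
  acc <- mean(as.integer(object$fitted_scores >= object$ensemble$threshold)
              == object$data$y)
  out <- list(fit = object,
              interactions = data.frame(
                interaction = vapply(object$interactions, function(s)
                  .interaction_label(object, s), character(1)),
                size = lengths(object$interactions),
                score = object$interaction_scores),
              alphas = object$ensemble$alphas,
              training_accuracy = acc)
  class(out) <- "summary.mgr_fit"
  out
}

#' @export
print.summary.mgr_fit <- function(x, ...) {
  print(x$fit)
  cat("Boosting weights: ",
      paste(format(x$alphas, digits = 3), collapse = ", "), "\n", sep = "")
  cat("Training accuracy: ", sprintf("%.4f", x$training_accuracy), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.mgr_fit <- function(object, ...) {
  stats::setNames(lapply(object$ensemble$members, `[[`, "coefficients"),
                  vapply(object$ensemble$members, function(m)
                    .interaction_label(object, m$interaction), character(1)))
}

#' Predict disease status from a fitted interaction classifier
#'
#' @param object an \code{"mgr_fit"}.
#' @param newdata integer code matrix / data frame with the training
#'   columns, or a \code{\link{discrete_matrix}}; defaults to the training
#'   data.
#' @param type \code{"class"} for 0/1 labels, \code{"score"} for the
#'   weighted vote share in \eqn{[0, 1]}.
#' @param ... unused.
#' @export
predict.mgr_fit <- function(object, newdata = NULL,
                            type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    score <- object$fitted_scores
  } else {
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
    score <- predict(object$ensemble, newdata, type = "score")
  }
  if (type == "score") score
  else as.integer(score >= object$ensemble$threshold)
}

#' @export
fitted.mgr_fit <- function(object, ...) object$fitted_scores

#' @export
residuals.mgr_fit <- function(object, ...) {
  object$data$y - object$fitted_scores
}

#' Plot a fitted interaction classifier
#'
#' Barplot of the selected interactions' influence-measure scores, with the
#' boosting vote weights overlaid as points (scaled to the score axis).
#'
#' @param x an \code{"mgr_fit"}.
#' @param ... passed to \code{barplot}.
#' @export
plot.mgr_fit <- function(x, ...) {
  labs <- vapply(x$interactions, function(s) .interaction_label(x, s),
                 character(1))
  bp <- graphics::barplot(x$interaction_scores, names.arg = labs,
                          ylab = paste(x$measure, "score"),
                          main = "Selected interactions", las = 2, ...)
  ord <- match(vapply(x$ensemble$members, function(m)
    paste(m$interaction, collapse = ","), character(1)),
    vapply(x$interactions, paste, character(1), collapse = ","))
  a <- x$ensemble$alphas / max(x$ensemble$alphas) *
    max(x$interaction_scores)
  graphics::points(bp[ord], a, pch = 19)
  invisible(x)
}
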