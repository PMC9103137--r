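#' @title Ridge sub-classifiers, boosting and cross-validated evaluation
#' @description Each selected interaction becomes one ridge-regression
#' sub-classifier fitted on the interaction's variables plus all their
#' product terms (the joint action of the variables — for binary codes every
#' product column is the AND of its members, which is what lets a linear
#' ridge fit capture XOR-type interactions). The sub-classifiers are then
#' combined by an AdaBoost-style reweighting scheme into the final
#' classifier, evaluated by stratified cross-validation.
#' @name classification
NULL

#' Expand an interaction into singleton and product features
#'
#' Builds the feature table of an interaction of \eqn{m} variables: the
#' \eqn{m} singleton columns plus one product column per subset of size
#' \eqn{\ge 2}, i.e. \eqn{2^m - 1} columns in a deterministic order
#' (subsets by size, then lexicographically by index).
#'
#' @param x integer code matrix (or \code{\link{discrete_matrix}}).
#' @param interaction integer vector of variable indices, \eqn{m \le 12}
#'   (feature blow-up guard).
#' @return numeric matrix with \eqn{2^m - 1} named columns.
#' @examples
#' dm <- gen_module2(n = 6, seed = 1)
#' head(expand_products(dm, c(2, 3)))
#' @export
expand_products <- function(x, interaction) {
  if (inherits(x, "discrete_matrix")) x <- x$x
  stopifnot(is.matrix(x))
  m <- length(interaction)
  if (m < 1L) stop("interaction must contain at least one variable")
  if (m > 12L) stop("interaction of ", m, " variables would expand to ",
                    2^m - 1, " features; limit is 12")
  interaction <- sort(as.integer(interaction))
  nms <- colnames(x) %||% paste0("X", seq_len(ncol(x)))
  cols <- list()
  for (s in seq_len(m)) {
    # combn() would treat a length-1 vector as seq_len(), so guard it
    combs <- if (m == 1L) matrix(interaction, 1L, 1L)
             else utils::combn(interaction, s)
    for (c in seq_len(ncol(combs))) {
      idx <- combs[, c]
      v <- x[, idx[1L]]
      for (j in idx[-1L]) v <- v * x[, j]
      cols[[paste(nms[idx], collapse = ":")]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

# ridge fit via MASS::lm.ridge; zero-variance columns are dropped (lm.ridge
# standardizes columns) and given coefficient zero. Returns c(intercept, beta).
.ridge_coef <- function(X, y, lambda) {
  v <- apply(X, 2, stats::var)
  keep <- which(v > 0)
  beta <- numeric(ncol(X) + 1L)
  if (length(keep) == 0L) {
    beta[1L] <- mean(y)
    return(beta)
  }
  Xk <- X[, keep, drop = FALSE]
  if (length(keep) == 1L) {
    # lm.ridge cannot take a one-column design; same estimator in its
    # convention (center, scale to unit population sd, penalize the slope)
    xc <- Xk[, 1L] - mean(Xk[, 1L])
    s <- sqrt(mean(xc^2))
    z <- xc / s
    bz <- sum(z * (y - mean(y))) / (sum(z^2) + lambda)
    b <- bz / s
    beta[1L] <- mean(y) - mean(Xk[, 1L]) * b
    beta[1L + keep] <- b
    return(beta)
  }
  fit <- MASS::lm.ridge(y ~ Xk, lambda = lambda)
  co <- stats::coef(fit)
  beta[1L] <- co[1L]
  beta[1L + keep] <- co[-1L]
  beta
}

.ridge_predict <- function(beta, X) as.vector(cbind(1, X) %*% beta)

#' Fit one ridge sub-classifier
#'
#' Ridge regression of the 0/1 labels on the interaction's expanded feature
#' table (\code{\link{expand_products}}); the penalty is chosen by internal
#' cross-validation on squared error over a 10-point logarithmic grid
#' spanning \eqn{[10^{-3}, 10^3]}. A sample is classified 1 when its fitted
#' value is at least 0.5.
#'
#' @param dm a \code{\link{discrete_matrix}} (training data) with both
#'   classes present.
#' @param interaction integer vector of variable indices.
#' @param cv_folds internal CV folds for the penalty (default 5, reduced
#'   automatically for tiny samples).
#' @param seed optional seed for the internal CV fold draw.
#' @param lambda_grid penalty grid.
#' @return object of class \code{"subclassifier"}: coefficients, selected
#'   penalty, interaction, feature names.
#' @export
fit_subclassifier <- function(dm, interaction, cv_folds = 5, seed = NULL,
                              lambda_grid = 10^seq(-3, 3, length.out = 10)) {
  dm <- as_discrete_matrix(dm)
  if (min(table(factor(dm$y, levels = 0:1))) < 2L)
    stop("training data must contain at least 2 samples of each class")
  interaction <- .check_subset(dm, interaction)
  X <- expand_products(dm$x, interaction)
  y <- dm$y
  n <- dm$n
  folds <- max(2L, min(cv_folds, n))
  fold_id <- local_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_mse <- vapply(lambda_grid, function(lam) {
    err <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      beta <- .ridge_coef(X[tr, , drop = FALSE], y[tr], lam)
      pred <- .ridge_predict(beta, X[!tr, , drop = FALSE])
      err <- err + sum((y[!tr] - pred)^2)
    }
    err / n
  }, numeric(1))
  lambda <- lambda_grid[which.min(cv_mse)]
  beta <- .ridge_coef(X, y, lambda)
  structure(list(interaction = interaction,
                 feature_names = colnames(X),
                 coefficients = stats::setNames(beta,
                                                c("(Intercept)",
                                                  colnames(X))),
                 lambda = lambda, cv_mse = cv_mse,
                 lambda_grid = lambda_grid),
            class = "subclassifier")
}

#' @export
print.subclassifier <- function(x, ...) {
  cat("Ridge sub-classifier on {",
      paste(x$interaction, collapse = ", "), "}: ",
      length(x$feature_names), " feature(s), lambda = ",
      format(x$lambda, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
predict.subclassifier <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "discrete_matrix")) newdata <- newdata$x
  X <- expand_products(newdata, object$interaction)
  score <- .ridge_predict(object$coefficients, X)
  if (type == "score") score else as.integer(score >= 0.5)
}

#' Combine sub-classifiers by boosting
#'
#' AdaBoost-style combination over the fixed pool of per-interaction
#' sub-classifiers: each round picks the member with the smallest weighted
#' training error \eqn{\epsilon}, gives it vote weight
#' \eqn{\alpha = \frac12 \log[(1-\epsilon)/\epsilon]} (with \eqn{\epsilon}
#' clamped away from 0 and 1 so \eqn{\alpha} stays finite), and reweights
#' the samples multiplicatively toward the mistakes. Rounds stop when the
#' pool is exhausted or no remaining member beats chance
#' (\eqn{\epsilon \ge 0.5}); if even the first member is at chance, the
#' single best sub-classifier is used alone with a warning.
#'
#' @param dm training \code{\link{discrete_matrix}}.
#' @param interactions list of integer vectors (one per interaction).
#' @param cv_folds,seed passed to \code{\link{fit_subclassifier}}.
#' @return object of class \code{"mgr_ensemble"}: \code{members} (fitted
#'   sub-classifiers in boosting order), \code{alphas}, \code{threshold}
#'   (0.5 on the normalized weighted-vote scale).
#' @export
boost_combine <- function(dm, interactions, cv_folds = 5, seed = NULL) {
  dm <- as_discrete_matrix(dm)
  stopifnot(length(interactions) >= 1L)
  members <- lapply(seq_along(interactions), function(i) {
    fit_subclassifier(dm, interactions[[i]], cv_folds = cv_folds,
                      seed = derive_seed(seed, paste0("sub", i)))
  })
  n <- dm$n
  ypm <- ifelse(dm$y == 1L, 1, -1)
  H <- vapply(members, function(m) {
    ifelse(predict(m, dm, type = "class") == 1L, 1, -1)
  }, numeric(n))
  if (n == 1L) H <- matrix(H, nrow = 1L)
  w <- rep(1 / n, n)
  remaining <- seq_along(members)
  order_used <- integer(0)
  alphas <- numeric(0)
  eps_clamp <- function(e) min(max(e, 1e-10), 1 - 1e-10)
  while (length(remaining) > 0L) {
    errs <- vapply(remaining, function(j) sum(w[H[, j] != ypm]), numeric(1))
    pick <- remaining[order(errs)[1L]]
    eps <- min(errs)
    if (eps >= 0.5) {
      if (length(order_used) == 0L) {
        warning("no sub-classifier beats chance on weighted data; ",
                "falling back to the single best sub-classifier")
        raw_err <- vapply(remaining, function(j) mean(H[, j] != ypm),
                          numeric(1))
        pick <- remaining[order(raw_err)[1L]]
        order_used <- pick
        alphas <- 1
      }
      break
    }
    alpha <- 0.5 * log((1 - eps_clamp(eps)) / eps_clamp(eps))
    w <- w * exp(-alpha * ypm * H[, pick])
    w <- w / sum(w)
    order_used <- c(order_used, pick)
    alphas <- c(alphas, alpha)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(members = members[order_used], alphas = alphas,
                 threshold = 0.5),
            class = "mgr_ensemble")
}

#' @export
print.mgr_ensemble <- function(x, ...) {
  cat("Boosted ensemble of ", length(x$members), " ridge sub-classifier(s)\n",
      sep = "")
  for (i in seq_along(x$members))
    cat("  {", paste(x$members[[i]]$interaction, collapse = ", "),
        "}  alpha = ", format(x$alphas[i], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @describeIn boost_combine predict with the ensemble; \code{"score"} is
#'   the normalized weighted vote share for class 1 in \eqn{[0, 1]}.
predict.mgr_ensemble <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  votes <- vapply(object$members, function(m) {
    ifelse(predict(m, newdata, type = "class") == 1L, 1, -1)
  }, numeric(if (inherits(newdata, "discrete_matrix")) newdata$n
             else nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  a <- object$alphas / sum(object$alphas)
  share <- as.vector(votes %*% a + 1) / 2  # map [-1,1] -> [0,1]
  if (type == "score") share else as.integer(share >= object$threshold)
}

#' Confusion-matrix metrics
#'
#' @param truth,pred 0/1 vectors; class 1 is the positive (disease) class.
#' @return named vector: accuracy, sensitivity (TP rate), specificity
#'   (TN rate), and the confusion counts tp, fp, tn, fn. Undefined rates
#'   (an absent class) are \code{NaN}.
#' @export
confusion_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fn <- sum(truth == 1L & pred == 0L)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

# stratified fold assignment: per-fold class proportions differ from the
# global ones by at most one sample
.stratified_folds <- function(y, folds, seed = NULL) {
  local_seed(seed, {
    id <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
}

#' Cross-validated evaluation of the full pipeline
#'
#' Stratified k-fold evaluation in which the \emph{entire} selection
#' pipeline (optional triple screening, backward-dropping search, overlap
#' filtering, forward adding, sub-classifier fitting and boosting) is re-run
#' on each training fold via \code{\link{mgr_fit}} and assessed on the
#' held-out fold, so the reported metrics account for selection variability.
#'
#' @param dm a \code{\link{discrete_matrix}}; each class must have at least
#'   \code{folds} members.
#' @param folds number of folds (default 5).
#' @param seed integer root seed (fold draw and per-fold pipelines).
#' @param ... pipeline arguments passed to \code{\link{mgr_fit}}
#'   (\code{measure}, \code{k}, \code{B}, \code{z}, \code{screening}, ...).
#' @return object of class \code{"mgr_cv"}: \code{per_fold} (data frame of
#'   per-fold metrics), \code{average}, \code{fold_id}, \code{fits}.
#' @examples
#' \donttest{
#' cv <- evaluate_cv(gen_module2(seed = 5), k = 4, B = 30, seed = 5)
#' cv$average
#' }
#' @export
evaluate_cv <- function(dm, folds = 5, seed = NULL, ...) {
  dm <- as_discrete_matrix(dm)
  if (min(table(factor(dm$y, levels = 0:1))) < folds)
    stop("each class needs at least ", folds, " samples for ", folds,
         "-fold CV")
  fold_id <- .stratified_folds(dm$y, folds, seed = derive_seed(seed, "folds"))
  per_fold <- vector("list", folds)
  fits <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    dm_tr <- discrete_matrix(dm$x[tr, , drop = FALSE], dm$y[tr],
                             dm$variable_names)
    fit <- mgr_fit(dm_tr, seed = derive_seed(seed, paste0("fold", f)), ...)
    pred <- predict(fit, dm$x[!tr, , drop = FALSE])
    per_fold[[f]] <- c(fold = f, confusion_metrics(dm$y[!tr], pred))
    fits[[f]] <- fit
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  avg <- colMeans(per_fold[c("accuracy", "sensitivity", "specificity")],
                  na.rm = TRUE)
  structure(list(per_fold = per_fold, average = avg, fold_id = fold_id,
                 folds = folds, fits = fits),
            class = "mgr_cv")
}

#' @export
print.mgr_cv <- function(x, ...) {
  cat(x$folds, "-fold cross-validated pipeline evaluation\n", sep = "")
  print(round(x$per_fold[c("fold", "accuracy", "sensitivity",
                           "specificity")], 4), row.names = FALSE)
  cat("Average: accuracy ", sprintf("%.4f", x$average["accuracy"]),
      ", sensitivity ", sprintf("%.4f", x$average["sensitivity"]),
      ", specificity ", sprintf("%.4f", x$average["specificity"]), "\n",
      sep = "")
  invisible(x)
}
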