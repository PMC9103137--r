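#' @title Preprocessing: cleaning, filtering and two-means discretization
#' @description Utilities that turn a raw samples-by-biomarkers table into
#' the binary-coded \code{\link{discrete_matrix}} the influence measures
#' operate on: label cleaning, intensity clamping and variability filtering
#' (the classic expression-array recipe: floor/ceiling clamp, max/min and
#' max-min exclusion, base-10 log, two-means discretization), optional
#' preliminary univariate filtering, and a verification procedure that
#' dry-runs the interaction search on a random probe of variables to judge a
#' candidate preprocessing recipe before committing to a full run.
#' @name preprocessing
NULL

#' Clean a raw table into a numeric matrix and binary labels
#'
#' @param df data frame: samples in rows, one column holding a two-level
#'   status label, remaining columns numeric biomarker values.
#' @param label_col name of the label column.
#' @param positive label value mapped to class 1; defaults to the
#'   lexicographically larger of the two observed values (maps "M" over "B",
#'   "ALL" stays explicit via this argument when needed).
#' @return list with \code{x} (numeric matrix), \code{y} (0/1 integer
#'   vector) and \code{dropped_rows} (count of rows removed for missing
#'   values). Rows or columns that are entirely missing are dropped with a
#'   message; rows with any remaining missing entry are dropped with a
#'   logged count.
#' @export
clean_matrix <- function(df, label_col, positive = NULL) {
  stopifnot(is.data.frame(df))
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found")
  lab <- df[[label_col]]
  vals <- unique(lab[!is.na(lab)])
  if (length(vals) != 2L)
    stop("label column must have exactly 2 statuses, found ", length(vals),
         ": ", paste(utils::head(vals, 5), collapse = ", "))
  if (is.null(positive)) positive <- sort(as.character(vals))[2L]
  if (!positive %in% as.character(vals))
    stop("positive label '", positive, "' not among observed statuses")
  y <- as.integer(as.character(lab) == positive)

  xv <- df[setdiff(names(df), label_col)]
  all_na_col <- vapply(xv, function(v) all(is.na(v)), logical(1))
  if (any(all_na_col)) {
    message("dropping ", sum(all_na_col), " all-missing variable(s)")
    xv <- xv[!all_na_col]
  }
  for (nm in names(xv)) {
    v <- xv[[nm]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("unparseable numeric value in column '", nm, "', row ", bad[1])
      xv[[nm]] <- vn
    }
  }
  x <- as.matrix(xv)
  all_na_row <- rowSums(!is.na(x)) == 0L
  if (any(all_na_row)) {
    message("dropping ", sum(all_na_row), " all-missing row(s)")
    x <- x[!all_na_row, , drop = FALSE]
    y <- y[!all_na_row]
  }
  some_na <- rowSums(is.na(x)) > 0L
  if (any(some_na)) {
    message("dropping ", sum(some_na), " row(s) with missing entries")
    x <- x[!some_na, , drop = FALSE]
    y <- y[!some_na]
  }
  list(x = x, y = y, dropped_rows = sum(all_na_row) + sum(some_na))
}

#' Clamp intensities and drop low-variability variables
#'
#' Clips every value into \code{[floor_value, ceiling_value]}, then removes
#' variables whose post-clamp max/min ratio is at most
#' \code{ratio_threshold} or whose post-clamp range (max - min) is at most
#' \code{range_threshold}. Defaults reproduce the standard expression-array
#' recipe (floor 100, ceiling 16000, exclude max/min <= 5 or
#' max - min <= 500).
#'
#' @param x numeric matrix, samples in rows.
#' @param floor_value,ceiling_value clamp bounds (either may be NULL).
#' @param ratio_threshold,range_threshold exclusion bounds (either may be
#'   NULL to skip that rule).
#' @return the clamped matrix with excluded variables removed; attribute
#'   \code{"removed"} records their names.
#' @export
clamp_and_filter <- function(x, floor_value = 100, ceiling_value = 16000,
                             ratio_threshold = 5, range_threshold = 500) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!is.null(floor_value)) x[x < floor_value] <- floor_value
  if (!is.null(ceiling_value)) x[x > ceiling_value] <- ceiling_value
  mx <- apply(x, 2, max)
  mn <- apply(x, 2, min)
  drop <- rep(FALSE, ncol(x))
  if (!is.null(ratio_threshold)) drop <- drop | (mx / mn <= ratio_threshold)
  if (!is.null(range_threshold)) drop <- drop | (mx - mn <= range_threshold)
  if (all(drop)) stop("filtering removed every variable")
  out <- x[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(x)[drop]
  out
}

#' Elementwise base-10 logarithm
#'
#' @param x numeric matrix with strictly positive entries (guaranteed after
#'   flooring intensities at a positive value).
#' @return \code{log10(x)}.
#' @export
log10_transform <- function(x) {
  if (any(x <= 0)) stop("log10 transform requires strictly positive values")
  log10(x)
}

# exact 1-D two-means on one slice: clusters of an optimal 2-partition are
# contiguous in sorted order, so enumerate thresholds and minimize SSE
.two_means_slice <- function(v) {
  if (length(unique(v)) < 2L)
    return(list(codes = integer(length(v)), constant = TRUE, threshold = NA))
  s <- sort(v)
  m <- length(s)
  cs1 <- cumsum(s)
  cs2 <- cumsum(s^2)
  i <- seq_len(m - 1L)
  sse <- (cs2[i] - cs1[i]^2 / i) +
    ((cs2[m] - cs2[i]) - (cs1[m] - cs1[i])^2 / (m - i))
  sse[s[i] == s[i + 1L]] <- Inf   # split must fall between distinct values
  best <- which.min(sse)          # ties: lowest threshold wins
  thr <- (s[best] + s[best + 1L]) / 2
  list(codes = as.integer(v > thr), constant = FALSE, threshold = thr)
}

#' Two-means discretization
#'
#' Splits each slice (one variable across all samples, or one sample across
#' all variables) into binary codes by exact one-dimensional 2-means: the
#' optimal 2-cluster partition of scalar data is a threshold split, found by
#' enumerating thresholds between sorted distinct values and minimizing
#' within-cluster SSE. The cluster with the lower mean is coded 0, so codes
#' are stable across runs; exact SSE ties go to the lower threshold.
#' Constant slices get all-zero codes with a warning.
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary outcome vector (carried through to the result).
#' @param axis \code{"variable"} discretizes each column across samples
#'   (e.g. morphology features); \code{"sample"} discretizes each row across
#'   variables (e.g. expression arrays).
#' @param seed unused by the deterministic exact solver; accepted for
#'   interface stability.
#' @return a \code{\link{discrete_matrix}}.
#' @export
discretize_two_means <- function(x, y, axis = c("variable", "sample"),
                                 seed = NULL) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(x), is.numeric(x))
  codes <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  n_const <- 0L
  if (axis == "variable") {
    for (j in seq_len(ncol(x))) {
      r <- .two_means_slice(x[, j])
      if (r$constant) n_const <- n_const + 1L
      codes[, j] <- r$codes
    }
  } else {
    for (i in seq_len(nrow(x))) {
      r <- .two_means_slice(x[i, ])
      if (r$constant) n_const <- n_const + 1L
      codes[i, ] <- r$codes
    }
  }
  if (n_const > 0L)
    warning(n_const, " constant ", axis, " slice(s) coded all-0")
  discrete_matrix(codes, y)
}

#' Preliminary univariate filtering
#'
#' Cheap per-variable screening applied before the interaction search:
#' two-sample t-test (keep variables with p below \code{threshold}) or
#' fold-change (keep variables whose between-class mean ratio, in either
#' direction, exceeds \code{threshold}). Column order is preserved.
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary outcome vector.
#' @param method one of \code{"none"}, \code{"t-test"}, \code{"fold-change"}.
#' @param threshold p-value cutoff (t-test) or ratio cutoff (fold-change).
#' @return the matrix restricted to retained variables.
#' @export
preliminary_filter <- function(x, y, method = c("none", "t-test",
                                                "fold-change"),
                               threshold = 0.05) {
  method <- match.arg(method)
  if (method == "none") return(x)
  stopifnot(is.matrix(x), length(y) == nrow(x))
  g1 <- y == 1L
  if (method == "t-test") {
    keep <- vapply(seq_len(ncol(x)), function(j) {
      p <- tryCatch(stats::t.test(x[g1, j], x[!g1, j])$p.value,
                    error = function(e) 1)
      isTRUE(p < threshold)
    }, logical(1))
  } else {
    m1 <- colMeans(x[g1, , drop = FALSE])
    m0 <- colMeans(x[!g1, , drop = FALSE])
    fc <- pmax(abs(m1) / pmax(abs(m0), .Machine$double.eps),
               abs(m0) / pmax(abs(m1), .Machine$double.eps))
    keep <- fc > threshold
  }
  if (!any(keep)) stop("preliminary filter removed every variable")
  x[, keep, drop = FALSE]
}

#' Preprocessing configuration
#'
#' Bundles the knobs of the preprocessing stage. The defaults reproduce the
#' expression-array recipe; set the clamp/filter fields to NULL and
#' \code{log_base10 = FALSE} for already-scaled data (the \code{"bcw"}
#' recipe is exactly that plus per-variable discretization).
#'
#' @param floor_value,ceiling_value,ratio_threshold,range_threshold see
#'   \code{\link{clamp_and_filter}}; any may be NULL to skip.
#' @param log_base10 apply \code{\link{log10_transform}} after filtering.
#' @param discretize_axis \code{"variable"} or \code{"sample"}.
#' @param prelim_filter,prelim_threshold see \code{\link{preliminary_filter}}.
#' @param seed optional seed carried to the discretizer.
#' @return list of class \code{"preprocess_config"}.
#' @export
preprocess_config <- function(floor_value = 100, ceiling_value = 16000,
                              ratio_threshold = 5, range_threshold = 500,
                              log_base10 = TRUE,
                              discretize_axis = c("sample", "variable"),
                              prelim_filter = "none",
                              prelim_threshold = 0.05, seed = NULL) {
  discretize_axis <- match.arg(discretize_axis)
  for (v in c(ratio_threshold, range_threshold))
    if (!is.null(v) && v <= 0) stop("thresholds must be positive when set")
  structure(list(floor_value = floor_value, ceiling_value = ceiling_value,
                 ratio_threshold = ratio_threshold,
                 range_threshold = range_threshold, log_base10 = log_base10,
                 discretize_axis = discretize_axis,
                 prelim_filter = prelim_filter,
                 prelim_threshold = prelim_threshold, seed = seed),
            class = "preprocess_config")
}

#' Apply a preprocessing configuration
#'
#' Runs clamp/filter, optional preliminary filter, optional log10, and
#' two-means discretization in order, logging the variable count after each
#' sub-step.
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary outcome vector.
#' @param config a \code{\link{preprocess_config}}.
#' @return a \code{\link{discrete_matrix}}; attribute \code{"counts"} holds
#'   the per-stage variable counts.
#' @export
apply_preprocess <- function(x, y, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  counts <- c(input = ncol(x))
  if (!is.null(config$ratio_threshold) || !is.null(config$range_threshold) ||
      !is.null(config$floor_value) || !is.null(config$ceiling_value)) {
    x <- clamp_and_filter(x, config$floor_value, config$ceiling_value,
                          config$ratio_threshold, config$range_threshold)
    counts <- c(counts, clamp_filter = ncol(x))
  }
  if (!identical(config$prelim_filter, "none")) {
    x <- preliminary_filter(x, y, config$prelim_filter,
                            config$prelim_threshold)
    counts <- c(counts, prelim_filter = ncol(x))
  }
  if (isTRUE(config$log_base10)) x <- log10_transform(x)
  dm <- discretize_two_means(x, y, axis = config$discretize_axis,
                             seed = config$seed)
  counts <- c(counts, discretized = dm$p)
  message(paste(names(counts), counts, sep = ": ", collapse = " -> "))
  attr(dm, "counts") <- counts
  dm
}

#' Verify a candidate preprocessing recipe on a random variable probe
#'
#' Before running the full interaction search under a candidate
#' preprocessing recipe, applies the recipe, samples \code{n_probe} of the
#' resulting discrete variables, runs the search-plus-classifier pipeline on
#' the probe under cross-validation, and compares the accuracy to the
#' majority-class baseline. The recipe is judged \code{reasonable} when the
#' probe accuracy beats the baseline by at least \code{margin}.
#'
#' @param x numeric matrix, samples in rows.
#' @param y binary outcome vector.
#' @param config a \code{\link{preprocess_config}}.
#' @param n_probe number of variables to probe (default 100; if fewer are
#'   available the full set is used with a warning).
#' @param margin required accuracy gain over the majority baseline
#'   (default 0.05).
#' @param folds cross-validation folds.
#' @param seed integer seed controlling the probe draw and the pipeline.
#' @param ... further arguments passed to \code{\link{evaluate_cv}} (e.g.
#'   \code{k}, \code{B}, \code{measure}).
#' @return list with \code{accuracy}, \code{baseline}, \code{margin},
#'   \code{reasonable}, \code{probe_variables}.
#' @export
verify_preprocessing <- function(x, y, config = preprocess_config(),
                                 n_probe = 100, margin = 0.05, folds = 5,
                                 seed = NULL, ...) {
  dm <- apply_preprocess(x, y, config)
  if (dm$p < n_probe) {
    warning("only ", dm$p, " variables available; probing all of them")
    n_probe <- dm$p
  }
  probe <- local_seed(derive_seed(seed, "probe"),
                      sort(sample.int(dm$p, n_probe)))
  dm_probe <- discrete_matrix(dm$x[, probe, drop = FALSE], dm$y)
  cv <- evaluate_cv(dm_probe, folds = folds,
                    seed = derive_seed(seed, "cv"), ...)
  baseline <- max(dm$pi1, 1 - dm$pi1)
  acc <- cv$average["accuracy"]
  list(accuracy = unname(acc), baseline = baseline, margin = margin,
       reasonable = unname(acc > baseline + margin),
       probe_variables = probe)
}
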