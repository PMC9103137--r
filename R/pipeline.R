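#' Pipeline configuration
#'
#' Bundles every stage's settings for \code{\link{run_pipeline}}: input
#' location, preprocessing, the influence measure, search sizes, and
#' cross-validation. Each stage is seeded from \code{seed} through a
#' deterministic fan-out, so inserting or removing a stage never shifts the
#' random streams of the others.
#'
#' @param input path of a delimited samples-by-variables table, or NULL when
#'   \code{run_pipeline} is given data directly.
#' @param label_col name of the outcome column.
#' @param positive label value coded 1 (see \code{\link{clean_matrix}}).
#' @param sep field separator of the input table.
#' @param preprocess a \code{\link{preprocess_config}}, or NULL when the
#'   input is already discrete.
#' @param measure,k,B,z,screening,screening_threshold,stride,epsilon_frac
#'   passed to \code{\link{mgr_fit}}.
#' @param folds cross-validation folds.
#' @param seed integer root seed.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input = NULL, label_col = "Y", positive = NULL,
                            sep = ",", preprocess = NULL,
                            measure = "mgr", k = NULL, B = NULL, z = NULL,
                            screening = NULL, screening_threshold = 100,
                            stride = 1000, epsilon_frac = 0.01,
                            folds = 5, seed = 1) {
  structure(list(input = input, label_col = label_col, positive = positive,
                 sep = sep, preprocess = preprocess, measure = measure,
                 k = k, B = B, z = z, screening = screening,
                 screening_threshold = screening_threshold, stride = stride,
                 epsilon_frac = epsilon_frac, folds = folds, seed = seed),
            class = "pipeline_config")
}

#' Run the full selection-and-classification pipeline
#'
#' Executes preprocessing (when configured), cross-validated interaction
#' selection and classification, and a final fit on all samples, logging
#' the variable counts at every reduction. The report is a plain list that
#' serializes deterministically to JSON via \code{\link{write_report}}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param data optional raw data: list with numeric matrix \code{x} and
#'   binary \code{y}, or a \code{\link{discrete_matrix}}; overrides
#'   \code{config$input}.
#' @return list of class \code{"pipeline_report"} with elements
#'   \code{counts}, \code{cv} (per-fold and average metrics),
#'   \code{interactions} (from the final full-data fit), \code{config_echo}.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(k = 4, B = 30, seed = 9),
#'                     data = gen_module2(seed = 9))
#' rep$cv$average
#' }
#' @export
run_pipeline <- function(config, data = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()
  if (is.null(data)) {
    if (is.null(config$input)) stop("no input file and no data given")
    df <- utils::read.table(config$input, header = TRUE, sep = config$sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    cm <- clean_matrix(df, config$label_col, positive = config$positive)
    data <- cm
  }
  if (inherits(data, "discrete_matrix")) {
    dm <- data
  } else if (!is.null(config$preprocess)) {
    pp <- config$preprocess
    pp$seed <- pp$seed %||% derive_seed(config$seed, "preprocess")
    dm <- apply_preprocess(data$x, data$y, pp)
    counts$preprocess <- as.list(attr(dm, "counts"))
  } else {
    dm <- discrete_matrix(data$x, data$y)
  }
  counts$variables_in <- dm$p
  counts$samples <- dm$n

  cv <- evaluate_cv(dm, folds = config$folds,
                    seed = derive_seed(config$seed, "cv"),
                    measure = config$measure, k = config$k, B = config$B,
                    z = config$z, screening = config$screening,
                    screening_threshold = config$screening_threshold,
                    stride = config$stride,
                    epsilon_frac = config$epsilon_frac)

  fit <- mgr_fit(dm, measure = config$measure, k = config$k, B = config$B,
                 z = config$z, screening = config$screening,
                 screening_threshold = config$screening_threshold,
                 stride = config$stride, epsilon_frac = config$epsilon_frac,
                 seed = derive_seed(config$seed, "fit"))
  counts$interactions <- length(fit$interactions)
  if (!is.null(fit$screen))
    counts$screened_variables <- fit$screen$variable_cutoff
  message("pipeline: ", counts$variables_in, " variables -> ",
          counts$interactions, " interaction(s); mean CV accuracy ",
          sprintf("%.4f", cv$average["accuracy"]))

  structure(list(
    counts = counts,
    cv = list(per_fold = cv$per_fold, average = as.list(cv$average)),
    interactions = lapply(seq_along(fit$interactions), function(i) list(
      variables = fit$data$variable_names[fit$interactions[[i]]],
      indices = fit$interactions[[i]],
      score = fit$interaction_scores[i],
      size = length(fit$interactions[[i]]))),
    measure = config$measure,
    config_echo = unclass(config)[c("measure", "k", "B", "z", "folds",
                                    "seed")],
    fit = fit),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (measure: ", x$measure, ")\n", sep = "")
  cat("Samples: ", x$counts$samples, ", variables: ",
      x$counts$variables_in, ", interactions: ", x$counts$interactions,
      "\n", sep = "")
  cat("CV average: accuracy ",
      sprintf("%.4f", x$cv$average$accuracy), ", sensitivity ",
      sprintf("%.4f", x$cv$average$sensitivity), ", specificity ",
      sprintf("%.4f", x$cv$average$specificity), "\n", sep = "")
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the report (without the embedded fit object) as pretty-printed
#' JSON. Identical configuration and seed produce byte-identical files.
#'
#' @param report a \code{"pipeline_report"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$fit <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
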