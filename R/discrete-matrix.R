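#' Discrete design matrix with a binary outcome
#'
#' Container for an \eqn{n \times p} matrix of discretized biomarker codes
#' together with a binary outcome label per sample. All influence-measure and
#' subset-search functions in the package operate on this class. Codes are
#' small non-negative integers (after discretization binary data uses 0/1);
#' the outcome takes values 0 (e.g. benign / AML) and 1 (e.g. malignant /
#' ALL), and \code{pi1} records the sample proportion of class 1.
#'
#' @param x numeric matrix or data frame of non-negative integer codes,
#'   samples in rows, variables in columns.
#' @param y binary outcome vector (0/1, or a logical) of length \code{nrow(x)}.
#' @param variable_names optional character vector of unique variable names;
#'   defaults to the column names of \code{x} or \code{X1..Xp}.
#' @return An object of class \code{"discrete_matrix"}: a list with elements
#'   \code{x} (integer matrix), \code{y} (integer vector), \code{n}, \code{p},
#'   \code{pi1} and \code{variable_names}.
#' @examples
#' dm <- discrete_matrix(matrix(c(0, 0, 1, 1), 4, 1), c(1, 0, 1, 1))
#' dm$pi1
#' @export
discrete_matrix <- function(x, y, variable_names = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("codes must not contain missing values")
  if (any(x < 0) || any(x != round(x)))
    stop("all codes must be non-negative integers")
  storage.mode(x) <- "integer"
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (length(y) != nrow(x))
    stop("length of 'y' (", length(y), ") must equal nrow(x) (", nrow(x), ")")
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("'y' must contain only 0 and 1")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("need n >= 1 and p >= 1")
  nm <- variable_names %||% colnames(x) %||% paste0("X", seq_len(ncol(x)))
  if (length(nm) != ncol(x) || anyDuplicated(nm))
    stop("variable names must be unique and match the number of columns")
  colnames(x) <- nm
  structure(list(x = x, y = y, n = nrow(x), p = ncol(x),
                 pi1 = mean(y), variable_names = nm),
            class = "discrete_matrix")
}

#' @export
print.discrete_matrix <- function(x, ...) {
  cat("Discrete design matrix: ", x$n, " samples x ", x$p, " variables\n",
      sep = "")
  cat("Class balance: pi1 = ", format(x$pi1, digits = 4),
      " (", sum(x$y), " of ", x$n, " samples in class 1)\n", sep = "")
  cat("Codes per variable: ",
      paste(range(apply(x$x, 2, function(v) length(unique(v)))),
            collapse = "-"), " categories\n", sep = "")
  invisible(x)
}

as_discrete_matrix <- function(x, y = NULL) {
  if (inherits(x, "discrete_matrix")) return(x)
  discrete_matrix(x, y)
}

#' Read a discrete design matrix from delimited text
#'
#' Reads a samples-by-variables table (header row of variable names, one
#' label column) and returns a \code{\link{discrete_matrix}}. Values must
#' parse as integers; run the preprocessing functions first for raw
#' continuous data.
#'
#' @param path file path of a CSV/TSV table.
#' @param label_col name of the outcome column.
#' @param positive value of \code{label_col} coded as class 1; by default
#'   the lexicographically larger of the two observed labels (so
#'   \code{"M" > "B"} maps malignant to 1).
#' @param sep field separator, \code{","} by default.
#' @return a \code{\link{discrete_matrix}}.
#' @export
read_discrete_matrix <- function(path, label_col, positive = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cm <- clean_matrix(df, label_col, positive = positive)
  discrete_matrix(cm$x, cm$y)
}

#' Write a discrete design matrix to delimited text
#'
#' @param dm a \code{\link{discrete_matrix}}.
#' @param path output file path.
#' @param label_col name used for the outcome column.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_discrete_matrix <- function(dm, path, label_col = "Y", sep = ",") {
  dm <- as_discrete_matrix(dm)
  df <- as.data.frame(dm$x)
  df[[label_col]] <- dm$y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
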