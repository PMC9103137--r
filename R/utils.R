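# internal helpers shared across the package

# x*log(x) with the 0*log(0) := 0 convention
xlogx <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos])
  out
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs the code against the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-stage seed fan-out: inserting a stage never shifts the
# stream of another stage. Kept below 2^31 - 1.
derive_seed <- function(root_seed, stage) {
  if (is.null(root_seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 7919 + h * 104729) %% 2147483647)
}

# TRUE if integer vector a precedes b lexicographically (shorter prefix wins)
lex_less <- function(a, b) {
  m <- min(length(a), length(b))
  for (i in seq_len(m)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# order a list of integer vectors lexicographically
lex_order <- function(sets) {
  n <- length(sets)
  if (n <= 1L) return(seq_len(n))
  keys <- vapply(sets, function(s) paste(sprintf("%09d", s), collapse = ","),
                 character(1))
  order(keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
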