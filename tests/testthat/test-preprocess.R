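test_that("clean_matrix maps two-status labels and rejects bad tables", {
  df <- data.frame(f1 = c(1, 2, 3, 4), f2 = c(5, 6, 7, 8),
                   diagnosis = c("M", "B", "B", "M"),
                   stringsAsFactors = FALSE)
  cm <- clean_matrix(df, "diagnosis")
  expect_equal(cm$y, c(1L, 0L, 0L, 1L))   # "M" > "B" lexicographically
  expect_equal(ncol(cm$x), 2L)
  expect_equal(cm$x[, "f1"], c(1, 2, 3, 4))

  # explicit positive label overrides the default
  cm2 <- clean_matrix(df, "diagnosis", positive = "B")
  expect_equal(cm2$y, c(0L, 1L, 1L, 0L))

  df3 <- df
  df3$diagnosis <- c("M", "B", "U", "M")
  expect_error(clean_matrix(df3, "diagnosis"), "exactly 2 statuses")

  dfb <- df
  dfb$f1 <- c("1", "2", "oops", "4")
  expect_error(clean_matrix(dfb, "diagnosis"), "f1.*row 3")

  # rows with missing entries are dropped with a message
  dfm <- df
  dfm$f2[2] <- NA
  expect_message(cmm <- clean_matrix(dfm, "diagnosis"), "missing")
  expect_equal(nrow(cmm$x), 3L)
})

test_that("clamping and variability filtering follow the exclusion rules", {
  x <- cbind(keep = c(-10, 500, 20000),   # clamps to (100, 500, 16000)
             ratio = c(100, 250, 400),    # 400/100 = 4 <= 5 -> excluded
             range = c(1000, 1200, 1400)) # range 400 <= 500 -> excluded
  out <- clamp_and_filter(x)
  expect_equal(colnames(out), "keep")
  expect_equal(out[, "keep"], c(100, 500, 16000))
  expect_equal(sort(attr(out, "removed")), c("range", "ratio"))

  expect_error(clamp_and_filter(x[, 2, drop = FALSE]), "every variable")

  # relaxing a threshold never removes a variable stricter settings kept
  set.seed(4)
  xr <- matrix(runif(300, 50, 20000), 30, 10,
               dimnames = list(NULL, paste0("g", 1:10)))
  strict <- clamp_and_filter(xr, ratio_threshold = 8, range_threshold = 2000)
  relaxed <- clamp_and_filter(xr, ratio_threshold = 5, range_threshold = 500)
  expect_true(all(colnames(strict) %in% colnames(relaxed)))
})

test_that("log10 transform is exact and guards non-positive input", {
  expect_equal(log10_transform(matrix(c(100, 16000), 1)),
               matrix(c(2, 4.20412), 1), tolerance = 1e-5)
  x <- matrix(runif(20, 1, 100), 4, 5)
  expect_equal(10^log10_transform(x), x, tolerance = 1e-9)
  expect_error(log10_transform(matrix(c(1, 0), 1)), "positive")
})

test_that("two-means discretization is the exact 1-D optimum", {
  x <- matrix(c(0.9, 1.0, 1.1, 4.8, 5.0, 5.2), ncol = 1)
  dm <- discretize_two_means(x, y = c(0, 0, 0, 1, 1, 1))
  expect_equal(dm$x[, 1], c(0L, 0L, 0L, 1L, 1L, 1L))

  expect_warning(dmc <- discretize_two_means(matrix(2, 5, 1), rep(0:1, c(2, 3))),
                 "constant")
  expect_equal(dmc$x[, 1], rep(0L, 5))

  # per-sample axis splits rows, not columns
  xs <- rbind(c(1, 1, 9, 9), c(8, 8, 2, 2))
  dms <- discretize_two_means(xs, y = c(0, 1), axis = "sample")
  expect_equal(unname(dms$x[1, ]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(dms$x[2, ]), c(1L, 1L, 0L, 0L))

  # SSE never worse than stats::kmeans with restarts; lower-mean cluster is 0
  for (seed in 1:10) {
    set.seed(seed)
    v <- c(rnorm(15), rnorm(10, mean = sample(1:4, 1)))
    dm2 <- discretize_two_means(matrix(v, ncol = 1), y = rep(0:1, c(12, 13)))
    codes <- dm2$x[, 1]
    sse <- function(cl) sum(tapply(v, cl, function(g) sum((g - mean(g))^2)))
    km <- kmeans(v, centers = 2, nstart = 10)
    expect_lte(sse(codes), sse(km$cluster) + 1e-9)
    expect_lte(mean(v[codes == 0]), mean(v[codes == 1]))
  }
})

test_that("preliminary filtering keeps signal and calibrates type I error", {
  set.seed(7)
  y <- rep(0:1, each = 100)
  x <- cbind(signal = rnorm(200, mean = 3 * y), matrix(rnorm(200 * 40), 200))
  colnames(x) <- c("signal", paste0("n", 1:40))
  kept <- preliminary_filter(x, y, "t-test", 0.05)
  expect_true("signal" %in% colnames(kept))
  # pure noise: about 5% retained
  set.seed(8)
  hits <- replicate(40, {
    xn <- matrix(rnorm(100 * 50), 100,
                 dimnames = list(NULL, paste0("v", 1:50)))
    kp <- tryCatch(preliminary_filter(xn, rep(0:1, each = 50), "t-test"),
                   error = function(e) xn[, 0, drop = FALSE])
    ncol(kp)
  })
  expect_lt(abs(mean(hits) / 50 - 0.05), 0.03)
  expect_identical(preliminary_filter(x, y, "none"), x)
  expect_error(preliminary_filter(x, y, "wavelet"), "arg")
})

test_that("the expression-array recipe composes deterministically", {
  set.seed(12)
  x <- matrix(rexp(60 * 40, rate = 1 / 2000), 60, 40,
              dimnames = list(NULL, paste0("g", 1:40)))
  y <- rep(0:1, 30)
  cfg <- preprocess_config(discretize_axis = "sample")
  expect_message(dm1 <- apply_preprocess(x, y, cfg), "discretized")
  dm2 <- suppressMessages(apply_preprocess(x, y, cfg))
  expect_identical(dm1$x, dm2$x)
  expect_true(all(dm1$x %in% 0:1))
  expect_true(dm1$p <= 40)
})

test_that("preprocessing verification separates signal from permuted labels", {
  set.seed(31)
  n <- 80
  y <- rep(0:1, each = n / 2)
  # one strong continuous marker plus noise; two-means recovers it
  x <- cbind(matrix(rnorm(n * 19), n), marker = rnorm(n, mean = 4 * y))
  colnames(x) <- paste0("v", 1:20)
  cfg <- preprocess_config(floor_value = NULL, ceiling_value = NULL,
                           ratio_threshold = NULL, range_threshold = NULL,
                           log_base10 = FALSE, discretize_axis = "variable")
  expect_warning(
    v <- verify_preprocessing(x, y, cfg, n_probe = 100, seed = 1,
                              folds = 4, k = 3, B = 25),
    "probing all")
  expect_true(v$reasonable)
  expect_gt(v$accuracy, v$baseline + v$margin)

  set.seed(32)
  yp <- sample(y)
  vp <- suppressWarnings(
    verify_preprocessing(x, yp, cfg, n_probe = 100, seed = 1,
                         folds = 4, k = 3, B = 25))
  expect_false(vp$reasonable)
})
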