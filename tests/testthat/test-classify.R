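test_that("product expansion enumerates all subset products in order", {
  x <- cbind(a = c(0L, 1L, 1L), b = c(1L, 1L, 0L), c = c(1L, 0L, 1L))
  f2 <- expand_products(x, c(1, 2))
  expect_equal(colnames(f2), c("a", "b", "a:b"))
  expect_equal(f2[, "a:b"], as.numeric(x[, 1] * x[, 2]))

  f3 <- expand_products(x, 1:3)
  expect_equal(ncol(f3), 7L)  # 2^3 - 1

  # binary codes: every product column is the AND of its members
  set.seed(5)
  xb <- matrix(sample(0:1, 40 * 4, replace = TRUE), 40, 4)
  fb <- expand_products(xb, 1:4)
  for (nm in colnames(fb)) {
    idx <- as.integer(sub("X", "", strsplit(nm, ":")[[1]]))
    expect_equal(fb[, nm],
                 as.numeric(apply(xb[, idx, drop = FALSE] == 1, 1, all)))
  }
  expect_error(expand_products(matrix(0L, 2, 13), 1:13), "limit is 12")
})

test_that("ridge sub-classifier separates what its features admit", {
  # y equals a single binary feature exactly: perfect training fit
  set.seed(1)
  x <- matrix(sample(0:1, 60 * 2, replace = TRUE), 60, 2)
  dm <- discrete_matrix(x, x[, 1])
  sc <- fit_subclassifier(dm, 1, seed = 1)
  expect_equal(mean(predict(sc, dm) == dm$y), 1)

  # balanced XOR: exact with the product term, at most 75% without it
  xr <- cbind(a = rep(c(0L, 1L, 0L, 1L), 25), b = rep(c(0L, 0L, 1L, 1L), 25))
  yx <- (xr[, 1] + xr[, 2]) %% 2L
  dmx <- discrete_matrix(xr, yx)
  full <- fit_subclassifier(dmx, c(1, 2), seed = 2)
  expect_equal(mean(predict(full, dmx) == yx), 1)
  raw <- .ridge_raw_accuracy <- local({
    # ridge restricted to the raw singletons (no product column)
    X <- xr
    best <- 0
    for (lam in 10^seq(-3, 3, length.out = 10)) {
      beta <- mgrselect:::.ridge_coef(X, yx, lam)
      pred <- as.integer(mgrselect:::.ridge_predict(beta, X) >= 0.5)
      best <- max(best, mean(pred == yx))
    }
    best
  })
  expect_lte(raw, 0.75)

  # pure noise: training accuracy near the majority baseline
  set.seed(3)
  xn <- matrix(sample(0:1, 400 * 2, replace = TRUE), 400, 2)
  yn <- rep(c(0L, 1L), c(120, 280))
  dmn <- discrete_matrix(xn, yn)
  scn <- fit_subclassifier(dmn, c(1, 2), seed = 3)
  expect_lt(abs(mean(predict(scn, dmn) == yn) - 0.7), 0.08)

  expect_error(fit_subclassifier(discrete_matrix(xn, rep(1L, 400)), 1),
               "each class")
})

test_that("boosting combines complementary weak rules profitably", {
  # two features, each correct on a disjoint 75% of the sample
  n <- 200
  y <- rep(c(0L, 1L), each = n / 2)
  a <- y
  b <- y
  a[1:50] <- 1L - a[1:50]        # feature 1 wrong on the first quarter
  b[151:200] <- 1L - b[151:200]  # feature 2 wrong on the last quarter
  dm <- discrete_matrix(cbind(a, b), y)
  ens <- boost_combine(dm, list(1L, 2L), seed = 4)
  acc_ens <- mean(predict(ens, dm) == y)
  acc_single <- sapply(1:2, function(j) {
    mean(predict(fit_subclassifier(dm, j, seed = 4), dm) == y)
  })
  expect_gte(acc_ens, max(acc_single))
  expect_equal(length(ens$members), 2L)

  # each added member beats chance on the weights it was picked under
  expect_true(all(ens$alphas > 0))

  # one interaction: the ensemble is that sub-classifier with positive weight
  e1 <- boost_combine(dm, list(1L), seed = 5)
  expect_equal(length(e1$members), 1L)
  expect_gt(e1$alphas[1], 0)
  expect_equal(predict(e1, dm),
               predict(fit_subclassifier(dm, 1L,
                                         seed = mgrselect:::derive_seed(5, "sub1")),
                       dm))

  # zero training error in round one: alpha stays finite
  dmp <- discrete_matrix(cbind(y, 1L - y), y)
  ep <- boost_combine(dmp, list(1L), seed = 6)
  expect_true(is.finite(ep$alphas[1]))
})

test_that("confusion metrics satisfy their identities", {
  truth <- c(rep(1L, 10), rep(0L, 10))
  pred <- c(rep(1L, 9), 0L, rep(0L, 8), 1L, 1L)
  m <- confusion_metrics(truth, pred)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["sensitivity"]), 0.90)
  expect_equal(unname(m["specificity"]), 0.80)
  # identities on random tables vs a naive recount
  for (s in 1:20) {
    set.seed(s)
    tr <- sample(0:1, 30, replace = TRUE)
    pr <- sample(0:1, 30, replace = TRUE)
    m <- confusion_metrics(tr, pr)
    expect_equal(unname(m["accuracy"]),
                 (m[["tp"]] + m[["tn"]]) / 30)
    expect_equal(unname(m["tp"] + m["fn"]), sum(tr == 1))
    expect_equal(unname(m["tn"] + m["fp"]), sum(tr == 0))
    expect_equal(unname(m["accuracy"]), mean(tr == pr))
  }
})

test_that("cross-validation folds are stratified and metrics averaged", {
  dm <- gen_module2(n = 150, seed = 13)
  cv <- evaluate_cv(dm, folds = 5, seed = 13, k = 4, B = 25)
  expect_equal(nrow(cv$per_fold), 5L)
  # per-fold class proportions within one sample of the global split
  for (f in 1:5) {
    yf <- dm$y[cv$fold_id == f]
    expect_lte(abs(sum(yf) - length(yf) * dm$pi1), 1 + 1e-9)
  }
  expect_equal(unname(cv$average["accuracy"]),
               mean(cv$per_fold$accuracy))
  expect_error(evaluate_cv(discrete_matrix(matrix(0:1, 10, 1),
                                           rep(c(0L, 1L), c(2, 8))),
                           folds = 5), "at least 5")

  # perfectly separable data is classified perfectly
  set.seed(14)
  xs <- matrix(sample(0:1, 100 * 3, replace = TRUE), 100, 3)
  dms <- discrete_matrix(xs, xs[, 2])
  cvs <- evaluate_cv(dms, folds = 5, seed = 14, k = 2, B = 15)
  expect_equal(unname(cvs$average["accuracy"]), 1)
})

test_that("the mgr pipeline beats chance and the all-variable ridge baseline", {
  accs <- sapply(1:8, function(s) {
    dm <- gen_module2(n = 200, seed = 2100 + s)
    cv <- evaluate_cv(dm, folds = 5, seed = s, k = 4, B = 58)
    # all-variable ridge baseline (no selection, no product terms)
    base_acc <- local({
      fold_id <- mgrselect:::.stratified_folds(dm$y, 5, seed = s)
      mean(sapply(1:5, function(f) {
        tr <- fold_id != f
        beta <- mgrselect:::.ridge_coef(dm$x[tr, ], dm$y[tr], 1)
        pred <- as.integer(
          mgrselect:::.ridge_predict(beta, dm$x[!tr, ]) >= 0.5)
        mean(pred == dm$y[!tr])
      }))
    })
    c(pipeline = unname(cv$average["accuracy"]), baseline = base_acc)
  })
  expect_gt(mean(accs["pipeline", ]), 0.6)
  expect_gte(mean(accs["pipeline", ]), mean(accs["baseline", ]))
})
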