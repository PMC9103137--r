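test_that("initial-size calculators match direct arithmetic", {
  b72 <- initial_size_bounds(72)
  expect_equal(b72$poisson_bound, 12L)  # 72^2 / 2^12 = 1.27 >= 1, /2^13 < 1
  expect_equal(b72$adequacy_bound, 4L)  # 72 / 2^4 = 4.5 >= 4, /2^5 < 4
  expect_equal(b72$recommended, c(4L, 12L))
  expect_warning(b1 <- initial_size_bounds(1), "too small")
  expect_equal(b1$poisson_bound, 0L)
  expect_equal(b1$adequacy_bound, 0L)
  # non-binary codes shrink both bounds
  b3 <- initial_size_bounds(72, categories = 3)
  expect_true(b3$poisson_bound < 12L && b3$adequacy_bound < 4L)
})

test_that("repetition calculator evaluates the coverage formula", {
  r <- bda_repetitions(p = 30, k = 6, z = 4)
  expect_equal(r$B_hat, ceiling(choose(30, 4) / choose(6, 4) *
                                  log(choose(30, 4))))
  expect_equal(r$B_hat, 18670)
  expect_equal(r$upper_bound, 2 * 18670)
  expect_equal(bda_repetitions(10, 10, 1)$B_hat, ceiling(log(10)))
  expect_error(bda_repetitions(5, 6, 2), "z <= k <= p")
})

test_that("backward dropping returns the best pending combination", {
  dm <- gen_module2(n = 200, seed = 3)
  rs <- backward_drop(dm, c(1, 2, 3, 4, 5), "mgr")
  expect_s3_class(rs, "return_set")
  expect_equal(nrow(rs$path), 5L)       # pending sizes 5 down to 1
  expect_equal(rs$path$size, 5:1)
  expect_equal(rs$score, max(rs$path$score))
  # the recorded score is the measure recomputed on the variables
  expect_equal(rs$score, mgr(dm, subset = rs$variables), tolerance = 1e-12)

  # single-variable initial subset returned unchanged
  rs1 <- backward_drop(dm, 7, "mgr")
  expect_equal(rs1$variables, 7L)

  # greedy never beats the exhaustive best subset of the initial set
  for (seed in 1:20) {
    dmr <- random_binary_dm(n = 60, p = 8, seed = seed)
    init <- sort(sample.int(8, 5))
    for (meas in c("mgr", "i_score")) {
      rs <- backward_drop(dmr, init, meas)
      expect_lte(rs$score, oracle_best_subset(dmr, init, meas) + 1e-12)
    }
  }
})

test_that("the planted pair is the usual core of signal-bearing starts", {
  # over seeded starts containing {2,3}, the return set usually keeps the pair
  core <- 0L
  runs <- 0L
  for (s in 1:40) {
    dm <- gen_module2(n = 200, seed = 1200 + s)
    set.seed(s)
    extra <- sample(setdiff(4:10, 1), 3)
    init <- sort(c(2L, 3L, extra))       # X1 excluded: pair pathway only
    rs <- backward_drop(dm, init, "mgr")
    runs <- runs + 1L
    if (all(c(2L, 3L) %in% rs$variables)) core <- core + 1L
  }
  expect_gt(core / runs, 0.5)
})

test_that("run_bda is seed-stable and collapses duplicate return sets", {
  dm <- gen_module2(seed = 21)
  r1 <- run_bda(dm, k = 4, B = 40, seed = 9)
  r2 <- run_bda(dm, k = 4, B = 40, seed = 9)
  expect_identical(lapply(r1, `[[`, "variables"),
                   lapply(r2, `[[`, "variables"))
  expect_identical(vapply(r1, `[[`, numeric(1), "score"),
                   vapply(r2, `[[`, numeric(1), "score"))
  keys <- vapply(r1, function(s) paste(s$variables, collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(diff(vapply(r1, `[[`, numeric(1), "score")) <= 1e-12))
  expect_error(run_bda(dm, k = 11, B = 5), "exceeds p")

  # B = 1 reproduces a single backward drop
  set.seed(33)
  init <- sort(sample.int(dm$p, 4))
  single <- local({
    r <- run_bda(dm, k = 4, B = 1, seed = 33)
    r[[1]]
  })
  expect_equal(single$variables, backward_drop(dm, init, "mgr")$variables)
})

test_that("initial draws cover all z-subsets at the calculated repetitions", {
  p <- 10
  k <- 5
  z <- 2
  B <- bda_repetitions(p, k, z)$upper_bound
  all_pairs <- utils::combn(p, z)
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    seen <- matrix(FALSE, p, p)
    for (b in seq_len(B)) {
      init <- sample.int(p, k)
      prs <- utils::combn(sort(init), 2)
      seen[t(prs)] <- TRUE
    }
    covered <- all(apply(all_pairs, 2, function(pr) seen[pr[1], pr[2]]))
    if (covered) ok <- ok + 1L
  }
  expect_gte(ok / 20, 0.95)
})

test_that("overlap filtering keeps disjoint high scorers", {
  mk <- function(v, s) structure(list(variables = as.integer(v), score = s),
                                 class = "return_set")
  out <- filter_overlaps(list(mk(c(1, 2), 0.9), mk(c(2, 3), 0.8), mk(4, 0.5)))
  expect_equal(lapply(out, `[[`, "variables"), list(c(1L, 2L), 4L))

  disj <- filter_overlaps(list(mk(1, 0.3), mk(2, 0.2), mk(3, 0.1)))
  expect_equal(length(disj), 3L)

  # equal scores: lexicographically smaller variable set wins
  tie <- filter_overlaps(list(mk(c(2, 5), 0.4), mk(c(1, 5), 0.4)))
  expect_equal(tie[[1]]$variables, c(1L, 5L))
  expect_equal(length(tie), 1L)
})

test_that("forward adding drops null passengers but keeps real signal", {
  dropped <- 0L
  for (s in 1:20) {
    dm <- gen_module2(n = 300, seed = 400 + s)
    rs <- list(structure(list(variables = c(2L, 3L, 7L), score = NA_real_),
                         class = "return_set"))
    out <- forward_add(dm, rs, "mgr")
    expect_true(all(c(2L, 3L) %in% out[[1]]$variables))
    if (!7L %in% out[[1]]$variables) dropped <- dropped + 1L
    expect_equal(out[[1]]$score, mgr(dm, subset = out[[1]]$variables),
                 tolerance = 1e-12)
  }
  expect_gt(dropped / 20, 0.5)

  # singleton unchanged; fully contributing sets unchanged
  dm <- gen_module2(n = 400, seed = 77)
  s1 <- forward_add(dm, list(structure(list(variables = 4L, score = 0),
                                       class = "return_set")), "mgr")
  expect_equal(s1[[1]]$variables, 4L)
  set.seed(78)
  x <- matrix(sample(0:1, 400 * 5, replace = TRUE), 400, 5)
  y <- (x[, 1] + x[, 2] + x[, 3]) %% 2L
  dm3 <- discrete_matrix(x, y)
  s3 <- forward_add(dm3, list(structure(list(variables = 1:3, score = NA_real_),
                                        class = "return_set")), "mgr")
  expect_equal(s3[[1]]$variables, 1:3)
})

test_that("null return-set sizes reflect each measure's size-bias growth", {
  # mgr's null bias accelerates with subset size, so on pure-noise starts
  # the backward drop tends to keep the full initial subset; the i-score's
  # bias saturates, so it sheds variables more readily
  sizes <- sapply(1:12, function(s) {
    dm <- gen_null(n = 200, p = 10, seed = 3000 + s)
    mean_size <- function(meas) {
      rs <- run_bda(dm, k = 5, B = 20, measure = meas, seed = s)
      mean(lengths(lapply(rs, `[[`, "variables")))
    }
    c(mgr = mean_size("mgr"), i = mean_size("i_score"))
  })
  expect_gt(mean(sizes["mgr", ]), mean(sizes["i", ]))
  # signal-bearing data: both measures isolate the planted structure
  dm <- gen_module2(n = 200, seed = 901)
  for (meas in c("mgr", "i_score")) {
    fin <- forward_add(dm, filter_overlaps(
      run_bda(dm, k = 5, B = 40, measure = meas, seed = 1)), meas)
    sets <- lapply(fin, `[[`, "variables")
    expect_true(any(vapply(sets, identical, logical(1), 1L)))
    expect_true(any(vapply(sets, identical, logical(1), c(2L, 3L))))
  }
})
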