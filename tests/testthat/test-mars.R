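test_that("least-squares solver matches the normal-equations oracle", {
  set.seed(3)
  for (i in 1:10) {
    B <- cbind(1, matrix(rnorm(6), 6, 1))
    y <- rnorm(6)
    got <- fit_least_squares(B, y, ridge_eps = 1e-8)
    want <- oracle_ridge(B, y, eps = 1e-8)
    expect_equal(got$coefficients, want$coefficients, tolerance = 1e-8)
    expect_equal(got$rss, want$rss, tolerance = 1e-8)
  }
})

test_that("least-squares handles exact fits and rank deficiency", {
  B <- cbind(1, c(0, 1, 2, 3))
  y <- 2 + 5 * B[, 2]  # in the column span
  expect_lt(fit_least_squares(B, y, ridge_eps = 0)$rss, 1e-10)

  Bdup <- cbind(B, B[, 2])  # duplicated column
  got <- fit_least_squares(Bdup, y, ridge_eps = 1e-8)
  expect_true(all(is.finite(got$coefficients)))
  expect_lt(got$rss, 1e-6)

  expect_error(fit_least_squares(matrix(1, 0, 1), numeric()), "non-empty")
  expect_error(fit_least_squares(matrix(1, 3, 1), c(1, 2)), "do not match")
})

test_that("GCV follows the penalized-residual formula with an n-guard", {
  expect_equal(gcv_score(0, 10, 1, 0), 0)
  expect_equal(gcv_score(10, 10, 1, 0, penalty = 3), 1 / 0.81)
  expect_identical(gcv_score(1, 10, 4, 2, penalty = 3), Inf)  # C = 10 >= n
  expect_error(gcv_score(-1, 10, 1, 0), "rss")

  # strictly increasing in rss at fixed complexity
  expect_lt(gcv_score(5, 30, 3, 2), gcv_score(6, 30, 3, 2))
  # weakly increasing in complexity at fixed rss (while C < n)
  expect_lte(gcv_score(5, 30, 3, 2), gcv_score(5, 30, 4, 3))
})

test_that("forward pass finds the best first split (exhaustive oracle)", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    m <- sample(1:3, 1)
    X <- random_design(n, m)
    y <- rnorm(n)
    if (length(unique(y)) < 2) next
    fwd <- forward_pass(X, y, fit_config())
    want <- oracle_first_split(X, y)
    if (is.null(want)) {
      expect_identical(length(fwd$bases), 1L)
      next
    }
    # the accepted first split must be the enumerated optimum
    if (length(fwd$bases) > 1L) {
      first <- fwd$bases[[2]]
      expect_equal(first$vars[1], want$v)
      expect_equal(first$knots[1], want$t)
    }
  }
})

test_that("forward pass fits noiseless indicator targets exactly", {
  d <- binary_design(2, reps = 3)
  X <- dose_matrix(d)

  # constant response: intercept only
  fwd <- forward_pass(d, rep(4, nrow(d)), fit_config())
  expect_identical(length(fwd$bases), 1L)
  expect_lt(fwd$rss, 1e-10)

  # main effect on variable 1
  y <- 3 * X[, 1]
  fwd <- forward_pass(d, y, fit_config())
  expect_equal(fwd$bases[[2]]$vars, 1L)
  expect_lt(fwd$rss, 1e-10)

  # pure interaction needs a degree-2 basis
  y2 <- 5 * (X[, 1] > 0) * (X[, 2] > 0)
  fwd2 <- forward_pass(d, y2, fit_config())
  degs <- vapply(fwd2$bases, basis_degree, integer(1))
  expect_true(any(degs == 2L))
  expect_lt(fwd2$rss, 1e-10)
})

test_that("forward pass never increases RSS along accepted steps", {
  set.seed(21)
  d <- binary_design(3, reps = 2)
  X <- dose_matrix(d)
  y <- 1 + 2 * X[, 1] + rnorm(nrow(d), sd = 0.3)
  fwd <- forward_pass(d, y, fit_config())
  # every prefix of the accepted bases must fit no better than the full set
  rss_prefix <- vapply(seq_along(fwd$bases), function(k) {
    fit_least_squares(build_basis_matrix(fwd$bases[seq_len(k)], X), y,
                      1e-8)$rss
  }, numeric(1))
  expect_true(all(diff(rss_prefix) <= 1e-8))
})

test_that("backward pass returns the GCV optimum on its deletion path", {
  set.seed(5)
  for (i in 1:8) {
    d <- binary_design(3, reps = 2)
    X <- dose_matrix(d)
    y <- 1 + 1.5 * X[, 1] + 2 * X[, 2] * X[, 3] + rnorm(nrow(d), sd = 0.5)
    cfg <- fit_config(max_terms = 7)  # oracle enumerates <= 6 terms
    fwd <- forward_pass(d, y, cfg)
    if (length(fwd$bases) - 1L > 6L) next  # oracle sized for <= 6 terms
    pruned <- backward_pass(fwd, d, y, cfg)
    opt <- oracle_best_subset(fwd, d, y, penalty = cfg$gcv_penalty)
    # greedy can never beat the exhaustive optimum
    expect_gte(pruned$gcv, opt$gcv - 1e-8 * max(1, opt$gcv))
    # and must equal it whenever the optimum lies on the deletion path
    on_path <- any(vapply(pruned$prune_path, function(s)
      identical(sort(s$idx), sort(opt$idx)), logical(1)))
    if (on_path)
      expect_equal(pruned$gcv, opt$gcv, tolerance = 1e-8)
  }
})

test_that("backward pass leaves an intercept-only model unchanged", {
  d <- binary_design(2, reps = 3)
  y <- rep(2.5, nrow(d))
  fwd <- forward_pass(d, y, fit_config())
  pruned <- backward_pass(fwd, d, y, fit_config())
  expect_identical(length(pruned$bases), 1L)
  expect_equal(pruned$coefficients[1], 2.5)
})

test_that("pure-noise responses are usually pruned to the intercept", {
  set.seed(17)
  d <- generate_design()  # 36 rows
  cfg <- fit_config()
  n_intercept_only <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    y <- rnorm(nrow(d), mean = 10, sd = 1)
    m <- mars(d, y, cfg)
    if (length(m$bases) == 1L) n_intercept_only <- n_intercept_only + 1L
  }
  expect_gte(n_intercept_only / n_seeds, 0.6)
})

test_that("mars recovers representable targets and reports consistent rss", {
  d <- binary_design(2, reps = 3)
  X <- dose_matrix(d)
  y <- 1 + 2 * (X[, 1] > 0) + 3 * (X[, 2] > 0)
  m <- mars(d, y)
  expect_lt(m$rss, 1e-10)
  r2 <- 1 - m$rss / sum((y - mean(y))^2)
  expect_gt(r2, 0.999)
  # stored rss equals the residual sum of squares of the predictions
  expect_equal(sum((y - predict(m, d))^2), m$rss, tolerance = 1e-8)

  # constant response: single coefficient equal to the constant
  mc <- mars(d, rep(7, nrow(d)))
  expect_identical(length(mc$coefficients), 1L)
  expect_equal(mc$coefficients[1], 7)
})

test_that("prediction at the all-zero dose row returns the intercept", {
  d <- binary_design(2, reps = 3)
  X <- dose_matrix(d)
  y <- 2 + 4 * (X[, 1] > 0)
  m <- mars(d, y)
  zero_row <- matrix(0, 1, 2)
  expect_equal(drop(predict(m, zero_row)), m$coefficients[1])
  expect_error(predict(m, matrix(0, 1, 5)), "probiotic columns")
})

test_that("fits are equivariant under relabeling of the probiotic columns", {
  set.seed(31)
  d <- binary_design(3, reps = 2)
  X <- dose_matrix(d)
  y <- 1 + 2 * X[, 2] + 3 * X[, 1] * X[, 3] + rnorm(nrow(d), sd = 0.1)
  perm <- c(3L, 1L, 2L)
  Xp <- X[, perm]
  colnames(Xp) <- colnames(X)[perm]
  m1 <- mars(X, y)
  m2 <- mars(Xp, y)
  # identical predictions on the training rows under the relabeling
  expect_equal(predict(m2, Xp), predict(m1, X), tolerance = 1e-8)
  expect_equal(m2$rss, m1$rss, tolerance = 1e-8)
})
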