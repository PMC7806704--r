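test_that("basis evaluation multiplies hinge factors", {
  expect_equal(evaluate_basis(hinge_basis(), c(5, -3)), 1)  # intercept
  b1 <- hinge_basis(vars = 1, knots = 0, dirs = 1)
  expect_equal(evaluate_basis(b1, c(2, 5)), 2)
  b2 <- hinge_basis(vars = c(1, 2), knots = c(1, 0), dirs = c(1, 1))
  expect_equal(evaluate_basis(b2, c(3, 2)), 4)
  bneg <- hinge_basis(vars = 1, knots = 2, dirs = -1)
  expect_equal(evaluate_basis(bneg, c(0.5, 9)), 1.5)
  expect_equal(evaluate_basis(bneg, c(3, 9)), 0)
})

test_that("basis construction rejects invalid factor sets", {
  expect_error(hinge_basis(vars = c(1, 1), knots = c(0, 1), dirs = c(1, 1)),
               "same variable")
  expect_error(hinge_basis(vars = 1, knots = Inf, dirs = 1), "finite")
  expect_error(hinge_basis(vars = 1, knots = 0, dirs = 2), "\\+1 or -1")
  expect_error(evaluate_basis(hinge_basis(vars = 3, knots = 0, dirs = 1),
                              c(1, 2)),
               "exceeds design width")
})

test_that("basis matrix has an all-ones intercept column and tracks rows", {
  X <- matrix(c(0, 1, 1), ncol = 1, dimnames = list(NULL, "A"))
  bases <- list(hinge_basis(), hinge_basis(vars = 1, knots = 0, dirs = 1))
  B <- build_basis_matrix(bases, X)
  expect_equal(B[, 1], rep(1, 3))
  expect_equal(B[, 2], c(0, 1, 1))

  # duplicated design rows give duplicated matrix rows
  Xdup <- X[c(1, 2, 2, 3), , drop = FALSE]
  Bdup <- build_basis_matrix(bases, Xdup)
  expect_identical(Bdup[2, ], Bdup[3, ])
  expect_error(build_basis_matrix(bases, X[0, , drop = FALSE]), "no rows")
})

test_that("hinge identity h(x-t) - h(t-x) = x - t holds on a grid", {
  grid <- expand.grid(x = seq(-3, 3, by = 0.25), t = seq(-2, 2, by = 0.5))
  expect_equal(hinge(grid$x - grid$t) - hinge(grid$t - grid$x),
               grid$x - grid$t)
})

test_that("every basis column is non-negative on random designs", {
  set.seed(11)
  for (i in 1:20) {
    X <- random_design(10, 3)
    b <- hinge_basis(vars = sample(3, 2), knots = runif(2, -1, 2),
                     dirs = sample(c(-1L, 1L), 2, replace = TRUE))
    expect_true(all(evaluate_basis(b, X) >= 0))
  }
})
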