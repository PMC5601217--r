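test_that("single identical columns give a perfect first canonical correlation", {
  x <- with_seed(1, scale(rnorm(30)))
  fit <- cca(cbind(a = as.numeric(x)), cbind(b = as.numeric(x)))
  expect_equal(fit$r[1], 1, tolerance = 1e-10)
})

test_that("two single columns give r1 = |sample correlation| exactly", {
  d <- with_seed(2, list(x = rnorm(40), y = rnorm(40)))
  fit <- cca(cbind(d$x), cbind(d$y))
  expect_equal(fit$r[1], abs(cor(d$x, d$y)), tolerance = 1e-12)
})

test_that("SVD solution matches the generalized-eigenproblem oracle", {
  for (s in 1:10) {
    d <- with_seed(100 + s, list(X = matrix(rnorm(30 * 4), 30, 4),
                                 Y = matrix(rnorm(30 * 6), 30, 6)))
    fit <- cca(d$X, d$Y)
    orc <- cca_oracle(d$X, d$Y)
    expect_equal(fit$r, orc$r[seq_len(fit$m)], tolerance = 1e-8)
    # weights match up to scale and sign
    for (j in seq_len(fit$m)) {
      a1 <- fit$a[, j] / sqrt(sum(fit$a[, j]^2))
      a2 <- orc$a[, j] / sqrt(sum(orc$a[, j]^2))
      expect_lt(min(sum((a1 - a2)^2), sum((a1 + a2)^2)), 1e-8)
    }
  }
})

test_that("model invariants hold: ordering, variate correlations, orthogonality", {
  d <- with_seed(7, list(X = matrix(rnorm(50 * 5), 50, 5),
                         Y = matrix(rnorm(50 * 7), 50, 7)))
  fit <- cca(d$X, d$Y)
  expect_true(all(diff(fit$r) <= 1e-12))
  for (i in seq_len(fit$m))
    expect_equal(cor(fit$U[, i], fit$V[, i]), fit$r[i], tolerance = 1e-8)
  cu <- cor(fit$U); cv <- cor(fit$V)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-6)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-6)
  expect_lte(fit$m, min(ncol(d$X), ncol(d$Y), nrow(d$X) - 1))
})

test_that("canonical correlations are invariant to affine column rescaling", {
  d <- with_seed(8, list(X = matrix(rnorm(40 * 4), 40, 4),
                         Y = matrix(rnorm(40 * 5), 40, 5)))
  f1 <- cca(d$X, d$Y)
  x2 <- sweep(d$X, 2, c(1000, 0.001, 3, 42), "*")
  x2 <- sweep(x2, 2, c(-5, 7, 0, 100), "+")
  f2 <- cca(x2, d$Y)
  expect_equal(f1$r, f2$r, tolerance = 1e-8)
})

test_that("rank-deficient blocks are rejected unless ridge regularization is on", {
  x <- with_seed(9, matrix(rnorm(30 * 3), 30, 3))
  xd <- cbind(x, x[, 1] + x[, 2])
  y <- with_seed(10, matrix(rnorm(30 * 4), 30, 4))
  expect_error(cca(xd, y), "rank deficient")
  fit <- cca(xd, y, ridge = 1e-6)
  expect_s3_class(fit, "cca")
  expect_true(all(is.finite(fit$r)))
})

test_that("predict reproduces training variates and respects centering/linearity", {
  d <- with_seed(11, list(X = matrix(rnorm(40 * 4), 40, 4),
                          Y = matrix(rnorm(40 * 5), 40, 5)))
  fit <- cca(d$X, d$Y)
  pr <- predict(fit, X = d$X, Y = d$Y)
  expect_equal(pr$U, fit$U, tolerance = 1e-10)
  expect_equal(pr$V, fit$V, tolerance = 1e-10)
  # a row at the column means projects to zero
  at_mean <- matrix(colMeans(d$X), 1)
  expect_lt(max(abs(predict(fit, X = at_mean)$U)), 1e-10)
  # duplicated subject rows give duplicated variate rows
  dup <- d$X[c(1, 1, 2), ]
  pu <- predict(fit, X = dup)$U
  expect_equal(pu[1, ], pu[2, ], tolerance = 1e-12)
  expect_error(predict(fit, X = d$X[, 1:2]), "columns")
})

test_that("loadings are own-block correlations; sign convention favors the top variable", {
  d <- with_seed(12, list(X = matrix(rnorm(60 * 3), 60, 3),
                          Y = matrix(rnorm(60 * 4), 60, 4)))
  fit <- cca_fit(d$X, d$Y)
  lo <- cca_loadings(fit)
  expect_equal(lo$clinical, cor(d$X, fit$U), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(lo$clinical) <= 1 + 1e-12))
  for (i in seq_len(fit$m)) {
    j <- which.max(abs(lo$clinical[, i]))
    expect_gte(lo$clinical[j, i], 0)
  }
  # p = 1: the single variable is its own variate, loading 1
  f1 <- cca_fit(cbind(only = d$X[, 1]), d$Y)
  lo1 <- cca_loadings(f1)
  expect_equal(abs(lo1$clinical[1, 1]), 1, tolerance = 1e-10)
})

test_that("loadings and weights may disagree in sign", {
  # x2 correlates positively with the latent but receives a negative weight
  # because x1 already carries the latent plus shared noise
  d <- with_seed(13, {
    z <- rnorm(300); e <- rnorm(300)
    list(X = cbind(x1 = z + e, x2 = 0.5 * z + e),
         Y = cbind(y = z, matrix(rnorm(600), 300, 2)))
  })
  fit <- cca_fit(d$X, d$Y)
  lo <- cca_loadings(fit)
  expect_gt(lo$clinical["x2", 1], 0)
  expect_lt(fit$a["x2", 1], 0)
})

test_that("sample canonical correlation converges to the planted value with n", {
  err <- vapply(c(500, 5000), function(n) {
    med <- median(vapply(1:10, function(s) {
      d <- toy_blocks(n, 0.7, p = 3, k = 4, seed = 7000 + 17 * s + n)
      abs(cca(d$X, d$Y)$r[1] - 0.7)
    }, numeric(1)))
    med
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("zero-variance variables yield NA loadings with a warning", {
  d <- with_seed(14, list(X = matrix(rnorm(30 * 3), 30, 3),
                          Y = matrix(rnorm(30 * 3), 30, 3)))
  xz <- cbind(d$X, flat = rep(1, 30))
  fit <- cca_fit(xz, d$Y, ridge = 1e-8)
  expect_warning(lo <- cca_loadings(fit), "zero-variance")
  expect_true(all(is.na(lo$clinical[4, ])))
  expect_false(anyNA(lo$clinical[1:3, ]))
})
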