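test_that("outlier screening applies the floor and mean+3SD rules once", {
  r <- screen_outliers(c(90, 300, 310))
  expect_equal(r$removed, 90)
  expect_equal(r$kept, c(300, 310))
  # constant sample: only the floor rule can remove anything
  r <- screen_outliers(rep(200, 20))
  expect_equal(length(r$removed), 0)
  r <- screen_outliers(c(rep(200, 20), 50))
  expect_equal(r$removed, 50)
  # 49 x 200 plus one 2000: direct arithmetic decides the ceiling
  x <- c(rep(200, 49), 2000)
  m <- sum(x) / 50
  s <- sqrt(sum((x - m)^2) / 49)
  expect_lt(m + 3 * s, 2000)
  r <- screen_outliers(x)
  expect_equal(r$removed, 2000)
  expect_equal(length(r$kept), 49)
  expect_error(screen_outliers(numeric(0)), "empty")
})

test_that("quantiles interpolate the order statistics", {
  expect_equal(unname(rt_quantiles(1:9, 0.5)), 5)
  expect_equal(unname(rt_quantiles(rep(7, 12))), rep(7, 5))
  # 20-point sample against a direct order-statistic interpolation
  set.seed(8)
  x <- sort(rnorm(20, 400, 60))
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    h <- (20 - 1) * p + 1
    manual <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
    expect_equal(unname(rt_quantiles(x, p)), manual)
  }
  expect_true(all(diff(rt_quantiles(rnorm(100, 400, 50),
                                    seq(0.1, 0.9, 0.1))) >= 0))
  expect_error(rt_quantiles(1:50, c(0, 0.5)), "strictly")
  expect_error(rt_quantiles(1:3, c(0.1, 0.3, 0.5, 0.7, 0.9)), "smaller")
})

test_that("delta plots capture location shifts exactly", {
  set.seed(9)
  x <- rnorm(400, 400, 50)
  # identical samples: all zero
  dp0 <- delta_plot(x, x)
  expect_equal(dp0$deltas, rep(0, 5))
  expect_equal(c(dp0$c0, dp0$c1, dp0$c2), c(0, 0, 0))
  # pure 20 ms shift: constant deltas, level term only
  dp <- delta_plot(x, x + 20)
  expect_equal(dp$deltas, rep(20, 5), tolerance = 1e-12)
  expect_equal(dp$c0, 20 * sqrt(5))  # unit-norm constant basis
  expect_equal(dp$c1, 0, tolerance = 1e-9)
  expect_equal(dp$c2, 0, tolerance = 1e-9)
  # two small samples against hand-computed quantile differences
  a <- c(310, 320, 335, 350, 360, 370, 385, 400, 420, 450)
  b <- c(325, 345, 350, 370, 385, 395, 410, 430, 455, 490)
  dp2 <- delta_plot(a, b)
  expect_equal(dp2$deltas,
               unname(quantile(b, c(.1, .3, .5, .7, .9), type = 7) -
                      quantile(a, c(.1, .3, .5, .7, .9), type = 7)))
  expect_equal(dp2$means,
               unname((quantile(b, c(.1, .3, .5, .7, .9), type = 7) +
                       quantile(a, c(.1, .3, .5, .7, .9), type = 7)) / 2))
})

test_that("orthogonal polynomials on unequal spacing reproduce least squares", {
  x <- c(302, 341, 377, 419, 486)  # realistic unequal quantile means
  set.seed(10)
  y <- rnorm(5, 20, 5)
  fit <- fit_orthogonal_polys(x, y, 2)
  # basis orthonormality
  g <- crossprod(fit$basis)
  expect_lt(max(abs(g - diag(3))), 1e-10)
  # reconstruction equals the directly solved quadratic least squares
  X <- cbind(1, x, x^2)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit$fitted, drop(X %*% beta), tolerance = 1e-10)
  # constant and linear data load only the low-order terms
  cfit <- fit_orthogonal_polys(x, rep(4, 5), 2)$coefficients
  expect_equal(unname(cfit), c(4 * sqrt(5), 0, 0), tolerance = 1e-10)
  lfit <- fit_orthogonal_polys(x, 2 + 0.05 * x, 2)$coefficients
  expect_equal(unname(lfit["c2"]), 0, tolerance = 1e-10)
  # adding a constant to y moves only c0
  f1 <- fit_orthogonal_polys(x, y, 2)$coefficients
  f2 <- fit_orthogonal_polys(x, y + 100, 2)$coefficients
  expect_equal(f1[c("c1", "c2")], f2[c("c1", "c2")], tolerance = 1e-9)
  expect_error(fit_orthogonal_polys(rep(5, 5), y, 2), "degenerate|collinear")
  expect_error(fit_orthogonal_polys(x[1:2], y[1:2], 2), "at least")
})

test_that("the pairwise-difference scale estimator matches exhaustive enumeration", {
  # worked example: pairwise |differences| of {1,2,3} are {1,1,2};
  # h = 2, k = C(2,2) = 1, so the estimate is 1 times the constant
  expect_equal(robust_scale(c(1, 2, 3)), 2.2219)
  expect_equal(robust_scale(rep(6, 8)), 0)
  # exhaustive enumeration oracle for all n up to 10
  set.seed(11)
  for (n in 2:10) {
    x <- rnorm(n, 400, 50)
    d <- sort(as.vector(dist(x)))
    k <- choose(floor(n / 2) + 1, 2)
    expect_equal(robust_scale(x), 2.2219 * d[k])
  }
  # translation invariance and scale equivariance
  x <- rnorm(25, 400, 50)
  expect_equal(robust_scale(x + 123), robust_scale(x))
  expect_equal(robust_scale(-2.5 * x), 2.5 * robust_scale(x))
})

test_that("pooling aligns participants and preserves the grand mean", {
  # single participant: the transform is the identity
  x <- c(300, 350, 420, 500)
  ps <- pool_participants(list(a = x))
  expect_equal(ps$pooled, x)

  # two participants with means 300/600 and scales q/2q: closed form
  x1 <- c(280, 300, 320)
  x2 <- 2 * x1  # mean 600, robust scale doubled
  ps <- pool_participants(list(a = x1, b = x2))
  expect_equal(ps$m_dot, 450)
  expect_equal(unname(ps$q_i["b"]), 2 * unname(ps$q_i["a"]))
  expect_equal(ps$transformed$a, 450 + (x1 - 300) * 1.5)
  expect_equal(ps$transformed$b, 450 + (x2 - 600) * 0.75)
  expect_equal(mean(ps$pooled), 450)

  # grand-mean identity and rank preservation on random heterogeneous data
  set.seed(12)
  samples <- lapply(1:6, function(i)
    rnorm(30 + 5 * i, 300 + 40 * i, 30 + 8 * i))
  names(samples) <- paste0("P", 1:6)
  ps <- pool_participants(samples)
  expect_equal(mean(ps$pooled), ps$m_dot, tolerance = 1e-9)
  for (nm in names(samples))
    expect_equal(order(ps$transformed[[nm]]), order(samples[[nm]]))
  expect_equal(length(ps$pooled), sum(lengths(samples)))

  # degenerate participants are named in the error
  expect_error(pool_participants(list(ok = c(1, 2, 3),
                                      flat = c(5, 5, 5))), "flat")
})
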