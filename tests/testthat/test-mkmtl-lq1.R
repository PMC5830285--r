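test_that("lemma1_minimizer closed forms", {
  r1 <- lemma1_minimizer(c(1, 1), 1)
  expect_equal(r1$eta, c(0.5, 0.5))
  expect_equal(r1$value, 4)
  r2 <- lemma1_minimizer(c(1, 0), 1)
  expect_equal(r2$eta, c(1, 0))
  expect_equal(r2$value, 1)
  r3 <- lemma1_minimizer(c(4, 1), 1)
  expect_equal(r3$eta, c(2 / 3, 1 / 3))
  expect_equal(r3$value, 9)
  expect_error(lemma1_minimizer(c(-1, 2), 1), "input error")
})

test_that("lemma1_minimizer agrees with numerical minimization", {
  set.seed(18)
  for (r in c(1, 2)) {
    for (rep in 1:4) {
      a <- runif(4, 0.2, 3)
      cf <- lemma1_minimizer(a, r)
      ref <- ref_lemma1_optim(a, r)
      expect_equal(cf$value, ref$value, tolerance = 1e-5)
      expect_equal(cf$eta, ref$eta, tolerance = 1e-3, ignore_attr = TRUE)
    }
  }
})

test_that("solve_alpha reduces to kernel ridge regression for k = T = 1", {
  ds <- make_toy_ds(m = 30, p = 4, Tn = 1, seed = 19)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  lam <- 3
  alpha <- solve_alpha(pool, mu = 1, nu = matrix(1, 1, 1), lam = lam,
                       ylist = list(ds$Y[, 1]))
  K <- pool$grams[[1]]
  pred <- -as.vector(K %*% alpha[[1]])
  expect_equal(pred, as.vector(ref_krr(K, ds$Y[, 1], lam)), tolerance = 1e-10)
  # y = 0 -> alpha = 0
  a0 <- solve_alpha(pool, 1, matrix(1, 1, 1), lam, list(rep(0, 30)))
  expect_equal(a0[[1]], rep(0, 30))
  # small-lam limit: alpha ~ -lam * y
  tiny <- solve_alpha(pool, 1, matrix(1, 1, 1), 1e-6, list(ds$Y[, 1]))
  expect_equal(tiny[[1]], -1e-6 * ds$Y[, 1], tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("update_nu returns boundary weights with the right structure", {
  ds <- make_toy_ds(m = 20, p = 4, Tn = 3, seed = 20)
  pool <- build_pool(ds, specs = list(kernel_spec("linear"),
                                      kernel_spec("gaussian", 1)))
  alpha <- lapply(1:3, function(t) rnorm(20))
  expect_error(update_nu(pool, c(0.5, 0.5), alpha, q = 1.5),
               "configuration error")
  # q = 2 degenerate limit: nu fixed at 1
  expect_equal(update_nu(pool, c(0.5, 0.5), alpha, q = 2), matrix(1, 2, 3))
  # T = 1: a single task gets weight 1 whatever q
  a1 <- list(alpha[[1]])
  nu1 <- update_nu(pool, c(0.5, 0.5), a1, q = 3,
                   task_index = list(1:20))
  expect_equal(as.vector(nu1), rep(1, 2), tolerance = 1e-12)
  # q = 3 row maximizes the linear form over the qbar-ball
  nu <- update_nu(pool, c(0.5, 0.5), alpha, q = 3)
  qbar <- 3
  expect_equal(rowSums(nu^qbar), rep(1, 2), tolerance = 1e-10)
  # cross-check row 1 against a numerical maximizer
  aj <- vapply(1:3, function(t) {
    0.5 * as.numeric(crossprod(alpha[[t]], pool$grams[[1]] %*% alpha[[t]]))
  }, 0)
  ref <- ref_numax_optim(aj, qbar)
  expect_equal(sum(nu[1, ] * aj), ref$value, tolerance = 1e-5)
  expect_equal(nu[1, ], ref$nu, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("update_mu follows the Lemma-1 closed form", {
  ds <- make_toy_ds(m = 15, p = 3, Tn = 2, seed = 21)
  pool <- build_pool(ds, specs = list(kernel_spec("linear"),
                                      kernel_spec("gaussian", 1)))
  alpha <- lapply(1:2, function(t) rnorm(15))
  nu <- matrix(1, 2, 2)
  mu <- update_mu(pool, nu, alpha)
  b <- vapply(1:2, function(j) {
    sum(vapply(1:2, function(t) {
      as.numeric(crossprod(alpha[[t]], pool$grams[[j]] %*% alpha[[t]]))
    }, 0))
  }, 0)
  expect_equal(mu, sqrt(b) / sum(sqrt(b)), tolerance = 1e-12)
  expect_equal(sum(mu), 1, tolerance = 1e-12)
})

test_that("fit_mkmtl: single kernel and task recovers KRR quickly", {
  ds <- make_toy_ds(m = 40, p = 5, Tn = 1, seed = 22)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  fit <- fit_mkmtl(ds, pool, q = 2, lam = 2, tol = 1e-10)
  K <- pool$grams[[1]]
  pred <- predict_mkmtl(fit, pool_cross(pool, ds$X))
  expect_equal(as.vector(pred),
               as.vector(ref_krr(K, ds$Y[, 1], 2)), tolerance = 1e-10)
  expect_lte(length(fit$objective_trace), 4)
})

test_that("fit_mkmtl: duplicated kernels leave predictions invariant", {
  ds <- make_toy_ds(m = 35, p = 5, Tn = 2, seed = 23)
  p1 <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  p2 <- build_pool(ds, specs = list(kernel_spec("gaussian", 1),
                                    kernel_spec("gaussian", 1)))
  f1 <- fit_mkmtl(ds, p1, q = 3, lam = 2, tol = 1e-10)
  f2 <- fit_mkmtl(ds, p2, q = 3, lam = 2, tol = 1e-10)
  Xn <- matrix(rnorm(10 * 5), 10, 5)
  expect_equal(predict(f1, Xn), predict(f2, Xn), tolerance = 1e-8)
})

test_that("fit_mkmtl trace is non-increasing and weights stay feasible", {
  ds <- make_toy_ds(m = 40, p = 6, Tn = 3, seed = 24)
  pool <- build_pool(ds)
  for (q in c(2.5, 3, Inf)) {
    fit <- fit_mkmtl(ds, pool, q = q, lam = 10, max_outer = 40)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
    expect_true(all(fit$feasibility_trace <= 1e-8))
    expect_equal(sum(fit$mu), 1, tolerance = 1e-10)
    expect_true(all(fit$mu >= 0))
    qbar <- if (is.infinite(q)) 1 else q / (q - 2)
    expect_true(all(rowSums(fit$nu^qbar) <= 1 + 1e-8))
  }
})

test_that("training residual is non-decreasing in the regularization", {
  # larger lam here scales the dual system toward interpolation, so the
  # residual decreases in lam: the ridge level is 1/lam
  ds <- make_toy_ds(m = 30, p = 4, Tn = 2, seed = 25)
  pool <- build_pool(ds)
  res <- vapply(c(0.1, 1, 10, 100), function(lam) {
    fit <- fit_mkmtl(ds, pool, q = 3, lam = lam, tol = 1e-9)
    sum((ds$Y - predict_mkmtl(fit, pool_cross(pool, ds$X)))^2)
  }, 0)
  expect_true(all(diff(res) <= 1e-8))
})

test_that("predict_mkmtl is linear in alpha and zero at alpha = 0", {
  ds <- make_toy_ds(m = 20, p = 4, Tn = 2, seed = 26)
  pool <- build_pool(ds, specs = list(kernel_spec("linear")))
  fit <- fit_mkmtl(ds, pool, q = 3, lam = 1, tol = 1e-8)
  cross <- pool_cross(pool, ds$X[1:5, ])
  fit0 <- fit
  fit0$alpha <- lapply(fit$alpha, function(a) a * 0)
  expect_equal(predict_mkmtl(fit0, cross), matrix(0, 5, 2),
               ignore_attr = TRUE)
  fit2 <- fit
  fit2$alpha <- lapply(fit$alpha, function(a) 2 * a)
  expect_equal(predict_mkmtl(fit2, cross), 2 * predict_mkmtl(fit, cross))
  expect_error(predict_mkmtl(fit, cross[0]), "shape mismatch")
})
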