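test_that("factor_kernels reconstructs Gram blocks", {
  # identity Gram: maps are orthonormal selector rows
  pool <- list(grams = list(diag(6) / 6), X = matrix(0, 6, 1), k = 1L)
  ti <- list(1:3, 4:6)
  fx <- factor_kernels(pool, ti)
  fj <- fx$factors[[1]]
  expect_equal(fj$rank, 6L)
  expect_equal(crossprod(fj$M[[1]], fj$M[[2]]), matrix(0, 3, 3),
               tolerance = 1e-12)
  expect_equal(crossprod(fj$M[[1]]), diag(3) / 6, tolerance = 1e-12)

  # rank-1 Gram
  v <- c(1, -2, 0.5)
  G1 <- tcrossprod(v)
  pool1 <- list(grams = list(G1), X = matrix(0, 3, 1), k = 1L)
  f1 <- factor_kernels(pool1, list(1:3))$factors[[1]]
  expect_equal(f1$rank, 1L)
  expect_equal(crossprod(f1$M[[1]]), G1, tolerance = 1e-10)

  # random PSD Gram, overlapping task blocks
  set.seed(27)
  B <- matrix(rnorm(25), 5, 5)
  G <- crossprod(B)
  poolr <- list(grams = list(G), X = matrix(0, 5, 1), k = 1L)
  tir <- list(1:3, 2:5)
  fr <- factor_kernels(poolr, tir)$factors[[1]]
  expect_lt(max(abs(crossprod(fr$M[[1]], fr$M[[2]]) - G[1:3, 2:5])), 1e-8)

  # non-PSD Gram rejected
  poolbad <- list(grams = list(matrix(c(1, 2, 2, 1), 2, 2)),
                  X = matrix(0, 2, 1), k = 1L)
  expect_error(factor_kernels(poolbad, list(1:2)), "not PSD")
})

test_that("solve_alpha_q special cases", {
  ds <- make_toy_ds(m = 25, p = 4, Tn = 2, seed = 28)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  ti <- list(1:25, 1:25)
  fx <- factor_kernels(pool, ti)
  ylist <- list(ds$Y[, 1], ds$Y[, 2])
  r <- fx$factors[[1]]$rank
  lam <- 2
  # Q = cI single kernel: scaled-kernel KRR
  cc <- 0.3
  al <- solve_alpha_q(fx, list(diag(cc, r)), lam, ylist)
  K <- pool$grams[[1]]
  for (t in 1:2) {
    expect_equal(al[[t]], -solve(cc * K + diag(1 / lam, 25), ylist[[t]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # y = 0 and Q = 0
  expect_equal(solve_alpha_q(fx, list(diag(cc, r)), lam,
                             list(rep(0, 25), rep(0, 25)))[[1]], rep(0, 25))
  a0 <- solve_alpha_q(fx, list(matrix(0, r, r)), lam, ylist)
  expect_equal(a0[[1]], -lam * ylist[[1]], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("objective_and_gradient matches its definition", {
  ds <- make_toy_ds(m = 20, p = 4, Tn = 2, seed = 29)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1),
                                      kernel_spec("linear")))
  ti <- list(1:20, 1:20)
  fx <- factor_kernels(pool, ti)
  ylist <- list(ds$Y[, 1], ds$Y[, 2])
  lam <- 1.5
  ranks <- vapply(fx$factors, function(f) f$rank, 0L)
  # Q = 0 value
  og0 <- objective_and_gradient(fx, lapply(ranks, function(r) matrix(0, r, r)),
                                lam, ylist)
  expect_equal(og0$f, sum(vapply(ylist, function(y) lam / 2 * sum(y^2), 0)),
               tolerance = 1e-10)
  # -2 * grad_j is PSD
  set.seed(30)
  Q <- project_Q(lapply(ranks, function(r) crossprod(matrix(rnorm(r * r), r))),
                 qbar = 2)
  og <- objective_and_gradient(fx, Q, lam, ylist)
  for (g in og$grad) {
    ev <- eigen(-2 * g, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  # central-difference agreement through the re-solved alpha
  eps <- 1e-5
  for (j in 1:2) {
    for (idx in list(c(1, 1), c(2, 3))) {
      Ep <- Q; Em <- Q
      D <- matrix(0, ranks[j], ranks[j])
      D[idx[1], idx[2]] <- eps / 2
      D[idx[2], idx[1]] <- D[idx[2], idx[1]] + eps / 2
      Ep[[j]] <- Q[[j]] + D
      Em[[j]] <- Q[[j]] - D
      fd <- (objective_and_gradient(fx, Ep, lam, ylist)$f -
               objective_and_gradient(fx, Em, lam, ylist)$f) / (2 * eps)
      sym_grad <- (og$grad[[j]][idx[1], idx[2]] +
                     og$grad[[j]][idx[2], idx[1]]) / 2
      expect_equal(fd, sym_grad, tolerance = 1e-4)
    }
  }
})

test_that("project_Q clips, rescales and is idempotent", {
  feas <- list(diag(0.2, 2), diag(0.1, 3))
  expect_equal(project_Q(feas, qbar = 1), feas, tolerance = 1e-12)
  # single block 2I_2 with qbar = 1 scales to trace 1
  out <- project_Q(list(diag(2, 2)), qbar = 1)
  expect_equal(out[[1]], diag(0.5, 2), tolerance = 1e-12)
  # negative eigenvalue clipped before scaling
  Qneg <- list(diag(c(1, -0.5)))
  out2 <- project_Q(Qneg, qbar = 1)
  ev <- eigen(out2[[1]], symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_lte(sum(diag(out2[[1]])), 1 + 1e-12)
  # double projection = single projection
  raw <- list(matrix(c(2, 1, 1, -1), 2, 2), diag(3, 2))
  p1 <- project_Q(raw, qbar = 1.5)
  expect_equal(project_Q(p1, qbar = 1.5), p1, tolerance = 1e-12)
})

test_that("fit_l21lq best-iterate bookkeeping and feasibility", {
  ds <- make_toy_ds(m = 30, p = 5, Tn = 2, seed = 31)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1),
                                      kernel_spec("linear")))
  fit <- fit_l21lq(ds, pool, q = 1.5, lam = 5, max_outer = 60)
  bt <- fit$best_trace
  expect_true(all(diff(bt) <= 0))
  expect_equal(fit$objective, min(fit$objective_trace))
  expect_lte(fit$objective, fit$objective_trace[1])  # <= f at Q_init
  expect_true(all(fit$feasibility_trace <= 1e-8))
  expect_lte(
    sum(vapply(fit$Q, function(Qj) sum(diag(Qj)), 0)^fit$qbar), 1 + 1e-9)
  expect_error(fit_l21lq(ds, pool, q = 2, lam = 1), "configuration error")
})

test_that("relaxing the trace bound never worsens the objective", {
  # the feasible sets are nested in the bound, so the attained objective is
  # non-increasing as the constraint relaxes (small slack for the
  # subgradient approximation)
  ds <- make_toy_ds(m = 30, p = 4, Tn = 1, seed = 32)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  fs <- vapply(c(0.5, 1, 5, 25), function(bnd) {
    fit_l21lq(ds, pool, q = 1, lam = 2, bound = bnd, max_outer = 150,
              tol = 1e-10)$objective
  }, 0)
  expect_true(all(diff(fs) <= 1e-6 * pmax(1, abs(fs[-length(fs)]))))
})

test_that("predict_l21lq: zero alpha, sign-flip invariance, KRR at Q = I", {
  ds <- make_toy_ds(m = 25, p = 4, Tn = 2, seed = 33)
  pool <- build_pool(ds, specs = list(kernel_spec("gaussian", 1)))
  ti <- list(1:25, 1:25)
  fx <- factor_kernels(pool, ti)
  r <- fx$factors[[1]]$rank
  lam <- 2
  ylist <- list(ds$Y[, 1], ds$Y[, 2])
  Q <- list(diag(1, r))
  alpha <- solve_alpha_q(fx, Q, lam, ylist)
  model <- structure(
    list(Q = Q, alpha = alpha, factors = fx, q = 1, qbar = 1, lam = lam,
         pool = pool, task_index = ti, task_names = ds$task_names),
    class = "mkmtl_l21lq")
  cross <- pool_cross(pool, ds$X)
  pred <- predict_l21lq(model, cross)
  K <- pool$grams[[1]]
  for (t in 1:2) {
    expect_equal(pred[, t], as.vector(ref_krr(K, ylist[[t]], lam)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # alpha = 0 -> zero predictions
  m0 <- model
  m0$alpha <- lapply(alpha, function(a) a * 0)
  expect_equal(predict_l21lq(m0, cross), matrix(0, 25, 2),
               ignore_attr = TRUE)
  # eigenvector sign flips leave predictions invariant
  m_flip <- model
  s <- rep(c(1, -1), length.out = r)
  m_flip$factors$factors[[1]]$V <- fx$factors[[1]]$V %*% diag(s)
  m_flip$factors$factors[[1]]$M <-
    lapply(fx$factors[[1]]$M, function(M) diag(s) %*% M)
  m_flip$Q <- list(diag(s) %*% Q[[1]] %*% diag(s))
  m_flip$alpha <- solve_alpha_q(m_flip$factors, m_flip$Q, lam, ylist)
  expect_equal(predict_l21lq(m_flip, cross), pred, tolerance = 1e-8)
  expect_error(predict_l21lq(model, cross[0]), "shape mismatch")
})
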