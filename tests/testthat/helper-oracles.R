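# Independent reference implementations used to cross-check the package's
# closed forms and solvers. These deliberately avoid the code paths they
# verify (general-purpose optimizers, plain ISTA, closed-form ridge).

# Row-wise lq prox by derivative-free minimization (small T only).
ref_prox_optim <- function(v, q, lam) {
  obj <- function(th) {
    pen <- if (is.infinite(q)) max(abs(th)) else sum(abs(th)^q)^(1 / q)
    0.5 * sum((th - v)^2) + lam * pen
  }
  best <- v
  best_f <- obj(v)
  for (start in list(v, v / 2, rep(0, length(v)) + 1e-3)) {
    res <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    if (res$value < best_f) {
      best <- res$par
      best_f <- res$value
    }
  }
  if (0.5 * sum(v^2) < best_f) best <- rep(0, length(v))
  best
}

# Momentum-free proximal gradient (ISTA) for the linear q=2 objective,
# using its own row-wise l2 shrink (not the package prox).
ref_ista_l21 <- function(X, Y, lam, max_iter = 50000L, tol = 1e-12) {
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  theta <- matrix(0, ncol(X), ncol(Y))
  obj <- function(Th) {
    R <- Y - X %*% Th
    0.5 * sum(R^2) + lam * sum(sqrt(rowSums(Th^2)))
  }
  f_prev <- obj(theta)
  for (l in seq_len(max_iter)) {
    G <- crossprod(X, X %*% theta - Y)
    V <- theta - G / L
    n2 <- sqrt(rowSums(V^2))
    shrink <- ifelse(n2 > lam / L, (n2 - lam / L) / pmax(n2, 1e-300), 0)
    theta <- V * shrink
    f <- obj(theta)
    if (abs(f_prev - f) <= tol * max(1, abs(f_prev))) break
    f_prev <- f
  }
  list(theta = theta, objective = obj(theta))
}

# Minimize sum(a / eta) over {eta >= 0, sum(eta^r) <= 1} through the
# boundary parametrization eta = z^2 / (sum((z^2)^r))^(1/r); the constrained
# problem becomes smooth and unconstrained in z.
ref_lemma1_optim <- function(a, r) {
  d <- length(a)
  to_eta <- function(z) {
    e <- z^2 + 1e-14
    e / sum(e^r)^(1 / r)
  }
  obj <- function(z) sum(a / to_eta(z))
  best <- NULL
  best_f <- Inf
  for (start in list(rep(1, d), sqrt(a + 0.1))) {
    for (mth in c("BFGS", "Nelder-Mead")) {
      res <- tryCatch(
        stats::optim(start, obj, method = mth,
                     control = list(maxit = 50000, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(res) && res$value < best_f) {
        best_f <- res$value
        best <- to_eta(res$par)
      }
    }
  }
  list(eta = best, value = best_f)
}

# Maximize sum(nu * a) over {nu >= 0, sum(nu^qbar) <= 1} (same boundary
# parametrization; the maximum sits on the constraint boundary).
ref_numax_optim <- function(a, qbar) {
  d <- length(a)
  to_nu <- function(z) {
    e <- z^2 + 1e-14
    e / sum(e^qbar)^(1 / qbar)
  }
  obj <- function(z) -sum(to_nu(z) * a)
  best <- NULL
  best_f <- Inf
  for (start in list(rep(1, d), sqrt(a + 0.1))) {
    for (mth in c("BFGS", "Nelder-Mead")) {
      res <- tryCatch(
        stats::optim(start, obj, method = mth,
                     control = list(maxit = 50000, reltol = 1e-15)),
        error = function(e) NULL)
      if (!is.null(res) && res$value < best_f) {
        best_f <- res$value
        best <- to_nu(res$par)
      }
    }
  }
  list(nu = best, value = -best_f)
}

# Closed-form kernel ridge regression with ridge 1/lam:
# yhat = Kcross (K + I/lam)^{-1} y
ref_krr <- function(K, y, lam, Kcross = K) {
  Kcross %*% solve(K + diag(1 / lam, nrow(K)), y)
}

# A small fully observed linear multitask dataset.
make_toy_ds <- function(m = 40, p = 6, Tn = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(m * p), m, p)
  theta <- matrix(rnorm(p * Tn), p, Tn)
  Y <- X %*% theta + 0.1 * matrix(rnorm(m * Tn), m, Tn)
  multitask_dataset(X, Y)
}
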