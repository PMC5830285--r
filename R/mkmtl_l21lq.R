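# l2,1-lq multikernel multitask regression.
#
# Each base kernel j contributes an implicit feature map; a symmetric PSD
# matrix Q_j acting in the kernel-j factor space couples the tasks, under the
# mixed trace constraint sum_j tr(Q_j)^qbar <= 1 with qbar = q/(2-q),
# q in [1, 2). Everything is kernelized through the eigendecomposition of the
# pooled Gram G_j = V S^2 V': the per-task maps M_tj = S^{-1} V' G_j[, t-cols]
# satisfy M_tj' M_t'j = G_j[t-cols, t'-cols], so no explicit features are
# formed. The outer problem min_Q f(Q), with f the optimal-alpha dual value,
# is solved by projected subgradient (a Euclidean mirror-descent instance)
# with best-iterate tracking; the gradient is -B_j/2 with
# B_j = sum_t M_tj alpha_t alpha_t' M_tj' (Danskin, alpha at its optimum).

#' Factor the pooled Gram matrices
#'
#' Eigendecomposes each training Gram, retains the eigenvalues above
#' `rank_tol` times the largest, and builds the per-task kernelization maps
#' `M_tj = S^{-1} V' G_j[, task-t columns]` (equal to `S V'` restricted, since
#' `G = V S^2 V'`). Reconstruction `M_tj' M_tj` recovers the corresponding
#' Gram block on the retained spectrum.
#'
#' @param pool a [kernel_pool].
#' @param task_index list of per-task observed-row index vectors (default:
#'   all rows for one shared sample set).
#' @param rank_tol relative eigenvalue cutoff.
#' @return A list of class `kernel_factors`; element j has `values` (retained
#'   eigenvalues of the Gram), `sv` (their square roots, the singular values
#'   of the implicit feature matrix), `V` (eigenvectors), `rank`, and `M`, the
#'   list of `rank x m_t` task maps. `task_index` is attached.
#' @export
factor_kernels <- function(pool, task_index = NULL, rank_tol = 1e-10) {
  m <- nrow(pool$X)
  if (is.null(task_index)) task_index <- list(seq_len(m))
  factors <- lapply(seq_len(pool$k), function(j) {
    G <- pool$grams[[j]]
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    mx <- max(eg$values)
    if (min(eg$values) < -1e-8 * max(mx, 1)) {
      stop("Gram matrix ", j, " is not PSD within tolerance (min eigenvalue ",
           signif(min(eg$values), 4), ")")
    }
    keep <- eg$values > rank_tol * mx
    vals <- eg$values[keep]
    V <- eg$vectors[, keep, drop = FALSE]
    sv <- sqrt(vals)
    M_full <- sv * t(V)           # = S^{-1} V' G  since G = V S^2 V'
    M <- lapply(task_index, function(idx) M_full[, idx, drop = FALSE])
    list(values = vals, sv = sv, V = V, rank = sum(keep), M = M)
  })
  structure(list(factors = factors, task_index = task_index,
                 k = pool$k, m = m),
            class = "kernel_factors")
}

#' Per-task dual variables for given PSD blocks
#'
#' Solves `alpha_t = -(sum_j M_tj' Q_j M_tj + I/lam)^{-1} y_t` by a
#' symmetric positive-definite solve.
#'
#' @param factors a [factor_kernels] result.
#' @param Q list of symmetric PSD matrices, `Q[[j]]` of size
#'   `rank_j x rank_j`.
#' @param lam positive regularization level.
#' @param ylist list of per-task target vectors.
#' @return List of dual vectors.
#' @export
solve_alpha_q <- function(factors, Q, lam, ylist) {
  Tn <- length(ylist)
  lapply(seq_len(Tn), function(t) {
    mt <- length(ylist[[t]])
    K <- matrix(0, mt, mt)
    for (j in seq_len(factors$k)) {
      Mtj <- factors$factors[[j]]$M[[t]]
      K <- K + crossprod(Mtj, Q[[j]] %*% Mtj)
    }
    as.vector(spd_solve(K, lam, -ylist[[t]]))
  })
}

#' Dual objective and its subgradient in Q
#'
#' Evaluates `f(Q) = sum_t [ -alpha_t' y_t - 1/2 alpha_t' K_t(Q) alpha_t -
#' alpha_t' alpha_t / (2 lam) ]` at the optimal `alpha` of [solve_alpha_q],
#' and the gradient blocks `-B_j / 2` with
#' `B_j = sum_t M_tj alpha_t alpha_t' M_tj'` (the optimal `alpha` is treated
#' as fixed, by Danskin's theorem).
#'
#' @inheritParams solve_alpha_q
#' @return A list with `f`, `grad` (list of matrices), and `alpha`.
#' @export
objective_and_gradient <- function(factors, Q, lam, ylist) {
  alpha <- solve_alpha_q(factors, Q, lam, ylist)
  f <- 0
  grad <- vector("list", factors$k)
  for (j in seq_len(factors$k)) {
    grad[[j]] <- matrix(0, factors$factors[[j]]$rank,
                        factors$factors[[j]]$rank)
  }
  for (t in seq_along(ylist)) {
    a <- alpha[[t]]
    quad <- 0
    for (j in seq_len(factors$k)) {
      Ma <- factors$factors[[j]]$M[[t]] %*% a
      quad <- quad + as.numeric(crossprod(Ma, Q[[j]] %*% Ma))
      grad[[j]] <- grad[[j]] - 0.5 * tcrossprod(Ma)
    }
    f <- f - sum(a * ylist[[t]]) - 0.5 * quad - sum(a^2) / (2 * lam)
  }
  list(f = f, grad = grad, alpha = alpha)
}

#' Project PSD blocks onto the mixed trace-constraint set
#'
#' Symmetrizes each block, clips negative eigenvalues to zero, and, if
#' `sum_j tr(Q_j)^qbar > bound`, rescales all blocks by the closed-form
#' constant `c = (bound / sum_j tr(Q_j)^qbar)^(1/qbar)` so the constraint
#' holds with equality. Total (never fails); idempotent on feasible input.
#'
#' @param Q list of symmetric matrices.
#' @param qbar trace-constraint exponent, `>= 1`.
#' @param bound right-hand side of the constraint (default 1).
#' @return List of feasible PSD blocks.
#' @export
project_Q <- function(Q, qbar, bound = 1) {
  Q <- lapply(Q, function(Qj) {
    Qj <- (Qj + t(Qj)) / 2
    eg <- eigen(Qj, symmetric = TRUE)
    if (min(eg$values) >= 0) return(Qj)
    pos <- pmax(eg$values, 0)
    eg$vectors %*% (pos * t(eg$vectors))
  })
  trs <- vapply(Q, function(Qj) sum(diag(Qj)), 0)
  s <- sum(trs^qbar)
  if (s > bound) {
    c_scale <- (bound / s)^(1 / qbar)
    Q <- lapply(Q, function(Qj) c_scale * Qj)
  }
  Q
}

l21lq_feasibility <- function(Q, qbar, bound = 1) {
  viol <- max(0, sum(vapply(Q, function(Qj) sum(diag(Qj)), 0)^qbar) - bound)
  for (Qj in Q) {
    ev <- eigen((Qj + t(Qj)) / 2, symmetric = TRUE, only.values = TRUE)$values
    viol <- max(viol, -min(ev))
  }
  viol
}

#' Fit the l2,1-lq multikernel multitask model
#'
#' Projected-subgradient loop `Q <- project_Q(Q - eta_l * grad f(Q))` with
#' `eta_l = step0 / sqrt(l)` and best-iterate tracking (the feasible `Q` with
#' the lowest objective seen is returned). `Q` is initialized block-diagonal
#' uniform, `Q_j = c I`, with `c` chosen on the constraint boundary. `step0`
#' defaults to a three-point heuristic on the first iteration (candidate
#' scales bracketing `1/||grad||`). Stops at `max_outer` iterations or when
#' the best objective improves by less than `tol` (relative) over a
#' 10-iteration window. An exponentiated-gradient variant
#' (`mirror = "entropic"`) replaces the Euclidean step by a matrix-entropy
#' step followed by the trace rescale.
#'
#' @param ds a [multitask_dataset].
#' @param pool a [kernel_pool] built on the same samples (default pool when
#'   `NULL`).
#' @param q kernel-norm exponent in `[1, 2)`; the trace exponent is
#'   `qbar = q/(2-q)`.
#' @param lam positive regularization level.
#' @param max_outer iteration cap.
#' @param step0 initial step scale (`NULL` for the heuristic).
#' @param tol relative best-objective improvement tolerance over a
#'   10-iteration window.
#' @param bound right-hand side of the trace constraint.
#' @param rank_tol eigenvalue cutoff for [factor_kernels].
#' @param mirror `"euclidean"` (default) or `"entropic"`.
#' @return An object of class `mkmtl_l21lq`: `Q` (best-iterate blocks),
#'   `alpha` (duals at the returned `Q`), `objective_trace` (per-iteration f),
#'   `best_trace` (running best, non-increasing), `feasibility_trace`,
#'   `factors`, `q`, `qbar`, `lam`, `pool`, `task_index`.
#' @export
fit_l21lq <- function(ds, pool = NULL, q = 1.5, lam = 1, max_outer = 100L,
                      step0 = NULL, tol = 1e-6, bound = 1,
                      rank_tol = 1e-10, mirror = c("euclidean", "entropic")) {
  mirror <- match.arg(mirror)
  if (q < 1 || q >= 2) stop("configuration error: q must lie in [1, 2)")
  if (lam <= 0) stop("lam must be positive")
  if (is.null(pool)) pool <- build_pool(ds)
  if (nrow(pool$X) != ds$m) stop("pool was not built on this dataset")
  qbar <- q / (2 - q)
  Tn <- ds$n_tasks
  task_index <- lapply(seq_len(Tn), function(t) which(ds$observed[, t]))
  ylist <- lapply(seq_len(Tn), function(t) ds$Y[task_index[[t]], t])
  factors <- factor_kernels(pool, task_index, rank_tol)
  ranks <- vapply(factors$factors, function(fj) fj$rank, 0L)

  # uniform block-diagonal start on the constraint boundary
  c0 <- (bound / sum(ranks^qbar))^(1 / qbar)
  Q <- lapply(ranks, function(r) diag(c0, r))

  og <- objective_and_gradient(factors, Q, lam, ylist)
  if (is.null(step0)) {
    gnorm <- sqrt(sum(vapply(og$grad, function(g) sum(g^2), 0)))
    cands <- c(0.1, 1, 10) / max(gnorm, 1e-12)
    fvals <- vapply(cands, function(s) {
      Qc <- project_Q(Map(function(Qj, Gj) Qj - s * Gj, Q, og$grad),
                      qbar, bound)
      objective_and_gradient(factors, Qc, lam, ylist)$f
    }, 0)
    step0 <- cands[which.min(fvals)]
  }

  best_f <- og$f
  best_Q <- Q
  ftrace <- og$f
  btrace <- og$f
  feas <- l21lq_feasibility(Q, qbar, bound)
  for (l in seq_len(max_outer)) {
    eta <- step0 / sqrt(l)
    if (mirror == "euclidean") {
      Q <- Map(function(Qj, Gj) Qj - eta * Gj, Q, og$grad)
    } else {
      Q <- Map(function(Qj, Gj) {
        eg <- eigen((Qj + t(Qj)) / 2, symmetric = TRUE)
        lg <- eg$vectors %*% (log(pmax(eg$values, 1e-12)) * t(eg$vectors))
        S <- lg - eta * Gj
        es <- eigen((S + t(S)) / 2, symmetric = TRUE)
        es$vectors %*% (exp(es$values) * t(es$vectors))
      }, Q, og$grad)
    }
    Q <- project_Q(Q, qbar, bound)
    fv <- l21lq_feasibility(Q, qbar, bound)
    feas <- c(feas, fv)
    if (fv > 1e-8) stop("feasibility violation at iteration ", l, ": ", fv)
    og <- objective_and_gradient(factors, Q, lam, ylist)
    ftrace <- c(ftrace, og$f)
    if (og$f < best_f) {
      best_f <- og$f
      best_Q <- Q
    }
    btrace <- c(btrace, best_f)
    if (l > 10L) {
      prev <- btrace[l - 9L]
      if (abs(prev - best_f) <= tol * max(1, abs(prev))) break
    }
  }
  alpha <- solve_alpha_q(factors, best_Q, lam, ylist)
  structure(
    list(Q = best_Q, alpha = alpha, objective = best_f,
         objective_trace = ftrace, best_trace = btrace,
         feasibility_trace = feas, factors = factors,
         q = q, qbar = qbar, lam = lam, bound = bound, pool = pool,
         task_index = task_index, task_names = ds$task_names),
    class = "mkmtl_l21lq"
  )
}

#' Predict from an l2,1-lq multikernel multitask model
#'
#' Embeds each new point through the training factorization,
#' `M_j(x) = S^{-1} V' G_j(. , x)`, and evaluates
#' `f_t(x) = -sum_j M_j(x)' Q_j M_tj alpha_t`.
#'
#' @param model an `mkmtl_l21lq` fit.
#' @param cross list of `n_new x m` cross-kernel matrices from [pool_cross].
#' @return An `n_new x T` prediction matrix.
#' @export
predict_l21lq <- function(model, cross) {
  if (length(cross) != model$factors$k) {
    stop("shape mismatch: expected ", model$factors$k, " cross-kernel blocks")
  }
  n_new <- nrow(cross[[1L]])
  Tn <- length(model$alpha)
  out <- matrix(0, n_new, Tn, dimnames = list(NULL, model$task_names))
  for (j in seq_len(model$factors$k)) {
    fj <- model$factors$factors[[j]]
    # rank x n_new embedding of the new points
    Mx <- (1 / fj$sv) * (t(fj$V) %*% t(cross[[j]]))
    for (t in seq_len(Tn)) {
      w <- model$Q[[j]] %*% (fj$M[[t]] %*% model$alpha[[t]])
      out[, t] <- out[, t] - as.vector(crossprod(Mx, w))
    }
  }
  out
}

#' @export
predict.mkmtl_l21lq <- function(object, newdata, ...) {
  predict_l21lq(object, pool_cross(object$pool, newdata))
}

#' @export
print.mkmtl_l21lq <- function(x, ...) {
  trs <- vapply(x$Q, function(Qj) sum(diag(Qj)), 0)
  cat("mkmtl_l21lq fit: q = ", x$q, " (qbar = ", signif(x$qbar, 4),
      "), lambda = ", x$lam, ", ", length(x$Q), " kernels, ",
      length(x$objective_trace) - 1L, " iterations\n", sep = "")
  cat("block traces:", paste(signif(trs, 3), collapse = " "), "\n")
  invisible(x)
}
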