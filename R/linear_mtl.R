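# Linear lq,1-regularized multitask regression by accelerated proximal
# gradient with Armijo-style backtracking on the Lipschitz constant.
#
# Objective: Phi(Theta) = 1/2 ||Y - X Theta||_F^2 + lam * sum_h ||theta_h.||_q
# The smooth part is handled by gradient steps on the search point
# Gamma^(l) = Theta^(l) + beta^(l) (Theta^(l) - Theta^(l-1)); the penalty by
# the row-wise prox. A monotone safeguard keeps the accepted-iterate
# objective non-increasing (the plain accelerated sequence can oscillate):
# when the candidate increases Phi, the previous iterate is retained as the
# solution estimate while the momentum sequence continues from the candidate.

check_complete <- function(ds) {
  if (!all(ds$observed)) {
    stop("the linear solver requires a fully observed Y; ",
         "use the kernel solvers with per-task masks instead")
  }
}

#' Linear multitask objective
#'
#' `1/2 ||Y - X Theta||_F^2 + lam * sum_h ||theta_h.||_q`.
#'
#' @param ds a [multitask_dataset] with fully observed `Y`.
#' @param theta numeric p x T parameter matrix.
#' @param q row-norm exponent (`>= 1`, may be `Inf`).
#' @param lam nonnegative regularization level.
#' @return A single number.
#' @export
mtl_objective <- function(ds, theta, q, lam) {
  check_complete(ds)
  theta <- as.matrix(theta)
  if (nrow(theta) != ds$p || ncol(theta) != ds$n_tasks) {
    stop("shape mismatch: theta must be ", ds$p, " x ", ds$n_tasks)
  }
  R <- ds$Y - ds$X %*% theta
  0.5 * sum(R^2) + lam * sum(row_lq_norm(theta, q))
}

#' Gradient of the squared-loss term
#'
#' Returns `t(X) %*% (X Theta - Y)`, the gradient of the smooth half of the
#' objective only; the nonsmooth penalty is handled by its prox.
#'
#' @inheritParams mtl_objective
#' @return A p x T matrix.
#' @export
mtl_gradient <- function(ds, theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) != ds$p || ncol(theta) != ds$n_tasks) {
    stop("shape mismatch: theta must be ", ds$p, " x ", ds$n_tasks)
  }
  crossprod(ds$X, ds$X %*% theta - ds$Y)
}

#' Fit the linear lq,1 multitask model
#'
#' Accelerated proximal gradient (Nesterov momentum
#' `beta_l = (t_{l-1} - 1)/t_l`, `t_l = (1 + sqrt(1 + 4 t_{l-1}^2))/2`) with
#' backtracking line search on the local Lipschitz constant `L`: a step is
#' accepted when
#' `F(Theta+) <= F(Gamma) + <Theta+ - Gamma, grad F(Gamma)> + L/2 ||Theta+ - Gamma||_F^2`,
#' else `L` is doubled; `L` may shrink by 0.9 between iterations. Each step is
#' `Theta+ = prox_{lam/L}(Gamma - grad F(Gamma)/L)` via [project_matrix_lq1].
#' Iteration stops when the relative change of the objective falls below
#' `tol` or after `max_iter` steps. Initialization is `Theta = 0`; the solver
#' is deterministic.
#'
#' @inheritParams mtl_objective
#' @param max_iter iteration cap.
#' @param tol relative objective-change tolerance.
#' @param L0 initial line-search constant.
#' @return An object of class `lq1_mtl` with elements `theta` (p x T),
#'   `objective_trace` (values of the accepted iterates, non-increasing),
#'   `iterations`, `converged`, `L`, `q`, `lam`, and `prox_residual`, the
#'   fixed-point residual `||Theta - prox(Theta - grad/L, lam/L)||_F`.
#' @export
fit_lq1_mtl <- function(ds, q = 2, lam = 1, max_iter = 10000L, tol = 1e-8,
                        L0 = 1) {
  check_complete(ds)
  if (lam < 0) stop("lam must be nonnegative")
  if (q < 1) stop("configuration error: q must be >= 1")
  X <- ds$X; Y <- ds$Y
  p <- ds$p; Tn <- ds$n_tasks

  Fval <- function(Th) { R <- Y - X %*% Th; 0.5 * sum(R^2) }
  Phi <- function(Th) Fval(Th) + lam * sum(row_lq_norm(Th, q))

  theta <- matrix(0, p, Tn)
  theta_prev <- theta
  z <- theta                 # momentum carrier (last candidate)
  z_prev <- theta
  t_acc <- 1
  L <- L0
  obj <- Phi(theta)
  trace <- obj
  converged <- FALSE

  for (l in seq_len(max_iter)) {
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    beta <- (t_acc - 1) / t_new
    Gamma <- z + beta * (z - z_prev)
    FG <- Fval(Gamma)
    G <- crossprod(X, X %*% Gamma - Y)
    L <- max(L * 0.9, 1e-12)
    repeat {
      cand <- project_matrix_lq1(Gamma - G / L, q, lam / L)
      D <- cand - Gamma
      model_val <- FG + sum(D * G) + (L / 2) * sum(D^2)
      if (Fval(cand) <= model_val + 1e-12 * abs(model_val)) break
      L <- L * 2
      if (L > 1e12 * L0) {
        stop("numerical error: line search diverged (L exceeded 1e12 * L0); ",
             "objective trace: ", paste(signif(utils::tail(trace, 5), 6),
                                        collapse = ", "))
      }
    }
    z_prev <- z
    z <- cand
    t_acc <- t_new
    cand_obj <- Phi(cand)
    # stop on the candidate's relative progress so a single momentum
    # overshoot cannot trigger a spurious flat-trace exit
    rel_change <- abs(cand_obj - obj) / max(1, abs(obj))
    # monotone safeguard: keep the best iterate as the solution estimate
    if (cand_obj <= obj) {
      theta_prev <- theta
      theta <- cand
      obj <- cand_obj
    }
    trace <- c(trace, obj)
    if (rel_change <= tol) {
      converged <- TRUE
      break
    }
  }

  Gth <- crossprod(X, X %*% theta - Y)
  prox_res <- sqrt(sum((theta - project_matrix_lq1(theta - Gth / L, q,
                                                   lam / L))^2))
  structure(
    list(theta = theta, objective_trace = trace,
         iterations = length(trace) - 1L, converged = converged, L = L,
         q = q, lam = lam, prox_residual = prox_res,
         task_names = ds$task_names, feature_names = ds$feature_names),
    class = "lq1_mtl"
  )
}

#' Predict from a linear multitask model
#'
#' @param theta a p x T parameter matrix or an `lq1_mtl` fit.
#' @param X_new numeric matrix with p columns.
#' @return An `n_new` x T matrix `X_new %*% theta`.
#' @export
predict_linear <- function(theta, X_new) {
  if (inherits(theta, "lq1_mtl")) theta <- theta$theta
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(theta)) {
    stop("shape mismatch: X_new has ", ncol(X_new),
         " columns but theta has ", nrow(theta), " rows")
  }
  X_new %*% theta
}

#' @export
predict.lq1_mtl <- function(object, newdata, ...) {
  predict_linear(object$theta, newdata)
}

#' @export
print.lq1_mtl <- function(x, ...) {
  nz <- sum(rowSums(abs(x$theta)) > 0)
  cat("lq1_mtl fit: q = ", x$q, ", lambda = ", x$lam, ", ",
      nz, "/", nrow(x$theta), " active feature rows, ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "iteration cap", ")\n", sep = "")
  invisible(x)
}
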