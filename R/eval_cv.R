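# Nested cross-validation protocol: an outer loop of evaluation folds and,
# inside each outer training set, an inner tuning loop that selects the grid
# point with the lowest validation nMSE. Z-scoring is refit inside every
# training fold so held-out rows never influence the transform.

#' Hyperparameter grid for a registered method
#'
#' @param lam_values positive ascending regularization grid; the default five
#'   decade points span 1e-1 .. 1e3.
#' @param q_values optional norm-exponent grid (method-dependent).
#' @param method method identifier (see [nested_cv]).
#' @return An object of class `tuning_grid` whose `points` data frame holds
#'   one row per candidate.
#' @export
tuning_grid <- function(lam_values = 10^(-1:3), q_values = NULL,
                        method = "lq1-mtl") {
  if (any(lam_values <= 0)) stop("lam_values must be positive")
  if (is.unsorted(lam_values)) stop("lam_values must be ascending")
  pts <- if (is.null(q_values)) {
    data.frame(lam = lam_values, q = NA_real_)
  } else {
    expand.grid(lam = lam_values, q = q_values)
  }
  structure(list(points = pts, method = method), class = "tuning_grid")
}

#' Default grid for each method
#'
#' Linear solver: q in 1, 2, 3, Inf; lq,l1 multikernel: q in 2.5, 3, 4;
#' l2,1-lq multikernel: q in 1, 1.5, 1.9; ridge and lasso tune lambda only.
#'
#' @param method method identifier.
#' @return A [tuning_grid].
#' @export
default_grid <- function(method) {
  q_values <- switch(method,
    "lq1-mtl" = c(1, 2, 3, Inf),
    "mkmtl-lq1" = c(2.5, 3, 4),
    "mkmtl-l21lq" = c(1, 1.5, 1.9),
    NULL)
  tuning_grid(q_values = q_values, method = method)
}

# --- method registry -------------------------------------------------------

# Each method provides fit(ds_z, pool, lam, q, control) -> model and
# predict(model, X_new_z, cross) -> n_new x T matrix. `pool`/`cross` are NULL
# for linear methods; kernel pools and cross blocks are built once per
# training fold and shared across grid points.

ridge_fit <- function(ds, lam) {
  XtX <- crossprod(ds$X) + diag(lam, ds$p)
  theta <- solve(XtX, crossprod(ds$X, ds$Y))
  structure(list(theta = theta), class = "ridge_mtl")
}

lasso_fit <- function(ds, lam) {
  # glmnet objective is 1/(2m) RSS + lambda ||theta||_1; rescale to match
  # the 1/2 RSS + lam ||theta||_1 convention used package-wide
  theta <- vapply(seq_len(ds$n_tasks), function(t) {
    fit <- glmnet::glmnet(ds$X, ds$Y[, t], family = "gaussian",
                          lambda = lam / ds$m, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-10)
    as.vector(fit$beta)
  }, numeric(ds$p))
  structure(list(theta = theta), class = "ridge_mtl")
}

mtl_methods <- function() {
  list(
    "lq1-mtl" = list(
      kernel = FALSE,
      fit = function(ds, pool, lam, q, control) {
        fit_lq1_mtl(ds, q = if (is.na(q)) 2 else q, lam = lam,
                    max_iter = control$max_iter %||% 2000L,
                    tol = control$tol %||% 1e-7)
      },
      predict = function(model, X_new, cross) predict_linear(model, X_new)
    ),
    "mkmtl-lq1" = list(
      kernel = TRUE,
      fit = function(ds, pool, lam, q, control) {
        fit_mkmtl(ds, pool, q = if (is.na(q)) 3 else q, lam = lam,
                  max_outer = control$max_outer %||% 30L,
                  tol = control$tol %||% 1e-5)
      },
      predict = function(model, X_new, cross) predict_mkmtl(model, cross)
    ),
    "mkmtl-l21lq" = list(
      kernel = TRUE,
      fit = function(ds, pool, lam, q, control) {
        fit_l21lq(ds, pool, q = if (is.na(q)) 1.5 else q, lam = lam,
                  max_outer = control$max_outer %||% 40L,
                  tol = control$tol %||% 1e-5)
      },
      predict = function(model, X_new, cross) predict_l21lq(model, cross)
    ),
    "ridge" = list(
      kernel = FALSE,
      fit = function(ds, pool, lam, q, control) ridge_fit(ds, lam),
      predict = function(model, X_new, cross) X_new %*% model$theta
    ),
    "lasso" = list(
      kernel = FALSE,
      fit = function(ds, pool, lam, q, control) lasso_fit(ds, lam),
      predict = function(model, X_new, cross) X_new %*% model$theta
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fit on training rows, predict held-out rows; z-scoring and (for kernel
# methods) the pool are built on the training rows only
fit_eval_split <- function(ds, train, test, entry, lam, q, control,
                           scale_y, kernel_specs, per_modality) {
  ds_tr <- subset_dataset(ds, train)
  zs <- suppressWarnings(zscore(ds_tr, scale_y = scale_y))
  X_te <- apply_scaler(zs$scaler, ds$X[test, , drop = FALSE])
  pool <- NULL; cross <- NULL
  if (entry$kernel) {
    pool <- build_pool(zs$dataset, specs = kernel_specs,
                       per_modality = per_modality)
    cross <- pool_cross(pool, X_te)
  }
  model <- entry$fit(zs$dataset, pool, lam, q, control)
  Yhat <- entry$predict(model, X_te, cross)
  if (scale_y) {
    Yhat <- sweep(sweep(Yhat, 2L, zs$scaler$y_scale, "*"),
                  2L, zs$scaler$y_center, "+")
  }
  list(Yhat = Yhat,
       Y = ds$Y[test, , drop = FALSE],
       observed = ds$observed[test, , drop = FALSE])
}

# as above, but the pool/cross pair is computed once and reused over a grid
eval_grid_on_split <- function(ds, train, test, entry, grid_points, control,
                               scale_y, kernel_specs, per_modality) {
  ds_tr <- subset_dataset(ds, train)
  zs <- suppressWarnings(zscore(ds_tr, scale_y = scale_y))
  X_te <- apply_scaler(zs$scaler, ds$X[test, , drop = FALSE])
  pool <- NULL; cross <- NULL
  if (entry$kernel) {
    pool <- build_pool(zs$dataset, specs = kernel_specs,
                       per_modality = per_modality)
    cross <- pool_cross(pool, X_te)
  }
  vapply(seq_len(nrow(grid_points)), function(g) {
    model <- entry$fit(zs$dataset, pool, grid_points$lam[g],
                       grid_points$q[g], control)
    Yhat <- entry$predict(model, X_te, cross)
    if (scale_y) {
      Yhat <- sweep(sweep(Yhat, 2L, zs$scaler$y_scale, "*"),
                    2L, zs$scaler$y_center, "+")
    }
    nmse(ds$Y[test, , drop = FALSE], Yhat,
         ds$observed[test, , drop = FALSE])
  }, 0)
}

#' Nested cross-validated evaluation of a method
#'
#' For each outer fold, an inner K-fold loop scores every grid point by mean
#' validation nMSE; the winning point is refit on the full outer training
#' set and evaluated on the outer test fold (per-task rMSE and correlation,
#' pooled nMSE and wR). Z-scoring is fit inside each training fold. A fold
#' whose fit fails is marked failed and reported; more than two failures
#' abort the run. Deterministic given `seed`.
#'
#' @param ds a [multitask_dataset].
#' @param method one of `"lq1-mtl"`, `"mkmtl-lq1"`, `"mkmtl-l21lq"`,
#'   `"ridge"`, `"lasso"`.
#' @param grid a [tuning_grid] (default: [default_grid] for the method).
#' @param outer,inner fold counts (defaults 10 and 5).
#' @param seed integer seed for the fold plan.
#' @param scale_y z-score the targets along with the features (predictions
#'   and metrics are mapped back to the original scale).
#' @param kernel_specs base-kernel list for the kernel methods.
#' @param per_modality build per-modality kernel pools.
#' @param control list of solver control parameters (`max_iter`, `max_outer`,
#'   `tol`).
#' @return An object of class `mtl_metrics_report`: `per_fold` data frame
#'   (selected grid point and metrics per outer fold), `rmse` and `cc`
#'   fold x task matrices, and `summary` (mean and sd of nMSE and wR across
#'   folds, per-task mean rMSE/CC).
#' @export
nested_cv <- function(ds, method, grid = default_grid(method),
                      outer = 10L, inner = 5L, seed = 1L,
                      scale_y = FALSE,
                      kernel_specs = default_kernel_specs(),
                      per_modality = FALSE, control = list()) {
  registry <- mtl_methods()
  if (!method %in% names(registry)) {
    stop("unknown method '", method, "'; registered: ",
         paste(names(registry), collapse = ", "))
  }
  entry <- registry[[method]]
  plan <- make_folds(ds$m, outer = outer, inner = inner, seed = seed)
  pts <- grid$points
  Tn <- ds$n_tasks

  per_fold <- data.frame(fold = seq_len(outer), lam = NA_real_, q = NA_real_,
                         nmse = NA_real_, wr = NA_real_, failed = FALSE)
  rmse_mat <- matrix(NA_real_, outer, Tn,
                     dimnames = list(NULL, ds$task_names))
  cc_mat <- rmse_mat
  failures <- 0L

  for (o in seq_len(outer)) {
    res <- tryCatch({
      if (nrow(pts) > 1L && length(plan$inner_folds[[o]]) > 0L) {
        scores <- sapply(plan$inner_folds[[o]], function(fold) {
          eval_grid_on_split(ds, fold$train, fold$test, entry, pts, control,
                             scale_y, kernel_specs, per_modality)
        })
        scores <- matrix(scores, nrow = nrow(pts))
        best <- which.min(rowMeans(scores))
      } else {
        best <- 1L
      }
      out <- fit_eval_split(ds, plan$outer_folds[[o]]$train,
                            plan$outer_folds[[o]]$test, entry,
                            pts$lam[best], pts$q[best], control,
                            scale_y, kernel_specs, per_modality)
      list(best = best, out = out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      per_fold$failed[o] <- TRUE
      warning("fold ", o, " failed: ", conditionMessage(res))
      if (failures > 2L) {
        stop("more than two folds failed; aborting (last error: ",
             conditionMessage(res), ")")
      }
      next
    }
    per_fold$lam[o] <- pts$lam[res$best]
    per_fold$q[o] <- pts$q[res$best]
    per_fold$nmse[o] <- nmse(res$out$Y, res$out$Yhat, res$out$observed)
    per_fold$wr[o] <- weighted_r(res$out$Y, res$out$Yhat, res$out$observed)
    rmse_mat[o, ] <- rmse_per_task(res$out$Y, res$out$Yhat, res$out$observed)
    cc_mat[o, ] <- cc_per_task(res$out$Y, res$out$Yhat, res$out$observed)
  }

  ok <- !per_fold$failed
  structure(
    list(method = method, per_fold = per_fold, rmse = rmse_mat, cc = cc_mat,
         summary = list(
           nmse_mean = mean(per_fold$nmse[ok]),
           nmse_sd = stats::sd(per_fold$nmse[ok]),
           wr_mean = mean(per_fold$wr[ok]),
           wr_sd = stats::sd(per_fold$wr[ok]),
           rmse_mean = colMeans(rmse_mat[ok, , drop = FALSE]),
           cc_mean = colMeans(cc_mat[ok, , drop = FALSE])),
         n_failed = failures, seed = seed, outer = outer, inner = inner),
    class = "mtl_metrics_report"
  )
}

#' @export
print.mtl_metrics_report <- function(x, ...) {
  cat("nested CV report for ", x$method, " (", x$outer, "x", x$inner,
      " folds, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  nMSE %.4f +/- %.4f   wR %.4f +/- %.4f\n",
              x$summary$nmse_mean, x$summary$nmse_sd,
              x$summary$wr_mean, x$summary$wr_sd))
  if (x$n_failed > 0L) cat("  failed folds:", x$n_failed, "\n")
  invisible(x)
}

#' Compare several methods under the same fold plan
#'
#' Runs [nested_cv] for each method with the same seed (hence identical fold
#' assignments) and tabulates per-task rMSE/CC means and the pooled
#' nMSE/wR mean and sd per method.
#'
#' @param ds a [multitask_dataset].
#' @param methods character vector of registered method names.
#' @param grid_map optional named list mapping method name to a
#'   [tuning_grid]; defaults to [default_grid] per method.
#' @param seed,outer,inner,scale_y,kernel_specs,per_modality,control passed
#'   to [nested_cv].
#' @return A data frame of class `mtl_comparison` with one row per method;
#'   the full reports are attached as attribute `"reports"`.
#' @export
compare_methods <- function(ds, methods, grid_map = NULL, seed = 1L,
                            outer = 10L, inner = 5L, scale_y = FALSE,
                            kernel_specs = default_kernel_specs(),
                            per_modality = FALSE, control = list()) {
  reports <- lapply(methods, function(mth) {
    grid <- if (!is.null(grid_map) && mth %in% names(grid_map)) {
      grid_map[[mth]]
    } else {
      default_grid(mth)
    }
    nested_cv(ds, mth, grid = grid, outer = outer, inner = inner, seed = seed,
              scale_y = scale_y, kernel_specs = kernel_specs,
              per_modality = per_modality, control = control)
  })
  names(reports) <- methods
  tab <- do.call(rbind, lapply(reports, function(r) {
    row <- data.frame(method = r$method,
                      nmse_mean = r$summary$nmse_mean,
                      nmse_sd = r$summary$nmse_sd,
                      wr_mean = r$summary$wr_mean,
                      wr_sd = r$summary$wr_sd)
    for (t in seq_along(r$summary$rmse_mean)) {
      row[[paste0("rmse_", names(r$summary$rmse_mean)[t])]] <-
        r$summary$rmse_mean[t]
      row[[paste0("cc_", names(r$summary$cc_mean)[t])]] <-
        r$summary$cc_mean[t]
    }
    row
  }))
  rownames(tab) <- NULL
  attr(tab, "reports") <- reports
  class(tab) <- c("mtl_comparison", class(tab))
  tab
}

#' Write / read a comparison table as CSV
#'
#' @param tab a comparison data frame from [compare_methods].
#' @param path CSV file path.
#' @return `read_report` returns the data frame (losslessly, up to the
#'   attached report objects which are not serialized).
#' @export
write_report <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
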