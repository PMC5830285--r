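# Evaluation metrics: per-task root mean squared error and Pearson
# correlation, and the two pooled summaries used for multitask cognitive
# score prediction -- normalized MSE (per-task squared residual norms scaled
# by the ground-truth spread, pooled over sum_t m_t) and the sample-size
# weighted mean correlation wR.

metric_mask <- function(Y, Yhat, observed) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch between Y and Yhat")
  if (is.null(observed)) observed <- matrix(TRUE, nrow(Y), ncol(Y))
  if (!all(dim(observed) == dim(Y))) stop("observed mask has wrong shape")
  list(Y = Y, Yhat = Yhat, observed = observed)
}

#' Per-task root mean squared error
#'
#' @param Y ground-truth m x T matrix.
#' @param Yhat predicted m x T matrix.
#' @param observed optional logical mask of scored entries.
#' @return Numeric vector of length T; a task with no observed entries is
#'   `NA`.
#' @export
rmse_per_task <- function(Y, Yhat, observed = NULL) {
  d <- metric_mask(Y, Yhat, observed)
  vapply(seq_len(ncol(d$Y)), function(t) {
    o <- d$observed[, t]
    if (!any(o)) return(NA_real_)
    sqrt(mean((d$Y[o, t] - d$Yhat[o, t])^2))
  }, 0)
}

#' Normalized mean squared error pooled over tasks
#'
#' `sum_t ||Y_t - Yhat_t||_2^2 / spread(Y_t) / sum_t m_t`, where `spread` is
#' the sample variance of the ground-truth scores of task t (the convention
#' of the multitask literature; `spread = "sd"` switches to the standard
#' deviation, since the printed definition is ambiguous between the two).
#'
#' @inheritParams rmse_per_task
#' @param spread `"variance"` (default) or `"sd"`.
#' @return A single nonnegative number.
#' @export
nmse <- function(Y, Yhat, observed = NULL, spread = c("variance", "sd")) {
  spread <- match.arg(spread)
  d <- metric_mask(Y, Yhat, observed)
  num <- 0; den <- 0
  for (t in seq_len(ncol(d$Y))) {
    o <- d$observed[, t]
    mt <- sum(o)
    if (mt == 0L) next
    v <- stats::var(d$Y[o, t])
    if (!is.finite(v) || v <= 0) {
      stop("zero-variance ground truth in task ",
           if (!is.null(colnames(d$Y))) colnames(d$Y)[t] else t)
    }
    s <- if (spread == "variance") v else sqrt(v)
    num <- num + sum((d$Y[o, t] - d$Yhat[o, t])^2) / s
    den <- den + mt
  }
  num / den
}

#' Sample-size weighted mean Pearson correlation (wR)
#'
#' `sum_t Corr(Y_t, Yhat_t) * m_t / sum_t m_t`. A task whose predictions (or
#' truths) have zero spread has no defined correlation and raises an error
#' rather than being dropped silently.
#'
#' @inheritParams rmse_per_task
#' @return A single number in `[-1, 1]`.
#' @export
weighted_r <- function(Y, Yhat, observed = NULL) {
  d <- metric_mask(Y, Yhat, observed)
  num <- 0; den <- 0
  for (t in seq_len(ncol(d$Y))) {
    o <- d$observed[, t]
    mt <- sum(o)
    if (mt == 0L) next
    if (stats::sd(d$Yhat[o, t]) == 0 || stats::sd(d$Y[o, t]) == 0) {
      stop("zero-spread values in task ",
           if (!is.null(colnames(d$Y))) colnames(d$Y)[t] else t,
           ": correlation undefined")
    }
    num <- num + stats::cor(d$Y[o, t], d$Yhat[o, t]) * mt
    den <- den + mt
  }
  num / den
}

#' Per-task Pearson correlations
#'
#' @inheritParams rmse_per_task
#' @return Numeric vector of length T (`NA` for empty tasks).
#' @export
cc_per_task <- function(Y, Yhat, observed = NULL) {
  d <- metric_mask(Y, Yhat, observed)
  vapply(seq_len(ncol(d$Y)), function(t) {
    o <- d$observed[, t]
    if (!any(o)) return(NA_real_)
    suppressWarnings(stats::cor(d$Y[o, t], d$Yhat[o, t]))
  }, 0)
}
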