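# Base-kernel pool construction.
#
# The default pool mirrors the candidate set used for cognitive-score
# prediction: Gaussian kernels at six bandwidths 2^-2..2^3, inhomogeneous
# polynomial kernels of degrees 1-3, and a linear kernel -- ten kernels in
# all. Training Gram matrices are normalized to unit trace; cross-kernel
# blocks for prediction are divided by the same training trace so train and
# test embeddings stay consistent. With modality blocks, the full pool is
# built per block on that block's columns only (10 x #blocks kernels).

#' Describe a base kernel
#'
#' @param family one of `"gaussian"`, `"polynomial"`, `"linear"`.
#' @param param bandwidth sigma (> 0) for Gaussian, degree (1, 2 or 3) for
#'   polynomial, ignored for linear. The Gaussian kernel is
#'   `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))` with sigma the listed
#'   bandwidth; the polynomial kernel is the inhomogeneous
#'   `(x'y + 1)^degree`, so its degree-1 member differs from the linear
#'   kernel `x'y` and the default pool has ten distinct members.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "polynomial", "linear"),
                        param = NULL) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (is.null(param) || param <= 0) stop("gaussian bandwidth must be > 0")
  } else if (family == "polynomial") {
    if (is.null(param) || !param %in% c(1, 2, 3)) {
      stop("polynomial degree must be 1, 2 or 3")
    }
  } else {
    param <- NULL
  }
  structure(list(family = family, param = param), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("kernel_spec:", x$family,
      if (!is.null(x$param)) paste0("(", x$param, ")"), "\n")
  invisible(x)
}

#' The default ten-kernel candidate set
#'
#' Six Gaussian bandwidths `2^-2 .. 2^3`, polynomial degrees 1-3, and a
#' linear kernel.
#'
#' @param bandwidths Gaussian bandwidths.
#' @param degrees polynomial degrees.
#' @param include_linear include the plain linear kernel.
#' @return A list of [kernel_spec] objects.
#' @export
default_kernel_specs <- function(bandwidths = 2^(-2:3), degrees = 1:3,
                                 include_linear = TRUE) {
  specs <- c(
    lapply(bandwidths, function(s) kernel_spec("gaussian", s)),
    lapply(degrees, function(d) kernel_spec("polynomial", d))
  )
  if (include_linear) specs <- c(specs, list(kernel_spec("linear")))
  specs
}

#' Evaluate a kernel between two sample sets
#'
#' @param spec a [kernel_spec].
#' @param A numeric n x p matrix.
#' @param B numeric n' x p matrix (default `A`).
#' @return The n x n' matrix of kernel evaluations `k(a_i, b_j)`.
#' @export
gram_matrix <- function(spec, A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("column mismatch: A has ", ncol(A), " columns, B has ", ncol(B))
  }
  ip <- tcrossprod(A, B)
  switch(spec$family,
    linear = ip,
    polynomial = (ip + 1)^spec$param,
    gaussian = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * ip
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * spec$param^2))
    }
  )
}

#' Normalize a square kernel matrix to unit trace
#'
#' @param K square numeric matrix with positive trace.
#' @return `K / sum(diag(K))`, whose trace is 1. Scaling by a positive
#'   constant preserves symmetry, positive semidefiniteness and the
#'   eigenvectors.
#' @export
unit_trace_normalize <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  tr <- sum(diag(K))
  if (tr <= 0) stop("nonpositive trace: cannot normalize")
  K / tr
}

#' Build the training kernel pool
#'
#' Computes the unit-trace-normalized training Gram matrix for every spec.
#' With `per_modality = TRUE` (requires `modality_blocks` on the dataset, or
#' an explicit `blocks` list), the full spec set is instantiated once per
#' modality block, each kernel evaluated on that block's feature columns
#' only, yielding `length(specs) * n_blocks` kernels.
#'
#' @param ds a [multitask_dataset] (typically already z-scored) or a plain
#'   numeric matrix.
#' @param specs list of [kernel_spec]s (default: the ten-kernel set).
#' @param per_modality build the pool per modality block.
#' @param blocks optional named list of column indices overriding the
#'   dataset's `modality_blocks`.
#' @return An object of class `kernel_pool` with `specs`, `grams`
#'   (unit-trace training Grams), `traces` (the normalization constants),
#'   `block` (modality label per kernel, `NA` when pooled), `X` (the training
#'   features, kept for cross-kernel evaluation) and `blocks`.
#' @export
build_pool <- function(ds, specs = default_kernel_specs(),
                       per_modality = FALSE, blocks = NULL) {
  X <- if (inherits(ds, "multitask_dataset")) ds$X else as.matrix(ds)
  if (is.null(blocks) && inherits(ds, "multitask_dataset")) {
    blocks <- ds$modality_blocks
  }
  if (per_modality) {
    if (is.null(blocks) || length(blocks) == 0L) {
      stop("per_modality = TRUE requires modality blocks")
    }
    if (any(lengths(blocks) == 0L)) stop("empty modality block")
    spec_list <- list(); gram_list <- list(); tr_list <- c(); blk <- c()
    cols <- list()
    for (b in names(blocks)) {
      Xb <- X[, blocks[[b]], drop = FALSE]
      for (sp in specs) {
        K <- gram_matrix(sp, Xb)
        tr <- sum(diag(K))
        if (tr <= 0) stop("nonpositive trace for a kernel in block ", b)
        spec_list <- c(spec_list, list(sp))
        gram_list <- c(gram_list, list(K / tr))
        tr_list <- c(tr_list, tr)
        blk <- c(blk, b)
        cols <- c(cols, list(blocks[[b]]))
      }
    }
  } else {
    spec_list <- specs
    gram_list <- vector("list", length(specs))
    tr_list <- numeric(length(specs))
    blk <- rep(NA_character_, length(specs))
    cols <- rep(list(seq_len(ncol(X))), length(specs))
    for (j in seq_along(specs)) {
      K <- gram_matrix(specs[[j]], X)
      tr <- sum(diag(K))
      if (tr <= 0) stop("nonpositive trace for kernel ", j)
      gram_list[[j]] <- K / tr
      tr_list[j] <- tr
    }
  }
  structure(
    list(specs = spec_list, grams = gram_list, traces = tr_list,
         block = blk, columns = cols, X = X, k = length(gram_list)),
    class = "kernel_pool"
  )
}

#' @export
print.kernel_pool <- function(x, ...) {
  cat("kernel_pool: ", x$k, " kernels on ", nrow(x$X), " samples\n", sep = "")
  invisible(x)
}

#' Cross-kernel blocks for new samples
#'
#' Evaluates every pool kernel between new rows and the training rows, scaled
#' by the training Gram's normalization trace, so that new-sample embeddings
#' are consistent with the unit-trace training Grams.
#'
#' @param pool a [kernel_pool].
#' @param X_new numeric matrix with the training feature columns.
#' @return A list of `n_new x m` matrices, one per kernel.
#' @export
pool_cross <- function(pool, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(pool$X)) {
    stop("shape mismatch: X_new has ", ncol(X_new),
         " columns; pool was built on ", ncol(pool$X))
  }
  lapply(seq_len(pool$k), function(j) {
    gram_matrix(pool$specs[[j]],
                X_new[, pool$columns[[j]], drop = FALSE],
                pool$X[, pool$columns[[j]], drop = FALSE]) / pool$traces[j]
  })
}
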