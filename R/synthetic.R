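# Synthetic multitask data generators.
#
# Three regimes emulate the statistical structure the solvers assume, so
# everything is testable without any clinical download:
#   linear           -- row-sparse shared-support linear model (the regime
#                       targeted by the lq,1 penalty),
#   kernel-nonlinear -- targets drawn in the RKHS of a source kernel via
#                       sparse dual coefficients, so a kernel learner can fit
#                       what a linear model cannot,
#   multimodal       -- feature blocks (modalities) each carrying an
#                       independent share of the signal, so no single block
#                       suffices.
# All generators are deterministic under the spec's seed and homoscedastic
# Gaussian in the noise; heavier-tailed noise is available behind a flag.

#' Describe a synthetic multitask dataset
#'
#' @param m samples, p features, n_tasks tasks.
#' @param p number of features.
#' @param n_tasks number of tasks.
#' @param s number of active (signal-carrying) feature rows, shared across
#'   tasks.
#' @param noise_sd Gaussian noise standard deviation; ignored when `snr` is
#'   given.
#' @param snr optional per-task signal-to-noise ratio (variance ratio); the
#'   noise sd is then derived per task from the realized coefficients.
#' @param mode one of `"linear"`, `"kernel-nonlinear"`, `"multimodal"`.
#' @param kernel_source a [kernel_spec] for the nonlinear regime.
#' @param block_sizes feature-block sizes for the multimodal regime (must sum
#'   to `p`).
#' @param support_overlap fraction of the active rows shared by all tasks
#'   (default 1 = identical support); the rest are drawn per task.
#' @param heavy_tails use scaled t(3) noise instead of Gaussian.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 200L, p = 50L, n_tasks = 5L, s = 5L,
                           noise_sd = 1, snr = NULL,
                           mode = c("linear", "kernel-nonlinear",
                                    "multimodal"),
                           kernel_source = NULL, block_sizes = NULL,
                           support_overlap = 1, heavy_tails = FALSE,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (s > p) stop("invalid spec: s must not exceed p")
  if (noise_sd < 0) stop("invalid spec: noise_sd must be nonnegative")
  if (!is.null(block_sizes) && sum(block_sizes) != p) {
    stop("invalid spec: block_sizes must sum to p")
  }
  if (mode == "kernel-nonlinear" && is.null(kernel_source)) {
    stop("invalid spec: kernel-nonlinear mode requires kernel_source")
  }
  if (mode == "multimodal" &&
      (is.null(block_sizes) || length(block_sizes) < 2L)) {
    stop("invalid spec: multimodal mode requires at least two block_sizes")
  }
  structure(list(m = as.integer(m), p = as.integer(p),
                 n_tasks = as.integer(n_tasks), s = as.integer(s),
                 noise_sd = noise_sd, snr = snr, mode = mode,
                 kernel_source = kernel_source, block_sizes = block_sizes,
                 support_overlap = support_overlap,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_noise <- function(n, sd, heavy) {
  if (heavy) sd * stats::rt(n, df = 3) / sqrt(3) else stats::rnorm(n, 0, sd)
}

# signal-scaled noise sd: per-task sd implied by a variance-ratio SNR given
# realized coefficients (X columns are standard normal, so the signal
# variance of task t is sum_h theta_ht^2)
noise_sd_from_snr <- function(theta, snr) {
  sqrt(colSums(theta^2) / snr)
}

#' Row-sparse linear multitask data
#'
#' `X` has standard-normal entries; `Theta` has `s` nonzero rows (a support
#' set shared across tasks, relaxed by `support_overlap`), nonzero entries
#' drawn uniformly from the union of `[-1.5, -0.5]` and `[0.5, 1.5]`;
#' `Y = X Theta + noise`. When `snr` is set the noise sd is derived per task
#' so the realized variance ratio matches it.
#'
#' @param spec a [synthetic_spec] with `mode = "linear"`.
#' @return A list with `dataset` (a [multitask_dataset]), `theta` (the true
#'   p x T coefficients) and `support` (the active row indices, union over
#'   tasks).
#' @export
gen_linear <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$mode == "linear")
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$m * spec$p), spec$m, spec$p)
    theta <- matrix(0, spec$p, spec$n_tasks)
    n_shared <- round(spec$support_overlap * spec$s)
    shared <- if (spec$s > 0) sample(spec$p, n_shared) else integer(0)
    for (t in seq_len(spec$n_tasks)) {
      own <- setdiff(seq_len(spec$p), shared)
      extra <- if (spec$s - n_shared > 0) {
        sample(own, spec$s - n_shared)
      } else integer(0)
      rows <- c(shared, extra)
      vals <- stats::runif(length(rows), 0.5, 1.5) *
        sample(c(-1, 1), length(rows), replace = TRUE)
      theta[rows, t] <- vals
    }
    signal <- X %*% theta
    sds <- if (!is.null(spec$snr) && spec$s > 0) {
      noise_sd_from_snr(theta, spec$snr)
    } else {
      rep(spec$noise_sd, spec$n_tasks)
    }
    E <- vapply(sds, function(sd_t) draw_noise(spec$m, sd_t, spec$heavy_tails),
                numeric(spec$m))
    ds <- multitask_dataset(X, signal + E)
    list(dataset = ds, theta = theta,
         support = sort(unique(which(rowSums(abs(theta)) > 0))))
  })
}

#' Kernel-generated nonlinear multitask data
#'
#' Draws `X` standard normal, builds the source-kernel Gram `K` on `X`, and
#' sets per-task function values `f_t = K c_t` with sparse dual coefficient
#' vectors `c_t` sharing their support pattern across tasks; each `f_t` is
#' rescaled to unit variance before noise is added. A regression using the
#' source kernel can represent `f_t` exactly, while a linear model in `X`
#' generally cannot.
#'
#' @param spec a [synthetic_spec] with `mode = "kernel-nonlinear"` and a
#'   `kernel_source`.
#' @return A list with `dataset`, `coefficients` (the m x T dual matrix,
#'   rescaled), and `f` (the noiseless function values).
#' @export
gen_kernel_nonlinear <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            spec$mode == "kernel-nonlinear")
  with_seed(spec$seed, {
    X <- matrix(stats::rnorm(spec$m * spec$p), spec$m, spec$p)
    K <- gram_matrix(spec$kernel_source, X)
    n_active <- max(spec$s, 1L)
    support <- sample(spec$m, min(n_active * 4L, spec$m))
    C <- matrix(0, spec$m, spec$n_tasks)
    for (t in seq_len(spec$n_tasks)) {
      C[support, t] <- stats::rnorm(length(support))
    }
    f <- K %*% C
    sc <- apply(f, 2L, stats::sd)
    sc[sc == 0] <- 1
    f <- sweep(f, 2L, sc, "/")
    C <- sweep(C, 2L, sc, "/")
    E <- matrix(draw_noise(spec$m * spec$n_tasks, spec$noise_sd,
                           spec$heavy_tails), spec$m, spec$n_tasks)
    list(dataset = multitask_dataset(X, f + E), coefficients = C, f = f)
  })
}

#' Multimodal multitask data
#'
#' Splits the features into named blocks ("modalities"); each block carries
#' an independent row-sparse linear component of the signal with equal
#' variance share, so combining blocks strictly increases the available
#' signal and no single block suffices. `snr` (or `noise_sd`) controls the
#' noise against the total signal.
#'
#' @param spec a [synthetic_spec] with `mode = "multimodal"` and
#'   `block_sizes`.
#' @return A list with `dataset` (modality blocks labeled `modality_1`, ...)
#'   and `theta` (the full p x T coefficient matrix).
#' @export
gen_multimodal <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$mode == "multimodal")
  with_seed(spec$seed, {
    nb <- length(spec$block_sizes)
    X <- matrix(stats::rnorm(spec$m * spec$p), spec$m, spec$p)
    starts <- cumsum(c(1L, spec$block_sizes))[seq_len(nb)]
    blocks <- lapply(seq_len(nb), function(b) {
      seq(starts[b], length.out = spec$block_sizes[b])
    })
    names(blocks) <- paste0("modality_", seq_len(nb))
    theta <- matrix(0, spec$p, spec$n_tasks)
    s_block <- max(1L, ceiling(spec$s / nb))
    for (b in seq_len(nb)) {
      rows <- blocks[[b]][sample(length(blocks[[b]]), min(s_block,
                                                          length(blocks[[b]])))]
      for (t in seq_len(spec$n_tasks)) {
        theta[rows, t] <- stats::runif(length(rows), 0.5, 1.5) *
          sample(c(-1, 1), length(rows), replace = TRUE)
      }
    }
    # equalize the variance share of each block's component
    for (b in seq_len(nb)) {
      ix <- blocks[[b]]
      v <- colSums(theta[ix, , drop = FALSE]^2)
      v[v == 0] <- 1
      theta[ix, ] <- sweep(theta[ix, , drop = FALSE], 2L, sqrt(v * nb), "/")
    }
    signal <- X %*% theta        # total signal variance ~ 1 per task
    sds <- if (!is.null(spec$snr)) {
      noise_sd_from_snr(theta, spec$snr)
    } else {
      rep(spec$noise_sd, spec$n_tasks)
    }
    E <- vapply(sds, function(sd_t) draw_noise(spec$m, sd_t, spec$heavy_tails),
                numeric(spec$m))
    ds <- multitask_dataset(X, signal + E, modality_blocks = blocks)
    list(dataset = ds, theta = theta, blocks = blocks)
  })
}

#' Write a simulated dataset as delimited tables plus a truth file
#'
#' Emits `<prefix>_features.csv`, `<prefix>_targets.csv` and
#' `<prefix>_truth.json` (coefficients / support / blocks), the layout
#' [load_dataset] reads back.
#'
#' @param sim a result from [gen_linear], [gen_kernel_nonlinear] or
#'   [gen_multimodal].
#' @param prefix output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_simulation <- function(sim, prefix) {
  ds <- sim$dataset
  fx <- paste0(prefix, "_features.csv")
  fy <- paste0(prefix, "_targets.csv")
  ft <- paste0(prefix, "_truth.json")
  utils::write.csv(as.data.frame(ds$X), fx, row.names = FALSE)
  utils::write.csv(as.data.frame(ds$Y), fy, row.names = FALSE)
  truth <- sim[setdiff(names(sim), "dataset")]
  jsonlite::write_json(truth, ft, digits = NA, auto_unbox = TRUE)
  invisible(c(features = fx, targets = fy, truth = ft))
}
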