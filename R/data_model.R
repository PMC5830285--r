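#' Construct a multitask dataset
#'
#' Bundles a numeric feature matrix `X` (samples x features) and a response
#' matrix `Y` (samples x tasks) together with optional per-task observation
#' masks and a partition of features into named modality blocks (e.g. MRI /
#' PET / demographics), validating the shared-shape invariants every solver
#' in the package relies on.
#'
#' @param X numeric matrix, m samples by p features.
#' @param Y numeric matrix (or vector, treated as one task), m by T.
#' @param task_names character vector of length T.
#' @param feature_names character vector of length p.
#' @param modality_blocks optional named list of integer (or character) column
#'   index vectors partitioning `1:p` exactly.
#' @param observed optional logical m x T matrix marking which scores are
#'   observed; defaults to all `TRUE`. Per-task sample counts `m_t` are its
#'   column sums.
#' @return An object of class `multitask_dataset` with elements `X`, `Y`,
#'   `task_names`, `feature_names`, `modality_blocks`, `observed`, `m`, `p`,
#'   `n_tasks`.
#' @export
multitask_dataset <- function(X, Y, task_names = NULL, feature_names = NULL,
                              modality_blocks = NULL, observed = NULL) {
  X <- as.matrix(X)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) {
    stop("shape error: X has ", nrow(X), " rows but Y has ", nrow(Y), " rows")
  }
  if (ncol(X) < 1L || ncol(Y) < 1L) stop("X and Y must each have at least one column")
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  if (!all(is.finite(Y))) stop("Y contains non-finite entries")

  p <- ncol(X); Tn <- ncol(Y); m <- nrow(X)
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(p))
  }
  if (is.null(task_names)) {
    task_names <- colnames(Y)
    if (is.null(task_names)) task_names <- paste0("task_", seq_len(Tn))
  }
  stopifnot(length(feature_names) == p, length(task_names) == Tn)
  colnames(X) <- feature_names
  colnames(Y) <- task_names

  if (!is.null(modality_blocks)) {
    if (is.null(names(modality_blocks)) || any(!nzchar(names(modality_blocks)))) {
      stop("modality_blocks must be a named list")
    }
    modality_blocks <- lapply(modality_blocks, function(ix) {
      if (is.character(ix)) ix <- match(ix, feature_names)
      ix <- as.integer(ix)
      if (anyNA(ix)) stop("modality_blocks refers to unknown feature names")
      ix
    })
    all_ix <- sort(unlist(modality_blocks, use.names = FALSE))
    if (!identical(all_ix, seq_len(p))) {
      stop("modality_blocks must partition the feature columns 1..p exactly")
    }
  }
  if (is.null(observed)) {
    observed <- matrix(TRUE, m, Tn)
  } else {
    observed <- as.matrix(observed)
    if (!is.logical(observed) || nrow(observed) != m || ncol(observed) != Tn) {
      stop("observed must be a logical m x T matrix")
    }
    if (any(colSums(observed) == 0L)) stop("every task needs at least one observed sample")
  }
  structure(
    list(X = X, Y = Y, task_names = task_names, feature_names = feature_names,
         modality_blocks = modality_blocks, observed = observed,
         m = m, p = p, n_tasks = Tn),
    class = "multitask_dataset"
  )
}

#' @export
print.multitask_dataset <- function(x, ...) {
  cat("multitask_dataset: ", x$m, " samples, ", x$p, " features, ",
      x$n_tasks, " tasks\n", sep = "")
  if (!is.null(x$modality_blocks)) {
    cat("modality blocks:",
        paste(sprintf("%s (%d)", names(x$modality_blocks),
                      lengths(x$modality_blocks)), collapse = ", "), "\n")
  }
  mt <- colSums(x$observed)
  if (any(mt < x$m)) cat("observed per task:", paste(mt, collapse = ", "), "\n")
  invisible(x)
}

# Read a delimited table with header; delimiter chosen by extension
# (.tsv/.txt -> tab, otherwise comma). Every cell must parse as a finite
# number; the first offending cell is named in the error.
read_numeric_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("no columns found in ", path)
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    vals <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(vals))
    if (length(bad) > 0L) {
      stop(sprintf(
        "parse error in %s: cell (row %d, column '%s') is '%s', not a finite number",
        path, bad[1L], colnames(df)[j], df[[j]][bad[1L]]))
    }
    mat[, j] <- vals
  }
  mat
}

#' Load a multitask dataset from delimited text tables
#'
#' Reads a feature table and a target table (CSV by default, TSV for
#' `.tsv`/`.txt` extensions; both with header rows) and assembles a
#' [multitask_dataset]. An optional modality map (a named list of column-name
#' vectors, or a path to a YAML/JSON file containing one) assigns feature
#' columns to modality blocks for per-modality kernel pooling.
#'
#' @param features_path path to the feature table (m x p, header row).
#' @param targets_path path to the target table (m x T, header row).
#' @param modality_map optional named list mapping block name -> feature column
#'   names, or a path to a YAML (`.yml`/`.yaml`) or JSON file with that layout.
#' @return A [multitask_dataset].
#' @export
load_dataset <- function(features_path, targets_path, modality_map = NULL) {
  X <- read_numeric_table(features_path)
  Y <- read_numeric_table(targets_path)
  if (nrow(X) != nrow(Y)) {
    stop("shape error: feature table has ", nrow(X),
         " rows but target table has ", nrow(Y))
  }
  blocks <- NULL
  if (!is.null(modality_map)) {
    if (is.character(modality_map) && length(modality_map) == 1L) {
      blocks <- if (grepl("\\.ya?ml$", modality_map, ignore.case = TRUE)) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
          stop("the yaml package is required to read a YAML modality map")
        }
        yaml::read_yaml(modality_map)
      } else {
        jsonlite::read_json(modality_map, simplifyVector = TRUE)
      }
    } else {
      blocks <- modality_map
    }
    blocks <- lapply(blocks, unlist, use.names = FALSE)
  }
  multitask_dataset(X, Y, modality_blocks = blocks)
}

#' Z-score a dataset on training-fold statistics
#'
#' Centers and scales every feature column (and optionally every target
#' column) using the mean and the sample (n-1 denominator) standard deviation
#' computed over `fit_index` only, so that held-out rows are transformed with
#' training statistics and no information leaks across folds. Columns with
#' zero spread on the fitting rows carry no signal and would divide by zero;
#' they are dropped with a warning.
#'
#' @param ds a [multitask_dataset].
#' @param fit_index integer vector of rows used to estimate the statistics
#'   (default: all rows).
#' @param scale_y logical; also z-score the target columns (default `FALSE`).
#' @return A list with `dataset` (the transformed [multitask_dataset]) and
#'   `scaler`, a record of the fitted statistics (serializable via
#'   [scaler_to_json]) that [apply_scaler] uses on new rows.
#' @export
zscore <- function(ds, fit_index = seq_len(ds$m), scale_y = FALSE) {
  stopifnot(inherits(ds, "multitask_dataset"))
  fit_index <- as.integer(fit_index)
  if (length(fit_index) == 0L) stop("fit_index must be nonempty")
  Xf <- ds$X[fit_index, , drop = FALSE]
  mu <- colMeans(Xf)
  sd_ <- apply(Xf, 2L, stats::sd)   # sample sd, n-1 denominator
  keep <- sd_ > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature column(s): ",
            paste(ds$feature_names[!keep], collapse = ", "))
  }
  scaler <- list(
    feature_names = ds$feature_names[keep],
    center = mu[keep], scale = sd_[keep],
    scale_y = isTRUE(scale_y)
  )
  Xz <- sweep(sweep(ds$X[, keep, drop = FALSE], 2L, scaler$center, "-"),
              2L, scaler$scale, "/")
  Y <- ds$Y
  if (isTRUE(scale_y)) {
    Yf <- ds$Y[fit_index, , drop = FALSE]
    ymu <- colMeans(Yf)
    ysd <- apply(Yf, 2L, stats::sd)
    if (any(ysd <= 0)) stop("zero-variance target column; cannot z-score Y")
    scaler$y_center <- ymu
    scaler$y_scale <- ysd
    Y <- sweep(sweep(Y, 2L, ymu, "-"), 2L, ysd, "/")
  }
  blocks <- ds$modality_blocks
  if (!is.null(blocks)) {
    blocks <- lapply(blocks, function(ix) {
      nm <- ds$feature_names[ix]
      match(intersect(nm, scaler$feature_names), scaler$feature_names)
    })
    blocks <- blocks[lengths(blocks) > 0L]
    if (length(blocks) == 0L) blocks <- NULL
  }
  out <- multitask_dataset(Xz, Y, task_names = ds$task_names,
                           feature_names = scaler$feature_names,
                           modality_blocks = blocks, observed = ds$observed)
  list(dataset = out, scaler = scaler)
}

#' Apply a fitted scaler to new feature rows
#'
#' @param scaler a scaler record from [zscore].
#' @param X_new numeric matrix with the original feature columns (extra
#'   columns dropped by name; the columns kept at fit time must be present).
#' @return The transformed matrix restricted to the scaler's columns.
#' @export
apply_scaler <- function(scaler, X_new) {
  X_new <- as.matrix(X_new)
  if (!is.null(colnames(X_new))) {
    miss <- setdiff(scaler$feature_names, colnames(X_new))
    if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
    X_new <- X_new[, scaler$feature_names, drop = FALSE]
  } else if (ncol(X_new) != length(scaler$feature_names)) {
    stop("X_new has ", ncol(X_new), " columns; scaler expects ",
         length(scaler$feature_names))
  }
  sweep(sweep(X_new, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Serialize / restore a scaler record as JSON
#'
#' @param scaler a scaler record from [zscore].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
scaler_to_json <- function(scaler, path = NULL) {
  js <- jsonlite::toJSON(scaler, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname scaler_to_json
#' @param json JSON string or file path produced by [scaler_to_json].
#' @export
scaler_from_json <- function(json) {
  sc <- jsonlite::fromJSON(json)
  sc$center <- stats::setNames(unlist(sc$center), sc$feature_names)
  sc$scale <- stats::setNames(unlist(sc$scale), sc$feature_names)
  sc
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a nested cross-validation fold plan
#'
#' Assigns samples to `outer` folds by a uniform random permutation (fold
#' sizes differ by at most one), and for each outer training set assigns its
#' rows to `inner` folds the same way. Deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param m number of samples.
#' @param outer number of outer folds (default 10).
#' @param inner number of inner tuning folds per outer fold (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: `outer_folds` is a list of
#'   `list(train, test)` index pairs; `inner_folds` is a parallel list, each
#'   element a list of `list(train, test)` pairs indexing into the full
#'   sample set (subsets of the outer training rows).
#' @export
make_folds <- function(m, outer = 10L, inner = 5L, seed = 1L) {
  m <- as.integer(m); outer <- as.integer(outer); inner <- as.integer(inner)
  if (outer < 2L) stop("configuration error: need at least 2 outer folds")
  if (m < outer) {
    stop("configuration error: m = ", m, " samples cannot fill ",
         outer, " outer folds")
  }
  split_folds <- function(idx, k) {
    assign <- rep(seq_len(k), length.out = length(idx))
    perm <- sample(idx)
    lapply(seq_len(k), function(f) {
      test <- sort(perm[assign == f])
      list(train = sort(setdiff(idx, test)), test = test)
    })
  }
  with_seed(seed, {
    outer_folds <- split_folds(seq_len(m), outer)
    inner_folds <- lapply(outer_folds, function(fold) {
      if (inner >= 2L && length(fold$train) >= inner) {
        split_folds(fold$train, inner)
      } else {
        list()
      }
    })
    structure(list(outer_folds = outer_folds, inner_folds = inner_folds,
                   m = m, outer = outer, inner = inner, seed = seed),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan: ", x$outer, " outer folds x ", x$inner,
      " inner folds over ", x$m, " samples (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Subset a dataset by row index, keeping masks and block structure.
subset_dataset <- function(ds, index) {
  multitask_dataset(ds$X[index, , drop = FALSE], ds$Y[index, , drop = FALSE],
                    task_names = ds$task_names,
                    feature_names = ds$feature_names,
                    modality_blocks = ds$modality_blocks,
                    observed = ds$observed[index, , drop = FALSE])
}
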