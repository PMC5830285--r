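# lq-regularized Euclidean projections.
#
# The row-sparse mixed-norm penalty lambda * sum_h ||theta_h.||_q enters the
# accelerated proximal-gradient solver only through its proximal operator,
#   argmin_Theta 1/2 ||Theta - V||_F^2 + lambda sum_h ||theta_h.||_q ,
# which decouples into p independent per-row problems
#   argmin_theta 1/2 ||theta - v||_2^2 + lambda ||theta||_q .
# Closed forms exist for q in {1, 2, Inf}; for other q in (1, Inf) the
# optimum solves theta_i + c theta_i^(q-1) = |v_i| with the scalar
# c = lambda * ||theta||_q^(1-q), found by a two-level bisection (outer on c,
# inner on each coordinate root).

# dual exponent: 1/q + 1/qbar = 1
dual_exponent <- function(q) {
  if (q == 1) return(Inf)
  if (is.infinite(q)) return(1)
  q / (q - 1)
}

# ||v||_q handling q = Inf and avoiding overflow for large finite q
lq_norm <- function(v, q) {
  a <- abs(v)
  if (is.infinite(q)) return(max(a))
  if (q == 1) return(sum(a))
  mx <- max(a)
  if (mx == 0) return(0)
  mx * sum((a / mx)^q)^(1 / q)
}

# row-wise lq norms of a matrix (column-major recycling divides row i by
# scale[i]); zero rows yield 0
row_lq_norm <- function(A, q) {
  A <- abs(A)
  if (is.infinite(q)) return(apply(A, 1L, max))
  if (q == 1) return(rowSums(A))
  mx <- apply(A, 1L, max)
  scale <- ifelse(mx == 0, 1, mx)
  scale * rowSums((A / scale)^q)^(1 / q)
}

# exact root of zeta(u) = sum_i max(a_i - u, 0) - lambda for the q = Inf
# prox, by scanning the piecewise-linear segments between sorted |v| values
linf_prox_threshold <- function(a, lam) {
  # caller guarantees sum(a) > lam
  s <- sort(a, decreasing = TRUE)
  cs <- cumsum(s)
  k <- seq_along(s)
  u <- (cs - lam) / k
  lower <- c(s[-1L], 0)
  ok <- which(u >= lower & u <= s)
  u[ok[1L]]
}

# Batched general-q prox on a nonnegative matrix A (rows already known to be
# above the dual-norm threshold). Outer bisection on the per-row constant c,
# inner bisection for the coordinate roots of phi_c^v(t) = t + c t^(q-1) - a.
prox_general_q_matrix <- function(A, q, lam, root_tol = 1e-10,
                                  max_bisect = 200L) {
  nr <- nrow(A)
  inner_iters <- min(max_bisect, 100L)
  theta_given_c <- function(cvec) {
    lo <- matrix(0, nr, ncol(A))
    hi <- A
    for (i in seq_len(inner_iters)) {
      mid <- (lo + hi) / 2
      f <- mid + cvec * mid^(q - 1) - A
      up <- f < 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
      if (max(hi - lo) < root_tol * max(1, max(A))) break
    }
    (lo + hi) / 2
  }
  gap <- function(cvec) {
    th <- theta_given_c(cvec)
    row_lq_norm(th, q) - (lam / cvec)^(1 / (q - 1))
  }
  rq <- row_lq_norm(A, q)
  c_lo <- lam * rq^(1 - q)           # g(c_lo) < 0 since theta(c_lo) < a
  c_hi <- c_lo
  for (i in seq_len(60L)) {
    need <- gap(c_hi) < 0
    if (!any(need)) break
    c_hi[need] <- c_hi[need] * 4
  }
  for (i in seq_len(max_bisect)) {
    cm <- (c_lo + c_hi) / 2
    g <- gap(cm)
    pos <- g > 0
    c_hi[pos] <- cm[pos]
    c_lo[!pos] <- cm[!pos]
    if (max((c_hi - c_lo) / c_lo) < root_tol) break
  }
  theta_given_c((c_lo + c_hi) / 2)
}

#' Proximal operator of the lq norm on a single row
#'
#' Computes `argmin_theta 1/2 ||theta - v||_2^2 + lam * ||theta||_q`. The
#' output is exactly zero iff the dual norm `||v||_qbar <= lam` (with
#' `qbar = q/(q-1)`); otherwise soft thresholding (q = 1), radial shrinkage
#' (q = 2), a piecewise-linear exact clip (q = Inf), or the two-level
#' bisection root-finder (other q) applies.
#'
#' @param v finite numeric vector.
#' @param q norm exponent, `>= 1` (may be `Inf`).
#' @param lam nonnegative regularization level.
#' @param root_tol relative tolerance for the bisection root-finders.
#' @param max_bisect iteration cap for the outer bisection.
#' @return Numeric vector of the same length as `v`.
#' @export
project_row_lq <- function(v, q, lam, root_tol = 1e-10, max_bisect = 200L) {
  if (!is.numeric(q) || length(q) != 1L || q < 1) {
    stop("configuration error: q must be a single number >= 1")
  }
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0) {
    stop("configuration error: lam must be a single nonnegative number")
  }
  if (!all(is.finite(v))) stop("input error: v contains non-finite entries")
  if (lam == 0) return(v)
  qbar <- dual_exponent(q)
  if (lq_norm(v, qbar) <= lam) return(rep(0, length(v)))
  a <- abs(v); s <- sign(v)
  if (q == 1) return(s * pmax(a - lam, 0))
  if (q == 2) {
    n2 <- sqrt(sum(v^2))
    return((n2 - lam) / n2 * v)
  }
  if (is.infinite(q)) {
    u <- linf_prox_threshold(a, lam)
    return(s * pmin(a, u))
  }
  th <- prox_general_q_matrix(matrix(a, nrow = 1L), q, lam,
                              root_tol, max_bisect)
  s * as.vector(th)
}

#' Row-wise lq,1 proximal operator on a matrix
#'
#' Applies [project_row_lq] independently to every row of `V`:
#' `argmin_Theta 1/2 ||Theta - V||_F^2 + lam * sum_h ||theta_h.||_q`.
#' The q = 1 and q = 2 cases are fully vectorized across rows, which is what
#' the linear solver's inner loop uses.
#'
#' @param V finite numeric matrix (features x tasks).
#' @inheritParams project_row_lq
#' @return Matrix of the same shape as `V`.
#' @export
project_matrix_lq1 <- function(V, q, lam, root_tol = 1e-10,
                               max_bisect = 200L) {
  V <- as.matrix(V)
  if (!all(is.finite(V))) stop("input error: V contains non-finite entries")
  if (!is.numeric(q) || length(q) != 1L || q < 1) {
    stop("configuration error: q must be a single number >= 1")
  }
  if (lam < 0) stop("configuration error: lam must be nonnegative")
  if (lam == 0) return(V)
  if (q == 1) {
    return(sign(V) * pmax(abs(V) - lam, 0))
  }
  if (q == 2) {
    n2 <- sqrt(rowSums(V^2))
    shrink <- ifelse(n2 > lam, (n2 - lam) / pmax(n2, .Machine$double.xmin), 0)
    return(V * shrink)
  }
  if (is.infinite(q)) {
    out <- t(apply(V, 1L, project_row_lq, q = Inf, lam = lam,
                   root_tol = root_tol, max_bisect = max_bisect))
    dim(out) <- dim(V)
    return(out)
  }
  qbar <- dual_exponent(q)
  active <- row_lq_norm(V, qbar) > lam
  out <- matrix(0, nrow(V), ncol(V))
  if (any(active)) {
    A <- abs(V[active, , drop = FALSE])
    th <- prox_general_q_matrix(A, q, lam, root_tol, max_bisect)
    out[active, ] <- sign(V[active, , drop = FALSE]) * th
  }
  dimnames(out) <- dimnames(V)
  out
}
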