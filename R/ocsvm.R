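## One-class SVM novelty stage over supervectors. The model is stated
## in the normalised dual form
##   min_a 1/2 sum_ij a_i a_j k(x_i, x_j)  s.t. 0 <= a_i <= 1/(nu l),
##   sum_i a_i = 1,
## with RBF kernel k(x,y) = exp(-gamma ||x-y||^2), decision
##   f(x) = sgn( sum_i a_i k(x_i, x) - rho ),  sgn(0) -> +1 (normal).
## The dual is solved by libsvm (e1071); libsvm's internal scaling
## (sum alpha = nu*l, box [0,1]) is divided out so the stored
## coefficients satisfy the constraints above exactly.

rbf_kernel <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Train a one-class SVM novelty detector
#'
#' @param X Numeric matrix of training vectors (rows = observations),
#'   typically Gaussian Mean Supervectors. Fed raw by default; set
#'   `standardize_cols = TRUE` to z-score columns first (the scaling is
#'   stored and reapplied at prediction).
#' @param nu Fraction parameter in (0, 1]: upper-bounds the training
#'   outlier fraction and lower-bounds the support-vector fraction.
#' @param gamma RBF kernel width.
#' @param seed Integer seed (kept for interface symmetry; the dual has a
#'   unique optimum so the solver is deterministic).
#' @param standardize_cols Optional per-column z-scoring.
#' @return An object of class `ocsvm_model` with support vectors `sv`,
#'   normalised coefficients `alpha` (sum 1, each in `[0, 1/(nu l)]`),
#'   offset `rho`, `gamma`, `nu`, and training count `l`.
#' @export
train_ocsvm <- function(X, nu, gamma, seed = 1L, standardize_cols = FALSE) {
  X <- as.matrix(X)
  l <- nrow(X)
  if (l < 2L) stop("train_ocsvm: need at least two training vectors")
  if (nu <= 0 || nu > 1) stop("train_ocsvm: nu must be in (0, 1]")
  if (gamma <= 0) stop("train_ocsvm: gamma must be positive")
  center <- NULL; scale <- NULL
  if (standardize_cols) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  fit <- e1071::svm(X, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma, nu = nu,
                    scale = FALSE, tolerance = 1e-7, fitted = FALSE)
  if (is.null(fit$coefs) || nrow(fit$SV) == 0L) {
    stop("train_ocsvm: solver returned no support vectors")
  }
  alpha <- as.numeric(fit$coefs) / (nu * l)   # libsvm: sum(coefs) = nu*l
  rho <- fit$rho / (nu * l)
  if (!is.finite(rho)) {
    # every coefficient at a bound (e.g. nu = 1): recover rho from the
    # KKT bound interval instead of the (undefined) free-SV condition
    alpha_full <- rep(0, l)
    alpha_full[fit$index] <- alpha
    rho <- suppressWarnings(select_rho(alpha_full, rbf_kernel(X, X, gamma),
                                       nu, l))
  }
  structure(list(sv = as.matrix(fit$SV), alpha = alpha, rho = rho,
                 gamma = gamma, nu = nu, l = l,
                 center = center, scale = scale, seed = seed),
            class = "ocsvm_model")
}

#' @export
print.ocsvm_model <- function(x, ...) {
  cat(sprintf("<ocsvm_model> nu = %g, gamma = %g, %d/%d support vectors, rho = %.6g\n",
              x$nu, x$gamma, nrow(x$sv), x$l, x$rho))
  invisible(x)
}

#' One-class SVM decision
#'
#' Evaluates the raw margin `g(x) = sum_i alpha_i k(x_i, x) - rho` and
#' its sign: `+1` inside the normal region, `-1` abnormal. The boundary
#' `g(x) = 0` is labelled normal.
#'
#' @param model An `ocsvm_model`.
#' @param x A single vector or a matrix of row vectors.
#' @return A list with `sign` (integer vector of +1/-1) and `margin`
#'   (numeric vector of raw decision values).
#' @export
ocsvm_decision <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$sv)) stop("ocsvm_decision: dimension mismatch")
  if (!is.null(model$center)) {
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  }
  K <- rbf_kernel(x, model$sv, model$gamma)
  g <- as.numeric(K %*% model$alpha) - model$rho
  list(sign = ifelse(g >= 0, 1L, -1L), margin = g)
}

#' Recover the offset rho from KKT boundary conditions
#'
#' At any unbounded support vector `x_i` (coefficient strictly inside
#' `(0, 1/(nu l))`) the KKT conditions give
#' `rho = sum_j alpha_j k(x_j, x_i)`. For robustness the value is
#' averaged over all unbounded support vectors; if none exists (every
#' coefficient at a bound) the midpoint of the interval implied by the
#' bounded points is used, with a warning.
#'
#' @param alphas Normalised dual coefficients (sum 1) for all training
#'   points (zeros included for non-SVs).
#' @param kernel_matrix Full l x l kernel Gram matrix of the training set.
#' @param nu,l The nu parameter and training count defining the box
#'   bound `1/(nu l)`.
#' @param tol Distance from the bounds below which a coefficient is
#'   considered bounded.
#' @return Scalar rho.
#' @export
select_rho <- function(alphas, kernel_matrix, nu, l, tol = 1e-8) {
  upper <- 1 / (nu * l)
  g <- as.numeric(kernel_matrix %*% alphas)   # sum_j alpha_j k(x_j, x_i)
  free <- alphas > tol & alphas < upper - tol
  if (any(free)) return(mean(g[free]))
  at_upper <- alphas >= upper - tol
  at_zero <- alphas <= tol
  lo <- if (any(at_upper)) max(g[at_upper]) else -Inf   # rho >= g at upper bound
  hi <- if (any(at_zero)) min(g[at_zero]) else Inf      # rho <= g at zero
  warning("select_rho: no unbounded support vector; using bound-interval midpoint")
  if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2 else if (is.finite(lo)) lo else hi
}
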