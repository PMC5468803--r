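## Diagonal-covariance GMM universal background model (UBM) trained by
## EM, MAP mean adaptation, and Gaussian Mean Supervector extraction.
## The UBM density is p(x | lambda) = sum_j w_j N(x; mu_j, diag(sigma2_j)).

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Train a diagonal-covariance GMM background model by EM
#'
#' Initialisation is seeded k-means++ on a subsample followed by a few
#' Lloyd iterations; EM then alternates posterior (E) and weighted
#' moment (M) steps until the relative log-likelihood improvement drops
#' below `tol` or `max_iter` is reached. Variances are floored at
#' `var_floor_frac` times the global per-dimension variance so
#' components cannot collapse on small training pools.
#'
#' @param frames Numeric matrix of feature frames (rows = frames).
#' @param J Number of mixture components.
#' @param seed Integer seed; the run is deterministic given it.
#' @param max_iter,tol EM stopping rule.
#' @param var_floor_frac Variance floor as a fraction of the global
#'   per-dimension variance.
#' @return An object of class `gmm_ubm` with elements `weights` (J),
#'   `means` (J x D), `vars` (J x D), `J`, `D`, and `loglik_trace`
#'   (per-iteration total log-likelihood, non-decreasing).
#' @export
train_ubm <- function(frames, J, seed = 1L, max_iter = 100L, tol = 1e-6,
                      var_floor_frac = 1e-3) {
  frames <- as.matrix(frames)
  n <- nrow(frames); D <- ncol(frames)
  if (J < 1L) stop("train_ubm: J must be >= 1")
  if (n < J) stop("train_ubm: fewer frames (", n, ") than components (", J, ")")
  gvar <- apply(frames, 2, stats::var)
  gvar[gvar <= 0 | !is.finite(gvar)] <- 1
  floor_v <- var_floor_frac * gvar

  mu <- with_seed(seed, {
    sub <- frames[sample.int(n, min(n, max(2000L, 20L * J))), , drop = FALSE]
    init_kmeanspp(sub, J)
  })
  vars <- matrix(gvar, J, D, byrow = TRUE)
  w <- rep(1 / J, J)

  ll_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- log_component_densities(frames, w, mu, vars)  # n x J
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)                               # posteriors
    nj <- colSums(resp)
    nj <- pmax(nj, 1e-300)
    w <- nj / n
    mu_new <- t(resp) %*% frames / nj
    ex2 <- t(resp) %*% (frames^2) / nj
    v_new <- pmax(ex2 - mu_new^2, rep(floor_v, each = J))
    mu <- mu_new; vars <- v_new
    if (is.finite(prev) && (ll - prev) < tol * abs(ll)) break
    prev <- ll
  }
  structure(list(weights = w, means = mu, vars = vars, J = J, D = D,
                 loglik_trace = ll_trace, var_floor = floor_v, seed = seed),
            class = "gmm_ubm")
}

# k-means++ seeding + short Lloyd refinement (RNG state managed by caller)
init_kmeanspp <- function(x, J) {
  n <- nrow(x)
  centers <- matrix(0, J, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (J > 1L) {
    d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:J) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  if (J > 1L && n > J) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 10L)),
      error = function(e) NULL)
    if (!is.null(km)) centers <- km$centers
  }
  centers
}

# n x J matrix of log(w_j) + log N(x_i; mu_j, diag(vars_j))
log_component_densities <- function(x, w, mu, vars) {
  n <- nrow(x); J <- nrow(mu); D <- ncol(mu)
  out <- matrix(0, n, J)
  const <- -0.5 * D * log(2 * pi)
  for (j in seq_len(J)) {
    diff2 <- sweep(x, 2, mu[j, ])^2
    q <- diff2 %*% (1 / vars[j, ])
    out[, j] <- log(w[j]) + const - 0.5 * sum(log(vars[j, ])) - 0.5 * q
  }
  out
}

#' @export
print.gmm_ubm <- function(x, ...) {
  cat(sprintf("<gmm_ubm> J = %d components, D = %d dims, EM iterations = %d\n",
              x$J, x$D, length(x$loglik_trace)))
  invisible(x)
}

#' Total log-likelihood of frames under a GMM
#'
#' @param gmm A `gmm_ubm`.
#' @param frames Feature matrix, rows = frames, D columns.
#' @return Scalar sum over frames of the log mixture density.
#' @export
gmm_loglik <- function(gmm, frames) {
  frames <- as.matrix(frames)
  if (ncol(frames) != gmm$D) stop("gmm_loglik: dimension mismatch")
  lp <- log_component_densities(frames, gmm$weights, gmm$means, gmm$vars)
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' MAP adaptation of UBM means to a segment
#'
#' Classical relevance-MAP mean adaptation: with posterior-weighted
#' occupancy `n_j` and mean `xbar_j` of the segment frames, each mean is
#' updated to `(n_j * xbar_j + r * mu_j) / (n_j + r)`. Weights and
#' covariances are left untouched. As the relevance factor grows the
#' adapted means collapse onto the UBM means (prior-dominated limit);
#' components with zero occupancy keep their prior mean.
#'
#' @param ubm A `gmm_ubm`.
#' @param frames Segment feature matrix (rows = frames).
#' @param relevance Relevance factor `r` (default 16).
#' @return J x D matrix of adapted means.
#' @export
map_adapt_means <- function(ubm, frames, relevance = 16) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 1L) stop("map_adapt_means: empty frame set")
  if (ncol(frames) != ubm$D) stop("map_adapt_means: dimension mismatch")
  lp <- log_component_densities(frames, ubm$weights, ubm$means, ubm$vars)
  mx <- apply(lp, 1, max)
  resp <- exp(lp - (mx + log(rowSums(exp(lp - mx)))))
  nj <- colSums(resp)
  sums <- t(resp) %*% frames
  adapted <- ubm$means
  alpha <- nj / (nj + relevance)
  pos <- nj > 0
  xbar <- sums[pos, , drop = FALSE] / nj[pos]
  adapted[pos, ] <- alpha[pos] * xbar + (1 - alpha[pos]) * ubm$means[pos, , drop = FALSE]
  adapted
}

#' Gaussian Mean Supervector of a feature sequence
#'
#' MAP-adapts the UBM means to the segment and concatenates them
#' component-wise into one `D*J` vector — a fixed-length embedding of a
#' variable-length segment.
#'
#' @inheritParams map_adapt_means
#' @param mfcc Feature matrix of the segment (rows = frames).
#' @return Numeric vector of length `D * J`.
#' @export
compute_gms <- function(ubm, mfcc, relevance = 16) {
  adapted <- map_adapt_means(ubm, mfcc, relevance)
  as.numeric(t(adapted))  # [mu_1; mu_2; ...; mu_J]
}
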