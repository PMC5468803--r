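# independent QP solution of the one-class dual via kernlab's interior
# point solver: min 1/2 a'Ka s.t. sum(a) = 1, 0 <= a_i <= 1/(nu l)
qp_oracle <- function(X, nu, gamma) {
  l <- nrow(X)
  K <- exp(-gamma * as.matrix(dist(X))^2)
  sol <- kernlab::ipop(c = rep(0, l), H = K + diag(1e-12, l),
                       A = matrix(1, 1, l), b = 1, r = 0,
                       l = rep(0, l), u = rep(1 / (nu * l), l),
                       sigf = 12, maxiter = 400)
  alpha <- as.numeric(kernlab::primal(sol))
  rho <- suppressWarnings(select_rho(alpha, K, nu, l))
  list(alpha = alpha, rho = rho, K = K)
}

oracle_margin <- function(orc, X, query, gamma) {
  ks <- exp(-gamma * colSums((t(X) - query)^2))
  sum(orc$alpha * ks) - orc$rho
}
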