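test_that("dual constraints hold for the trained model", {
  set.seed(2)
  X <- matrix(rnorm(60), ncol = 2)
  for (nu in c(0.1, 0.4, 0.8)) {
    for (gamma in c(0.1, 1)) {
      m <- train_ocsvm(X, nu = nu, gamma = gamma)
      expect_equal(sum(m$alpha), 1, tolerance = 1e-8)
      expect_true(all(m$alpha >= -1e-10))
      expect_true(all(m$alpha <= 1 / (nu * nrow(X)) + 1e-10))
    }
  }
  expect_error(train_ocsvm(X, nu = 0, gamma = 1), "nu")
  expect_error(train_ocsvm(X, nu = 0.5, gamma = -1), "gamma")
})

test_that("nu = 1 forces every coefficient to the bound 1/l", {
  set.seed(3)
  X <- matrix(rnorm(40), ncol = 2)
  m <- train_ocsvm(X, nu = 1, gamma = 0.5)
  expect_equal(nrow(m$sv), nrow(X))
  expect_equal(m$alpha, rep(1 / nrow(X), nrow(X)), tolerance = 1e-8)
})

test_that("KKT residuals vanish at unbounded support vectors", {
  set.seed(5)
  X <- matrix(rnorm(80), ncol = 2)
  m <- train_ocsvm(X, nu = 0.3, gamma = 0.5)
  upper <- 1 / (m$nu * m$l)
  free <- m$alpha > 1e-7 & m$alpha < upper - 1e-7
  expect_gt(sum(free), 0)
  g_free <- ocsvm_decision(m, m$sv[free, , drop = FALSE])$margin
  expect_lt(max(abs(g_free)), 1e-6)
})

test_that("decision signs agree with an independent QP oracle", {
  for (trial in 1:5) {
    set.seed(100 + trial)
    X <- matrix(rnorm(40, sd = 1.5), ncol = 2)
    nu <- 0.3; gamma <- 0.5
    m <- train_ocsvm(X, nu = nu, gamma = gamma)
    orc <- qp_oracle(X, nu, gamma)
    grid <- as.matrix(expand.grid(x = seq(-3, 3, length.out = 10),
                                  y = seq(-3, 3, length.out = 10)))
    dec <- ocsvm_decision(m, grid)
    for (i in seq_len(nrow(grid))) {
      g_orc <- oracle_margin(orc, X, grid[i, ], gamma)
      agree <- sign(g_orc) == sign(dec$margin[i]) ||
        max(abs(g_orc), abs(dec$margin[i])) < 1e-6
      expect_true(agree,
                  label = sprintf("trial %d point %d: oracle %.3g vs model %.3g",
                                  trial, i, g_orc, dec$margin[i]))
    }
  }
})

test_that("the nu-property bounds outlier and SV fractions", {
  set.seed(77)
  X <- matrix(rnorm(400), ncol = 2)
  l <- nrow(X)
  slack <- 2 / sqrt(l)
  for (nu in seq(0.1, 0.9, by = 0.1)) {
    m <- train_ocsvm(X, nu = nu, gamma = 0.5)
    out_frac <- mean(ocsvm_decision(m, X)$sign == -1L)
    sv_frac <- nrow(m$sv) / l
    expect_lte(out_frac, nu + slack)
    expect_gte(sv_frac, nu - slack)
  }
})

test_that("select_rho recovers the offset from KKT boundary points", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 2)
  nu <- 0.3; l <- nrow(X)
  m <- train_ocsvm(X, nu = nu, gamma = 0.7)
  # embed the trained alphas back into the full training ordering
  K <- exp(-0.7 * as.matrix(dist(X))^2)
  alpha_full <- rep(0, l)
  sv_idx <- match(apply(m$sv, 1, paste, collapse = ","),
                  apply(X, 1, paste, collapse = ","))
  alpha_full[sv_idx] <- m$alpha
  upper <- 1 / (nu * l)
  free <- which(alpha_full > 1e-7 & alpha_full < upper - 1e-7)
  # every unbounded SV implies the same rho
  rhos <- as.numeric(K[free, , drop = FALSE] %*% alpha_full)
  expect_lt(max(rhos) - min(rhos), 1e-6)
  expect_equal(select_rho(alpha_full, K, nu, l), m$rho, tolerance = 1e-6)
  # single unbounded SV: exact formula
  expect_equal(select_rho(alpha_full, K, nu, l, tol = 1e-8),
               mean(rhos), tolerance = 1e-10)

  # two symmetric points, nu = 1: both alphas at the bound 1/2, rho from
  # the 2x2 kernel matrix by hand
  X2 <- rbind(c(-1, 0), c(1, 0))
  m2 <- train_ocsvm(X2, nu = 1, gamma = 0.25)
  k12 <- exp(-0.25 * 4)
  expect_equal(m2$alpha, c(0.5, 0.5), tolerance = 1e-8)
  K2 <- matrix(c(1, k12, k12, 1), 2)
  expect_warning(r2 <- select_rho(c(0.5, 0.5), K2, 1, 2), "unbounded")
  expect_equal(r2, (1 + k12) / 2, tolerance = 1e-10)
})

test_that("queries far from all support vectors are abnormal", {
  set.seed(10)
  X <- matrix(rnorm(40), ncol = 2)
  m <- train_ocsvm(X, nu = 0.5, gamma = 1)
  expect_gt(m$rho, 0)
  far <- matrix(c(1e3, 1e3), 1)
  d <- ocsvm_decision(m, far)
  expect_identical(d$sign, -1L)
  expect_equal(d$margin, -m$rho, tolerance = 1e-12)
  expect_error(ocsvm_decision(m, c(1, 2, 3)), "dimension")
})

test_that("decisions are invariant to duplicating the training set", {
  set.seed(15)
  X <- matrix(rnorm(50), ncol = 2)
  m1 <- train_ocsvm(X, nu = 0.4, gamma = 0.5)
  m2 <- train_ocsvm(rbind(X, X), nu = 0.4, gamma = 0.5)
  grid <- matrix(rnorm(60), ncol = 2)
  d1 <- ocsvm_decision(m1, grid)
  d2 <- ocsvm_decision(m2, grid)
  expect_equal(d1$margin, d2$margin, tolerance = 1e-5)
  expect_identical(d1$sign, d2$sign)
})
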