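test_that("single-component EM reduces to the ML closed form", {
  set.seed(4)
  x <- matrix(rnorm(600, mean = 1.5, sd = 2), ncol = 3)
  g <- train_ubm(x, J = 1, seed = 1)
  expect_equal(as.numeric(g$means), colMeans(x), tolerance = 1e-8)
  n <- nrow(x)
  ml_var <- apply(x, 2, function(v) mean((v - mean(v))^2))
  expect_equal(as.numeric(g$vars), ml_var, tolerance = 1e-8)
  expect_equal(sum(g$weights), 1)
})

test_that("EM log-likelihood is monotone and deterministic under a seed", {
  set.seed(9)
  x <- matrix(c(rnorm(400, -2), rnorm(400, 2)), ncol = 2)
  g1 <- train_ubm(x, J = 3, seed = 42)
  g2 <- train_ubm(x, J = 3, seed = 42)
  expect_identical(g1$means, g2$means)
  expect_identical(g1$loglik_trace, g2$loglik_trace)
  dll <- diff(g1$loglik_trace)
  expect_true(all(dll >= -1e-8 * (1 + abs(g1$loglik_trace[-1]))))
  expect_error(train_ubm(x[1:2, ], J = 5), "fewer frames")
})

test_that("gmm_loglik equals a brute-force density summation", {
  set.seed(21)
  ubm <- fake_ubm(J = 3, D = 2)
  x <- matrix(rnorm(40), ncol = 2)
  got <- gmm_loglik(ubm, x)
  # independent oracle: explicit double loop with dnorm products
  ref <- 0
  for (i in seq_len(nrow(x))) {
    dens <- 0
    for (j in 1:3) {
      dens <- dens + ubm$weights[j] *
        prod(dnorm(x[i, ], ubm$means[j, ], sqrt(ubm$vars[j, ])))
    }
    ref <- ref + log(dens)
  }
  expect_equal(got, ref, tolerance = 1e-10)

  # additivity: a duplicated frame doubles its contribution
  one <- gmm_loglik(ubm, x[1, , drop = FALSE])
  expect_equal(gmm_loglik(ubm, x[c(1, 1), , drop = FALSE]), 2 * one)

  # J = 1 at the mean: closed form -(D/2)log(2pi) - (1/2) sum log sigma2
  u1 <- fake_ubm(J = 1, D = 4)
  closed <- -2 * log(2 * pi) - 0.5 * sum(log(u1$vars))
  expect_equal(gmm_loglik(u1, u1$means), closed, tolerance = 1e-12)
  expect_error(gmm_loglik(u1, matrix(0, 2, 3)), "dimension")
})

test_that("MAP mean adaptation matches the relevance closed form", {
  # hand case: J=1, 4 frames of mean 2, prior mean 0, r = 16 -> 8/20
  ubm <- fake_ubm(J = 1, D = 3)
  ubm$means[] <- 0; ubm$vars[] <- 1
  frames <- matrix(2, nrow = 4, ncol = 3)
  expect_equal(as.numeric(map_adapt_means(ubm, frames, relevance = 16)),
               rep(0.4, 3), tolerance = 1e-12)

  # prior-dominated limit returns the UBM means
  u2 <- fake_ubm(J = 4, D = 5, seed = 3)
  x <- matrix(rnorm(100, sd = 3), ncol = 5)
  expect_equal(map_adapt_means(u2, x, relevance = 1e9), u2$means,
               tolerance = 1e-6)

  # general case: equals (n_j xbar_j + r mu_j)/(n_j + r) with posteriors
  # recomputed independently
  r <- 16
  post <- matrix(0, nrow(x), u2$J)
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(u2$J)) {
      post[i, j] <- u2$weights[j] *
        prod(dnorm(x[i, ], u2$means[j, ], sqrt(u2$vars[j, ])))
    }
    post[i, ] <- post[i, ] / sum(post[i, ])
  }
  nj <- colSums(post)
  ref <- u2$means
  for (j in seq_len(u2$J)) {
    xbar <- colSums(post[, j] * x) / nj[j]
    ref[j, ] <- (nj[j] * xbar + r * u2$means[j, ]) / (nj[j] + r)
  }
  expect_equal(map_adapt_means(u2, x, r), ref, tolerance = 1e-8)
  expect_error(map_adapt_means(u2, x[0, , drop = FALSE]), "empty")
})

test_that("adapted means interpolate between prior mean and data mean", {
  set.seed(14)
  ubm <- fake_ubm(J = 2, D = 3)
  x <- matrix(rnorm(60, mean = 1), ncol = 3)
  lp <- acufall:::log_component_densities(x, ubm$weights, ubm$means, ubm$vars)
  post <- exp(lp - apply(lp, 1, function(r) max(r) + log(sum(exp(r - max(r))))))
  adapted <- map_adapt_means(ubm, x, relevance = 8)
  for (j in 1:2) {
    xbar <- colSums(post[, j] * x) / sum(post[, j])
    lo <- pmin(ubm$means[j, ], xbar); hi <- pmax(ubm$means[j, ], xbar)
    expect_true(all(adapted[j, ] >= lo - 1e-10 & adapted[j, ] <= hi + 1e-10))
  }
})

test_that("supervector length is D*J and invariant to sequence length", {
  for (spec in list(c(D = 2, J = 1), c(D = 5, J = 8), c(D = 13, J = 16),
                    c(D = 39, J = 64))) {
    ubm <- fake_ubm(J = spec["J"], D = spec["D"], seed = spec["J"])
    for (L in c(3, 50)) {
      sv <- compute_gms(ubm, matrix(rnorm(L * spec["D"]), ncol = spec["D"]))
      expect_length(sv, spec["D"] * spec["J"])
    }
  }
  # composition: equals map_adapt_means followed by row concatenation
  ubm <- fake_ubm(J = 3, D = 4)
  x <- matrix(rnorm(40), ncol = 4)
  expect_equal(compute_gms(ubm, x, 16),
               as.numeric(t(map_adapt_means(ubm, x, 16))))
  # relevance limit: supervector collapses to concatenated UBM means
  expect_equal(compute_gms(ubm, x, 1e12), as.numeric(t(ubm$means)),
               tolerance = 1e-8)
})

test_that("EM reaches the likelihood of an independent reference fit", {
  set.seed(33)
  x <- matrix(c(rnorm(500, -2), rnorm(500, 2)), ncol = 1)
  g <- train_ubm(x, J = 2, seed = 2)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this by name
  mc <- mclust::Mclust(as.numeric(x), G = 2, modelNames = "V",
                       verbose = FALSE)
  # same model family: our EM must come within a few nats of mclust's
  # maximised log-likelihood
  expect_gt(gmm_loglik(g, x), mc$loglik - 3)
})
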