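test_that("min_distance equals an exhaustive brute-force scan", {
  set.seed(30)
  for (trial in 1:20) {
    N <- sample(2:50, 1); D <- sample(2:10, 1)
    tpl <- matrix(rnorm(N * D), N, D)
    ts <- template_set(tpl)
    x <- rnorm(D)
    got <- min_distance(x, ts)
    dists <- vapply(seq_len(N), function(i) sqrt(sum((x - tpl[i, ])^2)),
                    numeric(1))
    expect_equal(got$d_min, min(dists), tolerance = 1e-12)
    expect_identical(got$index, which.min(dists))
  }
  # self-distance and single-template perturbation
  ts <- template_set(matrix(1:4, 1))
  expect_equal(min_distance(1:4, ts)$d_min, 0)
  expect_equal(min_distance(c(1 + 1e-3, 2, 3, 4), ts)$d_min, 1e-3)
  expect_error(min_distance(1:4, template_set()), "empty")
})

test_that("the fall rule is a strict inequality at the threshold", {
  expect_identical(template_decision(0, 0.5), "nonfall")
  expect_identical(template_decision(0.5, 0.5), "nonfall")
  expect_identical(template_decision(0.5 + 1e-9, 0.5), "fall")
  # beta = 0 passes every positive distance through; beta = Inf vetoes all
  expect_identical(template_decision(1e-12, 0), "fall")
  expect_identical(template_decision(1e12, Inf), "nonfall")
})

test_that("threshold lands at the equal-variance Gaussian intersection", {
  for (s in 1:3) {
    set.seed(400 + s)
    nonfall <- rnorm(1000, 1, 0.5)
    fall <- rnorm(1000, 3, 0.5)
    beta <- select_threshold(fall, nonfall)
    expect_equal(beta, 2.0, tolerance = 0.1)
    # equivariance: shifting both samples shifts beta identically
    expect_equal(select_threshold(fall + 5, nonfall + 5), beta + 5,
                 tolerance = 1e-8)
  }
  # crossing equals a brute-force scan of density sign changes
  set.seed(404)
  nonfall <- rgamma(500, 4, 4); fall <- rgamma(500, 9, 3)
  beta <- select_threshold(fall, nonfall)
  bw_f <- bw.nrd(fall); bw_n <- bw.nrd(nonfall)
  pad <- 3 * max(bw_f, bw_n)
  lo <- min(fall, nonfall) - pad; hi <- max(fall, nonfall) + pad
  df <- density(fall, bw = bw_f, from = lo, to = hi, n = 512)
  dn <- density(nonfall, bw = bw_n, from = lo, to = hi, n = 512)
  s <- sign(dn$y - df$y)
  crossings <- df$x[which(s[-512] > 0 & s[-1] <= 0) + 1]
  expect_true(beta %in% crossings)

  # separable case: beta falls in the empty gap
  set.seed(405)
  lown <- runif(200, 0, 1); highf <- runif(200, 3, 4)
  b2 <- select_threshold(highf, lown)
  expect_gt(b2, 1); expect_lt(b2, 3)

  expect_error(select_threshold(c(1, 2, 3), c(1, 2, 3)), "identical")
  w <- capture_warnings(select_threshold(rnorm(200, 1, .2), rnorm(200, 3, .2)))
  expect_match(w, "stochastically larger", all = FALSE)
})

test_that("object templates are exactly the stage-1 false alarms", {
  set.seed(50)
  cand <- matrix(rnorm(60), ncol = 2)
  labels <- rep(c("book", "chair"), 15)
  all_normal <- fake_ocsvm(2, sign = +1L)
  all_abn <- fake_ocsvm(2, sign = -1L)
  expect_equal(nrow(build_object_templates(cand, labels, all_normal)$templates), 0)
  expect_equal(nrow(build_object_templates(cand, labels, all_abn)$templates), 30)

  # boundary-straddling candidates: membership equals per-item decisions
  m <- train_ocsvm(matrix(rnorm(80), ncol = 2), nu = 0.5, gamma = 0.5)
  ts <- build_object_templates(cand, labels, m)
  keep <- vapply(seq_len(nrow(cand)),
                 function(i) ocsvm_decision(m, cand[i, ])$sign == -1L,
                 logical(1))
  expect_equal(ts$templates, cand[keep, , drop = FALSE], ignore_attr = TRUE)
  expect_identical(ts$labels, labels[keep])
})

test_that("background templates are the nearest pool items, deduplicated", {
  set.seed(60)
  pool <- matrix(rnorm(470 * 4 / 10), ncol = 4)   # 47 x 4 pool
  dev <- matrix(rnorm(22 * 4 / 2), ncol = 4)      # 11 x 4 dev events
  ts <- build_background_templates(dev, pool)
  # exhaustive double loop oracle
  sel <- integer(0)
  for (i in seq_len(nrow(dev))) {
    d <- apply(pool, 1, function(p) sqrt(sum((p - dev[i, ])^2)))
    sel <- c(sel, which.min(d))
  }
  expect_equal(ts$templates, pool[unique(sel), , drop = FALSE],
               ignore_attr = TRUE)
  # pool of one; dev event equal to a pool item
  one <- build_background_templates(dev, pool[3, , drop = FALSE])
  expect_equal(nrow(one$templates), 1)
  hit <- build_background_templates(pool[7, , drop = FALSE], pool)
  expect_equal(as.numeric(hit$templates[1, ]), pool[7, ])
})

test_that("template addition grows the set and monotonically shrinks D_min", {
  set.seed(70)
  ts <- template_set()
  ts <- add_template(ts, rnorm(5), label = "a")
  expect_equal(nrow(ts$templates), 1)
  for (k in 2:100) ts <- add_template(ts, rnorm(5), label = "x")
  expect_equal(nrow(ts$templates), 100)
  expect_error(add_template(ts, ts$templates[4, ]), "duplicate")

  # monotone veto: adding a template never increases any query's D_min
  queries <- matrix(rnorm(100), ncol = 5)
  before <- apply(queries, 1, function(q) min_distance(q, ts)$d_min)
  ts2 <- add_template(ts, rnorm(5))
  after <- apply(queries, 1, function(q) min_distance(q, ts2)$d_min)
  expect_true(all(after <= before + 1e-12))
  # hence adding the query itself flips it to nonfall at any beta
  q <- queries[1, ]
  ts3 <- add_template(ts, q)
  expect_equal(min_distance(q, ts3)$d_min, 0)
  expect_identical(template_decision(min_distance(q, ts3)$d_min, 0), "nonfall")
})
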