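test_that("a 44+44 corpus folds into four disjoint 11+11 folds", {
  manifest <- data.frame(
    id = sprintf("e%02d", 1:88),
    label = rep(c("human_fall", "music"), each = 44),
    stringsAsFactors = FALSE)
  plan <- make_folds(manifest, n_folds = 4, seed = 9)
  expect_length(plan$folds, 4)
  for (f in plan$folds) {
    expect_length(f, 22)
    expect_equal(sum(manifest$label[f] == "human_fall"), 11)
  }
  # disjoint and exhaustive
  all_idx <- sort(unlist(plan$folds))
  expect_identical(all_idx, 1:88)
  expect_identical(make_folds(manifest, 4, seed = 9)$folds, plan$folds)
  expect_false(identical(make_folds(manifest, 4, seed = 10)$folds, plan$folds))
  expect_error(make_folds(manifest[1:5, ], 4), "at least")
})

test_that("the F1 measure follows 2tp/(2tp+fn+fp)", {
  expect_equal(f1_measure(33, 0, 0), 1.0)
  expect_equal(f1_measure(0, 3, 0), 0.0)
  expect_equal(f1_measure(0, 0, 5), 0.0)
  expect_equal(f1_measure(2, 1, 1), 2 / 3, tolerance = 1e-10)
  expect_error(f1_measure(0, 0, 0), "undefined")
  expect_error(f1_measure(-1, 0, 0))
})

test_that("an always-fall detector on 4 rotations yields F1 = 2/3", {
  manifest <- data.frame(
    id = sprintf("e%02d", 1:88),
    label = rep(c("human_fall", "music"), 44),
    stringsAsFactors = FALSE)
  plan <- make_folds(manifest, n_folds = 4, seed = 2)
  tp <- fp <- fn <- 0
  for (r in plan$rotation) {
    test_idx <- unlist(plan$folds[-r])
    truth <- manifest$label[test_idx] == "human_fall"
    pred <- rep(TRUE, length(test_idx))       # stub: everything is a fall
    tp <- tp + sum(pred & truth)
    fp <- fp + sum(pred & !truth)
    fn <- fn + sum(!pred & truth)
  }
  expect_equal(c(tp, fp, fn), c(132, 132, 0))
  expect_equal(f1_measure(tp, fp, fn), 2 / 3, tolerance = 1e-10)
})

test_that("grid search enumerates the lattice and breaks ties in order", {
  g <- grid_space()
  lattice <- acufall:::enumerate_grid(g)
  expect_equal(nrow(lattice), 7 * 10 * 10)
  expect_setequal(unique(lattice$J), 2^(0:6))
  expect_equal(sort(unique(lattice$gamma)), 2^seq(-15, 3, by = 2))

  manifest <- data.frame(id = as.character(1:16),
                         label = rep(c("human_fall", "music"), 8))
  plan <- make_folds(manifest, n_folds = 4, seed = 1)
  small <- grid_space(J = c(2, 4), nu = c(0.1, 0.2), gamma = c(0.5, 1))

  # planted optimum is recovered per rotation
  best <- grid_search(plan, small, function(J, nu, gamma, rotation) {
    as.numeric(J == 4 && nu == 0.2 && gamma == 0.5)
  })
  expect_equal(best$J, rep(4, 4))
  expect_equal(best$nu, rep(0.2, 4))
  expect_equal(best$gamma, rep(0.5, 4))
  expect_equal(best$f1, rep(1, 4))

  # all-tie scorer: smallest J, smallest nu, largest gamma win
  tie <- grid_search(plan, small, function(J, nu, gamma, rotation) 0.5)
  expect_equal(tie$J, rep(2, 4))
  expect_equal(tie$nu, rep(0.1, 4))
  expect_equal(tie$gamma, rep(1, 4))

  # single-point grid returned unchanged
  single <- grid_search(plan, grid_space(J = 8, nu = 0.3, gamma = 2),
                        function(J, nu, gamma, rotation) 0.9)
  expect_equal(single[1, c("J", "nu", "gamma")],
               data.frame(J = 8, nu = 0.3, gamma = 2), ignore_attr = TRUE)
})

test_that("evaluate reports cumulative counts consistent with decisions", {
  fe <- tiny_frontend()
  rep1 <- evaluate(fe, set = "set2", method = "ocsvm_only",
                   condition = "clean",
                   grid = grid_space(J = NULL, nu = c(0.1, 0.3),
                                     gamma = 2^c(-11, -7)),
                   seed = 4)
  expect_s3_class(rep1, "eval_report")
  # F1 recomputable from the per-event decision table
  dec <- rep1$decisions
  tp <- sum(dec$predicted == "fall" & dec$label == "human_fall")
  fp <- sum(dec$predicted == "fall" & dec$label != "human_fall")
  fn <- sum(dec$predicted == "nonfall" & dec$label == "human_fall")
  expect_equal(unname(rep1$counts[c("tp", "fp", "fn")]), c(tp, fp, fn))
  expect_equal(rep1$f1, f1_measure(tp, fp, fn))
  # over 4 rotations every event is tested exactly 3 times
  expect_equal(nrow(dec), 3 * nrow(fe$parts[["set2.clean"]]$manifest))

  # determinism of the whole protocol at fixed frontend and seed
  rep2 <- evaluate(fe, set = "set2", method = "ocsvm_only",
                   condition = "clean",
                   grid = grid_space(J = NULL, nu = c(0.1, 0.3),
                                     gamma = 2^c(-11, -7)),
                   seed = 4)
  expect_identical(rep1$counts, rep2$counts)
  expect_identical(rep1$decisions, rep2$decisions)
})
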