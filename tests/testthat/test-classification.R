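test_that("the T criterion is the stated weighted sum", {
  expect_equal(t_value(1, 1, 1, 1), 1.0)
  expect_equal(t_value(0, 0, 0, 0), 0.0)
  expect_equal(t_value(0.8, 0.9, 0.7, 0.6), 0.73)
  expect_error(t_value(1.2, 0, 0, 0), "\\[0, 1\\]")
})

test_that("confusion metrics follow their defining identities", {
  m <- confusion_metrics(
    c(rep("pain", 4), rep("painless", 3)),
    c("pain", "pain", "pain", "painless", "painless", "painless", "pain"))
  expect_equal(m[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 2L, FP = 1L, FN = 1L))
  expect_equal(m$acc, 5 / 7)
  expect_equal(m$pre, 0.75)
  expect_equal(m$rec, 0.75)
  expect_equal(m$f1, 0.75)

  truth <- rep(c("pain", "painless"), 5)
  all_ok <- confusion_metrics(truth, truth)
  expect_equal(unlist(all_ok[c("acc", "pre", "rec", "f1")]),
               c(acc = 1, pre = 1, rec = 1, f1 = 1))
  expect_error(confusion_metrics(c("pain", "hurts"), c("pain", "pain")),
               "hurts")

  # F1 = harmonic mean of precision and recall on random tables
  for (seed in 1:20) {
    lab <- withr::with_seed(seed, list(
      t = sample(c("pain", "painless"), 40, replace = TRUE),
      p = sample(c("pain", "painless"), 40, replace = TRUE)))
    m <- confusion_metrics(lab$t, lab$p)
    if (!is.na(m$f1))
      expect_equal(m$f1, 2 * m$pre * m$rec / (m$pre + m$rec),
                   tolerance = 1e-12)
  }
})

test_that("outer folds are trial-exclusive, seeded partitions", {
  f <- make_outer_folds(1:8, seed = 3)
  expect_length(f, 4L)
  expect_setequal(unlist(f), 1:8)
  expect_true(all(lengths(f) == 2L))
  expect_identical(f, make_outer_folds(1:8, seed = 3))
  expect_false(identical(f, make_outer_folds(1:8, seed = 4)))
  expect_error(make_outer_folds(1:7, seed = 1), "equal sets")
})

test_that("the CSVM solves the cost-weighted margin problem", {
  ft <- toy_features(sep = 6)
  x <- painflex:::feature_matrix(ft)
  m <- train_csvm(x, ft$label, R = 1, C = 1)
  expect_equal(mean(predict(m, x)$label == ft$label), 1.0)

  # asymmetric cost pushes the boundary past an overlapping minority
  xs <- withr::with_seed(4, rbind(matrix(rnorm(100), ncol = 2),
                                  c(0.5, 0.5)))
  colnames(xs) <- c("F1", "F2")
  ys <- c(rep("painless", 50), "pain")
  rec_at <- function(R) {
    m <- train_csvm(xs, ys, R = R, C = 1, scale = FALSE)
    confusion_metrics(ys, predict(m, xs)$label)$rec
  }
  expect_equal(rec_at(2^10), 1.0)
  expect_lt(rec_at(1), 1.0)
  # recall of the pain class is non-decreasing in R
  recs <- vapply(-4:4, function(e) rec_at(2^e), 0)
  expect_true(all(diff(recs) >= 0))
})

test_that("label swap with R -> 1/R mirrors the decision boundary", {
  ft <- toy_features(sep = 2, per_trial = 16)
  x <- painflex:::feature_matrix(ft)
  R <- 4; C <- 2
  m1 <- train_csvm(x, ft$label, R = R, C = C, scale = FALSE)
  swapped <- ifelse(ft$label == "pain", "painless", "pain")
  m2 <- train_csvm(x, swapped, R = 1 / R, C = R * C, scale = FALSE)
  w1 <- coef(m1); w2 <- coef(m2)
  expect_equal(unclass(w1), -unclass(w2), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(attr(w1, "intercept"), -attr(w2, "intercept"),
               tolerance = 1e-4)
  expect_identical(predict(m1, x)$label,
                   ifelse(predict(m2, x)$label == "pain",
                          "painless", "pain"))
})

test_that("inner selection maximizes mean T deterministically", {
  ft <- toy_features(n_trials = 6, sep = 6)
  sets <- lapply(list(1:2, 3:4, 5:6), function(tr)
    ft[ft$trial_id %in% tr, ])
  spec1 <- classifier_spec(c_exponents = 0, r_exponents = 0)
  sel1 <- inner_select_csvm(sets, spec1)
  expect_equal(c(sel1$R, sel1$C), c(1, 1))
  sel <- inner_select_csvm(sets, classifier_spec("desk"))
  expect_equal(sel$T, 1.0)
  sel_b <- inner_select_csvm(sets, classifier_spec("desk"))
  expect_identical(sel[c("R", "C", "T")], sel_b[c("R", "C", "T")])
  expect_error(classifier_spec(c_exponents = numeric(0)))
  spec_bad <- classifier_spec()
  spec_bad$c_exponents <- numeric(0)
  expect_error(inner_select_csvm(sets, spec_bad), "empty")
})

test_that("Bayesian RF selection stays in bounds, is seeded, and finds
          the grid optimum on a small problem", {
  ft <- toy_features(n_trials = 6, per_trial = 10, sep = 1.2, seed = 9)
  sets <- lapply(list(1:2, 3:4, 5:6), function(tr)
    ft[ft$trial_id %in% tr, ])
  spec <- classifier_spec(rf_trees = c(10L, 60L), rf_leaf = c(1L, 10L),
                          rf_iterations = 8L)
  sel <- select_rf(sets, spec, seed = 5)
  expect_true(sel$n_trees >= 10 && sel$n_trees <= 60)
  expect_true(sel$min_leaf >= 1 && sel$min_leaf <= 10)
  sel2 <- select_rf(sets, spec, seed = 5)
  expect_identical(sel[c("n_trees", "min_leaf", "T")],
                   sel2[c("n_trees", "min_leaf", "T")])

  # exhaustive oracle over a 5x5 grid of the same objective
  grid <- expand.grid(nt = round(seq(10, 60, length.out = 5)),
                      nl = round(seq(1, 10, length.out = 5)))
  obj <- function(nt, nl) painflex:::inner_cv_t(
    sets, function(x, y) train_rf(x, y, nt, nl, seed = 5))
  best_grid <- max(mapply(obj, grid$nt, grid$nl))
  expect_gte(sel$T, best_grid - 0.02)
})

test_that("double cross-validation is leakage-free and reproducible", {
  ft <- toy_features(n_trials = 8, sep = 4)
  spec <- classifier_spec(c_exponents = c(-2, 0, 2),
                          r_exponents = c(0, 2))
  fit <- painflex(ft, "csvm", spec, seed = 11)
  fit2 <- painflex(ft, "csvm", spec, seed = 11)
  expect_identical(fit$metrics, fit2$metrics)
  expect_identical(fit$fold_trials, fit2$fold_trials)

  # trial-level integrity: test trials never appear in training folds
  for (f in seq_along(fit$folds)) {
    train_trials <- unlist(fit$fold_trials[-f])
    expect_length(intersect(fit$folds[[f]]$test_trials, train_trials), 0L)
  }
  # scaling statistics come from the training windows only
  f1 <- fit$folds[[1]]
  train <- ft[!ft$trial_id %in% f1$test_trials, ]
  expect_equal(unname(f1$model$center),
               unname(colMeans(painflex:::feature_matrix(train))))
  expect_gt(fit$mean_metrics["acc"], 0.9)
})

test_that("balanced label permutation drives accuracy to chance", {
  ft <- toy_features(n_trials = 8, per_trial = 12, sep = 4)
  spec <- classifier_spec(c_exponents = 0, r_exponents = 0)
  accs <- vapply(1:10, function(seed) {
    ft$label <- withr::with_seed(200 + seed, sample(
      rep(c("pain", "painless"), length.out = nrow(ft))))
    painflex(ft, "csvm", spec, seed = seed)$mean_metrics[["acc"]]
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  # each run individually is consistent with coin-flip predictions
  n_test <- nrow(ft)
  hits <- round(mean(accs) * n_test)
  expect_gt(binom.test(hits, n_test, 0.5)$p.value, 0.01)
})

test_that("cohort aggregation reproduces mean and sample sd", {
  ref <- reference_performance()
  agg <- aggregate_subjects(ref$svm[, -1])
  expect_equal(round(agg["mean", "accuracy"], 2), 87.90)
  expect_equal(round(agg["sd", "accuracy"], 2), 4.55)
  same <- rbind(a = c(acc = 0.9), b = c(acc = 0.9), c = c(acc = 0.9))
  agg2 <- aggregate_subjects(same)
  expect_equal(agg2["sd", "acc"], 0)
})

test_that("forward selection finds a dominant feature first and reports
          the full-set baseline", {
  ft <- toy_features(n_trials = 6, per_trial = 14, sep = 5, p = 6)
  # F1 carries all class signal; the rest is noise
  sfs <- sequential_forward_selection(ft, classifier_spec(), seed = 2,
                                      max_steps = 3)
  expect_identical(sfs$steps$feature[1], "F1")
  expect_true(is.finite(sfs$baseline_T))
  expect_identical(nrow(sfs$steps), 3L)
  expect_gte(max(sfs$steps$T), sfs$baseline_T - 0.05)
})
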