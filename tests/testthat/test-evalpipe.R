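test_that("fold plans split 88 subjects into groups of {18,18,18,17,17}", {
  ids <- sprintf("s%02d", 1:88)
  plan <- make_fold_plan(ids, k = 5, repeats = 3, master_seed = 1)
  for (r in 1:3) {
    sizes <- sort(lengths(plan$assignments[[r]]), decreasing = TRUE)
    expect_equal(unname(sizes), c(18L, 18L, 18L, 17L, 17L))
    expect_setequal(unlist(plan$assignments[[r]]), ids)
    expect_false(anyDuplicated(unlist(plan$assignments[[r]])) > 0)
  }
})

test_that("fold plans cover every subject exactly once per repeat", {
  ids <- letters[1:10]
  plan <- make_fold_plan(ids, k = 5, repeats = 4, master_seed = 3)
  for (r in 1:4) {
    expect_equal(unname(lengths(plan$assignments[[r]])), rep(2L, 5))
    expect_setequal(unlist(plan$assignments[[r]]), ids)
  }
  # identical under the same master seed, different across repeats
  plan2 <- make_fold_plan(ids, k = 5, repeats = 4, master_seed = 3)
  expect_identical(plan$assignments, plan2$assignments)
  expect_false(identical(plan$assignments[[1]], plan$assignments[[2]]))
  expect_error(make_fold_plan(letters[1:3], k = 5),
               class = "wmh_validation_error")
})

test_that("stratified plans balance classes across folds", {
  ids <- sprintf("s%02d", 1:20)
  labels <- rep(c("MS", "NMOSD"), each = 10)
  plan <- make_fold_plan(ids, k = 5, repeats = 2, master_seed = 5,
                         stratified = TRUE, labels = labels)
  for (r in 1:2) for (f in 1:5) {
    fold_labels <- labels[match(plan$assignments[[r]][[f]], ids)]
    expect_equal(sum(fold_labels == "MS"), 2)
  }
})

test_that("the learning-rate schedule decays 10% every ten epochs", {
  cfg <- train_config(epochs = 40)
  expect_equal(lr_at_epoch(cfg, 0:9), rep(0.01, 10))
  expect_equal(lr_at_epoch(cfg, 10:19), rep(0.009, 10))
  expect_equal(lr_at_epoch(cfg, 25), 0.0081)
  expect_equal(lr_at_epoch(cfg, 0:39),
               0.01 * 0.9^(floor((0:39) / 10)))
})

test_that("evaluate_model computes the confusion-matrix metrics exactly", {
  conf <- c(TP = 5, FN = 5, TN = 7, FP = 3)
  m <- ns$metrics_from_confusion(conf)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$accuracy, 0.6)
  perfect <- ns$metrics_from_confusion(c(TP = 4, FP = 0, TN = 6, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("zero-denominator metrics are flagged as undefined with a warning", {
  expect_warning(
    m <- ns$metrics_from_confusion(c(TP = 0, FP = 2, TN = 8, FN = 0)),
    "sensitivity")
  expect_true(is.nan(m$sensitivity))
})

test_that("training requires both classes and records lr/loss history", {
  cohort <- small_phantom_cohort(n_per_class = 3)
  m <- build_model(small_two_view_spec(), seed = 2)
  cfg <- train_config(epochs = 2, seed = 5)
  only_ms <- Filter(function(s) s$label == "MS", cohort)
  expect_error(train_model(build_model(small_two_view_spec(), 1),
                           only_ms, cfg),
               class = "wmh_validation_error")
  m <- train_model(m, cohort, cfg)
  expect_equal(m$history$epoch, 0:1)
  expect_equal(m$history$lr, c(0.01, 0.01))
  expect_true(all(is.finite(m$history$loss)))
})

test_that("training descends on a separable synthetic set", {
  # 8 easy-mode phantoms, 30 epochs: SGD at this batch size is noisy
  # epoch-to-epoch, so descent is asserted on the running minimum and on
  # the fit of the training set rather than on a single final loss
  cohort <- small_phantom_cohort(n_per_class = 4, seed = 31)
  m <- build_model(small_two_view_spec(), seed = 8)
  m <- train_model(m, cohort, train_config(epochs = 30, seed = 7))
  expect_lt(min(m$history$loss), m$history$loss[1])
  ev <- evaluate_model(m, cohort)
  expect_gte(ev$accuracy, 0.75)  # fits its own training set
})

test_that("training is deterministic under a fixed seed", {
  cohort <- small_phantom_cohort(n_per_class = 2, seed = 17)
  run <- function() {
    m <- build_model(small_two_view_spec(), seed = 3)
    m <- train_model(m, cohort, train_config(epochs = 2, seed = 9))
    list(h = m$history, st = ns$layer_state(m$net, buffers = FALSE))
  }
  a <- run(); b <- run()
  expect_identical(a$h, b$h)
  expect_identical(a$st, b$st)
})

test_that("augmentation expands only the training stream and keeps labels", {
  cohort <- small_phantom_cohort(n_per_class = 2, seed = 23)
  cfg <- train_config(epochs = 1, seed = 2,
                      augment = augment_spec(max_shift = 1,
                                             n_per_subject = 2, seed = 1))
  m <- build_model(small_two_view_spec(), seed = 5)
  m <- train_model(m, cohort, cfg)
  # 4 original + 8 augmented = 12 samples -> 3 batches of 4
  expect_true(all(is.finite(m$history$loss)))
  ev <- evaluate_model(m, cohort)
  expect_equal(ev$n, 4)  # evaluation untouched by augmentation
})

test_that("repeated CV predicts every subject once per repeat and aggregates by mean", {
  cohort <- small_phantom_cohort(n_per_class = 4, seed = 41)
  ids <- vapply(cohort, function(s) s$subject_id, "")
  labels <- vapply(cohort, function(s) s$label, "")
  plan <- make_fold_plan(ids, k = 2, repeats = 2, master_seed = 11,
                         stratified = TRUE, labels = labels)
  rep <- run_repeated_cv(cohort, small_two_view_spec(),
                         train_config(epochs = 2, seed = 1), plan)
  # bookkeeping: every subject predicted exactly once per repeat
  for (r in 1:2) {
    preds <- unlist(lapply(Filter(function(f) f$repeat_idx == r, rep$folds),
                           function(f) f$predictions$subject_id))
    expect_setequal(preds, ids)
    expect_false(anyDuplicated(preds) > 0)
  }
  # aggregate mean accuracy equals the arithmetic mean over repeats
  expect_equal(rep$aggregate$accuracy[["mean"]],
               mean(rep$per_repeat$accuracy))
  check_no_leakage(rep)
  check_metric_algebra(rep)
})

test_that("CV reports are deterministic given seed, config and cohort", {
  cohort <- small_phantom_cohort(n_per_class = 2, seed = 51)
  ids <- vapply(cohort, function(s) s$subject_id, "")
  labels <- vapply(cohort, function(s) s$label, "")
  plan <- make_fold_plan(ids, k = 2, repeats = 1, master_seed = 19,
                         stratified = TRUE, labels = labels)
  cfg <- train_config(epochs = 1, seed = 1)
  r1 <- run_repeated_cv(cohort, small_two_view_spec(), cfg, plan)
  r2 <- run_repeated_cv(cohort, small_two_view_spec(), cfg, plan)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$aggregate, r2$aggregate)
})

test_that("leakage and metric-algebra checks catch corrupted reports", {
  cohort <- small_phantom_cohort(n_per_class = 2, seed = 61)
  ids <- vapply(cohort, function(s) s$subject_id, "")
  labels <- vapply(cohort, function(s) s$label, "")
  plan <- make_fold_plan(ids, k = 2, repeats = 1, master_seed = 2,
                         stratified = TRUE, labels = labels)
  rep <- run_repeated_cv(cohort, small_two_view_spec(),
                         train_config(epochs = 1, seed = 1), plan)
  bad <- rep
  bad$folds[[1]]$train_ids <- c(bad$folds[[1]]$train_ids,
                                bad$folds[[1]]$val_ids[1])
  expect_error(check_no_leakage(bad), class = "wmh_leakage_error")
  bad2 <- rep
  bad2$per_repeat$accuracy[1] <- 0.123
  expect_error(check_metric_algebra(bad2), class = "wmh_metric_error")
})
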