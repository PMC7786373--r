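#' Training configuration
#'
#' Mini-batch SGD with momentum on 2-class cross-entropy. The learning rate
#' at epoch `e` (0-based) is `initial_lr * lr_decay_factor^floor(e / 10)`:
#' a 10% reduction every ten epochs. Dropout is active only during
#' training; augmentation, when configured, is applied to training folds
#' only.
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size mini-batch size (default 4).
#' @param initial_lr initial learning rate (default 0.01).
#' @param lr_decay_factor multiplicative decay applied every
#'   `lr_decay_every` epochs (default 0.9).
#' @param lr_decay_every epochs between decays (default 10).
#' @param momentum SGD momentum (default 0.9).
#' @param seed integer seed controlling shuffling, dropout and
#'   augmentation.
#' @param augment an [augment_spec], or `NULL` for no augmentation.
#' @param input_mode which volume feeds the network (see
#'   [forward_classify]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 4L, initial_lr = 0.01,
                         lr_decay_factor = 0.9, lr_decay_every = 10L,
                         momentum = 0.9, seed = 1L, augment = NULL,
                         input_mode = "mask") {
  stopifnot(epochs >= 1, initial_lr > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 momentum = momentum, seed = as.integer(seed),
                 augment = augment, input_mode = input_mode),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param cfg a [train_config].
#' @param epoch 0-based epoch index (vectorized).
#' @return `initial_lr * lr_decay_factor^floor(epoch / lr_decay_every)`.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$initial_lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

#' Repeated k-fold assignment plan
#'
#' For each repeat, the subject ids are shuffled with a seed derived from
#' `master_seed` and the repeat index, then split into `k` groups whose
#' sizes differ by at most one (the first `n mod k` groups get the extra
#' subject). Every subject appears in exactly one validation group per
#' repeat. Folds are random, not stratified, matching the study protocol;
#' set `stratified = TRUE` to balance classes across groups instead.
#'
#' @param subject_ids character vector of unique ids.
#' @param k folds (default 5).
#' @param repeats number of independent repeats (default 15).
#' @param master_seed integer seed.
#' @param stratified logical; per-class round-robin assignment.
#' @param labels required when `stratified = TRUE`; class label per
#'   subject.
#' @return A list of class `fold_plan` with `assignments[[r]][[f]]` the ids
#'   validated in fold `f` of repeat `r`.
#' @export
make_fold_plan <- function(subject_ids, k = 5L, repeats = 15L,
                           master_seed = 1L, stratified = FALSE,
                           labels = NULL) {
  n <- length(subject_ids)
  k <- as.integer(k)
  if (k > n)
    stop_wmh("wmh_validation_error", "k = %d exceeds %d subjects", k, n)
  if (anyDuplicated(subject_ids))
    stop_wmh("wmh_validation_error", "subject ids must be unique")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  assignments <- lapply(seq_len(repeats), function(r) {
    set.seed(derive_seed(master_seed, r))
    if (stratified) {
      stopifnot(!is.null(labels), length(labels) == n)
      fold_of <- integer(n)
      for (cl in unique(labels)) {
        i <- sample(which(labels == cl))
        fold_of[i] <- ((seq_along(i) - 1L) %% k) + 1L
      }
      lapply(seq_len(k), function(f) subject_ids[fold_of == f])
    } else {
      perm <- sample(subject_ids)
      split(perm, rep(seq_len(k), times = sizes))
    }
  })
  structure(list(k = k, repeats = as.integer(repeats),
                 master_seed = as.integer(master_seed),
                 subject_ids = subject_ids, assignments = assignments),
            class = "fold_plan")
}

# Forward a list of cubes in inference mode, in mini-batches; returns the
# (K, N) probability matrix.
predict_probs <- function(model, cubes, batch_size = 8L) {
  N <- length(cubes)
  out <- NULL
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    logits <- model_forward(model, make_batch(model, cubes[idx]),
                            training = FALSE)
    probs <- softmax_ce(logits, rep(1L, length(idx)))$probs
    out <- cbind(out, probs)
  }
  out
}

#' Train a model
#'
#' Mini-batch SGD with momentum on softmax cross-entropy. Deterministic
#' given `cfg$seed`; the learning rate follows [lr_at_epoch] and the
#' returned history records the loss and learning rate of every epoch.
#'
#' @param model a `wmh_model` (modified in place and also returned).
#' @param subjects list of preprocessed [subject_record]s containing both
#'   classes.
#' @param cfg a [train_config].
#' @param classes optional character vector fixing class order (sorted
#'   unique labels by default); element 1 is encoded as class 1.
#' @return The trained model, with `model$history` (data.frame of `epoch`,
#'   `lr`, `loss`) and `model$classes` set.
#' @export
train_model <- function(model, subjects, cfg, classes = NULL) {
  stopifnot(inherits(model, "wmh_model"), inherits(cfg, "train_config"))
  labels <- vapply(subjects, function(s) s$label, "")
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(unique(labels)) < 2L)
    stop_wmh("wmh_validation_error",
             "training set contains a single class (%s)", unique(labels))
  if (!is.null(cfg$augment)) {
    aug <- unlist(lapply(seq_along(subjects), function(i) {
      spec <- cfg$augment
      spec$seed <- derive_seed(cfg$seed, i)
      augment(subjects[[i]], spec)
    }), recursive = FALSE)
    subjects <- c(subjects, aug)
    labels <- vapply(subjects, function(s) s$label, "")
  }
  cubes <- lapply(subjects, subject_input_array, input_mode = cfg$input_mode)
  target <- match(labels, classes)
  n <- length(cubes)
  param_layers <- walk_layers(model$net)
  param_layers <- param_layers[vapply(param_layers,
                                      function(l) length(l$params) > 0, TRUE)]
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric())
  set.seed(derive_seed(cfg$seed, 7919L))
  for (e in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at_epoch(cfg, e)
    perm <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      batch <- make_batch(model, cubes[idx])
      logits <- model_forward(model, batch, training = TRUE)
      ce <- softmax_ce(logits, target[idx])
      model_backward(model, ce$dlogits)
      sgd_step(param_layers, lr, cfg$momentum)
      losses <- c(losses, ce$loss)
    }
    history <- rbind(history,
                     data.frame(epoch = e, lr = lr, loss = mean(losses)))
  }
  model$classes <- classes
  model$history <- history
  model
}

#' Evaluate a model on labelled subjects
#'
#' Argmax predictions, confusion counts against the true labels, and the
#' three summary metrics: accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`
#' (true-positive rate for `positive_class`) and specificity `TN/(TN+FP)`.
#' A zero denominator yields `NaN` with a warning.
#'
#' @param model a trained `wmh_model` (with `model$classes` set).
#' @param subjects nonempty list of preprocessed [subject_record]s.
#' @param positive_class the class counted as positive; defaults to
#'   `"NMOSD"` when present (the rarer disease being detected), otherwise
#'   the first class.
#' @param input_mode see [forward_classify].
#' @return A list of class `eval_result`: `confusion` (TP, FP, TN, FN),
#'   `accuracy`, `sensitivity`, `specificity`, `n`, `positive_class`,
#'   `predictions` (data.frame of id, label, predicted).
#' @export
evaluate_model <- function(model, subjects, positive_class = NULL,
                           input_mode = "mask") {
  stopifnot(length(subjects) >= 1)
  classes <- model$classes %||% sort(unique(vapply(subjects,
                                                   function(s) s$label, "")))
  if (is.null(positive_class))
    positive_class <- if ("NMOSD" %in% classes) "NMOSD" else classes[1]
  cubes <- lapply(subjects, subject_input_array, input_mode = input_mode)
  probs <- predict_probs(model, cubes)
  pred <- classes[max.col(t(probs), ties.method = "first")]
  truth <- vapply(subjects, function(s) s$label, "")
  conf <- confusion_counts(truth, pred, positive_class)
  c(metrics_from_confusion(conf),
    list(n = length(subjects), positive_class = positive_class,
         predictions = data.frame(
           subject_id = vapply(subjects, function(s) s$subject_id, ""),
           label = truth, predicted = pred, stringsAsFactors = FALSE))) |>
    structure(class = "eval_result")
}

confusion_counts <- function(truth, pred, positive_class) {
  c(TP = sum(truth == positive_class & pred == positive_class),
    FP = sum(truth != positive_class & pred == positive_class),
    TN = sum(truth != positive_class & pred != positive_class),
    FN = sum(truth == positive_class & pred != positive_class))
}

metrics_from_confusion <- function(conf) {
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  list(confusion = conf,
       accuracy = (conf[["TP"]] + conf[["TN"]]) / sum(conf),
       sensitivity = safe_div(conf[["TP"]], conf[["TP"]] + conf[["FN"]],
                              "sensitivity"),
       specificity = safe_div(conf[["TN"]], conf[["TN"]] + conf[["FP"]],
                              "specificity"))
}

#' Repeated cross-validation of a model specification
#'
#' For every repeat and fold of the plan a fresh model is built (and, when
#' `spec$pretrained` and a `pretrained_source` is given, its backbone
#' weights are loaded), trained on the other k-1 groups and evaluated on
#' the held-out group. Per-repeat metrics pool the k folds' confusion
#' counts (set `fold_average = TRUE` to average per-fold metrics instead);
#' the aggregate reports mean and sd across repeats. Full provenance
#' (per-fold train/validation ids, seeds and confusions) is retained.
#'
#' @param cohort list of preprocessed [subject_record]s.
#' @param spec a [model_spec].
#' @param cfg a [train_config].
#' @param plan a fold plan ([make_fold_plan]) over the cohort's subject ids.
#' @param positive_class see [evaluate_model].
#' @param pretrained_source optional weights for
#'   [load_pretrained_backbone].
#' @param fold_average average per-fold metrics instead of pooling
#'   confusion counts.
#' @return A list of class `cv_report` with `per_repeat`, `aggregate`,
#'   `folds` (provenance) and the echoed configuration.
#' @export
run_repeated_cv <- function(cohort, spec, cfg, plan, positive_class = NULL,
                            pretrained_source = NULL,
                            fold_average = FALSE) {
  ids <- vapply(cohort, function(s) s$subject_id, "")
  if (!setequal(ids, plan$subject_ids))
    stop_wmh("wmh_validation_error", "plan ids do not match cohort ids")
  labels <- vapply(cohort, function(s) s$label, "")
  classes <- sort(unique(labels))
  if (is.null(positive_class))
    positive_class <- if ("NMOSD" %in% classes) "NMOSD" else classes[1]
  folds <- list()
  per_repeat <- data.frame()
  for (r in seq_len(plan$repeats)) {
    rep_conf <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    fold_metrics <- list()
    for (f in seq_len(plan$k)) {
      val_ids <- plan$assignments[[r]][[f]]
      train_ids <- setdiff(ids, val_ids)
      seed_rf <- derive_seed(plan$master_seed, r, f)
      model <- build_model(spec, seed = seed_rf)
      if (isTRUE(spec$pretrained) && !is.null(pretrained_source))
        model <- load_pretrained_backbone(model, pretrained_source)
      cfg_rf <- cfg
      cfg_rf$seed <- seed_rf
      res <- tryCatch({
        model <- train_model(model, cohort[match(train_ids, ids)], cfg_rf,
                             classes = classes)
        evaluate_model(model, cohort[match(val_ids, ids)], positive_class,
                       input_mode = cfg$input_mode)
      }, error = function(e) {
        stop_wmh("wmh_cv_error", "repeat %d fold %d: %s", r, f,
                 conditionMessage(e))
      })
      rep_conf <- rep_conf + res$confusion
      fold_metrics[[f]] <- res
      folds[[length(folds) + 1L]] <-
        list(repeat_idx = r, fold = f, seed = seed_rf,
             train_ids = train_ids, val_ids = val_ids,
             confusion = res$confusion, accuracy = res$accuracy,
             sensitivity = res$sensitivity, specificity = res$specificity,
             predictions = res$predictions)
    }
    m <- if (fold_average) {
      list(accuracy = mean(vapply(fold_metrics, `[[`, 0, "accuracy")),
           sensitivity = mean(vapply(fold_metrics, `[[`, 0, "sensitivity")),
           specificity = mean(vapply(fold_metrics, `[[`, 0, "specificity")))
    } else {
      metrics_from_confusion(rep_conf)[c("accuracy", "sensitivity",
                                         "specificity")]
    }
    per_repeat <- rbind(per_repeat, data.frame(
      repeat_idx = r, TP = rep_conf[["TP"]], FP = rep_conf[["FP"]],
      TN = rep_conf[["TN"]], FN = rep_conf[["FN"]],
      accuracy = m$accuracy, sensitivity = m$sensitivity,
      specificity = m$specificity))
  }
  agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
  report <- list(
    per_repeat = per_repeat,
    aggregate = list(accuracy = agg(per_repeat$accuracy),
                     sensitivity = agg(per_repeat$sensitivity),
                     specificity = agg(per_repeat$specificity)),
    confusion_totals = colSums(per_repeat[, c("TP", "FP", "TN", "FN")]),
    folds = folds,
    positive_class = positive_class,
    classes = classes,
    fold_average = fold_average,
    config = list(spec = spec, train = cfg,
                  plan = plan[c("k", "repeats", "master_seed")]))
  class(report) <- "cv_report"
  report
}

#' @export
print.cv_report <- function(x, ...) {
  fmt <- function(m) sprintf("%.3f +/- %.3f", m[["mean"]], m[["sd"]])
  cat(sprintf(
    "<cv_report> %d-fold x %d repeats, positive class %s\n  accuracy    %s\n  sensitivity %s\n  specificity %s\n",
    x$config$plan$k, x$config$plan$repeats, x$positive_class,
    fmt(x$aggregate$accuracy), fmt(x$aggregate$sensitivity),
    fmt(x$aggregate$specificity)))
  invisible(x)
}

#' Structural no-leakage check
#'
#' Asserts from a report's provenance log that, for every (repeat, fold),
#' the trained-on ids and evaluated ids are disjoint, and that within each
#' repeat every subject is validated exactly once.
#'
#' @param report a `cv_report`.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
check_no_leakage <- function(report) {
  for (fd in report$folds) {
    if (length(intersect(fd$train_ids, fd$val_ids)) > 0)
      stop_wmh("wmh_leakage_error", "repeat %d fold %d shares subjects",
               fd$repeat_idx, fd$fold)
  }
  reps <- split(report$folds,
                vapply(report$folds, `[[`, 0, "repeat_idx"))
  all_ids <- sort(unique(unlist(lapply(report$folds, function(fd)
    c(fd$train_ids, fd$val_ids)))))
  for (fds in reps) {
    val <- unlist(lapply(fds, `[[`, "val_ids"))
    if (anyDuplicated(val) || !setequal(val, all_ids))
      stop_wmh("wmh_leakage_error",
               "repeat %d does not validate each subject exactly once",
               fds[[1]]$repeat_idx)
  }
  invisible(TRUE)
}

#' Metric-algebra check
#'
#' Verifies on the logged confusion counts of every repeat that
#' `accuracy * N = TP + TN` and that the three reported metrics equal their
#' defining ratios exactly (pooled reports only; fold-averaged reports
#' check the per-fold entries instead).
#'
#' @param report a `cv_report`.
#' @param tol numeric tolerance for the identities.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
check_metric_algebra <- function(report, tol = 1e-12) {
  rows <- if (report$fold_average) report$folds
          else split(report$per_repeat, seq_len(nrow(report$per_repeat)))
  for (row in rows) {
    conf <- if (report$fold_average) row$confusion
            else c(TP = row$TP, FP = row$FP, TN = row$TN, FN = row$FN)
    m <- metrics_from_confusion(conf)
    acc <- if (report$fold_average) row$accuracy else row$accuracy
    if (abs(acc * sum(conf) - (conf[["TP"]] + conf[["TN"]])) > tol)
      stop_wmh("wmh_metric_error", "accuracy identity violated")
    for (nm in c("accuracy", "sensitivity", "specificity")) {
      got <- if (report$fold_average) row[[nm]] else row[[nm]]
      if (!is.nan(got) && abs(got - m[[nm]]) > tol)
        stop_wmh("wmh_metric_error", "%s does not match its formula", nm)
    }
  }
  invisible(TRUE)
}
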