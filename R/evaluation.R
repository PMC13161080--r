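#' Stratified k-fold assignment, optionally grouped by student
#'
#' Per-class round-robin assignment after a seeded shuffle, so every
#' fold's class counts are within one sample of the global proportions.
#' With `groups` given (the default path for sliding-window samples),
#' whole groups are stratified by their modal label and every sample of a
#' group lands in one fold, preventing identity leakage across a
#' student's overlapping windows; stratification is then within one
#' group rather than one sample.
#'
#' @param labels integer class labels (1--4).
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @param groups optional grouping vector (e.g. student ids), same length
#'   as `labels`.
#' @return A list of class `"fold_plan"`: `k`, `assignments` (integer
#'   fold per sample), `stratified`, `grouped`, `seed`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1, groups = NULL) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(labels)
  assignments <- integer(n)
  if (is.null(groups)) {
    cnt <- table(labels)
    low <- cnt[cnt < k]
    if (length(low)) {
      stop(sprintf("class %s has only %d member(s), fewer than k = %d",
                   names(low)[1], low[1], k))
    }
    for (lv in names(cnt)) {
      idx <- sample(which(labels == lv))
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    stopifnot(length(groups) == n)
    gl <- tapply(labels, groups, function(x) modal_level(as.integer(x)))
    gnames <- names(gl)
    cnt <- table(unlist(gl))
    low <- cnt[cnt < k]
    if (length(low)) {
      stop(sprintf(
        "class %s has only %d group(s), fewer than k = %d folds",
        names(low)[1], low[1], k))
    }
    gfold <- stats::setNames(integer(length(gnames)), gnames)
    for (lv in names(cnt)) {
      g <- sample(gnames[gl == as.integer(lv)])
      gfold[g] <- rep_len(seq_len(k), length(g))
    }
    assignments <- unname(gfold[as.character(groups)])
  }
  structure(list(k = as.integer(k), assignments = assignments,
                 stratified = TRUE, grouped = !is.null(groups),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Confusion matrix of predicted versus true levels
#'
#' @param pred,truth integer vectors.
#' @param n_levels number of classes (default 4).
#' @return `n_levels` x `n_levels` integer matrix; rows are true classes,
#'   columns predictions.
#' @export
confusion_matrix <- function(pred, truth, n_levels = 4) {
  m <- matrix(0L, n_levels, n_levels,
              dimnames = list(true = 1:n_levels, pred = 1:n_levels))
  for (i in seq_along(pred)) {
    m[truth[i], pred[i]] <- m[truth[i], pred[i]] + 1L
  }
  m
}

#' Support-weighted classification metrics from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)` and recall `TP/(TP+FN)` (0 when
#' undefined), F1 their harmonic mean, and the weighted averages using
#' true-class supports as weights -- so performance on minority classes
#' (the at-risk affect levels) is weighted by prevalence rather than
#' ignored. Accuracy is the trace over the total.
#'
#' @param confusion square matrix of non-negative counts, rows = truth.
#' @return An object of class `"metric_report"`: `accuracy`,
#'   `precision_w`, `recall_w`, `f1_w`, `per_class` (data frame),
#'   `confusion`.
#' @export
weighted_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all zero")
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predn <- colSums(confusion)
  precision <- ifelse(predn > 0, tp / predn, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  structure(list(
    accuracy = sum(tp) / total,
    precision_w = sum(w * precision),
    recall_w = sum(w * recall),
    f1_w = sum(w * f1),
    per_class = data.frame(level = seq_along(tp), support = support,
                           precision = precision, recall = recall, f1 = f1),
    confusion = confusion
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  precision_w %.3f  recall_w %.3f  f1_w %.3f\n",
              x$accuracy, x$precision_w, x$recall_w, x$f1_w))
  invisible(x)
}

#' Paired t-test on per-fold metrics
#'
#' Classical paired t on the fold-wise differences `a - b`, two-sided p
#' from the t distribution with `n - 1` degrees of freedom. Zero variance
#' of the differences is flagged as degenerate: p is 1 when all
#' differences are zero and 0 otherwise (sign convention).
#'
#' @param metric_a,metric_b equal-length numeric vectors (one value per
#'   fold).
#' @return List `t`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p_value = 1, df = n - 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p_value = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Cross-validated evaluation of one model variant
#'
#' Trains and evaluates the variant on each fold of the plan; reports
#' per-fold weighted metrics, their mean and sd, and the pooled confusion
#' matrix.
#'
#' @param samples a [build_samples()] object.
#' @param plan a [stratified_kfold()] plan over `samples$y` (typically
#'   grouped by `samples$student`).
#' @param variant see [tsn()].
#' @param config a [tsn_config()].
#' @return List of class `"cv_result"`: `folds` (data frame of per-fold
#'   metrics), `mean`, `sd`, `confusion`, `variant`.
#' @export
run_cv <- function(samples, plan, variant = "full", config = tsn_config()) {
  stopifnot(length(plan$assignments) == length(samples$y))
  rows <- list()
  pooled <- matrix(0L, N_LEVELS, N_LEVELS)
  for (f in seq_len(plan$k)) {
    te <- which(plan$assignments == f)
    tr <- which(plan$assignments != f)
    fit <- tsn(subset_samples(samples, tr), variant = variant,
               config = config)
    test <- subset_samples(samples, te)
    pred <- predict(fit, test, type = "class")
    cm <- confusion_matrix(pred, test$y)
    mr <- weighted_metrics(cm)
    pooled <- pooled + cm
    rows[[f]] <- data.frame(fold = f, accuracy = mr$accuracy,
                            precision_w = mr$precision_w,
                            recall_w = mr$recall_w, f1_w = mr$f1_w)
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "precision_w", "recall_w", "f1_w")
  structure(list(folds = folds,
                 mean = colMeans(folds[metric_cols]),
                 sd = vapply(folds[metric_cols], stats::sd, 0),
                 confusion = pooled, variant = variant),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> variant '%s' over %d folds\n",
              x$variant, nrow(x$folds)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Ablation study over the four model variants
#'
#' Trains and evaluates baseline (short-term only), baseline + long-term
#' mean (concatenation), baseline + fusion gate, and the full
#' attention-gated model on identical fold plans and seeds, mirroring the
#' four-row ablation table.
#'
#' @inheritParams run_cv
#' @return List with `table` (data frame: variant x mean metrics with
#'   sds) and `cv` (named list of [run_cv()] results).
#' @export
run_ablation <- function(samples, plan, config = tsn_config()) {
  cvs <- lapply(tsn_variants, function(v) run_cv(samples, plan, v, config))
  names(cvs) <- tsn_variants
  table <- do.call(rbind, lapply(tsn_variants, function(v) {
    data.frame(variant = v,
               accuracy = cvs[[v]]$mean[["accuracy"]],
               precision_w = cvs[[v]]$mean[["precision_w"]],
               recall_w = cvs[[v]]$mean[["recall_w"]],
               f1_w = cvs[[v]]$mean[["f1_w"]],
               accuracy_sd = cvs[[v]]$sd[["accuracy"]],
               stringsAsFactors = FALSE)
  }))
  list(table = table, cv = cvs)
}

#' Accuracy as a function of the latent dimension
#'
#' Trains the full model at each requested latent dimension `d` on
#' identical folds and seeds, giving the accuracy-versus-dimension curve
#' used to choose `d`.
#'
#' @inheritParams run_cv
#' @param d_values dimensions to sweep (default `2^(3:8)`).
#' @return Data frame `d`, `accuracy`, `accuracy_sd`.
#' @export
sweep_dimension <- function(samples, plan, d_values = 2^(3:8),
                            config = tsn_config()) {
  rows <- lapply(d_values, function(dd) {
    cfg <- config
    cfg$d <- as.integer(dd)
    cv <- run_cv(samples, plan, "full", cfg)
    data.frame(d = dd, accuracy = cv$mean[["accuracy"]],
               accuracy_sd = cv$sd[["accuracy"]])
  })
  do.call(rbind, rows)
}

#' Attention and gate activations for inspection
#'
#' Per-sample attention weights over the history days and the mean gate
#' activation, for interpretability reports (which days the model deems
#' important, and how strongly the short-term state dominates).
#'
#' @param model a fitted [tsn()] (variant with a history).
#' @param samples evaluation samples.
#' @return List `alpha` (n x T matrix, rows summing to 1), `gate_mean`
#'   (per-sample mean of the gate vector, `NULL` for gateless variants),
#'   `student`, `day`.
#' @export
attention_report <- function(model, samples) {
  stopifnot(model$variant != "baseline")
  fwd <- predict(model, samples, type = "trace")
  alpha <- t(fwd$alpha)
  colnames(alpha) <- paste0("day_", seq_len(ncol(alpha)))
  list(alpha = alpha,
       gate_mean = if (!is.null(fwd$G)) rowMeans(fwd$G) else NULL,
       student = samples$student, day = samples$day)
}
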