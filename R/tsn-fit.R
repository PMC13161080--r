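#' Temporal sensitive network hyperparameters
#'
#' Defaults follow the configuration the method was tuned at: latent
#' dimension 32, learning rate 1e-3, batch size 64, Adam, at most 300
#' epochs with early stopping.
#'
#' @param d latent dimension of the daily behavior representation.
#' @param t_window history length in days feeding the attention pool.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed controlling initialization, shuffling and the
#'   validation split.
#' @param short_term_span days averaged into the short-term state vector
#'   (1 = the target day itself).
#' @param val_frac fraction of training samples held out, stratified, for
#'   early stopping.
#' @param class_weights use inverse-frequency class weights in the loss
#'   (off by default; plain cross-entropy suffices).
#' @return A list of class `"tsn_config"`.
#' @export
tsn_config <- function(d = 32, t_window = 3, lr = 1e-3, batch = 64,
                       max_epochs = 300, patience = 20, seed = 1,
                       short_term_span = 1, val_frac = 0.1,
                       class_weights = FALSE) {
  stopifnot(d >= 1, t_window >= 1, lr > 0, batch >= 1, max_epochs >= 1,
            patience >= 1, short_term_span >= 1)
  structure(list(d = as.integer(d), t_window = as.integer(t_window),
                 lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 short_term_span = as.integer(short_term_span),
                 val_frac = val_frac, class_weights = class_weights),
            class = "tsn_config")
}

#' Build supervised sliding-window samples from per-day features
#'
#' Each labeled day `t` of a student with a full `t_window`-day history
#' yields one sample: the history block holds days `t - t_window` to
#' `t - 1`, the short-term vector averages the most recent
#' `short_term_span` days ending at day `t`, and the target is day `t`'s
#' affect level. Days with missing labels are skipped as targets but may
#' appear in histories.
#'
#' @param daily data frame with columns `student_id`, `day`, the feature
#'   columns, and `label` (integer 1--4 or `NA`); features must already be
#'   imputed (finite).
#' @param feature_cols character vector naming the feature columns, fixed
#'   order.
#' @param t_window history length in days.
#' @param short_term_span see [tsn_config()].
#' @return An object of class `"tsn_samples"`: `XH` ((n * t_window) x p
#'   history matrix, sample-major), `Xs` (n x p), `y`, `student`, `day`,
#'   `t_window`, `feature_cols`.
#' @export
build_samples <- function(daily, feature_cols, t_window = 3,
                          short_term_span = 1) {
  stopifnot(all(c("student_id", "day", "label") %in% names(daily)),
            all(feature_cols %in% names(daily)))
  p <- length(feature_cols)
  xh_list <- list(); xs_list <- list()
  y <- integer(0); stu <- character(0); dy <- integer(0)
  for (sid in unique(daily$student_id)) {
    sub <- daily[daily$student_id == sid, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    X <- as.matrix(sub[, feature_cols, drop = FALSE])
    if (any(!is.finite(X))) {
      stop("non-finite features for student ", sid, "; impute first")
    }
    days <- sub$day
    for (i in seq_len(nrow(sub))) {
      if (is.na(sub$label[i])) next
      if (i <= t_window) next
      # require a contiguous daily history
      if (days[i] - days[i - t_window] != t_window) next
      hist_rows <- (i - t_window):(i - 1)
      short_rows <- max(1, i - short_term_span + 1):i
      xh_list[[length(xh_list) + 1]] <- X[hist_rows, , drop = FALSE]
      xs_list[[length(xs_list) + 1]] <-
        colMeans(X[short_rows, , drop = FALSE])
      y <- c(y, sub$label[i])
      stu <- c(stu, sid)
      dy <- c(dy, days[i])
    }
  }
  if (!length(y)) stop("no usable samples (check labels and t_window)")
  structure(list(
    XH = do.call(rbind, xh_list),
    Xs = do.call(rbind, xs_list),
    y = y, student = stu, day = dy,
    t_window = as.integer(t_window),
    feature_cols = feature_cols
  ), class = "tsn_samples")
}

#' @export
print.tsn_samples <- function(x, ...) {
  cat(sprintf("<tsn_samples> %d samples, %d students, T = %d, %d features\n",
              length(x$y), length(unique(x$student)), x$t_window,
              length(x$feature_cols)))
  cat("  level counts:", paste(tabulate(x$y, 4), collapse = "/"), "\n")
  invisible(x)
}

# Subset samples by index, keeping the history block aligned.
subset_samples <- function(samples, idx) {
  T <- samples$t_window
  hrows <- as.numeric(outer(seq_len(T), (idx - 1) * T, `+`))
  structure(list(
    XH = samples$XH[hrows, , drop = FALSE],
    Xs = samples$Xs[idx, , drop = FALSE],
    y = samples$y[idx], student = samples$student[idx],
    day = samples$day[idx], t_window = T,
    feature_cols = samples$feature_cols
  ), class = "tsn_samples")
}

# z-score columns using given (or freshly computed) statistics
scale_cols <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, `/`)
}

#' Fit a temporal sensitive network
#'
#' The model embeds each day's standardized behavior vector with a shared
#' affine-tanh map, scores the history days with a scalar tanh attention
#' head, softmax-normalizes the scores into weights, pools the history
#' into a long-term habit vector `L`, and fuses `L` with the short-term
#' state `S` through a learned sigmoid gate `G`:
#' `P = G * S + (1 - G) * L`. A final affine-softmax layer predicts the
#' four affect levels; training minimizes cross-entropy with Adam,
#' shuffled minibatches and early stopping on a stratified validation
#' split (best weights restored).
#'
#' Feature standardization statistics are computed from the training
#' samples only and stored in the fit, so held-out data passed to
#' [predict.tsn()] is standardized without leakage.
#'
#' @param samples a [build_samples()] object (raw, unstandardized
#'   features).
#' @param variant one of `"full"` (attention + gate), `"baseline_fm"`
#'   (gate over a uniform history mean), `"baseline_ltm"` (concatenation
#'   with a uniform history mean), `"baseline"` (short-term only).
#' @param config a [tsn_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `"tsn"` with components `params`, `variant`,
#'   `config`, `center`, `scale`, `trace` (per-epoch train/validation
#'   loss), `epochs_run`, `best_epoch`, `levels`, `feature_cols`.
#' @seealso [predict.tsn()], [ablation_variant()]
#' @export
tsn <- function(samples, variant = c("full", "baseline_fm", "baseline_ltm",
                                     "baseline"),
                config = tsn_config(), verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(samples, "tsn_samples"))
  n <- length(samples$y)
  p <- length(samples$feature_cols)
  T <- samples$t_window
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  # stratified validation split for early stopping
  val_idx <- integer(0)
  if (config$val_frac > 0 && n >= 20) {
    for (lv in sort(unique(samples$y))) {
      members <- which(samples$y == lv)
      n_val <- max(1, round(length(members) * config$val_frac))
      val_idx <- c(val_idx, sample(members, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  train <- subset_samples(samples, tr_idx)
  val <- if (length(val_idx)) subset_samples(samples, val_idx) else NULL

  center <- colMeans(rbind(train$Xs, train$XH))
  scl <- apply(rbind(train$Xs, train$XH), 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  std <- function(s) {
    s$Xs <- scale_cols(s$Xs, center, scl)
    s$XH <- scale_cols(s$XH, center, scl)
    s
  }
  train <- std(train)
  if (!is.null(val)) val <- std(val)

  w_class <- rep(1, N_LEVELS)
  if (isTRUE(config$class_weights)) {
    cnt <- pmax(tabulate(train$y, N_LEVELS), 1)
    w_class <- (length(train$y) / N_LEVELS) / cnt
  }

  params <- tsn_init(p, config$d, variant)
  theta <- tsn_flatten(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n_tr <- length(train$y)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  best_loss <- Inf; best_theta <- theta; best_epoch <- 0L; stall <- 0L

  eval_loss <- function(pp, s) {
    fw <- tsn_forward(pp, s$XH, s$Xs, T, variant)
    ce_loss(fw$probs, s$y)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    for (b0 in seq(1, n_tr, by = config$batch)) {
      bi <- ord[b0:min(b0 + config$batch - 1, n_tr)]
      bt <- subset_samples(train, bi)
      params <- tsn_relist(theta, params)
      fwd <- tsn_forward(params, bt$XH, bt$Xs, T, variant)
      loss <- ce_loss(fwd$probs, bt$y)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      sw <- if (isTRUE(config$class_weights)) w_class[bt$y] else NULL
      grad <- tsn_backward(params, fwd, bt$XH, bt$Xs, bt$y, T, variant, sw)
      gvec <- tsn_flatten(grad)
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * gvec
      v <- beta2 * v + (1 - beta2) * gvec^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - config$lr * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + loss * length(bi)
    }
    params <- tsn_relist(theta, params)
    train_loss <- ep_loss / n_tr
    val_loss <- if (!is.null(val)) eval_loss(params, val) else train_loss
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f",
                      epoch, train_loss, val_loss))
    }
    if (val_loss < best_loss - 1e-6) {
      best_loss <- val_loss; best_theta <- theta
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  params <- tsn_relist(best_theta, params)

  structure(list(params = params, variant = variant, config = config,
                 center = center, scale = scl,
                 feature_cols = samples$feature_cols,
                 trace = trace, epochs_run = nrow(trace),
                 best_epoch = best_epoch, levels = 1:4,
                 n_train = n_tr, n_val = length(val_idx)),
            class = "tsn")
}

#' Builder for an ablation variant of the network
#'
#' The four variants share the train/predict interface and differ only in
#' which mechanisms are active: `"baseline"` predicts from the short-term
#' state alone; `"baseline_ltm"` concatenates the short-term state with a
#' uniform (1/T-weighted) history mean, with neither attention nor gate;
#' `"baseline_fm"` gate-fuses the short-term state with the uniform
#' history mean; `"full"` uses attention weighting and the gate.
#'
#' @param name variant name.
#' @param config a [tsn_config()].
#' @return A function `f(samples, ...)` that fits the variant.
#' @export
ablation_variant <- function(name, config = tsn_config()) {
  name <- match.arg(name, tsn_variants)
  function(samples, ...) tsn(samples, variant = name, config = config, ...)
}

#' @export
print.tsn <- function(x, ...) {
  cat(sprintf("<tsn> variant '%s', d = %d, T = %d\n",
              x$variant, x$config$d, x$config$t_window))
  cat(sprintf("  trained %d epochs (best %d), train n = %d, val n = %d\n",
              x$epochs_run, x$best_epoch, x$n_train, x$n_val))
  if (nrow(x$trace)) {
    cat(sprintf("  best validation loss %.4f\n", min(x$trace$val_loss)))
  }
  invisible(x)
}

#' @export
summary.tsn <- function(object, ...) {
  np <- length(tsn_flatten(object$params))
  cat(sprintf("Temporal sensitive network (variant '%s')\n", object$variant))
  cat(sprintf("  latent dimension d = %d, history T = %d, %d parameters\n",
              object$config$d, object$config$t_window, np))
  cat(sprintf("  epochs run %d, best epoch %d, best val loss %.4f\n",
              object$epochs_run, object$best_epoch,
              min(object$trace$val_loss)))
  cat("  features:", paste(object$feature_cols, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.tsn <- function(object, ...) object$params

#' Predict affect levels or class probabilities
#'
#' @param object a fitted [tsn()] model.
#' @param samples a [build_samples()] object with the same feature columns.
#' @param type `"class"` for hard levels, `"prob"` for the n x 4
#'   probability matrix, `"trace"` for the forward activations (attention
#'   weights `alpha`, gate `G`, fused representation `P`, probabilities).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.tsn <- function(object, samples,
                        type = c("class", "prob", "trace"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(samples, "tsn_samples"),
            identical(samples$feature_cols, object$feature_cols),
            samples$t_window == object$config$t_window)
  Xs <- scale_cols(samples$Xs, object$center, object$scale)
  XH <- if (is.null(samples$XH)) NULL else
    scale_cols(samples$XH, object$center, object$scale)
  fwd <- tsn_forward(object$params, XH, Xs, samples$t_window, object$variant)
  switch(type,
    class = max.col(fwd$probs, ties.method = "first"),
    prob = fwd$probs,
    trace = fwd)
}

#' @export
fitted.tsn <- function(object, samples, ...) {
  predict(object, samples, type = "prob")
}

#' Deviance residuals of a fitted network
#'
#' For classification, `sqrt(-2 log p[true level])` per sample: zero for a
#' confident correct prediction, large when the truth was given low
#' probability.
#'
#' @param object a fitted [tsn()] model.
#' @param samples evaluation samples.
#' @param ... unused.
#' @export
residuals.tsn <- function(object, samples, ...) {
  probs <- predict(object, samples, type = "prob")
  p <- probs[cbind(seq_along(samples$y), samples$y)]
  sqrt(-2 * log(pmax(p, 1e-12)))
}

#' Plot the training trajectory
#'
#' @param x a fitted [tsn()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tsn <- function(x, ...) {
  graphics::matplot(x$trace$epoch,
                    cbind(x$trace$train_loss, x$trace$val_loss),
                    type = "l", lty = 1:2, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey50")
  graphics::legend("topright", c("train", "validation"), lty = 1:2,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
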