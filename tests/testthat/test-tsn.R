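fwd_of <- function(params, XH, Xs, T, variant = "full") {
  tsnaffect:::tsn_forward(params, XH, Xs, T, variant)
}

test_that("forward-pass invariants hold under parameter fuzzing", {
  set.seed(51)
  for (i in 1:120) {
    d <- sample(2:6, 1); T <- sample(1:5, 1); p <- sample(2:6, 1)
    n <- sample(1:3, 1)
    params <- tsnaffect:::tsn_init(p, d, "full")
    params <- lapply(params, function(x) x + rnorm(length(x), 0, 0.5))
    XH <- matrix(rnorm(n * T * p), ncol = p)
    Xs <- matrix(rnorm(n * p), ncol = p)
    fwd <- fwd_of(params, XH, Xs, T)
    # attention weights form a simplex over the T history days
    expect_equal(unname(colSums(fwd$alpha)), rep(1, n), tolerance = 1e-9)
    expect_true(all(fwd$alpha > 0))
    # attention scores are tanh-bounded
    expect_true(all(abs(fwd$I) < 1))
    # gate strictly inside the open unit box
    expect_true(all(fwd$G > 0 & fwd$G < 1))
    # fused representation between its two sources, coordinate-wise
    lo <- pmin(fwd$Es, fwd$L); hi <- pmax(fwd$Es, fwd$L)
    expect_true(all(fwd$P >= lo - 1e-12 & fwd$P <= hi + 1e-12))
    # embedded representations in the tanh range
    expect_true(all(abs(fwd$E) < 1))
    expect_true(all(abs(fwd$Es) < 1))
    # prediction rows on the probability simplex
    expect_equal(unname(rowSums(fwd$probs)), rep(1, n), tolerance = 1e-9)
    expect_true(all(fwd$probs >= 0))
  }
})

test_that("attention reduces to closed forms", {
  # d = 1, identity-ish embedding: craft I = [log 2, 0]
  params <- list(A = matrix(1, 1, 1), a = 0, w_d = 1, b_d = 0,
                 W_e = matrix(0, 1, 1), W_f = matrix(0, 1, 1), b_g = 0,
                 W_o = matrix(0, 4, 1), b_o = numeric(4))
  x1 <- atanh(atanh(log(2)))  # tanh(w_d * tanh(x1)) = log 2
  XH <- matrix(c(x1, 0), 2, 1)
  fwd <- fwd_of(params, XH, matrix(0, 1, 1), 2)
  expect_equal(as.numeric(fwd$alpha), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # uniform scores give uniform weights and L equals the day mean
  XH3 <- matrix(0, 3, 1)
  f3 <- fwd_of(params, XH3, matrix(0, 1, 1), 3)
  expect_equal(as.numeric(f3$alpha), rep(1 / 3, 3))
  # zero output weights give uniform class probabilities
  expect_equal(as.numeric(f3$probs), rep(0.25, 4))
})

test_that("gate and fusion obey their limiting cases", {
  d <- 3
  base <- tsnaffect:::tsn_init(2, d, "full")
  XH <- matrix(rnorm(6), 3, 2); Xs <- matrix(rnorm(2), 1, 2)
  # zero gate parameters: G = 1/2 everywhere
  p0 <- base; p0$W_e[] <- 0; p0$W_f[] <- 0; p0$b_g[] <- 0
  f0 <- fwd_of(p0, XH, Xs, 3)
  expect_equal(as.numeric(f0$G), rep(0.5, d))
  expect_equal(unname(f0$P), unname(0.5 * f0$Es + 0.5 * f0$L))
  # saturated positive bias: short-term dominance, P -> s_short
  p1 <- p0; p1$b_g[] <- 50
  f1 <- fwd_of(p1, XH, Xs, 3)
  expect_equal(unname(f1$P), unname(f1$Es), tolerance = 1e-12)
  # saturated negative bias: long-term dominance, P -> L
  p2 <- p0; p2$b_g[] <- -50
  f2 <- fwd_of(p2, XH, Xs, 3)
  expect_equal(unname(f2$P), unname(f2$L), tolerance = 1e-12)
  # one-hot attention selects a single day
  p3 <- base
  f3 <- fwd_of(p3, XH, Xs, 3)
  agree <- f3$alpha[, 1]
  L_manual <- t(f3$E) %*% agree
  expect_equal(as.numeric(f3$L), as.numeric(L_manual), tolerance = 1e-9)
})

test_that("cross-entropy loss has its closed-form anchors", {
  perfect <- diag(4)[c(1, 3), ]
  expect_equal(ce_loss(perfect, c(1, 3)), 0, tolerance = 1e-10)
  uniform <- matrix(0.25, 2, 4)
  expect_equal(ce_loss(uniform, c(2, 4)), log(4), tolerance = 1e-12)
  set.seed(52)
  z <- matrix(rexp(40), 10, 4); z <- z / rowSums(z)
  expect_gte(ce_loss(z, sample(1:4, 10, replace = TRUE)), 0)
  expect_error(ce_loss(uniform, c(0, 2)), "labels")
  expect_error(ce_loss(uniform, c(1, 5)), "labels")
})

test_that("analytic gradients match finite differences for all variants", {
  for (v in tsnaffect:::tsn_variants) {
    err <- tsn_gradient_check(n_draws = 8, d = 3, t_window = 4,
                              variant = v, seed = 4)
    expect_lt(err, 1e-4)
  }
})

test_that("softmax logits are shift-invariant", {
  set.seed(53)
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(tsnaffect:::row_softmax(z),
               tsnaffect:::row_softmax(z + 5), tolerance = 1e-12)
})

test_that("training drives loss near zero on a separable construction", {
  s <- separable_samples(n = 120)
  cfg <- tsn_config(d = 8, lr = 5e-3, batch = 32, max_epochs = 150,
                    patience = 150, seed = 2, val_frac = 0)
  fit <- tsn(s, "full", cfg)
  expect_lt(min(fit$trace$train_loss), 0.1)
  expect_equal(unname(mean(predict(fit, s) == s$y)), 1)
})

test_that("training is bit-reproducible and early stopping engages", {
  s <- separable_samples(n = 80)
  cfg <- tsn_config(d = 4, max_epochs = 30, patience = 5, seed = 9)
  f1 <- tsn(s, "full", cfg)
  f2 <- tsn(s, "full", cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$params, f2$params)
  # early stopping: training halts within patience epochs of the best
  cfg2 <- tsn_config(d = 4, max_epochs = 300, patience = 4, seed = 9)
  f3 <- tsn(s, "baseline", cfg2)
  expect_lte(f3$epochs_run, f3$best_epoch + cfg2$patience)
})

test_that("ablation variants share the interface and degenerate correctly", {
  s <- separable_samples(n = 80)
  cfg <- tsn_config(d = 4, max_epochs = 5, patience = 5, seed = 1)
  for (v in tsnaffect:::tsn_variants) {
    fit <- ablation_variant(v, cfg)(s)
    expect_s3_class(fit, "tsn")
    pr <- predict(fit, s, type = "prob")
    expect_equal(dim(pr), c(80L, 4L))
  }
  expect_error(ablation_variant("lstm"), "arg")

  # the baseline ignores history: permuting past days changes nothing
  fitb <- tsn(s, "baseline", cfg)
  s_perm <- s
  set.seed(5)
  perm <- unlist(lapply(seq_len(80), function(i) (i - 1) * 3 + sample(3)))
  s_perm$XH <- s$XH[perm, , drop = FALSE]
  expect_equal(predict(fitb, s_perm, type = "prob"),
               predict(fitb, s, type = "prob"))

  # full model with history identical to the short-term state: P = s_short
  params <- tsnaffect:::tsn_init(4, 3, "full")
  Xs <- matrix(rnorm(4), 1, 4)
  XH <- Xs  # T = 1, same day
  fwd <- fwd_of(params, XH, Xs, 1)
  expect_equal(unname(fwd$P), unname(fwd$Es), tolerance = 1e-12)
})

test_that("residuals and plot methods behave", {
  s <- separable_samples(n = 60)
  cfg <- tsn_config(d = 4, max_epochs = 10, patience = 10, seed = 3)
  fit <- tsn(s, "full", cfg)
  r <- residuals(fit, s)
  expect_length(r, 60)
  expect_true(all(r >= 0))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
  expect_output(print(fit), "variant 'full'")
  expect_output(summary(fit), "parameters")
})

test_that("history gradient never fully detaches (attention shortcut)", {
  set.seed(54)
  params <- tsnaffect:::tsn_init(3, 4, "full")
  params <- lapply(params, function(x) x + rnorm(length(x), 0, 0.4))
  T <- 4
  XH <- matrix(rnorm(T * 3), T, 3); Xs <- matrix(rnorm(3), 1, 3)
  base_fwd <- fwd_of(params, XH, Xs, T)
  y <- 2
  # numerically: each history day moves the loss
  for (k in seq_len(T)) {
    XH2 <- XH
    XH2[k, ] <- XH2[k, ] + 1e-3
    f2 <- fwd_of(params, XH2, Xs, T)
    expect_gt(abs(ce_loss(f2$probs, y) - ce_loss(base_fwd$probs, y)), 0)
  }
})
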