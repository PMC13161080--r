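# Temporal sensitive network internals: vectorized batch forward and
# backward passes for the four model variants. All samples in a batch share
# the same history length T; history rows are stored sample-major
# (sample 1 days 1..T, sample 2 days 1..T, ...).

N_LEVELS <- 4L

tsn_variants <- c("baseline", "baseline_ltm", "baseline_fm", "full")

sigmoid <- function(x) 1 / (1 + exp(-x))

# Uniform init scaled by 1/sqrt(fan-in), seeded by the caller.
init_mat <- function(nrow, ncol) {
  matrix(stats::runif(nrow * ncol, -1, 1) / sqrt(ncol), nrow, ncol)
}

# Parameter skeleton for a variant. p = raw feature count, d = latent dim.
# Output dimension is 2d for the concatenation variant, d otherwise.
tsn_init <- function(p, d, variant) {
  variant <- match.arg(variant, tsn_variants)
  out_dim <- if (variant == "baseline_ltm") 2L * d else d
  params <- list(A = init_mat(d, p), a = numeric(d))
  if (variant == "full") {
    params$w_d <- as.numeric(init_mat(1, d))
    params$b_d <- 0
  }
  if (variant %in% c("baseline_fm", "full")) {
    params$W_e <- init_mat(d, d)
    params$W_f <- init_mat(d, d)
    params$b_g <- numeric(d)
  }
  params$W_o <- init_mat(N_LEVELS, out_dim)
  params$b_o <- numeric(N_LEVELS)
  params
}

tsn_flatten <- function(params) unlist(params, use.names = FALSE)

tsn_relist <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    len <- length(skeleton[[nm]])
    piece <- vec[pos + seq_len(len)]
    if (is.matrix(skeleton[[nm]])) {
      dim(piece) <- dim(skeleton[[nm]])
    }
    out[[nm]] <- piece
    pos <- pos + len
  }
  out
}

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass for a batch.
#   XH: (n*T) x p history features (NULL for baseline), Xs: n x p short-term
# Returns activations needed for the backward pass; `probs` is n x 4.
tsn_forward <- function(params, XH, Xs, t_window, variant) {
  n <- nrow(Xs)
  d <- nrow(params$A)
  Es <- tanh(Xs %*% t(params$A) + rep(params$a, each = n))
  fwd <- list(n = n, Es = Es)
  use_hist <- variant != "baseline"
  if (use_hist) {
    T <- t_window
    E <- tanh(XH %*% t(params$A) + rep(params$a, each = n * T))
    if (variant == "full") {
      u <- as.numeric(E %*% params$w_d + params$b_d)
      I <- tanh(u)
      Im <- matrix(I, nrow = T)           # T x n, sample-major columns
      Im <- Im - rep(apply(Im, 2, max), each = T)
      eI <- exp(Im)
      alpha <- eI / rep(colSums(eI), each = T)
    } else {
      I <- NULL
      alpha <- matrix(1 / T, T, n)
    }
    w <- as.numeric(alpha)                # matches XH row order
    grp <- rep(seq_len(n), each = T)
    L <- rowsum(E * w, grp)
    fwd$E <- E; fwd$I <- I; fwd$alpha <- alpha; fwd$L <- L
  }
  P <- switch(variant,
    baseline = Es,
    baseline_ltm = cbind(Es, fwd$L),
    baseline_fm = ,
    full = {
      Z <- Es %*% t(params$W_e) + fwd$L %*% t(params$W_f) +
        rep(params$b_g, each = n)
      G <- sigmoid(Z)
      fwd$G <- G
      G * Es + (1 - G) * fwd$L
    })
  fwd$P <- P
  logits <- P %*% t(params$W_o) + rep(params$b_o, each = n)
  fwd$probs <- row_softmax(logits)
  fwd
}

#' Cross-entropy loss for four-level predictions
#'
#' Mean over the batch of `-log p[true level]`, with probabilities clamped
#' at `1e-12` before the log. Zero for perfect one-hot predictions,
#' `log(4)` for uniform ones.
#'
#' @param probs numeric matrix, one row per sample, rows on the simplex.
#' @param labels integer levels in 1--4.
#' @return Non-negative scalar.
#' @export
ce_loss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1) || any(labels > ncol(probs))) {
    stop("labels must be integers in 1..", ncol(probs))
  }
  p <- probs[cbind(seq_len(nrow(probs)), labels)]
  mean(-log(pmax(p, 1e-12)))
}

# Backward pass: gradients of the mean CE loss over the batch, same
# structure as `params`. `fwd` must come from tsn_forward on the same batch.
# `sample_weights` rescales each sample's loss contribution (class
# weighting); they are normalized to mean 1 by the caller.
tsn_backward <- function(params, fwd, XH, Xs, labels, t_window, variant,
                         sample_weights = NULL) {
  n <- fwd$n
  d <- nrow(params$A)
  Y <- matrix(0, n, N_LEVELS)
  Y[cbind(seq_len(n), as.integer(labels))] <- 1
  dlogits <- (fwd$probs - Y) / n
  if (!is.null(sample_weights)) dlogits <- dlogits * sample_weights
  g <- list(A = matrix(0, d, ncol(params$A)), a = numeric(d))
  g$W_o <- t(dlogits) %*% fwd$P
  g$b_o <- colSums(dlogits)
  dP <- dlogits %*% params$W_o
  dEs <- matrix(0, n, d)
  dL <- NULL
  if (variant == "baseline") {
    dEs <- dP
  } else if (variant == "baseline_ltm") {
    dEs <- dP[, seq_len(d), drop = FALSE]
    dL <- dP[, d + seq_len(d), drop = FALSE]
  } else {
    G <- fwd$G
    dG <- dP * (fwd$Es - fwd$L)
    dEs <- dP * G
    dL <- dP * (1 - G)
    dZ <- dG * G * (1 - G)
    g$W_e <- t(dZ) %*% fwd$Es
    g$W_f <- t(dZ) %*% fwd$L
    g$b_g <- colSums(dZ)
    dEs <- dEs + dZ %*% params$W_e
    dL <- dL + dZ %*% params$W_f
  }
  if (variant != "baseline") {
    T <- t_window
    idx <- rep(seq_len(n), each = T)
    alpha_v <- as.numeric(fwd$alpha)
    dE <- dL[idx, , drop = FALSE] * alpha_v
    if (variant == "full") {
      # through the attention weights
      dalpha_v <- rowSums(fwd$E * dL[idx, , drop = FALSE])
      dalpha <- matrix(dalpha_v, nrow = T)
      dot <- colSums(fwd$alpha * dalpha)
      dI <- fwd$alpha * (dalpha - rep(dot, each = T))
      du <- as.numeric(dI) * (1 - as.numeric(fwd$I)^2)
      g$w_d <- as.numeric(t(fwd$E) %*% du)
      g$b_d <- sum(du)
      dE <- dE + outer(du, params$w_d)
    }
    dpreH <- dE * (1 - fwd$E^2)
    g$A <- g$A + t(dpreH) %*% XH
    g$a <- g$a + colSums(dpreH)
  }
  dpreS <- dEs * (1 - fwd$Es^2)
  g$A <- g$A + t(dpreS) %*% Xs
  g$a <- g$a + colSums(dpreS)
  g[names(params)]
}

# Numerical gradient of the batch CE loss by central differences, for
# verification against the analytic backward pass.
tsn_numeric_grad <- function(params, XH, Xs, labels, t_window, variant,
                             h = 1e-5) {
  theta <- tsn_flatten(params)
  gn <- numeric(length(theta))
  for (i in seq_along(theta)) {
    for (s in c(1, -1)) {
      th <- theta
      th[i] <- th[i] + s * h
      p2 <- tsn_relist(th, params)
      fw <- tsn_forward(p2, XH, Xs, t_window, variant)
      gn[i] <- gn[i] + s * ce_loss(fw$probs, labels)
    }
  }
  gn / (2 * h)
}

#' Verify analytic gradients against finite differences
#'
#' Draws random small instances (parameters, inputs, labels), computes the
#' analytic gradient of the cross-entropy loss through the full forward
#' pass, and compares with central finite differences. A diagnostic for
#' the hand-derived backward pass; the maximum relative error should be
#' well below `1e-4`.
#'
#' @param n_draws number of random instances (default 50).
#' @param d latent dimension (default 3).
#' @param t_window history length in days (default 4).
#' @param n_features raw feature count (default 6).
#' @param batch samples per instance (default 2).
#' @param variant model variant, see [tsn()].
#' @param seed RNG seed.
#' @return Maximum relative gradient error over all draws and coordinates.
#' @export
tsn_gradient_check <- function(n_draws = 50, d = 3, t_window = 4,
                               n_features = 6, batch = 2,
                               variant = "full", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  worst <- 0
  for (r in seq_len(n_draws)) {
    params <- tsn_init(n_features, d, variant)
    # perturb away from the symmetric init
    params <- lapply(params, function(x) x + stats::rnorm(length(x), 0, 0.3))
    XH <- if (variant == "baseline") NULL else
      matrix(stats::rnorm(batch * t_window * n_features), ncol = n_features)
    Xs <- matrix(stats::rnorm(batch * n_features), ncol = n_features)
    y <- sample.int(N_LEVELS, batch, replace = TRUE)
    fwd <- tsn_forward(params, XH, Xs, t_window, variant)
    ga <- tsn_flatten(tsn_backward(params, fwd, XH, Xs, y, t_window, variant))
    gn <- tsn_numeric_grad(params, XH, Xs, y, t_window, variant)
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)
    worst <- max(worst, max(rel))
  }
  worst
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
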