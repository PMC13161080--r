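#' Jenks natural-breaks classification
#'
#' Exact optimal partition of a univariate sample into `k` contiguous
#' classes minimizing the within-class sum of squared deviations from class
#' means (SDCM), computed by dynamic programming over (index, class) with
#' prefix-sum evaluation of segment costs. Unlike quantile or equal-width
#' cuts, the breaks fall at "natural" gaps in the data distribution.
#' Goodness of variance fit is `gvf = 1 - SDCM/SDAM`, where SDAM is the
#' total sum of squared deviations.
#'
#' Ties in the optimum are broken toward the smaller upper class (the
#' latest feasible break index), so the result is deterministic.
#' Breakpoints are reported as midpoints between adjacent class boundary
#' values.
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes (default 3).
#' @param feature_name optional label carried into the model.
#' @param class_labels class names, low to high; defaults to
#'   Low/Medium/High for `k = 3`.
#' @return An object of class `"jenks_breaks"`: `breakpoints` (length
#'   `k - 1`, strictly ascending), `class_labels`, `gvf`, `sdam`, `sdcm`,
#'   and `sizes` (class sizes over the sorted sample).
#' @export
jenks_breaks <- function(values, k = 3, feature_name = NULL,
                         class_labels = NULL) {
  stopifnot(k >= 2)
  values <- values[!is.na(values)]
  if (length(unique(values)) < k) {
    stop(sprintf("need at least %d distinct values, got %d",
                 k, length(unique(values))))
  }
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # SSE of x[i..j] around its mean, via prefix sums
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    m <- j - i + 1
    max(s2 - s^2 / m, 0)
  }
  # dp[c, j] = min SDCM of x[1..j] split into c classes
  dp <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  for (cl in 2:k) {
    for (j in cl:n) {
      best <- Inf; arg <- 0L
      for (i in cl:j) {
        cost <- dp[cl - 1, i - 1] + sse(i, j)
        # >= : prefer the latest break (smaller upper class) on ties
        if (cost < best || (cost == best && i > arg)) {
          best <- cost; arg <- i
        }
      }
      dp[cl, j] <- best
      back[cl, j] <- arg
    }
  }
  bounds <- integer(k - 1)  # index of last element of each lower class
  j <- n
  for (cl in k:2) {
    i <- back[cl, j]
    bounds[cl - 1] <- i - 1L
    j <- i - 1L
  }
  sdcm <- dp[k, n]
  sdam <- sse(1, n)
  if (is.null(class_labels)) {
    class_labels <- if (k == 3) c("Low", "Medium", "High")
                    else paste0("C", seq_len(k))
  }
  stopifnot(length(class_labels) == k)
  structure(list(
    feature_name = feature_name,
    breakpoints = (x[bounds] + x[bounds + 1]) / 2,
    class_labels = class_labels,
    gvf = if (sdam > 0) 1 - sdcm / sdam else 1,
    sdam = sdam, sdcm = sdcm,
    sizes = diff(c(0L, bounds, n))
  ), class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("<jenks_breaks>%s k = %d, gvf = %.3f\n",
              if (is.null(x$feature_name)) "" else paste0(" ", x$feature_name),
              length(x$class_labels), x$gvf))
  cat("  breaks:", paste(signif(x$breakpoints, 5), collapse = ", "), "\n")
  cat("  sizes: ", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Assign values to Jenks classes
#'
#' A value equal to a breakpoint goes to the lower class (half-open
#' convention); values outside the fitted range fall into the nearest
#' extreme class.
#'
#' @param model a [jenks_breaks()] model.
#' @param values numeric vector.
#' @return Character vector of class labels.
#' @export
assign_class <- function(model, values) {
  idx <- findInterval(values, model$breakpoints, left.open = TRUE) + 1L
  model$class_labels[idx]
}
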