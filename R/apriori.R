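#' Discretize a student feature table into mining transactions
#'
#' Each student becomes one transaction of `"feature=Class"` items (one per
#' fitted feature) plus a single `"level=L"` label token taken from the
#' `level` column. Class assignment follows [assign_class()] (value at a
#' breakpoint goes to the lower class; out-of-range values to the nearest
#' extreme class).
#'
#' @param table data frame with one row per student, a `level` column
#'   (integer 1--4) and one numeric column per fitted feature.
#' @param models named list of [jenks_breaks()] models, names matching
#'   feature columns of `table`.
#' @return A list of character vectors (the transactions), one per row of
#'   `table`, with attribute `"student_id"` if the table has that column.
#' @export
discretize <- function(table, models) {
  stopifnot(is.data.frame(table), "level" %in% names(table))
  feats <- names(models)
  miss <- setdiff(feats, names(table))
  if (length(miss)) stop("table lacks feature column(s): ",
                         paste(miss, collapse = ", "))
  tx <- lapply(seq_len(nrow(table)), function(i) {
    items <- vapply(feats, function(f) {
      paste0(f, "=", assign_class(models[[f]], table[[f]][i]))
    }, "")
    c(unname(items), paste0("level=", table$level[i]))
  })
  if ("student_id" %in% names(table)) {
    attr(tx, "student_id") <- table$student_id
  }
  tx
}

support_count <- function(itemset, tx_sets) {
  sum(vapply(tx_sets, function(t) all(itemset %in% t), TRUE))
}

#' Apriori frequent-itemset mining
#'
#' Level-wise generation with candidate pruning by the downward-closure
#' property (every subset of a frequent itemset is frequent). Supports are
#' exact fractions of the transaction count.
#'
#' @param transactions list of character vectors (see [discretize()]).
#' @param min_support minimum support in `(0, 1]` (default 0.5).
#' @return Data frame with columns `items` (list column of sorted
#'   character vectors), `size`, `count`, `support`, ordered by size then
#'   lexicographically.
#' @export
apriori <- function(transactions, min_support = 0.5) {
  if (length(transactions) < 1) stop("need at least one transaction")
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  n <- length(transactions)
  tx_sets <- lapply(transactions, function(t) sort(unique(as.character(t))))
  universe <- sort(unique(unlist(tx_sets)))
  cnt1 <- vapply(universe, function(it)
    sum(vapply(tx_sets, function(t) it %in% t, TRUE)), 0L)
  keep <- cnt1 / n >= min_support
  freq <- lapply(universe[keep], function(it) it)
  counts <- cnt1[keep]
  all_items <- list()
  all_counts <- integer(0)
  level <- freq
  level_counts <- counts
  while (length(level)) {
    all_items <- c(all_items, level)
    all_counts <- c(all_counts, level_counts)
    # candidate generation: join sets sharing all but the last item
    k <- length(level[[1]])
    cand <- list()
    if (length(level) >= 2) {
      prefixes <- vapply(level, function(s)
        paste(s[-k], collapse = "\r"), "")
      for (grp in split(seq_along(level), prefixes)) {
        if (length(grp) < 2) next
        cmb <- utils::combn(grp, 2)
        for (j in seq_len(ncol(cmb))) {
          s <- sort(union(level[[cmb[1, j]]], level[[cmb[2, j]]]))
          cand[[length(cand) + 1]] <- s
        }
      }
    }
    if (!length(cand)) break
    cand <- unique(cand)
    # prune: every k-subset must be frequent
    level_keys <- vapply(level, paste, "", collapse = "\r")
    survives <- vapply(cand, function(s) {
      subs <- vapply(seq_along(s), function(i)
        paste(s[-i], collapse = "\r"), "")
      all(subs %in% level_keys)
    }, TRUE)
    cand <- cand[survives]
    if (!length(cand)) break
    cc <- vapply(cand, support_count, 0L, tx_sets = tx_sets)
    sel <- cc / n >= min_support
    level <- cand[sel]
    level_counts <- cc[sel]
  }
  ord <- order(lengths(all_items),
               vapply(all_items, paste, "", collapse = "\r"))
  data.frame(
    items = I(all_items[ord]),
    size = lengths(all_items)[ord],
    count = all_counts[ord],
    support = all_counts[ord] / n,
    stringsAsFactors = FALSE
  )
}

#' Association rules with label consequents
#'
#' From the frequent itemsets, emits rules `antecedent -> level token`
#' where the antecedent contains behavior items only and the consequent is
#' a single label token. Confidence is
#' `support(antecedent + consequent) / support(antecedent)` and lift is
#' `confidence / support(consequent)`. Rules are sorted by confidence then
#' support, descending, ties lexicographic by antecedent.
#'
#' @param frequent output of [apriori()].
#' @param min_confidence minimum confidence (default 0.5).
#' @param label_prefix prefix identifying label tokens (default
#'   `"level="`).
#' @return Data frame with columns `antecedent` (items joined by `" & "`),
#'   `consequent`, `support`, `confidence`, `lift`, `n_items`.
#' @export
generate_rules <- function(frequent, min_confidence = 0.5,
                           label_prefix = "level=") {
  key <- vapply(frequent$items, paste, "", collapse = "\r")
  sup <- stats::setNames(frequent$support, key)
  rows <- list()
  for (i in seq_len(nrow(frequent))) {
    s <- frequent$items[[i]]
    is_label <- startsWith(s, label_prefix)
    if (sum(is_label) != 1 || length(s) < 2) next
    consequent <- s[is_label]
    antecedent <- s[!is_label]
    a_key <- paste(antecedent, collapse = "\r")
    if (!a_key %in% key) next  # cannot happen by downward closure
    conf <- frequent$support[i] / sup[[a_key]]
    if (conf < min_confidence) next
    c_sup <- sup[[consequent]]
    rows[[length(rows) + 1]] <- data.frame(
      antecedent = paste(antecedent, collapse = " & "),
      consequent = consequent,
      support = frequent$support[i],
      confidence = unname(conf),
      lift = unname(if (!is.null(c_sup)) conf / c_sup
                    else NA_real_),
      n_items = length(antecedent),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0), n_items = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$confidence, -out$support, out$antecedent), , drop = FALSE]
}

#' Shortlist behavioral features backed by strong rules
#'
#' Features appearing in any surviving rule's antecedent, ranked by the
#' best confidence among rules containing them. The shortlist is advisory
#' metadata for model configuration (which features to carry into the
#' temporal network). An empty rule set retains all features with a
#' warning.
#'
#' @param rules output of [generate_rules()].
#' @param all_features character vector of the full feature universe.
#' @return Data frame `feature`, `best_confidence`, ranked; all features
#'   with `NA` confidence if no rules survive.
#' @export
select_features <- function(rules, all_features) {
  if (nrow(rules) == 0) {
    warning("no association rules survive; retaining all features")
    return(data.frame(feature = all_features,
                      best_confidence = NA_real_,
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(rules$antecedent, " & ", fixed = TRUE)
  feat <- lapply(toks, function(t) sub("=.*$", "", t))
  df <- data.frame(feature = unlist(feat),
                   confidence = rep(rules$confidence, lengths(feat)),
                   stringsAsFactors = FALSE)
  best <- tapply(df$confidence, df$feature, max)
  out <- data.frame(feature = names(best),
                    best_confidence = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$best_confidence, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
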