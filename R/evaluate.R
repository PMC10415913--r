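# ---- nearest shrunken centroid (PAM-style) classifier -----------------------

# Train on X (samples x features), y (factor, 2+ classes).  delta is the
# soft-thresholding amount applied to the standardized centroid deviations.
nsc_train <- function(X, y, delta = 0) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  n <- nrow(X); p <- ncol(X)
  nk <- table(y)
  overall <- colMeans(X)
  cent <- matrix(0, length(classes), p)
  for (k in seq_along(classes))
    cent[k, ] <- colMeans(X[y == classes[k], , drop = FALSE])
  # pooled within-class sd per feature
  ss <- numeric(p)
  for (cl in classes) {
    Xi <- X[y == cl, , drop = FALSE]
    ss <- ss + colSums(sweep(Xi, 2L, colMeans(Xi))^2)
  }
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  dev <- sweep(cent, 2L, overall) / outer(mk, s + s0)
  dev_shr <- sign(dev) * pmax(abs(dev) - delta, 0)
  cent_shr <- sweep(outer(mk, s + s0) * dev_shr, 2L, overall, "+")
  list(classes = classes, centroids = cent_shr, s = s, s0 = s0,
       prior = as.numeric(nk) / n, delta = delta,
       max_dev = max(abs(dev)))
}

# Class posteriors from the shrunken-centroid discriminant scores.
nsc_predict <- function(fit, X) {
  disc <- vapply(seq_along(fit$classes), function(k) {
    rowSums(sweep(X, 2L, fit$centroids[k, ])^2 / rep((fit$s + fit$s0)^2, each = nrow(X))) -
      2 * log(fit$prior[k])
  }, numeric(nrow(X)))
  disc <- matrix(disc, nrow = nrow(X))
  post <- exp(-0.5 * (disc - apply(disc, 1L, min)))
  post <- post / rowSums(post)
  colnames(post) <- fit$classes
  list(class = fit$classes[max.col(-disc, ties.method = "first")],
       posterior = post)
}

# Pick the shrinkage delta by inner stratified CV on the training set:
# smallest error, ties resolved towards more shrinkage.
nsc_select_delta <- function(X, y, n_delta = 8L, inner_folds = 3L) {
  probe <- nsc_train(X, y, delta = 0)
  deltas <- seq(0, probe$max_dev, length.out = n_delta)
  folds <- stratified_folds(y, min(inner_folds, min(table(y))))
  err <- vapply(deltas, function(d) {
    mistakes <- 0L
    for (f in unique(folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      fit <- nsc_train(X[tr, , drop = FALSE], y[tr], delta = d)
      pred <- nsc_predict(fit, X[!tr, , drop = FALSE])$class
      mistakes <- mistakes + sum(pred != y[!tr])
    }
    mistakes
  }, numeric(1))
  deltas[max(which(err == min(err)))]
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so class ratios stay within one sample per fold.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Rank-based AUC of scores for the positive class.
auc_score <- function(scores, truth_pos) {
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated classification performance of one rule's gene signature
#'
#' The rule's participating genes (antecedent and consequent together,
#' signs stripped) define the feature set; a nearest-shrunken-centroid
#' classifier with internally cross-validated shrinkage is evaluated by
#' stratified k-fold cross-validation, repeated `repeats` times.  Accuracy,
#' sensitivity (case class) and specificity are pooled over the folds of
#' each repeat and averaged across repeats; the AUC pools the case
#' posterior scores across all folds and repeats.
#'
#' @param omics `paired_omics` (expression features; methylation can be
#'   appended with `use_methylation = TRUE`).
#' @param rule_items character vector of the rule's directional items, or a
#'   single rule string like `"A+, B- -> C+"`.
#' @param folds number of CV folds (default 10; capped at the smaller class
#'   size).
#' @param repeats repeated CV rounds (default 10).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param use_methylation also include the genes' methylation rows as
#'   features.
#' @return one-row data.frame: `accuracy`, `accuracy_sd`, `sensitivity`,
#'   `sensitivity_sd`, `specificity`, `specificity_sd`, `auc`,
#'   `std_err_rate` (SD of the per-repeat overall error rate).
#' @export
evaluate_rule <- function(omics, rule_items, folds = 10L, repeats = 10L,
                          seed = 1L, use_methylation = FALSE) {
  if (length(rule_items) == 1L && grepl("->", rule_items, fixed = TRUE))
    rule_items <- trimws(strsplit(gsub("->", ",", rule_items, fixed = TRUE),
                                  ",", fixed = TRUE)[[1L]])
  genes <- unique(item_genes(rule_items))
  missing <- setdiff(genes, omics$gene_ids)
  if (length(missing))
    stopf("rule gene(s) not present in the data: %s",
          paste(missing, collapse = ", "))
  X <- t(omics$expression[genes, , drop = FALSE])
  if (use_methylation)
    X <- cbind(X, t(omics$methylation[genes, , drop = FALSE]))
  y <- factor(omics$labels, levels = c(0L, 1L))
  k <- min(folds, min(table(y)))
  if (k < 2L) stopf("need at least 2 samples per class for cross-validation")

  with_seed(seed, {
    acc <- sens <- spec <- err <- numeric(repeats)
    pooled_scores <- numeric(0); pooled_truth <- logical(0)
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, k)
      pred <- character(length(y))
      score <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        delta <- nsc_select_delta(X[tr, , drop = FALSE], y[tr])
        fit <- nsc_train(X[tr, , drop = FALSE], y[tr], delta = delta)
        pr <- nsc_predict(fit, X[!tr, , drop = FALSE])
        pred[!tr] <- pr$class
        score[!tr] <- pr$posterior[, "1"]
      }
      pos <- y == "1"
      acc[r] <- mean(pred == as.character(y))
      sens[r] <- mean(pred[pos] == "1")
      spec[r] <- mean(pred[!pos] == "0")
      err[r] <- 1 - acc[r]
      pooled_scores <- c(pooled_scores, score)
      pooled_truth <- c(pooled_truth, pos)
    }
    data.frame(accuracy = mean(acc), accuracy_sd = stats::sd(acc),
               sensitivity = mean(sens), sensitivity_sd = stats::sd(sens),
               specificity = mean(spec), specificity_sd = stats::sd(spec),
               auc = auc_score(pooled_scores, pooled_truth),
               std_err_rate = stats::sd(err))
  })
}

#' ROC curve points for one rule's pooled cross-validation scores
#'
#' Also reports the optimal operating point by Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores case-class scores.
#' @param truth_pos logical vector, TRUE for case samples.
#' @return data.frame `threshold`, `sensitivity`, `specificity` with
#'   attribute `youden` (the optimal row).
#' @export
roc_points <- function(scores, truth_pos) {
  thr <- sort(unique(c(-Inf, scores, Inf)))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(sensitivity = mean(pred[truth_pos]),
      specificity = mean(!pred[!truth_pos]))
  }, numeric(2)))
  out <- data.frame(threshold = thr, pts)
  j <- out$sensitivity + out$specificity - 1
  attr(out, "youden") <- out[which.max(j), ]
  out
}

#' Column-wise summary of per-rule evaluation metrics
#'
#' Arithmetic mean of every numeric metric column, rounded half away from
#' zero to `digits` decimal places (the convention of printed summary
#' rows).
#'
#' @param metrics data.frame of per-rule metric rows.
#' @param digits named or unnamed rounding digits per column (single value
#'   recycled); `NULL` skips rounding.
#' @return one-row data.frame of column means.
#' @export
summarize_rules <- function(metrics, digits = NULL) {
  num <- vapply(metrics, is.numeric, logical(1))
  if (!any(num)) stopf("no numeric metric columns to summarize")
  means <- colMeans(metrics[, num, drop = FALSE])
  if (!is.null(digits)) {
    d <- if (is.null(names(digits))) rep_len(digits, length(means))
         else unname(digits[names(means)])
    sel <- !is.na(d)
    means[sel] <- round_half_up(means[sel], d[sel])
  }
  as.data.frame(as.list(means))
}
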