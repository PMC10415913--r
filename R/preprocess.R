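#' Paired expression/methylation container
#'
#' Holds matched gene-by-sample expression and methylation matrices with a
#' shared gene ordering, shared sample ordering and a binary group label per
#' sample.
#'
#' @param expression,methylation numeric matrices with identical dimnames.
#' @param labels named binary vector (0/1) covering every sample.
#' @return object of class `paired_omics`.
#' @export
paired_omics <- function(expression, methylation, labels) {
  if (!identical(dimnames(expression), dimnames(methylation)))
    stopf("expression and methylation must share gene and sample orderings")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stopf("matrices need gene rownames and sample colnames")
  if (!all(colnames(expression) %in% names(labels)))
    stopf("labels missing for some samples")
  labels <- labels[colnames(expression)]
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  structure(list(gene_ids = rownames(expression),
                 sample_ids = colnames(expression),
                 expression = expression,
                 methylation = methylation,
                 labels = labels),
            class = "paired_omics")
}

#' @export
print.paired_omics <- function(x, ...) {
  cat(sprintf("paired_omics: %d genes x %d samples (%d cases / %d controls)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Match genes and samples across the two omics layers
#'
#' Restricts both matrices to the intersection of their gene IDs and of
#' their sample IDs, with IDs sorted lexicographically so the result does
#' not depend on input order.
#'
#' @param expr,meth gene-by-sample matrices (rownames = genes/probes,
#'   colnames = samples).
#' @param labels named binary group vector; samples without a label are
#'   dropped from the intersection.
#' @return a [paired_omics()] object.
#' @export
match_omics <- function(expr, meth, labels) {
  genes <- sort(intersect(rownames(expr), rownames(meth)))
  samples <- sort(intersect(intersect(colnames(expr), colnames(meth)),
                            names(labels)))
  if (length(genes) == 0L || length(samples) == 0L)
    stopf("no matched genes/samples between the two omics layers")
  paired_omics(expr[genes, samples, drop = FALSE],
               meth[genes, samples, drop = FALSE],
               labels[samples])
}

#' Gene-wise zero-mean normalization
#'
#' Subtracts each row's mean so every gene is centred at zero across
#' samples; row variances are unchanged.  Constant rows become all zeros.
#'
#' @param m numeric matrix.
#' @return matrix with every row mean 0 (|mean| < 1e-9).
#' @export
zero_mean_normalize <- function(m) {
  if (!all(is.finite(m))) stopf("zero_mean_normalize: matrix has non-finite values")
  m - rowMeans(m)
}

# limma-style hyperparameter fit: method of moments on log sample variances.
# Returns the prior df d0 and prior variance s0^2 for s^2 ~ scaled F.
fit_variance_prior <- function(s2, df) {
  s2 <- pmax(s2[is.finite(s2)], 0)
  if (length(s2) < 2L)
    return(list(d0 = Inf, s02 = max(mean(s2), .Machine$double.eps)))
  m <- stats::median(s2)
  if (m == 0) m <- 1
  s2 <- pmax(s2, 1e-5 * m)  # keep log() finite for zero-variance rows
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) return(list(d0 = Inf, s02 = mean(s2)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton solve trigamma(x) = y.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per-row pooled-variance contrast between the two label groups with the
#' row variances shrunk towards a common prior fitted by method of moments
#' on the log sample variances: the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t carries `d + d0`
#' degrees of freedom.  P-values are Benjamini-Hochberg adjusted across
#' probes.  Probes containing missing values are dropped before testing.
#'
#' @param m probe-by-sample matrix (rownames = probe IDs).
#' @param labels binary vector/named vector aligned with columns; the effect
#'   is mean(group 1) - mean(group 0).
#' @param genes optional probe-to-gene map (character, same length/order as
#'   rows); defaults to the probe IDs themselves.
#' @return data.frame of class `diff_test` with columns `probe`, `gene`,
#'   `effect`, `t`, `p`, `adj_p`, plus attributes `d0`, `s02`.
#' @export
moderated_t_test <- function(m, labels, genes = rownames(m)) {
  if (is.null(rownames(m))) stopf("matrix needs probe rownames")
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  g1 <- labels == 1L; g0 <- labels == 0L
  if (sum(g1) < 2L || sum(g0) < 2L)
    stopf("each group needs at least 2 samples (got %d/%d)", sum(g1), sum(g0))

  keep <- rowSums(!is.finite(m)) == 0L
  if (!all(keep)) {
    warning(sprintf("dropping %d probe(s) with missing values", sum(!keep)))
    m <- m[keep, , drop = FALSE]; genes <- genes[keep]
  }
  if (nrow(m) == 0L) stopf("no probes left after missing-value filtering")

  n1 <- sum(g1); n0 <- sum(g0); d <- n1 + n0 - 2L
  m1 <- rowMeans(m[, g1, drop = FALSE]); m0 <- rowMeans(m[, g0, drop = FALSE])
  v1 <- apply(m[, g1, drop = FALSE], 1L, stats::var)
  v0 <- apply(m[, g0, drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / d

  prior <- fit_variance_prior(s2, d)
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  tstat <- ifelse(se > 0, (m1 - m0) / se, 0)
  # total df capped at the summed residual df across probes (prior df can
  # be infinite when the log-variance spread is sub-theoretical)
  df_total <- min(d + d0, d * nrow(m))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(probe = rownames(m), gene = genes,
                    effect = m1 - m0, t = tstat, p = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  class(res) <- c("diff_test", "data.frame")
  res
}

#' Keep one probe per gene: the smallest adjusted p-value
#'
#' Ties are broken by the lexicographically smallest probe ID so the
#' selection is deterministic.
#'
#' @param result a `diff_test` data.frame from [moderated_t_test()].
#' @return `diff_test` with exactly one row per gene, ordered by gene ID.
#' @export
collapse_probes <- function(result) {
  ord <- order(result$gene, result$adj_p, result$probe)
  res <- result[ord, , drop = FALSE]
  res <- res[!duplicated(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("diff_test", "data.frame")
  res
}

#' Genes significant in both omics layers and present in the PPI universe
#'
#' @param expr_result,meth_result per-gene `diff_test` tables (after
#'   [collapse_probes()]).
#' @param ppi_genes character vector of genes present in the PPI graph.
#' @param alpha significance cutoff on the BH-adjusted p-value (strict
#'   `adj_p < alpha`).
#' @return sorted character vector of gene IDs; empty (with a warning) when
#'   nothing passes.
#' @export
select_significant_intersection <- function(expr_result, meth_result,
                                            ppi_genes, alpha = 0.05) {
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  sig_e <- expr_result$gene[expr_result$adj_p < alpha]
  sig_m <- meth_result$gene[meth_result$adj_p < alpha]
  out <- sort(intersect(intersect(sig_e, sig_m), ppi_genes))
  if (length(out) == 0L)
    warning("no genes significant in both omics and present in the PPI graph")
  out
}
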