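#' Discretize zero-mean expression data
#'
#' A value above 0 is up-regulation (1), below 0 down-regulation (0).
#' Values exactly 0 (constant rows after centring) map to 0 so they never
#' create items.
#'
#' @param m zero-mean normalized expression matrix.
#' @return binary matrix of the same shape.
#' @export
discretize_expression <- function(m) {
  (m > 0) + 0L
}

#' Discretize zero-mean methylation data
#'
#' The coding is inverted relative to expression: a value below 0 is
#' hypo-methylation (1, permissive for expression), above 0
#' hyper-methylation (0).  Exact zeros map to 0.
#'
#' @param m zero-mean normalized methylation matrix.
#' @return binary matrix of the same shape.
#' @export
discretize_methylation <- function(m) {
  (m < 0) + 0L
}

#' Merge discretized omics into the post-discretized sample-by-item matrix
#'
#' The two transposed binary matrices are combined into one sample x (2n)
#' matrix: column i (first half) is item `<gene_i>+`, set when a gene is
#' up-regulated AND hypo-methylated in that sample; column i+n (second half)
#' is `<gene_i>-`, set when down-regulated AND hyper-methylated.  Discordant
#' states (up/hyper, down/hypo) set neither, so a gene never contributes
#' both its "+" and "-" item in one sample.
#'
#' @param ddie,ddim binary gene-by-sample matrices from
#'   [discretize_expression()] / [discretize_methylation()].
#' @return list with `pdid` (m x 2n binary matrix) and `item_ids`.
#' @export
post_discretize <- function(ddie, ddim) {
  if (!identical(dim(ddie), dim(ddim)) ||
      !identical(dimnames(ddie), dimnames(ddim)))
    stopf("discretized matrices must have identical dimensions and dimnames")
  te <- t(ddie)  # samples x genes
  tm <- t(ddim)
  plus <- (te == 1L & tm == 1L) + 0L
  minus <- (te == 0L & tm == 0L) + 0L
  item_ids <- c(paste0(rownames(ddie), "+"), paste0(rownames(ddie), "-"))
  pdid <- cbind(plus, minus)
  colnames(pdid) <- item_ids
  list(pdid = pdid, item_ids = item_ids)
}

#' Convert the post-discretized matrix into a transaction database
#'
#' One transaction per sample holding the item IDs set in that sample's
#' row.  Empty transactions are retained: they count in the transaction
#' total and therefore in every support denominator.
#'
#' @param pd result of [post_discretize()].
#' @return object of class `transaction_db`: `transactions` (named list of
#'   character vectors) and `n_transactions`.
#' @export
to_transactions <- function(pd) {
  tx <- apply(pd$pdid, 1L, function(r) pd$item_ids[r == 1L], simplify = FALSE)
  structure(list(transactions = tx, n_transactions = length(tx)),
            class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("transaction_db: %d transactions, %d distinct items\n",
              x$n_transactions, length(unique(unlist(x$transactions)))))
  invisible(x)
}
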