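# Independent oracles used across the suite.  These deliberately share no
# code with the implementation: enumeration, triple-loop dynamic
# programming, and direct formula transcription only.

# Exhaustive frequent-itemset enumeration over the powerset (Apriori-style
# reference; only usable for small item universes).
oracle_frequent_sets <- function(transactions, min_support, max_size = 4L) {
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (size in seq_len(min(max_size, length(items)))) {
    combos <- utils::combn(items, size, simplify = FALSE)
    for (set in combos) {
      cnt <- sum(vapply(transactions, function(t) all(set %in% t), logical(1)))
      if (cnt / n >= min_support - 1e-12)
        out[[length(out) + 1L]] <- list(items = set, support = cnt / n)
    }
  }
  out
}

oracle_support <- function(transactions, set) {
  mean(vapply(transactions, function(t) all(set %in% t), logical(1)))
}

# Floyd-Warshall all-pairs shortest paths on a symmetric weight matrix
# (Inf = no edge).
oracle_floyd_warshall <- function(adj) {
  d <- adj
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# Brute-force Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Random transaction database over items a, b, c, ...
random_db <- function(n_items, n_transactions, p_item = 0.4) {
  items <- letters[seq_len(n_items)]
  tx <- lapply(seq_len(n_transactions), function(i)
    items[stats::runif(n_items) < p_item])
  names(tx) <- paste0("s", seq_len(n_transactions))
  structure(list(transactions = tx, n_transactions = n_transactions),
            class = "transaction_db")
}

# Canonical string form for itemset lists, for set comparison.
set_keys <- function(sets, supports) {
  keys <- vapply(seq_along(sets), function(i)
    sprintf("%s=%.10f", paste(sort(sets[[i]]), collapse = ","), supports[i]), "")
  sort(keys)
}

# Tiny deterministic paired-omics object for unit tests.
tiny_omics <- function(n_genes = 6, n_per_group = 5, seed = 42, shift = 3) {
  withr::with_seed(seed, {
    m <- 2 * n_per_group
    genes <- paste0("g", seq_len(n_genes))
    samples <- paste0("s", seq_len(m))
    labels <- stats::setNames(rep(c(1L, 0L), each = n_per_group), samples)
    expr <- matrix(rnorm(n_genes * m), n_genes, m, dimnames = list(genes, samples))
    meth <- matrix(rnorm(n_genes * m), n_genes, m, dimnames = list(genes, samples))
    expr[1:2, labels == 1L] <- expr[1:2, labels == 1L] + shift
    meth[1:2, labels == 1L] <- meth[1:2, labels == 1L] - shift
    paired_omics(expr, meth, labels)
  })
}
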