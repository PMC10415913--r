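#' Per-item support, filtered and ordered for mining
#'
#' Supports are fractions of the transaction total (empty transactions
#' included).  Items below `min_support` are dropped; survivors are ordered
#' by descending support with ties broken lexicographically -- the ordering
#' used to build the gene-set tree.
#'
#' @param db `transaction_db`.
#' @param min_support minimum support as a fraction of transactions
#'   (default 0 = keep everything).
#' @return named numeric vector of supports.
#' @export
item_frequencies <- function(db, min_support = 0) {
  if (db$n_transactions == 0L) stopf("empty transaction database")
  counts <- table(unlist(db$transactions))
  supp <- as.numeric(counts) / db$n_transactions
  names(supp) <- names(counts)
  supp <- supp[supp >= min_support - 1e-12]
  supp[order(-supp, names(supp))]
}

#' Mine all frequent directional gene sets with FP-growth
#'
#' Pattern growth over conditional databases (the conditional-pattern-base
#' form of FP-growth on the gene-set tree): items are ordered by descending
#' support, and each item's conditional database -- its prefix paths -- is
#' mined recursively.  Every itemset of size 1..`max_size` whose support is
#' at least `min_support` is returned with its exact support.
#'
#' @param db `transaction_db`.
#' @param min_support minimum support; a fraction of the transaction count
#'   by default, or an absolute count when `count_based = TRUE`.
#' @param max_size largest itemset size to enumerate (default 4).
#' @param count_based interpret `min_support` as an absolute transaction
#'   count.
#' @return data.frame of class `gene_sets` with list-column `items`
#'   (sorted item IDs), `support`, `count` and `size`.
#' @export
mine_frequent <- function(db, min_support, max_size = 4L, count_based = FALSE) {
  check_count(max_size, "max_size", min = 1L)
  n <- db$n_transactions
  if (n == 0L) stopf("empty transaction database")
  min_count <- if (count_based) min_support else min_support * n
  min_count <- max(min_count, 1e-9) - 1e-9

  supp <- item_frequencies(db)
  freq_items <- names(supp)[supp * n >= min_count]
  empty <- data.frame(support = numeric(0), count = numeric(0), size = integer(0))
  if (length(freq_items) == 0L) {
    empty$items <- list(); class(empty) <- c("gene_sets", "data.frame")
    return(empty[, c("items", "support", "count", "size")])
  }
  # recode to ranks: 1 = most frequent; transactions become ascending rank vectors
  rank_of <- stats::setNames(seq_along(freq_items), freq_items)
  tx <- lapply(db$transactions, function(t) {
    r <- rank_of[t[t %in% freq_items]]
    sort(unname(r))
  })
  tx <- tx[lengths(tx) > 0L]

  acc <- new.env(parent = emptyenv())
  acc$sets <- list(); acc$counts <- list()
  mine_rec <- function(tx, wt, suffix) {
    u <- unlist(tx, use.names = FALSE)
    if (length(u) == 0L) return(invisible())
    w <- rep.int(wt, lengths(tx))
    cnt <- vapply(split(w, u), sum, numeric(1))
    its <- as.integer(names(cnt))
    keep <- cnt >= min_count
    its <- its[keep]; cnt <- cnt[keep]
    for (k in seq_along(its)) {
      it <- its[k]
      acc$sets[[length(acc$sets) + 1L]] <- c(it, suffix)
      acc$counts[[length(acc$counts) + 1L]] <- cnt[k]
      if (length(suffix) + 1L < max_size) {
        has <- vapply(tx, function(t) any(t == it), logical(1))
        cond <- lapply(tx[has], function(t) t[t < it])
        nz <- lengths(cond) > 0L
        if (any(nz))
          mine_rec(cond[nz], wt[has][nz], c(it, suffix))
      }
    }
    invisible()
  }
  mine_rec(tx, rep.int(1, length(tx)), integer(0))

  counts <- unlist(acc$counts)
  sets <- lapply(acc$sets, function(s) sort(freq_items[s]))
  out <- data.frame(support = counts / n, count = counts,
                    size = lengths(sets))
  out$items <- sets
  out <- out[, c("items", "support", "count", "size")]
  out <- out[order(out$size, vapply(out$items, paste, "", collapse = ",")), ]
  rownames(out) <- NULL
  class(out) <- c("gene_sets", "data.frame")
  out
}

#' Filter gene sets by their dynamic support threshold
#'
#' Keeps the sets whose support is at least their own distance-derived
#' threshold (mean pairwise threshold over the set's genes) instead of the
#' static user cutoff.  Each surviving record carries its threshold in
#' column `dbvs`.
#'
#' @param sets `gene_sets` from [mine_frequent()].
#' @param wv_msc pairwise support-threshold matrix from
#'   [wv_threshold_matrix()].
#' @param uvmin_s user minimum support (singleton fallback).
#' @return filtered `gene_sets` with a `dbvs` column.
#' @export
filter_by_dbvs <- function(sets, wv_msc, uvmin_s) {
  if (nrow(sets) == 0L) {
    sets$dbvs <- numeric(0)
    return(sets)
  }
  dbvs <- vapply(sets$items, dbv_threshold, numeric(1),
                 wv = wv_msc, uvmin = uvmin_s)
  out <- sets[sets$support >= dbvs - 1e-12, , drop = FALSE]
  out$dbvs <- dbvs[sets$support >= dbvs - 1e-12]
  rownames(out) <- NULL
  class(out) <- c("gene_sets", "data.frame")
  out
}

#' Generate rules from frequent gene sets under dynamic confidence/lift cutoffs
#'
#' Every non-empty antecedent/consequent bipartition of every surviving set
#' of size >= 2 is evaluated (multi-item consequents included).  A rule is
#' kept iff its confidence reaches the set's dynamic confidence threshold
#' AND its lift reaches the set's dynamic lift threshold.  Confidence is
#' `support(A u B) / support(A)`, lift is `confidence / support(B)`.
#'
#' @param sets `gene_sets` surviving [filter_by_dbvs()] (must carry `dbvs`).
#' @param all_sets the unfiltered [mine_frequent()] output, used to look up
#'   subset supports (every subset of a frequent set is frequent).
#' @param wv_mcc,wv_mlc pairwise confidence/lift threshold matrices.
#' @param uvmin_c,ud_min_l user minimum confidence and lift (singleton
#'   fallbacks for the per-set thresholds).
#' @param wesd distance matrix for the average-distance criterion; `NULL`
#'   sets `avg_wesd` to `NA`.
#' @return data.frame of class `rule_set`: `antecedent`/`consequent`
#'   list-columns, `rule` string, `support`, `confidence`, `lift`,
#'   `avg_wesd`, `dbvs`, `dbvc`, `dbvl`.
#' @export
generate_rules <- function(sets, all_sets, wv_mcc, wv_mlc,
                           uvmin_c, ud_min_l = 1, wesd = NULL) {
  supp_env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(all_sets)))
    assign(itemset_key(all_sets$items[[i]]), all_sets$support[i], envir = supp_env)
  lookup <- function(items) {
    key <- itemset_key(items)
    if (!exists(key, envir = supp_env, inherits = FALSE))
      stopf("internal: subset %s of a frequent set is missing from the lattice",
            paste(items, collapse = ","))
    get(key, envir = supp_env, inherits = FALSE)
  }

  rows <- list()
  cand <- sets[sets$size >= 2L, , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    items <- cand$items[[i]]
    s_all <- cand$support[i]
    dbvc <- dbv_threshold(items, wv_mcc, uvmin_c)
    dbvl <- dbv_threshold(items, wv_mlc, ud_min_l)
    aw <- if (is.null(wesd)) NA_real_ else
      suppressWarnings(avg_wesd(items, wesd))
    k <- length(items)
    for (mask in seq_len(2L^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)))
      A <- items[sel]; B <- items[!sel]
      conf <- s_all / lookup(A)
      lift <- conf / lookup(B)
      if (conf >= dbvc - 1e-12 && lift >= dbvl - 1e-12) {
        rows[[length(rows) + 1L]] <- list(
          antecedent = A, consequent = B, support = s_all,
          confidence = conf, lift = lift, avg_wesd = aw,
          dbvs = cand$dbvs[i], dbvc = dbvc, dbvl = dbvl)
      }
    }
  }
  out <- data.frame(
    rule = vapply(rows, function(r) rule_string(r$antecedent, r$consequent), ""),
    support = vapply(rows, `[[`, numeric(1), "support"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    lift = vapply(rows, `[[`, numeric(1), "lift"),
    avg_wesd = vapply(rows, `[[`, numeric(1), "avg_wesd"),
    dbvs = vapply(rows, `[[`, numeric(1), "dbvs"),
    dbvc = vapply(rows, `[[`, numeric(1), "dbvc"),
    dbvl = vapply(rows, `[[`, numeric(1), "dbvl"),
    stringsAsFactors = FALSE)
  out$antecedent <- lapply(rows, `[[`, "antecedent")
  out$consequent <- lapply(rows, `[[`, "consequent")
  out <- out[, c("rule", "antecedent", "consequent", "support", "confidence",
                 "lift", "avg_wesd", "dbvs", "dbvc", "dbvl")]
  rownames(out) <- NULL
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Write mined rules as TSV (and optionally JSON)
#' @param rules `rule_set` data.frame.
#' @param path output TSV path.
#' @param json_path optional JSON path.
#' @export
write_rules <- function(rules, path, json_path = NULL) {
  flat <- rules
  flat$antecedent <- vapply(rules$antecedent, paste, "", collapse = ",")
  flat$consequent <- vapply(rules$consequent, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
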