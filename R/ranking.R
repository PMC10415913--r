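#' Build the TOPSIS decision matrix from mined rules
#'
#' Rows are rules, columns the four criteria: support, confidence and lift
#' (benefit criteria, to maximize) and the average network distance
#' (cost criterion, to minimize).  No normalization is applied by default
#' -- the matrix holds the raw metric values; min-max (every column spans
#' \[0,1\]) and vector (unit Euclidean column norm) normalization are
#' available.  Optional criterion weights multiply the (normalized)
#' columns.
#'
#' @param rules `rule_set` data.frame with `support`, `confidence`, `lift`
#'   and `avg_wesd` columns.
#' @param normalization one of `"none"`, `"minmax"`, `"vector"`.
#' @param weights numeric length-4 weight vector (default equal).
#' @return object of class `decision_matrix`: `values` (n x 4 matrix),
#'   `benefit` (logical per criterion), `rules` (the input rows).
#' @export
build_decision_matrix <- function(rules, normalization = c("none", "minmax", "vector"),
                                  weights = rep(1, 4)) {
  normalization <- match.arg(normalization)
  if (nrow(rules) == 0L) stopf("empty rule list")
  if (length(weights) != 4L || any(weights <= 0)) stopf("need 4 positive weights")
  v <- cbind(support = rules$support, confidence = rules$confidence,
             lift = rules$lift, avg_wesd = rules$avg_wesd)
  if (any(!is.finite(v))) stopf("decision matrix has missing cells")
  if (normalization == "minmax") {
    rng <- apply(v, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    v <- sweep(sweep(v, 2L, rng[1L, ]), 2L, span, "/")
  } else if (normalization == "vector") {
    nrm <- sqrt(colSums(v^2))
    nrm[nrm == 0] <- 1
    v <- sweep(v, 2L, nrm, "/")
  }
  v <- sweep(v, 2L, weights, "*")
  structure(list(values = v,
                 benefit = c(support = TRUE, confidence = TRUE,
                             lift = TRUE, avg_wesd = FALSE),
                 rules = rules,
                 normalization = normalization,
                 weights = weights),
            class = "decision_matrix")
}

#' Positive and negative ideal solutions
#'
#' The positive ideal solution takes the column maximum on benefit criteria
#' and the column minimum on cost criteria; the negative ideal solution the
#' reverse.
#'
#' @param dm `decision_matrix`.
#' @return list with numeric vectors `pis` and `nis`.
#' @export
pis_nis <- function(dm) {
  hi <- apply(dm$values, 2L, max)
  lo <- apply(dm$values, 2L, min)
  list(pis = ifelse(dm$benefit, hi, lo),
       nis = ifelse(dm$benefit, lo, hi))
}

#' Distances of every rule from the ideal solutions
#'
#' City-block by default: `d+ = sum_j |pis_j - p_ij|`,
#' `d- = sum_j |p_ij - nis_j|` (absolute differences keep the distances
#' non-negative for cost criteria); Euclidean available.
#'
#' @param dm `decision_matrix`.
#' @param pis,nis vectors from [pis_nis()].
#' @param distance `"cityblock"` (default) or `"euclidean"`.
#' @return list with vectors `d_plus`, `d_minus`.
#' @export
topsis_distances <- function(dm, pis, nis,
                             distance = c("cityblock", "euclidean")) {
  distance <- match.arg(distance)
  dp <- abs(sweep(-dm$values, 2L, pis, "+"))
  dn <- abs(sweep(dm$values, 2L, nis, "-"))
  if (distance == "cityblock") {
    list(d_plus = rowSums(dp), d_minus = rowSums(dn))
  } else {
    list(d_plus = sqrt(rowSums(dp^2)), d_minus = sqrt(rowSums(dn^2)))
  }
}

#' Relative closeness to the positive ideal solution
#'
#' Classical orientation (default): `S = d- / (d+ + d-)`, so S near 1 means
#' close to the positive ideal.  The `"literal"` orientation puts `d+` in
#' the numerator instead.  Rules where `d+ + d- = 0` (the decision matrix
#' is constant in every criterion) get `S = 0.5` with a warning.
#'
#' @param d_plus,d_minus vectors from [topsis_distances()].
#' @param orientation `"classical"` or `"literal"`.
#' @return numeric vector of closeness scores in \[0,1\].
#' @export
relative_closeness <- function(d_plus, d_minus,
                               orientation = c("classical", "literal")) {
  orientation <- match.arg(orientation)
  tot <- d_plus + d_minus
  num <- if (orientation == "classical") d_minus else d_plus
  s <- ifelse(tot > 0, num / tot, 0.5)
  if (any(tot == 0))
    warning("degenerate criteria (d+ + d- = 0) for some rules; S set to 0.5")
  s
}

#' Rank rules by relative closeness
#'
#' Rank 1 is the largest closeness score.  Ties are broken by higher
#' support, then higher confidence, then the lexicographically smallest
#' rule string, so ranking is a deterministic permutation invariant to
#' input order.  Rules below `closeness_threshold` are flagged `final =
#' FALSE` but still reported.
#'
#' @param rules `rule_set` data.frame (needs `rule`, `support`,
#'   `confidence`).
#' @param closeness vector of closeness scores aligned with `rules`.
#' @param d_plus,d_minus optional distance vectors to carry through.
#' @param closeness_threshold optional final-rule cutoff on S; `NULL`
#'   flags every rule final.
#' @return `ranked_rules` data.frame ordered by rank with columns of
#'   `rules` plus `d_plus`, `d_minus`, `closeness`, `rank`, `final`.
#' @export
rank_rules <- function(rules, closeness, d_plus = NA_real_, d_minus = NA_real_,
                       closeness_threshold = NULL) {
  if (length(closeness) != nrow(rules))
    stopf("closeness length (%d) != number of rules (%d)",
          length(closeness), nrow(rules))
  out <- rules
  out$d_plus <- d_plus
  out$d_minus <- d_minus
  out$closeness <- closeness
  ord <- order(-closeness, -rules$support, -rules$confidence, rules$rule)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$final <- if (is.null(closeness_threshold)) TRUE
               else out$closeness >= closeness_threshold
  rownames(out) <- NULL
  class(out) <- c("ranked_rules", "data.frame")
  out
}

#' One-call TOPSIS ranking of a rule table
#'
#' Convenience wrapper: decision matrix, ideal solutions, distances,
#' closeness and ranking in one step.
#'
#' @inheritParams build_decision_matrix
#' @inheritParams topsis_distances
#' @inheritParams relative_closeness
#' @inheritParams rank_rules
#' @return `ranked_rules` data.frame (see [rank_rules()]).
#' @export
topsis_rank <- function(rules, normalization = "none", weights = rep(1, 4),
                        distance = "cityblock", orientation = "classical",
                        closeness_threshold = NULL) {
  dm <- build_decision_matrix(rules, normalization = normalization,
                              weights = weights)
  ideal <- pis_nis(dm)
  d <- topsis_distances(dm, ideal$pis, ideal$nis, distance = distance)
  s <- relative_closeness(d$d_plus, d$d_minus, orientation = orientation)
  rank_rules(rules, s, d_plus = d$d_plus, d_minus = d$d_minus,
             closeness_threshold = closeness_threshold)
}

#' Write a ranked rule table as TSV (and optionally JSON)
#' @param ranked `ranked_rules` data.frame.
#' @param path output TSV path.
#' @param json_path optional JSON path.
#' @export
write_ranked_rules <- function(ranked, path, json_path = NULL) {
  flat <- ranked
  if (!is.null(flat$antecedent))
    flat$antecedent <- vapply(flat$antecedent, paste, "", collapse = ",")
  if (!is.null(flat$consequent))
    flat$consequent <- vapply(flat$consequent, paste, "", collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
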