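#' Combined co-expression / co-methylation similarity matrix
#'
#' For every gene pair the raw score is the product of the expression
#' Pearson correlation, the functional similarity (BioSIM surrogate, in
#' \[0,1\], default all ones) and the methylation Pearson correlation.  The
#' raw products can be negative, so the full matrix is min-max normalized
#' over all off-diagonal pairs into \[0,1\]; the diagonal is fixed at 1
#' (self-similarity).  Zero-variance rows get correlation 0 with a warning.
#'
#' @param expr,meth gene-by-sample matrices restricted to the selected
#'   genes (rows aligned).
#' @param biosim optional symmetric gene-by-gene similarity matrix in
#'   \[0,1\]; `NULL` means all ones.
#' @return symmetric matrix in \[0,1\] with attribute `raw` (the
#'   pre-normalization products).
#' @export
cecm_matrix <- function(expr, meth, biosim = NULL) {
  genes <- rownames(expr)
  if (!identical(genes, rownames(meth)))
    stopf("expression and methylation gene orderings differ")
  n <- length(genes)
  if (n < 2L) stopf("need at least 2 genes")
  if (ncol(expr) < 3L) stopf("need at least 3 samples for correlations")
  if (is.null(biosim)) {
    biosim <- matrix(1, n, n, dimnames = list(genes, genes))
  } else {
    biosim <- biosim[genes, genes, drop = FALSE]
    if (any(biosim < 0 | biosim > 1)) stopf("biosim values must lie in [0, 1]")
  }
  zv_e <- apply(expr, 1L, stats::sd) == 0
  zv_m <- apply(meth, 1L, stats::sd) == 0
  if (any(zv_e | zv_m))
    warning(sprintf("%d zero-variance gene row(s): correlations treated as 0",
                    sum(zv_e | zv_m)))
  safe_cor <- function(m, zv) {
    r <- suppressWarnings(stats::cor(t(m)))
    r[zv, ] <- 0; r[, zv] <- 0
    r[!is.finite(r)] <- 0
    r
  }
  re <- safe_cor(expr, zv_e)
  rm_ <- safe_cor(meth, zv_m)
  raw <- re * biosim * rm_
  off <- raw[upper.tri(raw)]
  rng <- range(off)
  cecm <- if (diff(rng) == 0) {
    warning("all pairwise similarity products identical; CECM set to 0.5")
    matrix(0.5, n, n, dimnames = dimnames(raw))
  } else {
    (raw - rng[1L]) / diff(rng)
  }
  diag(cecm) <- 1
  cecm <- pmin(pmax(cecm, 0), 1)
  attr(cecm, "raw") <- raw
  cecm
}

#' Dissimilarity from the combined similarity: 1 - CECM
#' @param cecm matrix from [cecm_matrix()].
#' @return symmetric matrix in \[0,1\] with zero diagonal.
#' @export
dissimilarity <- function(cecm) {
  if (any(cecm < 0 | cecm > 1)) stopf("CECM values must lie in [0, 1]")
  1 - cecm
}

#' Mask the dissimilarity matrix with the PPI adjacency
#'
#' Builds the weighted gene network: an edge (p, q) exists iff the PPI
#' adjacency H(p, q) is non-zero, with weight `H(p, q) * D_simt(p, q)`.
#' Genes absent from the edge list become isolated nodes.  Self-edges are
#' never created.
#'
#' @param dsim dissimilarity matrix from [dissimilarity()].
#' @param ppi edge data.frame (`from`, `to`, optional `weight`, default 1);
#'   edges touching genes outside `dsim` are ignored.
#' @return undirected `igraph` graph over the genes of `dsim` with edge
#'   attribute `weight`.
#' @export
mask_with_ppi <- function(dsim, ppi) {
  genes <- rownames(dsim)
  w <- if ("weight" %in% names(ppi)) as.numeric(ppi$weight) else rep(1, nrow(ppi))
  keep <- ppi$from %in% genes & ppi$to %in% genes &
    ppi$from != ppi$to & w != 0
  e <- ppi[keep, , drop = FALSE]
  w <- w[keep]
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (nrow(e)) {
    ew <- w * dsim[cbind(match(e$from, genes), match(e$to, genes))]
    g <- igraph::add_edges(g, rbind(e$from, e$to))
    g <- igraph::set_edge_attr(g, "weight", value = ew)
    g <- igraph::simplify(g, edge.attr.comb = "first")
  }
  g
}

#' All-pairs weighted shortest distances on the masked gene network
#'
#' Dijkstra on the non-negative edge weights.  Unreachable pairs stay
#' `Inf`; the summary statistics (max/min/mean) ignore the diagonal and
#' non-finite cells.
#'
#' @param graph weighted `igraph` from [mask_with_ppi()].
#' @return list: `wesd` (symmetric matrix, 0 diagonal, `Inf` for
#'   unreachable pairs), `max`, `min`, `mean`.
#' @export
all_pairs_wesd <- function(graph) {
  w <- igraph::E(graph)$weight
  if (!is.null(w) && any(w < 0)) stopf("negative edge weights are not allowed")
  d <- igraph::distances(graph, algorithm = "dijkstra")
  d <- d[igraph::V(graph)$name, igraph::V(graph)$name, drop = FALSE]
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  list(wesd = d,
       max = if (length(fin)) max(fin) else NA_real_,
       min = if (length(fin)) min(fin) else NA_real_,
       mean = if (length(fin)) mean(fin) else NA_real_)
}

#' Distance-modulated pairwise threshold matrix
#'
#' Scales a user minimum threshold by how far a gene pair sits from the
#' typical network distance:
#' `WV(p,q) = UVmin * (1 - c1 * (WeSD(p,q) - med) / (c2 * MAD))` for
#' `p != q` and `UVmin` on the diagonal, clamped at 0 from below.  `med`
#' and `MAD` (unscaled median absolute deviation; `c2 = 1.4826` supplies
#' the Gaussian consistency scaling) are computed over the finite
#' off-diagonal distances.  Close pairs therefore face a threshold above
#' `UVmin`, distant pairs a lower one.  Unreachable pairs, or a degenerate
#' spread (MAD = 0), fall back to `UVmin`.
#'
#' @param wesd distance matrix from [all_pairs_wesd()].
#' @param uvmin user minimum threshold (support, confidence or lift).
#' @param c1 damping factor on the deviation (default 0.10).
#' @param c2 MAD consistency constant (default 1.4826).
#' @return symmetric matrix of per-pair thresholds, >= 0.
#' @export
wv_threshold_matrix <- function(wesd, uvmin, c1 = 0.10, c2 = 1.4826) {
  check_number(uvmin, "uvmin", lower = 0, strict_lower = TRUE)
  check_number(c1, "c1", lower = 0, strict_lower = TRUE)
  check_number(c2, "c2", lower = 0, strict_lower = TRUE)
  off <- wesd[upper.tri(wesd)]
  fin <- off[is.finite(off)]
  out <- matrix(uvmin, nrow(wesd), ncol(wesd), dimnames = dimnames(wesd))
  if (length(fin) == 0L) {
    warning("no finite off-diagonal distances; thresholds fall back to uvmin")
    return(out)
  }
  med <- stats::median(fin)
  mad_ <- stats::median(abs(fin - med))
  if (mad_ == 0) {
    warning("degenerate distance spread (MAD = 0); thresholds fall back to uvmin")
    return(out)
  }
  wv <- uvmin * (1 - c1 * (wesd - med) / (c2 * mad_))
  wv[!is.finite(wesd)] <- uvmin
  diag(wv) <- uvmin
  pmax(wv, 0)
}

#' Per-gene-set dynamic threshold
#'
#' The mean of the pairwise threshold matrix over all unordered distinct
#' gene pairs of the set (equivalently, the ordered-pair sum divided by two
#' and by the number of pairs).  Directional items are first stripped to
#' their underlying genes; a set that maps to a single gene returns
#' `uvmin`.
#'
#' @param items character vector of directional items (or bare gene IDs).
#' @param wv threshold matrix from [wv_threshold_matrix()].
#' @param uvmin fallback for singleton sets.
#' @return scalar threshold.
#' @export
dbv_threshold <- function(items, wv, uvmin) {
  genes <- unique(item_genes(items))
  if (length(genes) < 2L) return(uvmin)
  missing <- setdiff(genes, rownames(wv))
  if (length(missing)) stopf("gene(s) not in threshold matrix: %s",
                             paste(missing, collapse = ", "))
  sub <- wv[genes, genes, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Average network distance over a rule's gene set
#'
#' The mean weighted shortest distance over all unordered gene pairs of the
#' rule's full gene set (antecedent and consequent together).  Unreachable
#' pairs contribute the maximum finite distance in the matrix; a set that
#' maps to a single gene returns 0 with a warning.
#'
#' @param items directional items (or bare gene IDs) of the rule.
#' @param wesd distance matrix from [all_pairs_wesd()].
#' @return scalar mean distance.
#' @export
avg_wesd <- function(items, wesd) {
  genes <- unique(item_genes(items))
  if (length(genes) < 2L) {
    warning("gene set maps to a single gene; average distance is 0")
    return(0)
  }
  sub <- wesd[genes, genes, drop = FALSE]
  d <- sub[upper.tri(sub)]
  if (any(!is.finite(d))) {
    fin_all <- wesd[upper.tri(wesd)]
    fin_all <- fin_all[is.finite(fin_all)]
    mx <- if (length(fin_all)) max(fin_all) else 0
    d[!is.finite(d)] <- mx
  }
  mean(d)
}
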