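#' Pipeline configuration
#'
#' Validates every field; unknown arguments are rejected by R's matching.
#' `ud_min_s`/`ud_min_c`/`ud_min_l` are the user minimum support /
#' confidence / lift thresholds the dynamic per-gene-set cutoffs are scaled
#' from; `c1` damps the distance deviation and `c2` is the Gaussian MAD
#' consistency constant.
#'
#' @param expression,methylation,labels,ppi input paths (may be `NULL` when
#'   the pipeline is invoked on in-memory data).
#' @param biosim optional similarity-matrix path.
#' @param probe_map optional probe-to-gene TSV (columns `probe`, `gene`);
#'   absent means probes are genes.
#' @param outdir artifact directory (`NULL` = no files written).
#' @param alpha BH-adjusted significance cutoff (strict `<`).
#' @param ud_min_s user minimum support, a fraction of transactions unless
#'   `count_based_support`.
#' @param ud_min_c user minimum confidence in (0, 1].
#' @param ud_min_l user minimum lift (default 1).
#' @param c1,c2 dynamic-threshold constants (defaults 0.10 and 1.4826).
#' @param max_itemset_size largest mined itemset (default 4).
#' @param count_based_support interpret `ud_min_s` as an absolute count.
#' @param topsis list of TOPSIS options: `normalization`, `distance`,
#'   `orientation`, `weights`, `closeness_threshold`.
#' @param evaluation list: `enabled`, `top_k`, `folds`, `repeats`.
#' @param seed master seed; stage seeds are derived from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, methylation = NULL,
                            labels = NULL, ppi = NULL, biosim = NULL,
                            probe_map = NULL, outdir = NULL,
                            alpha = 0.05,
                            ud_min_s = 0.3, ud_min_c = 0.5, ud_min_l = 1,
                            c1 = 0.10, c2 = 1.4826,
                            max_itemset_size = 4L,
                            count_based_support = FALSE,
                            topsis = list(), evaluation = list(),
                            seed = 1L, log_level = c("info", "quiet")) {
  top_defaults <- list(normalization = "none", distance = "cityblock",
                       orientation = "classical", weights = rep(1, 4),
                       closeness_threshold = NULL)
  ev_defaults <- list(enabled = FALSE, top_k = 10L, folds = 10L, repeats = 10L)
  unknown <- setdiff(names(topsis), names(top_defaults))
  if (length(unknown)) stopf("unknown topsis option(s): %s", paste(unknown, collapse = ", "))
  unknown <- setdiff(names(evaluation), names(ev_defaults))
  if (length(unknown)) stopf("unknown evaluation option(s): %s", paste(unknown, collapse = ", "))
  topsis <- utils::modifyList(top_defaults, topsis)
  evaluation <- utils::modifyList(ev_defaults, evaluation)
  cfg <- list(
    expression = expression, methylation = methylation, labels = labels,
    ppi = ppi, biosim = biosim, probe_map = probe_map, outdir = outdir,
    alpha = check_number(alpha, "alpha", 0, 1, strict_lower = TRUE),
    ud_min_s = check_number(ud_min_s, "ud_min_s", 0, Inf, strict_lower = TRUE),
    ud_min_c = check_number(ud_min_c, "ud_min_c", 0, 1, strict_lower = TRUE),
    ud_min_l = check_number(ud_min_l, "ud_min_l", 0, Inf, strict_lower = TRUE),
    c1 = check_number(c1, "c1", 0, Inf, strict_lower = TRUE),
    c2 = check_number(c2, "c2", 0, Inf, strict_lower = TRUE),
    max_itemset_size = check_count(max_itemset_size, "max_itemset_size", min = 1L),
    count_based_support = check_flag(count_based_support, "count_based_support"),
    topsis = topsis, evaluation = evaluation,
    seed = check_count(seed, "seed"),
    log_level = match.arg(log_level))
  if (!cfg$count_based_support && cfg$ud_min_s > 1)
    stopf("'ud_min_s' must be in (0, 1] unless count_based_support = TRUE")
  structure(cfg, class = "pipeline_config")
}

plog <- function(cfg, fmt, ...) {
  if (cfg$log_level != "quiet") message(sprintf(fmt, ...))
}

empty_pipeline_result <- function(counts) {
  list(ranked = NULL, rules = NULL, gene_list = character(0),
       wesd = NULL, transactions = NULL, evaluation = NULL, counts = counts)
}

#' Run the full multi-omics rule mining pipeline
#'
#' preprocess (match, normalize, moderated test on both layers, probe
#' collapsing, significance + PPI intersection) -> discretize ->
#' network distances -> dynamic-threshold FP-growth mining -> TOPSIS
#' ranking -> optional per-rule cross-validated evaluation.  All stage
#' randomness derives from `config$seed`.  When `config$outdir` is set,
#' every intermediate artifact is written there.
#'
#' @param config a [pipeline_config()] (or a list coercible to one).
#' @param data optional in-memory inputs overriding the config paths: a
#'   list with `expr`, `meth`, `labels`, `ppi`, and optionally `biosim`,
#'   `probe_map`.
#' @return list with `ranked` (ranked rule table), `rules`, `gene_list`,
#'   `wesd`, `transactions`, `evaluation` and a `counts` log of stage
#'   sizes; `ranked` is `NULL` when the pipeline exits early (no
#'   significant genes, no frequent sets, no rules).
#' @export
run_pipeline <- function(config, data = NULL) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  cfg <- config
  if (is.null(data)) {
    for (f in c("expression", "methylation", "labels", "ppi"))
      if (is.null(cfg[[f]])) stopf("pipeline stage 'input': missing path '%s'", f)
    data <- list(expr = read_matrix(cfg$expression),
                 meth = read_matrix(cfg$methylation),
                 labels = read_labels(cfg$labels),
                 ppi = read_edge_list(cfg$ppi),
                 biosim = if (!is.null(cfg$biosim)) read_square_matrix(cfg$biosim),
                 probe_map = if (!is.null(cfg$probe_map))
                   utils::read.delim(cfg$probe_map, stringsAsFactors = FALSE))
  }
  out <- if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    function(name) file.path(cfg$outdir, name)
  } else function(name) NULL
  counts <- list()

  # -- preprocess -------------------------------------------------------------
  omics <- match_omics(data$expr, data$meth, data$labels)
  counts$matched_genes <- length(omics$gene_ids)
  counts$matched_samples <- length(omics$sample_ids)
  plog(cfg, "preprocess: %d matched probes, %d matched samples",
       counts$matched_genes, counts$matched_samples)

  expr_n <- zero_mean_normalize(omics$expression)
  meth_n <- zero_mean_normalize(omics$methylation)
  gene_of <- if (!is.null(data$probe_map)) {
    map <- stats::setNames(data$probe_map$gene, data$probe_map$probe)
    unname(map[omics$gene_ids])
  } else omics$gene_ids
  tt_e <- collapse_probes(moderated_t_test(expr_n, omics$labels, genes = gene_of))
  tt_m <- collapse_probes(moderated_t_test(meth_n, omics$labels, genes = gene_of))
  ppi_genes <- unique(c(data$ppi$from, data$ppi$to))
  genes <- select_significant_intersection(tt_e, tt_m, ppi_genes, alpha = cfg$alpha)
  counts$significant_genes <- length(genes)
  plog(cfg, "preprocess: %d genes significant in both omics and in the PPI graph",
       length(genes))
  if (!is.null(out("stats_expression.tsv"))) {
    utils::write.table(tt_e, out("stats_expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tt_m, out("stats_methylation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(genes, out("gene_list.txt"))
  }
  if (length(genes) == 0L) {
    plog(cfg, "pipeline halted: no significant genes")
    return(empty_pipeline_result(counts))
  }

  # per-gene matrices for the selected genes (rows = collapsed best probes)
  probe_e <- tt_e$probe[match(genes, tt_e$gene)]
  probe_m <- tt_m$probe[match(genes, tt_m$gene)]
  expr_g <- expr_n[probe_e, , drop = FALSE]; rownames(expr_g) <- genes
  meth_g <- meth_n[probe_m, , drop = FALSE]; rownames(meth_g) <- genes

  # -- discretize -------------------------------------------------------------
  pd <- post_discretize(discretize_expression(expr_g),
                        discretize_methylation(meth_g))
  db <- to_transactions(pd)
  counts$transactions <- db$n_transactions
  if (!is.null(out("transactions.txt"))) write_transactions(db, out("transactions.txt"))

  # -- network distances ------------------------------------------------------
  if (length(genes) < 2L) {
    plog(cfg, "pipeline halted: fewer than 2 significant genes")
    return(empty_pipeline_result(counts))
  }
  cecm <- cecm_matrix(expr_g, meth_g, biosim = data$biosim)
  graph <- mask_with_ppi(dissimilarity(cecm), data$ppi)
  wd <- all_pairs_wesd(graph)
  counts$network_edges <- igraph::ecount(graph)
  wv_msc <- wv_threshold_matrix(wd$wesd, cfg$ud_min_s, cfg$c1, cfg$c2)
  wv_mcc <- wv_threshold_matrix(wd$wesd, cfg$ud_min_c, cfg$c1, cfg$c2)
  wv_mlc <- wv_threshold_matrix(wd$wesd, cfg$ud_min_l, cfg$c1, cfg$c2)
  if (!is.null(out("wesd.tsv"))) {
    write_square_matrix_tsv(wd$wesd, out("wesd.tsv"))
    write_square_matrix_tsv(wv_msc, out("wv_msc.tsv"))
  }

  # -- mining -----------------------------------------------------------------
  freq <- mine_frequent(db, cfg$ud_min_s, max_size = cfg$max_itemset_size,
                        count_based = cfg$count_based_support)
  counts$frequent_sets <- nrow(freq)
  plog(cfg, "mining: %d frequent sets (min support %.3g)", nrow(freq), cfg$ud_min_s)
  kept <- filter_by_dbvs(freq, wv_msc, cfg$ud_min_s)
  counts$sets_after_dbvs <- nrow(kept)
  if (nrow(kept) == 0L) {
    plog(cfg, "pipeline halted: no gene sets pass the dynamic support threshold")
    return(empty_pipeline_result(counts))
  }
  rules <- generate_rules(kept, freq, wv_mcc, wv_mlc,
                          uvmin_c = cfg$ud_min_c, ud_min_l = cfg$ud_min_l,
                          wesd = wd$wesd)
  counts$rules <- nrow(rules)
  plog(cfg, "mining: %d rules pass the dynamic confidence/lift thresholds",
       nrow(rules))
  if (!is.null(out("rules.tsv"))) write_rules(rules, out("rules.tsv"))
  if (nrow(rules) == 0L) {
    plog(cfg, "pipeline halted: no rules survive")
    return(empty_pipeline_result(counts))
  }

  # -- ranking ----------------------------------------------------------------
  ranked <- topsis_rank(rules,
                        normalization = cfg$topsis$normalization,
                        weights = cfg$topsis$weights,
                        distance = cfg$topsis$distance,
                        orientation = cfg$topsis$orientation,
                        closeness_threshold = cfg$topsis$closeness_threshold)
  counts$rules_ranked <- nrow(ranked)
  if (!is.null(out("ranked_rules.tsv")))
    write_ranked_rules(ranked, out("ranked_rules.tsv"), out("ranked_rules.json"))

  # -- evaluation (optional) --------------------------------------------------
  evaluation <- NULL
  if (isTRUE(cfg$evaluation$enabled)) {
    sel <- paired_omics(expr_g, meth_g, omics$labels)
    top <- utils::head(ranked, cfg$evaluation$top_k)
    evaluation <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
      ev <- evaluate_rule(sel, c(top$antecedent[[i]], top$consequent[[i]]),
                          folds = cfg$evaluation$folds,
                          repeats = cfg$evaluation$repeats,
                          seed = cfg$seed + i)
      cbind(data.frame(rule = top$rule[i]), ev)
    }))
    if (!is.null(out("evaluation.tsv")))
      utils::write.table(evaluation, out("evaluation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  list(ranked = ranked, rules = rules, gene_list = genes, wesd = wd,
       transactions = db, evaluation = evaluation, counts = counts)
}
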