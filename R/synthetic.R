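#' Configuration for the synthetic paired-omics generator
#'
#' Defaults emulate the structure of a two-group sarcoma multi-omics study:
#' 13 case and 13 control samples with matched genes across expression and
#' methylation, a small number of differential gene modules wired into the
#' PPI graph, and gene-wise Gaussian noise.  `effect_size` is the group mean
#' shift in units of `noise_sd`.
#'
#' @param n_genes total number of genes.
#' @param n_samples_case,n_samples_control samples per group.
#' @param n_modules number of planted co-directional modules.
#' @param module_size genes per module (>= 2).
#' @param effect_size mean shift of planted genes, in noise-SD units.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param ppi_background_density probability of a background PPI edge
#'   between any gene pair not already inside a module clique.
#' @param probes_per_gene replicate probes per gene (independent noise,
#'   shared signal); probe IDs are `<gene>_p<k>` when > 1.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return validated config list (class `synth_config`).
#' @export
synth_config <- function(n_genes = 100L,
                         n_samples_case = 13L,
                         n_samples_control = 13L,
                         n_modules = 2L,
                         module_size = 4L,
                         effect_size = 4,
                         noise_sd = 1,
                         ppi_background_density = 0.02,
                         probes_per_gene = 1L,
                         seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_samples_case = check_count(n_samples_case, "n_samples_case", min = 1L),
    n_samples_control = check_count(n_samples_control, "n_samples_control", min = 1L),
    n_modules = check_count(n_modules, "n_modules", min = 0L),
    module_size = check_count(module_size, "module_size", min = 2L),
    effect_size = check_number(effect_size, "effect_size", lower = 0, strict_lower = TRUE),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0, strict_lower = TRUE),
    ppi_background_density = check_number(ppi_background_density,
                                          "ppi_background_density", 0, 1),
    probes_per_gene = check_count(probes_per_gene, "probes_per_gene", min = 1L),
    seed = check_count(seed, "seed"))
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stopf("'n_modules' x 'module_size' (%d) exceeds 'n_genes' (%d)",
          cfg$n_modules * cfg$module_size, cfg$n_genes)
  structure(cfg, class = "synth_config")
}

#' Generate a paired expression/methylation dataset with planted modules
#'
#' Planted genes receive a co-directional group shift: an "up-hypo" gene is
#' over-expressed and under-methylated in cases (methylation suppresses
#' expression, so the two shifts are anti-correlated), a "down-hyper" gene
#' the reverse.  Module genes form cliques in the PPI edge list; background
#' gene pairs get sparse random edges.  The functional-similarity matrix
#' defaults to all ones, which reduces the combined co-expression /
#' co-methylation similarity to pure Pearson correlation.
#'
#' @param config a [synth_config()].
#' @return list with elements
#'   \item{omics}{`paired_omics` object (probe-level matrices, labels)}
#'   \item{ppi}{PPI edge data.frame (`from`, `to`, `weight`)}
#'   \item{biosim}{gene-by-gene similarity matrix (all ones)}
#'   \item{probe_map}{data.frame `probe` -> `gene`}
#'   \item{truth}{planted modules, per-gene directions and the expected
#'     top directional item sets}
#' @export
#' @examples
#' sim <- generate_paired_omics(synth_config(n_genes = 20, seed = 7))
#' dim(sim$omics$expression)
generate_paired_omics <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  with_seed(config$seed, {
    n <- config$n_genes
    m <- config$n_samples_case + config$n_samples_control
    genes <- sprintf("G%04d", seq_len(n))
    samples <- c(sprintf("case_%02d", seq_len(config$n_samples_case)),
                 sprintf("ctrl_%02d", seq_len(config$n_samples_control)))
    labels <- c(rep(1L, config$n_samples_case), rep(0L, config$n_samples_control))
    names(labels) <- samples

    n_planted <- config$n_modules * config$module_size
    planted <- genes[seq_len(n_planted)]
    modules <- if (config$n_modules > 0L)
      split(planted, rep(seq_len(config$n_modules), each = config$module_size))
    else list()
    direction <- character(0)
    if (n_planted > 0L) {
      direction <- sample(c("up-hypo", "down-hyper"), n_planted, replace = TRUE)
      names(direction) <- planted
    }

    shift <- config$effect_size * config$noise_sd
    k <- config$probes_per_gene
    probe_gene <- rep(genes, each = k)
    probes <- if (k == 1L) genes else
      paste0(probe_gene, "_p", rep(seq_len(k), times = n))

    expr <- matrix(stats::rnorm(length(probes) * m, sd = config$noise_sd),
                   nrow = length(probes), ncol = m,
                   dimnames = list(probes, samples))
    meth <- matrix(stats::rnorm(length(probes) * m, sd = config$noise_sd),
                   nrow = length(probes), ncol = m,
                   dimnames = list(probes, samples))
    case_cols <- labels == 1L
    for (g in planted) {
      rows <- which(probe_gene == g)
      sgn <- if (direction[[g]] == "up-hypo") 1 else -1
      expr[rows, case_cols] <- expr[rows, case_cols] + sgn * shift
      meth[rows, case_cols] <- meth[rows, case_cols] - sgn * shift
    }

    # PPI: full cliques inside modules, Erdos-Renyi background elsewhere
    from <- character(0); to <- character(0)
    for (mod in modules) {
      pr <- utils::combn(mod, 2L)
      from <- c(from, pr[1L, ]); to <- c(to, pr[2L, ])
    }
    in_module <- paste(from, to)
    all_pairs <- utils::combn(genes, 2L)
    bg <- !(paste(all_pairs[1L, ], all_pairs[2L, ]) %in% in_module)
    keep <- bg & stats::runif(ncol(all_pairs)) < config$ppi_background_density
    ppi <- data.frame(from = c(from, all_pairs[1L, keep]),
                      to = c(to, all_pairs[2L, keep]),
                      weight = 1, stringsAsFactors = FALSE)

    biosim <- matrix(1, n, n, dimnames = list(genes, genes))

    item_of <- function(g) paste0(g, if (direction[[g]] == "up-hypo") "+" else "-")
    truth <- list(
      planted_modules = modules,
      planted_directions = as.list(direction),
      expected_top_rules = lapply(modules, function(mod)
        vapply(mod, item_of, "", USE.NAMES = FALSE)))

    omics <- paired_omics(expr, meth, labels)
    list(omics = omics, ppi = ppi, biosim = biosim,
         probe_map = data.frame(probe = probes, gene = probe_gene,
                                stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' Expression/methylation as gene-by-sample TSV, labels as a two-column TSV,
#' PPI as a two-column edge list, similarity matrix as square TSV, truth as
#' JSON.
#'
#' @param sim result of [generate_paired_omics()].
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    biosim = file.path(dir, "biosim.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    truth = file.path(dir, "truth.json"))
  write_matrix_tsv(sim$omics$expression, paths[["expression"]])
  write_matrix_tsv(sim$omics$methylation, paths[["methylation"]])
  write_labels_tsv(sim$omics$labels, paths[["labels"]])
  write_edge_list_tsv(sim$ppi, paths[["ppi"]])
  write_square_matrix_tsv(sim$biosim, paths[["biosim"]])
  utils::write.table(sim$probe_map, paths[["probe_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = FALSE)
  paths
}
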