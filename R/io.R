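#' Read a gene-by-sample matrix from TSV/CSV
#'
#' The first column holds gene/probe identifiers (duplicates permitted:
#' multiple probes may map to one gene), the header row holds sample
#' identifiers (duplicates rejected).  The separator is taken from the file
#' extension (`.csv` = comma, anything else = tab).
#'
#' @param path file path.
#' @param sep field separator; defaults by extension.
#' @return numeric matrix with probe/gene rownames and sample colnames.
#' @export
read_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("'%s': need a header line and at least one data row", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  header <- cells[[1L]]
  # header may or may not carry a leading ID-column name
  body_len <- lengths(cells[-1L])
  ragged <- which(body_len != body_len[1L])
  if (length(ragged))
    stopf("'%s': ragged row %d (%d fields, expected %d)",
          path, ragged[1L] + 1L, body_len[ragged[1L]], body_len[1L])
  n_fields <- body_len[1L]
  samples <- if (length(header) == n_fields) header[-1L] else header
  if (length(samples) != n_fields - 1L)
    stopf("'%s': header has %d sample IDs but rows have %d value fields",
          path, length(samples), n_fields - 1L)
  if (anyDuplicated(samples))
    stopf("'%s': duplicated sample ID '%s'", path, samples[duplicated(samples)][1L])
  ids <- vapply(cells[-1L], `[[`, "", 1L)
  vals <- lapply(cells[-1L], function(x) x[-1L])
  m <- matrix(NA_real_, nrow = length(ids), ncol = n_fields - 1L,
              dimnames = list(ids, samples))
  for (i in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[i]]))
    bad <- which(is.na(v) & !(toupper(trimws(vals[[i]])) %in% c("NA", "NAN", "")))
    if (length(bad))
      stopf("'%s': non-numeric cell at row %d, column %d ('%s')",
            path, i + 1L, bad[1L] + 1L, vals[[i]][bad[1L]])
    m[i, ] <- v
  }
  m
}

#' Write a matrix in the TSV dialect read by [read_matrix()]
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample/label file
#'
#' @param path TSV with columns `sample_id` and `label` (binary group
#'   indicator, e.g. 0 = control, 1 = case).
#' @return named integer vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("'%s': expected two columns (sample, label)", path)
  labs <- df[[2L]]
  if (anyDuplicated(df[[1L]])) stopf("'%s': duplicated sample ID", path)
  u <- sort(unique(labs))
  if (length(u) != 2L) stopf("'%s': labels must take exactly two values", path)
  out <- as.integer(labs == u[2L])
  names(out) <- df[[1L]]
  out
}

#' @rdname read_labels
#' @param labels named vector as returned by [read_labels()].
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two gene identifiers per line (tab-separated), optional third numeric
#' weight column.  Self-loops are dropped; duplicate/reversed edges are
#' collapsed (keeping the first weight seen).
#'
#' @param path TSV edge list.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, header = TRUE)
  if (ncol(df) < 2L) stopf("'%s': expected at least two columns", path)
  w <- if (ncol(df) >= 3L) as.numeric(df[[3L]]) else rep(1, nrow(df))
  edges <- data.frame(from = as.character(df[[1L]]), to = as.character(df[[2L]]),
                      weight = w, stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to), paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @rdname read_edge_list
#' @param edges data.frame with columns `from`, `to` and optionally `weight`.
#' @export
write_edge_list_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square gene-by-gene matrix (similarity or distance) from TSV
#' @param path TSV written by [write_square_matrix_tsv()].
#' @return symmetric numeric matrix.
#' @export
read_square_matrix <- function(path) {
  m <- read_matrix(path)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stopf("'%s': not a square matrix with matching row/column IDs", path)
  m
}

#' @rdname read_square_matrix
#' @param m square matrix.
#' @export
write_square_matrix_tsv <- function(m, path) {
  write_matrix_tsv(m, path, id_col = "gene_id")
}

#' Serialize transactions in basket format
#'
#' One line per sample: sample ID, tab, comma-separated item IDs.  Empty
#' transactions are written (and read back) as an empty item field; they
#' still count towards the transaction total.
#'
#' @param db transaction database from [to_transactions()].
#' @param path output path.
#' @export
write_transactions <- function(db, path) {
  items <- vapply(db$transactions, paste, "", collapse = ",")
  writeLines(paste(names(db$transactions), items, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  tx <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) character(0)
    else strsplit(p[2L], ",", fixed = TRUE)[[1L]]
  })
  names(tx) <- ids
  structure(list(transactions = tx, n_transactions = length(tx)),
            class = "transaction_db")
}

#' Load a pipeline configuration file
#'
#' JSON (always) or YAML (when the \pkg{yaml} package is installed).  Unknown
#' keys are rejected so that typos do not silently fall back to defaults; see
#' [pipeline_config()] for the recognised fields.
#'
#' @param path config file path (`.json`, `.yml`/`.yaml`).
#' @return validated config list (class `pipeline_config`).
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}
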