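#' @keywords internal
"_PACKAGE"

# Run code with a private RNG stream so callers' .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (printed tables use commercial rounding,
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Map directional item identifiers to their underlying genes
#'
#' Items are gene identifiers suffixed with `"+"` (up-regulated and
#' hypo-methylated) or `"-"` (down-regulated and hyper-methylated).  All
#' network-distance lookups operate on the underlying genes; the sign only
#' affects transaction membership.
#'
#' @param items character vector of item IDs such as `"TP53-"`.
#' @return character vector of gene IDs.
#' @export
#' @examples
#' item_genes(c("STAT3+", "TP53-"))
item_genes <- function(items) {
  sub("[+-]$", "", items)
}

# Single itemset -> canonical string key (items sorted).
itemset_key <- function(items) paste(sort(items), collapse = "\x1f")

rule_string <- function(antecedent, consequent) {
  paste(paste(sort(antecedent), collapse = ", "),
        "->",
        paste(sort(consequent), collapse = ", "))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("'%s' must be TRUE or FALSE", nm)
  x
}

check_number <- function(x, nm, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", nm)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stopf("'%s' must be in %s%g, %g]", nm, if (strict_lower) "(" else "[", lower, upper)
  as.numeric(x)
}

check_count <- function(x, nm, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stopf("'%s' must be an integer >= %d", nm, min)
  as.integer(x)
}
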