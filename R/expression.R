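# Fold-change expression screen: rank genes by flower-organ / developmental
# stage enrichment relative to the developed rosette and form category sets.

#' Per-gene log2 fold change against a reference column
#'
#' Computes `log2(category) - log2(reference)` on a linear-scale expression
#' matrix. Genes with a nonpositive or missing value in either column are
#' excluded and reported. When several probes map to one gene (duplicated
#' ids), the maximum value per column is taken first, preserving
#' "enriched anywhere" semantics.
#'
#' @param mat numeric matrix with gene ids as rownames and condition labels
#'   as colnames, linear scale; or a data.frame whose first column is
#'   `gene_id`.
#' @param category,reference column names.
#' @return List with `log2fc` (named numeric, one entry per usable gene) and
#'   `excluded` (character vector of excluded gene ids).
#' @examples
#' m <- matrix(c(1, 1, 4, 2), 2, 2, dimnames = list(c("g1", "g2"), c("R", "FL")))
#' log2fc(m, "FL", "R")$log2fc
#' @export
log2fc <- function(mat, category, reference) {
  mat <- as_expression_matrix(mat)
  if (!all(c(category, reference) %in% colnames(mat))) {
    stop("matrix must contain columns ", category, " and ", reference)
  }
  fl <- mat[, category]
  r <- mat[, reference]
  ok <- is.finite(fl) & is.finite(r) & fl > 0 & r > 0
  list(log2fc = stats::setNames(log2(fl[ok]) - log2(r[ok]), rownames(mat)[ok]),
       excluded = rownames(mat)[!ok])
}

as_expression_matrix <- function(mat) {
  if (is.data.frame(mat)) {
    ids <- as.character(mat[[1L]])
    mat <- as.matrix(mat[, -1L, drop = FALSE])
    rownames(mat) <- ids
  }
  if (is.null(rownames(mat))) stop("expression matrix needs gene ids as rownames")
  if (anyDuplicated(rownames(mat))) {
    mat <- collapse_probes(mat)
  }
  mat
}

# Maximum per gene across duplicated probe rows.
collapse_probes <- function(mat) {
  g <- factor(rownames(mat), levels = unique(rownames(mat)))
  out <- apply(mat, 2L, function(v) tapply(v, g, max))
  rownames(out) <- levels(g)
  out
}

#' Filter and order up-regulated genes
#'
#' Genes with log2 fold change strictly greater than `threshold` (default 1,
#' i.e. a 2-fold cutoff with exactly-2-fold genes excluded), ordered by
#' decreasing log2FC with ties broken by gene id.
#'
#' @param values named numeric vector of log2 fold changes.
#' @param threshold log2FC cutoff (strict inequality).
#' @return Character vector of gene ids.
#' @export
rank_and_filter <- function(values, threshold = 1) {
  stopifnot(!is.null(names(values)))
  v <- values[is.finite(values) & values > threshold]
  names(v)[order(-v, names(v))]
}

#' Venn region counts for up to 6 gene sets
#'
#' Counts genes per membership pattern (2^k - 1 regions). Region names join
#' the member set names with `&`.
#'
#' @param sets named list of character vectors (2 to 6 sets).
#' @return Named integer vector over all non-empty membership patterns.
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2L) stop("venn_counts needs at least 2 sets")
  if (k > 6L) stop("more than 6 sets makes an unreadable venn diagram")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  all_genes <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  names(counts) <- apply(patterns, 1L, function(p) {
    paste(names(sets)[as.logical(p)], collapse = "&")
  })
  counts
}

#' @rdname venn_counts
#' @return `union_unique()`: character vector, union of all sets in
#'   first-seen order.
#' @export
union_unique <- function(sets) {
  unique(unlist(sets, use.names = FALSE))
}

#' Full enrichment screen over all categories
#'
#' Runs [log2fc()] + [rank_and_filter()] for every non-reference column,
#' computes Venn region counts and the union gene set, and reports probe
#' coverage per category.
#'
#' @param mat expression matrix (see [log2fc()]).
#' @param reference reference column name (developed rosette).
#' @param categories category columns (default: all other columns).
#' @param threshold log2FC cutoff, strict.
#' @return Object of class `screen_result`: list with `log2fc` (per-category
#'   named vectors), `up_sets`, `venn`, `union`, `coverage`.
#' @export
screen_expression <- function(mat, reference, categories = NULL, threshold = 1) {
  mat <- as_expression_matrix(mat)
  if (is.null(categories)) categories <- setdiff(colnames(mat), reference)
  fc <- lapply(categories, function(cat) log2fc(mat, cat, reference))
  names(fc) <- categories
  up <- lapply(fc, function(x) rank_and_filter(x$log2fc, threshold))
  coverage <- data.frame(category = categories,
                         n_measured = vapply(fc, function(x) length(x$log2fc), integer(1)),
                         n_excluded = vapply(fc, function(x) length(x$excluded), integer(1)),
                         n_up = lengths(up), stringsAsFactors = FALSE)
  structure(list(log2fc = lapply(fc, `[[`, "log2fc"),
                 up_sets = up,
                 venn = if (length(up) >= 2L) venn_counts(up) else NULL,
                 union = union_unique(up),
                 coverage = coverage,
                 threshold = threshold),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>", length(x$up_sets), "categories, union of",
      length(x$union), "up-regulated genes (log2FC >", x$threshold, ")\n")
  print(x$coverage, row.names = FALSE)
  invisible(x)
}
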