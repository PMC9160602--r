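#' Read a validated miRNA-gene interaction table
#'
#' @param path Tab-delimited file with header columns `mirna`, `gene`, and
#'   optionally `source`. `(mirna, gene)` pairs are deduplicated across
#'   sources for set logic.
#' @return A tibble with `mirna`, `gene`, `source`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) abort(paste0("interaction table not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mirna", "gene") %in% names(tbl))) {
    abort("interaction table must have 'mirna' and 'gene' columns")
  }
  if (!"source" %in% names(tbl)) tbl$source <- NA_character_
  as_tibble(tbl)[c("mirna", "gene", "source")]
}

#' Read a context gene list
#'
#' A list of genes with documented expression in a cellular context relevant
#' to the phenotype (for example mature testis, or pre-embryonic-genome-
#' activation embryos), used to filter shared targets.
#'
#' @param path A file with one gene symbol per line, or a TSV with a `gene`
#'   column.
#' @param label Context label stored on the result.
#' @return A tibble with `label` and unique, non-empty `gene` symbols.
#' @export
read_context_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) abort(paste0("context list not found: ", path))
  first <- readLines(path, n = 1L)
  genes <- if (grepl("\t", first) || identical(tolower(first), "gene")) {
    readr::read_tsv(path, show_col_types = FALSE)[["gene"]]
  } else {
    readLines(path, warn = FALSE)
  }
  genes <- unique(trimws(genes))
  genes <- genes[nzchar(genes)]
  tibble(label = label, gene = genes)
}

# Deduplicated target set of one miRNA.
targets_of <- function(table, mirna) {
  unique(table$gene[table$mirna == mirna])
}

#' Shared validated targets of a miRNA pair
#'
#' The intersection of the two miRNAs' validated target gene sets.
#'
#' @param table An interaction tibble from [read_interactions()].
#' @param mirna_a,mirna_b miRNA names.
#' @return Character vector of shared gene symbols. A miRNA absent from the
#'   table contributes an empty set, with a warning.
#' @export
shared_targets <- function(table, mirna_a, mirna_b) {
  for (m in c(mirna_a, mirna_b)) {
    if (!m %in% table$mirna) {
      warn(paste0("miRNA absent from interaction table: ", m))
    }
  }
  intersect(targets_of(table, mirna_a), targets_of(table, mirna_b))
}

#' Filter a gene set by expression context
#'
#' Case-insensitive intersection with a context gene list.
#'
#' @param genes Character vector of gene symbols.
#' @param context A context tibble from [read_context_list()] or a character
#'   vector of symbols.
#' @return The subset of `genes` (original case) present in the context.
#' @export
filter_by_context <- function(genes, context) {
  ctx <- if (is.data.frame(context)) context$gene else context
  genes[toupper(genes) %in% toupper(ctx)]
}

#' Genes co-targeted by multiple differentially correlated pairs
#'
#' Counts, for every gene, how many classified pairs have that gene in their
#' shared-target set, and keeps genes reaching `min_pairs`. Restricting
#' `class` reproduces summaries such as "targeted by both members of 3+ CH
#' pairs".
#'
#' @param pairs A tibble with `mirna_a`, `mirna_b` and optionally `class`
#'   (e.g. `tidy()` of a `diffcorr` object).
#' @param table An interaction tibble.
#' @param min_pairs Minimum number of pairs sharing the gene, default 1.
#' @param class Optional class filter (`"CH"` or `"CL"`).
#' @return A tibble with `gene` and `n_pairs`, descending by `n_pairs`.
#' @export
co_target_count <- function(pairs, table, min_pairs = 1, class = NULL) {
  if (!is.null(class)) pairs <- pairs[pairs$class %in% class, , drop = FALSE]
  if (nrow(pairs) == 0) return(tibble(gene = character(), n_pairs = integer()))
  shared <- purrr::map2(pairs$mirna_a, pairs$mirna_b,
                        function(a, b) suppressWarnings(
                          shared_targets(table, a, b)))
  tibble(gene = unlist(shared)) |>
    count(.data$gene, name = "n_pairs") |>
    filter(.data$n_pairs >= min_pairs) |>
    arrange(dplyr::desc(.data$n_pairs), .data$gene)
}

#' Map miRNA names through a homolog table
#'
#' Optional convenience for interaction tables keyed by human miRNA names: a
#' two-column mapping (`from`, `to`) is applied to a vector of names; names
#' without a mapping are returned unchanged.
#'
#' @param names Character vector of miRNA names.
#' @param mapping A data frame whose first two columns are from-name and
#'   to-name.
#' @return Mapped character vector.
#' @export
map_homologs <- function(names, mapping) {
  m <- setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  out <- unname(m[names])
  ifelse(is.na(out), names, out)
}
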