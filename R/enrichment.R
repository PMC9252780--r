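#' Build the ATC drug-class tree from a gene-to-code mapping
#'
#' The Anatomical Therapeutic Chemical classification is a five-level
#' hierarchy whose codes have 1, 3, 4, 5 and 7 characters (e.g. `C` for
#' cardiovascular-system drugs down to `C07AB07` for bisoprolol). A node is
#' created for every prefix level of every mapped code, and each node's gene
#' set is the union over its subtree, so a gene targeted by a level-5 drug
#' code belongs to all five ancestors.
#'
#' @param mapping Tibble/data frame with columns `gene_id` and `atc_code`
#'   (codes at any level), or a path to such a TSV.
#' @return Tibble of class `atc_tree` with one row per node: `code`, `level`,
#'   `parent` (`NA` at level 1) and `gene_set` (list column of character
#'   vectors).
#' @export
build_atc_tree <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1) {
    mapping <- readr::read_tsv(mapping, col_types = readr::cols(
      gene_id = readr::col_character(), atc_code = readr::col_character()
    ), progress = FALSE)
  }
  mapping <- as_tibble(mapping)
  stopifnot(all(c("gene_id", "atc_code") %in% names(mapping)))
  if (nrow(mapping) == 0) {
    return(structure(
      tibble(code = character(), level = integer(), parent = character(),
             gene_set = list()),
      class = c("atc_tree", class(tibble()))))
  }
  bad <- !grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$",
                mapping$atc_code)
  if (any(bad)) {
    abort(sprintf("malformed ATC code '%s' at mapping row %d",
                  mapping$atc_code[which(bad)[1]], which(bad)[1]))
  }

  prefix_lengths <- c(1L, 3L, 4L, 5L, 7L)
  expanded <- list_rbind(map(seq_len(nrow(mapping)), function(i) {
    code <- mapping$atc_code[i]
    lens <- prefix_lengths[prefix_lengths <= nchar(code)]
    tibble(code = substring(code, 1, lens),
           level = match(lens, prefix_lengths),
           gene_id = mapping$gene_id[i])
  }))
  nodes <- expanded |>
    group_by(.data$code, .data$level) |>
    summarise(gene_set = list(sort(unique(.data$gene_id))), .groups = "drop") |>
    arrange(.data$code)
  nodes$parent <- vapply(seq_len(nrow(nodes)), function(i) {
    lvl <- nodes$level[i]
    if (lvl == 1) NA_character_ else
      substring(nodes$code[i], 1, prefix_lengths[lvl - 1])
  }, character(1))
  structure(nodes[, c("code", "level", "parent", "gene_set")],
            class = c("atc_tree", class(nodes)))
}

#' Fisher exact drug-class enrichment for one node
#'
#' Tests whether phenotype-associated genes (conventionally those at
#' q-value <= 0.05) are over-represented among the genes of one ATC node via
#' Fisher's exact test on the 2x2 table of association status by class
#' membership. The default is one-sided (enrichment); genes absent from the
#' ATC mapping count as out-of-class, and the node's gene set is intersected
#' with the universe.
#'
#' @param associated Character vector of associated gene ids (must be a
#'   subset of `universe`).
#' @param node_genes Character vector: the node's gene set.
#' @param universe Character vector of all genes tested for the phenotype.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return One-row tibble with the table counts `a` (associated, in class),
#'   `b` (associated, out of class), `c` (not associated, in class), `d`
#'   (neither) and the Fisher exact `p`.
#' @export
fisher_enrichment <- function(associated, node_genes, universe,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) abort("empty gene universe")
  if (!all(associated %in% universe)) {
    abort("`associated` must be a subset of `universe`")
  }
  node_genes <- intersect(node_genes, universe)
  a <- length(intersect(associated, node_genes))
  b <- length(setdiff(associated, node_genes))
  c <- length(setdiff(node_genes, associated))
  d <- length(universe) - a - b - c
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                          alternative = alternative)$p.value
  tibble(a = a, b = b, c = c, d = d, p = min(p, 1))
}

#' Drug-target enrichment over the ATC hierarchy
#'
#' Runs [fisher_enrichment()] at every node of an ATC tree and annotates each
#' node with the minimum p-value in the subtree rooted there (used to color
#' node strokes when the collapsed tree hides a significant descendant).
#'
#' @param tree An `atc_tree` from [build_atc_tree()].
#' @param associated Character vector of associated gene ids.
#' @param universe Character vector of all tested genes.
#' @param alternative Passed to [fisher_enrichment()].
#' @return The tree tibble augmented with `a`, `b`, `c`, `d`, `p` and
#'   `min_p_subtree` columns.
#' @export
atc_enrichment <- function(tree, associated, universe,
                           alternative = "greater") {
  stopifnot(inherits(tree, "atc_tree"))
  if (nrow(tree) == 0) return(tree)
  res <- list_rbind(map(tree$gene_set, function(gs) {
    fisher_enrichment(associated, gs, universe, alternative = alternative)
  }))
  out <- dplyr::bind_cols(tree, res)
  subtree_min_p(out)
}

#' Subtree minimum p-value propagation
#'
#' Sets `min_p_subtree` at each node to the minimum of its own p-value and
#' the `min_p_subtree` of its children (post-order over the hierarchy).
#'
#' @param results Node tibble with `code`, `level`, `parent`, `p` columns.
#' @return `results` with the `min_p_subtree` column added/updated.
#' @export
subtree_min_p <- function(results) {
  results <- as_tibble(results)
  results$min_p_subtree <- results$p
  for (lvl in sort(unique(results$level), decreasing = TRUE)) {
    if (lvl == 1) next
    at <- which(results$level == lvl)
    for (i in at) {
      pi <- match(results$parent[i], results$code)
      if (!is.na(pi)) {
        results$min_p_subtree[pi] <- min(results$min_p_subtree[pi],
                                         results$min_p_subtree[i])
      }
    }
  }
  results
}

#' Export an ATC enrichment table as a nested JSON tree
#'
#' @param results Annotated node tibble from [atc_enrichment()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_atc_json <- function(results, path) {
  as_node <- function(code) {
    i <- match(code, results$code)
    children <- results$code[!is.na(results$parent) &
                               results$parent == code]
    list(
      code = code,
      level = results$level[i],
      n_genes = length(results$gene_set[[i]]),
      a = results$a[i], b = results$b[i], c = results$c[i], d = results$d[i],
      p = results$p[i],
      min_p_subtree = results$min_p_subtree[i],
      children = map(children, as_node)
    )
  }
  roots <- results$code[is.na(results$parent)]
  jsonlite::write_json(map(roots, as_node), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Gene list for external ontology enrichment
#'
#' Pathway/ontology enrichment (KEGG, GO, HPO) is delegated to external
#' services; this adapter emits the associated-gene list only when more than
#' five genes are significantly associated, and never performs a remote call.
#'
#' @param results Association tibble with `gene_id` and `q` columns.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param min_genes Minimum significant-gene count to emit a list
#'   (default 5, exclusive).
#' @return Character vector of gene ids, or `NULL` (with a message) when the
#'   gate is not met.
#' @export
ontology_gene_list <- function(results, q_threshold = 0.05, min_genes = 5) {
  genes <- unique(results$gene_id[!is.na(results$q) &
                                    results$q <= q_threshold])
  if (length(genes) <= min_genes) {
    inform(sprintf(
      "only %d significant gene(s); ontology enrichment needs more than %d",
      length(genes), min_genes))
    return(invisible(NULL))
  }
  genes
}
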