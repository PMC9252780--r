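#' Read gene annotations
#'
#' Loads gene records from a GFF3 file or a seven-column TSV
#' (`gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`, `biotype`, with a
#' header row). Only protein-coding and lincRNA genes are retained; records of
#' any other biotype are skipped and their count reported in a message.
#'
#' Coordinates are 1-based and inclusive on both ends (Ensembl convention).
#'
#' @param path Path to the annotation file.
#' @param format Either `"tsv"` or `"gff3"`. Defaults to a guess from the file
#'   extension.
#' @return A tibble with one row per retained gene and columns `gene_id`,
#'   `symbol`, `chrom`, `start`, `end`, `strand`, `biotype`. The number of
#'   skipped records is stored in the `"n_skipped"` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "gene_id\tsymbol\tchrom\tstart\tend\tstrand\tbiotype",
#'   "ENSG1\tGENE1\t1\t10000\t20000\t+\tprotein_coding"
#' ), tf)
#' read_gene_annotations(tf)
read_gene_annotations <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  genes <- switch(format,
    tsv  = read_gene_tsv(path),
    gff3 = read_gene_gff3(path)
  )
  if (nrow(genes) == 0) {
    warn(paste0("no gene records read from ", path))
  }
  keep <- genes$biotype %in% allowed_biotypes()
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d record(s) with biotype outside {%s}",
                   n_skipped, paste(allowed_biotypes(), collapse = ", ")))
  }
  genes <- genes[keep, , drop = FALSE]
  validate_gene_regions(genes)
  attr(genes, "n_skipped") <- n_skipped
  genes
}

allowed_biotypes <- function() c("protein_coding", "lincRNA")

read_gene_tsv <- function(path) {
  genes <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      symbol  = readr::col_character(),
      chrom   = readr::col_character(),
      start   = readr::col_double(),
      end     = readr::col_double(),
      strand  = readr::col_character(),
      biotype = readr::col_character()
    ),
    progress = FALSE
  )
  required <- c("gene_id", "symbol", "chrom", "start", "end", "strand", "biotype")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation TSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(genes$start) | is.na(genes$end) | is.na(genes$gene_id))
  if (length(bad) > 0) {
    # +1 for the header row so the number matches the file
    abort(sprintf("malformed annotation row at line %d of %s", bad[1] + 1L, path))
  }
  genes[required]
}

read_gene_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  md <- as.data.frame(gr)
  biotype <- md[["biotype"]] %||% md[["gene_biotype"]] %||% md[["gene_type"]]
  if (is.null(biotype)) biotype <- rep(NA_character_, nrow(md))
  tibble(
    gene_id = as.character(md[["ID"]] %||% md[["gene_id"]]),
    symbol  = as.character(md[["Name"]] %||% md[["gene_id"]] %||% md[["ID"]]),
    chrom   = as.character(md$seqnames),
    start   = as.numeric(md$start),
    end     = as.numeric(md$end),
    strand  = as.character(md$strand),
    biotype = as.character(biotype)
  )
}

validate_gene_regions <- function(genes) {
  # the spec's strand symbols; tolerate the unicode minus found in some dumps
  genes$strand[genes$strand == "−"] <- "-"
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    abort(paste0("unknown strand symbol for gene(s): ",
                 paste(head(genes$gene_id[bad_strand], 5), collapse = ", ")))
  }
  if (any(genes$start > genes$end)) {
    abort("gene region with start > end")
  }
  invisible(genes)
}

#' Pad gene regions to variant-extraction intervals
#'
#' Expands each gene's boundaries into the genomic interval from which
#' variants are extracted. Protein-coding genes get strand-aware padding
#' (upstream = the transcription-start side, so a minus-strand gene is padded
#' upstream on its right/end side); lincRNA genes are never padded and keep
#' their annotated boundaries. Interval starts are clamped at position 1.
#'
#' Defaults add 2.5 kb per coding gene: 1.5 kb upstream and 1 kb downstream.
#'
#' @param genes A tibble of gene regions as returned by
#'   [read_gene_annotations()].
#' @param upstream_bp,downstream_bp Non-negative padding in base pairs.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` giving the
#'   padded interval of each input gene (1-based, inclusive).
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "ENSG1", symbol = "GENE1", chrom = "1",
#'   start = 10000, end = 20000, strand = "+", biotype = "protein_coding"
#' )
#' pad_region(genes) # 1:8500-21000
pad_region <- function(genes, upstream_bp = 1500, downstream_bp = 1000) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  genes <- validate_gene_regions(as_tibble(genes))
  coding <- genes$biotype == "protein_coding"
  plus <- genes$strand == "+"
  start <- genes$start -
    ifelse(coding, ifelse(plus, upstream_bp, downstream_bp), 0)
  end <- genes$end +
    ifelse(coding, ifelse(plus, downstream_bp, upstream_bp), 0)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(start, 1),
    end = end
  )
}
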