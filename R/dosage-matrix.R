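#' Construct a dosage matrix
#'
#' The central genotype container: a samples-by-variants matrix of additive
#' allele dosages in \[0, 2\] (`NA` marks a missing dosage) together with
#' per-variant metadata. Minor allele frequency and per-variant missing rate
#' are computed from the carried samples when not supplied.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param sample_ids Character vector of row identifiers.
#' @param variants Tibble with one row per column of `dosages`; must contain
#'   `variant_id`, and may contain `chrom`, `pos`, `ref`, `alt`, `maf`, `info`,
#'   `missing_rate`.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (nrow(dosages) != length(sample_ids)) {
    abort("number of rows of `dosages` must equal length of `sample_ids`")
  }
  if (ncol(dosages) != nrow(variants)) {
    abort("number of columns of `dosages` must equal rows of `variants`")
  }
  if (!"variant_id" %in% names(variants)) {
    abort("`variants` must have a `variant_id` column")
  }
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in [0, 2]")
  }
  dimnames(dosages) <- list(as.character(sample_ids), variants$variant_id)
  if (!"maf" %in% names(variants) || anyNA(variants$maf)) {
    variants$maf <- unname(compute_maf(dosages))
  }
  if (!"missing_rate" %in% names(variants) || anyNA(variants$missing_rate)) {
    variants$missing_rate <- unname(colMeans(is.na(dosages)))
  }
  if (!"info" %in% names(variants)) {
    variants$info <- NA_real_
  }
  structure(
    list(dosages = dosages, sample_ids = as.character(sample_ids),
         variants = variants),
    class = "dosage_matrix"
  )
}

compute_maf <- function(dosages) {
  if (ncol(dosages) == 0) return(numeric(0))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (ncol(x$dosages) > 0) {
    cat(sprintf("  MAF range: %.4g-%.4g; missing: %.3g%%\n",
                min(x$variants$maf, na.rm = TRUE),
                max(x$variants$maf, na.rm = TRUE),
                100 * mean(is.na(x$dosages))))
  }
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Coerce a dosage matrix to a long tibble
#'
#' @param x A `dosage_matrix`.
#' @param ... Unused.
#' @method as_tibble dosage_matrix
#' @export
as_tibble.dosage_matrix <- function(x, ...) {
  as_tibble(x$dosages, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "variant_id",
                        values_to = "dosage")
}

#' Read genotype dosages for a genomic region
#'
#' Extracts additive dosages for all variants falling inside `region`
#' (1-based inclusive: `start <= pos <= end`). Two dialects are supported:
#' VCF with a per-sample dosage FORMAT field (default `DS`), and a TSV dosage
#' matrix (`sample_id` column plus one column per variant) with a sidecar
#' per-variant metadata TSV (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#' `maf`, `info`).
#'
#' For VCF input the imputation info score is taken from the INFO key named by
#' `info_key`, falling back to `R2`; absent keys leave `info` as `NA`. MAF and
#' missing rate are recomputed from the extracted samples unless supplied in
#' metadata.
#'
#' @param path Genotype file (VCF, possibly bgzipped, or dosage TSV).
#' @param region One-row data frame (or list) with `chrom`, `start`, `end`,
#'   e.g. one row of [pad_region()] output. `NULL` keeps every variant.
#' @param format `"vcf"` or `"tsv"` (guessed from the extension by default).
#' @param meta_path Sidecar variant metadata TSV (required for TSV input).
#' @param dosage_key VCF FORMAT key carrying the dosage (default `"DS"`).
#' @param info_key VCF INFO key carrying the imputation quality score.
#' @return A [dosage_matrix()].
#' @export
read_dosages <- function(path, region = NULL, format = c("auto", "vcf", "tsv"),
                         meta_path = NULL, dosage_key = "DS",
                         info_key = "INFO") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "tsv"
  }
  dm <- switch(format,
    vcf = read_dosages_vcf(path, dosage_key, info_key),
    tsv = read_dosages_tsv(path, meta_path)
  )
  if (!is.null(region)) {
    region <- as.list(as.data.frame(region)[1, ])
    keep <- dm$variants$chrom == as.character(region$chrom) &
      dm$variants$pos >= region$start & dm$variants$pos <= region$end
    dm <- subset_dosage_matrix(dm, variants = which(keep))
  }
  dm
}

read_dosages_vcf <- function(path, dosage_key, info_key) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  fmt <- as.character(vcf@gt[, "FORMAT"])
  has_key <- vapply(strsplit(fmt, ":", fixed = TRUE),
                    function(keys) dosage_key %in% keys, logical(1))
  if (any(!has_key)) {
    abort(sprintf("variant %s has no %s dosage field",
                  ids[which(!has_key)[1]], dosage_key))
  }
  ds <- vcfR::extract.gt(vcf, element = dosage_key, as.numeric = TRUE)
  # vcfR returns variants x samples; transpose to samples x variants
  ds <- t(ds)
  info <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = info_key))
  )
  if (all(is.na(info))) {
    info <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "R2")))
  }
  variants <- tibble(
    variant_id = ids,
    chrom = as.character(fix$CHROM),
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    info = if (length(info) == n_var) info else NA_real_
  )
  dosage_matrix(ds, rownames(ds), variants)
}

read_dosages_tsv <- function(path, meta_path) {
  if (is.null(meta_path)) {
    abort("TSV dosage input requires `meta_path` (per-variant metadata)")
  }
  dos <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    variant_id = readr::col_character(), chrom = readr::col_character(),
    .default = readr::col_double(), ref = readr::col_character(),
    alt = readr::col_character()
  ), progress = FALSE)
  vid <- setdiff(names(dos), "sample_id")
  missing_meta <- setdiff(vid, meta$variant_id)
  if (length(missing_meta) > 0) {
    abort(paste0("variants missing from metadata: ",
                 paste(head(missing_meta, 5), collapse = ", ")))
  }
  meta <- meta[match(vid, meta$variant_id), ]
  dosage_matrix(as.matrix(dos[vid]), dos$sample_id, meta)
}

#' Write a dosage matrix to the TSV dialect
#'
#' Writes the dosage TSV (`sample_id` + one column per variant) and the
#' sidecar per-variant metadata TSV read back by [read_dosages()].
#'
#' @param dm A `dosage_matrix`.
#' @param path Output dosage TSV path.
#' @param meta_path Output metadata TSV path.
#' @return `dm`, invisibly.
#' @export
write_dosages_tsv <- function(dm, path, meta_path) {
  out <- as_tibble(dm$dosages)
  out <- dplyr::bind_cols(tibble(sample_id = dm$sample_ids), out)
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(dm$variants, meta_path, progress = FALSE)
  invisible(dm)
}

subset_dosage_matrix <- function(dm, samples = NULL, variants = NULL) {
  if (!is.null(variants)) {
    dm$dosages <- dm$dosages[, variants, drop = FALSE]
    dm$variants <- dm$variants[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    dm$dosages <- dm$dosages[samples, , drop = FALSE]
    dm$sample_ids <- dm$sample_ids[samples]
    # per-variant statistics refer to the carried samples
    dm$variants$maf <- compute_maf(dm$dosages)
    dm$variants$missing_rate <- colMeans(is.na(dm$dosages))
  }
  dm
}

#' Variant quality-control filter
#'
#' Keeps variants with minor allele frequency and imputation info score at or
#' above the thresholds (inclusive) and per-variant missing rate at or below
#' `missing_max`. Variants with an unknown (`NA`) info score pass the info
#' filter. Column order is preserved.
#'
#' @param dm A `dosage_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param info_min Minimum imputation info score (default 0.6).
#' @param missing_max Maximum per-variant missing fraction (default 0.02;
#'   variants with a strictly greater rate are excluded).
#' @return A filtered `dosage_matrix` (possibly with zero variants).
#' @export
filter_variants <- function(dm, maf_min = 0.01, info_min = 0.6,
                            missing_max = 0.02) {
  stopifnot(inherits(dm, "dosage_matrix"))
  v <- dm$variants
  info_ok <- is.na(v$info) | v$info >= info_min
  keep <- info_ok & !is.na(v$maf) & v$maf >= maf_min &
    v$missing_rate <= missing_max
  subset_dosage_matrix(dm, variants = which(keep))
}

#' Sample missingness filter
#'
#' Removes samples whose fraction of missing dosages strictly exceeds
#' `missing_max`. Row order is preserved.
#'
#' @inheritParams filter_variants
#' @param missing_max Maximum tolerated missing fraction per sample
#'   (default 0.02).
#' @return A filtered `dosage_matrix`.
#' @export
filter_samples_missingness <- function(dm, missing_max = 0.02) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (ncol(dm$dosages) == 0) return(dm)
  rate <- rowMeans(is.na(dm$dosages))
  subset_dosage_matrix(dm, samples = which(rate <= missing_max))
}

#' Prune related samples
#'
#' Builds the relatedness graph whose edges are kinship pairs with coefficient
#' at or above `threshold` (0.0884 by default, the conventional third-degree
#' cutoff) and iteratively removes the node of highest degree — ties broken by
#' a seeded random choice — until no edges remain. This degree-peeling keeps
#' more samples than removing one member of every pair independently, and is
#' deterministic given `seed`.
#'
#' @param pairs Tibble/data frame with columns `id1`, `id2` and a kinship
#'   coefficient column (named `kinship` or `coefficient`).
#' @param samples Character vector of candidate sample ids.
#' @param threshold Kinship coefficient at or above which a pair counts as
#'   related (default 0.0884).
#' @param seed Integer seed for tie-breaking.
#' @return Character vector of retained sample ids (a subset of `samples`,
#'   original order preserved).
#' @export
prune_related <- function(pairs, samples, threshold = 0.0884, seed = 1L) {
  stopifnot(threshold >= 0)
  samples <- as.character(samples)
  pairs <- as_tibble(pairs)
  coef_col <- intersect(c("kinship", "coefficient"), names(pairs))[1]
  if (is.na(coef_col)) abort("`pairs` needs a `kinship` or `coefficient` column")
  pairs <- pairs[pairs[[coef_col]] >= threshold, , drop = FALSE]
  known <- pairs$id1 %in% samples & pairs$id2 %in% samples
  if (any(!known)) {
    warn(sprintf("%d kinship pair(s) reference unknown sample ids; ignored",
                 sum(!known)))
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(samples)

  g <- igraph::graph_from_data_frame(
    pairs[, c("id1", "id2")], directed = FALSE,
    vertices = unique(c(pairs$id1, pairs$id2))
  )
  dropped <- character(0)
  withr::with_seed(seed, {
    while (igraph::ecount(g) > 0) {
      deg <- igraph::degree(g)
      top <- names(deg)[deg == max(deg)]
      victim <- if (length(top) == 1) top else sample(top, 1)
      dropped <- c(dropped, victim)
      g <- igraph::delete_vertices(g, victim)
    }
  })
  setdiff(samples, dropped)
}
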