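#' Per-gene principal components of genotype dosages
#'
#' Computes a compact representation of the genetic variability in a gene
#' region: missing dosages are mean-imputed per variant, columns are centered
#' (not variance-scaled), and a full singular value decomposition yields the
#' principal components. The smallest number `k` of leading components whose
#' cumulative explained-variance ratio reaches `variance_retained` is kept;
#' the per-sample projection on those components is the gene's score matrix
#' used by the association and Mendelian-randomization stages.
#'
#' Each loading column is oriented so that its largest-magnitude entry is
#' positive, making serialized components stable across runs. The
#' decomposition is deterministic; `seed` is accepted for signature stability
#' with randomized solvers but is unused.
#'
#' @param dm A [dosage_matrix()] that has passed quality control.
#' @param variance_retained Target fraction of variance to retain
#'   (default 0.95).
#' @param gene_id Optional gene identifier carried into the result.
#' @param seed Unused; reserved for randomized solvers.
#' @return An object of class `gene_pcs` with elements `gene_id`, `loadings`
#'   (variants x k, orthonormal columns), `explained_variance_ratio`
#'   (length k), `scores` (samples x k), `variance_retained_target`, and
#'   `variant_means` (length m centering vector).
#' @export
compute_gene_pcs <- function(dm, variance_retained = 0.95, gene_id = NULL,
                             seed = NULL) {
  stopifnot(inherits(dm, "dosage_matrix"))
  stopifnot(variance_retained > 0, variance_retained <= 1)
  x <- dm$dosages
  if (ncol(x) == 0) abort("no variants in region")
  if (nrow(x) < 2) abort("need at least 2 samples for PCA")

  x <- mean_impute(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  col_var <- apply(xc, 2, var)
  if (all(col_var == 0)) abort("no genetic variance in region")

  sv <- svd(xc)
  d2 <- sv$d^2
  # drop numerically-null directions so ratios stay in (0, 1]
  tol <- max(d2) * 1e-12
  r <- sum(d2 > tol)
  d2 <- d2[seq_len(r)]
  evr <- d2 / sum(d2)
  k <- which(cumsum(evr) >= variance_retained - 1e-12)[1]
  if (is.na(k)) k <- r

  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  dimnames(loadings) <- list(dm$variants$variant_id, paste0("PC", seq_len(k)))

  scores <- xc %*% loadings
  dimnames(scores) <- list(dm$sample_ids, paste0("PC", seq_len(k)))

  structure(
    list(
      gene_id = gene_id %||% "gene",
      loadings = loadings,
      explained_variance_ratio = evr[seq_len(k)],
      scores = scores,
      variance_retained_target = variance_retained,
      variant_means = setNames(mu, dm$variants$variant_id)
    ),
    class = "gene_pcs"
  )
}

mean_impute <- function(x) {
  if (!anyNA(x)) return(x)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[!miss, j])
  }
  x
}

#' @export
print.gene_pcs <- function(x, ...) {
  cat(sprintf(
    "<gene_pcs> %s: %d PCs over %d variants (%.1f%% variance, target %.0f%%)\n",
    x$gene_id, ncol(x$loadings), nrow(x$loadings),
    100 * sum(x$explained_variance_ratio),
    100 * x$variance_retained_target))
  invisible(x)
}

#' @describeIn compute_gene_pcs One row per retained component: index,
#'   explained-variance ratio and its cumulative sum.
#' @param x A `gene_pcs` object.
#' @param ... Unused.
#' @method tidy gene_pcs
#' @export
tidy.gene_pcs <- function(x, ...) {
  tibble(
    pc = seq_along(x$explained_variance_ratio),
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @describeIn compute_gene_pcs One-row summary (gene, k, variants, variance
#'   retained).
#' @method glance gene_pcs
#' @export
glance.gene_pcs <- function(x, ...) {
  tibble(
    gene_id = x$gene_id,
    n_pcs = ncol(x$loadings),
    n_variants = nrow(x$loadings),
    n_samples = nrow(x$scores),
    variance_retained = sum(x$explained_variance_ratio),
    variance_retained_target = x$variance_retained_target
  )
}

#' Project dosages onto stored gene principal components
#'
#' Centers the (mean-imputed) dosages with the means stored at fit time and
#' multiplies by the stored loadings. Projecting the training matrix
#' reproduces the stored scores exactly.
#'
#' @param dm A [dosage_matrix()] whose variants match `pcs` (same ids, same
#'   order).
#' @param pcs A `gene_pcs` object from [compute_gene_pcs()].
#' @return Samples x k numeric score matrix.
#' @export
project_gene_pcs <- function(dm, pcs) {
  stopifnot(inherits(dm, "dosage_matrix"), inherits(pcs, "gene_pcs"))
  want <- rownames(pcs$loadings)
  have <- dm$variants$variant_id
  if (!identical(have, want)) {
    missing <- setdiff(want, have)
    extra <- setdiff(have, want)
    abort(paste0(
      "variant mismatch between dosages and loadings",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))
    ))
  }
  x <- mean_impute(dm$dosages)
  xc <- sweep(x, 2, pcs$variant_means, "-")
  scores <- xc %*% pcs$loadings
  rownames(scores) <- dm$sample_ids
  scores
}

#' Serialize gene principal components
#'
#' Writes scores and loadings as TSV plus a JSON sidecar carrying the gene id,
#' explained-variance ratios, retention target and centering means.
#'
#' @param pcs A `gene_pcs` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_gene_pcs <- function(pcs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(tibble(sample_id = rownames(pcs$scores)),
                     as_tibble(pcs$scores)),
    file.path(dir, paste0(pcs$gene_id, "_scores.tsv")), progress = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(tibble(variant_id = rownames(pcs$loadings)),
                     as_tibble(pcs$loadings)),
    file.path(dir, paste0(pcs$gene_id, "_loadings.tsv")), progress = FALSE)
  jsonlite::write_json(
    list(gene_id = pcs$gene_id,
         explained_variance_ratio = pcs$explained_variance_ratio,
         variance_retained_target = pcs$variance_retained_target,
         variant_means = as.list(pcs$variant_means)),
    file.path(dir, paste0(pcs$gene_id, "_pcs.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
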