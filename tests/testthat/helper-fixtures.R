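# In-code fixtures and independent oracles shared across test files.

make_genes <- function() {
  tibble::tribble(
    ~gene_id, ~symbol, ~chrom, ~start, ~end, ~strand, ~biotype,
    "ENSG1", "GENE1", "1", 10000, 20000, "+", "protein_coding",
    "ENSG2", "GENE2", "1", 10000, 20000, "-", "protein_coding",
    "ENSG3", "GENE3", "2", 500, 900, "+", "lincRNA",
    "ENSG4", "GENE4", "3", 800, 2000, "+", "protein_coding"
  )
}

write_gene_tsv <- function(genes, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(genes, path, progress = FALSE)
  path
}

# Minimal VCF with a DS FORMAT field and an INFO score per record.
write_test_vcf <- function(path = tempfile(fileext = ".vcf"),
                           drop_ds_at = integer(0)) {
  records <- list(
    list(chrom = "1", pos = 9000, id = "rs1", info = 0.95,
         ds = c(0.1, 1.0, 2.0)),
    list(chrom = "1", pos = 15000, id = "rs2", info = 0.80,
         ds = c(1.0, 0.0, 1.5)),
    list(chrom = "1", pos = 25000, id = "rs3", info = 0.99,
         ds = c(0.0, 0.5, 1.0))
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3"
  )
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (i %in% drop_ds_at) {
      fmt <- "GT"
      smp <- rep("0/1", 3)
    } else {
      fmt <- "GT:DS"
      smp <- paste0("0/1:", r$ds)
    }
    lines <- c(lines, paste(c(r$chrom, r$pos, r$id, "A", "G", ".", "PASS",
                              paste0("INFO=", r$info), fmt, smp),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Exact one-sided hypergeometric tail P(X >= a) by direct enumeration.
oracle_hyper_tail <- function(a, b, c, d) {
  n_assoc <- a + b
  n_class <- a + c
  total <- a + b + c + d
  x_max <- min(n_assoc, n_class)
  if (a > x_max) return(0)
  sum(vapply(a:x_max, function(x) {
    exp(lchoose(n_class, x) + lchoose(total - n_class, n_assoc - x) -
          lchoose(total, n_assoc))
  }, numeric(1)))
}

# Direct Bernoulli log-likelihood at a fitted logistic solution.
oracle_bernoulli_loglik <- function(y, X, coef) {
  eta <- drop(X %*% coef)
  sum(y * eta - log1p(exp(eta)))
}

# Dosage matrix with exact prescribed singular values after centering:
# column-orthonormal U orthogonal to the ones vector times diag(d) times a
# random orthogonal V, shifted into [0, 2].
make_exact_sv_dm <- function(n, d, seed = 11) {
  withr::with_seed(seed, {
    m <- length(d)
    A <- cbind(1, matrix(rnorm(n * m), n, m))
    Q <- qr.Q(qr(A))
    U <- Q[, 2:(m + 1), drop = FALSE]
    V <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
    X <- U %*% diag(d, m) %*% t(V)
    stopifnot(max(abs(X)) < 1)  # keep dosages in range after the +1 shift
    dosage_matrix(X + 1, sprintf("S%d", seq_len(n)),
                  tibble::tibble(variant_id = sprintf("v%d", seq_len(m))))
  })
}

rand_dm <- function(n, m, seed, ld_rho = 0.3) {
  simulate_genotypes(n, m, ld_rho = ld_rho, seed = seed)
}
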