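#' Simulate an LD-structured dosage matrix
#'
#' Draws two haplotypes per sample from a latent Gaussian AR(1) process with
#' adjacent-site correlation `ld_rho`, thresholded at each variant's
#' allele-frequency quantile, and sums them into additive dosages in
#' \{0, 1, 2\}. One knob controls linkage disequilibrium; the model aims for
#' the statistical structure association tests assume, not population-genetic
#' realism. Optional imputation noise shrinks dosages toward their
#' expectation `2*maf` by a per-variant factor `sqrt(info)`, so the
#' synthetic info score (empirical dosage variance over the binomial
#' expectation `2*maf*(1-maf)`) is a monotone analogue of release metadata. Deterministic given `seed`.
#'
#' @param n_samples,n_variants Matrix dimensions.
#' @param maf Per-variant minor allele frequencies: a single value, a vector
#'   of length `n_variants`, or `NULL` to draw from Uniform(0.01, 0.5).
#' @param ld_rho Adjacent-variant latent correlation in \[0, 1).
#' @param info Per-variant target info scores in (0, 1\]; 1 (default) leaves
#'   dosages hard calls.
#' @param missing_rate Fraction of entries set missing at random (default 0).
#' @param chrom,pos_start,pos_step Variant coordinates written into the
#'   metadata.
#' @param seed Integer seed (mandatory).
#' @return A [dosage_matrix()] whose variant table carries the realized
#'   `maf`, `info` and coordinates.
#' @export
simulate_genotypes <- function(n_samples, n_variants, maf = NULL,
                               ld_rho = 0.6, info = 1, missing_rate = 0,
                               chrom = "1", pos_start = 10000L,
                               pos_step = 500L, seed) {
  stopifnot(ld_rho >= 0, ld_rho < 1, missing_rate >= 0, missing_rate < 1)
  if (missing(seed)) abort("`seed` is mandatory")
  withr::with_seed(seed, {
    maf <- if (is.null(maf)) runif(n_variants, 0.01, 0.5) else
      rep_len(maf, n_variants)
    stopifnot(all(maf > 0), all(maf <= 0.5))
    info <- rep_len(info, n_variants)
    stopifnot(all(info > 0), all(info <= 1))

    thresholds <- qnorm(maf)
    hap <- function() {
      z <- matrix(rnorm(n_samples * n_variants), n_samples, n_variants)
      if (ld_rho > 0 && n_variants > 1) {
        for (j in 2:n_variants) {
          z[, j] <- ld_rho * z[, j - 1] + sqrt(1 - ld_rho^2) * z[, j]
        }
      }
      sweep(z, 2, thresholds, "<") * 1
    }
    dos <- hap() + hap()

    if (any(info < 1)) {
      # shrink toward the expected dosage 2*maf: variance -> info * 2maf(1-maf)
      expect <- matrix(2 * maf, n_samples, n_variants, byrow = TRUE)
      lam <- matrix(sqrt(info), n_samples, n_variants, byrow = TRUE)
      dos <- expect + lam * (dos - expect)
      dos <- pmin(pmax(dos, 0), 2)
    }

    if (missing_rate > 0) {
      dos[runif(length(dos)) < missing_rate] <- NA_real_
    }

    emp_var <- apply(dos, 2, var, na.rm = TRUE)
    info_emp <- pmin(emp_var / (2 * maf * (1 - maf)), 1)
    variants <- tibble(
      variant_id = sprintf("var%03d", seq_len(n_variants)),
      chrom = chrom,
      pos = pos_start + pos_step * (seq_len(n_variants) - 1L),
      ref = "A", alt = "G",
      info = info_emp
    )
    dosage_matrix(dos, sprintf("S%05d", seq_len(n_samples)), variants)
  })
}

#' Simulate a phenotype with covariate confounding
#'
#' Builds an age-like and a sex-like covariate, adds causal-variant genetic
#' effects scaled so the genetic component explains `heritability` of the
#' total phenotypic variance, and returns either the continuous trait or a
#' binary trait from thresholding the liability at the `prevalence` quantile.
#'
#' @param dm A [dosage_matrix()].
#' @param kind `"continuous"` or `"binary"`.
#' @param heritability Fraction of phenotypic variance explained by the
#'   causal variants, in \[0, 1) (default 0.2).
#' @param n_causal Number of causal variants (default 3; 0 gives a null
#'   trait). Ignored when `causal_idx` is given.
#' @param causal_idx Optional explicit causal variant column indices.
#' @param prevalence Case fraction for binary traits (default 0.1).
#' @param covariate_beta Length-2 effects of (age, sex) on the trait, on the
#'   standardized-covariate scale (default `c(0.3, 0.2)`).
#' @param seed Integer seed (mandatory).
#' @return A list: `data` (tibble with `sample_id`, `age`, `sex` and the
#'   phenotype column `y`), `phenotypes` (one-row spec tibble usable by
#'   [run_phewas()]), and `truth` (causal indices, effect sizes, realized
#'   genetic-variance fraction).
#' @export
simulate_phenotype <- function(dm, kind = c("continuous", "binary"),
                               heritability = 0.2, n_causal = 3,
                               causal_idx = NULL, prevalence = 0.1,
                               covariate_beta = c(0.3, 0.2), seed) {
  kind <- match.arg(kind)
  if (missing(seed)) abort("`seed` is mandatory")
  if (heritability < 0 || heritability >= 1) {
    abort("heritability must lie in [0, 1)")
  }
  withr::with_seed(seed, {
    n <- length(dm$sample_ids)
    m <- ncol(dm$dosages)
    age <- rnorm(n, 55, 8)
    sex <- rbinom(n, 1, 0.5)

    causal_idx <- causal_idx %||% if (n_causal > 0)
      sort(sample.int(m, min(n_causal, m))) else integer(0)
    g <- if (length(causal_idx) > 0) {
      betas <- rnorm(length(causal_idx))
      drop(mean_impute(dm$dosages[, causal_idx, drop = FALSE]) %*% betas)
    } else {
      betas <- numeric(0)
      rep(0, n)
    }

    cov_part <- covariate_beta[1] * scale(age)[, 1] +
      covariate_beta[2] * scale(sex)[, 1]
    var_g <- var(g)
    if (heritability > 0 && var_g > 0) {
      # scale genetic + noise so the genetic share of their variance is h2
      g <- g * sqrt(heritability / var_g)
      e <- rnorm(n, sd = sqrt(1 - heritability))
    } else {
      g <- rep(0, n)
      e <- rnorm(n)
    }
    liability <- cov_part + g + e
    realized_h2 <- var(g) / var(g + e)

    if (kind == "binary") {
      y <- as.integer(liability > quantile(liability, 1 - prevalence))
      ph_kind <- "binary"
    } else {
      y <- liability
      ph_kind <- "continuous"
    }
    list(
      data = tibble(sample_id = dm$sample_ids, age = age, sex = sex, y = y),
      phenotypes = tibble(name = "y", kind = ph_kind),
      truth = list(causal_idx = causal_idx, betas = betas,
                   realized_h2 = realized_h2, heritability = heritability,
                   prevalence = if (kind == "binary") prevalence else NA_real_)
    )
  })
}

#' Simulate a Mendelian-randomization scenario
#'
#' Generates the gene-to-exposure-to-outcome causal chain under valid
#' instrumental-variable assumptions: causal variants in the gene region
#' drive a continuous exposure with variance share `exposure_h2`
#' (first-stage strength), and the outcome is `causal_beta` times the
#' exposure plus independent noise. A nonzero `pleiotropy` adds a direct
#' genetic path to the outcome, violating the exclusion restriction for
#' sensitivity studies.
#'
#' @param n_samples,n_variants,ld_rho Passed to [simulate_genotypes()].
#' @param causal_beta True causal effect of exposure on outcome
#'   (default 0.5).
#' @param exposure_h2 Variance in the exposure explained by the gene
#'   (default 0.1).
#' @param n_causal Causal variant count (default 3).
#' @param pleiotropy Direct genetic effect on the outcome, as a fraction of
#'   the genetic exposure component added straight to the outcome
#'   (default 0).
#' @param binary_outcome Make the outcome binary via a logistic model
#'   (default `FALSE`).
#' @param seed Integer seed (mandatory).
#' @return A list: `dm`, `data` (tibble with `sample_id`, `age`, `sex`,
#'   `exposure`, `outcome`), `true_beta`, and `truth` (causal indices and
#'   components).
#' @export
simulate_mr_scenario <- function(n_samples = 5000, n_variants = 20,
                                 ld_rho = 0.4, causal_beta = 0.5,
                                 exposure_h2 = 0.1, n_causal = 3,
                                 pleiotropy = 0, binary_outcome = FALSE,
                                 seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  dm <- simulate_genotypes(n_samples, n_variants, ld_rho = ld_rho,
                           seed = seed)
  withr::with_seed(seed + 1L, {
    n <- n_samples
    age <- rnorm(n, 55, 8)
    sex <- rbinom(n, 1, 0.5)
    causal_idx <- sort(sample.int(n_variants, min(n_causal, n_variants)))
    g <- drop(dm$dosages[, causal_idx, drop = FALSE] %*%
                rnorm(length(causal_idx)))
    g <- (g - mean(g)) / sd(g) * sqrt(exposure_h2)
    exposure <- g + 0.1 * scale(age)[, 1] +
      rnorm(n, sd = sqrt(1 - exposure_h2))

    direct <- pleiotropy * g
    if (binary_outcome) {
      eta <- -2 + causal_beta * exposure + direct
      outcome <- rbinom(n, 1, stats::plogis(eta))
    } else {
      outcome <- causal_beta * exposure + direct + rnorm(n)
    }
    list(
      dm = dm,
      data = tibble(sample_id = dm$sample_ids, age = age, sex = sex,
                    exposure = exposure, outcome = outcome),
      true_beta = causal_beta,
      truth = list(causal_idx = causal_idx, exposure_h2 = exposure_h2,
                   pleiotropy = pleiotropy)
    )
  })
}

#' Simulate a p-value mixture with truth labels
#'
#' Null p-values are Uniform(0, 1); non-null p-values are two-sided normal
#' tail probabilities of draws from Normal(`effect_shift`, 1). Drives
#' false-discovery-rate calibration checks.
#'
#' @param m_tests Number of tests.
#' @param frac_nonnull Fraction of non-null tests in \[0, 1\].
#' @param effect_shift Mean shift of the non-null z-scores (default 3).
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `p` and `nonnull` (logical truth labels).
#' @export
simulate_pvalue_mixture <- function(m_tests, frac_nonnull = 0.1,
                                    effect_shift = 3, seed) {
  stopifnot(frac_nonnull >= 0, frac_nonnull <= 1)
  if (missing(seed)) abort("`seed` is mandatory")
  withr::with_seed(seed, {
    n_alt <- round(m_tests * frac_nonnull)
    n_null <- m_tests - n_alt
    p_null <- runif(n_null)
    z_alt <- rnorm(n_alt, mean = effect_shift)
    p_alt <- 2 * pnorm(abs(z_alt), lower.tail = FALSE)
    out <- tibble(
      p = c(p_null, p_alt),
      nonnull = rep(c(FALSE, TRUE), c(n_null, n_alt))
    )
    out[sample.int(m_tests), ]
  })
}

#' Simulate kinship pairs
#'
#' Generates related pairs at a given rate among a sample set (coefficients
#' near standard degrees of relatedness) plus unrelated background pairs,
#' for exercising relatedness pruning.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_related Number of related pairs (coefficient drawn from
#'   \{0.25, 0.125, 0.0884\} with jitter upward).
#' @param n_unrelated Number of background pairs with coefficients below the
#'   third-degree cutoff.
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `id1`, `id2`, `kinship`.
#' @export
simulate_kinship_pairs <- function(sample_ids, n_related = 10,
                                   n_unrelated = 20, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  withr::with_seed(seed, {
    draw_pair <- function(k) {
      if (k == 0) return(tibble(id1 = character(), id2 = character()))
      idx <- replicate(k, sample(seq_along(sample_ids), 2))
      tibble(id1 = sample_ids[idx[1, ]], id2 = sample_ids[idx[2, ]])
    }
    rel <- draw_pair(n_related)
    rel$kinship <- sample(c(0.25, 0.125, 0.0884), n_related, replace = TRUE) +
      runif(n_related, 0, 0.01)
    unrel <- draw_pair(n_unrelated)
    unrel$kinship <- runif(n_unrelated, 0, 0.08)
    out <- bind_rows(rel, unrel)
    out[out$id1 != out$id2, ]
  })
}
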