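#' Nested-model F statistic
#'
#' The gene-based association statistic for continuous outcomes compares a
#' null model (covariates only) with a full model that adds the gene's PC
#' scores:
#' \deqn{F = \frac{(RSS_1 - RSS_2)/(|P_2| - |P_1|)}{RSS_2/(n - |P_2|)}}
#' which under the null follows an F distribution with
#' (|P2| - |P1|, n - |P2|) degrees of freedom. Parameter counts include the
#' intercept, so the numerator degrees of freedom equal the number of added
#' PCs.
#'
#' @param rss1,rss2 Residual sums of squares of the null and full model
#'   (`rss2 <= rss1` for nested least squares).
#' @param p1,p2 Parameter counts of the null and full model (`p1 < p2 < n`).
#' @param n Sample count.
#' @return A list with `statistic`, `df1`, `df2`. A saturated-fit
#'   `rss2 = 0` yields `statistic = Inf`.
#' @export
#' @examples
#' f_statistic(100, 50, 3, 8, 108) # F = 20, df = (5, 100)
f_statistic <- function(rss1, rss2, p1, p2, n) {
  if (p2 >= n) abort("saturated model: p2 >= n")
  if (p1 >= p2) abort("models are not nested: need p1 < p2")
  stopifnot(rss1 >= 0, rss2 >= 0)
  df1 <- p2 - p1
  df2 <- n - p2
  stat <- if (rss2 == 0) Inf else ((rss1 - rss2) / df1) / (rss2 / df2)
  list(statistic = max(stat, 0), df1 = df1, df2 = df2)
}

# Design-matrix assembly with rank check; intercept always first column.
build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  covariates <- as.matrix(covariates)
  X <- cbind("(Intercept)" = 1, covariates)
  X
}

assert_full_rank <- function(X, context = "design") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient ", context, "; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(qrX)
}

rss_of <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Gene association test for a continuous phenotype
#'
#' Fits the covariates-only null model and the full model adding the k gene
#' PC scores by least squares, and tests the gain in fit with the nested
#' [f_statistic()]. The p-value comes from the upper tail of the
#' F(k, n - |P2|) distribution.
#'
#' @param scores Samples x k matrix of gene PC scores (rows named by sample
#'   id), or a `gene_pcs` object.
#' @param y Numeric outcome vector aligned with the rows of `scores`
#'   (missing values allowed; complete-case analysis).
#' @param covariates Optional numeric matrix/data frame of covariates aligned
#'   with `scores` (no intercept column; one is added).
#' @param gene_id,phenotype_name Labels carried into the result.
#' @return One-row tibble: `gene_id`, `phenotype_name`, `test`, `statistic`,
#'   `df1`, `df2`, `n`, `n_pcs`, `p`, `converged`.
#' @export
test_gene_continuous <- function(scores, y, covariates = NULL,
                                 gene_id = NULL, phenotype_name = "trait") {
  if (inherits(scores, "gene_pcs")) {
    gene_id <- gene_id %||% scores$gene_id
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  k <- ncol(scores)
  stopifnot(k >= 1)
  cc <- stats::complete.cases(y, scores,
                              if (!is.null(covariates)) as.matrix(covariates))
  y <- y[cc]
  scores <- scores[cc, , drop = FALSE]
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[cc, , drop = FALSE]
  n <- length(y)

  X0 <- build_design(covariates, n)
  X1 <- cbind(X0, scores)
  if (n < ncol(X1) + 1) abort("too few complete cases for the full model")
  assert_full_rank(X1, "full-model design")

  rss1 <- rss_of(y, X0)
  rss2 <- rss_of(y, X1)
  rss2 <- min(rss2, rss1)  # guard against sign of rounding noise
  fs <- f_statistic(rss1, rss2, ncol(X0), ncol(X1), n)
  p <- stats::pf(fs$statistic, fs$df1, fs$df2, lower.tail = FALSE)
  tibble(
    gene_id = gene_id %||% "gene", phenotype_name = phenotype_name,
    test = "f_test", statistic = fs$statistic,
    df1 = fs$df1, df2 = fs$df2, n = n, n_pcs = k,
    p = max(p, .Machine$double.xmin), converged = TRUE
  )
}

# Logistic IRLS via stats::glm.fit with the scan's convergence policy:
# max 25 iterations, deviance tolerance 1e-8, separation flagged when any
# coefficient exceeds 30 on the logit scale.
fit_logistic <- function(y, X, maxit = 25, epsilon = 1e-8) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)
  ))
  converged <- isTRUE(fit$converged) &&
    all(abs(fit$coefficients[!is.na(fit$coefficients)]) <= 30)
  list(deviance = fit$deviance, converged = converged,
       coefficients = fit$coefficients)
}

#' Gene association test for a binary phenotype (analysis of deviance)
#'
#' Fits nested logistic regressions by iteratively reweighted least squares.
#' The statistic is the drop in deviance from the null (covariates-only)
#' model to the full model adding the k gene PC scores, which under the null
#' follows a chi-squared distribution with k degrees of freedom; this equals
#' twice the log-likelihood gain, i.e. the likelihood-ratio test.
#' Non-convergence or separation (any coefficient beyond 30 on the logit
#' scale) flags the result and sets the p-value to `NA`.
#'
#' @inheritParams test_gene_continuous
#' @param y Binary (0/1) outcome vector; both classes must be present among
#'   complete cases.
#' @export
test_gene_binary <- function(scores, y, covariates = NULL,
                             gene_id = NULL, phenotype_name = "trait") {
  if (inherits(scores, "gene_pcs")) {
    gene_id <- gene_id %||% scores$gene_id
    scores <- scores$scores
  }
  scores <- as.matrix(scores)
  k <- ncol(scores)
  stopifnot(k >= 1)
  cc <- stats::complete.cases(y, scores,
                              if (!is.null(covariates)) as.matrix(covariates))
  y <- y[cc]
  if (!all(y %in% c(0, 1))) abort("binary phenotype must be coded 0/1")
  if (length(unique(y)) < 2) abort("degenerate phenotype: single outcome class")
  scores <- scores[cc, , drop = FALSE]
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[cc, , drop = FALSE]
  n <- length(y)

  X0 <- build_design(covariates, n)
  X1 <- cbind(X0, scores)
  assert_full_rank(X1, "full-model design")

  f0 <- fit_logistic(y, X0)
  f1 <- fit_logistic(y, X1)
  converged <- f0$converged && f1$converged
  stat <- max(f0$deviance - f1$deviance, 0)
  p <- if (converged) {
    max(stats::pchisq(stat, df = k, lower.tail = FALSE), .Machine$double.xmin)
  } else NA_real_
  tibble(
    gene_id = gene_id %||% "gene", phenotype_name = phenotype_name,
    test = "deviance", statistic = stat,
    df1 = k, df2 = NA_integer_, n = n, n_pcs = k,
    p = p, converged = converged
  )
}

#' Phenome-wide gene-based association scan
#'
#' Runs the nested-model test of every gene against every phenotype:
#' [test_gene_continuous()] for continuous phenotypes and [test_gene_binary()]
#' for binary ones. Samples are restricted per phenotype to complete cases.
#' In single-sex strata the sample set is filtered on the genetic-sex column
#' and that column is dropped from the covariates. Binary phenotypes with
#' fewer cases than `min_cases` are skipped with a message.
#'
#' @param genes A `gene_pcs` object or a (possibly named) list of them.
#' @param data Tibble keyed by `sample_id` holding phenotype and covariate
#'   columns.
#' @param phenotypes Tibble with columns `name` (column of `data`) and `kind`
#'   (`"continuous"` or `"binary"`).
#' @param covariates Character vector of covariate column names in `data`.
#' @param stratum `"combined"` (default), `"female"` or `"male"`.
#' @param sex_col Name of the genetic-sex covariate column (0 = female,
#'   1 = male) used for stratification.
#' @param min_cases Minimum case count for binary phenotypes (default 50).
#' @return Tibble with one row per gene x phenotype (plus a `stratum`
#'   column), as described in [test_gene_continuous()].
#' @export
run_phewas <- function(genes, data, phenotypes, covariates = character(),
                       stratum = c("combined", "female", "male"),
                       sex_col = "sex", min_cases = 50) {
  stratum <- match.arg(stratum)
  if (inherits(genes, "gene_pcs")) genes <- list(genes)
  data <- as_tibble(data)
  stopifnot("sample_id" %in% names(data))
  phenotypes <- as_tibble(phenotypes)
  stopifnot(all(c("name", "kind") %in% names(phenotypes)))
  missing_ph <- setdiff(phenotypes$name, names(data))
  if (length(missing_ph) > 0) {
    abort(paste0("phenotype column(s) absent from data: ",
                 paste(missing_ph, collapse = ", ")))
  }

  if (stratum != "combined") {
    if (!sex_col %in% names(data)) {
      abort(paste0("stratified run needs the sex column `", sex_col, "`"))
    }
    want <- if (stratum == "female") 0 else 1
    data <- data[!is.na(data[[sex_col]]) & data[[sex_col]] == want, ,
                 drop = FALSE]
    covariates <- setdiff(covariates, sex_col)
  }

  results <- list()
  for (gi in seq_along(genes)) {
    pcs <- genes[[gi]]
    stopifnot(inherits(pcs, "gene_pcs"))
    idx <- match(data$sample_id, rownames(pcs$scores))
    present <- !is.na(idx)
    d <- data[present, , drop = FALSE]
    sc <- pcs$scores[idx[present], , drop = FALSE]
    cov_mat <- if (length(covariates) > 0) as.matrix(d[covariates]) else NULL

    for (pi in seq_len(nrow(phenotypes))) {
      ph <- phenotypes$name[pi]
      kind <- phenotypes$kind[pi]
      y <- d[[ph]]
      if (kind == "binary") {
        n_cases <- sum(y == 1, na.rm = TRUE)
        n_controls <- sum(y == 0, na.rm = TRUE)
        if (n_cases < min_cases || n_controls == 0 || n_cases == 0) {
          inform(sprintf("skipping %s for %s: %d case(s), below minimum %d",
                         ph, pcs$gene_id, n_cases, min_cases))
          next
        }
        res <- test_gene_binary(sc, y, cov_mat, gene_id = pcs$gene_id,
                                phenotype_name = ph)
      } else {
        res <- test_gene_continuous(sc, y, cov_mat, gene_id = pcs$gene_id,
                                    phenotype_name = ph)
      }
      results[[length(results) + 1]] <- res
    }
  }
  out <- if (length(results)) list_rbind(results) else
    tibble(gene_id = character(), phenotype_name = character(),
           test = character(), statistic = numeric(), df1 = integer(),
           df2 = integer(), n = integer(), n_pcs = integer(),
           p = numeric(), converged = logical())
  mutate(out, stratum = stratum)
}
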