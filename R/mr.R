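#' Per-PC instrument effect estimates
#'
#' For each gene PC, fits two covariate-adjusted marginal regressions: the
#' exposure on the PC (linear) and the outcome on the PC (linear for a
#' continuous outcome, logistic for a binary one, in which case the effect is
#' on the log-odds scale). PC scores are orthogonal on the estimation sample,
#' which justifies per-PC marginal models in place of one joint fit.
#'
#' @param scores Samples x k matrix of gene PC scores, or a `gene_pcs`
#'   object.
#' @param exposure Numeric exposure vector aligned with `scores` rows.
#' @param outcome Numeric outcome vector (continuous, or 0/1 binary).
#' @param covariates Optional covariate matrix/data frame.
#' @param outcome_kind `"continuous"` or `"binary"` (guessed from the values
#'   by default).
#' @return Tibble with one row per PC: `pc_index`, `beta_x`, `se_x`, `p_x`,
#'   `beta_y`, `se_y`, `p_y`, `converged`.
#' @export
instrument_effects <- function(scores, exposure, outcome, covariates = NULL,
                               outcome_kind = NULL) {
  if (inherits(scores, "gene_pcs")) scores <- scores$scores
  scores <- as.matrix(scores)
  cc <- stats::complete.cases(exposure, outcome, scores,
                              if (!is.null(covariates)) as.matrix(covariates))
  scores <- scores[cc, , drop = FALSE]
  exposure <- exposure[cc]
  outcome <- outcome[cc]
  covariates <- if (!is.null(covariates)) as.matrix(covariates)[cc, , drop = FALSE]
  n <- nrow(scores)
  n_cov <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n < n_cov + 2) abort("too few complete cases for instrument estimation")
  outcome_kind <- outcome_kind %||%
    if (all(outcome %in% c(0, 1))) "binary" else "continuous"
  if (outcome_kind == "binary" && length(unique(outcome)) < 2) {
    abort("degenerate outcome: single class")
  }

  base <- build_design(covariates, n)
  rows <- map(seq_len(ncol(scores)), function(k) {
    X <- cbind(base, pc = scores[, k])
    ex <- marginal_linear(exposure, X)
    if (outcome_kind == "continuous") {
      oy <- marginal_linear(outcome, X)
      conv <- TRUE
    } else {
      oy <- marginal_logistic(outcome, X)
      conv <- oy$converged
    }
    tibble(pc_index = k,
           beta_x = ex$beta, se_x = ex$se, p_x = ex$p,
           beta_y = oy$beta, se_y = oy$se, p_y = oy$p,
           converged = conv)
  })
  list_rbind(rows)
}

# coefficient of the last column of X in a least-squares fit
marginal_linear <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  j <- ncol(X)
  beta <- unname(fit$coefficients[j])
  se <- sqrt(sigma2 * XtX_inv[j, j])
  t <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(t), df = df, lower.tail = FALSE))
}

marginal_logistic <- function(y, X) {
  fit <- fit_logistic(y, X)
  j <- ncol(X)
  beta <- unname(fit$coefficients[j])
  if (!fit$converged || is.na(beta)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                converged = FALSE))
  }
  # observed-information SE from the IRLS weights at the solution
  eta <- drop(X %*% fit$coefficients)
  mu <- stats::plogis(eta)
  W <- mu * (1 - mu)
  cov_beta <- chol2inv(chol(crossprod(X * sqrt(W))))
  se <- sqrt(cov_beta[j, j])
  z <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE), converged = TRUE)
}

#' Relevance filter for PC instruments
#'
#' Removes PCs not associated with the exposure (exposure p-value strictly
#' greater than `p_max`, default 0.05) so the retained instruments satisfy
#' the relevance assumption. A PC with p exactly equal to `p_max` is kept.
#' Non-converged instrument fits are excluded as well.
#'
#' @param effects Tibble from [instrument_effects()].
#' @param p_max Exposure-association p-value threshold (default 0.05).
#' @return List with `kept` (filtered tibble) and `excluded` (integer PC
#'   indices).
#' @export
filter_relevance <- function(effects, p_max = 0.05) {
  conv <- if ("converged" %in% names(effects)) effects$converged else
    rep(TRUE, nrow(effects))
  keep <- !is.na(effects$p_x) & effects$p_x <= p_max & conv %in% TRUE
  if (!any(keep)) {
    abort("no relevant instruments: all PCs have exposure P > p_max")
  }
  list(kept = effects[keep, , drop = FALSE],
       excluded = effects$pc_index[!keep])
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-instrument effects into the fixed-effect IVW estimator
#' \deqn{\hat\beta_{IVW} = \frac{\sum_k \hat\beta_{Xk}\hat\beta_{Yk}
#'   se(\hat\beta_{Yk})^{-2}}{\sum_k \hat\beta_{Xk}^2
#'   se(\hat\beta_{Yk})^{-2}}}
#' with standard error \eqn{(\sum_k \hat\beta_{Xk}^2
#' se(\hat\beta_{Yk})^{-2})^{-1/2}} and a two-sided normal p-value. With one
#' instrument this collapses to the Wald ratio `beta_y / beta_x`.
#' First-stage uncertainty (`se_x`) does not enter the estimator.
#'
#' @param effects Tibble with columns `beta_x`, `beta_y`, `se_y` (one row per
#'   instrument).
#' @return One-row tibble: `beta_ivw`, `se_ivw`, `p_ivw`, `n_instruments`.
#' @export
ivw <- function(effects) {
  stopifnot(nrow(effects) >= 1)
  if (any(is.na(effects$se_y)) || any(effects$se_y <= 0)) {
    abort("all instruments need a positive outcome standard error")
  }
  w <- effects$se_y^-2
  denom <- sum(effects$beta_x^2 * w)
  beta <- sum(effects$beta_x * effects$beta_y * w) / denom
  se <- denom^-0.5
  z <- beta / se
  tibble(beta_ivw = beta, se_ivw = se,
         p_ivw = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         n_instruments = nrow(effects))
}

#' cis-Mendelian randomization through a gene's principal components
#'
#' Estimates the causal effect of an exposure on an outcome using the gene's
#' PCs as instrumental variables: per-PC effects ([instrument_effects()]),
#' relevance filtering ([filter_relevance()]), and the IVW combination
#' ([ivw()]). Exposure and outcome are estimated on the same sample
#' (one-sample design). The gene-vs-exposure association p-value from the
#' nested-model scan is recorded to help judge instrument strength.
#'
#' @param pcs A `gene_pcs` object.
#' @param data Tibble keyed by `sample_id` with exposure, outcome and
#'   covariate columns.
#' @param exposure,outcome Column names in `data`; the exposure must be
#'   continuous.
#' @param covariates Character vector of covariate column names.
#' @param p_max Relevance threshold passed to [filter_relevance()].
#' @param outcome_kind `"continuous"` or `"binary"` (guessed by default).
#'   For a binary outcome the causal estimate is a log odds ratio per
#'   exposure unit.
#' @return An object of class `mr_result`: the IVW estimate, per-PC effects
#'   with inclusion flags, instrument counts and the gene-exposure p-value.
#'   `tidy()` returns the per-PC table, `glance()` the one-row summary, and
#'   `autoplot()` the per-instrument effect scatter with the IVW slope.
#' @export
run_cis_mr <- function(pcs, data, exposure, outcome, covariates = character(),
                       p_max = 0.05, outcome_kind = NULL) {
  stopifnot(inherits(pcs, "gene_pcs"))
  data <- as_tibble(data)
  stopifnot("sample_id" %in% names(data))
  for (col in c(exposure, outcome, covariates)) {
    if (!col %in% names(data)) abort(paste0("column not in data: ", col))
  }
  idx <- match(data$sample_id, rownames(pcs$scores))
  present <- !is.na(idx)
  d <- data[present, , drop = FALSE]
  sc <- pcs$scores[idx[present], , drop = FALSE]
  cov_mat <- if (length(covariates) > 0) as.matrix(d[covariates]) else NULL

  effects <- instrument_effects(sc, d[[exposure]], d[[outcome]], cov_mat,
                                outcome_kind = outcome_kind)
  flt <- filter_relevance(effects, p_max = p_max)
  est <- ivw(flt$kept)
  gene_exposure_p <- test_gene_continuous(sc, d[[exposure]], cov_mat,
                                          gene_id = pcs$gene_id,
                                          phenotype_name = exposure)$p

  effects$included <- !effects$pc_index %in% flt$excluded
  structure(
    list(
      gene_id = pcs$gene_id,
      exposure_name = exposure,
      outcome_name = outcome,
      beta_ivw = est$beta_ivw, se_ivw = est$se_ivw, p_ivw = est$p_ivw,
      n_instruments_total = nrow(effects),
      n_instruments_used = est$n_instruments,
      excluded_pcs = flt$excluded,
      gene_exposure_p = gene_exposure_p,
      effects = effects
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<mr_result> %s: %s -> %s\n  beta_IVW = %.4g (se %.4g, p %.3g), %d/%d PCs used\n",
    x$gene_id, x$exposure_name, x$outcome_name,
    x$beta_ivw, x$se_ivw, x$p_ivw,
    x$n_instruments_used, x$n_instruments_total))
  invisible(x)
}

#' @describeIn run_cis_mr Per-instrument effects with inclusion flags.
#' @param x An `mr_result`.
#' @param ... Unused.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) x$effects

#' @describeIn run_cis_mr One-row IVW summary.
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(
    gene_id = x$gene_id, exposure = x$exposure_name, outcome = x$outcome_name,
    beta_ivw = x$beta_ivw, se_ivw = x$se_ivw, p_ivw = x$p_ivw,
    n_instruments_total = x$n_instruments_total,
    n_instruments_used = x$n_instruments_used,
    gene_exposure_p = x$gene_exposure_p
  )
}

#' @describeIn run_cis_mr Scatter of per-PC exposure vs outcome effects;
#'   excluded PCs drawn smaller, IVW estimate as the slope of the fitted
#'   line through the origin.
#' @param object An `mr_result`.
#' @method autoplot mr_result
#' @export
autoplot.mr_result <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_abline(slope = object$beta_ivw, intercept = 0,
                         colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_y - 1.96 * .data$se_y,
      ymax = .data$beta_y + 1.96 * .data$se_y), width = 0,
      colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$included),
                        show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 2.5, `FALSE` = 1)) +
    ggplot2::labs(
      x = "Effect on exposure (per PC unit)",
      y = "Effect on outcome (per PC unit)",
      title = sprintf("%s: %s on %s", object$gene_id, object$exposure_name,
                      object$outcome_name),
      subtitle = sprintf("IVW slope %.3g (p = %.3g)", object$beta_ivw,
                         object$p_ivw)
    ) +
    ggplot2::theme_minimal()
}
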