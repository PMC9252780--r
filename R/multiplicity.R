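#' Storey q-values
#'
#' False-discovery-rate q-values: calling every test with q-value at most
#' alpha significant bounds the expected false-discovery proportion by alpha.
#' The null proportion pi0 is estimated on the grid lambda = 0.05, 0.10, ...,
#' 0.95 via a cubic smoother evaluated at the last grid point
#' (`pi0_method = "smoother"`), or fixed at 1 (`pi0_method = "fixed_one"`),
#' in which case the q-values coincide with Benjamini-Hochberg adjusted
#' p-values. Then
#' \deqn{q_i = \min_{j: p_j \ge p_i} \pi_0 m p_j / rank(p_j)}
#' clipped to (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param pi0_method `"smoother"` (default) or `"fixed_one"`.
#' @param lambda_grid Grid for the pi0 smoother.
#' @return Tibble with columns `p`, `q` (input order preserved) and
#'   attributes `pi0` and `m`.
#' @export
qvalues <- function(p, pi0_method = c("smoother", "fixed_one"),
                    lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  pi0_method <- match.arg(pi0_method)
  check_pvalues(p)
  m <- length(p)
  pi0 <- if (pi0_method == "fixed_one") 1 else estimate_pi0(p, lambda_grid)

  o <- order(p)
  ranks <- seq_len(m)
  q_sorted <- pi0 * m * p[o] / ranks
  # step-up: running minimum from the largest p downwards
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  out <- tibble(p = p, q = q)
  attr(out, "pi0") <- pi0
  attr(out, "m") <- m
  out
}

estimate_pi0 <- function(p, lambda_grid) {
  m <- length(p)
  pi0_l <- vapply(lambda_grid,
                  function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  if (length(lambda_grid) >= 4) {
    fit <- stats::smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  } else {
    pi0 <- pi0_l[length(pi0_l)]
  }
  # an estimate below 1/m would imply fewer than one null test
  min(max(pi0, 1 / m), 1)
}

check_pvalues <- function(p) {
  if (length(p) == 0) abort("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  invisible(p)
}

#' Bonferroni correction
#'
#' `min(p * m, 1)` elementwise; `m` is the test count of the chosen
#' multiplicity axis and may exceed `length(p)` (e.g. correcting a single
#' gene's p-value over all 1746 phenotypes of a scan).
#'
#' @param p P-values in (0, 1].
#' @param m Number of tests on the axis (default `length(p)`).
#' @return Numeric vector of corrected p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) abort("m must be >= 1")
  if (m < length(p)) abort("m must be at least length(p)")
  check_pvalues(p)
  pmin(p * m, 1)
}

#' Genomic inflation factor lambda
#'
#' The ratio of the median observed association statistic to the median
#' expected under the null. Because genes carry heterogeneous degrees of
#' freedom, each p-value is first transformed to its 1-df chi-squared
#' quantile, making lambda comparable across genes:
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`.
#' Values well above 1 mark pleiotropic genes (or residual confounding).
#'
#' @param p P-values in (0, 1].
#' @return The scalar inflation factor.
#' @export
inflation_lambda <- function(p) {
  check_pvalues(p)
  obs <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(obs) / stats::qchisq(0.5, df = 1)
}

#' Quantile-quantile plot coordinates
#'
#' Observed p-values sorted ascending against uniform-order-statistic
#' expectations `(i - 0.5)/m`, both on the -log10 scale.
#'
#' @param p P-values in (0, 1].
#' @return Tibble with columns `expected` and `observed` (-log10 scale),
#'   one row per input p-value.
#' @export
qq_points <- function(p) {
  check_pvalues(p)
  m <- length(p)
  tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(p))
  )
}

#' QQ plot of association p-values
#'
#' @param object Numeric vector of p-values, or a tibble with a `p` column
#'   (e.g. [run_phewas()] output).
#' @param ... Unused.
#' @return A ggplot object: observed vs expected -log10 p with the identity
#'   line and the lambda inflation factor in the subtitle.
#' @export
plot_qq <- function(object, ...) {
  p <- if (is.data.frame(object)) object$p else object
  p <- p[!is.na(p)]
  pts <- qq_points(p)
  lam <- inflation_lambda(p)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.2f", lam)
    ) +
    ggplot2::theme_minimal()
}

#' Attach multiplicity columns to association results
#'
#' Augments a [run_phewas()] result tibble with q-values (Storey) and
#' Bonferroni-corrected p-values computed along the chosen axis: `"per_gene"`
#' corrects each gene's p-values across its phenotypes, `"per_phenotype"`
#' corrects each phenotype's p-values across genes.
#'
#' @param results Tibble with `gene_id`, `phenotype_name`, `p` columns.
#' @param axis `"per_gene"` or `"per_phenotype"`.
#' @param pi0_method Passed to [qvalues()].
#' @return `results` with added `q` and `bonferroni` columns.
#' @export
adjust_results <- function(results, axis = c("per_gene", "per_phenotype"),
                           pi0_method = "smoother") {
  axis <- match.arg(axis)
  key <- if (axis == "per_gene") "gene_id" else "phenotype_name"
  q_na <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- qvalues(p[ok], pi0_method = pi0_method)$q
    out
  }
  bonf_na <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- pmin(p[ok] * sum(ok), 1)
    out
  }
  results |>
    group_by(.data[[key]]) |>
    mutate(q = q_na(.data$p), bonferroni = bonf_na(.data$p)) |>
    ungroup()
}
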