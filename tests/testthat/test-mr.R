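test_that("the IVW estimator follows its closed form", {
  one <- ivw(tibble::tibble(beta_x = 0.5, beta_y = 0.25, se_y = 0.1))
  expect_equal(one$beta_ivw, 0.5)  # Wald ratio for a single instrument

  two <- ivw(tibble::tibble(beta_x = c(1, 1), beta_y = c(0.2, 0.4),
                            se_y = c(0.1, 0.1)))
  expect_equal(two$beta_ivw, 0.3)

  expect_error(ivw(tibble::tibble(beta_x = 1, beta_y = 1, se_y = 0)),
               "positive outcome standard error")
})

test_that("IVW equals the weighted through-origin regression slope", {
  withr::with_seed(15, {
    for (rep in 1:5) {
      k <- sample(2:8, 1)
      eff <- tibble::tibble(beta_x = rnorm(k), beta_y = rnorm(k),
                            se_y = runif(k, 0.05, 0.5))
      got <- ivw(eff)
      ref <- lm(beta_y ~ 0 + beta_x, data = eff, weights = eff$se_y^-2)
      expect_equal(got$beta_ivw, unname(coef(ref)), tolerance = 1e-12)
      # and the precision-weighted mean of Wald ratios with
      # weights beta_x^2 / se_y^2
      w <- eff$beta_x^2 / eff$se_y^2
      expect_equal(got$beta_ivw,
                   sum(w * eff$beta_y / eff$beta_x) / sum(w),
                   tolerance = 1e-12)
    }
  })
})

test_that("the relevance filter keeps P <= 0.05 and errors when empty", {
  eff <- tibble::tibble(pc_index = 1:3, beta_x = 1, se_x = 1,
                        p_x = c(0.04, 0.05, 0.2),
                        beta_y = 1, se_y = 1, p_y = 0.5)
  flt <- filter_relevance(eff)
  expect_equal(flt$kept$pc_index, c(1, 2))  # exactly 0.05 is kept
  expect_equal(flt$excluded, 3)

  all_null <- dplyr::mutate(eff, p_x = c(0.06, 0.5, 0.9))
  expect_error(filter_relevance(all_null), "no relevant instruments")
})

test_that("per-PC effects match single-covariate regression oracles", {
  withr::with_seed(16, {
    n <- 400
    scores <- matrix(rnorm(n * 3), n, 3,
                     dimnames = list(NULL, paste0("PC", 1:3)))
    covar <- cbind(age = rnorm(n))
    exposure <- 0.5 * scores[, 1] + 0.1 * covar[, 1] + rnorm(n)
    outcome <- rbinom(n, 1, plogis(-1 + 0.3 * exposure))

    eff <- instrument_effects(scores, exposure, outcome, covar)
    expect_equal(nrow(eff), 3)
    for (k in 1:3) {
      lin <- summary(lm(exposure ~ covar + scores[, k]))$coefficients
      expect_equal(eff$beta_x[k], lin[3, "Estimate"], tolerance = 1e-8)
      expect_equal(eff$se_x[k], lin[3, "Std. Error"], tolerance = 1e-8)
      expect_equal(eff$p_x[k], lin[3, "Pr(>|t|)"], tolerance = 1e-8)
      log <- summary(glm(outcome ~ covar + scores[, k],
                         family = binomial()))$coefficients
      expect_equal(eff$beta_y[k], log[3, "Estimate"], tolerance = 1e-6)
      expect_equal(eff$se_y[k], log[3, "Std. Error"], tolerance = 1e-5)
    }
    # PC1 genuinely drives the exposure
    expect_lt(eff$p_x[1], 1e-10)
  })
})

test_that("null instruments carry uniform exposure p-values", {
  withr::with_seed(17, {
    p <- replicate(300, {
      n <- 80
      scores <- matrix(rnorm(n), n, 1)
      instrument_effects(scores, rnorm(n), rnorm(n))$p_x
    })
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  })
})

test_that("cis-MR recovers a planted causal effect end to end", {
  scn <- simulate_mr_scenario(n_samples = 4000, n_variants = 12,
                              causal_beta = 0.5, exposure_h2 = 0.15,
                              seed = 18)
  pcs <- compute_gene_pcs(scn$dm, gene_id = "GENE")
  fit <- run_cis_mr(pcs, scn$data, "exposure", "outcome",
                    covariates = c("age", "sex"))
  expect_s3_class(fit, "mr_result")
  ci <- fit$beta_ivw + c(-1.96, 1.96) * fit$se_ivw
  expect_gt(scn$true_beta, ci[1])
  expect_lt(scn$true_beta, ci[2])
  expect_equal(fit$n_instruments_used + length(fit$excluded_pcs),
               fit$n_instruments_total)
  expect_lt(fit$gene_exposure_p, 1e-6)

  tdy <- tidy(fit)
  expect_equal(sum(tdy$included), fit$n_instruments_used)
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("binary outcomes give a log-odds causal effect of the right sign", {
  scn <- simulate_mr_scenario(n_samples = 6000, n_variants = 10,
                              causal_beta = 0.6, exposure_h2 = 0.2,
                              binary_outcome = TRUE, seed = 19)
  pcs <- compute_gene_pcs(scn$dm)
  fit <- run_cis_mr(pcs, scn$data, "exposure", "outcome",
                    covariates = "age")
  expect_gt(fit$beta_ivw, 0)
  expect_lt(fit$p_ivw, 0.05)
})

test_that("IVW is scale-equivariant and sign-antisymmetric in the exposure", {
  scn <- simulate_mr_scenario(n_samples = 3000, n_variants = 8,
                              causal_beta = 0.4, exposure_h2 = 0.2, seed = 20)
  pcs <- compute_gene_pcs(scn$dm)
  base <- run_cis_mr(pcs, scn$data, "exposure", "outcome")

  doubled <- dplyr::mutate(scn$data, exposure = 2 * exposure)
  fit2 <- run_cis_mr(pcs, doubled, "exposure", "outcome")
  expect_equal(fit2$beta_ivw, base$beta_ivw / 2, tolerance = 1e-10)

  flipped <- dplyr::mutate(scn$data, exposure = -exposure)
  fitn <- run_cis_mr(pcs, flipped, "exposure", "outcome")
  expect_equal(fitn$beta_ivw, -base$beta_ivw, tolerance = 1e-10)
})
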