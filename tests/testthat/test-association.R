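test_that("the nested F statistic follows its closed form", {
  same <- f_statistic(50, 50, 3, 8, 108)
  expect_equal(same$statistic, 0)
  expect_equal(c(same$df1, same$df2), c(5, 100))

  gain <- f_statistic(100, 50, 3, 8, 108)
  expect_equal(gain$statistic, 20)

  perfect <- f_statistic(10, 0, 1, 3, 50)
  expect_equal(perfect$statistic, Inf)

  expect_error(f_statistic(10, 5, 3, 60, 50), "saturated")
  expect_error(f_statistic(10, 5, 5, 3, 50), "nested")
})

test_that("the continuous test matches anova() on nested linear models", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 120
      k <- sample(1:4, 1)
      scores <- matrix(rnorm(n * k), n, k,
                       dimnames = list(NULL, paste0("PC", 1:k)))
      covar <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
      y <- 0.2 * covar[, 1] + drop(scores %*% runif(k, -0.3, 0.3)) + rnorm(n)

      got <- test_gene_continuous(scores, y, covar)
      ref <- anova(lm(y ~ covar), lm(y ~ covar + scores))
      expect_equal(got$statistic, ref$F[2], tolerance = 1e-10)
      expect_equal(got$p, ref$`Pr(>F)`[2], tolerance = 1e-10)
      expect_equal(got$df1, k)
      expect_equal(got$df2, n - (ncol(covar) + 1 + k))
    }
  })
})

test_that("with one PC the F test reduces to the squared t test", {
  withr::with_seed(41, {
    n <- 90
    pc <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "PC1"))
    y <- 0.3 * pc[, 1] + rnorm(n)
    got <- test_gene_continuous(pc, y)
    sm <- summary(lm(y ~ pc))
    tval <- sm$coefficients["pc", "t value"]
    expect_equal(got$statistic, tval^2, tolerance = 1e-10)
    expect_equal(got$p, sm$coefficients["pc", "Pr(>|t|)"], tolerance = 1e-10)
  })
})

test_that("a noiseless linear signal drives the p-value to the floor", {
  withr::with_seed(3, {
    scores <- matrix(rnorm(50 * 2), 50, 2)
    y <- 2 * scores[, 1]
    got <- test_gene_continuous(scores, y)
    expect_true(is.infinite(got$statistic) || got$statistic > 1e10)
    expect_lt(got$p, 1e-15)
  })
})

test_that("rank-deficient designs are reported with the offending column", {
  withr::with_seed(12, {
    n <- 40
    scores <- matrix(rnorm(n * 2), n, 2,
                     dimnames = list(NULL, c("PC1", "PC2")))
    covar <- cbind(dup = scores[, 1])
    expect_error(test_gene_continuous(scores, rnorm(n), covar),
                 "collinear")
  })
})

test_that("the deviance statistic equals twice the log-likelihood gain", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      n <- 300
      k <- sample(1:3, 1)
      scores <- matrix(rnorm(n * k), n, k,
                       dimnames = list(NULL, paste0("PC", 1:k)))
      covar <- cbind(age = rnorm(n))
      eta <- -0.5 + 0.3 * covar[, 1] + drop(scores %*% runif(k, -0.4, 0.4))
      y <- rbinom(n, 1, plogis(eta))

      got <- test_gene_binary(scores, y, covar)
      f0 <- glm(y ~ covar, family = binomial())
      f1 <- glm(y ~ covar + scores, family = binomial())
      X0 <- model.matrix(f0); X1 <- model.matrix(f1)
      ll0 <- oracle_bernoulli_loglik(y, X0, coef(f0))
      ll1 <- oracle_bernoulli_loglik(y, X1, coef(f1))
      expect_equal(got$statistic, 2 * (ll1 - ll0), tolerance = 1e-6)
      # and matches the analysis-of-deviance table
      ref <- anova(f0, f1, test = "Chisq")
      expect_equal(got$statistic, ref$Deviance[2], tolerance = 1e-8)
      expect_equal(got$p, ref$`Pr(>Chi)`[2], tolerance = 1e-8)
    }
  })
})

test_that("binary-test guards: degenerate class and separation flagging", {
  withr::with_seed(6, {
    scores <- matrix(rnorm(60), 60, 1)
    expect_error(test_gene_binary(scores, rep(1, 60)), "degenerate")
    # perfectly separated outcome -> flagged, p missing
    y <- as.integer(scores[, 1] > 0)
    got <- test_gene_binary(scores, y)
    expect_false(got$converged)
    expect_true(is.na(got$p))
  })
})

test_that("under the null the binary statistic averages near its df", {
  withr::with_seed(61, {
    k <- 3
    stats <- replicate(200, {
      n <- 250
      scores <- matrix(rnorm(n * k), n, k)
      y <- rbinom(n, 1, 0.3)
      test_gene_binary(scores, y)$statistic
    })
    # mean of chi^2_k is k; se of the mean over 200 reps is sqrt(2k/200)
    expect_lt(abs(mean(stats) - k), 4 * sqrt(2 * k / 200))
  })
})

test_that("null continuous p-values are uniform", {
  withr::with_seed(71, {
    p <- replicate(400, {
      n <- 100
      scores <- matrix(rnorm(n * 2), n, 2)
      test_gene_continuous(scores, rnorm(n))$p
    })
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  })
})

test_that("power increases with effect size", {
  withr::with_seed(81, {
    power_at <- function(beta) {
      mean(replicate(60, {
        n <- 150
        scores <- matrix(rnorm(n * 2), n, 2)
        y <- beta * scores[, 1] + rnorm(n)
        test_gene_continuous(scores, y)$p < 0.05
      }))
    }
    pw <- vapply(c(0.05, 0.2, 0.5), power_at, numeric(1))
    expect_true(all(diff(pw) >= 0))
    expect_gt(pw[3], 0.9)
  })
})

test_that("run_phewas crosses genes with phenotypes and handles strata", {
  withr::with_seed(91, {
    dm1 <- rand_dm(300, 8, seed = 101)
    dm2 <- rand_dm(300, 6, seed = 102)
    pcs <- list(compute_gene_pcs(dm1, gene_id = "G1"),
                compute_gene_pcs(dm2, gene_id = "G2"))
    data <- tibble::tibble(
      sample_id = dm1$sample_ids,
      age = rnorm(300, 50, 5), sex = rbinom(300, 1, 0.5),
      t1 = rnorm(300), t2 = rnorm(300),
      d1 = rbinom(300, 1, 0.4)
    )
    phen <- tibble::tibble(name = c("t1", "t2", "d1"),
                           kind = c("continuous", "continuous", "binary"))
    res <- run_phewas(pcs, data, phen, covariates = c("age", "sex"))
    expect_equal(nrow(res), 6)
    expect_setequal(unique(res$gene_id), c("G1", "G2"))
    expect_equal(unique(res$stratum), "combined")

    # stratified run drops the sex covariate and filters samples
    fem <- run_phewas(pcs[[1]], data, phen[1, ], covariates = c("age", "sex"),
                      stratum = "female")
    expect_equal(fem$n, sum(data$sex == 0))

    # single-sex input tested in the other stratum: binary phenotype skipped
    males_only <- dplyr::filter(data, sex == 1)
    expect_message(
      skipped <- run_phewas(pcs[[1]], males_only,
                            tibble::tibble(name = "d1", kind = "binary"),
                            covariates = "age", stratum = "female"),
      "skipping"
    )
    expect_equal(nrow(skipped), 0)
  })
})

test_that("a planted causal gene attracts the smallest scan p-value", {
  withr::with_seed(111, {
    genes <- lapply(1:3, function(i) {
      compute_gene_pcs(rand_dm(800, 10, seed = 200 + i),
                       gene_id = paste0("G", i))
    })
    causal_dm <- rand_dm(800, 10, seed = 202)  # same genotypes as G2
    sim <- simulate_phenotype(causal_dm, "continuous", heritability = 0.15,
                              seed = 5)
    res <- run_phewas(genes, sim$data, sim$phenotypes,
                      covariates = c("age", "sex"))
    expect_equal(res$gene_id[which.min(res$p)], "G2")
  })
})
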