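test_that("HWE exact test handles degenerate and monomorphic input", {
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  expect_error(hwe_exact_test(0, 0, 0), class = "pargwas_parameter_error")
  expect_error(hwe_exact_test(-1, 2, 0), class = "pargwas_parameter_error")
})

test_that("HWE exact test equals exhaustive enumeration on random tables", {
  withr::with_seed(101, {
    # all-heterozygote case with even N: full enumeration of matching parity
    for (N in c(4, 10, 50)) {
      expect_equal(hwe_exact_test(0, N, 0), hwe_enum_oracle(0, N, 0),
                   tolerance = 1e-12)
    }
    for (rep in 1:200) {
      cts <- as.integer(stats::rmultinom(1, sample(1:200, 1), c(1, 1, 1)))
      if (sum(cts) == 0) next
      expect_equal(hwe_exact_test(cts[1], cts[2], cts[3]),
                   hwe_enum_oracle(cts[1], cts[2], cts[3]),
                   tolerance = 1e-12)
    }
  })
})

test_that("snp_summary counts genotypes as specified", {
  codes <- matrix(c(0L, 0L, 1L, 2L, NA), ncol = 1)
  G <- genotype_matrix(codes, paste0("s", 1:5))
  ss <- snp_summary(G)
  expect_equal(ss$n_AA, 2L)
  expect_equal(ss$n_AB, 1L)
  expect_equal(ss$n_BB, 1L)
  expect_equal(ss$n_missing, 1L)
  expect_equal(ss$call_rate, 0.8)
  expect_equal(ss$q, 3 / 8)
})

test_that("snp_summary agrees with a naive per-cell tally on random data", {
  withr::with_seed(7, {
    G <- simulate_genotypes(40, 100, maf = c(0.05, 0.5), missing_rate = 0.1,
                            seed = 71)
    ss <- snp_summary(G)
    for (j in seq_len(100)) {
      col <- G$codes[, j]
      expect_identical(ss$n_AA[j], sum(col == 0L, na.rm = TRUE))
      expect_identical(ss$n_AB[j], sum(col == 1L, na.rm = TRUE))
      expect_identical(ss$n_BB[j], sum(col == 2L, na.rm = TRUE))
      expect_identical(ss$n_missing[j], sum(is.na(col)))
      expect_equal(ss$call_rate[j], mean(!is.na(col)))
    }
    # row-sum invariant
    expect_true(all(ss$n_AA + ss$n_AB + ss$n_BB + ss$n_missing == 40L))
  })
})

test_that("monomorphic and all-missing SNPs produce flagged summaries", {
  codes <- cbind(rep(0L, 4), rep(2L, 4), rep(NA_integer_, 4))
  G <- genotype_matrix(codes, paste0("s", 1:4))
  ss <- snp_summary(G)
  expect_equal(ss$q, c(0, 1, NA_real_))
  expect_equal(ss$hwe_p[1:2], c(1, 1))
  expect_equal(ss$call_rate[3], 0)
  expect_true(is.na(ss$hwe_p[3]))
})

test_that("score test degenerates correctly and matches n*r^2 identities", {
  G <- simulate_genotypes(30, 10, maf = 0.4, missing_rate = 0, seed = 2)
  st_const <- score_test(G, rep(1.5, 30))
  expect_true(all(st_const$chi2 == 0))
  expect_true(all(st_const$p == 1))
  # trait identical to the genotype: r = 1 so chi2 = n
  y <- as.numeric(G$codes[, 1])
  st <- score_test(G, y)
  expect_equal(st$chi2[1], 30)
})

test_that("score test equals n*R^2 from an independent least-squares fit", {
  withr::with_seed(13, {
    G <- simulate_genotypes(120, 50, maf = c(0.1, 0.5), missing_rate = 0.05,
                            seed = 14)
    y <- simulate_phenotype(G, betas = 0, noise_sd = 1, seed = 15)$trait
    st <- score_test(G, y)
    for (j in seq_len(50)) {
      ok <- !is.na(G$codes[, j])
      fit <- stats::lm(y[ok] ~ G$codes[ok, j])
      expect_equal(st$chi2[j], sum(ok) * summary(fit)$r.squared,
                   tolerance = 1e-8)
    }
  })
})

test_that("for a binary trait the score test is the Armitage trend statistic", {
  cc <- simulate_case_control(60, 80, n_snp = 30, seed = 16)
  G <- cc$genotypes
  y <- cc$phenotypes$trait
  st <- score_test(G, y)
  for (j in seq_len(30)) {
    ok <- !is.na(G$codes[, j])
    g <- G$codes[ok, j]; yy <- y[ok]
    n <- sum(ok)
    # Cochran-Armitage trend statistic from the 2x3 table, weights (0,1,2)
    tab <- table(factor(yy, levels = 0:1), factor(g, levels = 0:2))
    w <- 0:2
    ni <- colSums(tab); ri <- tab[2, ]; R <- sum(ri); N <- sum(tab)
    denom <- R * (N - R) * (N * sum(w^2 * ni) - sum(w * ni)^2)
    if (denom == 0) next
    ca <- N * (N * sum(w * ri) - R * sum(w * ni))^2 / denom
    expect_equal(st$chi2[j], ca, tolerance = 1e-9)
  }
})

test_that("score-test p-values are calibrated under the null", {
  G <- simulate_genotypes(300, 2000, maf = c(0.1, 0.5), missing_rate = 0.02,
                          seed = 17)
  y <- simulate_phenotype(G, betas = 0, noise_sd = 1, seed = 18)$trait
  st <- score_test(G, y)
  rate <- mean(st$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("linear regression matches the closed-form simple-regression slope", {
  withr::with_seed(19, {
    G <- simulate_genotypes(80, 10, maf = 0.3, missing_rate = 0, seed = 20)
    ph <- simulate_phenotype(G, betas = 0.3, noise_sd = 1, seed = 21)
    mr <- ml_regression(G, ph, "trait", model = "linear")
    for (j in seq_len(10)) {
      g <- as.numeric(G$codes[, j]); y <- ph$trait
      beta_hat <- stats::cov(g, y) / stats::var(g)
      expect_equal(mr$beta[j], beta_hat, tolerance = 1e-10)
    }
  })
})

test_that("regression matches lm/glm with covariates", {
  G <- simulate_genotypes(150, 8, maf = 0.3, missing_rate = 0.03, seed = 22)
  ph <- simulate_phenotype(G, betas = 0.2, noise_sd = 1, seed = 23)
  ph$age <- withr::with_seed(24, stats::rnorm(150, 50, 8))
  ph$bin <- withr::with_seed(25, stats::rbinom(150, 1, 0.4))
  lin <- ml_regression(G, ph, "trait", covariates = "age", model = "linear")
  log_ <- ml_regression(G, ph, "bin", covariates = "age", model = "logistic")
  for (j in seq_len(8)) {
    ok <- !is.na(G$codes[, j])
    d <- data.frame(y = ph$trait[ok], g = G$codes[ok, j], age = ph$age[ok],
                    b = ph$bin[ok])
    fl <- summary(stats::lm(y ~ g + age, data = d))$coefficients
    expect_equal(lin$beta[j], fl["g", 1], tolerance = 1e-8)
    expect_equal(lin$se[j], fl["g", 2], tolerance = 1e-8)
    fg <- summary(stats::glm(b ~ g + age, data = d,
                             family = stats::binomial()))$coefficients
    expect_equal(log_$beta[j], fg["g", 1], tolerance = 1e-5)
    expect_equal(log_$se[j], fg["g", 2], tolerance = 1e-5)
  }
})

test_that("degenerate regression designs yield flagged rows, not crashes", {
  codes <- cbind(rep(1L, 20), c(rep(0L, 10), rep(2L, 10)))
  G <- genotype_matrix(codes, paste0("s", 1:20))
  ph <- data.frame(id = G$sample_ids,
                   trait = c(rep(0, 10), rep(1, 10)))
  # zero-variance genotype
  lin <- ml_regression(G, ph, "trait", model = "linear")
  expect_equal(lin$status[1], "zero_variance")
  # perfectly separated logistic model
  logist <- ml_regression(G, ph, "trait", model = "logistic")
  expect_true(logist$status[2] %in% c("separation", "not_converged"))
  expect_true(is.na(logist$p[2]))
  # exact linear fit: se below 1e-8 is flagged as degenerate
  ph2 <- data.frame(id = G$sample_ids, trait = 2 * as.numeric(codes[, 2]))
  lin2 <- ml_regression(G, ph2, "trait", model = "linear")
  expect_equal(lin2$beta[2], 2, tolerance = 1e-10)
  expect_equal(lin2$status[2], "degenerate_se")
})
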