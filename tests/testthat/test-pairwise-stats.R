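test_that("ibs_pair endpoints and brute-force agreement", {
  g <- c(0L, 1L, 2L, 1L, 0L)
  expect_equal(ibs_pair(g, g)$value, 1)
  expect_equal(ibs_pair(rep(0L, 5), rep(2L, 5))$value, 0)
  expect_equal(ibs_pair(c(NA_integer_, NA_integer_),
                        c(1L, NA_integer_))$n_shared, 0L)
  expect_true(is.na(ibs_pair(c(NA_integer_, NA_integer_), c(1L, 2L))$value))
  withr::with_seed(41, {
    for (rep in 1:20) {
      gi <- sample(c(0:2, NA), 50, replace = TRUE)
      gk <- sample(c(0:2, NA), 50, replace = TRUE)
      ok <- !is.na(gi) & !is.na(gk)
      if (!any(ok)) next
      manual <- mean(1 - abs(gi[ok] - gk[ok]) / 2)
      expect_equal(ibs_pair(gi, gk)$value, manual, tolerance = 1e-12)
    }
  })
})

test_that("ibs_matrix equals a two-nested-loop reference on 20 x 100 data", {
  G <- simulate_genotypes(20, 100, maf = c(0.1, 0.5), missing_rate = 0.1,
                          seed = 42)
  freqs <- allele_freqs(G)
  for (w in c("none", "freq")) {
    pm <- ibs_matrix(G, weight = w)
    for (i in 1:19) for (k in (i + 1):20) {
      gi <- G$codes[i, ]; gk <- G$codes[k, ]
      ok <- !is.na(gi) & !is.na(gk)
      ref <- if (w == "none") {
        mean(1 - abs(gi[ok] - gk[ok]) / 2)
      } else {
        use <- ok & freqs > 0 & freqs < 1
        p <- freqs[use]
        mean((gi[use] / 2 - p) * (gk[use] / 2 - p) / (p * (1 - p)))
      }
      expect_equal(pm$values[i, k], ref, tolerance = 1e-12)
    }
    expect_identical(pm$values, t(pm$values))
  }
})

test_that("ibs diagonal conventions and duplicated individuals", {
  G <- simulate_genotypes(6, 50, maf = 0.3, missing_rate = 0, seed = 43)
  codes2 <- rbind(G$codes, G$codes[1, ])
  G2 <- genotype_matrix(codes2, c(G$sample_ids, "dup"))
  pm <- ibs_matrix(G2)
  expect_equal(pm$values[1, 7], 1)            # duplicate pair: full sharing
  expect_true(all(diag(pm$values) == 1))
  kin <- ibs_matrix(G2, weight = "freq")
  f <- homozygosity(G2)$F
  expect_equal(diag(kin$values), 0.5 * (1 + f), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("IBS values are bounded and invariant to SNP permutation", {
  G <- simulate_genotypes(12, 40, maf = 0.3, missing_rate = 0.05, seed = 44)
  pm <- ibs_matrix(G)
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  perm <- withr::with_seed(45, sample(40))
  pm2 <- ibs_matrix(G[, perm])
  expect_equal(pm$values, pm2$values, tolerance = 1e-12)
})

test_that("EM with no double heterozygotes equals direct phase counting", {
  # table with empty double-het cell: haplotype counts are unambiguous
  ct <- matrix(c(10, 4, 1,
                 3, 0, 2,
                 1, 5, 6), 3, 3, byrow = TRUE)
  f <- em_haplotype_freqs(ct)
  n2 <- 2 * sum(ct)
  c_AB <- 2 * ct[3, 3] + ct[3, 2] + ct[2, 3]
  c_Ab <- 2 * ct[3, 1] + ct[3, 2] + ct[2, 1]
  c_aB <- 2 * ct[1, 3] + ct[1, 2] + ct[2, 3]
  c_ab <- 2 * ct[1, 1] + ct[1, 2] + ct[2, 1]
  expect_equal(f$f_AB, c_AB / n2, tolerance = 1e-9)
  expect_equal(f$f_Ab, c_Ab / n2, tolerance = 1e-9)
  expect_equal(f$f_aB, c_aB / n2, tolerance = 1e-9)
  expect_equal(f$f_ab, c_ab / n2, tolerance = 1e-9)
})

test_that("EM on a duplicated polymorphic locus finds complete LD", {
  g <- c(rep(0L, 6), rep(1L, 8), rep(2L, 6))
  ct <- matrix(tabulate(g * 3L + g + 1L, nbins = 9L), 3, 3, byrow = TRUE)
  f <- em_haplotype_freqs(ct)
  expect_equal(f$f_AB + f$f_ab, 1, tolerance = 1e-9)
  expect_equal(f$f_Ab, 0, tolerance = 1e-9)
  expect_equal(f$f_aB, 0, tolerance = 1e-9)
})

test_that("EM rejects monomorphic or invalid tables", {
  ct <- matrix(0, 3, 3); ct[1, 1] <- 5; ct[1, 3] <- 5
  expect_error(em_haplotype_freqs(ct), class = "pargwas_degenerate_error")
  expect_error(em_haplotype_freqs(matrix(-1, 3, 3)),
               class = "pargwas_parameter_error")
  expect_error(em_haplotype_freqs(matrix(0, 3, 3)),
               class = "pargwas_parameter_error")
})

test_that("EM log-likelihood beats a simplex grid search", {
  withr::with_seed(46, {
    for (rep in 1:4) {
      ct <- random_ld_table(n = 50)
      f <- em_haplotype_freqs(ct)
      best_grid <- grid_best_loglik(ct, step = 0.005)
      expect_gte(f$loglik, best_grid - 1e-9)
      # expected genotype-table counts under the EM solution sum to n
      probs <- pargwas:::two_locus_cell_probs(f$f_AB, f$f_Ab, f$f_aB, f$f_ab)
      expect_equal(sum(probs) * sum(ct), sum(ct), tolerance = 1e-9)
    }
  })
})

test_that("ld_pair endpoints: perfect LD, equilibrium, and flags", {
  g <- c(rep(0L, 8), rep(1L, 8), rep(2L, 8))
  res <- ld_pair(g, g)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  expect_equal(res$Dprime, 1, tolerance = 1e-9)
  expect_equal(res$rho, 1)
  # monomorphic locus flagged
  res2 <- ld_pair(g, rep(0L, 24))
  expect_equal(res2$status, "monomorphic")
  expect_true(is.na(res2$r2))
  # all-heterozygote locus: allele-polymorphic (D defined) but no genotype
  # variance, so composite rho is undefined
  res2b <- ld_pair(g, rep(1L, 24))
  expect_equal(res2b$status, "ok")
  expect_equal(res2b$D, 0, tolerance = 1e-9)
  expect_true(is.na(res2b$rho))
  # too few complete pairs
  res3 <- ld_pair(c(0L, 1L, NA, NA), c(NA, NA, 0L, 1L), min_n = 2)
  expect_equal(res3$status, "too_few_pairs")
  # independence: product-frequency table gives D = 0
  ct_dir <- c(outer(c(4L, 2L, 4L), c(4L, 2L, 4L)))
  g1 <- rep(rep(0:2, each = 3), times = ct_dir)
  g2 <- rep(rep(0:2, times = 3), times = ct_dir)
  res4 <- ld_pair(g1, g2)
  expect_equal(res4$D, 0, tolerance = 1e-9)
  expect_equal(res4$Dprime, 0, tolerance = 1e-6)
  expect_equal(res4$r2, 0, tolerance = 1e-9)
})

test_that("on phase-unambiguous data EM r2 equals the haplotype-count r2", {
  withr::with_seed(47, {
    # build genotypes from explicit haplotypes, rejecting double hets
    h1a <- rbinom(200, 1, 0.4); h1b <- h1a
    h2a <- rbinom(200, 1, 0.4); h2b <- ifelse(rbinom(200, 1, 0.7), h2a, rbinom(200, 1, 0.4))
    g1 <- h1a + h2a; g2 <- h1b + h2b
    keep <- !(g1 == 1 & g2 == 1)
    g1 <- g1[keep]; g2 <- g2[keep]
    ha <- c(h1a[keep], h2a[keep]); hb <- c(h1b[keep], h2b[keep])
    res <- ld_pair(as.integer(g1), as.integer(g2))
    expect_equal(res$r2, stats::cor(ha, hb)^2, tolerance = 1e-9)
    expect_lte(res$rho^2, 1)
  })
})

test_that("ld_matrix equals a pairwise ld_pair loop on 30 SNPs", {
  G <- simulate_genotypes(80, 30, maf = c(0.15, 0.5), missing_rate = 0.05,
                          ld_rho = 0.4, seed = 48)
  pm <- ld_matrix(G, stat = "r2", min_n = 2)
  for (i in 1:29) for (k in (i + 1):30) {
    ref <- ld_pair(G$codes[, i], G$codes[, k], min_n = 2)$r2
    expect_equal(pm$values[i, k], ref, tolerance = 1e-12)
  }
  expect_identical(pm$values, t(pm$values))
  expect_true(all(diag(pm$values) == 1))
  pm_d <- ld_matrix(G, stat = "dprime", min_n = 2)
  expect_true(all(abs(pm_d$values) <= 1 + 1e-9, na.rm = TRUE))
})

test_that("a base-pair window smaller than any gap leaves only the diagonal", {
  G <- simulate_genotypes(40, 6, maf = 0.3, missing_rate = 0, seed = 49)
  pm <- ld_matrix(G, max_bp_window = 10, min_n = 2)  # SNPs are 1 kb apart
  off <- pm$values; diag(off) <- NA
  expect_true(all(is.na(off)))
  expect_true(all(diag(pm$values) == 1))
  expect_error(ld_matrix(G, snp_subset = integer(0)),
               class = "pargwas_empty_error")
})
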