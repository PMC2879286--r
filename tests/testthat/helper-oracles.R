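# Independent oracles used across test files. These deliberately take a
# different computational route from the package implementation.

# Conditional exact HWE distribution by direct enumeration: genotype-count
# probabilities under any HWE frequency (0.5 used) restricted to the observed
# allele counts and renormalized.
hwe_enum_oracle <- function(n_AA, n_AB, n_BB) {
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0) return(1)
  rare <- min(nA, nB)
  hs <- seq.int(rare %% 2, rare, by = 2)
  probs <- vapply(hs, function(h)
    stats::dmultinom(c((nA - h) / 2, h, (nB - h) / 2),
                     prob = c(0.25, 0.5, 0.25)), numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hs == n_AB]
  sum(probs[log(probs) <= log(obs) + 1e-9])
}

# Multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies, written out independently for the grid-search oracle.
oracle_loglik <- function(ct, fAB, fAb, faB, fab) {
  pr <- rbind(c(fab^2, 2 * fab * faB, faB^2),
              c(2 * fab * fAb, 2 * fAB * fab + 2 * fAb * faB, 2 * faB * fAB),
              c(fAb^2, 2 * fAb * fAB, fAB^2))
  keep <- ct > 0
  if (any(pr[keep] <= 0)) return(-Inf)
  sum(ct[keep] * log(pr[keep]))
}

# Best log-likelihood over a full-simplex grid with the given step, plus a
# fine 0.001-step sweep along the one free dimension (f_AB) with the allele-
# frequency margins held at their observed values (where the MLE must lie,
# because the margins are fully observed for unphased two-locus data).
grid_best_loglik <- function(ct, step = 0.005) {
  n1 <- round(1 / step)
  best <- -Inf
  for (i in 0:n1) {
    jk <- expand.grid(j = 0:(n1 - i), k = 0:(n1 - i))
    jk <- jk[jk$j + jk$k <= n1 - i, ]
    fAB <- i * step
    fAb <- jk$j * step
    faB <- jk$k * step
    fab <- 1 - fAB - fAb - faB
    pr11 <- fab^2; pr12 <- 2 * fab * faB; pr13 <- faB^2
    pr21 <- 2 * fab * fAb; pr22 <- 2 * fAB * fab + 2 * fAb * faB
    pr23 <- 2 * faB * fAB
    pr31 <- fAb^2; pr32 <- 2 * fAb * fAB; pr33 <- fAB^2
    ll <- rep(0, nrow(jk))
    cells <- list(pr11, pr21, pr31, pr12, pr22, pr32, pr13, pr23, pr33)
    ok <- rep(TRUE, nrow(jk))
    for (c_i in 1:9) {
      cnt <- ct[c_i]
      if (cnt > 0) {
        p <- cells[[c_i]]
        ok <- ok & p > 0
        ll <- ll + cnt * log(pmax(p, 1e-300))
      }
    }
    ll[!ok] <- -Inf
    if (length(ll) > 0) best <- max(best, max(ll))
  }
  # fine profile sweep at the observed margins
  n <- sum(ct)
  pA <- (sum(ct[2, ]) + 2 * sum(ct[3, ])) / (2 * n)
  pB <- (sum(ct[, 2]) + 2 * sum(ct[, 3])) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  fAB <- seq(lo, hi, by = 0.001)
  prof <- vapply(fAB, function(f)
    oracle_loglik(ct, f, pA - f, pB - f, 1 - pA - pB + f), numeric(1))
  max(best, max(prof))
}

# Random 3x3 genotype-count table with both loci guaranteed polymorphic.
random_ld_table <- function(n = 60) {
  repeat {
    f <- as.numeric(stats::rmultinom(1, 1000, rep(1, 4))) / 1000
    pr <- rbind(c(f[4]^2, 2 * f[4] * f[3], f[3]^2),
                c(2 * f[4] * f[2], 2 * f[1] * f[4] + 2 * f[2] * f[3],
                  2 * f[3] * f[1]),
                c(f[2]^2, 2 * f[2] * f[1], f[1]^2))
    ct <- matrix(as.numeric(stats::rmultinom(1, n, as.numeric(pr))), 3, 3)
    n1 <- sum(ct[2, ]) + 2 * sum(ct[3, ])
    n2 <- sum(ct[, 2]) + 2 * sum(ct[, 3])
    if (n1 > 0 && n1 < 2 * n && n2 > 0 && n2 < 2 * n) return(ct)
  }
}

# Exhaustive tiling check for a pairwise plan.
plan_tiles_exactly <- function(plan) {
  cov <- matrix(0L, plan$n, plan$n)
  for (b in plan$blocks) {
    ri <- (b$rows$start + 1):b$rows$stop
    ci <- (b$cols$start + 1):b$cols$stop
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  all(cov == 1L)
}

# Small deterministic genotype fixture with known values.
tiny_genotypes <- function() {
  codes <- matrix(c(0L, 0L, 1L, 2L, NA,
                    1L, 1L, 1L, 1L, 1L,
                    0L, 2L, 0L, 2L, 0L), nrow = 5)
  genotype_matrix(codes, paste0("s", 1:5))
}
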