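# Type-3 and type-4 statistics: pairwise over individuals (IBS, genomic
# kinship) and pairwise over SNPs (linkage disequilibrium via two-locus EM).

#' Identity-by-state / kinship for one pair of individuals
#'
#' Unweighted (`weight = "none"`): the mean over pairwise-complete SNPs of
#' `1 - |g_i - g_k| / 2`, i.e. the average fraction of alleles shared by
#' state. Frequency-weighted (`weight = "freq"`, genomic kinship): the mean
#' over pairwise-complete polymorphic SNPs of
#' `(g_i/2 - p)(g_k/2 - p) / (p (1 - p))`, which has expectation 0 for
#' unrelated outbred pairs and 0.5 for self-comparison.
#'
#' @param g_i,g_k genotype code vectors of equal length (0/1/2/`NA`).
#' @param weight `"none"` or `"freq"`.
#' @param freqs per-SNP alternate-allele frequencies (required for
#'   `weight = "freq"`; use [allele_freqs()] on the full sample).
#' @return list with `value` (`NA` and a flag if no SNPs are shared) and
#'   `n_shared`.
#' @export
ibs_pair <- function(g_i, g_k, weight = c("none", "freq"), freqs = NULL) {
  weight <- match.arg(weight)
  if (length(g_i) != length(g_k))
    stop_parameter("genotype vectors must have equal length")
  ok <- !is.na(g_i) & !is.na(g_k)
  if (weight == "none") {
    n <- sum(ok)
    if (n == 0L) return(list(value = NA_real_, n_shared = 0L))
    list(value = mean(1 - abs(g_i[ok] - g_k[ok]) / 2), n_shared = n)
  } else {
    if (is.null(freqs)) stop_parameter("weight = 'freq' requires freqs")
    use <- ok & !is.na(freqs) & freqs > 0 & freqs < 1
    n <- sum(use)
    if (n == 0L) return(list(value = NA_real_, n_shared = 0L))
    p <- freqs[use]
    list(value = mean((g_i[use] / 2 - p) * (g_k[use] / 2 - p) / (p * (1 - p))),
         n_shared = n)
  }
}

ibs_block_kernel <- function(G, weight, freqs) {
  codes <- G$codes
  if (weight == "none") {
    called <- !is.na(codes)
    I0 <- (codes == 0L) & called; I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
    I1 <- (codes == 1L) & called; I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
    I2 <- (codes == 2L) & called; I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
    C <- called; storage.mode(C) <- "double"
    function(ri, ci) {
      # sum over shared SNPs of |g_i - g_k| via genotype-class cross products
      s_abs <- 2 * (I0[ri, , drop = FALSE] %*% t(I2[ci, , drop = FALSE]) +
                    I2[ri, , drop = FALSE] %*% t(I0[ci, , drop = FALSE])) +
        I0[ri, , drop = FALSE] %*% t(I1[ci, , drop = FALSE]) +
        I1[ri, , drop = FALSE] %*% t(I0[ci, , drop = FALSE]) +
        I1[ri, , drop = FALSE] %*% t(I2[ci, , drop = FALSE]) +
        I2[ri, , drop = FALSE] %*% t(I1[ci, , drop = FALSE])
      ns <- C[ri, , drop = FALSE] %*% t(C[ci, , drop = FALSE])
      vals <- ifelse(ns > 0, 1 - s_abs / (2 * ns), NA_real_)
      list(values = vals, n_shared = ns)
    }
  } else {
    poly <- !is.na(freqs) & freqs > 0 & freqs < 1
    X <- sweep(codes / 2, 2L, freqs, `-`)
    X <- sweep(X, 2L, sqrt(freqs * (1 - freqs)), `/`)
    X[is.na(X)] <- 0
    X[, !poly] <- 0
    U <- (!is.na(codes)) & rep(poly, each = nrow(codes))
    storage.mode(U) <- "double"
    function(ri, ci) {
      num <- X[ri, , drop = FALSE] %*% t(X[ci, , drop = FALSE])
      ns <- U[ri, , drop = FALSE] %*% t(U[ci, , drop = FALSE])
      vals <- ifelse(ns > 0, num / ns, NA_real_)
      list(values = vals, n_shared = ns)
    }
  }
}

#' IBS / genomic kinship matrix
#'
#' All `N(N-1)/2` pairs of individuals via [ibs_pair()] arithmetic, computed
#' block-wise under the pairwise partitioning scheme so any processor count
#' yields the same matrix. The diagonal is 1 for `weight = "none"`; for
#' `weight = "freq"` it is `0.5 * (1 + F_i)` with `F_i` the
#' method-of-moments inbreeding estimate from [homozygosity()].
#'
#' @param G a [genotype_matrix()] with at least 2 individuals.
#' @param weight `"none"` (average IBS) or `"freq"` (genomic kinship).
#' @param nprocs processor count.
#' @param executor see [run_tasks()].
#' @param side_max block-side bound passed to [pairwise_depth()].
#' @param exploit_symmetry skip blocks strictly below the diagonal and fill
#'   them by mirroring (efficiency opt-in; off by default, matching the
#'   full-square decomposition).
#' @return a [pair_matrix()] with statistic `"ibs"` or `"kinship"`.
#' @export
ibs_matrix <- function(G, weight = c("none", "freq"), nprocs = 1L,
                       executor = c("serial", "processes"),
                       side_max = 7000L, exploit_symmetry = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  weight <- match.arg(weight)
  executor <- match.arg(executor)
  n <- nrow(G$codes)
  if (n < 2L) stop_parameter("need at least 2 individuals")
  freqs <- if (weight == "freq") allele_freqs(G) else NULL
  kernel <- ibs_block_kernel(G, weight, freqs)
  pm <- run_pairwise_stat(n, G$sample_ids, kernel,
                          statistic = if (weight == "none") "ibs" else "kinship",
                          nprocs = nprocs, executor = executor,
                          side_max = side_max,
                          exploit_symmetry = exploit_symmetry)
  if (weight == "none") {
    diag(pm$values) <- 1
  } else {
    f <- homozygosity(G)$F
    diag(pm$values) <- 0.5 * (1 + f)
  }
  pm
}

#' Maximum-likelihood two-locus haplotype frequencies by EM
#'
#' Input is the 3x3 table of joint genotype counts at two biallelic loci
#' (rows: locus-1 code 0/1/2; columns: locus-2 code 0/1/2). All cells except
#' the double heterozygote resolve to known haplotype pairs; the double
#' heterozygote is split between the cis (`AB/ab`) and trans (`Ab/aB`)
#' phases proportionally to the current frequency estimates, and the
#' frequencies re-estimated, iterating from linkage-equilibrium starting
#' values until the largest frequency change is `<= 1e-10` (at most 1000
#' iterations). `A`/`B` denote the alternate alleles at the two loci.
#'
#' @param joint_counts 3x3 matrix of non-negative genotype counts; total
#'   `>= 2`; both loci must be polymorphic.
#' @return list with `f_AB`, `f_Ab`, `f_aB`, `f_ab` (summing to 1),
#'   `n_iter` and `loglik`.
#' @export
em_haplotype_freqs <- function(joint_counts) {
  ct <- as.matrix(joint_counts)
  if (!all(dim(ct) == c(3L, 3L)) || any(is.na(ct)) || any(ct < 0) ||
      any(ct != floor(ct)))
    stop_parameter("joint_counts must be a 3x3 table of non-negative counts")
  n <- sum(ct)
  if (n < 2) stop_parameter("need at least 2 observations")
  p1 <- (sum(ct[2L, ]) + 2 * sum(ct[3L, ])) / (2 * n)
  p2 <- (sum(ct[, 2L]) + 2 * sum(ct[, 3L])) / (2 * n)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop_pargwas("monomorphic locus: haplotype frequencies are degenerate",
                 "pargwas_degenerate_error")
  # phase-known haplotype counts from the eight unambiguous cells
  # (indices: [g1+1, g2+1]); haplotype labels: AB=alt/alt, Ab=alt/ref, ...
  c_AB <- 2 * ct[3L, 3L] + ct[3L, 2L] + ct[2L, 3L]
  c_Ab <- 2 * ct[3L, 1L] + ct[3L, 2L] + ct[2L, 1L]
  c_aB <- 2 * ct[1L, 3L] + ct[1L, 2L] + ct[2L, 3L]
  c_ab <- 2 * ct[1L, 1L] + ct[1L, 2L] + ct[2L, 1L]
  ndh <- ct[2L, 2L]
  f <- c(AB = p1 * p2, Ab = p1 * (1 - p2), aB = (1 - p1) * p2,
         ab = (1 - p1) * (1 - p2))
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- f[["AB"]] * f[["ab"]]
    trans <- f[["Ab"]] * f[["aB"]]
    share <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    f_new <- c(AB = (c_AB + ndh * share) / (2 * n),
               Ab = (c_Ab + ndh * (1 - share)) / (2 * n),
               aB = (c_aB + ndh * (1 - share)) / (2 * n),
               ab = (c_ab + ndh * share) / (2 * n))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta <= 1e-10 || it >= 1000L) break
  }
  list(f_AB = f[["AB"]], f_Ab = f[["Ab"]],
       f_aB = f[["aB"]], f_ab = f[["ab"]],
       n_iter = it, loglik = two_locus_loglik(ct, f))
}

# Multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies f = (AB, Ab, aB, ab), assuming random union of haplotypes.
two_locus_loglik <- function(ct, f) {
  probs <- two_locus_cell_probs(f[1L], f[2L], f[3L], f[4L])
  keep <- ct > 0
  sum(ct[keep] * log(probs[keep]))
}

two_locus_cell_probs <- function(fAB, fAb, faB, fab) {
  # cell [g1+1, g2+1] probability from random pairing of two haplotypes
  m <- matrix(0, 3L, 3L)
  m[1L, 1L] <- fab^2
  m[1L, 2L] <- 2 * fab * faB
  m[1L, 3L] <- faB^2
  m[2L, 1L] <- 2 * fab * fAb
  m[2L, 2L] <- 2 * fAB * fab + 2 * fAb * faB
  m[2L, 3L] <- 2 * faB * fAB
  m[3L, 1L] <- fAb^2
  m[3L, 2L] <- 2 * fAb * fAB
  m[3L, 3L] <- fAB^2
  m
}

#' Two-locus linkage disequilibrium for a pair of SNPs
#'
#' Computes `D`, `D'`, `r2` from the EM maximum-likelihood haplotype
#' frequencies, and `rho` as the Pearson correlation of the genotype codes
#' (composite LD, which never assumes phase). With `p_A = f_AB + f_Ab` etc.:
#' `D = f_AB - p_A p_B`; `D' = D / D_max` where `D_max = min(p_A p_b,
#' p_a p_B)` for `D > 0` and `min(p_A p_B, p_a p_b)` otherwise;
#' `r2 = D^2 / (p_A p_a p_B p_b)`. If EM converges to a boundary with
#' `D_max = 0`, `D'` is 0 when `D = 0` and `sign(D)` otherwise.
#'
#' @param g1,g2 genotype code vectors of equal length.
#' @param min_n smallest admissible number of pairwise-complete
#'   observations; below it the pair is flagged (EM is unstable on tiny
#'   counts).
#' @return list with `D`, `Dprime`, `r2`, `rho`, `n` and `status`
#'   (`"ok"`, `"too_few_pairs"` or `"monomorphic"`; flagged results carry
#'   `NA` statistics).
#' @export
ld_pair <- function(g1, g2, min_n = 2L) {
  if (length(g1) != length(g2))
    stop_parameter("genotype vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  na_res <- function(status)
    list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_, rho = NA_real_,
         n = n, status = status)
  if (n < max(2L, min_n)) return(na_res("too_few_pairs"))
  a <- g1[ok]; b <- g2[ok]
  ct <- matrix(tabulate(a * 3L + b + 1L, nbins = 9L), 3L, 3L, byrow = TRUE)
  pA <- (sum(ct[2L, ]) + 2 * sum(ct[3L, ])) / (2 * n)
  pB <- (sum(ct[, 2L]) + 2 * sum(ct[, 3L])) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(na_res("monomorphic"))
  f <- em_haplotype_freqs(ct)
  D <- f$f_AB - (f$f_AB + f$f_Ab) * (f$f_AB + f$f_aB)
  pa <- 1 - pA; pb <- 1 - pB
  d_max <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  dprime <- if (d_max > 0) D / d_max else if (D == 0) 0 else sign(D)
  r2 <- D^2 / (pA * pa * pB * pb)
  # composite LD needs genotype variance; an all-heterozygote locus is
  # allele-polymorphic but genotypically constant
  rho <- if (stats::var(a) == 0 || stats::var(b) == 0) NA_real_
         else stats::cor(a, b)
  list(D = D, Dprime = dprime, r2 = r2, rho = rho,
       n = n, status = "ok")
}

#' Pairwise-SNP LD matrix
#'
#' Computes the chosen LD statistic for all SNP pairs in the subset, block-
#' wise under the pairwise partitioning scheme. With `max_bp_window` set,
#' pairs on different chromosomes or farther apart than the window are left
#' missing (LD scans are usually restricted by physical distance). The
#' diagonal is 1.
#'
#' @param G a [genotype_matrix()].
#' @param stat `"r2"`, `"dprime"` or `"rho"`.
#' @param snp_subset SNP names or column indices; default all SNPs.
#' @param max_bp_window optional base-pair window; pairs outside it are
#'   `NA`.
#' @param min_n per-pair complete-observation floor (see [ld_pair()]).
#' @inheritParams ibs_matrix
#' @return a [pair_matrix()] over the SNP subset.
#' @export
ld_matrix <- function(G, stat = c("r2", "dprime", "rho"), snp_subset = NULL,
                      max_bp_window = NULL, min_n = 10L, nprocs = 1L,
                      executor = c("serial", "processes"), side_max = 7000L,
                      exploit_symmetry = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  stat <- match.arg(stat)
  executor <- match.arg(executor)
  jidx <- if (is.null(snp_subset)) seq_len(ncol(G$codes))
          else if (is.character(snp_subset)) match(snp_subset, G$snps$name)
          else as.integer(snp_subset)
  if (anyNA(jidx) || length(jidx) == 0L ||
      any(jidx < 1L) || any(jidx > ncol(G$codes)))
    stop_empty("empty or invalid SNP subset")
  if (length(jidx) < 2L) stop_empty("need at least 2 SNPs for LD")
  codes <- G$codes[, jidx, drop = FALSE]
  chrom <- G$snps$chrom[jidx]
  pos <- G$snps$pos[jidx]
  key <- c(r2 = "r2", dprime = "Dprime", rho = "rho")[[stat]]
  kernel <- function(ri, ci) {
    vals <- matrix(NA_real_, length(ri), length(ci))
    ns <- matrix(NA_real_, length(ri), length(ci))
    for (u in seq_along(ri)) {
      i <- ri[u]
      for (v in seq_along(ci)) {
        k <- ci[v]
        if (i == k) { vals[u, v] <- 1; ns[u, v] <- sum(!is.na(codes[, i])); next }
        if (!is.null(max_bp_window) &&
            (chrom[i] != chrom[k] || abs(pos[i] - pos[k]) > max_bp_window))
          next
        res <- ld_pair(codes[, i], codes[, k], min_n = min_n)
        vals[u, v] <- res[[key]]
        ns[u, v] <- res$n
      }
    }
    list(values = vals, n_shared = ns)
  }
  run_pairwise_stat(length(jidx), G$snps$name[jidx], kernel, statistic = stat,
                    nprocs = nprocs, executor = executor, side_max = side_max,
                    exploit_symmetry = exploit_symmetry)
}
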