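#' Simulate genotypes under Hardy-Weinberg equilibrium with optional LD
#'
#' Genotypes are built from two independent haplotypes per individual, so
#' every locus is marginally in HWE. Linkage disequilibrium between adjacent
#' loci is induced by first-order haplotype copying: on each haplotype the
#' allele at locus `j` is copied from locus `j-1` with probability `ld_rho`
#' and otherwise drawn fresh as Bernoulli(`maf[j]`). With `ld_rho = 1` and
#' equal MAFs adjacent loci are exact duplicates; with `ld_rho = 0` loci are
#' independent. Missing calls are applied i.i.d. at rate `missing_rate`.
#'
#' @param n_ind number of individuals (N >= 1).
#' @param n_snp number of SNPs (M >= 1).
#' @param maf minor/alternate allele frequency in (0,1): a scalar (recycled),
#'   a vector of length `n_snp`, or a length-2 range from which per-SNP
#'   frequencies are drawn uniformly (when `n_snp != 2`).
#' @param missing_rate per-call missingness probability in `[0,1)`.
#' @param ld_rho adjacent-locus haplotype copying probability in `[0,1]`.
#' @param seed integer seed; identical seeds give identical output.
#' @param keep_haplotypes if `TRUE`, attach the two pre-missingness haplotype
#'   matrices as `attr(, "haplotypes")` (used to compute true haplotypic LD
#'   in calibration checks).
#' @return a [genotype_matrix()] on chromosome "1" with positions spaced
#'   1 kb apart.
#' @export
simulate_genotypes <- function(n_ind, n_snp, maf = c(0.05, 0.5),
                               missing_rate = 0.01, ld_rho = 0,
                               seed = NULL, keep_haplotypes = FALSE) {
  if (!is_count(n_ind, 1L) || !is_count(n_snp, 1L))
    stop_parameter("n_ind and n_snp must be counts >= 1")
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      is.na(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop_parameter("missing_rate must be in [0,1)")
  if (!is.numeric(ld_rho) || length(ld_rho) != 1L || is.na(ld_rho) ||
      ld_rho < 0 || ld_rho > 1)
    stop_parameter("ld_rho must be in [0,1]")
  if (!is.numeric(maf) || any(is.na(maf)) || any(maf <= 0) || any(maf >= 1))
    stop_parameter("maf values must lie strictly in (0,1)")
  with_seed(seed, {
    mafs <- if (length(maf) == n_snp) {
      as.numeric(maf)
    } else if (length(maf) == 1L) {
      rep(maf, n_snp)
    } else if (length(maf) == 2L) {
      stats::runif(n_snp, min(maf), max(maf))
    } else {
      stop_parameter("maf must have length 1, 2 (range) or n_snp")
    }
    draw_hap <- function() {
      h <- matrix(0L, n_ind, n_snp)
      h[, 1L] <- stats::rbinom(n_ind, 1L, mafs[1L])
      if (n_snp > 1L) for (j in 2:n_snp) {
        copy <- stats::runif(n_ind) < ld_rho
        fresh <- stats::rbinom(n_ind, 1L, mafs[j])
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      }
      h
    }
    h1 <- draw_hap(); h2 <- draw_hap()
    codes <- h1 + h2
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n_ind * n_snp) < missing_rate, n_ind, n_snp)
      codes[miss] <- NA_integer_
    }
    wid <- max(4L, nchar(n_ind)); wjd <- max(4L, nchar(n_snp))
    snps <- data.frame(
      name = sprintf("snp%0*d", wjd, seq_len(n_snp)),
      chrom = "1", pos = seq_len(n_snp) * 1000L,
      ref = "A", alt = "C", stringsAsFactors = FALSE)
    G <- genotype_matrix(codes, sprintf("ind%0*d", wid, seq_len(n_ind)), snps)
    if (keep_haplotypes) attr(G, "haplotypes") <- list(h1 = h1, h2 = h2)
    attr(G, "mafs") <- mafs
    G
  })
}

#' Simulate a phenotype from genotypes
#'
#' Quantitative: `y = sum_j beta_j g_ij + e`, `e ~ N(0, noise_sd^2)`.
#' Binary: Bernoulli with logit equal to the same linear predictor.
#' Missing genotypes contribute 0 to the sum.
#'
#' @param G a [genotype_matrix()].
#' @param betas per-SNP effect sizes, scalar or length `M`.
#' @param noise_sd residual standard deviation (quantitative traits; must be
#'   positive).
#' @param binary simulate a 0/1 trait instead of a quantitative one.
#' @param seed integer seed.
#' @return data frame with columns `id` and `trait`.
#' @export
simulate_phenotype <- function(G, betas = 0, noise_sd = 1, binary = FALSE,
                               seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$codes)
  if (length(betas) == 1L) betas <- rep(betas, m)
  if (length(betas) != m)
    stop_parameter("betas must have length 1 or n_snp")
  if (!binary && (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
                  is.na(noise_sd) || noise_sd <= 0))
    stop_parameter("noise_sd must be positive for quantitative traits")
  g0 <- G$codes
  g0[is.na(g0)] <- 0L
  eta <- as.numeric(g0 %*% betas)
  with_seed(seed, {
    y <- if (binary) {
      stats::rbinom(length(eta), 1L, stats::plogis(eta))
    } else {
      eta + stats::rnorm(length(eta), 0, noise_sd)
    }
    data.frame(id = G$sample_ids, trait = as.numeric(y),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a case/control cohort
#'
#' Convenience wrapper emulating a case/control study design: genotypes as in
#' [simulate_genotypes()], and a binary phenotype with exactly `n_cases`
#' cases. Case status is assigned to the `n_cases` individuals with the
#' largest liability (genetic linear predictor plus standard-logistic noise),
#' so with null effects the assignment is random while the case count stays
#' exact.
#'
#' @param n_cases,n_controls sample sizes (>= 1).
#' @param n_snp number of SNPs.
#' @param betas per-SNP liability effects, scalar or length `n_snp`.
#' @param seed integer seed.
#' @inheritParams simulate_genotypes
#' @return list with elements `genotypes` ([genotype_matrix()]) and
#'   `phenotypes` (data frame `id`, `trait` with trait in {0,1}).
#' @export
simulate_case_control <- function(n_cases, n_controls, n_snp,
                                  maf = c(0.05, 0.5), missing_rate = 0.01,
                                  ld_rho = 0, betas = 0, seed = NULL) {
  if (!is_count(n_cases, 1L) || !is_count(n_controls, 1L))
    stop_parameter("n_cases and n_controls must be counts >= 1")
  n <- n_cases + n_controls
  with_seed(seed, {
    G <- simulate_genotypes(n, n_snp, maf = maf, missing_rate = missing_rate,
                            ld_rho = ld_rho, seed = NULL)
    m <- ncol(G$codes)
    if (length(betas) == 1L) betas <- rep(betas, m)
    if (length(betas) != m) stop_parameter("betas must have length 1 or n_snp")
    g0 <- G$codes; g0[is.na(g0)] <- 0L
    liability <- as.numeric(g0 %*% betas) + stats::rlogis(n)
    trait <- integer(n)
    trait[order(liability, decreasing = TRUE)[seq_len(n_cases)]] <- 1L
    list(genotypes = G,
         phenotypes = data.frame(id = G$sample_ids, trait = as.numeric(trait),
                                 stringsAsFactors = FALSE))
  })
}
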