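# Type-2 statistics: computed per individual across all markers.

#' Per-individual call rate and heterozygosity
#'
#' One row per sample in input order: number of called genotypes, call rate
#' and the fraction of called genotypes that are heterozygous. Missing
#' entries are skipped per individual.
#'
#' @param G a [genotype_matrix()].
#' @param nprocs processor count; the individual axis is partitioned
#'   linearly, results merged in order.
#' @param executor see [run_tasks()].
#' @return data frame with columns `id`, `n_called`, `call_rate`,
#'   `het_frac`, `status`.
#' @export
per_individual_summary <- function(G, nprocs = 1L,
                                   executor = c("serial", "processes")) {
  stopifnot(inherits(G, "genotype_matrix"))
  executor <- match.arg(executor)
  m <- ncol(G$codes)
  kernel <- function(from, to) {
    iidx <- from:to
    sub <- G$codes[iidx, , drop = FALSE]
    n_called <- rowSums(!is.na(sub))
    n_het <- rowSums(sub == 1L, na.rm = TRUE)
    data.frame(id = G$sample_ids[iidx],
               n_called = as.integer(n_called),
               call_rate = n_called / m,
               het_frac = ifelse(n_called > 0L, n_het / n_called, NA_real_),
               status = ifelse(n_called > 0L, "ok", "no_calls"),
               stringsAsFactors = FALSE)
  }
  run_linear_stat(nrow(G$codes), kernel, nprocs, executor, "type2")
}

#' Per-individual homozygosity and inbreeding
#'
#' For individual `i`, the observed homozygote count `o_hom` is compared
#' with its expectation under HWE at the sample allele frequencies:
#' `e_hom = sum_j (1 - 2 p_j (1 - p_j))` over the individual's called SNPs,
#' where `p_j` is the alternate-allele frequency computed once from the full
#' sample (including individual `i`). The method-of-moments inbreeding
#' estimate is `F = (o_hom - e_hom) / (n_called - e_hom)`. Monomorphic SNPs
#' contribute 1 to `e_hom` (and make `F` undefined if every used SNP is
#' monomorphic). Useful as a contamination / sample-quality check.
#'
#' @inheritParams per_individual_summary
#' @return data frame with columns `id`, `n_called`, `o_hom`, `e_hom`, `F`,
#'   `status`. Individuals with zero calls, or a zero denominator for `F`,
#'   are flagged rather than dropped.
#' @export
homozygosity <- function(G, nprocs = 1L,
                         executor = c("serial", "processes")) {
  stopifnot(inherits(G, "genotype_matrix"))
  executor <- match.arg(executor)
  p <- allele_freqs(G)          # frequencies fixed once, shared by all tasks
  ehom_j <- 1 - 2 * p * (1 - p) # per-SNP expected homozygosity; NA if no calls
  kernel <- function(from, to) {
    iidx <- from:to
    sub <- G$codes[iidx, , drop = FALSE]
    called <- !is.na(sub) & rep(!is.na(ehom_j), each = length(iidx))
    n_called <- rowSums(called)
    o_hom <- rowSums((sub == 0L | sub == 2L) & called, na.rm = TRUE)
    eh <- ehom_j
    eh[is.na(eh)] <- 0
    # per-row accumulation (not BLAS) so results are bit-identical however
    # the individual axis is chunked across processors
    em <- matrix(eh, nrow = length(iidx), ncol = length(eh), byrow = TRUE)
    e_hom <- rowSums(called * em)
    denom <- n_called - e_hom
    f <- ifelse(n_called > 0L & abs(denom) > .Machine$double.eps * n_called,
                (o_hom - e_hom) / denom, NA_real_)
    data.frame(id = G$sample_ids[iidx],
               n_called = as.integer(n_called),
               o_hom = as.integer(o_hom), e_hom = e_hom, F = f,
               status = ifelse(n_called == 0L, "no_calls",
                               ifelse(is.na(f), "undefined_F", "ok")),
               stringsAsFactors = FALSE)
  }
  run_linear_stat(nrow(G$codes), kernel, nprocs, executor, "type2")
}
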