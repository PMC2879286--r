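---
title: "Partitioned parallel GWA statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned parallel GWA statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pargwas)
```

# The problem

Genome-wide association (GWA) analyses repeat a small computation over a
very large index set: every SNP, every individual, every pair of
individuals, or every pair of SNPs. The computations are independent across
index elements, which makes them data-parallel, but the four index
structures call for different partitioning strategies, and a correct
parallel implementation must produce output *identical* to the serial one —
a reviewer should not have to wonder whether a discrepancy is biology or
scheduling.

`pargwas` packages these four computation types behind one scheme:
partition the index set, run blocks under a task-pull scheduler, merge
deterministically. This vignette documents the partitioning geometry, the
statistical definitions, the numerical choices, and what the tests do and
do not establish.

# Partitioning

## Linear (types 1 and 2)

`partition_linear(M, P)` cuts `M` items into `P` contiguous chunks of
`floor(M/P)` items, with the integer-division remainder attached to the
last chunk: 801 items over 4 processors gives 200, 200, 200, 201. The
remainder convention is fixed (last chunk) so that plans are reproducible;
`P > M` is a parameter error, since it cannot give every processor work.

## Pairwise (types 3 and 4)

An n×n symmetric pair grid is decomposed recursively:

* **Stage 1** halves `[0, n)` (remainder to the second half) and forms four
  quadrants — two *diagonal* (top-left, bottom-right) and two
  *off-diagonal*.
* **Each further stage** quarters every diagonal block into its own four
  quadrants, and cuts every off-diagonal block into four contiguous strips
  of near-equal size along its row axis.

This yields `4^depth` blocks that tile the grid exactly. Strips are cut
along rows where at least four rows are available; for very small blocks
the cut falls back to columns, and finally to a 2×2 split, so the exact
tiling property holds down to `n = 2^depth` (verified exhaustively in the
tests for all `n ≤ 64`, `depth ≤ 3`). Strip sizes are balanced (they differ
by at most one, extras to the last strips), which keeps block areas within
roughly one row plus one column of the ideal `n²/4^depth`.

`pairwise_depth(n, P, side_max)` picks the smallest depth such that
`4^depth ≥ P` (enough subsets for the processors) and
`ceil(n/2^depth) ≤ side_max` (each block's slice fits memory), with a floor
of one (at least 4 subsets). The default `side_max = 7000` encodes a
practical per-processor budget for pair matrices: it gives 4 subsets for up
to 14,000 items, 16 for 14,001–28,000 and 64 for 28,001–56,000. The flag is
exposed because the right budget depends on available RAM per worker.

Both off-diagonal quadrants are planned and computed, i.e. every
off-diagonal cell is produced twice, once in each triangle. That redundancy
is deliberate: the merge step *checks* the duplicates against each other
(tolerance 1e-12) and fails loudly on disagreement, which has caught real
kernel bugs during development. `exploit_symmetry = TRUE` skips the blocks
strictly below the diagonal and fills them by mirroring — an efficiency
opt-in, off by default.

# Execution and merging

`run_tasks()` executes a task list under one of two executors behind the
same contract: `"serial"` (a plain loop — the reference path, always used
for `nprocs = 1`) and `"processes"` (a forked pool via the base `parallel`
package with one fork per task, so idle workers pull the next unassigned
task). Workers receive only their block description and share the in-memory
dataset through the fork, rather than receiving serialized copies. A worker
failure becomes a `"failed"` result carrying the task id and diagnostic;
remaining tasks still run; failed tasks are not retried.

Merging is a pure function of the results and the plan: linear results are
concatenated in range order; pairwise blocks are placed at their grid
positions, duplicate cells checked, and the upper triangle kept. Results
are keyed by task id, so arrival order is irrelevant and output for
`nprocs = k` is identical — `identical()`, not approximately equal — to
`nprocs = 1`. One implementation detail matters for this guarantee: per-row
reductions inside kernels use `rowSums()`-style accumulation rather than
BLAS matrix–vector products, because BLAS accumulation order can vary with
operand shape and would break bit-reproducibility across chunkings.

The overhead model is deliberately minimal: `overhead(t1, tP, P) =
tP − t1/P`, and `predict_time(t1, ov, P) = t1/P + ov` extrapolates with the
overhead held constant. Constancy is an assumption, not a law — overheads
include partitioning, distribution and merging costs that grow slowly with
`P` — so predictions are indicative, best anchored at a reference
processor count near the target range.

# Statistical definitions

The per-statistic definitions are fixed as follows (all are
oracle-checked in the test suite):

* **HWE exact test** — two-sided conditional exact test. Given allele
  counts, the heterozygote count `h` has a known conditional distribution;
  the p-value sums the probabilities of all `h` (same parity, feasible
  range) whose probability is ≤ that of the observed count. No mid-p
  correction; ties are *included*, with a tie tolerance of 1e-9 on the log
  scale so that mathematically equal probabilities that differ only in
  floating-point rounding still count as ties. Monomorphic input returns 1.
* **Score test** — `chi2 = n·r²` with `r` the Pearson correlation of
  genotype code and trait over the `n` complete pairs; equals the
  Cochran–Armitage trend statistic for 0/1 traits. Zero genotype or trait
  variance gives `chi2 = 0`, `p = 1`. P-values come from the upper tail of
  chi-square(1) and are floored at the smallest positive double so that
  `-log10(p)` stays finite.
* **Regression** — per-SNP `trait ~ genotype + covariates`, complete cases
  per SNP, Wald `chi2 = (beta/se)²`. Linear models are solved by QR;
  logistic by Newton iterations to gradient norm ≤ 1e-8, at most 25
  iterations. Rank-deficient designs, non-convergence and separation
  (|slope| > 15 on the dosage scale, or a standard error above 100) yield
  flagged rows with diagnostic codes, never errors. Missingness is handled
  by per-SNP complete cases throughout; the package never imputes.
* **Inbreeding** — method-of-moments:
  `F = (o_hom − e_hom)/(n_called − e_hom)` with
  `e_hom = Σ_j (1 − 2p_j(1−p_j))` over the individual's called SNPs.
  Allele frequencies are computed once from the full sample, including the
  focal individual, matching common QC practice; no small-sample
  correction is applied (a leave-one-out or `n/(n−1)` variant would be a
  natural extension).
* **IBS / kinship** — unweighted IBS is the mean of `1 − |g_i − g_k|/2`
  over pairwise-complete SNPs; genomic kinship is the mean of
  `(g_i/2 − p)(g_k/2 − p)/(p(1−p))` over pairwise-complete polymorphic
  SNPs, so self-kinship is 0.5 in an outbred sample and the diagonal is set
  to `0.5·(1 + F_i)`.
* **LD** — maximum-likelihood two-locus haplotype frequencies by EM
  (below), then `D = f_AB − p_A p_B`, `D' = D/D_max`,
  `r² = D²/(p_A p_a p_B p_b)`. `rho` is the Pearson correlation of the raw
  genotype codes (composite LD) — defined without any phase assumption,
  which is also why the whole pipeline treats phased (`|`) and unphased
  (`/`) genotypes identically.

## Two-locus EM

All nine genotype cells except the double heterozygote resolve to known
haplotype pairs. The EM starts from linkage-equilibrium products of the
observed allele frequencies, splits the double-heterozygote count between
the cis (`AB/ab`) and trans (`Ab/aB`) phases proportionally to the current
estimates, re-estimates, and stops when the largest frequency change is
≤ 1e-10 or after 1000 iterations. Degenerate cases are handled
deterministically: a monomorphic locus is an error at the EM level and a
flagged missing result at the `ld_pair` level; if the solution reaches a
boundary where `D_max = 0`, `D'` is defined as 0 when `D = 0` and
`sign(D)` otherwise. Pairs with fewer complete observations than a floor
(default 10 in `ld_matrix`) are flagged rather than estimated, because EM
on tiny tables is unstable.

Because allele counts at each locus are fully observed in unphased
genotype data, the likelihood's margins are pinned to the sample allele
frequencies and only one free dimension (`f_AB`) remains. The test suite
exploits this: the EM solution must dominate both a full-simplex grid at
step 0.005 and a 0.001-step sweep along that free dimension — a grid fine
enough to certify the optimum without the ~1.7×10⁸ evaluations a 0.001
full-simplex grid would cost.

# The synthetic-data generator

`simulate_genotypes()` builds each individual from two independent
haplotypes, so every locus is marginally in Hardy–Weinberg equilibrium by
construction; LD between adjacent loci is induced by first-order copying
(allele copied from the previous locus with probability `ld_rho`, else
drawn fresh at its MAF), giving a one-parameter Markov LD structure with
known truth; missingness is i.i.d. Defaults: MAF drawn uniformly from
(0.05, 0.5) — the ascertainment range typical of genotyping arrays;
`missing_rate = 0.01`, an ordinary post-QC call-rate level;
`ld_rho = 0` unless LD is the object of study. A single integer seed
drives one generator and the caller's RNG state is restored afterwards.

The generator emulates what the statistics need — allele-frequency spectra,
HWE genotype proportions, adjacent-locus LD with computable haplotypic
truth, missingness, case/control labels with exact counts — and nothing
more. It does **not** emulate population structure, cryptic relatedness,
genotyping-batch artifacts, differential missingness, or realistic
recombination-map LD decay. Passing calibration tests on this generator
therefore shows the estimators are correct under their own assumptions; it
says nothing about robustness to stratification or relatedness, which are
exactly the features real-data QC uses these statistics to *detect*.

# Problem sizes and test design

The suite verifies the parallel-equals-serial contract on a simulated
200-individual × 2,000-SNP dataset for all four types at 1, 2 and 4
processors, with LD over a 100-SNP subset inside a 20 kb window — sizes
chosen so the full suite runs in about a minute while still exercising
multi-block plans in every computation type. Calibration checks use 2,000
null score tests (rejection rate at α = 0.05 within 3 binomial standard
errors), 400 individuals × 800 SNPs for mean F, and 200 SNP pairs at
n = 2,000 for EM r² against the known haplotypic truth (mean absolute
error below 0.02). Exact-test agreement with enumeration uses 500 random
genotype triples with totals up to 200 at 1e-12.

# Known limitations

* Statistics kernels are pure R (vectorized per block). For the scales the
  package targets in testing this is comfortable; genome-scale LD scans
  would want a compiled EM kernel behind the same interfaces.
* The `"processes"` executor relies on `fork()`, i.e. it is POSIX-only; on
  platforms without fork the serial executor is the fallback. A
  message-passing backend would slot behind the same `run_tasks()` contract
  but is not provided.
* Cox proportional-hazards models, score tests adjusted for a fitted
  polygenic model, haplotype phasing beyond two loci, and multiple-testing
  correction are out of scope.
* The TSV genotype format is an artifact of this package (VCF is the
  interchange format); it exists because a bit-exact, diffable text
  round-trip makes the determinism contract directly testable.
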