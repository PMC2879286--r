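Package: pargwas
Title: Partitioned Parallel Computation of Genome-Wide Association Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association (GWA) statistics organised around a
    generalized data-partitioning and task-pull parallelization scheme.
    Four computation types are distinguished by input structure: per-SNP
    statistics (genotype summaries, Hardy-Weinberg exact test, score and
    regression association tests), per-individual statistics (call rate,
    heterozygosity, inbreeding), pairwise-individual statistics (identity
    by state and genomic kinship matrices) and pairwise-SNP statistics
    (linkage disequilibrium D, D', r2 and composite rho via two-locus EM).
    Linear partitioning and recursive quadrant/row-strip partitioning of
    the pairwise grid distribute work across processors; a task-pull
    scheduler with deterministic merging guarantees that parallel and
    serial runs produce identical output. Includes a synthetic genotype
    and phenotype generator, TSV/VCF input and output, a simple overhead
    model for run-time extrapolation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
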