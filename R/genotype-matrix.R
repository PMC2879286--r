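#' Genotype matrix container
#'
#' The shared data model for all statistics in the package: `N` individuals
#' by `M` biallelic SNPs, each genotype coded as the number of copies of the
#' alternate allele (0, 1, 2) with `NA` for missing calls. SNP metadata
#' (name, chromosome, 1-based position, reference and alternate allele)
#' travels with the matrix.
#'
#' @param codes integer matrix, individuals in rows, SNPs in columns; values
#'   must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `codes`.
#' @param snps data frame with columns `name`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `codes`. If `NULL`, placeholder metadata is
#'   generated (chromosome `"0"`, positions `1..M`, alleles `A`/`B`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `sample_ids` and `snps`.
#' @export
genotype_matrix <- function(codes, sample_ids, snps = NULL) {
  if (!is.matrix(codes)) stop_parameter("codes must be a matrix")
  storage.mode(codes) <- "integer"
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad))
    stop_format(sprintf("genotype codes must be 0/1/2/NA (%d offending cells)",
                        sum(bad)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(codes))
    stop_parameter("length(sample_ids) must equal nrow(codes)")
  if (anyDuplicated(sample_ids))
    stop_format("duplicate sample ids")
  if (is.null(snps)) {
    m <- ncol(codes)
    snps <- data.frame(name = paste0("snp", seq_len(m)),
                       chrom = rep("0", m), pos = seq_len(m),
                       ref = rep("A", m), alt = rep("C", m),
                       stringsAsFactors = FALSE)
  }
  snps <- validate_snp_info(snps, ncol(codes))
  dimnames(codes) <- list(sample_ids, snps$name)
  structure(list(codes = codes, sample_ids = sample_ids, snps = snps),
            class = "genotype_matrix")
}

validate_snp_info <- function(snps, m) {
  need <- c("name", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps)))
    stop_format(paste("SNP metadata must have columns:",
                      paste(need, collapse = ", ")))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)[, need]
  if (nrow(snps) != m)
    stop_format("SNP metadata row count does not match genotype columns")
  snps$name <- as.character(snps$name)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$ref <- as.character(snps$ref)
  snps$alt <- as.character(snps$alt)
  if (anyDuplicated(snps$name)) stop_format("duplicate SNP names")
  if (any(is.na(snps$pos)) || any(snps$pos < 1L))
    stop_format("SNP positions must be >= 1")
  if (any(!nzchar(snps$ref)) || any(!nzchar(snps$alt)) ||
      any(snps$ref == snps$alt))
    stop_format("ref/alt alleles must be non-empty and distinct")
  rownames(snps) <- NULL
  snps
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  n <- nrow(x$codes); m <- ncol(x$codes)
  miss <- mean(is.na(x$codes))
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              n, m, 100 * miss))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  genotype_matrix(x$codes[i, j, drop = FALSE],
                  x$sample_ids[i], x$snps[j, , drop = FALSE])
}

#' Alternate-allele frequencies
#'
#' Sample frequency of the alternate allele at each SNP, from all non-missing
#' genotypes. SNPs with no calls get `NA`.
#'
#' @param G a [genotype_matrix()].
#' @return numeric vector of length `M`, named by SNP.
#' @export
allele_freqs <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  colMeans(G$codes, na.rm = TRUE) / 2
}
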