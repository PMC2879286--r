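# Readers and writers for the package's on-disk formats. All tabular output
# is deterministic: tab-separated, "NA" for missing, floats printed with six
# significant digits, so identical inputs produce byte-identical files.

fmt_cell <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.6g", x)
    out[is.na(x)] <- "NA"
    out
  } else {
    out <- as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
}

#' Read a VCF file into a genotype matrix
#'
#' Parses the GT field of a VCF (via the \pkg{vcfR} package) into
#' alternate-allele dosages. Only biallelic single-nucleotide records are
#' used; multiallelic or non-SNP records are skipped and their count
#' reported via [message()]. A genotype with any missing allele (`./.`,
#' `0/.`) becomes `NA`; phased separators (`|`) are treated exactly like
#' unphased ones, i.e. phase is discarded.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [genotype_matrix()] with SNPs in file order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_io(paste("cannot read VCF:", path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_io(paste("invalid VCF:",
                                                    conditionMessage(e))))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L)
    stop_empty("VCF contains no variant records")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0L)
    message(sprintf("read_vcf: skipped %d multiallelic/non-SNP record(s)",
                    n_skip))
  if (!any(keep)) stop_empty("no biallelic SNP records in VCF")
  vcf <- vcf[keep, ]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # map each distinct GT string to a dosage once, then broadcast
  u <- unique(as.vector(gt))
  code_of <- vapply(u, function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    if (!all(al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  codes <- matrix(code_of[match(as.vector(gt), u)], nrow = nrow(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(name = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  genotype_matrix(t(codes), colnames(gt), snps)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCFv4.2 file with a single GT FORMAT field, in the
#' matrix's SNP order. Round-trips through [read_vcf()].
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- apply(G$codes, 2, function(col) {
    out <- rep("./.", length(col))
    ok <- !is.na(col)
    out[ok] <- gt_str[col[ok] + 1L]
    out
  })
  # body: individuals in rows, SNPs in columns; build one line per SNP
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$sample_ids), collapse = "\t"))
  s <- G$snps
  recs <- vapply(seq_len(nrow(s)), function(j) {
    paste(c(s$chrom[j], s$pos[j], s$name[j], s$ref[j], s$alt[j],
            ".", "PASS", ".", "GT", body[, j]), collapse = "\t")
  }, character(1))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(paste("cannot write:", path)))
  on.exit(close(con))
  writeLines(c(lines, recs), con)
  invisible(path)
}

#' Read a genotype TSV (with optional SNP-metadata sidecar)
#'
#' Format: a header row `id<TAB>snp1<TAB>...`, then one row per sample with
#' codes in `{0,1,2,NA}`. SNP metadata is read from `snp_path` (default
#' `<path>.snps`) when that file exists; otherwise placeholder metadata is
#' generated.
#'
#' @param path genotype TSV path.
#' @param snp_path sidecar TSV with columns name/chrom/pos/ref/alt, or
#'   `NULL` to use `<path>.snps` if present.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, snp_path = NULL) {
  if (!file.exists(path)) stop_io(paste("cannot read:", path))
  lines <- readLines(path)
  if (length(lines) < 1L) stop_format("empty genotype file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L || header[1L] != "id")
    stop_format("genotype TSV header must start with 'id'")
  snp_names <- header[-1L]
  m <- length(snp_names)
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != m + 1L))
    stop_format(sprintf("ragged row at line %d (expected %d fields, got %d)",
                        which(nf != m + 1L)[1L] + 1L, m + 1L,
                        nf[which(nf != m + 1L)[1L]]))
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids)) stop_format("duplicate sample ids in genotype TSV")
  toks <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  bad <- !(toks %in% c("0", "1", "2", "NA"))
  if (any(bad)) {
    line <- (which(bad)[1L] - 1L) %/% m + 2L
    stop_format(sprintf("invalid genotype token '%s' at line %d",
                        toks[which(bad)[1L]], line))
  }
  codes <- matrix(suppressWarnings(as.integer(toks)),
                  nrow = length(body), ncol = m, byrow = TRUE)
  if (is.null(snp_path)) {
    cand <- paste0(path, ".snps")
    if (file.exists(cand)) snp_path <- cand
  }
  snps <- NULL
  if (!is.null(snp_path)) {
    snps <- utils::read.delim(snp_path, sep = "\t", header = TRUE,
                              colClasses = "character",
                              check.names = FALSE, quote = "")
    snps$pos <- as.integer(snps$pos)
    if (!identical(as.character(snps$name), snp_names))
      stop_format("SNP sidecar names do not match genotype header")
  } else {
    snps <- data.frame(name = snp_names, chrom = "0", pos = seq_len(m),
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  G <- genotype_matrix(codes, ids, snps)
  message(sprintf("read_genotype_tsv: %d individuals x %d SNPs",
                  nrow(codes), m))
  G
}

#' Write a genotype matrix as TSV (plus SNP-metadata sidecar)
#'
#' Deterministic, byte-stable output for identical input.
#'
#' @param G a [genotype_matrix()].
#' @param path output genotype TSV path.
#' @param snp_path sidecar path for SNP metadata (default `<path>.snps`).
#' @export
write_genotype_tsv <- function(G, path, snp_path = paste0(path, ".snps")) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(paste("cannot write:", path)))
  on.exit(close(con))
  header <- paste(c("id", G$snps$name), collapse = "\t")
  chr <- matrix(as.character(G$codes), nrow = nrow(G$codes))
  chr[is.na(G$codes)] <- "NA"
  rows <- vapply(seq_len(nrow(chr)), function(i)
    paste(c(G$sample_ids[i], chr[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, rows), con)
  write_table(G$snps, snp_path)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with an `id` column plus one or more numeric columns (binary traits
#' coded 0/1). `NA` cells are allowed; any other non-numeric cell is a
#' format error.
#'
#' @param path phenotype TSV path.
#' @return data frame with character `id` plus numeric columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_io(paste("cannot read:", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "")
  if (!"id" %in% names(df)) stop_format("phenotype file must have an 'id' column")
  if (ncol(df) < 2L) stop_format("phenotype file needs at least one trait column")
  if (anyDuplicated(df$id))
    stop_format(sprintf("duplicate id '%s' in phenotype file",
                        df$id[anyDuplicated(df$id)[1L]][1L]))
  out <- data.frame(id = as.character(df$id), stringsAsFactors = FALSE)
  for (col in setdiff(names(df), "id")) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & !is.na(raw) & raw != "NA"
    if (any(bad))
      stop_format(sprintf("non-numeric value '%s' in phenotype column '%s'",
                          raw[which(bad)[1L]], col))
    out[[col]] <- num
  }
  out
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, no quoting, `NA` for missing, doubles formatted with six
#' significant digits. Writing the same table twice yields byte-identical
#' files. An empty table produces a header-only file.
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(paste("cannot write:", path)))
  on.exit(close(con))
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0L) {
    writeLines(header, con)
    return(invisible(path))
  }
  cols <- lapply(df, fmt_cell)
  rows <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Write a symmetric pair matrix as TSV
#'
#' First row and column carry the identifiers.
#'
#' @param x a [pair_matrix()] or plain numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "pair_matrix")) {
    ids <- x$ids; values <- x$values
  } else {
    values <- as.matrix(x)
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(paste("cannot write:", path)))
  on.exit(close(con))
  header <- paste(c("id", ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i)
    paste(c(ids[i], fmt_cell(values[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a symmetric matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_io(paste("cannot read:", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, colnames(df)[-1L])
  m
}
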