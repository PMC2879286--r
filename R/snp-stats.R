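# Type-1 statistics: computed per SNP (or per SNP and trait).

chi2_p <- function(chi2) {
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  # floor at the smallest positive double so -log10(p) stays finite
  pmax(p, .Machine$double.xmin)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test. Given the allele counts implied by the
#' genotype counts, the heterozygote count follows a known conditional
#' distribution; the p-value is the total probability of all heterozygote
#' counts whose conditional probability is less than or equal to that of the
#' observed count (no mid-p correction; exact ties are included in the sum).
#'
#' @param n_AA,n_AB,n_BB genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote); non-negative, sum >= 1.
#' @return p-value in `(0, 1]`. Monomorphic input gives 1 (the observed
#'   configuration is the only one possible given the allele counts).
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (!is_count(n_AA) || !is_count(n_AB) || !is_count(n_BB))
    stop_parameter("genotype counts must be non-negative integers")
  n <- n_AA + n_AB + n_BB
  if (n < 1L) stop_parameter("all genotype counts are zero")
  nA <- 2L * n_AA + n_AB
  nB <- 2L * n_BB + n_AB
  if (nA == 0L || nB == 0L) return(1)
  rare <- min(nA, nB)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log of the conditional probability up to a constant in h
  logp <- hs * log(2) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nB - hs) / 2 + 1)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- match(n_AB, hs)
  # tie tolerance on the log scale: mathematically equal probabilities that
  # differ only by floating-point rounding still count as ties
  min(1, sum(probs[logp <= logp[obs] + 1e-9]))
}

snp_summary_kernel <- function(G) {
  force(G)
  function(from, to) {
    jidx <- from:to
    sub <- G$codes[, jidx, drop = FALSE]
    n <- nrow(sub)
    n_AA <- colSums(sub == 0L, na.rm = TRUE)
    n_AB <- colSums(sub == 1L, na.rm = TRUE)
    n_BB <- colSums(sub == 2L, na.rm = TRUE)
    n_missing <- n - (n_AA + n_AB + n_BB)
    called <- n - n_missing
    q <- ifelse(called > 0L, (n_AB + 2 * n_BB) / (2 * called), NA_real_)
    hwe_p <- vapply(seq_along(jidx), function(k) {
      if (called[k] == 0L) return(NA_real_)
      hwe_exact_test(n_AA[k], n_AB[k], n_BB[k])
    }, numeric(1))
    data.frame(snp = G$snps$name[jidx], chrom = G$snps$chrom[jidx],
               pos = G$snps$pos[jidx],
               n_AA = as.integer(n_AA), n_AB = as.integer(n_AB),
               n_BB = as.integer(n_BB), n_missing = as.integer(n_missing),
               call_rate = called / n, q = q, hwe_p = hwe_p,
               stringsAsFactors = FALSE)
  }
}

#' Per-SNP summary statistics
#'
#' Genotype counts, missingness, call rate, alternate-allele frequency and
#' the Hardy-Weinberg exact-test p-value, one row per SNP in input order.
#' All-missing SNPs get call rate 0 and `NA` statistics rather than an
#' error.
#'
#' @param G a [genotype_matrix()].
#' @param nprocs processor count; the SNP axis is partitioned linearly and
#'   the per-chunk results merged in order, so the output is identical for
#'   every `nprocs`.
#' @param executor see [run_tasks()].
#' @return data frame with columns `snp`, `chrom`, `pos`, `n_AA`, `n_AB`,
#'   `n_BB`, `n_missing`, `call_rate`, `q`, `hwe_p`.
#' @export
snp_summary <- function(G, nprocs = 1L, executor = c("serial", "processes")) {
  stopifnot(inherits(G, "genotype_matrix"))
  executor <- match.arg(executor)
  if (ncol(G$codes) < 1L) stop_empty("no SNPs")
  run_linear_stat(ncol(G$codes), snp_summary_kernel(G), nprocs, executor,
                  "type1")
}

assoc_row_names <- c("snp", "chrom", "pos", "n", "beta", "se", "chi2", "p",
                     "status")

score_test_kernel <- function(G, y) {
  force(G); force(y)
  function(from, to) {
    jidx <- from:to
    out <- lapply(jidx, function(j) {
      g <- G$codes[, j]
      ok <- !is.na(g) & !is.na(y)
      n <- sum(ok)
      if (n < 2L)
        return(data.frame(snp = G$snps$name[j], chrom = G$snps$chrom[j],
                          pos = G$snps$pos[j], n = n, beta = NA_real_,
                          se = NA_real_, chi2 = NA_real_, p = NA_real_,
                          status = "too_few_pairs", stringsAsFactors = FALSE))
      gg <- g[ok]; yy <- y[ok]
      vg <- stats::var(gg); vy <- stats::var(yy)
      if (vg == 0 || vy == 0) {
        chi2 <- 0; p <- 1; status <- "zero_variance"
      } else {
        r <- stats::cor(gg, yy)
        chi2 <- n * r^2
        p <- chi2_p(chi2)
        status <- "ok"
      }
      data.frame(snp = G$snps$name[j], chrom = G$snps$chrom[j],
                 pos = G$snps$pos[j], n = n, beta = NA_real_, se = NA_real_,
                 chi2 = chi2, p = p, status = status,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}

#' Score test for association
#'
#' Fast 1-df association test per SNP: `chi2 = n * r^2`, where `r` is the
#' Pearson correlation between genotype code and trait over the `n`
#' complete pairs. For a 0/1 trait this is the Cochran-Armitage trend
#' statistic. Pairs with a missing genotype or trait are dropped per SNP;
#' SNPs with zero genotype or trait variance report `chi2 = 0`, `p = 1`.
#'
#' @param G a [genotype_matrix()].
#' @param y numeric trait vector aligned with `G$sample_ids`, or a phenotype
#'   data frame (from [read_phenotypes()]) together with `trait`.
#' @param trait trait column name when `y` is a data frame.
#' @inheritParams snp_summary
#' @return data frame, one row per SNP: `snp`, `chrom`, `pos`, `n`, `beta`,
#'   `se` (both `NA` for the score test), `chi2`, `p`, `status`.
#' @export
score_test <- function(G, y, trait = NULL, nprocs = 1L,
                       executor = c("serial", "processes")) {
  stopifnot(inherits(G, "genotype_matrix"))
  executor <- match.arg(executor)
  y <- align_trait(G, y, trait)
  run_linear_stat(ncol(G$codes), score_test_kernel(G, y), nprocs, executor,
                  "type1")
}

align_trait <- function(G, y, trait) {
  if (is.data.frame(y)) {
    if (is.null(trait)) stop_parameter("trait column name required")
    if (!trait %in% names(y)) stop_parameter(paste("no trait column:", trait))
    idx <- match(G$sample_ids, y$id)
    if (anyNA(idx))
      stop_parameter("phenotype table is missing some genotyped samples")
    y <- y[[trait]][idx]
  }
  if (length(y) != nrow(G$codes))
    stop_parameter("trait vector length must equal the number of individuals")
  as.numeric(y)
}

# Newton solver for the per-SNP logistic model. Returns coefficients and
# standard errors, or a diagnostic code on failure.
logistic_newton <- function(X, y, tol = 1e-8, max_iter = 25L) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu))
    if (sqrt(sum(grad^2)) <= tol) {
      H <- crossprod(X, X * w)
      Vi <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(Vi)) return(list(status = "rank_deficient"))
      se <- sqrt(diag(Vi))
      # a formally converged fit with an absurd slope or exploding standard
      # error is a separated data configuration, not a usable estimate
      if (abs(b[2L]) > 15 || !is.finite(se[2L]) || se[2L] > 100)
        return(list(status = "separation"))
      return(list(status = "ok", beta = b, se = se))
    }
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(list(status = "rank_deficient"))
    b <- b + step
    if (any(abs(b) > 1e3)) return(list(status = "separation"))
  }
  list(status = "not_converged")
}

ml_regression_kernel <- function(G, y, covar, model) {
  force(G); force(y); force(covar); force(model)
  function(from, to) {
    jidx <- from:to
    out <- lapply(jidx, function(j) {
      g <- G$codes[, j]
      row <- data.frame(snp = G$snps$name[j], chrom = G$snps$chrom[j],
                        pos = G$snps$pos[j], n = NA_integer_,
                        beta = NA_real_, se = NA_real_, chi2 = NA_real_,
                        p = NA_real_, status = "ok", stringsAsFactors = FALSE)
      ok <- !is.na(g) & !is.na(y)
      if (!is.null(covar)) ok <- ok & stats::complete.cases(covar)
      n <- sum(ok)
      row$n <- n
      p_par <- 2L + if (is.null(covar)) 0L else ncol(covar)
      if (n <= p_par) { row$status <- "too_few_pairs"; return(row) }
      gg <- as.numeric(g[ok]); yy <- y[ok]
      if (stats::var(gg) == 0) { row$status <- "zero_variance"; return(row) }
      X <- cbind(1, gg)
      if (!is.null(covar)) X <- cbind(X, as.matrix(covar[ok, , drop = FALSE]))
      if (model == "linear") {
        qx <- qr(X)
        if (qx$rank < ncol(X)) { row$status <- "rank_deficient"; return(row) }
        coefs <- qr.coef(qx, yy)
        res <- yy - drop(X %*% coefs)
        sigma2 <- sum(res^2) / (n - ncol(X))
        V <- chol2inv(qr.R(qx))
        row$beta <- coefs[2L]
        row$se <- sqrt(sigma2 * V[2L, 2L])
      } else {
        if (!all(yy %in% c(0, 1))) {
          row$status <- "trait_not_binary"; return(row)
        }
        fit <- logistic_newton(X, yy)
        if (fit$status != "ok") { row$status <- fit$status; return(row) }
        row$beta <- fit$beta[2L]
        row$se <- fit$se[2L]
      }
      if (is.na(row$se) || row$se < 1e-8) {
        row$status <- "degenerate_se"
      } else {
        row$chi2 <- (row$beta / row$se)^2
        row$p <- chi2_p(row$chi2)
      }
      row
    })
    do.call(rbind, out)
  }
}

#' Per-SNP regression association tests
#'
#' Fits `trait ~ genotype + covariates` for each SNP on its complete cases
#' and reports the Wald test for the genotype term: `chi2 = (beta/se)^2`
#' against chi-square with 1 df. Linear models are solved in closed form
#' (QR); logistic models by Newton iterations (gradient norm `<= 1e-8`,
#' at most 25 iterations). Separation, non-convergence or a rank-deficient
#' design yields a flagged row with a diagnostic code, never an error.
#'
#' @param G a [genotype_matrix()].
#' @param pheno phenotype data frame (see [read_phenotypes()]).
#' @param trait trait column name; must be 0/1 for `model = "logistic"`.
#' @param covariates character vector of covariate column names.
#' @param model `"linear"` or `"logistic"`.
#' @inheritParams snp_summary
#' @return data frame, one row per SNP: `snp`, `chrom`, `pos`, `n`, `beta`,
#'   `se`, `chi2`, `p`, `status`.
#' @export
ml_regression <- function(G, pheno, trait, covariates = character(),
                          model = c("linear", "logistic"), nprocs = 1L,
                          executor = c("serial", "processes")) {
  stopifnot(inherits(G, "genotype_matrix"))
  model <- match.arg(model)
  executor <- match.arg(executor)
  y <- align_trait(G, pheno, trait)
  covar <- NULL
  if (length(covariates) > 0L) {
    miss <- setdiff(covariates, names(pheno))
    if (length(miss) > 0L)
      stop_parameter(paste("missing covariate column(s):",
                           paste(miss, collapse = ", ")))
    idx <- match(G$sample_ids, pheno$id)
    covar <- as.matrix(pheno[idx, covariates, drop = FALSE])
  }
  run_linear_stat(ncol(G$codes), ml_regression_kernel(G, y, covar, model),
                  nprocs, executor, "type1")
}
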