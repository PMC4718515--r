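#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test of Hardy-Weinberg proportions by full enumeration of
#' heterozygote counts conditional on the observed allele counts: the p-value
#' is the total probability of all configurations no more probable than the
#' observed one. Intended for founder genotypes (testing relatives violates
#' the independence assumption).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("all genotype counts are zero; the test is undefined")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  # log P(h | allele counts) up to a shared constant
  logp <- vapply(hets, function(h) {
    h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) - lfactorial((na - h) / 2)
  }, 0)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Quality-control filtering of a genotype matrix
#'
#' Applies the standard inclusion filters of array-based family studies:
#' per-SNP call rate, founder minor-allele frequency, an exact
#' Hardy-Weinberg test on founders, and (when an imputation info score is
#' supplied) a minimum info score. Flags are a pure function of the
#' genotypes — never of any trait. Set a threshold to `NA` to disable that
#' filter.
#'
#' @param genotypes SNP-by-individual matrix of allele counts or dosages
#'   (from [simulate_genotypes()] or [read_genotype_matrix()]).
#' @param ped A `ped_tbl`; founders are used for allele frequencies and the
#'   HWE test. When `maf_on_founders = FALSE` the full sample is used for
#'   the frequency (founders are still used for HWE).
#' @param info Optional named numeric vector of imputation info scores.
#' @param maf_min,callrate_min,hwe_p_min,info_min Filter thresholds.
#' @param maf_on_founders Compute the allele frequency on founders only?
#' @return A list with `genotypes` (rows passing all enabled filters) and
#'   `flags`, a tibble with per-SNP statistics and failure flags.
#' @export
qc_filter <- function(genotypes, ped, info = NULL, maf_min = 0.01,
                      callrate_min = 0.98, hwe_p_min = 1e-6, info_min = 0.3,
                      maf_on_founders = TRUE) {
  stopifnot(is.matrix(genotypes), inherits(ped, "ped_tbl"))
  snps <- rownames(genotypes) %||% as.character(seq_len(nrow(genotypes)))
  fo <- intersect(founders(ped), colnames(genotypes))
  freq_cols <- if (maf_on_founders) fo else colnames(genotypes)
  callrate <- rowMeans(!is.na(genotypes))
  f <- rowMeans(genotypes[, freq_cols, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  Gf <- round(genotypes[, fo, drop = FALSE])
  hwe_p <- vapply(seq_len(nrow(genotypes)), function(i) {
    g <- Gf[i, ][!is.na(Gf[i, ])]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, 0)
  info_v <- if (is.null(info)) rep(NA_real_, length(snps)) else
    unname(info[snps])
  flags <- tibble::tibble(
    snp = snps, maf = unname(maf), callrate = unname(callrate),
    hwe_p = hwe_p, info = info_v,
    maf_fail = if (is.na(maf_min)) FALSE else maf < maf_min,
    callrate_fail = if (is.na(callrate_min)) FALSE else callrate < callrate_min,
    hwe_fail = if (is.na(hwe_p_min)) FALSE else !is.na(hwe_p) & hwe_p <= hwe_p_min,
    info_fail = if (is.na(info_min) || is.null(info)) FALSE else
      !is.na(info_v) & info_v < info_min
  )
  flags$pass <- !(flags$maf_fail | flags$callrate_fail | flags$hwe_fail |
                    flags$info_fail)
  list(genotypes = genotypes[flags$pass, , drop = FALSE], flags = flags)
}

# shared engine: whiten trait/design/genotypes with the null-model covariance
# and return per-SNP score quantities. `fit0` is a vc_fit on the same data.
assoc_engine <- function(fit0, genotypes) {
  d <- fit0$data
  G <- genotypes[, d$id, drop = FALSE]
  # whiten by family blocks using the null-fit covariance (including scale)
  yt <- numeric(fit0$n)
  Xt <- matrix(0, fit0$n, ncol(fit0$blocks[[1]]$X))
  Gt <- matrix(0, nrow(G), fit0$n)
  h2 <- fit0$h2; c2 <- fit0$c2; e2 <- 1 - h2 - c2
  pos <- 0
  for (b in fit0$blocks) {
    V <- fit0$sigma2 * (h2 * b$K + c2 * b$H + e2 * diag(b$n))
    L <- chol(V)
    ix <- pos + seq_len(b$n)
    yt[ix] <- backsolve(L, b$y, transpose = TRUE)
    Xt[ix, ] <- backsolve(L, b$X, transpose = TRUE)
    gblk <- G[, b$ix, drop = FALSE]
    if (anyNA(gblk)) {  # per-SNP mean dosage imputation
      rm_ <- rowMeans(gblk, na.rm = TRUE)
      na_ix <- which(is.na(gblk), arr.ind = TRUE)
      gblk[na_ix] <- rm_[na_ix[, 1]]
      gblk[is.na(gblk)] <- 0
    }
    Gt[, ix] <- t(backsolve(L, t(gblk), transpose = TRUE))
    pos <- pos + b$n
  }
  qrX <- qr(Xt)
  yr <- qr.resid(qrX, yt)
  Gr <- t(qr.resid(qrX, t(Gt)))
  gg <- rowSums(Gr^2)
  gy <- as.vector(Gr %*% yr)
  mono <- gg < 1e-10
  beta <- ifelse(mono, NA_real_, gy / gg)
  se <- ifelse(mono, NA_real_, 1 / sqrt(gg))
  chisq <- ifelse(mono, NA_real_, gy^2 / gg)
  tibble::tibble(
    snp = rownames(G) %||% as.character(seq_len(nrow(G))),
    beta = beta, se = se, chisq = chisq,
    p = pchisq(chisq, 1, lower.tail = FALSE),
    n = fit0$n, monomorphic = mono
  )
}

#' Measured-genotype association test
#'
#' Tests a SNP for association with a continuous trait on a pedigree by
#' adding its allele count (or dosage) to the fixed effects of the
#' variance-component model. By default the variance components are profiled
#' once under the null model and held fixed, giving a score-type chi-squared
#' statistic per SNP; `refit = TRUE` re-estimates them under the alternative
#' and uses the full likelihood-ratio statistic.
#'
#' @param data Phenotype tibble (`fid`, `id`, trait, covariates).
#' @param ped A `ped_tbl`.
#' @param trait Trait column.
#' @param genotypes Genotype matrix (the tested SNP's row) or a single named
#'   vector of allele counts.
#' @param snp SNP row name to test (first row if omitted).
#' @param covariates Covariate columns for the null model.
#' @param condition_on Optional SNP row name(s) whose dosages enter the null
#'   model as covariates (conditional analysis).
#' @param refit Re-estimate variance components under the alternative?
#' @param null_fit Optional precomputed null `vc_fit` (for repeated calls).
#' @return A one-row tibble with `snp`, `beta`, `se`, `chisq`, `p`, `n`.
#' @export
measured_genotype_test <- function(data, ped, trait, genotypes, snp = NULL,
                                   covariates = character(0),
                                   condition_on = NULL, refit = FALSE,
                                   null_fit = NULL) {
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(genotypes, 1, dimnames = list("snp", names(genotypes)))
  }
  snp <- snp %||% rownames(genotypes)[1]
  d <- tibble::as_tibble(data)
  cv <- covariates
  if (!is.null(condition_on)) {
    for (cs in condition_on) {
      col <- paste0(".g_", cs)
      d[[col]] <- as.numeric(genotypes[cs, d$id])
      cv <- c(cv, col)
    }
  }
  if (refit) {
    col <- paste0(".g_", snp)
    d[[col]] <- as.numeric(genotypes[snp, d$id])
    fit0 <- fit_univariate(d, ped, trait, covariates = cv, screen = FALSE, se = FALSE)
    fit1 <- fit_univariate(d, ped, trait, covariates = c(cv, col),
                           screen = FALSE, se = FALSE)
    T <- max(0, 2 * (fit1$loglik - fit0$loglik))
    co <- fit1$coefficients[fit1$coefficients$term == col, ]
    return(tibble::tibble(snp = snp, beta = co$estimate, se = co$std.error,
                          chisq = T, p = pchisq(T, 1, lower.tail = FALSE),
                          n = fit1$n, monomorphic = FALSE))
  }
  if (is.null(null_fit)) {
    null_fit <- fit_univariate(d, ped, trait, covariates = cv,
                               screen = FALSE, se = FALSE)
  }
  res <- assoc_engine(null_fit, genotypes[snp, , drop = FALSE])
  if (res$monomorphic[1]) {
    warn(paste0("SNP ", snp, " has no residual genotype variation ",
                "(monomorphic or collinear with the conditioning set); test skipped"))
  }
  res
}

#' Genomic inflation factor
#'
#' Median-based lambda: the median association chi-squared statistic divided
#' by the theoretical null median of a 1-df chi-squared (0.4549). Values near
#' 1 indicate a calibrated test; inflation suggests unmodelled structure.
#'
#' @param p P-values (converted through the inverse chi-squared upper tail),
#'   or supply `chisq` directly.
#' @param chisq 1-df chi-squared statistics.
#' @return Lambda (scalar).
#' @export
genomic_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0) abort("supply p-values or chi-squared statistics")
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0) abort("no finite statistics")
  median(chisq) / qchisq(0.5, df = 1)
}

#' Genome-wide measured-genotype association scan
#'
#' QC-filters a genotype matrix, runs the measured-genotype test for every
#' passing SNP against a pedigree trait, classifies results at the
#' genome-wide (`5e-8`) and suggestive (`1e-5`) thresholds, and attaches the
#' genomic inflation factor. Results are ordered by position (when supplied)
#' then SNP id, so reruns are byte-identical.
#'
#' @param data Phenotype tibble.
#' @param ped A `ped_tbl`.
#' @param trait Trait column.
#' @param genotypes SNP-by-individual genotype matrix.
#' @param covariates Covariate columns for the null model.
#' @param info Optional named info-score vector (enables the info filter).
#' @param positions Optional tibble `snp`, `chrom`, `pos` for ordering and
#'   plotting.
#' @param condition_on Optional SNP id(s) to condition on.
#' @param qc Apply [qc_filter()] first?
#' @param genomewide,suggestive Significance thresholds.
#' @param ... Passed to [qc_filter()].
#' @return A tibble of class `gwas_result` (one row per tested SNP) with
#'   attributes `lambda`, `n_genomewide`, `n_suggestive` and `flags` (the QC
#'   table).
#' @export
run_gwas <- function(data, ped, trait, genotypes, covariates = character(0),
                     info = NULL, positions = NULL, condition_on = NULL,
                     qc = TRUE, genomewide = 5e-8, suggestive = 1e-5, ...) {
  if (nrow(genotypes) == 0) {
    warn("empty genotype set: lambda undefined")
    out <- tibble::tibble(snp = character(0), maf = numeric(0),
                          beta = numeric(0), se = numeric(0),
                          chisq = numeric(0), p = numeric(0), n = integer(0),
                          significance = character(0))
    attr(out, "lambda") <- NA_real_
    class(out) <- c("gwas_result", class(out))
    return(out)
  }
  flags <- NULL
  if (qc) {
    qcres <- qc_filter(genotypes, ped, info = info, ...)
    genotypes <- qcres$genotypes
    flags <- qcres$flags
    maf <- setNames(qcres$flags$maf, qcres$flags$snp)
  } else {
    fo <- intersect(founders(ped), colnames(genotypes))
    f <- rowMeans(genotypes[, fo, drop = FALSE], na.rm = TRUE) / 2
    maf <- setNames(pmin(f, 1 - f), rownames(genotypes))
  }
  d <- tibble::as_tibble(data)
  cv <- covariates
  if (!is.null(condition_on)) {
    for (cs in condition_on) {
      col <- paste0(".g_", cs)
      d[[col]] <- as.numeric(genotypes[cs, d$id])
      cv <- c(cv, col)
    }
    genotypes <- genotypes[setdiff(rownames(genotypes), condition_on), , drop = FALSE]
  }
  fit0 <- fit_univariate(d, ped, trait, covariates = cv, screen = FALSE, se = FALSE)
  res <- assoc_engine(fit0, genotypes)
  res$maf <- unname(maf[res$snp])
  res$significance <- dplyr::case_when(
    is.na(res$p) ~ "none",
    res$p < genomewide ~ "genome-wide",
    res$p < suggestive ~ "suggestive",
    TRUE ~ "none"
  )
  if (!is.null(positions)) {
    res <- dplyr::left_join(res, positions, by = "snp")
    res <- dplyr::arrange(res, .data$chrom, .data$pos, .data$snp)
  } else {
    res <- dplyr::arrange(res, .data$snp)
  }
  res <- dplyr::relocate(res, "snp", "maf")
  attr(res, "lambda") <- genomic_lambda(chisq = res$chisq)
  attr(res, "n_genomewide") <- sum(res$significance == "genome-wide")
  attr(res, "n_suggestive") <- sum(res$significance == "suggestive")
  attr(res, "flags") <- flags
  class(res) <- c("gwas_result", class(res))
  res
}

#' Manhattan-style plot of a GWAS result
#'
#' @param object A `gwas_result` from [run_gwas()].
#' @param genomewide,suggestive Threshold lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_result <- function(object, genomewide = 5e-8, suggestive = 1e-5,
                                 ...) {
  df <- tibble::as_tibble(object)
  df$index <- seq_len(nrow(df))
  xvar <- if ("pos" %in% names(df)) "pos" else "index"
  colvar <- if ("chrom" %in% names(df)) "chrom" else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = -log10(.data$p)))
  p <- if (is.null(colvar)) p + ggplot2::geom_point(size = 0.7) else
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colvar]])),
                            size = 0.7, show.legend = FALSE)
  p +
    ggplot2::geom_hline(yintercept = -log10(genomewide), linetype = "solid") +
    ggplot2::geom_hline(yintercept = -log10(suggestive), linetype = "dashed") +
    ggplot2::labs(x = if (xvar == "pos") "position" else "SNP index",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
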