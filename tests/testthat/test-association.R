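test_that("the exact HWE test matches a full enumeration oracle", {
  # independent oracle: conditional distribution of the heterozygote count
  # computed from genotype-configuration multinomial coefficients
  hwe_oracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    na <- 2 * n - nA
    hets <- seq(nA %% 2, min(nA, na), by = 2)
    logw <- vapply(hets, function(h) {
      lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
        lfactorial((na - h) / 2) + h * log(2) +
        lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
    }, 0)
    pr <- exp(logw)
    expect_equal(sum(pr), 1, tolerance = 1e-10)  # enumeration normalizes
    obs <- pr[match(nAa, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }
  cases <- list(c(57, 14, 50), c(10, 21, 10), c(68, 28, 4), c(0, 1, 99),
                c(100, 40, 60), c(3, 4, 3))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  }
  expect_lt(hwe_exact_test(57, 14, 50), 1e-6)  # gross heterozygote deficit
  expect_equal(hwe_exact_test(25, 0, 0), 1)    # monomorphic site
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3) # hand-enumerated two-sample case
  expect_error(hwe_exact_test(0, 0, 0), "undefined")
})

test_that("QC filters exclude SNPs on frequency, info, call rate and HWE", {
  ped <- ped_founders_only(400)
  withr::with_seed(55, {
    g_ok <- rbinom(400, 2, 0.3)
    g_rare <- rbinom(400, 2, 0.005)    # MAF ~0.5%
    g_miss <- g_ok; g_miss[1:40] <- NA # call rate 90%
  })
  g_hwe <- c(rep(0, 170), rep(1, 30), rep(2, 200))  # het deficit
  G <- rbind(ok = g_ok, rare = g_rare, miss = g_miss, hwe = g_hwe)
  colnames(G) <- ped$id
  info <- c(ok = 0.99, rare = 0.98, miss = 0.97, hwe = 0.95)
  res <- qc_filter(G, ped, info = info)
  expect_setequal(rownames(res$genotypes), "ok")
  fl <- res$flags
  expect_true(fl$maf_fail[fl$snp == "rare"])
  expect_true(fl$callrate_fail[fl$snp == "miss"])
  expect_true(fl$hwe_fail[fl$snp == "hwe"])
  # info filter alone
  info2 <- c(ok = 0.2, rare = 0.99, miss = 0.99, hwe = 0.99)
  res2 <- qc_filter(G, ped, info = info2, maf_min = NA, callrate_min = NA,
                    hwe_p_min = NA)
  expect_false("ok" %in% rownames(res2$genotypes))
  # all filters disabled: identity
  res3 <- qc_filter(G, ped, maf_min = NA, callrate_min = NA, hwe_p_min = NA,
                    info_min = NA)
  expect_equal(rownames(res3$genotypes), rownames(G))
})

test_that("the measured-genotype test equals least squares on unrelated founders", {
  n <- 500
  ped <- ped_founders_only(n)
  g <- simulate_genotypes(ped, 1, maf = 0.3, seed = 301)
  withr::with_seed(302, {
    y <- 0.4 * as.numeric(g[1, ]) + rnorm(n)
  })
  d <- tibble::tibble(fid = ped$fid, id = ped$id, y = y)
  res <- measured_genotype_test(d, ped, "y", g, snp = "snp00001")
  ols <- summary(lm(y ~ as.numeric(g[1, d$id])))
  expect_lt(abs(res$beta - ols$coefficients[2, 1]), 1e-6)
  # score-type chi-squared agrees with the OLS t-test up to the finite-sample
  # degrees-of-freedom correction in the residual variance
  expect_lt(abs(log10(res$p) - log10(ols$coefficients[2, 4])), 0.5)
  # the statistic is exactly the drop in whitened residual sum of squares,
  # i.e. the score form with the null-model residual variance
  lm0 <- lm(y ~ 1, data = d)
  lm1 <- lm(y ~ as.numeric(g[1, d$id]), data = d)
  T_exp <- (sum(resid(lm0)^2) - sum(resid(lm1)^2)) / (sum(resid(lm0)^2) / n)
  expect_equal(res$chisq, T_exp, tolerance = 1e-6)
  # exact re-fit route agrees with the profiled route on founders
  res2 <- measured_genotype_test(d, ped, "y", g, snp = "snp00001", refit = TRUE)
  expect_lt(abs(res2$beta - res$beta), 1e-6)
})

test_that("genomic lambda is the median statistic over the null median", {
  q <- qchisq(ppoints(999), df = 1)
  expect_equal(genomic_lambda(chisq = q), 1, tolerance = 1e-6)
  expect_equal(genomic_lambda(chisq = 2 * q), 2, tolerance = 1e-6)
  p <- pchisq(q, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p = p), 1, tolerance = 1e-6)
  expect_error(genomic_lambda(), "supply")
  expect_error(genomic_lambda(p = numeric(0)), "supply")
})

test_that("a spiked-in causal SNP is the only genome-wide hit and conditioning removes it", {
  ped <- simulate_pedigree(35, seed = 311)
  spec <- trait_model_spec(traits = "q", h2 = 0.5, c2 = 0, sigma2 = 1,
                           mean = 0, beta = NULL)
  d <- simulate_traits(ped, spec, seed = 312)
  G <- simulate_genotypes(ped, 300, maf = c(0.05, 0.5), seed = 313)
  d <- add_snp_effect(d, G, "snp00007", "q", 1)
  res <- run_gwas(d, ped, "q", G)
  hits <- res$snp[res$significance == "genome-wide"]
  expect_equal(hits, "snp00007")
  # conditional analysis on the causal variant: no residual signal
  res_c <- run_gwas(d, ped, "q", G, condition_on = "snp00007")
  expect_false("snp00007" %in% res_c$snp)
  expect_gt(min(res_c$p, na.rm = TRUE), 1e-6)
  expect_equal(sum(res_c$significance == "genome-wide"), 0)
  # deterministic outputs: rerun is identical
  res_rerun <- run_gwas(d, ped, "q", G)
  expect_identical(tibble::as_tibble(res), tibble::as_tibble(res_rerun))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("empty genotype sets give an empty result with lambda flagged undefined", {
  ped <- ped_nuclear()
  d <- tibble::tibble(fid = ped$fid, id = ped$id, y = rnorm(4))
  G <- matrix(numeric(0), 0, 4, dimnames = list(NULL, ped$id))
  expect_warning(res <- run_gwas(d, ped, "y", G), "lambda undefined")
  expect_equal(nrow(res), 0)
  expect_true(is.na(attr(res, "lambda")))
})

test_that("QC flags do not depend on the trait", {
  ped <- ped_founders_only(200)
  g <- simulate_genotypes(ped, 20, maf = c(0.05, 0.4), seed = 321)
  f1 <- qc_filter(g, ped)$flags
  f2 <- qc_filter(g, ped)$flags   # no trait enters the call at all
  expect_identical(f1, f2)
  expect_false(any(c("p", "beta") %in% names(f1)))
})
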