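test_that("all generators are reproducible under a fixed seed", {
  p1 <- simulate_pedigree(4, seed = 5)
  p2 <- simulate_pedigree(4, seed = 5)
  expect_identical(p1, p2)
  t1 <- simulate_traits(p1, trait_model_spec(), seed = 6)
  t2 <- simulate_traits(p1, trait_model_spec(), seed = 6)
  expect_identical(t1, t2)
  b1 <- simulate_binary_trait(p1, seed = 7)
  b2 <- simulate_binary_trait(p1, seed = 7)
  expect_identical(b1, b2)
  g1 <- simulate_genotypes(p1, 20, seed = 8)
  g2 <- simulate_genotypes(p1, 20, seed = 8)
  expect_identical(g1, g2)
})

test_that("simulated studies satisfy the family size and depth constraints", {
  ped <- simulate_pedigree(35, min_size = 10, min_generations = 3, seed = 42)
  sizes <- table(ped$fid)
  expect_equal(length(sizes), 35)
  expect_true(all(sizes >= 10))
  depth <- tapply(ped$generation, ped$fid, max)
  expect_true(all(depth >= 3))
  # extended structure populates the 0.5 / 0.25 / 0.125 kinship classes
  cp <- classify_pairs(ped)
  for (v in c(0.5, 0.25, 0.125)) {
    expect_gt(sum(cp$n_pairs[abs(cp$two_phi - v) < 1e-12]), 0)
  }
  expect_error(simulate_pedigree(2, min_size = 10, min_generations = 1),
               "unattainable")
})

test_that("sibling trait covariance matches the variance-component prediction", {
  ped <- ped_sib_pairs(3000)
  # pure-noise limit: unrelated trait values across siblings
  d0 <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0, c2 = 0,
                                              sigma2 = 1, mean = 0, beta = NULL),
                        seed = 31)
  c1 <- d0$y[endsWith(d0$id, "_c1")]
  c2 <- d0$y[endsWith(d0$id, "_c2")]
  expect_lt(abs(cor(c1, c2)), 0.05)
  # h2 = 0.5: sibling covariance = 2phi_sib / 2 * sigma2_g = 0.25 * sigma2
  d1 <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0.5, c2 = 0,
                                              sigma2 = 1, mean = 0, beta = NULL),
                        seed = 32)
  s1 <- d1$y[endsWith(d1$id, "_c1")]
  s2 <- d1$y[endsWith(d1$id, "_c2")]
  expect_lt(abs(cov(s1, s2) - 0.25), 0.05)
})

test_that("covariate effects are recovered by regression on unrelated samples", {
  n <- 3000
  ped <- ped_founders_only(n)
  cov <- tibble::tibble(fid = ped$fid, id = ped$id,
                        oc = rbinom(n, 1, 0.5))
  # oral-contraceptive effect of 0.87 trait units
  spec <- trait_model_spec(traits = "y", h2 = 0, c2 = 0, sigma2 = 0.3,
                           mean = 0, beta = list(y = c(oc = 0.87)))
  withr::with_seed(77, {
    d <- simulate_traits(ped, spec, covariates = cov)
  })
  slope <- coef(lm(y ~ oc, data = d))[["oc"]]
  expect_lt(abs(slope - 0.87), 0.05)
})

test_that("threshold-liability affection matches its prevalence and familial structure", {
  # symmetric threshold
  ped <- ped_founders_only(2000)
  b <- simulate_binary_trait(ped, h2 = 0.5, prevalence = 0.5, seed = 11)
  expect_lt(abs(mean(b$affected) - 0.5), 0.04)
  # no genetic component: affection independent across siblings
  sibs <- ped_sib_pairs(5000)
  b0 <- simulate_binary_trait(sibs, h2 = 0, prevalence = 0.1, seed = 12)
  a1 <- b0$affected[endsWith(b0$id, "_c1")]
  a2 <- b0$affected[endsWith(b0$id, "_c2")]
  p_rec <- mean(a2[a1 == 1])
  expect_lt(abs(p_rec - 0.1), 0.03)
  # h2 = 0.67: joint sibling affection matches the bivariate-normal orthant
  # probability with liability correlation 0.67/2 = 0.335
  b1 <- simulate_binary_trait(sibs, h2 = 0.67, prevalence = 0.1, seed = 13)
  s1 <- b1$affected[endsWith(b1$id, "_c1")]
  s2 <- b1$affected[endsWith(b1$id, "_c2")]
  thr <- qnorm(0.9)
  p_orth <- mvtnorm::pmvnorm(lower = c(thr, thr), upper = c(Inf, Inf),
                             corr = matrix(c(1, 0.335, 0.335, 1), 2))[1]
  expect_gt(p_orth, 0.1^2)  # recurrence above independence
  expect_lt(abs(mean(s1 & s2) - p_orth), 3.5 * sqrt(p_orth / 5000))
})

test_that("proband ascertainment retains qualifying families with one proband each", {
  ped <- build_pedigree(tibble::tibble(
    fid = rep(c("A", "B"), each = 3),
    id = c("af", "am", "ac", "bf", "bm", "bc"),
    father = c(NA, NA, "af", NA, NA, "bf"),
    mother = c(NA, NA, "am", NA, NA, "bm"),
    sex = c(1, 2, 1, 1, 2, 1)
  ))
  # keyed by id (build_pedigree reorders rows topologically)
  status <- tibble::tibble(
    id = c("af", "am", "ac", "bf", "bm", "bc"),
    affected = c(0, 0, 1, 0, 0, 1),
    onset_age = c(NA, NA, 40, NA, NA, 60)
  )
  phen <- dplyr::left_join(tibble::tibble(fid = ped$fid, id = ped$id),
                           status, by = "id")
  # family A: onset 40 qualifies; family B: onset 60, no affected relatives
  out <- ascertain_families(phen, ped)
  expect_setequal(unique(out$fid), "A")
  expect_equal(out$id[out$proband], "ac")

  # no affected anywhere: empty result with a warning
  none <- phen; none$affected <- 0; none$onset_age <- NA
  expect_warning(res <- ascertain_families(none, ped), "no family")
  expect_equal(nrow(res), 0)

  # all families qualify: identity with one proband per family
  all_q <- phen
  all_q$onset_age[all_q$id %in% c("ac", "bc")] <- 30
  out2 <- ascertain_families(all_q, ped)
  expect_setequal(unique(out2$fid), c("A", "B"))
  expect_equal(as.vector(tapply(out2$proband, out2$fid, sum)), c(1, 1))

  # ties in onset broken by id order; affected relative rescues late onset
  fam <- build_pedigree(tibble::tibble(
    fid = "C", id = c("f", "m", "x", "y"),
    father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
    sex = c(1, 2, 1, 1)
  ))
  ph <- tibble::tibble(fid = "C", id = c("f", "m", "x", "y"),
                       affected = c(0, 0, 1, 1), onset_age = c(NA, NA, 50, 50))
  out3 <- ascertain_families(ph, fam)   # both qualify via affected sibling
  expect_equal(out3$id[out3$proband], "x")
})

test_that("gene dropping is Mendelian and matches target allele frequencies", {
  ped <- simulate_pedigree(5, seed = 21)
  g <- simulate_genotypes(ped, 50, maf = 0.3, seed = 22)
  # exhaustive Mendelian-compatibility check: child count must lie between
  # the minimum and maximum transmissible counts of its parents
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in which(!ped$founder)) {
    gf <- g[, idx[ped$father[i]]]
    gm <- g[, idx[ped$mother[i]]]
    lo <- (gf == 2) + (gm == 2)
    hi <- (gf > 0) + (gm > 0)
    expect_true(all(g[, i] >= lo & g[, i] <= hi))
  }
  # founder allele frequency
  pedf <- ped_founders_only(5000)
  gf <- simulate_genotypes(pedf, 1, maf = 0.2, seed = 23)
  expect_lt(abs(mean(gf) / 2 - 0.2), 0.01)
})

test_that("an additive SNP effect is recovered by regression on founders", {
  n <- 2000
  ped <- ped_founders_only(n)
  g <- simulate_genotypes(ped, 1, maf = 0.2, seed = 41)
  cov <- tibble::tibble(fid = ped$fid, id = ped$id)
  spec <- trait_model_spec(traits = "y", h2 = 0, c2 = 0, sigma2 = 0.25,
                           mean = 0, beta = NULL)
  d <- simulate_traits(ped, spec, covariates = cov, seed = 42)
  d <- add_snp_effect(d, g, "snp00001", "y", 0.5)
  slope <- coef(lm(d$y ~ as.numeric(g[1, d$id])))[[2]]
  expect_lt(abs(slope - 0.5), 0.06)
})

test_that("trait model specs validate their variance decomposition", {
  expect_error(trait_model_spec(h2 = 0.7, c2 = 0.4), "h2 \\+ c2")
  expect_error(trait_model_spec(rho_g = 1.2, traits = c("a", "b"),
                                beta = NULL, h2 = 0.3, c2 = 0),
               "correlations")
  expect_error(trait_model_spec(sigma2 = 0), "sigma2")
  # exp transform returns a strictly positive trait whose log is the
  # analysis-scale value
  ped <- ped_nuclear()
  cov <- tibble::tibble(fid = ped$fid, id = ped$id)
  sp <- trait_model_spec(traits = "y", h2 = 0.4, c2 = 0, sigma2 = 1,
                         mean = 1, beta = NULL, transform = "exp")
  d <- simulate_traits(ped, sp, covariates = cov, seed = 3)
  expect_true(all(d$y > 0))
})
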