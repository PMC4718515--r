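test_that("the phenotypic-correlation decomposition matches its closed form", {
  # worked example at the study's published precision
  expect_equal(derived_rho_p(0.52, 0.54, 0.87, 0.82), 0.8463, tolerance = 1e-4)
  expect_equal(round(derived_rho_p(0.52, 0.54, 0.87, 0.82), 2), 0.85)
  expect_equal(derived_rho_p(0.3, 0.7, 0, 0), 0)
  expect_equal(derived_rho_p(1, 1, 0.6, -0.9), 0.6)  # environmental term vanishes
  expect_error(derived_rho_p(1.2, 0.5, 0, 0), "\\[0, 1\\]")
  expect_error(derived_rho_p(0.5, 0.5, 2, 0), "\\[-1, 1\\]")
})

test_that("the decomposition is bounded in [-1, 1] over the whole parameter range", {
  grid <- expand.grid(h1 = seq(0, 1, 0.2), h2 = seq(0, 1, 0.2),
                      rg = seq(-1, 1, 0.5), re = seq(-1, 1, 0.5))
  vals <- mapply(derived_rho_p, grid$h1, grid$h2, grid$rg, grid$re)
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
})

test_that("a duplicated trait drives the fitted correlation to the boundary", {
  # with an exact copy the joint likelihood diverges on the perfect-
  # correlation ridge: the identifiable quantities are the total correlation
  # (rho_p -> 1, via whichever component the optimizer loads) and the
  # boundary flag; components whose variance collapses are unidentified
  ped <- simulate_pedigree(8, seed = 201)
  d <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0.5, c2 = 0.2,
                                             sigma2 = 1, mean = 0, beta = NULL),
                       seed = 202)
  d$y2 <- d$y
  fit <- fit_bivariate(d, ped, c("y", "y2"), se = FALSE,
                       control = list(lrt = FALSE))
  expect_gt(fit$rho_p, 0.95)
  expect_gt(max(fit$rho_g, fit$rho_e), 0.95)
  expect_true(fit$rho_boundary)
})

test_that("independently simulated traits show near-zero correlations", {
  ped <- simulate_pedigree(12, seed = 211)
  spec0 <- trait_model_spec(traits = c("a", "b"), h2 = c(0.5, 0.5),
                            c2 = c(0.2, 0.2), sigma2 = 1, mean = 0,
                            beta = NULL, rho_g = 0, rho_e = 0, rho_c = 0)
  d <- simulate_traits(ped, spec0, seed = 212)
  fit <- fit_bivariate(d, ped, c("a", "b"), se = FALSE)
  expect_lt(abs(fit$rho_g), 0.45)
  expect_lt(abs(fit$rho_e), 0.3)
  expect_gt(fit$p_rho_g, 1e-4)
  expect_gt(fit$p_rho_e, 1e-4)
})

test_that("bivariate marginals collapse to the univariate fits when correlations vanish", {
  ped <- simulate_pedigree(10, seed = 221)
  d <- simulate_traits(ped, etp_tp_spec(), seed = 222)
  biv <- fit_bivariate(d, ped, c("etp", "tp"), se = FALSE,
                       control = list(lrt = FALSE,
                                      fix = list(rho_g = 0, rho_e = 0,
                                                 rho_c = 0)))
  u1 <- fit_univariate(d, ped, "etp", screen = FALSE, se = FALSE)
  u2 <- fit_univariate(d, ped, "tp", screen = FALSE, se = FALSE)
  expect_equal(unname(biv$h2[1]), u1$h2, tolerance = 5e-3)
  expect_equal(unname(biv$h2[2]), u2$h2, tolerance = 5e-3)
  expect_equal(unname(biv$c2[1]), u1$c2, tolerance = 5e-3)
  expect_equal(unname(biv$c2[2]), u2$c2, tolerance = 5e-3)
})

test_that("strongly pleiotropic generative models yield matching bivariate estimates", {
  ped <- simulate_pedigree(15, seed = 231)
  d <- simulate_traits(ped, etp_tp_spec(), seed = 232)
  fit <- fit_bivariate(d, ped, c("etp", "tp"),
                       covariates = list(etp = c("age_c", "age2", "oc"),
                                         tp = c("age_c", "age2", "female", "oc")),
                       se = TRUE)
  expect_lt(abs(fit$rho_g - 0.87), 0.15)
  expect_lt(abs(fit$rho_e - 0.82), 0.15)
  expect_lt(fit$p_rho_g, 1e-4)
  # derived rho_p consistent with the decomposition of the point estimates
  expect_equal(fit$rho_p,
               derived_rho_p(fit$h2[[1]], fit$h2[[2]], fit$rho_g, fit$rho_e),
               tolerance = 1e-10)
  expect_true(is.finite(fit$se_rho_g) && fit$se_rho_g > 0)
  g <- glance(fit)
  expect_equal(g$rho_g, fit$rho_g)
  tt <- tidy(fit)
  expect_true("rho_p" %in% tt$term)
})

test_that("a binary trait can enter the bivariate model on the liability scale", {
  # shared-genetics generative model: threshold one trait of a correlated pair
  ped <- simulate_pedigree(25, seed = 241)
  spec <- trait_model_spec(traits = c("liab", "q"), h2 = c(0.6, 0.5),
                           c2 = c(0, 0), sigma2 = c(1, 1), mean = 0,
                           beta = NULL, rho_g = 0.8, rho_e = 0.1, rho_c = 0)
  d <- simulate_traits(ped, spec, seed = 242)
  d$aff <- as.integer(d$liab > qnorm(0.8))
  d$liab <- NULL
  fit <- fit_bivariate(d, ped, c("aff", "q"), binary = TRUE, se = FALSE,
                       control = list(lrt = FALSE, n_points = 256, n_shifts = 2))
  expect_true(fit$binary)
  expect_gt(fit$rho_g, 0.3)
  expect_lt(abs(fit$h2[[1]] - 0.6), 0.35)
  expect_gt(fit$rho_g, fit$rho_e)
})
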