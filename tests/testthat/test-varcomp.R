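test_that("the log transform is exact, monotone and rejects nonpositive input", {
  expect_equal(transform_trait(2.67), 0.98208, tolerance = 1e-4)
  expect_equal(transform_trait(1), 0)
  x <- c(0.3, 2.5, 7, 100, 0.0001)
  expect_equal(order(transform_trait(x)), order(x))
  expect_equal(exp(transform_trait(x)), x)
  expect_error(transform_trait(c(1, -2, 3)), "record\\(s\\): 2")
})

test_that("the pedigree likelihood reduces to iid normal densities without structure", {
  set.seed(1)
  y <- rnorm(12)
  X <- matrix(1, 12)
  K <- diag(12); rownames(K) <- colnames(K) <- paste0("i", 1:12)
  ll <- mvn_loglik(y, X, beta = 0, sigma2g = 0, sigma2c = 0, sigma2e = 1,
                   kin = K)
  expect_equal(ll, sum(dnorm(y, log = TRUE)), tolerance = 1e-10)
})

test_that("the family likelihood matches a brute-force multivariate-normal density", {
  ped <- ped_trio()
  K <- kinship_matrix(ped)
  H <- household_matrix(ped)
  set.seed(2)
  y <- rnorm(3, 5, 2)
  X <- cbind(1, c(0.2, -1, 0.7))
  beta <- c(4.4, 0.3)
  s <- c(g = 0.9, c = 0.4, e = 0.7)
  ll <- mvn_loglik(y, X, beta, s["g"], s["c"], s["e"], K, H,
                   fid = ped$fid)
  # independent oracle: explicit inversion and determinant
  V <- s["g"] * K + s["c"] * H + s["e"] * diag(3)
  r <- y - X %*% beta
  direct <- -0.5 * (3 * log(2 * pi) + log(det(V)) +
                      t(r) %*% solve(V) %*% r)
  expect_lt(abs(ll - drop(direct)), 1e-8)
})

test_that("the likelihood is invariant to a consistent relabelling of individuals", {
  ped <- ped_nuclear()
  K <- kinship_matrix(ped); H <- household_matrix(ped)
  set.seed(3)
  y <- rnorm(4); X <- cbind(1, rnorm(4))
  perm <- c(3, 1, 4, 2)
  ll1 <- mvn_loglik(y, X, c(0, 1), 0.5, 0.2, 0.6, K, H, ped$fid)
  ll2 <- mvn_loglik(y[perm], X[perm, ], c(0, 1), 0.5, 0.2, 0.6,
                    K[perm, perm], H[perm, perm], ped$fid[perm])
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("boundary-corrected LRT p-values follow the chi-square mixture", {
  expect_equal(lrt_boundary(-100, -100, 1), 0.5)
  expect_equal(lrt_boundary(-100, -100 + 2.706 / 2, 1), 0.05, tolerance = 2e-3)
  expect_lt(lrt_boundary(-100, -50, 1), 1e-10)
  # interior parameter: plain chi-square
  expect_equal(lrt_boundary(-100, -98, 0, df = 1),
               pchisq(4, 1, lower.tail = FALSE))
  expect_error(lrt_boundary(-100, -101, 1), "below the null")
})

test_that("fixed effects equal ordinary least squares when individuals are unrelated", {
  n <- 300
  ped <- ped_founders_only(n)
  withr::with_seed(8, {
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    y <- 1 + 0.5 * x1 - 0.8 * x2 + rnorm(n)
  })
  d <- tibble::tibble(fid = ped$fid, id = ped$id, y = y, x1 = x1, x2 = x2)
  fit <- fit_univariate(d, ped, "y", covariates = c("x1", "x2"),
                        screen = FALSE, se = FALSE)
  ols <- coef(lm(y ~ x1 + x2, data = d))
  expect_lt(max(abs(fit$coefficients$estimate - ols)), 1e-6)
})

test_that("variance fractions are invariant to affine rescaling of the trait", {
  ped <- simulate_pedigree(8, seed = 61)
  d <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0.5, c2 = 0.2,
                                             sigma2 = 1, mean = 0, beta = NULL),
                       seed = 62)
  f1 <- fit_univariate(d, ped, "y", se = FALSE)
  d$y2 <- 3 * d$y + 10
  f2 <- fit_univariate(d, ped, "y2", se = FALSE)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-3)
  expect_equal(f2$c2, f1$c2, tolerance = 1e-3)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-2)
  expect_true(f1$h2 + f1$c2 <= 1)
})

test_that("the fitted likelihood dominates the generating parameters", {
  for (s in 1:3) {
    ped <- simulate_pedigree(6, seed = 70 + s)
    d <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0.4, c2 = 0.2,
                                               sigma2 = 2, mean = 1, beta = NULL),
                         seed = 80 + s)
    fit <- fit_univariate(d, ped, "y", se = FALSE)
    K <- kinship_matrix(ped); H <- household_matrix(ped)
    ll_truth <- mvn_loglik(d$y, matrix(1, nrow(d)), 1,
                           0.4 * 2, 0.2 * 2, 0.4 * 2, K, H, d$fid)
    expect_gte(fit$loglik, ll_truth - 1e-6)
  }
})

test_that("null simulations give calibrated boundary tests and near-zero estimates", {
  # h2 = 0 truth: the h2 LRT should reject at ~5% and estimates hug zero
  ped <- ped_sib_pairs(50)
  nrep <- 100
  p <- h <- numeric(nrep)
  for (r in seq_len(nrep)) {
    d <- simulate_traits(ped, trait_model_spec(traits = "y", h2 = 0, c2 = 0,
                                               sigma2 = 1, mean = 0, beta = NULL),
                         seed = 9000 + r)
    f <- fit_univariate(d, ped, "y", se = FALSE)
    p[r] <- f$p_h2; h[r] <- f$h2
  }
  expect_lt(median(h), 0.08)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.00)
  expect_lte(rate, 0.12)   # 3+ binomial SDs around the nominal 5%
})

test_that("covariate screening retains true effects and drops noise covariates", {
  ped <- simulate_pedigree(12, seed = 91)
  spec <- etp_like_spec()
  d <- simulate_traits(ped, spec, seed = 92)
  fit <- fit_univariate(d, ped, "etp",
                        covariates = c("age_c", "age2", "female", "oc",
                                       "smoking", "activity"))
  expect_true(all(c("age_c", "oc") %in% fit$covariates))
  expect_gt(fit$covariate_variance, 0.02)
  expect_lt(abs(fit$residual_kurtosis), 1.5)
  tt <- tidy(fit)
  expect_true(all(c("fixed", "variance") %in% tt$effect))
  g <- glance(fit)
  expect_equal(g$n, fit$n)
  expect_s3_class(autoplot(fit), "ggplot")
})
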