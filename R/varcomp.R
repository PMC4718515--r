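#' Log-transform a positive trait
#'
#' Natural-log transform used to normalize right-skewed assay traits before
#' variance-component modelling. Monotone, hence rank-preserving, and
#' reversible via `exp()`.
#'
#' @param values Strictly positive numeric vector (`NA` passed through).
#' @return `log(values)`.
#' @export
transform_trait <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0) {
    abort(paste0("trait must be strictly positive for the log transform; ",
                 "offending record(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  log(values)
}

#' Gaussian pedigree log-likelihood
#'
#' Log-density of a continuous trait under the variance-component model with
#' covariance `kin * sigma2g + hh * sigma2c + I * sigma2e` and mean
#' `X %*% beta`, summed over independent family blocks. Exposed mainly so the
#' likelihood can be validated against direct multivariate-normal density
#' computations.
#'
#' @param y Trait vector.
#' @param X Design matrix (including the intercept column).
#' @param beta Fixed-effect coefficients.
#' @param sigma2g,sigma2c,sigma2e Variance components (additive genetic,
#'   household, residual); nonnegative, not all zero.
#' @param kin Twice-kinship matrix for the same individuals (ordering must
#'   match `y`).
#' @param hh Household matrix (same ordering); `NULL` for no household term.
#' @param fid Family id vector defining the independent blocks; a single
#'   block is assumed when `NULL`.
#' @return Log-likelihood (scalar).
#' @export
mvn_loglik <- function(y, X, beta, sigma2g, sigma2c, sigma2e, kin, hh = NULL,
                       fid = NULL) {
  n <- length(y)
  if (is.null(dim(X))) X <- matrix(X, n)
  if (sigma2g < 0 || sigma2c < 0 || sigma2e < 0 || sigma2g + sigma2c + sigma2e <= 0) {
    abort("variance components must be nonnegative and not all zero")
  }
  if (is.null(hh)) hh <- diag(0, n)
  if (is.null(fid)) fid <- rep("all", n)
  r <- y - as.vector(X %*% beta)
  ll <- 0
  for (fam in split(seq_len(n), fid)) {
    V <- sigma2g * kin[fam, fam, drop = FALSE] +
      sigma2c * hh[fam, fam, drop = FALSE] +
      sigma2e * diag(length(fam))
    L <- tryCatch(chol(V), error = function(e) {
      abort(paste0("singular covariance for family ", fid[fam[1]]))
    })
    z <- backsolve(L, r[fam], transpose = TRUE)
    ll <- ll - 0.5 * (length(fam) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  }
  ll
}

# --- internal machinery -----------------------------------------------------

# Per-family likelihood blocks for the analysis rows of `d` (a subset of the
# pedigree, in pedigree order): trait, design, and the K/H sub-blocks of the
# phenotyped members.
vc_blocks <- function(y, X, d_ids, d_fid, pblocks) {
  n <- length(y)
  fams <- split(seq_len(n), d_fid)
  lapply(fams, function(ix) {
    pb <- pblocks[[d_fid[ix[1]]]]
    sub <- match(d_ids[ix], pb$ids)
    list(ix = ix, y = y[ix], X = X[ix, , drop = FALSE],
         K = pb$K[sub, sub, drop = FALSE], H = pb$H[sub, sub, drop = FALSE],
         n = length(ix))
  })
}

# Profile log-likelihood at fractions (h2, c2): beta and the total variance
# are profiled out in closed form (GLS / mean residual quadratic form).
# Returns loglik plus the profiled estimates.
vc_profile_ll <- function(h2, c2, blocks, lambda = NULL) {
  e2 <- 1 - h2 - c2
  if (h2 < 0 || c2 < 0 || e2 < 1e-10) return(list(ll = -Inf))
  p <- ncol(blocks[[1]]$X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0
  logdet <- 0; n <- 0
  for (b in blocks) {
    V0 <- h2 * b$K + c2 * b$H + e2 * diag(b$n)
    L <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    Xs <- backsolve(L, b$X, transpose = TRUE)
    ys <- backsolve(L, b$y, transpose = TRUE)
    XtVX <- XtVX + crossprod(Xs)
    XtVy <- XtVy + crossprod(Xs, ys)[, 1]
    ytVy <- ytVy + sum(ys^2)
    logdet <- logdet + 2 * sum(log(diag(L)))
    n <- n + b$n
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- ytVy - sum(beta * XtVy)
  s2 <- max(rss / n, 1e-12)
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  list(ll = ll, beta = beta, sigma2 = s2, XtVX = XtVX, n = n)
}

# Full (non-profiled in variance) negative log-likelihood in
# (h2, c2, log sigma2) with beta profiled; used for the observed-information
# standard errors of the variance fractions.
vc_nll3 <- function(par, blocks) {
  h2 <- par[1]; c2 <- par[2]; s2 <- exp(par[3])
  e2 <- 1 - h2 - c2
  if (h2 < 0 || c2 < 0 || e2 < 1e-10 || s2 <= 0) return(1e10)
  p <- ncol(blocks[[1]]$X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0
  logdet <- 0; n <- 0
  for (b in blocks) {
    V <- s2 * (h2 * b$K + c2 * b$H + e2 * diag(b$n))
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    Xs <- backsolve(L, b$X, transpose = TRUE)
    ys <- backsolve(L, b$y, transpose = TRUE)
    XtVX <- XtVX + crossprod(Xs)
    XtVy <- XtVy + crossprod(Xs, ys)[, 1]
    ytVy <- ytVy + sum(ys^2)
    logdet <- logdet + 2 * sum(log(diag(L)))
    n <- n + b$n
  }
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - sum(beta * XtVy)
  0.5 * (n * log(2 * pi) + logdet + rss)
}

# maximize the profile likelihood over the (h2, c2) simplex via a softmax
# parameterization with a coarse grid start plus fixed restarts
vc_maximize <- function(blocks, fix_h2 = NULL, fix_c2 = NULL) {
  obj <- function(h2, c2) vc_profile_ll(h2, c2, blocks)$ll
  if (!is.null(fix_h2) && !is.null(fix_c2)) {
    return(list(h2 = fix_h2, c2 = fix_c2, ll = obj(fix_h2, fix_c2), converged = TRUE))
  }
  if (!is.null(fix_h2) || !is.null(fix_c2)) {
    # 1-D: optimize the free fraction on [0, 1 - fixed)
    fixed <- fix_h2 %||% fix_c2
    f <- function(x) {
      if (!is.null(fix_h2)) -obj(fix_h2, x) else -obj(x, fix_c2)
    }
    op <- optimize(f, c(0, 1 - fixed - 1e-8))
    est <- op$minimum
    if (f(0) <= op$objective) est <- 0  # boundary check
    h2 <- if (!is.null(fix_h2)) fix_h2 else est
    c2 <- if (!is.null(fix_c2)) fix_c2 else est
    return(list(h2 = h2, c2 = c2, ll = obj(h2, c2), converged = TRUE))
  }
  softmax <- function(u) {
    z <- exp(c(u, 0)); z <- z / sum(z)
    c(h2 = z[1], c2 = z[2])
  }
  nll_u <- function(u) {
    p <- softmax(u)
    -vc_profile_ll(p[1], p[2], blocks)$ll
  }
  # coarse grid start
  grid <- expand.grid(h2 = c(0.001, 0.1, 0.3, 0.5, 0.7, 0.9),
                      c2 = c(0.001, 0.1, 0.25, 0.4))
  grid <- grid[grid$h2 + grid$c2 < 0.999, ]
  ll_grid <- mapply(obj, grid$h2, grid$c2)
  best <- which.max(ll_grid)
  to_u <- function(h2, c2) {
    e2 <- max(1 - h2 - c2, 1e-6)
    log(c(max(h2, 1e-6), max(c2, 1e-6)) / e2)
  }
  starts <- list(to_u(grid$h2[best], grid$c2[best]), to_u(0.4, 0.2), to_u(0.05, 0.05))
  fits <- lapply(starts, function(u0) {
    optim(u0, nll_u, method = "Nelder-Mead",
          control = list(reltol = 1e-12, maxit = 1000))
  })
  vals <- vapply(fits, function(f) f$value, 0)
  op <- fits[[which.min(vals)]]
  p <- softmax(op$par)
  list(h2 = unname(p[1]), c2 = unname(p[2]), ll = -op$value,
       converged = op$convergence == 0)
}

#' Boundary-corrected likelihood-ratio test
#'
#' For a single variance component tested against its boundary value 0, the
#' LRT statistic is asymptotically a 50:50 mixture of a point mass at zero and
#' a chi-squared with 1 df, so the p-value is half the chi-squared upper tail.
#' Interior parameters (e.g. a correlation tested against 0) use the plain
#' chi-squared reference.
#'
#' @param loglik_null,loglik_alt Log-likelihoods of the nested fits.
#' @param n_boundary_params Number of tested parameters on the boundary
#'   (0, 1 or 2).
#' @param df Degrees of freedom for the interior case (`n_boundary_params = 0`).
#' @return p-value.
#' @export
lrt_boundary <- function(loglik_null, loglik_alt, n_boundary_params = 1, df = 1) {
  T <- 2 * (loglik_alt - loglik_null)
  if (T < -1e-6 * max(1, abs(loglik_alt))) {
    abort("alternative log-likelihood is below the null beyond tolerance")
  }
  T <- max(T, 0)
  if (n_boundary_params == 0) {
    pchisq(T, df = df, lower.tail = FALSE)
  } else if (n_boundary_params == 1) {
    0.5 * pchisq(T, df = 1, lower.tail = FALSE)
  } else if (n_boundary_params == 2) {
    0.5 * pchisq(T, df = 1, lower.tail = FALSE) +
      0.25 * pchisq(T, df = 2, lower.tail = FALSE)
  } else {
    abort("n_boundary_params must be 0, 1 or 2")
  }
}

#' Univariate variance-component fit of a continuous trait
#'
#' Maximum-likelihood estimation of heritability (`h2`) and the shared
#' household effect (`c2`) of a continuous trait on a pedigree, with fixed
#' covariate effects. The phenotypic covariance between relatives is
#' `2 phi sigma2_g + H sigma2_c + I sigma2_e`; fractions are reported relative
#' to the total variance after covariates. Candidate covariates can be
#' screened in a single pass: the full model is fitted, covariates with Wald
#' p < `screen_alpha` are retained, and the model is refitted.
#'
#' @param data Phenotype tibble with `fid`, `id`, the trait column and
#'   covariate columns. Individuals present in the pedigree but absent here
#'   (or with missing values) are dropped from the likelihood while still
#'   contributing kinship paths.
#' @param ped A `ped_tbl`.
#' @param trait Name of the trait column.
#' @param covariates Character vector of candidate covariate columns (may be
#'   empty).
#' @param screen Screen covariates at `screen_alpha` before the final fit?
#' @param screen_alpha Wald significance level for covariate retention.
#' @param log_transform Apply [transform_trait()] to the trait first?
#' @param se Compute observed-information standard errors (delta method on
#'   the fractions)?
#' @return An object of class `vc_fit`; see [tidy.vc_fit()] and
#'   [glance.vc_fit()].
#' @examples
#' ped <- simulate_pedigree(6, seed = 1)
#' spec <- trait_model_spec()
#' dat <- simulate_traits(ped, spec, seed = 2)
#' fit <- fit_univariate(dat, ped, "etp", covariates = c("age_c", "age2", "oc"))
#' glance(fit)
#' @export
fit_univariate <- function(data, ped, trait, covariates = character(0),
                           screen = TRUE, screen_alpha = 0.05,
                           log_transform = FALSE, se = TRUE) {
  stopifnot(inherits(ped, "ped_tbl"))
  if (!trait %in% names(data)) abort(paste0("trait column not found: ", trait))
  miss_cov <- setdiff(covariates, names(data))
  if (length(miss_cov) > 0) {
    abort(paste0("covariate column(s) not found: ", paste(miss_cov, collapse = ", ")))
  }
  d <- tibble::as_tibble(data)
  if (log_transform) d[[trait]] <- transform_trait(d[[trait]])
  keep <- !is.na(d[[trait]]) & d$id %in% ped$id
  if (length(covariates) > 0) {
    keep <- keep & stats::complete.cases(d[covariates])
  }
  d <- d[keep, , drop = FALSE]
  d <- d[match(intersect(ped$id, d$id), d$id), , drop = FALSE]  # pedigree order
  if (length(unique(d$fid)) < 2) abort("need phenotyped members in at least 2 families")
  y <- d[[trait]]
  if (sd(y) < 1e-12) abort("trait is constant; variance components are undefined")

  pblocks <- ped_blocks(ped)

  make_X <- function(cv) {
    X <- cbind(`(Intercept)` = rep(1, nrow(d)))
    if (length(cv) > 0) X <- cbind(X, as.matrix(d[cv]))
    X
  }
  fit_once <- function(cv) {
    blocks <- vc_blocks(y, make_X(cv), d$id, d$fid, pblocks)
    opt <- vc_maximize(blocks)
    prof <- vc_profile_ll(opt$h2, opt$c2, blocks)
    list(cv = cv, blocks = blocks, opt = opt, prof = prof)
  }
  wald <- function(f) {
    Vb <- f$prof$sigma2 * solve(f$prof$XtVX)
    se_b <- sqrt(pmax(diag(Vb), 0))
    z <- f$prof$beta / se_b
    tibble::tibble(term = colnames(f$blocks[[1]]$X), estimate = f$prof$beta,
                   std.error = se_b, statistic = z,
                   p.value = 2 * pnorm(-abs(z)))
  }

  f <- fit_once(covariates)
  screened_out <- character(0)
  if (screen && length(covariates) > 0) {
    w <- wald(f)
    keep_cv <- w$term[w$term != "(Intercept)" & w$p.value < screen_alpha]
    screened_out <- setdiff(covariates, keep_cv)
    if (length(screened_out) > 0) f <- fit_once(keep_cv)
  }
  opt <- f$opt; prof <- f$prof; blocks <- f$blocks
  w <- wald(f)

  # boundary LRTs for the variance fractions
  null_h2 <- vc_maximize(blocks, fix_h2 = 0)
  null_c2 <- vc_maximize(blocks, fix_c2 = 0)
  p_h2 <- lrt_boundary(null_h2$ll, opt$ll, 1)
  p_c2 <- lrt_boundary(null_c2$ll, opt$ll, 1)

  se_h2 <- se_c2 <- NA_real_
  se_flagged <- FALSE
  if (se) {
    par_hat <- c(opt$h2, opt$c2, log(prof$sigma2))
    Hn <- tryCatch(numDeriv::hessian(vc_nll3, par_hat, blocks = blocks),
                   error = function(e) NULL)
    if (!is.null(Hn)) {
      Vn <- tryCatch(solve(Hn), error = function(e) NULL)
      if (!is.null(Vn) && all(diag(Vn)[1:2] > 0)) {
        se_h2 <- sqrt(Vn[1, 1]); se_c2 <- sqrt(Vn[2, 2])
      }
    }
    se_flagged <- opt$h2 < 1e-3 || opt$c2 < 1e-3 || opt$h2 + opt$c2 > 0.999
  }

  xb <- numeric(length(y))
  for (b in blocks) xb[b$ix] <- as.vector(b$X %*% prof$beta)
  resid <- y - xb
  cov_var <- if (ncol(blocks[[1]]$X) > 1) max(0, 1 - var(resid) / var(y)) else 0
  kurt <- excess_kurtosis(resid)

  structure(list(
    trait = trait, h2 = opt$h2, c2 = opt$c2, sigma2 = prof$sigma2,
    se_h2 = se_h2, se_c2 = se_c2, se_at_boundary = se_flagged,
    p_h2 = p_h2, p_c2 = p_c2, loglik = opt$ll,
    coefficients = w, covariates = f$cv, screened_out = screened_out,
    covariate_variance = cov_var, residual_kurtosis = kurt,
    kurtosis_flag = kurt > 0.8,
    n = length(y), n_families = length(blocks),
    converged = opt$converged,
    data = d, blocks = blocks
  ), class = "vc_fit")
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Variance-component fit:", x$trait, "\n")
  cat(sprintf("  h2 = %.3f (SE %.3f, LRT p = %.3g)\n", x$h2, x$se_h2, x$p_h2))
  cat(sprintf("  c2 = %.3f (SE %.3f, LRT p = %.3g)\n", x$c2, x$se_c2, x$p_c2))
  cat(sprintf("  total variance = %.4g, covariate variance fraction = %.3f\n",
              x$sigma2, x$covariate_variance))
  cat(sprintf("  n = %d in %d families, loglik = %.3f%s\n", x$n, x$n_families,
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  if (nrow(x$coefficients) > 0) {
    cat("  covariates retained:",
        paste(setdiff(x$coefficients$term, "(Intercept)"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a univariate variance-component fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A tibble of fixed-effect terms (`effect = "fixed"`, Wald tests)
#'   followed by the variance fractions (`effect = "variance"`, boundary-LRT
#'   p-values).
#' @export
tidy.vc_fit <- function(x, ...) {
  fixed <- dplyr::mutate(x$coefficients, effect = "fixed")
  varrows <- tibble::tibble(
    term = c("h2", "c2"), estimate = c(x$h2, x$c2),
    std.error = c(x$se_h2, x$se_c2), statistic = NA_real_,
    p.value = c(x$p_h2, x$p_c2), effect = "variance"
  )
  dplyr::bind_rows(fixed, varrows)
}

#' One-row summary of a univariate variance-component fit
#'
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the variance fractions, their standard
#'   errors and LRT p-values, the covariate variance fraction, residual
#'   kurtosis, log-likelihood and sample sizes.
#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, h2 = x$h2, se_h2 = x$se_h2, p_h2 = x$p_h2,
    c2 = x$c2, se_c2 = x$se_c2, p_c2 = x$p_c2,
    sigma2 = x$sigma2, covariate_variance = x$covariate_variance,
    residual_kurtosis = x$residual_kurtosis,
    logLik = x$loglik, n = x$n, n_families = x$n_families,
    converged = x$converged
  )
}

#' Variance-decomposition plot for a fit
#'
#' Stacked bar of the additive-genetic, household and residual fractions of
#' the phenotypic variance (after covariates).
#'
#' @param object A `vc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vc_fit <- function(object, ...) {
  df <- tibble::tibble(
    component = factor(c("additive genetic (h2)", "household (c2)", "residual"),
                       levels = c("residual", "household (c2)", "additive genetic (h2)")),
    fraction = c(object$h2, object$c2, 1 - object$h2 - object$c2),
    trait = object$trait
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$fraction,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = NULL, y = "fraction of residual phenotypic variance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
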