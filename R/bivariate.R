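#' Phenotypic correlation implied by the variance-component decomposition
#'
#' Combines the genetic and environmental correlations of a trait pair with
#' the two heritabilities into the model-implied phenotypic correlation:
#' `rho_p = sqrt(h2_1 * h2_2) * rho_g + sqrt(1 - h2_1) * sqrt(1 - h2_2) * rho_e`.
#' The household term is deliberately absent from this two-component
#' decomposition; for traits with a household share it is therefore an
#' approximation (exact when the household cross-correlation equals `rho_e`).
#'
#' @param h2_1,h2_2 Heritabilities of the two traits, in `[0, 1]`.
#' @param rho_g,rho_e Genetic and environmental correlations, in `[-1, 1]`.
#' @return The phenotypic correlation.
#' @examples
#' derived_rho_p(0.52, 0.54, 0.87, 0.82)  # ~0.85
#' @export
derived_rho_p <- function(h2_1, h2_2, rho_g, rho_e) {
  if (any(c(h2_1, h2_2) < 0 | c(h2_1, h2_2) > 1)) {
    abort("heritabilities must lie in [0, 1]")
  }
  if (any(abs(c(rho_g, rho_e)) > 1)) abort("correlations must lie in [-1, 1]")
  sqrt(h2_1 * h2_2) * rho_g + sqrt(1 - h2_1) * sqrt(1 - h2_2) * rho_e
}

# --- shared machinery -------------------------------------------------------

# natural parameter vector for the continuous-continuous model:
# (h2_1, c2_1, h2_2, c2_2, log s2_1, log s2_2, rho_g, rho_e, rho_c)
biv_components <- function(q) {
  h2 <- q[c(1, 3)]; c2 <- q[c(2, 4)]; s2 <- exp(q[5:6])
  rg <- q[7]; re <- q[8]; rc <- q[9]
  e2 <- 1 - h2 - c2
  if (any(h2 < 0) || any(c2 < 0) || any(e2 < 1e-10) || any(abs(c(rg, re, rc)) > 1)) {
    return(NULL)
  }
  mk <- function(frac, rho) {
    s <- sqrt(frac * s2)
    matrix(c(s[1]^2, rho * s[1] * s[2], rho * s[1] * s[2], s[2]^2), 2)
  }
  list(G = mk(h2, rg), C = mk(c2, rc), E = mk(e2, re),
       h2 = h2, c2 = c2, s2 = s2, rho = c(g = rg, e = re, c = rc))
}

# profile (over beta) loglik for the continuous bivariate model
biv_ll <- function(q, blocks, p_tot) {
  cm <- biv_components(q)
  if (is.null(cm)) return(list(ll = -Inf))
  XtVX <- matrix(0, p_tot, p_tot); XtVy <- numeric(p_tot); ytVy <- 0
  logdet <- 0; N <- 0
  for (b in blocks) {
    m <- b$m
    i1 <- seq_len(m); i2 <- m + i1
    Im <- diag(m)
    Sig <- matrix(0, 2 * m, 2 * m)
    Sig[i1, i1] <- cm$G[1, 1] * b$K + cm$C[1, 1] * b$H + cm$E[1, 1] * Im
    Sig[i2, i2] <- cm$G[2, 2] * b$K + cm$C[2, 2] * b$H + cm$E[2, 2] * Im
    cross <- cm$G[1, 2] * b$K + cm$C[1, 2] * b$H + cm$E[1, 2] * Im
    Sig[i1, i2] <- cross
    Sig[i2, i1] <- t(cross)
    Sig <- Sig[b$obs, b$obs, drop = FALSE]
    L <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(L)) return(list(ll = -Inf))
    Xs <- backsolve(L, b$X, transpose = TRUE)
    ys <- backsolve(L, b$y, transpose = TRUE)
    XtVX <- XtVX + crossprod(Xs)
    XtVy <- XtVy + crossprod(Xs, ys)[, 1]
    ytVy <- ytVy + sum(ys^2)
    logdet <- logdet + 2 * sum(log(diag(L)))
    N <- N + length(b$y)
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  rss <- ytVy - sum(beta * XtVy)
  list(ll = -0.5 * (N * log(2 * pi) + logdet + rss), beta = beta,
       XtVX = XtVX, N = N)
}

# transform natural -> unconstrained and back; `fix` is a named list of
# parameters pinned to a value (rho_g = 0 etc.)
biv_pack <- function(q) {
  e2 <- pmax(1 - q[c(1, 3)] - q[c(2, 4)], 1e-8)
  c(log(pmax(q[1], 1e-8) / e2[1]), log(pmax(q[2], 1e-8) / e2[1]),
    log(pmax(q[3], 1e-8) / e2[2]), log(pmax(q[4], 1e-8) / e2[2]),
    q[5], q[6], atanh(pmin(pmax(q[7:9], -0.999), 0.999)))
}
biv_unpack <- function(u, fix = list()) {
  sm <- function(a, b) {
    z <- exp(c(a, b))
    z / (1 + sum(z))
  }
  p1 <- sm(u[1], u[2]); p2 <- sm(u[3], u[4])
  q <- c(p1[1], p1[2], p2[1], p2[2], u[5], u[6], tanh(u[7]), tanh(u[8]), tanh(u[9]))
  for (nm in names(fix)) {
    i <- match(nm, c("h2_1", "c2_1", "h2_2", "c2_2", "ls_1", "ls_2",
                     "rho_g", "rho_e", "rho_c"))
    q[i] <- fix[[nm]]
  }
  q
}

#' Bivariate variance-component fit of a trait pair
#'
#' Joint maximum-likelihood fit of two traits on a pedigree, partitioning
#' their cross-covariance into genetic, household and residual-environment
#' parts: the cross-trait covariance between individuals is
#' `2 phi rho_g sg1 sg2 + H rho_c sc1 sc2 + I rho_e se1 se2`. Reports the
#' genetic and environmental correlations with likelihood-ratio p-values
#' (interior parameters, plain chi-squared), and the derived phenotypic
#' correlation via [derived_rho_p()]. When `binary = TRUE`, the first trait
#' is a 0/1 affection status analyzed on the liability scale: the continuous
#' trait's parameters are profiled at their univariate maximum and the
#' liability heritability, threshold and cross-trait correlations are
#' estimated through the conditional rectangle likelihood.
#'
#' @param data Phenotype tibble with `fid`, `id`, both trait columns and
#'   covariates.
#' @param ped A `ped_tbl`.
#' @param traits Character vector of the two trait columns (binary trait
#'   first when `binary = TRUE`).
#' @param covariates Either one character vector (shared by both traits) or a
#'   named list keyed by trait.
#' @param binary Is the first trait a binary affection status?
#' @param rho_c How to treat the household cross-correlation:
#'   `"estimate"` (default), `"zero"`, or a fixed numeric value. Ignored for
#'   binary fits (the liability carries no household term).
#' @param se Compute observed-information standard errors?
#' @param control Optimizer/integration controls: `maxit`; `lrt = FALSE`
#'   skips the constrained refits behind the correlation LRTs; `fix` (a
#'   named list such as `list(rho_g = 0)`) pins natural parameters; binary
#'   fits additionally accept the [mvn_rect_prob()] controls `n_points`,
#'   `n_shifts`, `seed`.
#' @return An object of class `biv_fit`.
#' @export
fit_bivariate <- function(data, ped, traits, covariates = character(0),
                          binary = FALSE, rho_c = "estimate", se = TRUE,
                          control = list()) {
  stopifnot(inherits(ped, "ped_tbl"), length(traits) == 2)
  if (binary) {
    return(fit_bivariate_binary(data, ped, traits, covariates, se, control))
  }
  ctl <- modifyList(list(maxit = 2000, lrt = TRUE), control)
  d <- tibble::as_tibble(data)
  if (!all(traits %in% names(d))) abort("both trait columns must be present")
  covs <- if (is.list(covariates)) covariates else
    setNames(list(covariates, covariates), traits)
  allcov <- unique(unlist(covs))
  keep <- d$id %in% ped$id & (!is.na(d[[traits[1]]]) | !is.na(d[[traits[2]]]))
  if (length(allcov) > 0) keep <- keep & stats::complete.cases(d[allcov])
  d <- d[keep, , drop = FALSE]
  d <- d[match(intersect(ped$id, d$id), d$id), , drop = FALSE]
  obs1 <- !is.na(d[[traits[1]]]); obs2 <- !is.na(d[[traits[2]]])
  if (!any(obs1 & obs2)) abort("the two traits have no overlapping observations")

  # univariate starting fits (also provide the constrained-marginal reference)
  uni <- lapply(1:2, function(t) {
    fit_univariate(d[!is.na(d[[traits[t]]]), , drop = FALSE], ped, traits[t],
                   covariates = covs[[traits[t]]], screen = FALSE, se = FALSE)
  })

  pblocks <- ped_blocks(ped)
  X1 <- cbind(`(Intercept)` = rep(1, nrow(d)),
              if (length(covs[[traits[1]]]) > 0) as.matrix(d[covs[[traits[1]]]]))
  X2 <- cbind(`(Intercept)` = rep(1, nrow(d)),
              if (length(covs[[traits[2]]]) > 0) as.matrix(d[covs[[traits[2]]]]))
  p1 <- ncol(X1); p2 <- ncol(X2); p_tot <- p1 + p2
  fams <- split(seq_len(nrow(d)), d$fid)
  blocks <- lapply(fams, function(ix) {
    m <- length(ix)
    pbk <- pblocks[[d$fid[ix[1]]]]
    sub <- match(d$id[ix], pbk$ids)
    o1 <- which(obs1[ix]); o2 <- which(obs2[ix])
    obs <- c(o1, m + o2)
    Xf <- matrix(0, length(o1) + length(o2), p_tot)
    if (length(o1) > 0) Xf[seq_along(o1), 1:p1] <- X1[ix[o1], , drop = FALSE]
    if (length(o2) > 0) Xf[length(o1) + seq_along(o2), p1 + 1:p2] <-
        X2[ix[o2], , drop = FALSE]
    list(m = m, obs = obs, X = Xf,
         y = c(d[[traits[1]]][ix[o1]], d[[traits[2]]][ix[o2]]),
         K = pbk$K[sub, sub, drop = FALSE], H = pbk$H[sub, sub, drop = FALSE])
  })

  # cross-trait residual correlation for starting the rho parameters
  r0 <- {
    both <- obs1 & obs2
    r1 <- d[[traits[1]]] - predict_fixed(uni[[1]], d)
    r2 <- d[[traits[2]]] - predict_fixed(uni[[2]], d)
    suppressWarnings(stats::cor(r1[both], r2[both]))
  }
  if (!is.finite(r0)) r0 <- 0
  fix <- list()
  if (identical(rho_c, "zero")) fix$rho_c <- 0
  if (is.numeric(rho_c)) fix$rho_c <- rho_c
  if (!is.null(ctl$fix)) fix <- modifyList(fix, ctl$fix)  # e.g. rho_g = 0
  q0 <- c(uni[[1]]$h2, uni[[1]]$c2, uni[[2]]$h2, uni[[2]]$c2,
          log(uni[[1]]$sigma2), log(uni[[2]]$sigma2),
          0.9 * r0, 0.9 * r0, 0.9 * r0)
  maximize <- function(fix, q_start = q0) {
    nll_u <- function(u) -biv_ll(biv_unpack(u, fix), blocks, p_tot)$ll
    op <- optim(biv_pack(q_start), nll_u, method = "Nelder-Mead",
                control = list(maxit = ctl$maxit, reltol = 1e-9))
    q <- biv_unpack(op$par, fix)
    list(q = q, ll = -op$value, converged = op$convergence == 0)
  }
  full <- maximize(fix)
  p_rho_g <- p_rho_e <- NA_real_
  n0g <- n0e <- list(ll = NA_real_)
  if (isTRUE(ctl$lrt)) {
    n0g <- maximize(c(fix, list(rho_g = 0)), full$q)
    n0e <- maximize(c(fix, list(rho_e = 0)), full$q)
    p_rho_g <- lrt_boundary(n0g$ll, full$ll, 0, df = 1)
    p_rho_e <- lrt_boundary(n0e$ll, full$ll, 0, df = 1)
  }

  cm <- biv_components(full$q)
  prof <- biv_ll(full$q, blocks, p_tot)
  rho_p <- derived_rho_p(cm$h2[1], cm$h2[2], cm$rho["g"], cm$rho["e"])

  se_q <- rep(NA_real_, 9); Vq <- NULL
  if (se) {
    free <- setdiff(1:9, match(sub("^ls", "ls", names(fix)),
                               c("h2_1", "c2_1", "h2_2", "c2_2", "ls_1", "ls_2",
                                 "rho_g", "rho_e", "rho_c")))
    nllq <- function(qf) {
      q <- full$q; q[free] <- qf
      -biv_ll(q, blocks, p_tot)$ll
    }
    Hn <- tryCatch(numDeriv::hessian(nllq, full$q[free]), error = function(e) NULL)
    if (!is.null(Hn)) {
      Vsub <- tryCatch(solve(Hn), error = function(e) NULL)
      if (!is.null(Vsub)) {
        Vq <- matrix(0, 9, 9)
        Vq[free, free] <- Vsub
        se_q[free] <- sqrt(pmax(diag(Vsub), 0))
      }
    }
  }
  # delta-method p for the derived phenotypic correlation (approximate)
  p_rho_p <- NA_real_; se_rho_p <- NA_real_
  if (!is.null(Vq)) {
    g <- rho_p_gradient(cm$h2[1], cm$h2[2], cm$rho["g"], cm$rho["e"])
    J <- numeric(9); J[c(1, 3, 7, 8)] <- g
    v <- drop(t(J) %*% Vq %*% J)
    if (is.finite(v) && v > 0) {
      se_rho_p <- sqrt(v)
      p_rho_p <- 2 * pnorm(-abs(rho_p / se_rho_p))
    }
  }

  beta <- prof$beta
  terms <- c(paste0(traits[1], ":", colnames(X1)), paste0(traits[2], ":", colnames(X2)))
  Vb <- tryCatch(solve(prof$XtVX), error = function(e) matrix(NA, p_tot, p_tot))
  coefs <- tibble::tibble(term = terms, estimate = beta,
                          std.error = sqrt(pmax(diag(Vb), 0)))

  structure(list(
    traits = traits, binary = FALSE,
    h2 = setNames(cm$h2, traits), c2 = setNames(cm$c2, traits),
    sigma2 = setNames(cm$s2, traits),
    se_h2 = setNames(se_q[c(1, 3)], traits), se_c2 = setNames(se_q[c(2, 4)], traits),
    rho_g = unname(cm$rho["g"]), se_rho_g = se_q[7], p_rho_g = p_rho_g,
    rho_e = unname(cm$rho["e"]), se_rho_e = se_q[8], p_rho_e = p_rho_e,
    rho_c = unname(cm$rho["c"]), se_rho_c = se_q[9],
    rho_p = unname(rho_p), se_rho_p = se_rho_p, p_rho_p = p_rho_p,
    rho_boundary = max(abs(cm$rho[c("g", "e")])) > 0.995,
    coefficients = coefs, loglik = full$ll,
    loglik_rho_g0 = n0g$ll, loglik_rho_e0 = n0e$ll,
    converged = full$converged, n = sum(obs1) + sum(obs2),
    n_overlap = sum(obs1 & obs2), n_families = length(blocks),
    univariate = uni
  ), class = "biv_fit")
}

predict_fixed <- function(fit, d) {
  X <- cbind(1, if (length(fit$covariates) > 0) as.matrix(d[fit$covariates]))
  as.vector(X %*% fit$coefficients$estimate)
}

rho_p_gradient <- function(h1, h2, rg, re) {
  d_h1 <- 0.5 * rg * sqrt(h2 / max(h1, 1e-10)) -
    0.5 * re * sqrt((1 - h2) / max(1 - h1, 1e-10))
  d_h2 <- 0.5 * rg * sqrt(h1 / max(h2, 1e-10)) -
    0.5 * re * sqrt((1 - h1) / max(1 - h2, 1e-10))
  c(d_h1, d_h2, sqrt(h1 * h2), sqrt((1 - h1) * (1 - h2)))
}

# binary (liability) x continuous fit: continuous-trait parameters profiled at
# their univariate ML, then (h2_liab, threshold, rho_g, rho_e) estimated from
# the joint likelihood f(y_cont) * P(affection | y_cont), the latter a
# conditional-normal rectangle probability.
fit_bivariate_binary <- function(data, ped, traits, covariates, se, control) {
  ctl <- modifyList(list(maxit = 800, n_points = 512, n_shifts = 4, seed = 761,
                         size_cap = 60), control)
  d <- tibble::as_tibble(data)
  covs <- if (is.list(covariates)) covariates else
    setNames(list(character(0), covariates), traits)
  bt <- traits[1]; qt <- traits[2]
  if (!all(traits %in% names(d))) abort("both trait columns must be present")
  allcov <- unique(unlist(covs))
  keep <- d$id %in% ped$id & !(is.na(d[[bt]]) & is.na(d[[qt]]))
  if (length(allcov) > 0) keep <- keep & stats::complete.cases(d[allcov])
  d <- d[keep, , drop = FALSE]
  d <- d[match(intersect(ped$id, d$id), d$id), , drop = FALSE]

  uni2 <- fit_univariate(d[!is.na(d[[qt]]), , drop = FALSE], ped, qt,
                         covariates = covs[[qt]], screen = FALSE, se = FALSE)
  h2_2 <- uni2$h2; c2_2 <- uni2$c2; s2_2 <- uni2$sigma2
  e2_2 <- 1 - h2_2 - c2_2

  pblocks <- ped_blocks(ped)
  r2 <- d[[qt]] - predict_fixed(uni2, d)
  obs1 <- !is.na(d[[bt]]); obs2 <- !is.na(d[[qt]])
  Xb <- if (length(covs[[bt]]) > 0) as.matrix(d[covs[[bt]]]) else
    matrix(0, nrow(d), 0)
  pb <- ncol(Xb)
  fams <- split(seq_len(nrow(d)), d$fid)
  fam_seeds <- seq_along(fams) * 131L + ctl$seed
  blocks <- lapply(seq_along(fams), function(i) {
    ix <- fams[[i]]
    pbk <- pblocks[[d$fid[ix[1]]]]
    sub <- match(d$id[ix], pbk$ids)
    o1 <- which(obs1[ix]); o2 <- which(obs2[ix])
    list(o1 = o1, o2 = o2, aff = d[[bt]][ix[o1]], r2 = r2[ix[o2]],
         X1 = Xb[ix[o1], , drop = FALSE],
         K = pbk$K[sub, sub, drop = FALSE], H = pbk$H[sub, sub, drop = FALSE],
         seed = fam_seeds[i])
  })

  nll <- function(par, n_points = ctl$n_points) {
    h2_1 <- stats::plogis(par[1]); thr <- par[2]
    rg <- tanh(par[3]); re <- tanh(par[4])
    beta1 <- if (pb > 0) par[5:(4 + pb)] else numeric(0)
    e2_1 <- 1 - h2_1
    ll <- 0
    for (b in blocks) {
      S22 <- s2_2 * (h2_2 * b$K[b$o2, b$o2, drop = FALSE] +
                       c2_2 * b$H[b$o2, b$o2, drop = FALSE] +
                       e2_2 * diag(length(b$o2)))
      if (length(b$o2) > 0) {
        L22 <- tryCatch(chol(S22), error = function(e) NULL)
        if (is.null(L22)) return(1e10)
        z <- backsolve(L22, b$r2, transpose = TRUE)
        ll <- ll - 0.5 * (length(b$o2) * log(2 * pi) +
                            2 * sum(log(diag(L22))) + sum(z^2))
      }
      if (length(b$o1) == 0) next
      S11 <- h2_1 * b$K[b$o1, b$o1, drop = FALSE] + e2_1 * diag(length(b$o1))
      xb1 <- if (pb > 0) as.vector(b$X1 %*% beta1) else numeric(length(b$o1))
      if (length(b$o2) > 0) {
        S12 <- rg * sqrt(h2_1) * sqrt(h2_2 * s2_2) * b$K[b$o1, b$o2, drop = FALSE] +
          re * sqrt(e2_1) * sqrt(e2_2 * s2_2) *
          (outer(b$o1, b$o2, `==`) * 1)
        W <- backsolve(L22, t(S12), transpose = TRUE)      # L22^-T S12^T
        mu_c <- as.vector(crossprod(W, z))
        S_c <- S11 - crossprod(W)
        S_c <- (S_c + t(S_c)) / 2
        diag(S_c) <- pmax(diag(S_c), 1e-8)
      } else {
        mu_c <- numeric(length(b$o1)); S_c <- S11
      }
      ctr <- thr - xb1 - mu_c
      lower <- ifelse(b$aff == 1, ctr, -Inf)
      upper <- ifelse(b$aff == 1, Inf, ctr)
      pr <- tryCatch(
        mvn_rect_prob(lower, upper, S_c, n_points = n_points,
                      n_shifts = ctl$n_shifts, seed = b$seed),
        error = function(e) NULL)
      if (is.null(pr)) return(1e10)
      ll <- ll + attr(pr, "log")
    }
    -ll
  }

  yb_obs <- d[[bt]][obs1]
  start <- c(stats::qlogis(0.5), -qnorm(mean(yb_obs)), atanh(0.3), atanh(0.05),
             if (pb > 0) rep(0, pb))
  maximize <- function(fixg = NULL, fixe = NULL) {
    f <- function(par) {
      if (!is.null(fixg)) par[3] <- atanh(fixg)
      if (!is.null(fixe)) par[4] <- atanh(fixe)
      nll(par)
    }
    op <- optim(start, f, method = "Nelder-Mead",
                control = list(maxit = ctl$maxit, reltol = 1e-9))
    par <- op$par
    if (!is.null(fixg)) par[3] <- atanh(fixg)
    if (!is.null(fixe)) par[4] <- atanh(fixe)
    list(par = par, ll = -op$value, converged = op$convergence == 0)
  }
  full <- maximize()
  n0g <- maximize(fixg = 0)
  n0e <- maximize(fixe = 0)
  h2_1 <- stats::plogis(full$par[1]); thr <- full$par[2]
  rg <- tanh(full$par[3]); re <- tanh(full$par[4])
  p_rho_g <- lrt_boundary(n0g$ll, full$ll, 0, df = 1)
  p_rho_e <- lrt_boundary(n0e$ll, full$ll, 0, df = 1)
  rho_p <- derived_rho_p(h2_1, h2_2, rg, re)

  se_q <- rep(NA_real_, 4)
  if (se) {
    nat <- function(q) nll(c(stats::qlogis(min(max(q[1], 1e-6), 1 - 1e-6)),
                             q[2], atanh(pmin(pmax(q[3:4], -0.999), 0.999)),
                             if (pb > 0) full$par[5:(4 + pb)]),
                           n_points = max(ctl$n_points, 2048))
    Hn <- tryCatch(
      numDeriv::hessian(nat, c(h2_1, thr, rg, re),
                        method.args = list(d = 0.05, r = 2)),
      error = function(e) NULL)
    if (!is.null(Hn)) {
      Vn <- tryCatch(solve(Hn), error = function(e) NULL)
      if (!is.null(Vn)) se_q <- sqrt(pmax(diag(Vn), 0))
    }
  }

  structure(list(
    traits = traits, binary = TRUE,
    h2 = setNames(c(h2_1, h2_2), traits), c2 = setNames(c(0, c2_2), traits),
    sigma2 = setNames(c(1, s2_2), traits),
    se_h2 = setNames(c(se_q[1], NA), traits), se_c2 = setNames(c(NA, NA), traits),
    threshold = thr, se_threshold = se_q[2],
    rho_g = rg, se_rho_g = se_q[3], p_rho_g = p_rho_g,
    rho_e = re, se_rho_e = se_q[4], p_rho_e = p_rho_e,
    rho_c = 0, se_rho_c = NA_real_,
    rho_p = rho_p, se_rho_p = NA_real_, p_rho_p = NA_real_,
    rho_boundary = max(abs(c(rg, re))) > 0.995,
    coefficients = tibble::tibble(term = character(0), estimate = numeric(0),
                                  std.error = numeric(0)),
    loglik = full$ll, loglik_rho_g0 = n0g$ll, loglik_rho_e0 = n0e$ll,
    converged = full$converged, n = sum(obs1) + sum(obs2),
    n_overlap = sum(obs1 & obs2), n_families = length(blocks),
    univariate = list(NULL, uni2)
  ), class = "biv_fit")
}

#' @export
print.biv_fit <- function(x, ...) {
  cat("Bivariate variance-component fit:", paste(x$traits, collapse = " x "),
      if (x$binary) "(liability x continuous)" else "", "\n")
  cat(sprintf("  h2: %s\n", paste(sprintf("%s = %.3f", x$traits, x$h2), collapse = ", ")))
  cat(sprintf("  rho_g = %.3f (SE %.3f, LRT p = %.3g)\n", x$rho_g, x$se_rho_g, x$p_rho_g))
  cat(sprintf("  rho_e = %.3f (SE %.3f, LRT p = %.3g)\n", x$rho_e, x$se_rho_e, x$p_rho_e))
  cat(sprintf("  derived rho_p = %.3f\n", x$rho_p))
  cat(sprintf("  n = %d trait observations (%d overlapping) in %d families\n",
              x$n, x$n_overlap, x$n_families))
  if (x$rho_boundary) cat("  note: a correlation is at its boundary\n")
  invisible(x)
}

#' @rdname tidy.vc_fit
#' @export
tidy.biv_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("h2_", x$traits), paste0("c2_", x$traits),
             "rho_g", "rho_e", "rho_c", "rho_p"),
    estimate = c(x$h2, x$c2, x$rho_g, x$rho_e, x$rho_c, x$rho_p),
    std.error = c(x$se_h2, x$se_c2, x$se_rho_g, x$se_rho_e, x$se_rho_c, x$se_rho_p),
    statistic = NA_real_,
    p.value = c(NA, NA, NA, NA, x$p_rho_g, x$p_rho_e, NA, x$p_rho_p),
    effect = "variance"
  )
}

#' @rdname glance.vc_fit
#' @export
glance.biv_fit <- function(x, ...) {
  tibble::tibble(
    trait1 = x$traits[1], trait2 = x$traits[2],
    h2_1 = x$h2[1], h2_2 = x$h2[2],
    rho_g = x$rho_g, se_rho_g = x$se_rho_g, p_rho_g = x$p_rho_g,
    rho_e = x$rho_e, se_rho_e = x$se_rho_e, p_rho_e = x$p_rho_e,
    rho_p = x$rho_p, p_rho_p = x$p_rho_p,
    logLik = x$loglik, n_overlap = x$n_overlap, n_families = x$n_families,
    converged = x$converged
  )
}
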