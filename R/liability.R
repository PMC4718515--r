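#' Family log-likelihood of a binary trait under the liability model
#'
#' The latent liability of a family is multivariate normal with mean
#' `X %*% beta`, unit trait-scale variance and correlation
#' `kin * h2 + I * (1 - h2)` (optionally plus a household share). A member is
#' affected when liability exceeds `threshold`. The family's likelihood is
#' the MVN rectangle probability that every member's liability falls on the
#' observed side of the threshold, evaluated with the randomized
#' quasi-Monte-Carlo integrator [mvn_rect_prob()] under a fixed internal seed
#' (common random numbers across likelihood evaluations).
#'
#' @param affected 0/1 affection vector for one family.
#' @param X Design matrix (no intercept needed; the threshold plays that
#'   role). Use a zero-column matrix for no covariates.
#' @param beta Liability-scale coefficients (positive = increases liability).
#' @param h2 Liability heritability in `[0, 1]`.
#' @param kin Twice-kinship block for the family.
#' @param threshold Liability threshold (e.g. `qnorm(1 - prevalence)`).
#' @param c2,hh Optional household share and household block.
#' @param n_points,n_shifts,seed Integration controls passed to
#'   [mvn_rect_prob()].
#' @param size_cap Maximum family size (integration cost guard).
#' @return Log-likelihood (scalar), with the rectangle probability's
#'   Monte-Carlo standard error in attribute `se`.
#' @export
family_binary_loglik <- function(affected, X, beta, h2, kin, threshold,
                                 c2 = 0, hh = NULL, n_points = 512,
                                 n_shifts = 4, seed = 761, size_cap = 60) {
  m <- length(affected)
  if (m > size_cap) {
    abort(paste0("family of size ", m, " exceeds the integration size cap (",
                 size_cap, "); raise `size_cap` (and the accuracy budget) to proceed"))
  }
  if (h2 < 0 || h2 > 1 || c2 < 0 || h2 + c2 > 1) abort("need 0 <= h2, c2, h2 + c2 <= 1")
  if (is.null(dim(X))) X <- matrix(X, m)
  xb <- if (ncol(X) > 0) as.vector(X %*% beta) else numeric(m)
  e2 <- 1 - h2 - c2
  Sig <- h2 * kin + e2 * diag(m)
  if (c2 > 0) {
    if (is.null(hh)) abort("household block `hh` needed when c2 > 0")
    Sig <- Sig + c2 * hh
  }
  ctr <- threshold - xb  # bounds on the centered liability
  lower <- ifelse(affected == 1, ctr, -Inf)
  upper <- ifelse(affected == 1, Inf, ctr)
  p <- mvn_rect_prob(lower, upper, Sig, n_points = n_points,
                     n_shifts = n_shifts, seed = seed)
  structure(attr(p, "log"), se = attr(p, "se"))
}

#' Liability-threshold variance-component fit of a binary trait
#'
#' Maximum-likelihood estimation of the liability-scale heritability of a
#' binary disease trait on a pedigree, by the probit (threshold) model:
#' affection indicates a latent standard-normal liability, correlated
#' `2 phi h2` between relatives, exceeding an estimated threshold. With
#' `correct_ascertainment = TRUE`, each family's likelihood is divided by the
#' marginal probability of its proband's observed affection status —
#' single-proband conditioning — so that estimates generalize to the
#' unselected population despite recruitment through affected index cases.
#'
#' @param data Phenotype tibble with `fid`, `id`, the 0/1 affection column,
#'   covariate columns and (for the correction) a logical `proband` column
#'   flagging exactly one member per family.
#' @param ped A `ped_tbl`.
#' @param trait Name of the affection column.
#' @param covariates Covariate columns entering the liability mean.
#' @param correct_ascertainment Condition each family on its proband's
#'   affection status?
#' @param proband Name of the proband flag column.
#' @param reverse_sign Report covariate coefficients with the reversed sign
#'   convention used by some legacy variance-component software (negative
#'   coefficient = increases liability), for side-by-side comparison.
#' @param se Compute observed-information standard errors? (Adds Hessian
#'   evaluations at a higher integration accuracy.)
#' @param control List of integration/optimization controls: `n_points`,
#'   `n_shifts`, `seed`, `size_cap`, `maxit`; `lrt = FALSE` skips the
#'   boundary LRT refit; `polish = TRUE` adds a Newton refinement of the
#'   optimum (recommended for small or independence-structured problems).
#' @return An object of class `liab_fit`.
#' @export
fit_liability <- function(data, ped, trait, covariates = character(0),
                          correct_ascertainment = FALSE, proband = "proband",
                          reverse_sign = FALSE, se = TRUE, control = list()) {
  stopifnot(inherits(ped, "ped_tbl"))
  ctl <- modifyList(list(n_points = 512, n_shifts = 4, seed = 761,
                         size_cap = 60, maxit = 500, lrt = TRUE), control)
  if (!trait %in% names(data)) abort(paste0("trait column not found: ", trait))
  d <- tibble::as_tibble(data)
  if (!all(stats::na.omit(d[[trait]]) %in% c(0, 1))) {
    abort("binary trait must be coded 0/1")
  }
  keep <- !is.na(d[[trait]]) & d$id %in% ped$id
  if (length(covariates) > 0) keep <- keep & stats::complete.cases(d[covariates])
  d <- d[keep, , drop = FALSE]
  d <- d[match(intersect(ped$id, d$id), d$id), , drop = FALSE]
  yb <- d[[trait]]
  if (length(unique(yb)) < 2) abort("no variation in affection status")
  if (correct_ascertainment) {
    if (!proband %in% names(d)) abort("proband flags required for the ascertainment correction")
    pb_per_fam <- tapply(d[[proband]], d$fid, sum)
    if (any(pb_per_fam != 1)) {
      abort("exactly one proband per family is required for the correction")
    }
  }

  pblocks <- ped_blocks(ped)
  X <- if (length(covariates) > 0) as.matrix(d[covariates]) else matrix(0, nrow(d), 0)
  fams <- split(seq_len(nrow(d)), d$fid)
  fam_seeds <- seq_along(fams) * 131L + ctl$seed
  blocks <- lapply(seq_along(fams), function(i) {
    ix <- fams[[i]]
    pbk <- pblocks[[d$fid[ix[1]]]]
    sub <- match(d$id[ix], pbk$ids)
    pb <- if (correct_ascertainment) ix[which(d[[proband]][ix])] else NA_integer_
    list(ix = ix, aff = yb[ix], X = X[ix, , drop = FALSE],
         K = pbk$K[sub, sub, drop = FALSE], proband = pb, seed = fam_seeds[i])
  })

  p <- ncol(X)
  nll <- function(par, n_points = ctl$n_points) {
    h2 <- stats::plogis(par[1])
    thr <- par[2]
    beta <- if (p > 0) par[3:(2 + p)] else numeric(0)
    ll <- 0
    for (b in blocks) {
      lf <- family_binary_loglik(b$aff, b$X, beta, h2, b$K, thr,
                                 n_points = n_points, n_shifts = ctl$n_shifts,
                                 seed = b$seed, size_cap = ctl$size_cap)
      if (correct_ascertainment) {
        j <- match(b$proband, b$ix)
        xbp <- if (p > 0) sum(b$X[j, ] * beta) else 0
        lp <- if (b$aff[j] == 1) {
          pnorm(thr - xbp, lower.tail = FALSE, log.p = TRUE)
        } else {
          pnorm(thr - xbp, log.p = TRUE)
        }
        lf <- lf - lp
      }
      ll <- ll + lf
    }
    -ll
  }

  # start from an independence probit fit
  start_thr <- -qnorm(mean(yb))
  start <- c(stats::qlogis(0.5), start_thr)
  if (p > 0) {
    g <- glm(yb ~ X, family = binomial(link = "probit"))
    start <- c(stats::qlogis(0.5), -coef(g)[1], coef(g)[-1])
  }
  op <- optim(start, nll, method = "Nelder-Mead",
              control = list(maxit = ctl$maxit, reltol = 1e-9))
  # Newton polish: tightens the optimum on smooth likelihood surfaces (exact
  # for independence structures); steps are only accepted when they improve.
  if (isTRUE(ctl$polish %||% FALSE)) {
    for (it in 1:5) {
      gr <- tryCatch(numDeriv::grad(nll, op$par), error = function(e) NULL)
      Hm <- tryCatch(numDeriv::hessian(nll, op$par), error = function(e) NULL)
      if (is.null(gr) || is.null(Hm)) break
      step <- tryCatch(solve(Hm, gr), error = function(e) NULL)
      if (is.null(step)) {  # flat directions (e.g. h2 on unrelated samples)
        ridge <- diag(nrow(Hm)) * (1e-8 + 1e-8 * max(abs(diag(Hm))))
        step <- tryCatch(solve(Hm + ridge, gr), error = function(e) NULL)
      }
      if (is.null(step) || !all(is.finite(step))) break
      cand <- op$par - step
      vc <- nll(cand)
      if (is.finite(vc) && vc < op$value - 1e-12) {
        op$par <- cand; op$value <- vc
        if (sum(abs(step)) < 1e-10) break
      } else break
    }
  }
  h2_hat <- stats::plogis(op$par[1])
  thr_hat <- op$par[2]
  beta_hat <- if (p > 0) setNames(op$par[3:(2 + p)], covariates) else numeric(0)
  loglik <- -op$value

  # boundary LRT for h2: refit with h2 fixed at 0
  p_h2 <- NA_real_
  if (ctl$lrt) {
    nll0 <- function(par) nll(c(-30, par))
    start0 <- c(thr_hat, beta_hat)
    op0 <- if (length(start0) == 1) {
      o <- optimize(function(t) nll0(t), interval = thr_hat + c(-3, 3))
      list(value = o$objective)
    } else {
      optim(start0, nll0, method = "Nelder-Mead",
            control = list(maxit = ctl$maxit, reltol = 1e-9))
    }
    p_h2 <- lrt_boundary(-op0$value, loglik, 1)
  }

  se_h2 <- NA_real_; se_beta <- rep(NA_real_, p); se_thr <- NA_real_
  if (se) {
    nat <- function(q) nll(c(stats::qlogis(min(max(q[1], 1e-6), 1 - 1e-6)), q[-1]),
                           n_points = max(ctl$n_points, 2048))
    q_hat <- c(h2_hat, thr_hat, beta_hat)
    Hn <- tryCatch(
      numDeriv::hessian(nat, q_hat, method.args = list(d = 0.05, r = 2)),
      error = function(e) NULL)
    if (!is.null(Hn)) {
      Vn <- tryCatch(solve(Hn), error = function(e) NULL)
      if (!is.null(Vn)) {
        dg <- diag(Vn)
        if (dg[1] > 0) se_h2 <- sqrt(dg[1])
        if (dg[2] > 0) se_thr <- sqrt(dg[2])
        if (p > 0) se_beta <- sqrt(pmax(dg[3:(2 + p)], 0))
      }
    }
  }

  sgn <- if (reverse_sign) -1 else 1
  coefs <- tibble::tibble(
    term = covariates, estimate = sgn * unname(beta_hat), std.error = se_beta,
    statistic = unname(beta_hat) / se_beta,
    p.value = 2 * pnorm(-abs(unname(beta_hat) / se_beta))
  )
  xb <- if (p > 0) as.vector(X %*% beta_hat) else numeric(nrow(d))
  prevalence <- mean(pnorm(xb - thr_hat))

  structure(list(
    trait = trait, h2 = h2_hat, se_h2 = se_h2, p_h2 = p_h2,
    threshold = thr_hat, se_threshold = se_thr, prevalence = prevalence,
    coefficients = coefs, sign_convention = if (reverse_sign)
      "negative increases liability" else "positive increases liability",
    loglik = loglik, ascertainment_corrected = correct_ascertainment,
    converged = op$convergence == 0, n = nrow(d),
    n_families = length(blocks), n_affected = sum(yb)
  ), class = "liab_fit")
}

#' @export
print.liab_fit <- function(x, ...) {
  cat("Liability-threshold fit:", x$trait,
      if (x$ascertainment_corrected) "(ascertainment-corrected)" else "", "\n")
  cat(sprintf("  liability h2 = %.3f (SE %.3f, LRT p = %.3g)\n",
              x$h2, x$se_h2, x$p_h2))
  cat(sprintf("  threshold = %.3f (implied prevalence %.3f)\n",
              x$threshold, x$prevalence))
  cat(sprintf("  n = %d (%d affected) in %d families, loglik = %.3f%s\n",
              x$n, x$n_affected, x$n_families, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @rdname tidy.vc_fit
#' @export
tidy.liab_fit <- function(x, ...) {
  fixed <- dplyr::mutate(x$coefficients, effect = "fixed")
  varrows <- tibble::tibble(
    term = c("h2", "threshold"), estimate = c(x$h2, x$threshold),
    std.error = c(x$se_h2, x$se_threshold), statistic = NA_real_,
    p.value = c(x$p_h2, NA_real_), effect = c("variance", "threshold")
  )
  dplyr::bind_rows(fixed, varrows)
}

#' @rdname glance.vc_fit
#' @export
glance.liab_fit <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, h2 = x$h2, se_h2 = x$se_h2, p_h2 = x$p_h2,
    threshold = x$threshold, prevalence = x$prevalence,
    ascertainment_corrected = x$ascertainment_corrected,
    logLik = x$loglik, n = x$n, n_affected = x$n_affected,
    n_families = x$n_families, converged = x$converged
  )
}
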