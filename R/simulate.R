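#' Simulate extended ascertainment-style study pedigrees
#'
#' Generates families of the kind recruited in extended-pedigree thrombosis
#' studies: a founder couple, their children (who marry in spouses and have
#' children of their own), and optionally a fourth generation. Households are
#' assigned by nuclear unit: every couple and their still-unmarried children
#' share a household; married-in spouses start a new household with their
#' partner.
#'
#' @param n_families Number of families.
#' @param min_size Minimum living members per family (families are redrawn
#'   until the constraint holds).
#' @param max_size Maximum members per family; larger draws are redrawn
#'   (keeps families at a recruitable size and within the liability
#'   integrator's family-size cap).
#' @param min_generations Minimum number of generations per family.
#' @param mean_children Mean number of children per couple (children are
#'   `1 + Poisson(mean_children - 1)`, so every couple has at least one).
#' @param p_marry Probability that a second-generation child marries (and so
#'   founds the third generation).
#' @param p_fourth_generation Probability that a family extends to a fourth
#'   generation.
#' @param p_marry_gen3 Probability that a third-generation child marries when
#'   the family has a fourth generation.
#' @param seed Integer seed; the same seed reproduces the pedigree exactly.
#' @return A `ped_tbl` (see [build_pedigree()]).
#' @export
simulate_pedigree <- function(n_families = 35, min_size = 10,
                              min_generations = 3, mean_children = 3.4,
                              p_marry = 0.85, p_fourth_generation = 0.4,
                              p_marry_gen3 = 0.5, max_size = 55, seed = NULL) {
  if (n_families < 1 || min_size < 1 || min_generations < 1) {
    abort("pedigree simulation parameters must be positive")
  }
  if (min_generations > 4) {
    abort("at most 4 generations are generated; lower `min_generations`")
  }
  if (min_generations < 2 && min_size > 2) {
    abort("unattainable constraints: a single-generation family has only the founder couple")
  }
  if (min_size > max_size) abort("unattainable constraints: min_size exceeds max_size")
  lambda <- mean_children - 1
  if (lambda < 0) abort("`mean_children` must be at least 1")
  with_seed(seed, {
    fams <- lapply(seq_len(n_families), function(f) {
      for (attempt in 1:200) {
        fam <- sim_one_family(f, lambda, p_marry, p_fourth_generation,
                              p_marry_gen3, min_generations)
        if (nrow(fam) >= min_size && nrow(fam) <= max_size &&
            max(fam$gen) >= min_generations) return(fam)
      }
      abort(paste0("could not satisfy size/generation constraints for family ", f,
                   "; check `min_size`/`min_generations` against the fertility parameters"))
    })
    records <- dplyr::bind_rows(fams)
    build_pedigree(records[, c("fid", "id", "father", "mother", "sex",
                               "household", "proband")])
  })
}

sim_one_family <- function(f, lambda, p_marry, p_g4, p_marry3, min_gen) {
  fid <- sprintf("F%02d", f)
  env <- new.env()
  env$id <- character(0); env$father <- character(0); env$mother <- character(0)
  env$sex <- character(0); env$household <- character(0); env$gen <- integer(0)
  env$counter <- 0L; env$n_couple <- 0L
  new_id <- function() {
    env$counter <- env$counter + 1L
    sprintf("%s_I%03d", fid, env$counter)
  }
  new_household <- function() {
    env$n_couple <- env$n_couple + 1L
    sprintf("%s_H%02d", fid, env$n_couple)
  }
  add <- function(id, father, mother, sex, household, gen) {
    env$id <- c(env$id, id); env$father <- c(env$father, father)
    env$mother <- c(env$mother, mother); env$sex <- c(env$sex, sex)
    env$household <- c(env$household, household); env$gen <- c(env$gen, gen)
  }

  # generation 1: founder couple
  hh1 <- new_household()
  g1f <- new_id(); g1m <- new_id()
  add(g1f, NA, NA, "male", hh1, 1L)
  add(g1m, NA, NA, "female", hh1, 1L)

  make_children <- function(father, mother, household, gen) {
    nk <- 1L + rpois(1, lambda)
    kids <- vapply(seq_len(nk), function(k) new_id(), "")
    for (kid in kids) {
      add(kid, father, mother, sample(c("male", "female"), 1), household, gen)
    }
    kids
  }
  marry_off <- function(person, gen) {
    person_sex <- env$sex[match(person, env$id)]
    spouse <- new_id()
    sp_sex <- if (person_sex == "male") "female" else "male"
    hh <- new_household()
    add(spouse, NA, NA, sp_sex, hh, gen)
    env$household[match(person, env$id)] <- hh  # married child joins the new unit
    if (person_sex == "male") list(father = person, mother = spouse, hh = hh)
    else list(father = spouse, mother = person, hh = hh)
  }

  has_g4 <- runif(1) < p_g4 || min_gen >= 4
  g2 <- make_children(g1f, g1m, hh1, 2L)
  g3_all <- list()
  for (i in seq_along(g2)) {
    marries <- runif(1) < p_marry
    if (i == length(g2) && length(g3_all) == 0 && min_gen >= 3) {
      marries <- TRUE  # guarantee a third generation
    }
    if (marries) {
      cpl <- marry_off(g2[i], 2L)
      kids <- make_children(cpl$father, cpl$mother, cpl$hh, 3L)
      g3_all[[length(g3_all) + 1L]] <- kids
    }
  }
  if (has_g4 && length(g3_all) > 0) {
    any_married <- FALSE
    for (bi in seq_along(g3_all)) {
      kids3 <- g3_all[[bi]]
      for (j in seq_along(kids3)) {
        force4 <- !any_married && bi == length(g3_all) &&
          j == length(kids3) && min_gen >= 4
        if (runif(1) < p_marry3 || force4) {
          cpl <- marry_off(kids3[j], 3L)
          make_children(cpl$father, cpl$mother, cpl$hh, 4L)
          any_married <- TRUE
        }
      }
    }
  }
  tibble::tibble(fid = fid, id = env$id, father = env$father,
                 mother = env$mother, sex = env$sex, household = env$household,
                 proband = FALSE, gen = env$gen)
}

#' Simulate study covariates for a pedigree
#'
#' Generates the candidate covariates screened in the variance-component
#' models: age (older in earlier generations, so the covariate has
#' pedigree-realistic structure), sex (taken from the pedigree),
#' oral-contraceptive use (women aged 18-50), smoking and physical activity
#' (adults). `age_c` is age centred at 40 years and `age2` its square, the
#' basis used for the nonlinear age trend.
#'
#' @param ped A `ped_tbl`.
#' @param seed Integer seed.
#' @param age_sd Within-generation age standard deviation (years).
#' @param p_oc,p_smoking,p_activity Bernoulli rates for the binary covariates.
#' @return A tibble `fid`, `id`, `sex`, `age`, `age_c`, `age2`, `female`,
#'   `oc`, `smoking`, `activity`.
#' @export
simulate_covariates <- function(ped, seed = NULL, age_sd = 6,
                                p_oc = 0.3, p_smoking = 0.3, p_activity = 0.5) {
  stopifnot(inherits(ped, "ped_tbl"))
  with_seed(seed, {
    n <- nrow(ped)
    depth <- stats::ave(ped$generation, ped$fid, FUN = max)
    gen_mean <- 15 + 23 * (depth - ped$generation)
    age <- pmin(pmax(rnorm(n, gen_mean, age_sd), 2), 101)
    female <- as.numeric(ped$sex == "female")
    oc <- rbinom(n, 1, p_oc) * as.numeric(female == 1 & age >= 18 & age <= 50)
    smoking <- rbinom(n, 1, p_smoking) * as.numeric(age >= 18)
    activity <- rbinom(n, 1, p_activity) * as.numeric(age >= 18)
    tibble::tibble(
      fid = ped$fid, id = ped$id, sex = ped$sex,
      age = age, age_c = age - 40, age2 = (age - 40)^2,
      female = female, oc = oc, smoking = smoking, activity = activity
    )
  })
}

#' Specify a generative trait model
#'
#' Describes one or two continuous traits by their variance decomposition on
#' the analysis scale: additive-genetic fraction `h2`, shared-household
#' fraction `c2`, residual fraction `1 - h2 - c2`, total residual variance
#' `sigma2` (after covariates), fixed covariate effects `beta`, and — for a
#' trait pair — the genetic, environmental and household cross-trait
#' correlations. Defaults describe an endogenous-thrombin-potential-like
#' trait: moderate heritability with a substantial household component, an
#' age trend with curvature, and a strong oral-contraceptive effect.
#'
#' @param traits Character vector of one or two trait names.
#' @param h2,c2 Per-trait variance fractions (recycled); `h2 + c2 <= 1`.
#' @param sigma2 Per-trait total variance of the random part (genetic +
#'   household + residual), in squared trait units.
#' @param mean Per-trait intercept on the analysis scale.
#' @param beta Named list (by trait) of named coefficient vectors; names must
#'   match covariate columns (e.g. `age_c`, `age2`, `female`, `oc`).
#' @param rho_g,rho_e Genetic and residual-environment cross-trait
#'   correlations (used only for two traits).
#' @param rho_c Household cross-trait correlation; defaults to `rho_e`, the
#'   convention under which the two-component phenotypic-correlation
#'   decomposition remains exact.
#' @param transform `"identity"` (default) or `"exp"` to return traits on a
#'   raw positive scale (so that a log transform recovers the analysis scale).
#' @return An object of class `trait_model_spec`.
#' @export
trait_model_spec <- function(traits = "etp",
                             h2 = 0.52, c2 = 0.23, sigma2 = 1.2,
                             mean = 48.53,
                             beta = list(etp = c(age_c = 0.01, age2 = -3e-4, oc = 0.87)),
                             rho_g = 0, rho_e = 0, rho_c = NULL,
                             transform = c("identity", "exp")) {
  k <- length(traits)
  if (k < 1 || k > 2) abort("one or two traits are supported")
  h2 <- rep_len(h2, k); c2 <- rep_len(c2, k)
  sigma2 <- rep_len(sigma2, k); mean <- rep_len(mean, k)
  if (any(h2 < 0 | c2 < 0 | h2 + c2 > 1)) {
    abort("need h2 >= 0, c2 >= 0 and h2 + c2 <= 1 for every trait")
  }
  if (any(sigma2 <= 0)) abort("sigma2 must be positive")
  if (abs(rho_g) > 1 || abs(rho_e) > 1) abort("correlations must lie in [-1, 1]")
  if (is.null(rho_c)) rho_c <- rho_e
  if (abs(rho_c) > 1) abort("correlations must lie in [-1, 1]")
  if (is.null(beta)) beta <- setNames(rep(list(numeric(0)), k), traits)
  if (!all(traits %in% names(beta))) {
    missing_b <- setdiff(traits, names(beta))
    beta[missing_b] <- list(numeric(0))
  }
  structure(
    list(traits = traits, h2 = h2, c2 = c2, sigma2 = sigma2, mean = mean,
         beta = beta[traits], rho_g = rho_g, rho_e = rho_e, rho_c = rho_c,
         transform = match.arg(transform)),
    class = "trait_model_spec"
  )
}

# 2x2 (or 1x1) component covariance matrices implied by a spec
component_matrices <- function(spec) {
  k <- length(spec$traits)
  sg <- sqrt(spec$h2 * spec$sigma2)
  sc <- sqrt(spec$c2 * spec$sigma2)
  se <- sqrt((1 - spec$h2 - spec$c2) * spec$sigma2)
  mk <- function(s, rho) {
    if (k == 1) return(matrix(s^2, 1, 1))
    m <- diag(s, 2) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(s, 2)
    (m + t(m)) / 2
  }
  list(G = mk(sg, spec$rho_g), C = mk(sc, spec$rho_c), E = mk(se, spec$rho_e))
}

#' Simulate polygenic traits with household effects on a pedigree
#'
#' Draws trait values family by family from the multivariate normal implied by
#' the variance-component model: for a family with twice-kinship block `K`,
#' household block `H` and component matrices `G`, `C`, `E` (from the spec),
#' the stacked trait vector has covariance
#' `G %x% K + C %x% H + E %x% I` and mean `X beta` plus the trait intercept.
#' Sampling directly from the model the inference modules assume is what makes
#' exact parameter-recovery experiments possible.
#'
#' @param ped A `ped_tbl`.
#' @param spec A [trait_model_spec()].
#' @param covariates Covariate tibble (from [simulate_covariates()] or user
#'   data) with one row per pedigree member; generated with
#'   [simulate_covariates()] when `NULL`.
#' @param seed Integer seed.
#' @return The covariate tibble with one additional column per trait.
#' @export
simulate_traits <- function(ped, spec, covariates = NULL, seed = NULL) {
  stopifnot(inherits(ped, "ped_tbl"), inherits(spec, "trait_model_spec"))
  with_seed(seed, {
    if (is.null(covariates)) covariates <- simulate_covariates(ped)
    covariates <- covariates[match(ped$id, covariates$id), , drop = FALSE]
    if (anyNA(covariates$id)) abort("covariates missing for some pedigree members")
    comps <- component_matrices(spec)
    for (m in comps) {
      if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
        abort("implied component covariance is not positive semi-definite")
      }
    }
    k <- length(spec$traits)
    n <- nrow(ped)
    vals <- matrix(0, n, k)
    for (b in ped_blocks(ped)) {
      m <- length(b$rows)
      Sig <- kronecker(comps$G, b$K) + kronecker(comps$C, b$H) +
        kronecker(comps$E, diag(m))
      L <- chol_psd(Sig)
      z <- as.vector(t(L) %*% rnorm(k * m))
      vals[b$rows, ] <- matrix(z, m, k)
    }
    out <- covariates
    for (t in seq_len(k)) {
      b <- spec$beta[[t]]
      xb <- rep(spec$mean[t], n)
      if (length(b) > 0) {
        miss <- setdiff(names(b), names(covariates))
        if (length(miss) > 0) {
          abort(paste0("covariate column(s) not found: ", paste(miss, collapse = ", ")))
        }
        xb <- xb + as.matrix(covariates[names(b)]) %*% b
      }
      y <- as.vector(xb) + vals[, t]
      if (spec$transform == "exp") y <- exp(y)
      out[[spec$traits[t]]] <- y
    }
    out
  })
}

# Cholesky tolerant of semi-definite blocks (e.g. h2 + c2 = 1 with duplicated
# household rows): falls back to an eigen square root.
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(ev)))
}

#' Simulate a threshold-liability binary trait
#'
#' A latent standard-scale liability is drawn from the polygenic model
#' (`2 phi h2` genetic, optional household share `c2`, residual
#' `1 - h2 - c2`), shifted by covariate effects, and thresholded at the
#' standard-normal quantile of `1 - prevalence`: individuals whose liability
#' exceeds the threshold are affected. For affected individuals an age at
#' onset is drawn uniformly between 18 and their current age (only the
#' under-45 criterion of the ascertainment rule consumes it).
#'
#' @param ped A `ped_tbl`.
#' @param h2 Liability-scale heritability.
#' @param prevalence Population prevalence `K` in (0, 1).
#' @param covariates Covariate tibble; generated when `NULL` (ages are needed
#'   for onset simulation).
#' @param beta Named coefficient vector on the liability scale (positive
#'   values increase liability), over covariate columns; default none.
#' @param c2 Household share of liability variance (default 0: disease
#'   liability is modelled without a common-household term).
#' @param trait Name of the affection column in the output.
#' @param keep_liability Keep the latent liability column (useful for checks).
#' @param seed Integer seed.
#' @return The covariate tibble plus columns `<trait>` (0/1 affection),
#'   `onset_age` (`NA` when unaffected) and optionally `liability`.
#' @export
simulate_binary_trait <- function(ped, h2 = 0.67, prevalence = 0.10,
                                  covariates = NULL, beta = NULL, c2 = 0,
                                  trait = "affected", keep_liability = FALSE,
                                  seed = NULL) {
  stopifnot(inherits(ped, "ped_tbl"))
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must lie in (0, 1)")
  if (h2 < 0 || h2 > 1 || c2 < 0 || h2 + c2 > 1) abort("need 0 <= h2, c2 and h2 + c2 <= 1")
  with_seed(seed, {
    if (is.null(covariates)) covariates <- simulate_covariates(ped)
    covariates <- covariates[match(ped$id, covariates$id), , drop = FALSE]
    spec <- trait_model_spec(traits = ".liab", h2 = h2, c2 = c2, sigma2 = 1,
                             mean = 0, beta = list(.liab = beta %||% numeric(0)))
    sim <- simulate_traits(ped, spec, covariates)
    liab <- sim$.liab
    thr <- qnorm(1 - prevalence)
    affected <- as.integer(liab > thr)
    onset <- rep(NA_real_, nrow(covariates))
    aff <- which(affected == 1)
    if (length(aff) > 0) {
      lo <- pmin(18, covariates$age[aff] * 0.9)
      onset[aff] <- lo + runif(length(aff)) * (covariates$age[aff] - lo)
    }
    out <- covariates
    out[[trait]] <- affected
    out$onset_age <- onset
    if (keep_liability) out$liability <- liab
    out
  })
}

#' Ascertainment rule for family retention
#'
#' Builds the predicate that identifies qualifying probands: affected
#' individuals with onset before `max_onset_age`, or affected individuals
#' with at least `min_affected_first_degree` affected first-degree relatives
#' (parents, full siblings, children).
#'
#' @param max_onset_age Onset-age threshold in years.
#' @param min_affected_first_degree Minimum affected first-degree relatives
#'   for late-onset cases to qualify.
#' @return An object of class `ascertainment_rule`.
#' @export
ascertainment_rule <- function(max_onset_age = 45, min_affected_first_degree = 1) {
  structure(list(max_onset_age = max_onset_age,
                 min_affected_first_degree = min_affected_first_degree),
            class = "ascertainment_rule")
}

#' Apply proband ascertainment to a simulated study
#'
#' Drops families without a qualifying proband and flags exactly one proband
#' per retained family: the qualifying member with the earliest onset, ties
#' broken by id order. This mimics recruitment of families through an
#' affected index case, the sampling scheme the ascertainment correction in
#' [fit_liability()] undoes.
#'
#' @param phenotypes Tibble with `fid`, `id`, an affection column and
#'   `onset_age` (as produced by [simulate_binary_trait()]).
#' @param ped The `ped_tbl` the phenotypes were simulated on (needed to count
#'   affected first-degree relatives).
#' @param rule An [ascertainment_rule()].
#' @param trait Name of the affection column.
#' @return The phenotype rows of retained families with a logical `proband`
#'   column. Zero rows (with a warning) when no family qualifies.
#' @export
ascertain_families <- function(phenotypes, ped, rule = ascertainment_rule(),
                               trait = "affected") {
  stopifnot(inherits(ped, "ped_tbl"), inherits(rule, "ascertainment_rule"))
  if (!all(c("fid", "id", trait, "onset_age") %in% names(phenotypes))) {
    abort("phenotypes must have fid, id, the affection column and onset_age")
  }
  aff <- setNames(phenotypes[[trait]] == 1, phenotypes$id)
  n_fdr <- vapply(seq_len(nrow(phenotypes)), function(i) {
    pid <- phenotypes$id[i]
    row <- ped[ped$id == pid, ]
    if (nrow(row) == 0) return(0L)
    fam <- ped[ped$fid == row$fid, ]
    parents <- c(row$father, row$mother)
    children <- fam$id[(!is.na(fam$father) & fam$father == pid) |
                         (!is.na(fam$mother) & fam$mother == pid)]
    sibs <- fam$id[fam$id != pid &
                     !is.na(fam$father) & !is.na(row$father) & fam$father == row$father &
                     !is.na(fam$mother) & !is.na(row$mother) & fam$mother == row$mother]
    rel <- unique(stats::na.omit(c(parents, children, sibs)))
    sum(aff[rel], na.rm = TRUE)
  }, integer(1))
  qualifies <- phenotypes[[trait]] == 1 &
    (phenotypes$onset_age < rule$max_onset_age |
       n_fdr >= rule$min_affected_first_degree)
  qualifies[is.na(qualifies)] <- FALSE

  out <- phenotypes
  out$proband <- FALSE
  keep_fams <- character(0)
  for (f in unique(phenotypes$fid)) {
    rows <- which(phenotypes$fid == f & qualifies)
    if (length(rows) == 0) next
    ord <- rows[order(phenotypes$onset_age[rows], phenotypes$id[rows])]
    out$proband[ord[1]] <- TRUE
    keep_fams <- c(keep_fams, f)
  }
  out <- out[out$fid %in% keep_fams, , drop = FALSE]
  if (nrow(out) == 0) warn("no family contains a qualifying proband")
  out
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn Bernoulli(MAF) independently per locus;
#' every non-founder inherits one allele from each parent uniformly at random
#' (Mendelian gene dropping). Genotypes are additive allele counts 0/1/2.
#'
#' @param ped A `ped_tbl`.
#' @param n_snps Number of independent loci.
#' @param maf Minor-allele frequency: a scalar, a vector of length `n_snps`,
#'   or a length-2 range to draw per-SNP frequencies uniformly from.
#' @param seed Integer seed.
#' @return Integer matrix of allele counts, SNPs in rows (named `snp00001`,
#'   ...), individuals in columns (pedigree order), with the generative
#'   frequencies in attribute `maf`.
#' @export
simulate_genotypes <- function(ped, n_snps = 1, maf = 0.2, seed = NULL) {
  stopifnot(inherits(ped, "ped_tbl"))
  with_seed(seed, {
    if (length(maf) == 2 && n_snps != 2) {
      maf <- runif(n_snps, maf[1], maf[2])
    } else {
      maf <- rep_len(maf, n_snps)
    }
    if (any(maf <= 0 | maf >= 1)) abort("maf must lie in (0, 1)")
    n <- nrow(ped)
    a1 <- matrix(0L, n_snps, n)
    a2 <- matrix(0L, n_snps, n)
    idx <- setNames(seq_len(n), ped$id)
    for (i in seq_len(n)) {  # pedigree order: parents precede children
      if (ped$founder[i]) {
        a1[, i] <- rbinom(n_snps, 1, maf)
        a2[, i] <- rbinom(n_snps, 1, maf)
      } else {
        pick <- function(j) {
          if (is.na(j)) return(rbinom(n_snps, 1, maf))  # unknown parent: population allele
          ifelse(runif(n_snps) < 0.5, a1[, j], a2[, j])
        }
        a1[, i] <- pick(idx[ped$father[i]])
        a2[, i] <- pick(idx[ped$mother[i]])
      }
    }
    g <- a1 + a2
    dimnames(g) <- list(sprintf("snp%05d", seq_len(n_snps)), ped$id)
    attr(g, "maf") <- maf
    g
  })
}

#' Add an additive SNP effect to a simulated trait
#'
#' Shifts a trait by `effect_size` per copy of the alternate allele — the
#' generative counterpart of the measured-genotype association test.
#'
#' @param phenotypes Phenotype tibble with an `id` column.
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param snp SNP row name (or index).
#' @param trait Trait column to shift.
#' @param effect_size Trait units per allele.
#' @return The phenotype tibble with the shifted trait.
#' @export
add_snp_effect <- function(phenotypes, genotypes, snp, trait, effect_size) {
  g <- genotypes[snp, phenotypes$id]
  phenotypes[[trait]] <- phenotypes[[trait]] + effect_size * as.numeric(g)
  phenotypes
}
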