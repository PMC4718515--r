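---
title: "Variance-component models for extended-pedigree family studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component models for extended-pedigree family studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedvc)
```

## The model

`pedvc` implements the classical variance-component analysis of quantitative
and binary traits measured on extended pedigrees, the design used in
family studies of thrombosis-related phenotypes such as the parameters of the
thrombin-generation assay (lag time, thrombin peak, endogenous thrombin
potential) and venous thromboembolism (VTE) status.

For a continuous trait $y$ measured on $n$ related individuals, the model is

$$y = X\beta + g + c + e,$$

where $X\beta$ are fixed covariate effects and the three random components
have covariances

$$\mathrm{cov}(g) = 2\Phi\,\sigma^2_g,\qquad
  \mathrm{cov}(c) = H\,\sigma^2_c,\qquad
  \mathrm{cov}(e) = I\,\sigma^2_e.$$

$2\Phi$ is twice the kinship matrix — the expected additive genetic
relationship, computed by the recursive founder-to-descendant algorithm in
`kinship_matrix()` — and $H$ is the household indicator matrix (entry 1 when
two individuals share a living environment). Because families are mutually
unrelated, all computations factor into family blocks. Heritability and the
household effect are reported as fractions of the phenotypic variance after
covariates,

$$h^2 = \sigma^2_g/\sigma^2_p,\qquad c^2 = \sigma^2_c/\sigma^2_p,
  \qquad \sigma^2_p = \sigma^2_g + \sigma^2_c + \sigma^2_e.$$

The residual component absorbs non-additive genetic effects (dominance,
epistasis, gene–environment interaction), so $h^2$ is a lower bound on the
broad-sense genetic contribution.

A binary disease trait is analyzed on the liability scale: affection
indicates that a latent standard-normal liability, with relative covariance
$2\Phi h^2 + I(1-h^2)$, exceeds an estimated threshold (probit link).
Pairs of traits are analyzed jointly: the cross-trait covariance is
partitioned with genetic, household and residual correlations
($\rho_g$, $\rho_c$, $\rho_e$), and the model-implied phenotypic correlation
is

$$\rho_p = \sqrt{h^2_1 h^2_2}\,\rho_g +
  \sqrt{(1-h^2_1)(1-h^2_2)}\,\rho_e,$$

computed by `derived_rho_p()`. Note the household term is absent from this
two-component formula: it is exact when $\rho_c = \rho_e$ (the synthetic-data
generator's default) or when a trait has no household share, and an
approximation otherwise.

## Estimation and numerical choices

**Univariate fits** (`fit_univariate()`). The fixed effects and the total
variance have closed-form (GLS) profiles at any value of the fractions
$(h^2, c^2)$, so the optimization is reduced to two dimensions on the simplex
$h^2, c^2 \ge 0$, $h^2 + c^2 \le 1$. The fractions are parameterized by a
softmax map (boundaries reachable in the limit), started from the best point
of a coarse grid plus two fixed restarts, and maximized with Nelder–Mead.
Standard errors come from the numerically differentiated observed
information of the profile likelihood in $(h^2, c^2, \log\sigma^2_p)$; they
are flagged when an estimate sits essentially on the boundary, where Wald
theory degrades. Null hypotheses that pin a variance fraction to its
boundary are tested with the 50:50 $\chi^2_0$:$\chi^2_1$ mixture
(`lrt_boundary()`); interior parameters (correlations) use the plain
$\chi^2_1$ reference.

Candidate covariates (age, age$^2$, sex, oral-contraceptive use, smoking,
physical activity) are screened in a single pass: the full model is fitted,
terms with Wald $p < 0.05$ are retained, and the model is refitted. Age
enters centred at 40 years with its square, so the reported coefficient is
the effect of a one-year deviation. A residual excess kurtosis above 0.8 is
flagged (not an error): the Gaussian likelihood is then questionable and a
log transform (`transform_trait()`) is the usual remedy for right-skewed
assay traits.

**Liability fits** (`fit_liability()`). Each family's likelihood is the
probability that the latent MVN liability vector falls on the observed side
of the threshold in every member — an $m$-dimensional rectangle probability.
These are evaluated with the separation-of-variables transform with greedy
variable reordering and a randomized Richtmyer quasi-Monte-Carlo lattice
(`mvn_rect_prob()`, compiled code; default 512–2048 points). The lattice
shifts use a fixed internal seed, so likelihood evaluations are common
random numbers: the surface seen by the optimizer is deterministic and
smooth, and two identical calls agree bit for bit. Families are capped at
60 members (the lattice carries 61 dimensions); the pedigree simulator's
`max_size` default keeps generated families inside the cap. An optional
Newton polish (`control = list(polish = TRUE)`) tightens the optimum on
smooth surfaces — on unrelated samples the fit then agrees with IRLS probit
regression to $10^{-6}$.

**Ascertainment.** Families recruited through an affected proband
over-represent high-liability genotypes. With
`correct_ascertainment = TRUE`, each family's likelihood is divided by the
marginal probability of its proband's observed affection status —
single-proband conditioning, the classical correction. Sequential and
multiplex ascertainment schemes are out of scope. In simulation the
uncorrected fit on ascertained families overestimates prevalence and sits
systematically below the corrected fit in $h^2$.

**Bivariate fits** (`fit_bivariate()`). The joint $2m \times 2m$ family
blocks are assembled from the component matrices; fixed effects are again
profiled by GLS, and the nine remaining natural parameters (two fraction
pairs, two log variances, three correlations through $\tanh$ maps) are
maximized by Nelder–Mead started at the univariate fits and the cross-trait
residual correlation. $\rho_c$ is estimated by default and fixed to zero via
`rho_c = "zero"`; fits with $|\rho| > 0.995$ are flagged as boundary cases.
The $p$-value for the derived $\rho_p$ uses the delta method on the fitted
parameters and is approximate. For a binary-by-continuous pair the
continuous trait's parameters are first profiled at their univariate
maximum, then the liability heritability, threshold and cross-trait
correlations are estimated through the conditional likelihood
$f(y)\,P(\text{affection} \mid y)$, the latter a conditional-normal
rectangle probability. This two-stage profile sacrifices a little
efficiency for robustness and speed; it is the package's own design where
the field's standard software does not document its internals.

**Association** (`run_gwas()`, `measured_genotype_test()`). The measured
genotype test adds a SNP's allele count (or imputed dosage) to the fixed
effects. By default the variance components are profiled once under the
null model and held fixed: the data are whitened by the family Cholesky
factors and each SNP costs one residualized regression, giving the
score-form $\chi^2_1$ statistic. `refit = TRUE` re-estimates components per
SNP (full LRT). QC follows standard array practice — founder MAF $\ge$ 1%,
call rate $\ge$ 98%, founder exact Hardy–Weinberg $p > 10^{-6}$
(`hwe_exact_test()`, full enumeration), and an info-score floor of 0.3 when
imputation scores are supplied. MAF and HWE use founders only by default:
including relatives inflates frequencies and violates the HWE test's
independence assumption. Significance classes use the conventional
genome-wide ($5\times10^{-8}$) and suggestive ($1\times10^{-5}$) thresholds,
and calibration is summarized by the median-based inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$.

## What the synthetic-data generator emulates

`simulate_pedigree()` builds families the way extended thrombophilia
pedigrees are recruited: a founder couple, children who marry in spouses,
third and (in ~40% of families) fourth generations, redrawn until each
family has at least 10 members in at least 3 generations (defaults tuned so
35 families average ~27 members, ~950 individuals). Households follow
nuclear units: each couple and their unmarried children share one;
married-in spouses found a new one. Ages are generation-structured
(founders oldest, means 23 years apart, within-generation SD 6, truncated
to [2, 101]), so the age covariate has pedigree-realistic confounding with
genetic relatedness. Oral-contraceptive use is simulated for women aged
18–50, smoking and physical activity for adults.

`simulate_traits()` draws trait values from exactly the multivariate normal
the inference modules assume (family-block Cholesky of
$G \otimes 2\Phi + C \otimes H + E \otimes I$), rather than by explicit
allelic gene dropping of a polygenic background — the point of the
generator is parameter recovery under the model's own assumptions. Default
trait settings describe an endogenous-thrombin-potential-like phenotype:
$h^2 = 0.52$, $c^2 = 0.23$, an age trend with curvature, a strong
oral-contraceptive effect, and a total random variance chosen so covariates
explain about 10% of the trait. `simulate_binary_trait()` thresholds a
standard-scale liability at $\Phi^{-1}(1-K)$; the default disease model
($h^2 = 0.67$, $K = 0.10$, no household term) mirrors a strongly familial
thrombosis-like condition. Age at onset for affected individuals is drawn
uniformly between 18 and current age — only the under-45 criterion of the
ascertainment rule consumes it. `simulate_genotypes()` gene-drops unlinked
biallelic loci (founder alleles Bernoulli(MAF), Mendelian transmission), so
SNPs are in linkage equilibrium: conditional-analysis behaviour with real
LD structure is *not* exercised by these tests, and neither are genotyping
error, missingness mechanisms, non-Gaussian residuals, or assortative
mating.

A typical pipeline:

```{r example, eval = FALSE}
ped <- simulate_pedigree(n_families = 35, seed = 1)
dat <- simulate_traits(ped, trait_model_spec(), seed = 2)
fit <- fit_univariate(dat, ped, "etp",
                      covariates = c("age_c", "age2", "female", "oc",
                                     "smoking", "activity"))
glance(fit)
autoplot(fit)
```

## Monte-Carlo experiment sizes

The recovery and calibration experiments shipped in the test suite and the
acceptance script use sizes chosen so that each reported mean has a
Monte-Carlo standard error well below the band it is judged against:

- continuous-trait recovery: 20 replicates of 35 families (~950
  individuals each); per-replicate SD of $\hat h^2$ is ~0.08, so the mean
  carries SE ~0.02;
- liability recovery: 16 replicates; the per-replicate SD of the
  liability-$\hat h^2$ MLE at these conditions is ~0.16 (the realized
  genetic variance of a 35-family draw varies substantially), giving the
  mean SE ~0.04;
- genetic-correlation recovery: 20 replicates (per-replicate SD ~0.01);
- null GWAS calibration: 4 independent scans of 5,000 gene-dropped SNPs;
  one scan's median-based $\lambda$ has sampling SD ~0.04, the 4-scan mean
  ~0.02;
- null LRT calibration: 100 replicates of 50 sibling-pair families.

## Known limitations

- Autosomal additive kinship only: no inbred founders, no sex-linked or
  dominance relationship matrices, no identity-by-descent states beyond the
  kinship coefficient.
- The liability-$h^2$ MLE shows a small downward finite-sample tendency
  (of order 0.05 at 35 families) in our calibrations; standard errors near
  a variance boundary are reported but flagged.
- The ascertainment correction conditions on a single proband's affection
  status; it is approximate when the sampling rule also used onset age or
  affected relatives, though in our experiments the residual bias is well
  inside the recovery tolerance.
- Rectangle probabilities are quasi-Monte-Carlo estimates; with the default
  point counts the per-family relative error is ~$10^{-3}$, which perturbs
  the liability estimates far less than sampling noise but limits the
  precision of reported log-likelihood differences.
- `derived_rho_p()` ignores the household cross-correlation by design (see
  above); for trait pairs with household shares and $\rho_c \ne \rho_e$ it
  deviates from the fitted total correlation.
- The GWAS engine's default profiles variance components under the null
  once; with very strong single-SNP effects the score-form statistic is
  conservative relative to the exact per-SNP refit (available via
  `refit = TRUE`).
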