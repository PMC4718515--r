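# Hand-built fixture pedigrees used across the suite.

ped_trio <- function() {
  build_pedigree(tibble::tibble(
    fid = "T", id = c("dad", "mum", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
    sex = c("male", "female", "female")
  ))
}

# founder couple with two children
ped_nuclear <- function() {
  build_pedigree(tibble::tibble(
    fid = "N", id = c("f", "m", "c1", "c2"),
    father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
    sex = c("male", "female", "male", "female")
  ))
}

# two brothers married to two sisters, one child each: the children are
# double first cousins (2 phi = 0.25)
ped_double_first_cousins <- function() {
  build_pedigree(tibble::tibble(
    fid = "D",
    id     = c("gf1", "gm1", "gf2", "gm2", "b1", "b2", "s1", "s2", "k1", "k2"),
    father = c(NA, NA, NA, NA, "gf1", "gf1", "gf2", "gf2", "b1", "b2"),
    mother = c(NA, NA, NA, NA, "gm1", "gm1", "gm2", "gm2", "s1", "s2"),
    sex    = c("male", "female", "male", "female", "male", "male",
               "female", "female", "male", "female")
  ))
}

# shared father, two mothers: k1 and k2 are half siblings
ped_half_sibs <- function() {
  build_pedigree(tibble::tibble(
    fid = "H", id = c("f", "m1", "m2", "k1", "k2"),
    father = c(NA, NA, NA, "f", "f"),
    mother = c(NA, NA, NA, "m1", "m2"),
    sex = c("male", "female", "female", "male", "male")
  ))
}

# 4-generation, 12-member family (for topological-order checks)
ped_four_gen <- function() {
  build_pedigree(tibble::tibble(
    fid = "G",
    id     = c("k4", "p3a", "p3b", "p2a", "p2b", "g1a", "g1b", "sp2", "k3b",
               "g1c", "g1d", "k2c"),
    father = c("p3a", "p2a", NA, "g1a", NA, NA, NA, NA, "p2a",
               NA, NA, "g1c"),
    mother = c("p3b", "p2b", NA, "g1b", NA, NA, NA, NA, "p2b",
               NA, NA, "g1d"),
    sex    = c("female", "male", "female", "male", "female", "male", "female",
               "male", "male", "male", "female", "female")
  ))
}

# small households fixture: two households of 2, one singleton
ped_households <- function() {
  build_pedigree(tibble::tibble(
    fid = "W", id = c("a", "b", "c"),
    father = NA_character_, mother = NA_character_,
    sex = c("male", "female", "male"),
    household = c("h1", "h1", "h2")
  ))
}

# pure sib-pair families (many independent families of 4) for moment checks
ped_sib_pairs <- function(n_fam) {
  recs <- lapply(seq_len(n_fam), function(f) {
    fam <- sprintf("S%04d", f)
    ids <- paste0(fam, c("_f", "_m", "_c1", "_c2"))
    tibble::tibble(
      fid = fam, id = ids,
      father = c(NA, NA, ids[1], ids[1]),
      mother = c(NA, NA, ids[2], ids[2]),
      sex = c("male", "female", "male", "female"),
      household = fam
    )
  })
  build_pedigree(dplyr::bind_rows(recs))
}

# unrelated founders in distinct households
ped_founders_only <- function(n) {
  build_pedigree(tibble::tibble(
    fid = sprintf("U%04d", seq_len(n)), id = sprintf("u%04d", seq_len(n)),
    father = NA_character_, mother = NA_character_,
    sex = rep(c("male", "female"), length.out = n),
    household = sprintf("uh%04d", seq_len(n))
  ))
}

# the study-scale generative trait models used in recovery experiments
etp_like_spec <- function() {
  trait_model_spec(
    traits = "etp", h2 = 0.52, c2 = 0.23, sigma2 = 1.2, mean = 48.53,
    beta = list(etp = c(age_c = 0.01, age2 = -3e-4, oc = 0.87))
  )
}

etp_tp_spec <- function() {
  trait_model_spec(
    traits = c("etp", "tp"), h2 = c(0.52, 0.54), c2 = c(0.23, 0.27),
    sigma2 = c(1.2, 1.6), mean = c(48.53, 32.09),
    beta = list(etp = c(age_c = 0.01, age2 = -3e-4, oc = 0.87),
                tp = c(age_c = 0.01, age2 = -2e-4, female = 0.13, oc = 0.72)),
    rho_g = 0.87, rho_e = 0.82
  )
}
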