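#' Additive relationship (twice-kinship) matrix of a pedigree
#'
#' Computes twice the kinship coefficient, `2 * phi(i, j)`, for every pair of
#' individuals by the classical recursive algorithm on the topologically
#' ordered pedigree. `phi(i, j)` is the probability that two alleles sampled
#' at random, one from each individual, are identical by descent; `2 * phi` is
#' the expected additive genetic relationship that scales the polygenic
#' covariance between relatives (`2 * phi * sigma2_g`).
#'
#' @param ped A `ped_tbl` from [build_pedigree()].
#' @return A symmetric numeric matrix with individual ids as dimnames.
#'   Diagonal entries are `1 + F` (1 for non-inbred individuals); entries
#'   between members of different families are 0, so the matrix is
#'   block-diagonal by family.
#'
#' @details Recursion, with individuals ordered parents-before-children:
#'   `phi(i, i) = 1/2 + phi(father_i, mother_i) / 2` and, for `j` ordered
#'   before `i`, `phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2`;
#'   missing parents contribute 0. Founders are taken as non-inbred and
#'   mutually unrelated.
#'
#' @examples
#' ped <- build_pedigree(tibble::tibble(
#'   fid = "F1", id = c("p1", "p2", "c1"),
#'   father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
#'   sex = c("male", "female", "male")
#' ))
#' kinship_matrix(ped)["p1", "c1"]  # 0.5
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (b in ped_blocks(ped)) K[b$rows, b$rows] <- b$K
  K
}

# Per-family covariance building blocks: twice-kinship and household
# indicator matrices, plus the row indices into the pedigree. All model code
# works family by family, so the dense study-wide matrices are never needed
# internally.
ped_blocks <- function(ped) {
  n <- nrow(ped)
  lapply(split(seq_len(n), ped$fid), function(fam) {
    m <- length(fam)
    phi <- matrix(0, m, m)
    fi <- match(ped$father[fam], ped$id[fam])  # local parent indices, NA if founder
    mi <- match(ped$mother[fam], ped$id[fam])
    for (a in seq_len(m)) {
      pf <- fi[a]; pm <- mi[a]
      phi[a, a] <- 0.5 + if (!is.na(pf) && !is.na(pm)) phi[pf, pm] / 2 else 0
      if (a > 1) {
        for (b in seq_len(a - 1)) {
          v <- 0
          if (!is.na(pf)) v <- v + phi[pf, b]
          if (!is.na(pm)) v <- v + phi[pm, b]
          phi[a, b] <- phi[b, a] <- v / 2
        }
      }
    }
    h <- ped$household[fam]
    H <- outer(h, h, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
    diag(H) <- 1
    ids <- ped$id[fam]
    dimnames(phi) <- list(ids, ids)
    list(fid = ped$fid[fam[1]], rows = fam, ids = ids, K = 2 * phi, H = H * 1)
  })
}

#' Household-sharing matrix of a pedigree
#'
#' Indicator matrix of shared living environment: entry `(i, j)` is 1 when the
#' two individuals have the same non-missing household id (diagonal always 1).
#' This matrix scales the common-environment variance component
#' (`H * sigma2_c`). A missing household id means the individual shares a
#' household with nobody.
#'
#' @param ped A `ped_tbl` from [build_pedigree()].
#' @return A symmetric 0/1 numeric matrix with ids as dimnames.
#' @export
household_matrix <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  h <- ped$household
  same <- !is.na(h) & outer(h, h, `==`)
  same[is.na(same)] <- FALSE
  H <- matrix(as.numeric(same), nrow(ped), dimnames = list(ped$id, ped$id))
  diag(H) <- 1
  H
}

#' Count relative pairs by relationship class
#'
#' Enumerates all unordered pairs of individuals (including self pairs) and
#' tabulates them by relationship. The first-degree and second-degree classes
#' are distinguished by pedigree structure (parent-offspring vs siblings both
#' have `2 phi = 0.5`; grandparent-grandchild, avuncular, half-siblings and
#' double first cousins all have `2 phi = 0.25`); more remote classes are
#' binned purely by the `2 phi` value (3rd degree = 0.125, 4th = 0.0625, ...,
#' 7th = 0.0078125).
#'
#' @param ped A `ped_tbl` from [build_pedigree()].
#' @param kin Optional precomputed [kinship_matrix()] (recomputed if omitted).
#' @param within_family If `TRUE`, only pairs within the same family are
#'   counted (the cross-family pairs, necessarily unrelated, are dropped).
#'   Default `FALSE` counts every pair, so class counts sum to
#'   `n * (n + 1) / 2`.
#' @return A tibble with columns `relationship`, `two_phi`, `n_pairs`, ordered
#'   by decreasing `two_phi`.
#' @export
classify_pairs <- function(ped, kin = NULL, within_family = FALSE) {
  stopifnot(inherits(ped, "ped_tbl"))
  if (is.null(kin)) kin <- kinship_matrix(ped)
  n <- nrow(ped)
  counts <- list()
  bump <- function(label, value) {
    key <- paste0(label, "|", value)
    counts[[key]] <<- (counts[[key]] %||% 0) + 1
  }
  value_label <- function(v) {
    if (isTRUE(all.equal(v, 0.125))) "3rd degree"
    else if (isTRUE(all.equal(v, 0.0625))) "4th degree"
    else if (isTRUE(all.equal(v, 0.03125))) "5th degree"
    else if (isTRUE(all.equal(v, 0.015625))) "6th degree"
    else if (isTRUE(all.equal(v, 0.0078125))) "7th degree"
    else if (isTRUE(all.equal(v, 0))) "unrelated"
    else paste0("other (2phi=", signif(v, 4), ")")
  }
  for (fam in split(seq_len(n), ped$fid)) {
    fa <- setNames(ped$father[fam], ped$id[fam])
    mo <- setNames(ped$mother[fam], ped$id[fam])
    ids <- ped$id[fam]
    is_parent_of <- function(p, c) !is.na(fa[c]) && fa[[c]] == p ||
      !is.na(mo[c]) && mo[[c]] == p
    shares <- function(a, b) {
      sf <- !is.na(fa[a]) && !is.na(fa[b]) && fa[[a]] == fa[[b]]
      sm <- !is.na(mo[a]) && !is.na(mo[b]) && mo[[a]] == mo[[b]]
      c(sf, sm)
    }
    full_sib <- function(a, b) all(shares(a, b))
    grandparent_of <- function(g, c) {
      for (p in c(fa[[c]], mo[[c]])) {
        if (!is.na(p) && is_parent_of(g, p)) return(TRUE)
      }
      FALSE
    }
    avuncular <- function(a, b) {
      for (p in c(fa[[b]], mo[[b]])) if (!is.na(p) && full_sib(a, p)) return(TRUE)
      for (p in c(fa[[a]], mo[[a]])) if (!is.na(p) && full_sib(b, p)) return(TRUE)
      FALSE
    }
    m <- length(fam)
    for (ai in seq_len(m)) {
      bump("self", 1)
      if (ai > 1) {
        for (bi in seq_len(ai - 1)) {
          a <- ids[ai]; b <- ids[bi]
          v <- kin[fam[ai], fam[bi]]
          lbl <- if (is_parent_of(a, b) || is_parent_of(b, a)) "parent-offspring"
          else if (full_sib(a, b)) "siblings"
          else if (sum(shares(a, b)) == 1) "half siblings"
          else if (grandparent_of(a, b) || grandparent_of(b, a)) "grandparent-grandchild"
          else if (avuncular(a, b)) "avuncular"
          else if (isTRUE(all.equal(v, 0.25))) "double 1st cousins"
          else value_label(v)
          bump(lbl, v)
        }
      }
    }
  }
  res <- tibble::tibble(
    relationship = sub("\\|.*$", "", names(counts)),
    two_phi = as.numeric(sub("^.*\\|", "", names(counts))),
    n_pairs = as.numeric(unlist(counts))
  )
  if (!within_family) {
    sizes <- table(ped$fid)
    cross <- (n^2 - sum(sizes^2)) / 2
    if (cross > 0) {
      if (any(res$relationship == "unrelated")) {
        res$n_pairs[res$relationship == "unrelated"] <-
          res$n_pairs[res$relationship == "unrelated"] + cross
      } else {
        res <- dplyr::bind_rows(res, tibble::tibble(
          relationship = "unrelated", two_phi = 0, n_pairs = cross))
      }
    }
  }
  dplyr::arrange(res, dplyr::desc(.data$two_phi), .data$relationship)
}

#' Long-format table of nonzero relationship entries
#'
#' @param kin A matrix from [kinship_matrix()].
#' @return A tibble `id1`, `id2`, `two_phi` with one row per nonzero entry of
#'   the upper triangle (including the diagonal).
#' @export
kinship_pairs <- function(kin) {
  stopifnot(is.matrix(kin))
  ut <- upper.tri(kin, diag = TRUE) & kin != 0
  ij <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    id1 = rownames(kin)[ij[, 1]],
    id2 = colnames(kin)[ij[, 2]],
    two_phi = kin[ut]
  )
}
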