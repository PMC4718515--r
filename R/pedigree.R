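#' Build and validate a pedigree
#'
#' Takes a table of individual records and returns a validated, topologically
#' ordered pedigree (parents always precede their children). The pedigree is
#' the backbone of every analysis in the package: kinship and household
#' covariance matrices, trait simulation and all likelihoods are computed on
#' top of it.
#'
#' @param records A data frame with one row per individual and columns
#'   `fid` (family id), `id` (individual id, unique across the study),
#'   `father`, `mother` (ids or `NA` for founders), `sex` (`"male"`/`"female"`
#'   or the LINKAGE codes 1/2). Optional columns: `household` (shared-living
#'   group id, `NA` means the individual shares a household with nobody) and
#'   `proband` (logical or 0/1 flag of the family's ascertainment proband).
#'
#' @return A tibble of class `ped_tbl`, one row per individual, reordered so
#'   parents precede children, with added columns `founder` (logical) and
#'   `generation` (1 = founder generation; a child's generation is one more
#'   than the deeper of its parents').
#'
#' @details Validation enforces: unique ids; referenced parents present in the
#'   same family; fathers male and mothers female; either both parents present
#'   or both missing is *not* required (one known parent is allowed and the
#'   other treated as an unrelated founder is **not** assumed — the missing
#'   parent simply contributes no kinship path); and acyclicity (no individual
#'   is its own ancestor). Each family must contain at least one founder.
#'
#' @examples
#' trio <- tibble::tibble(
#'   fid = "F1", id = c("dad", "mum", "kid"),
#'   father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
#'   sex = c("male", "female", "female")
#' )
#' build_pedigree(trio)
#' @export
build_pedigree <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("fid", "id", "father", "mother", "sex")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree records lack required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ped <- tibble::as_tibble(records)
  ped$fid <- as.character(ped$fid)
  ped$id <- as.character(ped$id)
  ped$father <- normalize_parent(ped$father)
  ped$mother <- normalize_parent(ped$mother)
  ped$sex <- normalize_sex(ped$sex)
  if (!"household" %in% names(ped)) ped$household <- NA_character_
  ped$household <- as.character(ped$household)
  ped$household[!is.na(ped$household) & ped$household %in% c("0", "")] <- NA_character_
  if (!"proband" %in% names(ped)) ped$proband <- FALSE
  ped$proband <- as.logical(ped$proband)
  ped$proband[is.na(ped$proband)] <- FALSE

  if (anyDuplicated(ped$id)) {
    dups <- unique(ped$id[duplicated(ped$id)])
    abort(paste0("duplicate individual id(s): ", paste(head(dups, 5), collapse = ", ")))
  }
  self_parent <- ped$id == ped$father | ped$id == ped$mother
  if (any(self_parent, na.rm = TRUE)) {
    abort(paste0("individual is its own parent (cycle): ",
                 ped$id[which(self_parent)[1]]))
  }

  idx <- setNames(seq_len(nrow(ped)), ped$id)
  check_parent <- function(pid, role, want_sex) {
    present <- !is.na(pid)
    unknown <- present & !(pid %in% ped$id)
    if (any(unknown)) {
      abort(paste0("referenced ", role, " id not in pedigree: ",
                   pid[which(unknown)[1]], " (child ", ped$id[which(unknown)[1]], ")"))
    }
    j <- idx[pid[present]]
    bad_sex <- ped$sex[j] != want_sex
    if (any(bad_sex)) {
      abort(paste0(role, " is not ", want_sex, ": ", pid[present][which(bad_sex)[1]]))
    }
    bad_fam <- ped$fid[j] != ped$fid[present]
    if (any(bad_fam)) {
      abort(paste0(role, " belongs to a different family: ", pid[present][which(bad_fam)[1]]))
    }
  }
  check_parent(ped$father, "father", "male")
  check_parent(ped$mother, "mother", "female")

  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  ord <- topo_order(ped$id, ped$father, ped$mother)  # errors name a cycle member
  founder_by_fam <- tapply(ped$founder, ped$fid, any)
  if (!all(founder_by_fam)) {
    abort(paste0("family without a founder: ",
                 names(founder_by_fam)[which(!founder_by_fam)[1]]))
  }
  ped <- ped[ord, , drop = FALSE]

  # generation depth: founders are generation 1
  gen <- setNames(rep(1L, nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    if (!ped$founder[i]) {
      pg <- c(gen[ped$father[i]], gen[ped$mother[i]])
      gen[ped$id[i]] <- max(pg, na.rm = TRUE) + 1L
    }
  }
  ped$generation <- unname(gen[ped$id])

  class(ped) <- c("ped_tbl", class(tibble::tibble()))
  ped
}

# Kahn topological sort over the parent -> child DAG; errors on cycles,
# naming an individual on the cycle.
topo_order <- function(id, father, mother) {
  n <- length(id)
  idx <- setNames(seq_len(n), id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(father[i], mother[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        indeg[i] <- indeg[i] + 1L
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stuck <- setdiff(seq_len(n), out)
    abort(paste0("pedigree contains a cycle involving individual: ", id[stuck[1]]))
  }
  out
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x %in% c("0", "")] <- NA_character_
  x
}

normalize_sex <- function(x) {
  if (is.numeric(x)) x <- as.character(x)
  x <- tolower(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  if (any(is.na(out))) {
    abort(paste0("unrecognized sex code: ", x[which(is.na(out))[1]],
                 " (expected male/female or 1/2)"))
  }
  out
}

#' @export
print.ped_tbl <- function(x, ...) {
  nfam <- length(unique(x$fid))
  cat("# Pedigree: ", nrow(x), " individuals in ", nfam, " famil",
      if (nfam == 1) "y" else "ies", ", ",
      sum(x$founder), " founders, ", max(x$generation), " generation(s)\n",
      sep = "")
  NextMethod()
}

#' Founder ids of a pedigree
#' @param ped A `ped_tbl` from [build_pedigree()].
#' @return Character vector of founder ids.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "ped_tbl"))
  ped$id[ped$founder]
}
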