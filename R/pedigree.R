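#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric
NULL

#' Pedigree of a closed breeding population
#'
#' Stores a validated, topologically sorted pedigree: every parent precedes
#' its offspring, parents are coded as integer indices into the pedigree
#' itself (`NA` for an unknown parent), and the original animal identifiers
#' are retained in `id`. Construct via [readPedigree()] or [asPedigree()].
#'
#' @slot id character, unique animal identifiers in sorted order.
#' @slot sire,dam integer indices of the parents within `id`
#'   (`NA` = unknown).
#' @slot generation integer cohort label (spawning year) per animal.
#' @slot sex character, `"female"`/`"male"` (may be `NA`).
#' @slot family character full-sib family identifier (may be `NA` for
#'   founders).
#' @export
setClass("Pedigree", slots = c(
  id = "character",
  sire = "integer",
  dam = "integer",
  generation = "integer",
  sex = "character",
  family = "character"
))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  lens <- c(length(object@sire), length(object@dam), length(object@generation),
            length(object@sex), length(object@family))
  if (any(lens != n)) return("slot lengths differ")
  if (anyDuplicated(object@id)) {
    return(sprintf("duplicate animal id: %s",
                   object@id[duplicated(object@id)][1L]))
  }
  idx <- seq_len(n)
  bad <- which((!is.na(object@sire) & object@sire >= idx) |
               (!is.na(object@dam) & object@dam >= idx))
  if (length(bad)) {
    return(sprintf("pedigree not sorted: parent of '%s' does not precede it",
                   object@id[bad[1L]]))
  }
  TRUE
})

#' @describeIn Pedigree number of animals
#' @param ped a `Pedigree`
#' @export
nAnimals <- function(ped) length(ped@id)

#' @describeIn Pedigree animal identifiers in internal (sorted) order
#' @export
pedIds <- function(ped) ped@id

#' Coerce a pedigree to data.frame
#'
#' One row per animal in internal order, parent identifiers (not indices),
#' `"0"` for unknown parents.
#'
#' @param x a `Pedigree`
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.Pedigree <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    animal = x@id,
    sire = ifelse(is.na(x@sire), "0", x@id[ifelse(is.na(x@sire), 1L, x@sire)]),
    dam = ifelse(is.na(x@dam), "0", x@id[ifelse(is.na(x@dam), 1L, x@dam)]),
    generation = x@generation,
    sex = x@sex,
    family = x@family,
    stringsAsFactors = FALSE
  )
}

setMethod("show", "Pedigree", function(object) {
  n <- nAnimals(object)
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d animals (%d founders), %d full-sib families\n",
              n, nf, length(unique(stats::na.omit(object@family)))))
  if (!all(is.na(object@generation))) {
    gen <- table(object@generation)
    cat("  cohorts:", paste(sprintf("%s (n=%d)", names(gen), as.integer(gen)),
                            collapse = ", "), "\n")
  }
})

## Kahn topological sort on (parent -> offspring) edges; errors name a cycle
## member. Returns a permutation of the rows.
topoOrder <- function(id, sire_id, dam_id) {
  n <- length(id)
  pos <- seq_len(n)
  names(pos) <- id
  si <- unname(pos[sire_id])
  di <- unname(pos[dam_id])
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(si[i], di[i]))) {
      if (!is.na(p)) {
        if (p == i) stop(sprintf("animal '%s' is its own ancestor", id[i]))
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(n)
  m <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    m <- m + 1L
    out[m] <- v
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (m < n) {
    member <- id[setdiff(seq_len(n), out[seq_len(m)])[1L]]
    stop(sprintf("pedigree contains a cycle involving animal '%s'", member))
  }
  out
}

#' Build a Pedigree from vectors
#'
#' Validates identifiers, resolves parent references, topologically sorts so
#' that parents precede offspring, and returns a [Pedigree-class]. Input
#' order is never assumed: records may list offspring before parents.
#'
#' @param animal,sire,dam character vectors; `unknown` codes a missing
#'   parent.
#' @param generation integer-like cohort labels (e.g. spawning years).
#' @param sex character (`"female"`/`"male"`) or `NA`.
#' @param family full-sib family labels or `NA`.
#' @param unknown token marking an unknown parent (default `"0"`).
#' @return a sorted, validated `Pedigree`.
#' @export
asPedigree <- function(animal, sire, dam, generation = NA_integer_,
                       sex = NA_character_, family = NA_character_,
                       unknown = "0") {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n <- length(animal)
  if (anyDuplicated(animal)) {
    stop(sprintf("duplicate animal id: '%s'",
                 animal[duplicated(animal)][1L]))
  }
  sire[is.na(sire) | sire %in% c(unknown, "")] <- NA
  dam[is.na(dam) | dam %in% c(unknown, "")] <- NA
  missing_par <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(missing_par)) {
    stop(sprintf("parent id '%s' has no pedigree record", missing_par[1L]))
  }
  generation <- rep_len(suppressWarnings(as.integer(generation)), n)
  sex <- rep_len(as.character(sex), n)
  family <- rep_len(as.character(family), n)
  ord <- topoOrder(animal, sire, dam)
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]
  pos <- seq_len(n); names(pos) <- animal
  new("Pedigree",
      id = animal,
      sire = unname(pos[sire]),
      dam = unname(pos[dam]),
      generation = generation[ord],
      sex = sex[ord],
      family = family[ord])
}

#' Read a pedigree CSV
#'
#' Expects one header row with columns `animal,sire,dam` and optionally
#' `generation,sex,family`; `unknown` (default `"0"`) marks a missing
#' parent. Rejects duplicate identifiers, parents without a record of their
#' own, and cyclic parentage, naming the offending animal.
#'
#' @param path file path.
#' @param unknown unknown-parent token.
#' @param sep field separator.
#' @return a sorted [Pedigree-class].
#' @export
readPedigree <- function(path, unknown = "0", sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns animal, sire, dam")
  }
  getcol <- function(nm, default) if (nm %in% names(df)) df[[nm]] else default
  asPedigree(df$animal, df$sire, df$dam,
             generation = getcol("generation", NA),
             sex = getcol("sex", NA_character_),
             family = getcol("family", NA_character_),
             unknown = unknown)
}

## Mendelian-sampling variances d_i given parental inbreeding:
## both parents known 0.5 - 0.25(F_s + F_d); one known 0.75 - 0.25 F_p;
## none known 1.
mendelianVariance <- function(sire, dam, F) {
  Fs <- ifelse(is.na(sire), 0, F[ifelse(is.na(sire), 1L, sire)])
  Fd <- ifelse(is.na(dam), 0, F[ifelse(is.na(dam), 1L, dam)])
  ifelse(!is.na(sire) & !is.na(dam), 0.5 - 0.25 * (Fs + Fd),
  ifelse(!is.na(sire), 0.75 - 0.25 * Fs,
  ifelse(!is.na(dam), 0.75 - 0.25 * Fd, 1)))
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F by the Meuwissen-Luo algorithm
#' (equal to `diag(A) - 1` from the tabular relationship matrix but without
#' densifying A). An animal with an unknown parent on either side has
#' F = 0; founders have F = 0.
#'
#' @param ped a sorted [Pedigree-class].
#' @return numeric vector of F in `[0, 1)`, internal order.
#' @export
inbreeding <- function(ped) {
  n <- nAnimals(ped)
  s <- ped@sire; d <- ped@dam
  Fv <- numeric(n)
  Dv <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    Fs <- if (!is.na(s[i])) Fv[s[i]] else NA_real_
    Fd <- if (!is.na(d[i])) Fv[d[i]] else NA_real_
    Dv[i] <- if (!is.na(s[i]) && !is.na(d[i])) 0.5 - 0.25 * (Fs + Fd)
             else if (!is.na(s[i])) 0.75 - 0.25 * Fs
             else if (!is.na(d[i])) 0.75 - 0.25 * Fd
             else 1
    if (is.na(s[i]) || is.na(d[i])) next  # F stays 0
    ## accumulate A[i,i] = sum_j L_ij^2 D_j over ancestors j (incl. i)
    L[i] <- 1
    touched <- i
    acc <- 0
    for (j in seq(i, 1L)) {
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * Dv[j]
      if (!is.na(s[j])) { L[s[j]] <- L[s[j]] + 0.5 * lj; touched <- c(touched, s[j]) }
      if (!is.na(d[j])) { L[d[j]] <- L[d[j]] + 0.5 * lj; touched <- c(touched, d[j]) }
    }
    L[touched] <- 0
    Fv[i] <- acc - 1
  }
  Fv
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive relationship matrix A by the tabular method:
#' `A[i,j] = 0.5 * (A[j,s_i] + A[j,d_i])` for `j < i` and
#' `A[i,i] = 1 + 0.5 * A[s_i,d_i]`, unknown-parent terms zero. Intended for
#' verification and moderate pedigrees; the mixed-model machinery only ever
#' needs the sparse inverse ([aInverse()]).
#'
#' @param ped a sorted [Pedigree-class].
#' @param max_n guard against accidentally densifying a huge pedigree.
#' @return dense symmetric matrix with `dimnames` from `pedIds(ped)`.
#' @export
relationshipMatrix <- function(ped, max_n = 10000L) {
  n <- nAnimals(ped)
  if (n > max_n) {
    stop(sprintf("refusing to build a dense %d x %d A; raise max_n if intended",
                 n, n))
  }
  s <- ped@sire; d <- ped@dam
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    as_ <- if (is.na(s[i])) numeric(n) else A[, s[i]]
    ad_ <- if (is.na(d[i])) numeric(n) else A[, d[i]]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      A[j, i] <- A[i, j] <- 0.5 * (as_[j] + ad_[j])
    }
    A[i, i] <- 1 + (if (!is.na(s[i]) && !is.na(d[i])) 0.5 * A[s[i], d[i]] else 0)
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: writing `b_i = 1/d_i` with `d_i` the
#' Mendelian-sampling variance of animal i, add `b_i` at (i,i), `-b_i/2` at
#' (i, parent) and `b_i/4` within the known-parent block. With
#' `use_inbreeding = FALSE` the rules reduce to the classic non-inbred
#' constants (1, 4/3, 2); that flag exists for sensitivity checks only.
#'
#' @param ped a sorted [Pedigree-class].
#' @param F inbreeding coefficients (computed when `NULL` and
#'   `use_inbreeding`).
#' @param use_inbreeding logical; if `FALSE`, F is taken as zero.
#' @return sparse symmetric `Matrix` with `dimnames` from `pedIds(ped)`.
#' @export
aInverse <- function(ped, F = NULL, use_inbreeding = TRUE) {
  n <- nAnimals(ped)
  if (!use_inbreeding) {
    F <- numeric(n)
  } else if (is.null(F)) {
    F <- inbreeding(ped)
  }
  s <- ped@sire; d <- ped@dam
  di <- mendelianVariance(s, d, F)
  if (any(di <= 0)) {
    stop(sprintf("non-positive Mendelian-sampling variance for animal '%s'",
                 ped@id[which(di <= 0)[1L]]))
  }
  b <- 1 / di
  ii <- seq_len(n)
  ks <- which(!is.na(s))
  kd <- which(!is.na(d))
  kb <- which(!is.na(s) & !is.na(d))
  ## all triplets below have row >= col because parents precede offspring
  ti <- c(ii, ks, kd, s[ks], d[kd], pmax(s[kb], d[kb]))
  tj <- c(ii, s[ks], d[kd], s[ks], d[kd], pmin(s[kb], d[kb]))
  tx <- c(b, -b[ks] / 2, -b[kd] / 2, b[ks] / 4, b[kd] / 4,
          ifelse(s[kb] == d[kb], b[kb] / 2, b[kb] / 4))
  Ainv <- sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  Ainv <- forceSymmetric(Ainv, uplo = "L")
  dimnames(Ainv) <- list(ped@id, ped@id)
  Ainv
}
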