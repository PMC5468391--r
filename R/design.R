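#' Model specification for a single-trait animal model
#'
#' Describes the response, its transformation, the environment filter and
#' the effect structure of the harvest-trait mixed model: fixed generation,
#' sex and generation-by-sex effects, a linear age-at-harvest covariate
#' nested within sex-by-generation subclass, a global stocking-weight
#' covariate, and random animal-additive plus common full-sib family terms.
#'
#' @param trait response column name (e.g. `"weight"`).
#' @param environment `"pond"`, `"cage"`, or `NULL` (no filter).
#' @param transform `"identity"` or `"sqrt"`; `"sqrt"` is intended for
#'   harvest weight only (variance-stabilising transform of body weight).
#' @param age_covariate fit age-at-harvest slopes within sex-by-generation
#'   subclass.
#' @param stock_covariate fit a single stocking-weight slope.
#' @param animal include the random animal additive-genetic term (uses the
#'   sparse A-inverse).
#' @param family include the random common full-sib family term.
#' @param sire replace the animal term by a random sire term (used by the
#'   logit survival model); mutually exclusive with `animal`.
#' @return an object of class `ModelSpec` (a list).
#' @export
modelSpec <- function(trait, environment = NULL,
                      transform = c("identity", "sqrt"),
                      age_covariate = TRUE, stock_covariate = TRUE,
                      animal = TRUE, family = TRUE, sire = FALSE) {
  transform <- match.arg(transform)
  if (transform == "sqrt" && trait != "weight") {
    stop("sqrt transform is reserved for harvest weight")
  }
  if (sire && animal) {
    stop("animal and sire random terms are mutually exclusive")
  }
  structure(list(trait = trait, environment = environment,
                 transform = transform,
                 age_covariate = age_covariate,
                 stock_covariate = stock_covariate,
                 animal = animal, family = family, sire = sire),
            class = "ModelSpec")
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("ModelSpec: %s%s%s\n", x$trait,
              if (x$transform == "sqrt") " (sqrt)" else "",
              if (!is.null(x$environment)) paste0(" in ", x$environment) else ""))
  cat("  fixed: generation * sex",
      if (x$age_covariate) "+ age | sex:generation" else "",
      if (x$stock_covariate) "+ stocking weight" else "", "\n")
  cat("  random:", paste(c(if (x$animal) "animal (A)",
                           if (x$sire) "sire",
                           if (x$family) "family"), collapse = " + "), "\n")
  invisible(x)
}

## Fixed-effect matrix: intercept, generation, sex, generation:sex,
## centred age slopes per sex-by-generation subclass, centred stocking
## weight. Reference-level (corner-point) coding; aliased columns are
## dropped by pivoted QR so X is always full column rank.
buildFixedMatrix <- function(dd, spec) {
  n <- nrow(dd)
  gen <- droplevels(factor(dd$generation))
  sex <- droplevels(factor(dd$sex))
  parts <- list(`(Intercept)` = matrix(1, n, 1,
                                       dimnames = list(NULL, "(Intercept)")))
  add <- function(f, nm) {
    m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(m) <- paste0(nm, levels(f)[-1])
    m
  }
  if (nlevels(gen) > 1) parts$gen <- add(gen, "gen")
  if (nlevels(sex) > 1) parts$sex <- add(sex, "sex")
  if (nlevels(gen) > 1 && nlevels(sex) > 1) {
    ## full interaction dummies; columns aliased with the main effects are
    ## removed by the QR step below, leaving corner-point interaction terms
    gs <- droplevels(interaction(gen, sex, drop = TRUE))
    ia <- stats::model.matrix(~ gs)[, -1, drop = FALSE]
    colnames(ia) <- paste0("gen.sex", levels(gs)[-1])
    parts$gensex <- ia
  }
  if (isTRUE(spec$age_covariate) && "age_days" %in% names(dd) &&
      !all(is.na(dd$age_days))) {
    sg <- droplevels(interaction(sex, gen, drop = TRUE))
    age <- dd$age_days
    age_c <- age - stats::ave(age, sg, FUN = function(z) mean(z, na.rm = TRUE))
    age_c[is.na(age_c)] <- 0
    m <- sapply(levels(sg), function(l) age_c * (sg == l))
    m <- matrix(m, nrow = n)
    colnames(m) <- paste0("age.", levels(sg))
    parts$age <- m
  } else if (isTRUE(spec$age_covariate)) {
    stop("age covariate requested but 'age_days' entirely missing")
  }
  if (isTRUE(spec$stock_covariate)) {
    if (!"stock_weight" %in% names(dd) || all(is.na(dd$stock_weight))) {
      stop("stocking-weight covariate requested but entirely missing")
    }
    sw <- dd$stock_weight - mean(dd$stock_weight, na.rm = TRUE)
    sw[is.na(sw)] <- 0
    parts$stock <- matrix(sw, n, 1, dimnames = list(NULL, "stock_weight"))
  }
  X <- do.call(cbind, parts)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

#' Build design matrices for the animal model
#'
#' Constructs the response vector and the fixed/random design of the
#' harvest-trait mixed model `y = Xb + Za + Wc + e`: `X` is the full-rank
#' fixed-effect matrix (reference-level coding; aliased columns dropped and
#' reported), `Z` maps records to *all* pedigree animals (non-phenotyped
#' ancestors get zero columns, so their breeding values are still
#' predicted), and `W` maps records to full-sib family groups. Records with
#' a missing response are dropped for this trait only.
#'
#' @param data phenotype `data.frame`.
#' @param spec a [modelSpec()].
#' @param ped the [Pedigree-class] the records belong to.
#' @return list with `y`, `X`, `Z`, `W`, `data` (rows used), `animal_ids`,
#'   `family_ids`, `dropped` (aliased fixed columns).
#' @export
buildDesign <- function(data, spec, ped) {
  dd <- data
  if (!is.null(spec$environment)) {
    dd <- dd[dd$environment == spec$environment, , drop = FALSE]
    if (!nrow(dd)) stop("no records in environment ", spec$environment)
  }
  if (!spec$trait %in% names(dd)) stop("trait column missing: ", spec$trait)
  dd <- dd[!is.na(dd[[spec$trait]]), , drop = FALSE]
  y <- dd[[spec$trait]]
  if (spec$transform == "sqrt") {
    if (any(y < 0)) stop("negative values under sqrt transform")
    y <- sqrt(y)
  }
  X <- buildFixedMatrix(dd, spec)
  n <- nrow(dd)
  aidx <- match(dd$animal, pedIds(ped))
  if (anyNA(aidx)) {
    stop(sprintf("animal '%s' not in pedigree", dd$animal[which(is.na(aidx))[1L]]))
  }
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                            dims = c(n, nAnimals(ped)),
                            dimnames = list(NULL, pedIds(ped)))
  fam <- factor(dd$family)
  W <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(fam), x = 1,
                            dims = c(n, nlevels(fam)),
                            dimnames = list(NULL, levels(fam)))
  list(y = y, X = X, Z = Z, W = W, data = dd,
       animal_ids = pedIds(ped), family_ids = levels(fam),
       dropped = attr(X, "dropped"))
}
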