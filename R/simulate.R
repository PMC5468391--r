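## Defaults describing the selection program being emulated: a closed
## nucleus founded from 79 sires x 79 dams, three selection generations,
## nested 1 male x 2 female matings with imperfect success, 100-150 tagged
## offspring per full-sib family reared separately before tagging (hence a
## common full-sib effect), sib testing split between a pond (selection
## environment) and a cage (production environment), and EBV selection on
## pond harvest weight capped at 2 males / 4 females per family.

defaultComponents <- function() {
  list(
    pond = list(weight = c(1727.3, 3920.6, 2122.4),
                length = c(1.54, 2.87, 7.86),
                width = c(0.026, 0.20, 0.34),
                depth = c(0.37, 0.83, 0.69),
                survival = c(0.075, 0.61, pi^2 / 3)),
    cage = list(weight = c(563.9, 1141.7, 5312.4),
                length = c(0.29, 1.40, 2.77),
                width = c(0.095, 0.037, 0.12),
                depth = c(0.52, 0.19, 0.72),
                survival = c(2.40, 1.70, pi^2 / 3))
  )
}

defaultGeneticCor <- function() {
  tr <- c("weight", "length", "width", "depth", "survival")
  pond <- diag(5); cage <- diag(5)
  dimnames(pond) <- dimnames(cage) <- list(tr, tr)
  fill <- function(M, vals) {
    M[lower.tri(M)] <- vals
    M[upper.tri(M)] <- t(M)[upper.tri(M)]
    M
  }
  ## columns fill lower triangle by column: (w-l, w-wd, w-d, w-s, l-wd, l-d,
  ## l-s, wd-d, wd-s, d-s)
  pond <- fill(pond, c(0.99, 0.90, 0.96, 0.54, 0.94, 0.99, 0.21, 0.98,
                       -0.23, 0.16))
  cage <- fill(cage, c(0.92, 0.99, 0.97, -0.73, 0.95, 0.97, 0.75, 0.99,
                       0.04, 0.15))
  list(pond = pond, cage = cage)
}

defaultCrossEnvCor <- function() {
  c(weight = 0.90, length = 0.63, width = 0.79, depth = 0.62,
    survival = 0.70)
}

defaultTraitMeans <- function() {
  list(pond = c(weight = 245.7, length = 18.3, width = 7.7, depth = 3.4),
       cage = c(weight = 251.4, length = 17.6, width = 7.9, depth = 3.2))
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping: negative eigenvalues are floored at `eps`, the
#' matrix is reassembled and rescaled to unit diagonal. The Frobenius
#' distance moved is attached as attribute `"distance"` so projections are
#' visible rather than silent.
#'
#' @param R symmetric correlation-like matrix.
#' @param eps eigenvalue floor.
#' @return PSD correlation matrix with attribute `distance`.
#' @export
nearestPSD <- function(R, eps = 1e-6) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) {
    attr(R, "distance") <- 0
    return(R)
  }
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  R2 <- (R2 + t(R2)) / 2
  attr(R2, "distance") <- sqrt(sum((R2 - R)^2))
  R2
}

#' Configuration of the breeding-program simulator
#'
#' All defaults emulate the study conditions of the selection program the
#' package analyses; see the package vignette for the rationale behind
#' values the design leaves open (family-effect and residual correlations,
#' covariate distributions, fixed-effect magnitudes).
#'
#' @param traits body traits to simulate (subset of weight, length, width,
#'   depth). Survival is always simulated: as a correlated liability when
#'   `survival_liability = TRUE`, else as independent Bernoulli thinning.
#' @param n_founder_sires,n_founder_dams founder parents.
#' @param founder_mating `"paired"` mates founders 1:1; `"nested"` applies
#'   the program's one-male-two-female design already in the base cohort
#'   (requires twice as many dams as sires), which creates base-generation
#'   paternal half-sib families and strengthens the separation of additive
#'   from common-environment variance.
#' @param generations number of selection generations after the base.
#' @param offspring_per_family integer range, tagged offspring per family.
#' @param prop_pond fraction of each family's tagged sibs tested in pond.
#' @param base_pond_only if `TRUE` the base cohort is tested in pond only
#'   (cage testing starts with the first selection generation, as in the
#'   program emulated).
#' @param components per-environment, per-trait numeric `c(s2a, s2c, s2e)`
#'   true variance components.
#' @param genetic_cor among-trait additive correlation matrix per
#'   environment.
#' @param cross_env_cor additive correlation between pond and cage
#'   expression per trait.
#' @param family_cor_traits,family_cor_survival,family_cor_env correlation
#'   of family effects among body traits, body-survival, and across
#'   environments.
#' @param resid_cor_traits residual correlation among body traits within an
#'   animal.
#' @param survival_rate survivor proportion per environment.
#' @param survival_liability couple survival to the genetic/family
#'   structure through a liability threshold.
#' @param trait_means harvest means per environment and trait.
#' @param sex_effect_sd,gen_effect_sd,age_slope_sd_per_day,stock_slope_sd_per_g
#'   fixed-effect magnitudes in phenotypic-SD units.
#' @param age_mean,age_sd,stock_mean,stock_sd covariate distributions
#'   (days, grams).
#' @param selection `"ebv"`, `"phenotype"` or `"random"` ranking of pond
#'   survivors for parent selection.
#' @param n_sires,n_dams parents selected per generation.
#' @param max_males_per_family,max_females_per_family per-family caps on
#'   selected parents.
#' @param mating_success probability that a planned sire x dam mating
#'   produces a family.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(traits = c("weight", "length", "width", "depth"),
                             n_founder_sires = 79L, n_founder_dams = 79L,
                             founder_mating = c("paired", "nested"),
                             generations = 3L,
                             offspring_per_family = c(100L, 150L),
                             prop_pond = 0.65,
                             base_pond_only = TRUE,
                             components = defaultComponents(),
                             genetic_cor = defaultGeneticCor(),
                             cross_env_cor = defaultCrossEnvCor(),
                             family_cor_traits = 0.8,
                             family_cor_survival = 0.3,
                             family_cor_env = 0.9,
                             resid_cor_traits = 0.5,
                             survival_rate = c(pond = 0.55, cage = 0.438),
                             survival_liability = TRUE,
                             trait_means = defaultTraitMeans(),
                             sex_effect_sd = 0.5,
                             gen_effect_sd = 0.25,
                             age_slope_sd_per_day = 0.02,
                             stock_slope_sd_per_g = 0.1,
                             age_mean = 120, age_sd = 10,
                             stock_mean = 7.5, stock_sd = 1.5,
                             selection = c("ebv", "phenotype", "random"),
                             n_sires = 50L, n_dams = 100L,
                             max_males_per_family = 2L,
                             max_females_per_family = 4L,
                             mating_success = 0.85) {
  selection <- match.arg(selection)
  founder_mating <- match.arg(founder_mating)
  traits <- match.arg(traits, c("weight", "length", "width", "depth"),
                      several.ok = TRUE)
  if (founder_mating == "nested" && n_founder_dams < 2L * n_founder_sires) {
    stop("nested founder mating needs n_founder_dams >= 2 * n_founder_sires")
  }
  stopifnot(all(survival_rate > 0), all(survival_rate < 1),
            max_males_per_family >= 1L, max_females_per_family >= 1L,
            length(offspring_per_family) == 2L,
            prop_pond > 0, prop_pond < 1)
  structure(list(traits = traits,
                 n_founder_sires = as.integer(n_founder_sires),
                 n_founder_dams = as.integer(n_founder_dams),
                 founder_mating = founder_mating,
                 generations = as.integer(generations),
                 offspring_per_family = as.integer(offspring_per_family),
                 prop_pond = prop_pond, base_pond_only = base_pond_only,
                 components = components, genetic_cor = genetic_cor,
                 cross_env_cor = cross_env_cor,
                 family_cor_traits = family_cor_traits,
                 family_cor_survival = family_cor_survival,
                 family_cor_env = family_cor_env,
                 resid_cor_traits = resid_cor_traits,
                 survival_rate = survival_rate,
                 survival_liability = survival_liability,
                 trait_means = trait_means,
                 sex_effect_sd = sex_effect_sd, gen_effect_sd = gen_effect_sd,
                 age_slope_sd_per_day = age_slope_sd_per_day,
                 stock_slope_sd_per_g = stock_slope_sd_per_g,
                 age_mean = age_mean, age_sd = age_sd,
                 stock_mean = stock_mean, stock_sd = stock_sd,
                 selection = selection,
                 n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 max_males_per_family = as.integer(max_males_per_family),
                 max_females_per_family = as.integer(max_females_per_family),
                 mating_success = mating_success),
            class = "SimulationConfig")
}

## expression labels: trait x environment, trait-major within environment
exprLabels <- function(cfg) {
  tr <- c(cfg$traits, if (cfg$survival_liability) "survival")
  as.vector(outer(tr, c("pond", "cage"), paste, sep = "."))
}

## Sigma builders on the trait x environment expression vector
exprCovariances <- function(cfg) {
  tr <- c(cfg$traits, if (cfg$survival_liability) "survival")
  k <- length(tr); d <- 2L * k
  lab <- exprLabels(cfg)
  idx <- function(t, e) match(paste(t, e, sep = "."), lab)
  sd_of <- function(which) {
    s <- numeric(d)
    for (e in c("pond", "cage")) for (t in tr) {
      s[idx(t, e)] <- sqrt(cfg$components[[e]][[t]][which])
    }
    s
  }
  ## additive correlation
  Ra <- diag(d)
  for (e in c("pond", "cage")) {
    G <- cfg$genetic_cor[[e]][tr, tr, drop = FALSE]
    ii <- sapply(tr, idx, e = e)
    Ra[ii, ii] <- G
  }
  for (t1 in tr) for (t2 in tr) {
    r_within <- 0.5 * (cfg$genetic_cor$pond[t1, t2] +
                       cfg$genetic_cor$cage[t1, t2])
    rx <- 0.5 * (cfg$cross_env_cor[[t1]] + cfg$cross_env_cor[[t2]])
    val <- if (t1 == t2) cfg$cross_env_cor[[t1]] else r_within * rx
    Ra[idx(t1, "pond"), idx(t2, "cage")] <- val
    Ra[idx(t2, "cage"), idx(t1, "pond")] <- val
  }
  Ra <- nearestPSD(Ra)
  ## family-effect correlation
  fcor <- function(t1, t2) {
    if (t1 == t2) 1
    else if (t1 == "survival" || t2 == "survival") cfg$family_cor_survival
    else cfg$family_cor_traits
  }
  Rc <- diag(d)
  for (e1 in c("pond", "cage")) for (e2 in c("pond", "cage")) {
    for (t1 in tr) for (t2 in tr) {
      v <- fcor(t1, t2) * (if (e1 == e2) 1 else cfg$family_cor_env)
      i <- idx(t1, e1); j <- idx(t2, e2)
      if (i != j) Rc[i, j] <- v
    }
  }
  Rc <- nearestPSD(Rc)
  ## residual correlation: within-animal only (one environment per animal)
  ecor <- function(t1, t2) {
    if (t1 == t2) 1
    else if (t1 == "survival" || t2 == "survival") 0
    else cfg$resid_cor_traits
  }
  Re <- diag(d)
  for (e in c("pond", "cage")) for (t1 in tr) for (t2 in tr) {
    i <- idx(t1, e); j <- idx(t2, e)
    if (i != j) Re[i, j] <- ecor(t1, t2)
  }
  Re <- nearestPSD(Re)
  mk <- function(R, s) {
    S <- outer(s, s) * R
    dimnames(S) <- list(lab, lab)
    attr(S, "distance") <- attr(R, "distance")
    S
  }
  list(Sa = mk(Ra, sd_of(1L)), Sc = mk(Rc, sd_of(2L)),
       Se = mk(Re, sd_of(3L)), labels = lab, traits = tr)
}

#' Implied true parameters of a simulation configuration
#'
#' Heritability, common full-sib fraction and cross-environment genetic
#' correlation implied by the configured components — the targets that
#' parameter-recovery runs should reproduce. Correlations are reported
#' *after* the positive-semi-definite projection of the configured
#' correlation matrices, i.e. exactly what the generator uses.
#'
#' @param cfg a [simulationConfig()].
#' @return nested list per environment and trait (`h2`, `c2`) plus `r_g`
#'   per trait and the PSD projection distances.
#' @export
truthReport <- function(cfg) {
  S <- exprCovariances(cfg)
  tr <- S$traits
  out <- list()
  for (e in c("pond", "cage")) {
    out[[e]] <- lapply(stats::setNames(tr, tr), function(t) {
      v <- cfg$components[[e]][[t]]
      list(s2a = v[1L], s2c = v[2L], s2e = v[3L],
           h2 = v[1L] / sum(v), c2 = v[2L] / sum(v))
    })
  }
  rg <- sapply(tr, function(t) {
    i <- match(paste0(t, ".pond"), S$labels)
    j <- match(paste0(t, ".cage"), S$labels)
    S$Sa[i, j] / sqrt(S$Sa[i, i] * S$Sa[j, j])
  })
  out$r_g <- rg
  out$psd_projection_distance <- c(additive = attr(S$Sa, "distance"),
                                   family = attr(S$Sc, "distance"),
                                   residual = attr(S$Se, "distance"))
  out
}

## pairwise additive relationship with memoisation (used only for mate
## pairs and parental inbreeding during simulation)
makeKinship <- function() {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rel <- function(i, j, sire, dam) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      1 + 0.5 * rel(sire[i], dam[i], sire, dam)
    } else {
      ## j is the younger (higher index): recurse through its parents
      0.5 * (rel(sire[j], i, sire, dam) + rel(dam[j], i, sire, dam))
    }
    memo[[key]] <- val
    val
  }
  rel
}

#' Simulate the breeding program
#'
#' Generates a pedigree and phenotype table with the statistical structure
#' of the emulated selection program: founder additive values are drawn
#' from the trait-by-environment additive covariance, offspring receive
#' mid-parent values plus inbreeding-adjusted Mendelian sampling
#' `N(0, 0.5 (1 - mean(F_parents)) Sigma_a)`, one family deviate per
#' full-sib group, an individual residual, fixed generation/sex/age/
#' stocking-weight effects, survival through a liability threshold at the
#' configured incidence, per-family pond/cage allocation, and parent
#' selection on pond EBVs (true-variance BLUP), phenotype or at random
#' under per-family caps, with nested one-sire-two-dam matings that avoid
#' full-sib pairs and fail at random with the configured rate.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return list with `pedigree` ([Pedigree-class]), `phenotypes`
#'   (`data.frame` in the layout of [readPhenotypes()]), and `truth`
#'   ([truthReport()] plus realized summaries).
#' @export
simulateBreedingProgram <- function(cfg = simulationConfig(), seed = 1L) {
  set.seed(as.integer(seed))
  S <- exprCovariances(cfg)
  d <- length(S$labels)
  La <- t(chol(S$Sa + diag(1e-10 * max(diag(S$Sa)), d)))
  Lc <- t(chol(S$Sc + diag(1e-10 * max(diag(S$Sc)), d)))
  Le <- t(chol(S$Se + diag(1e-10 * max(diag(S$Se)), d)))
  body_traits <- cfg$traits
  has_sv <- cfg$survival_liability
  base_year <- 2009L

  nfs <- cfg$n_founder_sires; nfd <- cfg$n_founder_dams
  nF0 <- nfs + nfd
  id <- paste0("FND", seq_len(nF0))
  sire <- rep(NA_integer_, nF0); dam <- rep(NA_integer_, nF0)
  sex <- c(rep("male", nfs), rep("female", nfd))
  gen <- rep(base_year - 1L, nF0)
  fam <- rep(NA_character_, nF0)
  avals <- La %*% matrix(stats::rnorm(d * nF0), d)  # d x n additive values
  Fcoef <- numeric(nF0)
  rel <- makeKinship()

  pheno <- list()
  counter <- nF0
  ## base-cohort matings: 1:1 founder pairs, or nested 1 male x 2 females
  matings <- if (identical(cfg$founder_mating, "nested")) {
    data.frame(sire = rep(seq_len(nfs), each = 2L),
               dam = nfs + seq_len(2L * nfs))
  } else {
    data.frame(sire = seq_len(nfs),
               dam = nfs + seq_len(min(nfd, nfs)))
  }

  all_traits <- c("weight", "length", "width", "depth")
  for (g in 0:cfg$generations) {
    year <- base_year + g
    fam_tags <- paste0("FAM", year, "_", seq_len(nrow(matings)))
    acc <- list()  # per-family accumulators for this generation
    for (m in seq_len(nrow(matings))) {
      si <- matings$sire[m]; di <- matings$dam[m]
      noff <- sample(seq(cfg$offspring_per_family[1L],
                         cfg$offspring_per_family[2L]), 1L)
      Fbar <- 0.5 * (Fcoef[si] + Fcoef[di])
      msd <- sqrt(pmax(0.5 * (1 - Fbar), 1e-12))
      mid <- 0.5 * (avals[, si] + avals[, di])
      a_off <- mid + msd * (La %*% matrix(stats::rnorm(d * noff), d))
      c_fam <- as.numeric(Lc %*% stats::rnorm(d))
      e_off <- Le %*% matrix(stats::rnorm(d * noff), d)
      Foff <- 0.5 * rel(si, di, sire, dam)
      offsex <- sample(c("male", "female"), noff, replace = TRUE)
      if (g == 0L && cfg$base_pond_only) {
        env <- rep("pond", noff)
      } else {
        npond <- round(noff * cfg$prop_pond)
        env <- sample(c(rep("pond", npond), rep("cage", noff - npond)))
      }
      ids <- paste0("A", year, "_", counter + seq_len(noff))
      counter <- counter + noff
      age <- stats::rnorm(noff, cfg$age_mean, cfg$age_sd)
      stw <- stats::rnorm(noff, cfg$stock_mean, cfg$stock_sd)
      jrow <- function(t) match(paste(t, env, sep = "."), S$labels)
      pickrow <- function(Mt, j) Mt[cbind(j, seq_len(noff))]
      if (has_sv) {
        jsv <- jrow("survival")
        liab <- pickrow(a_off, jsv) + c_fam[jsv] + pickrow(e_off, jsv)
        vtot <- sapply(env, function(e) sum(cfg$components[[e]][["survival"]]))
        thr <- stats::qnorm(1 - cfg$survival_rate[env], sd = sqrt(vtot))
        surv <- as.integer(liab > thr)
      } else {
        surv <- stats::rbinom(noff, 1L, cfg$survival_rate[env])
      }
      vals <- lapply(stats::setNames(all_traits, all_traits), function(t) {
        if (!t %in% body_traits) return(rep(NA_real_, noff))
        j <- jrow(t)
        sdp <- sqrt(sapply(env, function(e) sum(cfg$components[[e]][[t]])))
        mu <- sapply(env, function(e) cfg$trait_means[[e]][[t]]) +
          cfg$gen_effect_sd * g * sdp +
          ifelse(offsex == "male", cfg$sex_effect_sd * sdp, 0) +
          cfg$age_slope_sd_per_day * (age - cfg$age_mean) * sdp +
          cfg$stock_slope_sd_per_g * (stw - cfg$stock_mean) * sdp
        out <- mu + pickrow(a_off, j) + c_fam[j] + pickrow(e_off, j)
        out[surv == 0L] <- NA_real_
        out
      })
      acc[[m]] <- list(
        ids = ids, sire = rep(si, noff), dam = rep(di, noff),
        sex = offsex, fam = rep(fam_tags[m], noff),
        Fv = rep(Foff, noff), a = a_off,
        df = data.frame(animal = ids, environment = env,
                        weight = vals$weight, length = vals$length,
                        width = vals$width, depth = vals$depth,
                        survival = surv, age_days = age, stock_weight = stw,
                        sex = offsex, generation = year,
                        family = fam_tags[m], stringsAsFactors = FALSE))
    }
    id <- c(id, unlist(lapply(acc, `[[`, "ids")))
    sire <- c(sire, unlist(lapply(acc, `[[`, "sire")))
    dam <- c(dam, unlist(lapply(acc, `[[`, "dam")))
    sex <- c(sex, unlist(lapply(acc, `[[`, "sex")))
    fam <- c(fam, unlist(lapply(acc, `[[`, "fam")))
    Fcoef <- c(Fcoef, unlist(lapply(acc, `[[`, "Fv")))
    gen <- c(gen, rep(year, sum(sapply(acc, function(x) length(x$ids)))))
    avals <- cbind(avals, do.call(cbind, lapply(acc, `[[`, "a")))
    pheno[[length(pheno) + 1L]] <- do.call(rbind, lapply(acc, `[[`, "df"))

    if (g == cfg$generations) break
    matings <- selectAndMate(cfg, id, sire, dam, gen, sex, fam,
                             do.call(rbind, pheno), year, rel)
  }

  phen <- do.call(rbind, pheno)
  rownames(phen) <- NULL
  ped <- asPedigree(id,
                    ifelse(is.na(sire), "0", id[ifelse(is.na(sire), 1L, sire)]),
                    ifelse(is.na(dam), "0", id[ifelse(is.na(dam), 1L, dam)]),
                    generation = gen, sex = sex, family = fam)
  truth <- truthReport(cfg)
  truth$realized <- list(
    n_animals = length(id),
    n_records = nrow(phen),
    survival = tapply(phen$survival, phen$environment, mean),
    mean_F = mean(Fcoef)
  )
  ## true additive values for validation studies
  tbv <- t(avals)
  rownames(tbv) <- id
  colnames(tbv) <- S$labels
  list(pedigree = ped, phenotypes = phen, truth = truth,
       true_breeding_values = tbv[pedIds(ped), , drop = FALSE],
       config = cfg, seed = as.integer(seed))
}

## rank pond-tested survivors of the current cohort and pick parents under
## per-family caps, then pair each sire with two non-full-sib dams
selectAndMate <- function(cfg, id, sire, dam, gen, sex, fam, phen, year, rel) {
  cand_rows <- phen$generation == year & phen$environment == "pond" &
    phen$survival == 1L
  cand <- phen$animal[cand_rows]
  if (!length(cand)) stop("no pond survivors available for selection")
  nfam <- length(unique(phen$family[cand_rows]))
  need_m <- cfg$n_sires; need_f <- cfg$n_dams
  cap_m <- nfam * cfg$max_males_per_family
  cap_f <- nfam * cfg$max_females_per_family
  if (need_m > cap_m || need_f > cap_f) {
    stop(sprintf(paste0("infeasible selection: need %d males / %d females ",
                        "but caps allow at most %d x %d = %d males and ",
                        "%d x %d = %d females"),
                 need_m, need_f, nfam, cfg$max_males_per_family, cap_m,
                 nfam, cfg$max_females_per_family, cap_f))
  }
  score <- switch(cfg$selection,
    random = stats::setNames(stats::runif(length(cand)), cand),
    phenotype = stats::setNames(phen$weight[cand_rows], cand),
    ebv = {
      ## BLUP of pond weight at the generating components (routine genetic
      ## evaluation as run by the program each season)
      ped_now <- asPedigree(id,
        ifelse(is.na(sire), "0", id[ifelse(is.na(sire), 1L, sire)]),
        ifelse(is.na(dam), "0", id[ifelse(is.na(dam), 1L, dam)]),
        generation = gen, sex = sex, family = fam)
      dsg <- buildDesign(phen[phen$environment == "pond" &
                                !is.na(phen$weight), , drop = FALSE],
                         modelSpec("weight", environment = "pond"), ped_now)
      vc <- cfg$components$pond$weight
      sys <- assembleMME(dsg$y, dsg$X, dsg$Z, dsg$W, aInverse(ped_now),
                         s2a = vc[1L], s2c = vc[2L], s2e = vc[3L])
      sol <- solveMME(sys)
      sol$a[cand]
    })
  ord <- cand[order(score[cand], decreasing = TRUE)]
  fam_of <- stats::setNames(phen$family[cand_rows], cand)
  sex_of <- stats::setNames(phen$sex[cand_rows], cand)
  pick <- function(want_sex, need, cap) {
    taken <- character(0)
    used <- integer(0)
    for (aid in ord) {
      if (length(taken) >= need) break
      if (sex_of[[aid]] != want_sex) next
      fm <- fam_of[[aid]]
      cnt <- if (fm %in% names(used)) used[[fm]] else 0L
      if (cnt >= cap) next
      taken <- c(taken, aid)
      used[fm] <- cnt + 1L
    }
    if (length(taken) < need) {
      stop(sprintf("only %d %ss selectable under caps (need %d)",
                   length(taken), want_sex, need))
    }
    taken
  }
  sel_m <- pick("male", need_m, cfg$max_males_per_family)
  sel_f <- pick("female", need_f, cfg$max_females_per_family)
  ## nested 1 male x 2 females, avoiding full-sib mates; imperfect success
  pos <- stats::setNames(seq_along(id), id)
  dams_pool <- sample(sel_f)
  out_s <- integer(0); out_d <- integer(0)
  for (sm in sel_m) {
    got <- 0L
    keep <- rep(TRUE, length(dams_pool))
    for (k in seq_along(dams_pool)) {
      if (got >= 2L) break
      df_ <- dams_pool[k]
      if (!is.na(fam_of[[sm]]) && identical(fam_of[[sm]], fam_of[[df_]])) next
      keep[k] <- FALSE
      got <- got + 1L
      if (stats::runif(1L) <= cfg$mating_success) {
        out_s <- c(out_s, pos[[sm]])
        out_d <- c(out_d, pos[[df_]])
      }
    }
    dams_pool <- dams_pool[keep]
  }
  if (!length(out_s)) stop("no successful matings")
  data.frame(sire = out_s, dam = out_d)
}
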