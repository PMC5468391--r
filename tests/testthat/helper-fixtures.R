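# Shared fixtures, generated in code.

# founder trio: sire, dam, offspring
trioPedigree <- function() {
  asPedigree(c("o1", "s1", "d1"), c("s1", "0", "0"), c("d1", "0", "0"),
             generation = c(1, 0, 0))
}

# random multi-generation pedigree with known structure
randomPedigree <- function(n_founders = 40, n_gen = 4, per_gen = 40,
                           seed = 1) {
  set.seed(seed)
  n <- n_founders + n_gen * per_gen
  id <- paste0("a", seq_len(n))
  sire <- dam <- rep("0", n)
  gen <- c(rep(0L, n_founders), rep(seq_len(n_gen), each = per_gen))
  for (i in seq(n_founders + 1L, n)) {
    prev <- which(gen == gen[i] - 1L)
    sire[i] <- id[sample(prev, 1)]
    dam[i] <- id[sample(prev, 1)]
    while (dam[i] == sire[i]) dam[i] <- id[sample(prev, 1)]
  }
  asPedigree(id, sire, dam, generation = gen)
}

# balanced hierarchical design: n_sires sires x dams_per_sire dams x n_off
# offspring, with simulated additive + family + residual phenotypes
simHierarchical <- function(n_sires = 50, dams_per_sire = 2, n_off = 10,
                            s2a = 2, s2c = 1.5, s2e = 4, seed = 1,
                            two_sexes = TRUE) {
  set.seed(seed)
  sid <- paste0("S", seq_len(n_sires))
  ndam <- n_sires * dams_per_sire
  did <- paste0("D", seq_len(ndam))
  k <- 0L
  anim <- sire <- dam <- fam <- character(0)
  for (i in seq_len(n_sires)) for (j in seq_len(dams_per_sire)) {
    k <- k + 1L
    ids <- paste0("O", k, "_", seq_len(n_off))
    anim <- c(anim, ids)
    sire <- c(sire, rep(sid[i], n_off))
    dam <- c(dam, rep(did[k], n_off))
    fam <- c(fam, rep(paste0("F", k), n_off))
  }
  nf <- n_sires + ndam
  ped <- asPedigree(c(sid, did, anim),
                    c(rep("0", nf), sire), c(rep("0", nf), dam),
                    generation = c(rep(0L, nf), rep(1L, length(anim))),
                    sex = c(rep("male", n_sires), rep("female", ndam),
                            sample(c("female", "male"), length(anim), TRUE)),
                    family = c(rep(NA, nf), fam))
  # additive values by pedigree recursion
  n <- nAnimals(ped)
  a <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    a[i] <- if (is.na(s)) rnorm(1, 0, sqrt(s2a))
            else 0.5 * (a[s] + a[d]) + rnorm(1, 0, sqrt(0.5 * s2a))
  }
  names(a) <- pedIds(ped)
  cf <- rnorm(k, 0, sqrt(s2c))
  names(cf) <- paste0("F", seq_len(k))
  idx <- match(anim, pedIds(ped))
  df <- data.frame(
    animal = anim, environment = "pond",
    weight = 100 + a[idx] + cf[fam] + rnorm(length(anim), 0, sqrt(s2e)),
    length = NA_real_, width = NA_real_, depth = NA_real_,
    survival = 1L,
    age_days = rnorm(length(anim), 120, 10),
    stock_weight = rnorm(length(anim), 7.5, 1.5),
    sex = ped@sex[idx], generation = 1L, family = fam,
    stringsAsFactors = FALSE)
  list(ped = ped, data = df, a = a, fam_effects = cf)
}

# small simulated program reused by several test files (cached per session)
smallProgram <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(
        n_founder_sires = 25, n_founder_dams = 25, generations = 2,
        offspring_per_family = c(14L, 20L), base_pond_only = FALSE,
        n_sires = 16, n_dams = 32, selection = "phenotype")
      cache <<- simulateBreedingProgram(cfg, seed = 42)
    }
    cache
  }
})
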