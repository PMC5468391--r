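tinyConfig <- function(n_sires = 6L, n_dams = 12L, selection = "phenotype",
                       ...) {
  simulationConfig(n_founder_sires = 12, n_founder_dams = 12,
                   generations = 1, offspring_per_family = c(12L, 16L),
                   base_pond_only = FALSE, n_sires = n_sires,
                   n_dams = n_dams, selection = selection, ...)
}

test_that("the same seed reproduces the program exactly", {
  s1 <- simulateBreedingProgram(tinyConfig(), seed = 9)
  s2 <- simulateBreedingProgram(tinyConfig(), seed = 9)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(pedIds(s1$pedigree), pedIds(s2$pedigree))
  expect_identical(s1$true_breeding_values, s2$true_breeding_values)
  s3 <- simulateBreedingProgram(tinyConfig(), seed = 10)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})

test_that("founder additive values match the configured covariance", {
  cfg <- simulationConfig(traits = "weight", survival_liability = FALSE,
                          n_founder_sires = 120, n_founder_dams = 120,
                          generations = 0,
                          offspring_per_family = c(2L, 3L),
                          base_pond_only = FALSE)
  vs <- sapply(1:3, function(s) {
    sim <- simulateBreedingProgram(cfg, seed = 300 + s)
    founders <- pedIds(sim$pedigree)[is.na(sim$pedigree@sire)]
    tbv <- sim$true_breeding_values[founders, ]
    c(var(tbv[, "weight.pond"]), var(tbv[, "weight.cage"]),
      cor(tbv[, "weight.pond"], tbv[, "weight.cage"]))
  })
  m <- rowMeans(vs)
  expect_equal(m[1], 1727.3, tolerance = 0.15)
  expect_equal(m[2], 563.9, tolerance = 0.15)
  expect_equal(m[3], 0.90, tolerance = 0.06)
})

test_that("no additive variance means no parent-offspring resemblance", {
  comps <- simulationConfig()$components
  for (e in names(comps)) comps[[e]][["weight"]] <- c(1e-8, 1000, 3000)
  cfg <- simulationConfig(traits = "weight", survival_liability = FALSE,
                          components = comps,
                          n_founder_sires = 40, n_founder_dams = 40,
                          generations = 1,
                          offspring_per_family = c(10L, 12L),
                          base_pond_only = FALSE, n_sires = 25,
                          n_dams = 50, selection = "random")
  ## regress family-mean offspring weight on midparent weight: with no
  ## additive variance the expected slope is zero
  slopes <- sapply(1:3, function(s) {
    sim <- simulateBreedingProgram(cfg, seed = 400 + s)
    ped <- sim$pedigree
    ph <- sim$phenotypes
    w <- stats::setNames(ph$weight, ph$animal)
    idx <- which(!is.na(ped@sire))
    kid <- pedIds(ped)[idx]
    midp <- 0.5 * (w[pedIds(ped)[ped@sire[idx]]] +
                     w[pedIds(ped)[ped@dam[idx]]])
    ok <- !is.na(w[kid]) & !is.na(midp)
    fam_kid <- tapply(w[kid][ok], midp[ok], mean)
    coef(lm(fam_kid ~ as.numeric(names(fam_kid))))[2]
  })
  expect_lt(abs(mean(slopes)), 0.2)
})

test_that("full sibs share half the additive plus the family variance", {
  sim <- smallProgram()
  ph <- sim$phenotypes
  pp <- ph[ph$environment == "pond" & !is.na(ph$weight), ]
  r <- resid(lm(weight ~ factor(generation) * sex + age_days + stock_weight,
                data = pp))
  covs <- unlist(lapply(split(r, pp$family), function(x) {
    if (length(x) < 2) return(NULL)
    m <- outer(x, x)
    mean(m[upper.tri(m)])
  }))
  expected <- 0.5 * 1727.3 + 3920.6
  expect_equal(mean(covs), expected, tolerance = 0.3)
})

test_that("realized base-cohort survival matches the configured incidence", {
  sim <- smallProgram()
  ph <- sim$phenotypes
  base <- ph[ph$generation == 2009, ]
  for (env in c("pond", "cage")) {
    x <- base$survival[base$environment == env]
    p_hat <- mean(x)
    p_true <- c(pond = 0.55, cage = 0.438)[[env]]
    expect_lt(abs(p_hat - p_true), 3.5 * sqrt(p_true * (1 - p_true) / length(x)))
  }
})

test_that("EBV selection produces a positive selection differential", {
  cfg <- tinyConfig(selection = "ebv")
  sim <- simulateBreedingProgram(cfg, seed = 21)
  ped <- sim$pedigree
  gen1 <- pedIds(ped)[ped@generation == 2010]
  parents <- unique(c(ped@sire[match(gen1, pedIds(ped))],
                      ped@dam[match(gen1, pedIds(ped))]))
  parents <- pedIds(ped)[parents]
  cohort <- pedIds(ped)[ped@generation == 2009]
  tbv <- sim$true_breeding_values[, "weight.pond"]
  expect_gt(mean(tbv[parents]), mean(tbv[cohort]))
})

test_that("infeasible family caps are rejected with the arithmetic shown", {
  cfg <- tinyConfig(n_sires = 100, n_dams = 200,
                    max_males_per_family = 1L, max_females_per_family = 1L)
  expect_error(simulateBreedingProgram(cfg, seed = 2),
               "infeasible selection")
})

test_that("truth report states the implied ratios and projections", {
  tr <- truthReport(simulationConfig())
  expect_equal(tr$pond$weight$h2, 1727.3 / 7770.3, tolerance = 1e-6)
  expect_equal(round(tr$pond$weight$h2, 3), 0.222)
  expect_equal(round(tr$pond$weight$c2, 3), 0.505)
  expect_true(all(abs(tr$r_g) <= 1))
  expect_true(all(tr$psd_projection_distance >= 0))

  ## with a weight-only configuration the correlation passes through intact
  cfg1 <- simulationConfig(traits = "weight", survival_liability = FALSE,
                           cross_env_cor = c(weight = 1))
  expect_equal(truthReport(cfg1)$r_g[["weight"]], 1, tolerance = 1e-5)
  cfg2 <- simulationConfig(traits = "weight", survival_liability = FALSE)
  expect_equal(truthReport(cfg2)$r_g[["weight"]], 0.90)
  expect_equal(truthReport(cfg2)$psd_projection_distance[["additive"]], 0)

  ## zero family variance implies c2 = 0
  comps <- simulationConfig()$components
  comps$pond$weight[2] <- 0
  tr2 <- truthReport(simulationConfig(components = comps))
  expect_equal(tr2$pond$weight$c2, 0)
})

test_that("nearest-PSD projection fixes indefinite correlation matrices", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)
  P <- nearestPSD(R)
  expect_gte(min(eigen(P, symmetric = TRUE)$values), 0)
  expect_equal(diag(P), rep(1, 3))
  expect_gt(attr(P, "distance"), 0)
  ## an already-PSD matrix is untouched
  R2 <- diag(3)
  expect_equal(attr(nearestPSD(R2), "distance"), 0)
})
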