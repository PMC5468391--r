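# Reduced-scale simulations: sizes chosen to keep the default test run
# fast while leaving the designs informative enough for the checks below.

crossEnvConfig <- function(...) {
  simulationConfig(traits = "weight", survival_liability = FALSE,
                   n_founder_sires = 30, n_founder_dams = 60,
                   founder_mating = "nested",
                   generations = 1, offspring_per_family = c(14L, 18L),
                   base_pond_only = FALSE, n_sires = 20, n_dams = 40,
                   selection = "phenotype", ...)
}

test_that("a shared genetic effect across environments is recovered as r_g near 1", {
  cfg <- crossEnvConfig(cross_env_cor = c(weight = 1))
  sim <- simulateBreedingProgram(cfg, seed = 77)
  expect_equal(sim$truth$r_g[["weight"]], 1, tolerance = 1e-5)
  fit <- remlBivariateCrossEnv(sim$phenotypes, "weight", sim$pedigree,
                               se = FALSE, tol = 1e-6)
  expect_gt(fit@theta[["ra"]], 0.8)
})

test_that("the converged genetic correlation is start-point independent", {
  cfg <- crossEnvConfig()
  sim <- simulateBreedingProgram(cfg, seed = 78)
  f1 <- remlBivariateCrossEnv(sim$phenotypes, "weight", sim$pedigree,
                              start_cor = 0.0, se = FALSE)
  f2 <- remlBivariateCrossEnv(sim$phenotypes, "weight", sim$pedigree,
                              start_cor = 0.9, se = FALSE)
  expect_lt(abs(f1@theta[["ra"]] - f2@theta[["ra"]]), 1e-3)
  expect_lt(abs(f1@logLik - f2@logLik), 1e-4)
})

test_that("cross-environment fit requires records in both environments", {
  sim <- smallProgram()
  pond_only <- sim$phenotypes[sim$phenotypes$environment == "pond", ]
  expect_error(remlBivariateCrossEnv(pond_only, "weight", sim$pedigree),
               "cage")
})

test_that("genetically independent traits give a near-zero correlation", {
  eye <- function() {
    tr <- c("weight", "length", "width", "depth", "survival")
    m <- diag(5); dimnames(m) <- list(tr, tr); m
  }
  cfg <- simulationConfig(traits = c("weight", "depth"),
                          survival_liability = FALSE,
                          genetic_cor = list(pond = eye(), cage = eye()),
                          family_cor_traits = 0, resid_cor_traits = 0,
                          n_founder_sires = 30, n_founder_dams = 30,
                          generations = 1,
                          offspring_per_family = c(14L, 18L),
                          base_pond_only = TRUE, prop_pond = 0.99,
                          n_sires = 20, n_dams = 40,
                          selection = "random")
  ## prop_pond near 1: nearly all records in pond, where the pair is fitted
  sim <- simulateBreedingProgram(cfg, seed = 79)
  fit <- remlBivariateWithinEnv(sim$phenotypes, c("weight", "depth"),
                                "pond", sim$pedigree, se = FALSE,
                                tol = 1e-6)
  co <- geneticCorrelation(fit)
  expect_lt(abs(co$genetic$estimate), 0.45)
  expect_lt(abs(co$phenotypic$estimate), 0.12)
})

test_that("correlated traits are recovered with the right sign and magnitude", {
  # pond weight-depth generated at a strong positive genetic correlation
  cfg <- simulationConfig(traits = c("weight", "depth"),
                          survival_liability = FALSE,
                          n_founder_sires = 30, n_founder_dams = 30,
                          generations = 1,
                          offspring_per_family = c(14L, 18L),
                          base_pond_only = TRUE, prop_pond = 0.99,
                          n_sires = 20, n_dams = 40,
                          selection = "random")
  sim <- simulateBreedingProgram(cfg, seed = 80)
  truth_rg <- cfg$genetic_cor$pond["weight", "depth"]  # 0.96
  fit <- remlBivariateWithinEnv(sim$phenotypes, c("weight", "depth"),
                                "pond", sim$pedigree, se = FALSE,
                                tol = 1e-6)
  co <- geneticCorrelation(fit)
  expect_gt(co$genetic$estimate, 0.6)
  expect_lt(abs(co$genetic$estimate - truth_rg), 0.35)
  expect_gt(co$phenotypic$estimate, 0.4)
})

test_that("correlation tables anchor on harvest weight with unit diagonal", {
  sim <- smallProgram()
  res <- correlationsWithinEnv(sim$phenotypes, sim$pedigree, "pond",
                               traits = c("weight", "depth"), se = FALSE,
                               tol = 1e-6)
  expect_equal(diag(res$genetic), c(weight = 1, depth = 1))
  expect_equal(res$genetic["weight", "depth"],
               res$genetic["depth", "weight"])
  expect_true(abs(res$genetic["weight", "depth"]) <= 1)
  expect_true(abs(res$phenotypic["weight", "depth"]) <= 1)
})
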