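test_that("ratio estimators reproduce hand arithmetic and obey bounds", {
  h <- heritability(c(s2a = 1727.3, s2c = 3920.6, s2e = 2122.4))
  cc <- commonFullsibEffect(c(s2a = 1727.3, s2c = 3920.6, s2e = 2122.4))
  expect_equal(h$estimate, 1727.3 / 7770.3, tolerance = 1e-12)
  expect_equal(cc$estimate, 3920.6 / 7770.3, tolerance = 1e-12)
  expect_equal(heritability(c(s2a = 0, s2c = 1, s2e = 1))$estimate, 0)
  expect_equal(commonFullsibEffect(c(s2a = 1, s2c = 0, s2e = 1))$estimate, 0)
  expect_error(heritability(c(s2a = 0, s2c = 0, s2e = 0)), "zero")
  # h2 + c2 <= 1 for any non-negative triple
  set.seed(1)
  for (i in 1:20) {
    v <- runif(3)
    expect_lte(heritability(v)$estimate + commonFullsibEffect(v)$estimate, 1)
  }
})

test_that("REML log-likelihood matches a dense GLS oracle", {
  sim <- simHierarchical(n_sires = 10, n_off = 5, seed = 7)
  d <- buildDesign(sim$data, modelSpec("weight"), sim$ped)
  Ainv <- aInverse(sim$ped)
  logdetA <- as.numeric(Matrix::determinant(
    Matrix::Matrix(relationshipMatrix(sim$ped)))$modulus)
  des <- AquaBLUP:::remlPrecompute(d$y, d$X, d$Z, d$W, Ainv, logdetA)
  th <- c(2, 1.5, 4)
  ll <- AquaBLUP:::remlLogLikUni(th, des)$logLik

  X <- as.matrix(d$X); Z <- as.matrix(d$Z); W <- as.matrix(d$W)
  A <- relationshipMatrix(sim$ped)
  n <- length(d$y); p <- ncol(X)
  V <- th[1] * Z %*% A %*% t(Z) + th[2] * W %*% t(W) + th[3] * diag(n)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  ll_oracle <- -0.5 * ((n - p) * log(2 * pi) +
                       as.numeric(determinant(V)$modulus) +
                       as.numeric(determinant(XVX)$modulus) +
                       as.numeric(t(d$y) %*% P %*% d$y))
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
  # profiled likelihood agrees at its own implied s2e
  pr <- AquaBLUP:::remlProfileLogLik(c(th[1] / th[3], th[2] / th[3]), des)
  full_at_profile <- AquaBLUP:::remlLogLikUni(
    c(th[1] / th[3], th[2] / th[3], 1) * pr$s2e, des)$logLik
  expect_equal(pr$logLik, full_at_profile, tolerance = 1e-8)
})

test_that("EM-REML iterations never decrease the log-likelihood", {
  sim <- simHierarchical(n_sires = 25, n_off = 8, seed = 12)
  fit <- remlFit(sim$data, modelSpec("weight"), sim$ped, method = "em",
                 max_iter = 40L, se = FALSE)
  tr <- fit@meta$ll_trace
  expect_gt(length(tr), 5)
  expect_true(all(diff(tr) > -1e-6))
})

test_that("the direct optimum is an EM fixed point", {
  sim <- simHierarchical(n_sires = 25, n_off = 6, s2a = 3, s2c = 1,
                         s2e = 2, seed = 31)
  fd <- remlFit(sim$data, modelSpec("weight"), sim$ped, se = FALSE)
  ## EM started at the direct solution must stay there (same stationary
  ## point of the restricted likelihood) and never exceed its logLik
  fe <- remlFit(sim$data, modelSpec("weight"), sim$ped, method = "em",
                start = unname(fd@theta), max_iter = 50L, se = FALSE)
  expect_equal(unname(fe@theta), unname(fd@theta), tolerance = 0.05)
  expect_lt(abs(fe@logLik - fd@logLik), 0.01)
})

test_that("data with no additive signal keeps s2a near the boundary", {
  h2 <- sapply(1:3, function(s) {
    sim <- simHierarchical(n_sires = 50, dams_per_sire = 4, n_off = 5,
                           s2a = 1e-12, s2c = 2, s2e = 3, seed = 12 + s)
    heritability(remlFit(sim$data, modelSpec("weight"), sim$ped,
                         se = FALSE))$estimate
  })
  expect_lt(mean(h2), 0.1)
})

test_that("balanced half-sib fit matches the ANOVA expected-mean-squares oracle", {
  # pure paternal half-sib structure: 20 dams per sire, 1 offspring per
  # dam, no family term; additive variance = 4 x between-sire component
  sim <- simHierarchical(n_sires = 100, dams_per_sire = 20, n_off = 1,
                         s2a = 2, s2c = 0, s2e = 6, seed = 17)
  spec <- modelSpec("weight", family = FALSE, age_covariate = FALSE,
                    stock_covariate = FALSE)
  fit <- remlFit(sim$data, spec, sim$ped, se = FALSE)
  famno <- as.integer(sub("F", "", sim$data$family))
  dsub <- data.frame(y = resid(lm(weight ~ sex, sim$data)),
                     sire = factor((famno - 1) %/% 20))
  av <- anova(lm(y ~ sire, dsub))
  k <- nrow(dsub) / nlevels(dsub$sire)
  s2_sire <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / k
  expect_equal(fit@theta[["s2a"]], 4 * s2_sire, tolerance = 0.2)
})

test_that("variance estimates are scale-equivariant and ratios invariant", {
  sim <- simHierarchical(n_sires = 30, n_off = 6, seed = 19)
  fit1 <- remlFit(sim$data, modelSpec("weight"), sim$ped, se = FALSE)
  dat2 <- sim$data
  dat2$weight <- 10 * dat2$weight
  fit2 <- remlFit(dat2, modelSpec("weight"), sim$ped, se = FALSE)
  expect_equal(unname(fit2@theta), unname(100 * fit1@theta),
               tolerance = 1e-3)
  expect_equal(heritability(fit2)$estimate, heritability(fit1)$estimate,
               tolerance = 1e-3)
  expect_equal(commonFullsibEffect(fit2)$estimate,
               commonFullsibEffect(fit1)$estimate, tolerance = 1e-3)
})

test_that("family-only model agrees with lme4 on components and logLik", {
  set.seed(23)
  nfam <- 60; noff <- 8
  fam <- rep(paste0("F", 1:nfam), each = noff)
  cf <- rnorm(nfam, 0, sqrt(2))
  names(cf) <- paste0("F", 1:nfam)
  n <- nfam * noff
  ids <- paste0("a", 1:n)
  ped <- asPedigree(ids, rep("0", n), rep("0", n))
  sexv <- sample(c("female", "male"), n, TRUE)
  y <- 10 + (sexv == "male") + cf[fam] + rnorm(n, 0, 2)
  df <- data.frame(animal = ids, environment = "pond", weight = y,
                   survival = 1, sex = sexv, generation = 1, family = fam)
  # all animals are unrelated founders, so A = I and the animal and
  # residual terms are jointly one per-record variance; lme4's family
  # model is the independent oracle for s2c and for that sum
  fit <- remlFit(df, modelSpec("weight", age_covariate = FALSE,
                               stock_covariate = FALSE, family = TRUE),
                 ped, se = FALSE)
  lfit <- lme4::lmer(y ~ sexv + (1 | fam), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  # with A = I and every animal phenotyped once, s2a and s2e are jointly
  # the residual; total non-family variance must match, as must s2c
  expect_equal(fit@theta[["s2c"]], vc$vcov[1], tolerance = 0.02)
  expect_equal(fit@theta[["s2a"]] + fit@theta[["s2e"]], vc$vcov[2],
               tolerance = 0.02)
})

test_that("boundary likelihood-ratio test uses the 50:50 chi-square mixture", {
  expect_equal(lrtVarianceComponent(-100, -100)$p_value, 0.5)
  lr <- lrtVarianceComponent(-100 + 2.706 / 2, -100)
  expect_equal(lr$statistic, 2.706, tolerance = 1e-12)
  expect_equal(lr$p_value, 0.05, tolerance = 0.001)
  expect_warning(out <- lrtVarianceComponent(-101, -100), "below")
  expect_equal(out$p_value, 1)
})
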