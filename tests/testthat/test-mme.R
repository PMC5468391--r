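test_that("variance ratios enter the coefficient matrix as specified", {
  sim <- simHierarchical(n_sires = 6, n_off = 4, seed = 2)
  d <- buildDesign(sim$data, modelSpec("weight"), sim$ped)
  Ainv <- aInverse(sim$ped)
  sys <- assembleMME(d$y, d$X, d$Z, d$W, Ainv, s2a = 1, s2c = 2, s2e = 1)
  expect_equal(sys$alpha1, 1)
  # arithmetic of the ratio for the reported pond-weight components
  sys2 <- assembleMME(d$y, d$X, d$Z, d$W, Ainv,
                      s2a = 1727.3, s2c = 3920.6, s2e = 2122.4)
  expect_equal(sys2$alpha1, 2122.4 / 1727.3, tolerance = 1e-12)
  expect_equal(round(sys2$alpha1, 4), 1.2287)
  expect_error(assembleMME(d$y, d$X, d$Z, d$W, Ainv, s2a = 0, s2c = 1,
                           s2e = 1), "strictly positive")
  # no family term: two-block system
  sys3 <- assembleMME(d$y, d$X, d$Z, NULL, Ainv, s2a = 1, s2e = 1)
  expect_equal(sys3$f, 0L)
  expect_equal(nrow(sys3$C), ncol(d$X) + ncol(d$Z))
})

test_that("intercept-only system returns the phenotype mean", {
  set.seed(4)
  ids <- paste0("a", 1:30)
  ped <- asPedigree(ids, rep("0", 30), rep("0", 30))
  y <- rnorm(30, 50, 5)
  X <- matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- Matrix::sparseMatrix(i = 1:30, j = 1:30, x = 1, dims = c(30, 30),
                            dimnames = list(NULL, ids))
  sys <- assembleMME(y, X, Z, NULL, aInverse(ped), s2a = 1e-8, s2e = 1)
  fit <- solveMME(sys)
  expect_equal(unname(fit$b[1L]), mean(y), tolerance = 1e-6)
})

test_that("sparse MME solutions equal the dense GLS solutions", {
  sim <- simHierarchical(n_sires = 5, dams_per_sire = 2, n_off = 2, seed = 5)
  d <- buildDesign(sim$data, modelSpec("weight"), sim$ped)
  A <- relationshipMatrix(sim$ped)
  Ainv <- aInverse(sim$ped)
  s2a <- 2; s2c <- 1.5; s2e <- 4
  sys <- assembleMME(d$y, d$X, d$Z, d$W, Ainv, s2a, s2c, s2e)
  fit <- solveMME(sys)
  expect_lt(fit$residual, 1e-8)

  # dense mixed-model oracle: GLS for b, then BLUP u = G U' Vinv (y - Xb)
  X <- as.matrix(d$X); Z <- as.matrix(d$Z); W <- as.matrix(d$W)
  V <- s2a * Z %*% A %*% t(Z) + s2c * W %*% t(W) + s2e * diag(length(d$y))
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
  r <- d$y - X %*% b_gls
  a_blup <- s2a * A %*% t(Z) %*% Vi %*% r
  c_blup <- s2c * t(W) %*% Vi %*% r
  expect_equal(unname(fit$b), as.numeric(b_gls), tolerance = 1e-8)
  expect_equal(unname(fit$a), as.numeric(a_blup), tolerance = 1e-8)
  expect_equal(unname(fit$c), as.numeric(c_blup), tolerance = 1e-8)
})

test_that("solutions shrink to zero as the variance ratios explode", {
  sim <- simHierarchical(n_sires = 8, n_off = 4, seed = 6)
  d <- buildDesign(sim$data, modelSpec("weight"), sim$ped)
  Ainv <- aInverse(sim$ped)
  sys <- assembleMME(d$y, d$X, d$Z, d$W, Ainv,
                     s2a = 1e-8, s2c = 1e-8, s2e = 1)  # alpha = 1e8
  fit <- solveMME(sys)
  expect_lt(max(abs(fit$a)), 1e-4 * sd(d$y))
  expect_lt(max(abs(fit$c)), 1e-4 * sd(d$y))
})

test_that("identical full-sib records receive identical EBVs", {
  # two full sibs with identical phenotypes are exchangeable
  ped <- asPedigree(c("s", "d", "t1", "t2"), c("0", "0", "s", "s"),
                    c("0", "0", "d", "d"),
                    family = c(NA, NA, "F", "F"))
  y <- c(10, 10)
  X <- matrix(1, 2, 1)
  Z <- Matrix::sparseMatrix(i = 1:2, j = 3:4, x = 1, dims = c(2, 4),
                            dimnames = list(NULL, pedIds(ped)))
  W <- Matrix::sparseMatrix(i = 1:2, j = c(1, 1), x = 1, dims = c(2, 1),
                            dimnames = list(NULL, "F"))
  sys <- assembleMME(y, X, Z, W, aInverse(ped), s2a = 1, s2c = 0.5, s2e = 1)
  fit <- solveMME(sys)
  expect_equal(fit$a[["t1"]], fit$a[["t2"]], tolerance = 1e-12)
})

test_that("prediction-error variances match the dense inverse", {
  sim <- simHierarchical(n_sires = 5, dams_per_sire = 2, n_off = 2, seed = 8)
  d <- buildDesign(sim$data, modelSpec("weight"), sim$ped)
  Ainv <- aInverse(sim$ped)
  s2a <- 2; s2c <- 1.5; s2e <- 4
  sys <- assembleMME(d$y, d$X, d$Z, d$W, Ainv, s2a, s2c, s2e)
  fit <- solveMME(sys)
  pr <- pevReliability(sys, fit, s2a = s2a, s2e = s2e,
                       F = inbreeding(sim$ped))
  Ci <- solve(as.matrix(sys$C))
  ia <- sys$p + seq_len(sys$q)
  expect_equal(pr$pev, diag(Ci)[ia] * s2e, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(pr$reliability >= 0 & pr$reliability <= 1))
})

test_that("an unphenotyped unrelated animal has zero reliability", {
  ped <- asPedigree(c("a", "b", "lone"), c("0", "0", "0"), c("0", "0", "0"))
  y <- c(5, 6)
  X <- matrix(1, 2, 1)
  Z <- Matrix::sparseMatrix(i = 1:2, j = 1:2, x = 1, dims = c(2, 3),
                            dimnames = list(NULL, pedIds(ped)))
  sys <- assembleMME(y, X, Z, NULL, aInverse(ped), s2a = 1, s2e = 1)
  fit <- solveMME(sys)
  pr <- pevReliability(sys, fit, s2a = 1, s2e = 1, animals = "lone")
  expect_equal(pr$reliability, 0, tolerance = 1e-10)
  expect_equal(pr$pev, 1, tolerance = 1e-10)  # full additive variance
})
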