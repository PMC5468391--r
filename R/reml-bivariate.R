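## Bivariate animal-model REML.
##
## Two trait expressions share the pedigree: additive effects have a full
## 2x2 covariance matrix Ga across expressions (kron(Ga^-1, A^-1) in the
## MME), family effects a full Gc, and the residual is either a free 2x2
## matrix on paired records (two traits on the same animals) or two
## independent variances on disjoint records (the same trait expressed in
## two environments: no animal is measured twice, so the residual
## covariance is structurally zero and fixed there).

padBlock <- function(S, roff, coff, K) {
  S <- as(as(S, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = S@i + 1L + roff, j = S@j + 1L + coff,
                       x = S@x, dims = c(K, K))
}

bivPrecompute <- function(d1, d2, W1, W2, Ainv, logdetA, paired) {
  X1 <- Matrix::Matrix(d1$X, sparse = TRUE)
  X2 <- Matrix::Matrix(d2$X, sparse = TRUE)
  n1 <- nrow(X1); n2 <- nrow(X2)
  p1 <- ncol(X1); p2 <- ncol(X2)
  q <- ncol(d1$Z); f <- ncol(W1)
  K <- p1 + p2 + 2L * q + 2L * f
  z1 <- function(n, m) Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                            x = numeric(0), dims = c(n, m))
  T1 <- cbind(X1, z1(n1, p2), d1$Z, z1(n1, q), W1, z1(n1, f))
  T2 <- cbind(z1(n2, p1), X2, z1(n2, q), d2$Z, z1(n2, f), W2)
  C11 <- Matrix::forceSymmetric(Matrix::crossprod(T1))
  C22 <- Matrix::forceSymmetric(Matrix::crossprod(T2))
  C12 <- if (paired) Matrix::crossprod(T1, T2) else NULL
  ia1 <- p1 + p2
  ia2 <- p1 + p2 + q
  ic1 <- p1 + p2 + 2L * q
  ic2 <- ic1 + f
  Pa11 <- Matrix::forceSymmetric(padBlock(Ainv, ia1, ia1, K))
  Pa22 <- Matrix::forceSymmetric(padBlock(Ainv, ia2, ia2, K))
  Pa12 <- padBlock(Ainv, ia1, ia2, K)
  Pa12 <- Matrix::forceSymmetric(Pa12 + Matrix::t(Pa12))
  If <- Matrix::Diagonal(f)
  Pc11 <- Matrix::forceSymmetric(padBlock(If, ic1, ic1, K))
  Pc22 <- Matrix::forceSymmetric(padBlock(If, ic2, ic2, K))
  Pc12 <- padBlock(If, ic1, ic2, K)
  Pc12 <- Matrix::forceSymmetric(Pc12 + Matrix::t(Pc12))
  ## same sparsity pattern as any iterate, with PD block weights
  Mtmpl <- C11 + C22 + Pa11 + Pa22 + 0.5 * Pa12 + Pc11 + Pc22 + 0.5 * Pc12
  if (paired) Mtmpl <- Mtmpl +
    0.25 * Matrix::forceSymmetric(C12 + Matrix::t(C12))
  ch0 <- Matrix::Cholesky(Matrix::forceSymmetric(Mtmpl), LDL = FALSE,
                          perm = TRUE)
  list(C11 = C11, C22 = C22, C12 = C12,
       T1ty1 = as.numeric(Matrix::crossprod(T1, d1$y)),
       T2ty2 = as.numeric(Matrix::crossprod(T2, d2$y)),
       T1ty2 = if (paired) as.numeric(Matrix::crossprod(T1, d2$y)) else NULL,
       T2ty1 = if (paired) as.numeric(Matrix::crossprod(T2, d1$y)) else NULL,
       y1 = d1$y, y2 = d2$y,
       Pa11 = Pa11, Pa22 = Pa22, Pa12 = Pa12,
       Pc11 = Pc11, Pc22 = Pc22, Pc12 = Pc12,
       n1 = n1, n2 = n2, p = p1 + p2, p1 = p1, p2 = p2, q = q, f = f,
       K = K, logdetA = logdetA, paired = paired, ch0 = ch0)
}

## theta: list(Ga = 2x2, Gc = 2x2, R0 = 2x2 (off-diag 0 unless paired))
bivLogLik <- function(theta, des, want_sol = FALSE) {
  Ga <- theta$Ga; Gc <- theta$Gc; R0 <- theta$R0
  detGa <- Ga[1, 1] * Ga[2, 2] - Ga[1, 2]^2
  detGc <- Gc[1, 1] * Gc[2, 2] - Gc[1, 2]^2
  detR <- R0[1, 1] * R0[2, 2] - R0[1, 2]^2
  if (detGa <= 0 || detGc <= 0 || detR <= 0 ||
      any(diag(Ga) <= 0) || any(diag(Gc) <= 0) || any(diag(R0) <= 0)) {
    return(list(logLik = -Inf))
  }
  Gai <- matrix(c(Ga[2, 2], -Ga[1, 2], -Ga[1, 2], Ga[1, 1]), 2) / detGa
  Gci <- matrix(c(Gc[2, 2], -Gc[1, 2], -Gc[1, 2], Gc[1, 1]), 2) / detGc
  if (des$paired) {
    Ri <- matrix(c(R0[2, 2], -R0[1, 2], -R0[1, 2], R0[1, 1]), 2) / detR
    w11 <- Ri[1, 1]; w22 <- Ri[2, 2]; w12 <- Ri[1, 2]
    logdetR <- des$n1 * log(detR)
  } else {
    w11 <- 1 / R0[1, 1]; w22 <- 1 / R0[2, 2]; w12 <- 0
    logdetR <- des$n1 * log(R0[1, 1]) + des$n2 * log(R0[2, 2])
  }
  M <- w11 * des$C11 + w22 * des$C22 +
    Gai[1, 1] * des$Pa11 + Gai[2, 2] * des$Pa22 + Gai[1, 2] * des$Pa12 +
    Gci[1, 1] * des$Pc11 + Gci[2, 2] * des$Pc22 + Gci[1, 2] * des$Pc12
  rhs <- w11 * des$T1ty1 + w22 * des$T2ty2
  yRy <- w11 * sum(des$y1^2) + w22 * sum(des$y2^2)
  if (des$paired && w12 != 0) {
    M <- M + w12 * Matrix::forceSymmetric(des$C12 + Matrix::t(des$C12))
    rhs <- rhs + w12 * (des$T1ty2 + des$T2ty1)
    yRy <- yRy + 2 * w12 * sum(des$y1 * des$y2)
  }
  ## optimizer probes of near-singular points fail quietly with -Inf
  ch <- tryCatch(suppressWarnings(
    Matrix::update(des$ch0, Matrix::forceSymmetric(M))),
    error = function(e) NULL)
  if (is.null(ch)) return(list(logLik = -Inf))
  sol <- as.numeric(Matrix::solve(ch, rhs))
  yPy <- yRy - sum(sol * rhs)
  logdetM <- 2 * as.numeric(
    Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  ntot <- des$n1 + des$n2
  logdetG <- des$q * log(detGa) + 2 * des$logdetA + des$f * log(detGc)
  m2l <- (ntot - des$p) * log(2 * pi) + logdetR + logdetG + logdetM + yPy
  out <- list(logLik = -0.5 * m2l)
  if (want_sol) out$solution <- sol
  out
}

thetaFromPar <- function(par, paired, floors) {
  v <- function(l, fl) fl + exp(l)
  Ga <- matrix(0, 2, 2)
  Ga[1, 1] <- v(par[1L], floors[1L]); Ga[2, 2] <- v(par[2L], floors[2L])
  Ga[1, 2] <- Ga[2, 1] <- tanh(par[3L]) * sqrt(Ga[1, 1] * Ga[2, 2])
  Gc <- matrix(0, 2, 2)
  Gc[1, 1] <- v(par[4L], floors[1L]); Gc[2, 2] <- v(par[5L], floors[2L])
  Gc[1, 2] <- Gc[2, 1] <- tanh(par[6L]) * sqrt(Gc[1, 1] * Gc[2, 2])
  R0 <- matrix(0, 2, 2)
  R0[1, 1] <- v(par[7L], floors[1L]); R0[2, 2] <- v(par[8L], floors[2L])
  if (paired) R0[1, 2] <- R0[2, 1] <- tanh(par[9L]) * sqrt(R0[1, 1] * R0[2, 2])
  list(Ga = Ga, Gc = Gc, R0 = R0)
}

#' Bivariate animal-model REML
#'
#' Joint REML fit of two trait expressions under the animal model with a
#' common full-sib family term, giving the full 2x2 additive and family
#' covariance matrices. Two uses:
#'
#' * `remlBivariateCrossEnv()` treats the *same* trait recorded in pond and
#'   in cage as two genetically distinct traits. No animal is measured in
#'   both environments, so the residual covariance is structurally zero and
#'   is fixed at zero; the off-diagonal of the additive matrix yields the
#'   between-environment genetic correlation that quantifies
#'   genotype-by-environment re-ranking.
#' * `remlBivariateWithinEnv()` fits two different traits recorded on the
#'   same animals in one environment, with a free residual covariance;
#'   genetic and phenotypic correlations follow from the component
#'   matrices.
#'
#' Covariances are parameterised through `atanh`-transformed correlations,
#' so every iterate is positive definite. The likelihood is maximised by
#' Nelder-Mead with a convergence-tightening restart; starting values come
#' from univariate fits of each trait (override via `start_cor`). Standard
#' errors of the derived correlations are delta-method values from a
#' numerically differentiated Hessian at the optimum.
#'
#' @param data phenotype `data.frame`.
#' @param ped a [Pedigree-class].
#' @param trait trait column (cross-env) .
#' @param traits length-2 character (within-env).
#' @param environment environment for the within-env fit.
#' @param transform response transform, as in [modelSpec()].
#' @param start_cor starting additive correlation in (-1, 1).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration budget scale.
#' @param se compute SEs / Hessian at the optimum.
#' @param use_inbreeding account for inbreeding in the A-inverse.
#' @return a [RemlFit-class]; see [geneticCorrelation()].
#' @export
remlBivariateCrossEnv <- function(data, trait, ped,
                                  transform = c("identity", "sqrt"),
                                  start_cor = 0.5, tol = 1e-8,
                                  max_iter = 200L, se = TRUE,
                                  use_inbreeding = TRUE) {
  transform <- match.arg(transform)
  for (env in c("pond", "cage")) {
    ok <- data$environment == env & !is.na(data[[trait]])
    if (!any(ok)) stop("no ", trait, " records in environment ", env)
  }
  spec1 <- modelSpec(trait, environment = "pond", transform = transform)
  spec2 <- modelSpec(trait, environment = "cage", transform = transform)
  remlBivariateEngine(data, ped, spec1, spec2, paired = FALSE,
                      start_cor = start_cor, tol = tol,
                      max_iter = max_iter, se = se,
                      use_inbreeding = use_inbreeding,
                      model = "bivariate_cross_env",
                      labels = c(paste0(trait, ".pond"),
                                 paste0(trait, ".cage")))
}

#' @rdname remlBivariateCrossEnv
#' @export
remlBivariateWithinEnv <- function(data, traits, environment, ped,
                                   start_cor = 0.5, tol = 1e-8,
                                   max_iter = 200L, se = TRUE,
                                   use_inbreeding = TRUE) {
  stopifnot(length(traits) == 2L)
  keep <- data$environment == environment &
    !is.na(data[[traits[1L]]]) & !is.na(data[[traits[2L]]])
  if (!any(keep)) stop("no complete records for ", paste(traits, collapse = "/"))
  dd <- data[keep, , drop = FALSE]
  spec1 <- modelSpec(traits[1L], environment = environment)
  spec2 <- modelSpec(traits[2L], environment = environment)
  remlBivariateEngine(dd, ped, spec1, spec2, paired = TRUE,
                      start_cor = start_cor, tol = tol,
                      max_iter = max_iter, se = se,
                      use_inbreeding = use_inbreeding,
                      model = "bivariate_within_env",
                      labels = paste0(traits, ".", environment))
}

remlBivariateEngine <- function(data, ped, spec1, spec2, paired, start_cor,
                                tol, max_iter, se, use_inbreeding, model,
                                labels) {
  d1 <- buildDesign(data, spec1, ped)
  d2 <- buildDesign(data, spec2, ped)
  if (paired && !identical(d1$data$animal, d2$data$animal)) {
    stop("paired bivariate fit requires identical record sets")
  }
  ## shared family coding across the two expressions
  fam_levels <- sort(unique(c(d1$data$family, d2$data$family)))
  mkW <- function(dd) {
    Matrix::sparseMatrix(i = seq_len(nrow(dd)),
                         j = match(dd$family, fam_levels), x = 1,
                         dims = c(nrow(dd), length(fam_levels)),
                         dimnames = list(NULL, fam_levels))
  }
  W1 <- mkW(d1$data); W2 <- mkW(d2$data)
  F <- if (use_inbreeding) inbreeding(ped) else numeric(nAnimals(ped))
  Ainv <- aInverse(ped, F = F, use_inbreeding = use_inbreeding)
  logdetA <- sum(log(mendelianVariance(ped@sire, ped@dam,
                                       if (use_inbreeding) F else numeric(nAnimals(ped)))))
  des <- bivPrecompute(d1, d2, W1, W2, Ainv, logdetA, paired)

  ## univariate starts
  u1 <- remlFit(data, spec1, ped, se = FALSE, use_inbreeding = use_inbreeding)
  u2 <- remlFit(data, spec2, ped, se = FALSE, use_inbreeding = use_inbreeding)
  floors <- 1e-8 * c(stats::var(d1$y), stats::var(d2$y))
  lv <- function(x, fl) log(max(x, 10 * fl))
  par0 <- c(lv(u1@theta["s2a"], floors[1]), lv(u2@theta["s2a"], floors[2]),
            atanh(start_cor),
            lv(u1@theta["s2c"], floors[1]), lv(u2@theta["s2c"], floors[2]),
            atanh(start_cor),
            lv(u1@theta["s2e"], floors[1]), lv(u2@theta["s2e"], floors[2]))
  if (paired) par0 <- c(par0, atanh(0.3))
  evals <- 0L
  obj <- function(par) {
    evals <<- evals + 1L
    th <- thetaFromPar(par, paired, floors)
    ll <- bivLogLik(th, des)$logLik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  ## the restricted likelihood can be multimodal in the correlation
  ## parameters when the additive variances are weakly identified: probe
  ## several correlation starts coarsely, then polish the best basin
  starts <- unique(round(c(start_cor, 0, 0.8), 6))
  coarse <- lapply(starts, function(r0) {
    p0 <- par0
    p0[3L] <- atanh(r0)
    p0[6L] <- atanh(r0)
    stats::optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 40L * max_iter, reltol = 1e-5))
  })
  best <- coarse[[which.min(vapply(coarse, `[[`, numeric(1), "value"))]]
  o1 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 200L * max_iter, reltol = tol))
  o2 <- stats::optim(o1$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 200L * max_iter, reltol = tol / 10))
  th <- thetaFromPar(o2$par, paired, floors)
  final <- bivLogLik(th, des, want_sol = TRUE)

  nm <- c("s2a1", "s2a2", "ra", "s2c1", "s2c2", "rc", "s2e1", "s2e2",
          if (paired) "re")
  theta <- c(th$Ga[1, 1], th$Ga[2, 2],
             th$Ga[1, 2] / sqrt(th$Ga[1, 1] * th$Ga[2, 2]),
             th$Gc[1, 1], th$Gc[2, 2],
             th$Gc[1, 2] / sqrt(th$Gc[1, 1] * th$Gc[2, 2]),
             th$R0[1, 1], th$R0[2, 2],
             if (paired) th$R0[1, 2] / sqrt(th$R0[1, 1] * th$R0[2, 2]))
  names(theta) <- nm
  boundary <- stats::setNames(rep(FALSE, length(nm)), nm)
  for (k in c("s2a1", "s2c1", "s2e1")) boundary[k] <- theta[k] <= 20 * floors[1]
  for (k in c("s2a2", "s2c2", "s2e2")) boundary[k] <- theta[k] <= 20 * floors[2]

  ## Hessian wrt untransformed (co)variances for delta-method SEs
  se_vec <- rep(NA_real_, length(nm)); names(se_vec) <- nm
  vcth <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  meta_cov <- list()
  if (se && !any(boundary)) {
    pack <- function(th) c(th$Ga[1, 1], th$Ga[2, 2], th$Ga[1, 2],
                           th$Gc[1, 1], th$Gc[2, 2], th$Gc[1, 2],
                           th$R0[1, 1], th$R0[2, 2],
                           if (paired) th$R0[1, 2])
    unpack <- function(v) {
      Ga <- matrix(c(v[1], v[3], v[3], v[2]), 2)
      Gc <- matrix(c(v[4], v[6], v[6], v[5]), 2)
      R0 <- matrix(c(v[7], if (paired) v[9] else 0,
                     if (paired) v[9] else 0, v[8]), 2)
      list(Ga = Ga, Gc = Gc, R0 = R0)
    }
    nll <- function(v) {
      ll <- bivLogLik(unpack(v), des)$logLik
      if (!is.finite(ll)) 1e10 else -ll
    }
    pk <- pack(th)
    H <- tryCatch(stats::optimHess(pk, nll,
                    control = list(ndeps = pmax(1e-4 * abs(pk), 1e-8))),
                  error = function(e) NULL)
    Vi <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(Vi) && all(diag(Vi) > 0)) meta_cov$vcov_cov_scale <- Vi
  }

  sol <- final$solution
  p1 <- des$p1; p2 <- des$p2; q <- des$q; f <- des$f
  a1 <- sol[p1 + p2 + seq_len(q)]; names(a1) <- pedIds(ped)
  a2 <- sol[p1 + p2 + q + seq_len(q)]; names(a2) <- pedIds(ped)
  new("RemlFit",
      theta = theta, se = se_vec, vcovTheta = vcth,
      logLik = final$logLik,
      converged = o2$convergence == 0L, niter = as.integer(evals),
      method = "direct", boundary = boundary, model = model,
      solutions = list(b = sol[seq_len(p1 + p2)],
                       a = cbind(a1, a2), c = sol[p1 + p2 + 2 * q + seq_len(2 * f)]),
      meta = c(list(labels = labels, paired = paired,
                    n1 = des$n1, n2 = des$n2,
                    Ga = th$Ga, Gc = th$Gc, R0 = th$R0,
                    trait1 = spec1$trait, trait2 = spec2$trait,
                    env1 = spec1$environment, env2 = spec2$environment),
               meta_cov))
}

#' Genetic (and phenotypic) correlation from a bivariate fit
#'
#' The additive genetic correlation `ra = cov_a / sqrt(va1 * va2)` with a
#' delta-method SE; for paired (within-environment) fits also the
#' phenotypic correlation from the summed component matrices.
#'
#' When either additive variance is pinned at the boundary floor the
#' likelihood carries no information about the correlation (it is exactly
#' flat in `ra`), so the estimate is reported as `NA` rather than the
#' arbitrary value the optimizer stopped at.
#'
#' @param fit a bivariate [RemlFit-class].
#' @return list with `genetic = list(estimate, se, defined)` and, when
#'   available, `phenotypic = list(estimate, se)`.
#' @export
geneticCorrelation <- function(fit) {
  stopifnot(is(fit, "RemlFit"), grepl("bivariate", fit@model))
  Ga <- fit@meta$Ga; Gc <- fit@meta$Gc; R0 <- fit@meta$R0
  if (any(fit@boundary[c("s2a1", "s2a2")])) {
    out <- list(genetic = list(estimate = NA_real_, se = NA_real_,
                               defined = FALSE))
    if (isTRUE(fit@meta$paired)) {
      P <- Ga + Gc + R0
      out$phenotypic <- list(estimate = P[1, 2] / sqrt(P[1, 1] * P[2, 2]),
                             se = NA_real_)
    }
    return(out)
  }
  ra <- Ga[1, 2] / sqrt(Ga[1, 1] * Ga[2, 2])
  se_ra <- NA_real_
  V <- fit@meta$vcov_cov_scale
  if (!is.null(V)) {
    ## order: va1 va2 cova vc1 vc2 covc ve1 ve2 [cove]
    g <- numeric(nrow(V))
    g[1] <- -ra / (2 * Ga[1, 1])
    g[2] <- -ra / (2 * Ga[2, 2])
    g[3] <- 1 / sqrt(Ga[1, 1] * Ga[2, 2])
    vv <- as.numeric(t(g) %*% V %*% g)
    if (is.finite(vv) && vv >= 0) se_ra <- sqrt(vv)
  }
  out <- list(genetic = list(estimate = ra, se = se_ra, defined = TRUE))
  if (isTRUE(fit@meta$paired)) {
    P <- Ga + Gc + R0
    rp <- P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    se_rp <- NA_real_
    if (!is.null(V)) {
      np <- nrow(V)
      gp <- numeric(np)
      dnum <- c(1, 1, if (np >= 9) 1)  # cov entries
      s1 <- P[1, 1]; s2 <- P[2, 2]; cv <- P[1, 2]
      ## d rp / d (v1 components) = -rp/(2 s1); / d cov = 1/sqrt(s1 s2)
      gp[c(1, 4, 7)] <- -rp / (2 * s1)
      gp[c(2, 5, 8)] <- -rp / (2 * s2)
      gp[3] <- 1 / sqrt(s1 * s2)
      gp[6] <- 1 / sqrt(s1 * s2)
      if (np >= 9) gp[9] <- 1 / sqrt(s1 * s2)
      vv <- as.numeric(t(gp) %*% V %*% gp)
      if (is.finite(vv) && vv >= 0) se_rp <- sqrt(vv)
    }
    out$phenotypic <- list(estimate = rp, se = se_rp)
  }
  out
}

#' Within-environment genetic and phenotypic correlations
#'
#' Pairwise bivariate animal-model fits of harvest weight with each other
#' trait in one environment (each pair includes the selection criterion,
#' which limits selection bias in the component estimates), returning the
#' additive genetic and phenotypic correlations with SEs. Set
#' `all_pairs = TRUE` to also fit the pairs not involving weight.
#'
#' @param data phenotype `data.frame`.
#' @param ped a [Pedigree-class].
#' @param environment `"pond"` or `"cage"`.
#' @param traits traits to correlate (first is the anchor, default weight).
#' @param all_pairs fit every pair, not just anchor pairs.
#' @param ... passed to [remlBivariateWithinEnv()].
#' @return list with matrices `genetic`, `genetic_se`, `phenotypic`,
#'   `phenotypic_se` (NA where a pair was not fitted) and the fits.
#' @export
correlationsWithinEnv <- function(data, ped, environment,
                                  traits = c("weight", "length", "width",
                                             "depth"),
                                  all_pairs = FALSE, ...) {
  k <- length(traits)
  mk <- function() matrix(NA_real_, k, k, dimnames = list(traits, traits))
  rg <- mk(); rg_se <- mk(); rp <- mk(); rp_se <- mk()
  diag(rg) <- 1; diag(rp) <- 1
  fits <- list()
  pairs <- if (all_pairs) utils::combn(k, 2, simplify = FALSE)
           else lapply(seq_len(k - 1L) + 1L, function(j) c(1L, j))
  for (pr in pairs) {
    t1 <- traits[pr[1L]]; t2 <- traits[pr[2L]]
    fit <- remlBivariateWithinEnv(data, c(t1, t2), environment, ped, ...)
    co <- geneticCorrelation(fit)
    rg[t1, t2] <- rg[t2, t1] <- co$genetic$estimate
    rg_se[t1, t2] <- rg_se[t2, t1] <- co$genetic$se
    rp[t1, t2] <- rp[t2, t1] <- co$phenotypic$estimate
    rp_se[t1, t2] <- rp_se[t2, t1] <- co$phenotypic$se
    fits[[paste(t1, t2, sep = ":")]] <- fit
  }
  list(genetic = rg, genetic_se = rg_se,
       phenotypic = rp, phenotypic_se = rp_se, fits = fits)
}
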