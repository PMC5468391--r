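#' REML fit of an animal model
#'
#' Holds restricted-maximum-likelihood estimates of the variance
#' components of an animal model with an optional common full-sib family
#' term, their asymptotic standard errors, the REML log-likelihood and the
#' mixed-model solutions (BLUE/BLUP) evaluated at the estimates.
#'
#' @slot theta named numeric vector of (co)variance parameters. Univariate:
#'   `s2a, s2c, s2e`. Bivariate: `s2a1, s2a2, ra, s2c1, s2c2, rc, s2e1,
#'   s2e2` and `re` when the residual covariance is free.
#' @slot se asymptotic SEs of `theta` (NA at a boundary).
#' @slot vcovTheta asymptotic covariance matrix of `theta`.
#' @slot logLik REML log-likelihood at the optimum.
#' @slot converged logical.
#' @slot niter iterations / function evaluations used.
#' @slot method `"direct"` or `"em"`.
#' @slot boundary named logical: component pinned at the variance floor.
#' @slot model `"univariate"`, `"bivariate_cross_env"` or
#'   `"bivariate_within_env"`.
#' @slot solutions list with `b`, `a` (EBVs), `c` at the REML estimates.
#' @slot meta list (trait, environment(s), n records, floor used, ...).
#' @export
setClass("RemlFit", slots = c(
  theta = "numeric", se = "numeric", vcovTheta = "matrix",
  logLik = "numeric", converged = "logical", niter = "integer",
  method = "character", boundary = "logical", model = "character",
  solutions = "list", meta = "list"
))

setMethod("show", "RemlFit", function(object) {
  cat(sprintf("RemlFit (%s, %s): logLik = %.4f, %s after %d evaluations\n",
              object@model, object@method, object@logLik,
              if (object@converged) "converged" else "NOT converged",
              object@niter))
  est <- data.frame(estimate = object@theta,
                    se = object@se[names(object@theta)])
  print(round(est, 5))
  if (any(object@boundary)) {
    cat("  at boundary:", paste(names(which(object@boundary)),
                                collapse = ", "), "\n")
  }
  if (object@model == "univariate") {
    h <- heritability(object)
    cc <- commonFullsibEffect(object)
    cat(sprintf("  h2 = %.3f (SE %.3f), c2 = %.3f (SE %.3f)\n",
                h$estimate, h$se, cc$estimate, cc$se))
  }
})

#' @describeIn RemlFit REML log-likelihood
#' @param object,fit a `RemlFit`
#' @export
remlLogLik <- function(fit) fit@logLik

#' @describeIn RemlFit named vector of variance-component estimates
#' @export
varianceComponents <- function(fit) fit@theta

#' @describeIn RemlFit estimated breeding values at the REML estimates
#' @export
ebv <- function(fit) fit@solutions$a

## ---- univariate restricted log-likelihood -------------------------------
## Precomputed pieces are carried in `des`:
##   TtT = crossprod([X Z W]), Tty, yty, Ainv, logdetA, dims.
## logL = -0.5 [ (n-p) log 2pi + n log s2e + q log s2a + logdetA
##               + f log s2c + log|M| + y'Py ]
## with M the variance-form MME matrix; log|V| + log|X'V^-1 X| =
## log|R| + log|G| + log|M| (Schur-complement identity).
remlPrecompute <- function(y, X, Z, W, Ainv, logdetA) {
  X <- Matrix::Matrix(X, sparse = TRUE)
  T_ <- if (is.null(W)) cbind(X, Z) else cbind(X, Z, W)
  TtT <- Matrix::forceSymmetric(Matrix::crossprod(T_))
  p <- ncol(X); q <- ncol(Z); f <- if (is.null(W)) 0L else ncol(W)
  K <- p + q + f
  ## full-size padded copies of the G-inverse blocks so every likelihood
  ## evaluation is a plain sparse addition (no subassignment)
  Ai3 <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  Ga <- Matrix::sparseMatrix(i = Ai3@i + 1L + p, j = Ai3@j + 1L + p,
                             x = Ai3@x, dims = c(K, K))
  Ga <- Matrix::forceSymmetric(Ga)
  Gc <- if (f > 0) {
    Matrix::Diagonal(K, x = c(numeric(p + q), rep(1, f)))
  } else NULL
  M0 <- TtT + Ga
  if (f > 0) M0 <- M0 + Gc
  ch0 <- Matrix::Cholesky(Matrix::forceSymmetric(M0), LDL = FALSE, perm = TRUE)
  list(TtT = TtT, Tty = as.numeric(Matrix::crossprod(T_, y)),
       yty = sum(y^2), n = length(y), p = p, q = q, f = f,
       Ainv = Ainv, Ga = Ga, Gc = Gc, logdetA = logdetA,
       T = T_, y = y, ch0 = ch0)
}

## numeric Cholesky with the precomputed symbolic analysis
cholUpdate <- function(des, M) {
  tryCatch(suppressWarnings(
    Matrix::update(des$ch0, Matrix::forceSymmetric(M))),
    error = function(e) NULL)
}

## Profiled restricted log-likelihood over the variance ratios
## gamma = (s2a/s2e, s2c/s2e); s2e is profiled out in closed form.
remlProfileLogLik <- function(gamma, des) {
  p <- des$p; q <- des$q; f <- des$f; n <- des$n
  M <- des$TtT + des$Ga / gamma[1L]
  if (f > 0) M <- M + des$Gc / gamma[2L]
  ch <- cholUpdate(des, M)
  if (is.null(ch)) return(list(logLik = -Inf))
  sol <- as.numeric(Matrix::solve(ch, des$Tty))
  yPy0 <- des$yty - sum(sol * des$Tty)
  if (yPy0 <= 0) return(list(logLik = -Inf))
  s2e <- yPy0 / (n - p)
  logdetM0 <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  m2l <- (n - p) * (log(2 * pi) + 1 + log(s2e)) +
    q * log(gamma[1L]) + des$logdetA +
    (if (f > 0) f * log(gamma[2L]) else 0) +
    as.numeric(logdetM0)
  list(logLik = -0.5 * m2l, s2e = s2e)
}

remlLogLikUni <- function(theta, des, want_sol = FALSE) {
  s2a <- theta[1L]; s2c <- theta[2L]; s2e <- theta[3L]
  p <- des$p; q <- des$q; f <- des$f; n <- des$n
  M <- des$TtT / s2e + des$Ga / s2a
  if (f > 0) M <- M + des$Gc / s2c
  ch <- cholUpdate(des, M)
  if (is.null(ch)) return(list(logLik = -Inf))
  rhs <- des$Tty / s2e
  sol <- as.numeric(Matrix::solve(ch, rhs))
  yPy <- des$yty / s2e - sum(sol * rhs)
  logdetM <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  m2l <- (n - p) * log(2 * pi) + n * log(s2e) +
    q * log(s2a) + des$logdetA +
    (if (f > 0) f * log(s2c) else 0) +
    logdetM + yPy
  out <- list(logLik = -0.5 * as.numeric(m2l))
  if (want_sol) {
    out$solution <- sol
    out$yPy <- yPy
  }
  out
}

## EM-REML update (alpha-form MME, dense inverse for the trace terms).
## Classic updates:
##   s2a+ = (a' Ainv a + tr(Ainv Caa) s2e) / q
##   s2c+ = (c'c + tr(Ccc) s2e) / f
##   s2e+ = (y'y - b'X'y - a'Z'y - c'W'y) / (n - p)
emStep <- function(theta, des) {
  s2a <- theta[1L]; s2c <- theta[2L]; s2e <- theta[3L]
  p <- des$p; q <- des$q; f <- des$f
  a1 <- s2e / s2a
  C <- des$TtT + des$Ga * a1
  if (f > 0) C <- C + des$Gc * (s2e / s2c)
  ia <- p + seq_len(q)
  Cd <- as.matrix(Matrix::forceSymmetric(C))
  Ci <- solve(Cd)
  sol <- Ci %*% des$Tty
  b <- sol[seq_len(p)]; a <- sol[ia]
  s2e_new <- (des$yty - sum(sol * des$Tty)) / (des$n - p)
  Ad <- as.matrix(des$Ainv)
  s2a_new <- (as.numeric(t(a) %*% Ad %*% a) +
                sum(Ad * Ci[ia, ia]) * s2e) / q
  if (f > 0) {
    ic <- p + q + seq_len(f)
    cc <- sol[ic]
    s2c_new <- (sum(cc^2) + sum(diag(Ci[ic, ic, drop = FALSE])) * s2e) / f
  } else s2c_new <- s2c
  c(s2a_new, s2c_new, s2e_new)
}

#' Univariate REML for the animal model with a family effect
#'
#' Estimates `(s2a, s2c, s2e)` of `y = Xb + Za + Wc + e` by restricted
#' maximum likelihood. The default estimator maximises the exact REML
#' log-likelihood — evaluated through one sparse Cholesky factorisation of
#' the variance-form mixed-model equations per point — over
#' log-transformed components by Nelder-Mead with a convergence-tightening
#' restart. `method = "em"` runs classic EM-REML (monotone in the
#' log-likelihood; dense trace computation, so suited to small systems).
#' Components are kept above a floor of `1e-8 * var(y)`; an estimate at the
#' floor is flagged as a boundary solution. Standard errors come from the
#' numerically differentiated curvature (observed information) of the REML
#' log-likelihood at the optimum.
#'
#' @param data phenotype `data.frame`.
#' @param spec a [modelSpec()].
#' @param ped a [Pedigree-class].
#' @param start optional numeric `c(s2a, s2c, s2e)`; defaults to equal
#'   thirds of the phenotypic variance.
#' @param method `"direct"` (default) or `"em"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap (EM) / evaluation budget scale (direct).
#' @param use_inbreeding account for inbreeding in the A-inverse.
#' @param se compute asymptotic SEs (skipped at a boundary).
#' @return a [RemlFit-class].
#' @export
remlFit <- function(data, spec, ped, start = NULL,
                    method = c("direct", "em"),
                    tol = 1e-8, max_iter = 200L,
                    use_inbreeding = TRUE, se = TRUE) {
  method <- match.arg(method)
  des0 <- buildDesign(data, spec, ped)
  F <- if (use_inbreeding) inbreeding(ped) else numeric(nAnimals(ped))
  Ainv <- aInverse(ped, F = F, use_inbreeding = use_inbreeding)
  logdetA <- sum(log(mendelianVariance(ped@sire, ped@dam,
                                       if (use_inbreeding) F else numeric(nAnimals(ped)))))
  W <- if (isTRUE(spec$family)) des0$W else NULL
  des <- remlPrecompute(des0$y, des0$X, des0$Z, W, Ainv, logdetA)
  vp <- stats::var(des0$y)
  floor_ <- 1e-8 * vp
  if (is.null(start)) start <- rep(vp / 3, 3)
  has_fam <- des$f > 0
  if (!has_fam) start[2L] <- 1  # unused slot

  evals <- 0L
  gfloor <- 1e-8
  obj <- function(l) {
    evals <<- evals + 1L
    g <- gfloor + exp(l)
    gam <- if (has_fam) g else c(g[1L], 1)
    ll <- remlProfileLogLik(gam, des)$logLik
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (method == "direct") {
    g0 <- c(start[1L] / start[3L], if (has_fam) start[2L] / start[3L])
    l0 <- log(pmax(g0, gfloor))
    o1 <- stats::optim(l0, obj, method = if (length(l0) > 1) "Nelder-Mead" else "BFGS",
                       control = list(maxit = 100L * max_iter, reltol = tol))
    o2 <- stats::optim(o1$par, obj, method = if (length(l0) > 1) "Nelder-Mead" else "BFGS",
                       control = list(maxit = 100L * max_iter, reltol = tol / 10))
    ghat <- gfloor + exp(o2$par)
    gam <- if (has_fam) ghat else c(ghat[1L], 1)
    pr <- remlProfileLogLik(gam, des)
    theta <- c(s2a = gam[1L] * pr$s2e,
               s2c = if (has_fam) gam[2L] * pr$s2e else 0,
               s2e = pr$s2e)
    converged <- o2$convergence == 0L
    niter <- evals
  } else {
    theta_cur <- c(start[1L], if (has_fam) start[2L] else 1, start[3L])
    ll_old <- remlLogLikUni(theta_cur, des)$logLik
    converged <- FALSE
    it <- 0L
    trace_ll <- ll_old
    repeat {
      it <- it + 1L
      theta_new <- emStep(theta_cur, des)
      theta_new <- pmax(theta_new, floor_)
      if (!has_fam) theta_new[2L] <- 1
      ll_new <- remlLogLikUni(theta_new, des)$logLik
      trace_ll <- c(trace_ll, ll_new)
      dpar <- max(abs(theta_new - theta_cur) / pmax(abs(theta_cur), 1e-12))
      dll <- abs(ll_new - ll_old) / max(abs(ll_old), 1)
      theta_cur <- theta_new
      ll_old <- ll_new
      if (dll < tol && dpar < 1e-6) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    theta <- c(s2a = theta_cur[1L],
               s2c = if (has_fam) theta_cur[2L] else 0,
               s2e = theta_cur[3L])
    niter <- it
    attr(theta, "ll_trace") <- trace_ll
  }

  full_theta <- c(theta[["s2a"]], if (has_fam) theta[["s2c"]] else 1,
                  theta[["s2e"]])
  final <- remlLogLikUni(full_theta, des, want_sol = TRUE)
  boundary <- c(s2a = theta[["s2a"]] <= 10 * floor_,
                s2c = has_fam && theta[["s2c"]] <= 10 * floor_,
                s2e = theta[["s2e"]] <= 10 * floor_)

  se_vec <- rep(NA_real_, 3)
  names(se_vec) <- names(theta)
  vc <- matrix(NA_real_, 3, 3, dimnames = list(names(theta), names(theta)))
  if (se && !any(boundary)) {
    free <- if (has_fam) 1:3 else c(1L, 3L)
    nll <- function(th3) {
      full <- theta
      full[free] <- th3
      -remlLogLikUni(c(full[["s2a"]], if (has_fam) full[["s2c"]] else 1,
                       full[["s2e"]]), des)$logLik
    }
    H <- tryCatch(stats::optimHess(theta[free], nll,
                    control = list(ndeps = pmax(1e-4 * abs(theta[free]),
                                                1e-8))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Vi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vi) && all(diag(Vi) > 0)) {
        vc[free, free] <- Vi
        se_vec[free] <- sqrt(diag(Vi))
      }
    }
  }

  sol <- final$solution
  p <- des$p; q <- des$q; f <- des$f
  b <- sol[seq_len(p)]; names(b) <- colnames(des0$X)
  a <- sol[p + seq_len(q)]; names(a) <- des0$animal_ids
  cc <- if (f > 0) {
    v <- sol[p + q + seq_len(f)]; names(v) <- des0$family_ids; v
  } else numeric(0)

  ll_trace <- attr(theta, "ll_trace")
  attr(theta, "ll_trace") <- NULL
  new("RemlFit",
      theta = theta, se = se_vec, vcovTheta = vc,
      logLik = final$logLik, converged = converged,
      niter = as.integer(niter), method = method, boundary = boundary,
      model = "univariate",
      solutions = list(b = b, a = a, c = cc),
      meta = list(trait = spec$trait, environment = spec$environment,
                  transform = spec$transform, n = des$n, p = des$p,
                  floor = floor_, dropped = des0$dropped,
                  ll_trace = ll_trace))
}

componentTriple <- function(vc) {
  if (is(vc, "RemlFit")) {
    if (vc@model != "univariate") stop("univariate components required")
    list(theta = vc@theta, vcov = vc@vcovTheta)
  } else {
    th <- vc
    if (is.null(names(th))) names(th) <- c("s2a", "s2c", "s2e")
    list(theta = th[c("s2a", "s2c", "s2e")], vcov = NULL)
  }
}

ratioEstimator <- function(vc, which) {
  ct <- componentTriple(vc)
  th <- ct$theta
  if (any(th < 0)) stop("negative variance component")
  S <- sum(th)
  if (S <= 0) stop("all components zero: ratio undefined")
  est <- th[[which]] / S
  se <- NA_real_
  if (!is.null(ct$vcov) && !anyNA(ct$vcov)) {
    ## delta method: d(num/S)/d theta_j = (S*1[j==num] - num) / S^2
    g <- -th[[which]] / S^2 + (names(th) == which) / S
    v <- as.numeric(t(g) %*% ct$vcov %*% g)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  list(estimate = unname(est), se = se)
}

#' Heritability from variance components
#'
#' `h2 = s2a / (s2a + s2c + s2e)`, with a delta-method SE from the
#' asymptotic covariance of the components when available.
#'
#' @param vc a univariate [RemlFit-class] or a named numeric
#'   `c(s2a, s2c, s2e)`.
#' @return list with `estimate` and `se`.
#' @export
heritability <- function(vc) ratioEstimator(vc, "s2a")

#' Common full-sib effect from variance components
#'
#' `c2 = s2c / (s2a + s2c + s2e)`; the fraction of phenotypic variance due
#' to maternal plus common rearing-environment effects shared by full sibs.
#'
#' @inheritParams heritability
#' @return list with `estimate` and `se`.
#' @export
commonFullsibEffect <- function(vc) ratioEstimator(vc, "s2c")

#' Likelihood-ratio test for a variance component on the boundary
#'
#' Tests a single variance component (e.g. the common full-sib `s2c`)
#' by `2 * (logLik_full - logLik_reduced)` referred to the 50:50 mixture of
#' a point mass at zero and a 1-df chi-square — the null value lies on the
#' boundary of the parameter space, so the naive 1-df reference would be
#' conservative.
#'
#' @param full,reduced [RemlFit-class] objects (or numeric log-likelihoods)
#'   for the nested pair differing by one variance component.
#' @param tol tolerance for a numerically negative statistic.
#' @return list with `statistic`, `p_value`, `warning` flag.
#' @export
lrtVarianceComponent <- function(full, reduced, tol = 1e-6) {
  llf <- if (is(full, "RemlFit")) full@logLik else as.numeric(full)
  llr <- if (is(reduced, "RemlFit")) reduced@logLik else as.numeric(reduced)
  stat <- 2 * (llf - llr)
  warn <- FALSE
  if (stat < -tol) {
    warning("full model log-likelihood below reduced model: p set to 1")
    return(list(statistic = stat, p_value = 1, warning = TRUE))
  }
  stat <- max(stat, 0)
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (stat == 0) p <- 0.5
  list(statistic = stat, p_value = p, warning = warn)
}
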