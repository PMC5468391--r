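#' Henderson's mixed-model equations
#'
#' Assembles the coefficient matrix and right-hand side of the mixed-model
#' equations for `y = Xb + Za + Wc + e` in variance-ratio form:
#'
#' \preformatted{
#'   | X'X      X'Z              X'W         | | b |   | X'y |
#'   | Z'X      Z'Z + Ainv a1    Z'W         | | a | = | Z'y |
#'   | W'X      W'Z              W'W + I a2  | | c |   | W'y |
#' }
#'
#' with `a1 = s2e/s2a` on the A-inverse block and `a2 = s2e/s2c` on the
#' family identity block. Omit the family term by passing `W = NULL`, which
#' reduces the system to the two-block animal-model equations.
#'
#' @param y response vector.
#' @param X fixed-effect matrix (full column rank).
#' @param Z animal incidence matrix (records x pedigree animals).
#' @param W family incidence matrix or `NULL`.
#' @param Ainv sparse A-inverse from [aInverse()].
#' @param s2a,s2c,s2e variance components (all strictly positive; `s2c`
#'   ignored when `W` is `NULL`).
#' @return an `MMESystem` list: `C` (sparse symmetric), `rhs`, block index
#'   vectors and the variance ratios.
#' @export
assembleMME <- function(y, X, Z, W, Ainv, s2a, s2c = NULL, s2e) {
  if (s2a <= 0 || s2e <= 0 || (!is.null(W) && (is.null(s2c) || s2c <= 0))) {
    stop("variance components must be strictly positive")
  }
  X <- Matrix::Matrix(X, sparse = TRUE)
  alpha1 <- s2e / s2a
  alpha2 <- if (!is.null(W)) s2e / s2c else NA_real_
  T_ <- if (is.null(W)) cbind(X, Z) else cbind(X, Z, W)
  C <- Matrix::forceSymmetric(Matrix::crossprod(T_))
  p <- ncol(X); q <- ncol(Z); f <- if (is.null(W)) 0L else ncol(W)
  ia <- p + seq_len(q)
  C[ia, ia] <- C[ia, ia] + Ainv * alpha1
  if (f > 0) {
    ic <- p + q + seq_len(f)
    C[ic, ic] <- C[ic, ic] + Matrix::Diagonal(f) * alpha2
  }
  rhs <- as.numeric(Matrix::crossprod(T_, y))
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs,
                 n = length(y), p = p, q = q, f = f,
                 alpha1 = alpha1, alpha2 = alpha2,
                 fixed_labels = colnames(X),
                 animal_labels = colnames(Z),
                 family_labels = if (f > 0) colnames(W) else character(0),
                 y = y, T = T_),
            class = "MMESystem")
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky solve (fill-reducing permutation) of the
#' assembled system, returning BLUE of the fixed effects and BLUP of the
#' animal (EBV) and family effects, together with the relative residual of
#' the normal equations as a convergence diagnostic.
#'
#' @param sys an `MMESystem` from [assembleMME()].
#' @return list with `b` (named fixed-effect solutions), `a` (named EBVs
#'   for every pedigree animal), `c` (named family solutions), `residual`
#'   (relative residual norm) and the Cholesky factor (reused by
#'   [pevReliability()]).
#' @export
solveMME <- function(sys) {
  ch <- Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, sys$rhs))
  res <- as.numeric(sys$C %*% sol) - sys$rhs
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(sys$rhs^2)), .Machine$double.eps)
  b <- sol[seq_len(sys$p)]
  names(b) <- sys$fixed_labels
  a <- sol[sys$p + seq_len(sys$q)]
  names(a) <- sys$animal_labels
  cc <- if (sys$f > 0) {
    v <- sol[sys$p + sys$q + seq_len(sys$f)]
    names(v) <- sys$family_labels
    v
  } else numeric(0)
  list(b = b, a = a, c = cc, residual = rel, chol = ch, solution = sol)
}

#' Prediction-error variance and reliability of EBVs
#'
#' For animal i, `PEV_i = Caa_ii * s2e` where `Caa` is the animal-block
#' diagonal of the inverse mixed-model coefficient matrix, and
#' `reliability_i = 1 - PEV_i / ((1 + F_i) * s2a)`. Diagonals of the
#' inverse are obtained exactly by per-animal sparse triangular solves, so
#' any subset of animals can be requested without densifying the system.
#'
#' @param sys an `MMESystem`.
#' @param fit the output of [solveMME()] on `sys` (for its Cholesky
#'   factor); recomputed when omitted.
#' @param s2a,s2e the variance components used to assemble the system.
#' @param F inbreeding coefficients aligned with the animal block (0 when
#'   omitted).
#' @param animals animal identifiers to report (default: all).
#' @return `data.frame` with animal, PEV and reliability (clamped to
#'   `[0, 1]`).
#' @export
pevReliability <- function(sys, fit = NULL, s2a, s2e, F = NULL,
                           animals = NULL) {
  if (is.null(fit)) fit <- solveMME(sys)
  labels <- sys$animal_labels
  if (is.null(animals)) animals <- labels
  j <- match(animals, labels)
  if (anyNA(j)) stop("unknown animal: ", animals[which(is.na(j))[1L]])
  if (is.null(F)) F <- numeric(sys$q)
  ch <- fit$chol
  ntot <- sys$p + sys$q + sys$f
  pev <- numeric(length(j))
  for (k in seq_along(j)) {
    e <- numeric(ntot)
    e[sys$p + j[k]] <- 1
    pev[k] <- sum(e * as.numeric(Matrix::solve(ch, e))) * s2e
  }
  rel <- 1 - pev / ((1 + F[j]) * s2a)
  data.frame(animal = animals, pev = pev,
             reliability = pmin(pmax(rel, 0), 1))
}
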