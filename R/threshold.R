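#' Logit sire-model GLMM for binary survival
#'
#' Fits survival (0/1, present at harvest) by a generalized linear mixed
#' model with logit link, random sire and common full-sib family
#' intercepts, and the same fixed structure as the body-trait animal model
#' (generation, sex, their interaction, age within sex-by-generation,
#' stocking weight). Estimation is Laplace approximation via
#' [lme4::glmer()]. On the logit scale the residual variance is the
#' logistic variance pi^2/3.
#'
#' @param data phenotype `data.frame` (all stocked fish, survivors or not).
#' @param ped a [Pedigree-class] (provides each animal's sire).
#' @param environment `"pond"` or `"cage"`; `NULL` for all records.
#' @param age_covariate,stock_covariate include the covariates.
#' @return object of class `LogitSireFit`: list with `s2s` (sire variance),
#'   `s2c` (family variance), `h2_logit` (from [logitHeritability()]),
#'   `p` (observed survivor proportion), `n`, `converged`, and the
#'   underlying `glmer` fit.
#' @export
fitLogitSireModel <- function(data, ped, environment = NULL,
                              age_covariate = TRUE, stock_covariate = TRUE) {
  dd <- data
  if (!is.null(environment)) dd <- dd[dd$environment == environment, , drop = FALSE]
  dd <- dd[!is.na(dd$survival), , drop = FALSE]
  if (!nrow(dd)) stop("no survival records")
  if (length(unique(dd$survival)) < 2L) {
    stop("survival has no variation (all ",
         unique(dd$survival)[1L], "); nothing to estimate")
  }
  idx <- match(dd$animal, pedIds(ped))
  if (anyNA(idx)) stop("phenotyped animal missing from pedigree")
  sire_idx <- ped@sire[idx]
  known <- !is.na(sire_idx)
  if (!all(known)) {
    dd <- dd[known, , drop = FALSE]
    sire_idx <- sire_idx[known]
  }
  spec <- modelSpec("survival", environment = environment,
                    age_covariate = age_covariate,
                    stock_covariate = stock_covariate,
                    animal = FALSE, family = FALSE, sire = TRUE)
  X <- buildFixedMatrix(dd, spec)
  Xr <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  mdat <- data.frame(y = dd$survival,
                     sire = pedIds(ped)[sire_idx],
                     fam = dd$family, stringsAsFactors = FALSE)
  mdat$Xr <- Xr
  form <- if (ncol(Xr)) y ~ Xr + (1 | sire) + (1 | fam)
          else y ~ 1 + (1 | sire) + (1 | fam)
  fit <- lme4::glmer(form, data = mdat, family = stats::binomial("logit"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2s <- vc$vcov[vc$grp == "sire"]
  s2c <- vc$vcov[vc$grp == "fam"]
  conv <- length(fit@optinfo$conv$lme4) == 0L
  structure(list(s2s = s2s, s2c = s2c,
                 h2_logit = logitHeritability(s2s, s2c),
                 p = mean(dd$survival), n = nrow(dd),
                 environment = environment, converged = conv, fit = fit),
            class = "LogitSireFit")
}

#' @export
print.LogitSireFit <- function(x, ...) {
  cat(sprintf(paste0("Logit sire model%s: n = %d, survival = %.3f\n",
                     "  s2_sire = %.4f, s2_family = %.4f (logit scale, ",
                     "residual pi^2/3)\n  h2 = %.3f%s\n"),
              if (!is.null(x$environment)) paste0(" (", x$environment, ")") else "",
              x$n, x$p, x$s2s, x$s2c, x$h2_logit,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' Sire-model heritability on the logit scale
#'
#' `h2 = 4 * s2s / (s2s + s2c + pi^2/3)`: the sire variance captures a
#' quarter of the additive variance, and the logistic link fixes the
#' residual variance at pi^2/3 (~3.29).
#'
#' @param s2s sire variance (logit scale).
#' @param s2c common full-sib variance (logit scale).
#' @return heritability estimate.
#' @export
logitHeritability <- function(s2s, s2c) {
  if (s2s < 0 || s2c < 0) stop("negative variance component")
  den <- s2s + s2c + pi^2 / 3
  if (den <= 0) stop("zero denominator")
  4 * s2s / den
}

#' Observed / liability scale conversion for a binary trait
#'
#' Threshold-model conversion between the observed (0/1) scale and the
#' underlying liability scale for a trait with incidence `p`, where
#' `z = dnorm(qnorm(1 - p))` is the normal density at the threshold that
#' cuts off proportion `p`. Two directions are exposed and are exact
#' inverses of each other:
#'
#' * `"as_applied"` (default): multiply by `z^2 / (p (1 - p))`. This factor
#'   is at most `2/pi` (attained at p = 0.5), so the result never exceeds
#'   the input.
#' * `"as_printed"`: multiply by `p (1 - p) / z^2` (the classical
#'   observed-to-liability direction of Robertson-Lerner / Dempster-Lerner
#'   as usually printed).
#'
#' The same conversion applies to the common full-sib fraction `c2`.
#'
#' @param h2 heritability (or c2) to convert, in `[0, 1]`.
#' @param p incidence (survivor proportion), strictly inside (0, 1).
#' @param direction `"as_applied"` or `"as_printed"`.
#' @return converted value.
#' @export
observedLiabilityTransform <- function(h2, p,
                                       direction = c("as_applied",
                                                     "as_printed")) {
  direction <- match.arg(direction)
  if (any(p <= 0) || any(p >= 1)) stop("incidence p must be inside (0, 1)")
  if (any(h2 < 0) || any(h2 > 1)) stop("h2 must be in [0, 1]")
  z <- stats::dnorm(stats::qnorm(1 - p))
  fac <- z^2 / (p * (1 - p))
  if (direction == "as_applied") h2 * fac else h2 / fac
}
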