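#' Genetic trend from estimated breeding values
#'
#' Cohort-mean EBVs by generation (spawning year), expressed as change
#' from a reference cohort in trait units and in genetic-standard-deviation
#' units (`sigma_A = sqrt(s2a)`). The reference is the base cohort by
#' default; `baseline = "first_selected_cohort"` instead zeroes the first
#' cohort after the base, for programs whose base precedes recording.
#'
#' @param ebvs named numeric vector of EBVs (e.g. [ebv()] of a
#'   [RemlFit-class], or one column of a bivariate fit's `solutions$a`).
#' @param ped the [Pedigree-class] supplying each animal's cohort.
#' @param s2a additive variance of the matching fit; `sigma_A`-unit values
#'   are `NA` when `s2a` is zero.
#' @param baseline reference cohort convention.
#' @param animals optional subset of animal ids to average over (e.g. only
#'   animals tested in one environment); default all animals with an EBV.
#' @param drop_founders exclude cohorts before the base population (the
#'   founder parents, which form no test cohort).
#' @return `data.frame` with generation, n, mean_ebv, actual (change from
#'   baseline) and sigma_a columns.
#' @export
geneticTrend <- function(ebvs, ped, s2a,
                         baseline = c("base_cohort", "first_selected_cohort"),
                         animals = NULL, drop_founders = TRUE) {
  baseline <- match.arg(baseline)
  ids <- names(ebvs)
  if (is.null(ids)) stop("ebvs must be a named vector")
  if (!is.null(animals)) {
    ebvs <- ebvs[ids %in% animals]
    ids <- names(ebvs)
  }
  gen <- ped@generation[match(ids, pedIds(ped))]
  if (anyNA(gen)) stop("animal without pedigree cohort")
  if (drop_founders) {
    nonf <- !(is.na(ped@sire) & is.na(ped@dam))
    keep <- ids %in% pedIds(ped)[nonf]
    ebvs <- ebvs[keep]; gen <- gen[keep]
  }
  mu <- tapply(ebvs, gen, mean)
  nn <- tapply(ebvs, gen, length)
  gens <- as.integer(names(mu))
  ref <- switch(baseline,
                base_cohort = 1L,
                first_selected_cohort = min(2L, length(mu)))
  actual <- as.numeric(mu - mu[ref])
  sig <- if (s2a > 0) actual / sqrt(s2a) else rep(NA_real_, length(actual))
  data.frame(generation = gens, n = as.integer(nn),
             mean_ebv = as.numeric(mu), actual = actual, sigma_a = sig)
}

#' Assemble a selection-response table across traits
#'
#' Binds per-trait [geneticTrend()] results into one long table per
#' environment and generation, in the shape of a direct-plus-correlated
#' response report (selection trait first, correlated traits after).
#'
#' @param trends named list: `trends[[environment]][[trait]]` is a
#'   [geneticTrend()] data.frame.
#' @return `data.frame` with environment, generation, trait, actual,
#'   sigma_a.
#' @export
correlatedResponseTable <- function(trends) {
  out <- list()
  for (env in names(trends)) {
    for (tr in names(trends[[env]])) {
      td <- trends[[env]][[tr]]
      out[[length(out) + 1L]] <- data.frame(
        environment = env, generation = td$generation, trait = tr,
        actual = td$actual, sigma_a = td$sigma_a,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
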