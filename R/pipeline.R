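## End-to-end orchestration: simulate -> analyze -> report, with plain CSV
## and JSON artifacts. Every output embeds the seed and a configuration
## hash so a run is reproducible from its own logs.

fnv1aHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte keeps everything inside double-safe 32-bit range
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Simulate a breeding program to files
#'
#' Runs [simulateBreedingProgram()] and writes `pedigree.csv`,
#' `phenotypes.csv`, `truth.json` and `run_info.json` (seed + config hash)
#' to `out_dir`.
#'
#' @param cfg a [simulationConfig()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the simulation list.
#' @export
cmdSimulate <- function(cfg = simulationConfig(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateBreedingProgram(cfg, seed = seed)
  utils::write.csv(as.data.frame(sim$pedigree),
                   file.path(out_dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(list(seed = seed, config_hash = fnv1aHash(cfg)),
                       file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sim)
}

#' Run the full genetic analysis sequence
#'
#' Reproduces the study's analysis chain on a pedigree/phenotype pair,
#' separately per environment: descriptive statistics, univariate REML per
#' trait (variance components, h2, c2, family-effect likelihood-ratio
#' test), within-environment genetic/phenotypic correlations with harvest
#' weight, cross-environment genetic correlations per trait, the logit
#' sire model for survival with observed/liability conversions, and
#' EBV genetic trends (direct response in weight, correlated responses in
#' the other traits). Failing stages are recorded and the remaining stages
#' still run.
#'
#' @param pedigree a [Pedigree-class] or path to a pedigree CSV.
#' @param phenotypes phenotype `data.frame` or path to CSV.
#' @param out_dir output directory for `results.json` and CSV tables
#'   (`NULL` to skip writing).
#' @param traits traits to analyze.
#' @param environments environments to analyze.
#' @param seed recorded in outputs (analysis itself is deterministic).
#' @param liability_direction passed to [observedLiabilityTransform()].
#' @param baseline passed to [geneticTrend()].
#' @param trend_animals `"tested"` restricts cohort means to animals tested
#'   in that environment, `"all"` uses every pedigree animal.
#' @param correlations,cross_env,survival_glmm,trends stage switches.
#' @return list of results (also serialized to JSON when `out_dir` given).
#' @export
cmdAnalyze <- function(pedigree, phenotypes, out_dir = NULL,
                       traits = c("weight", "length", "width", "depth"),
                       environments = c("pond", "cage"), seed = NULL,
                       liability_direction = "as_applied",
                       baseline = "base_cohort",
                       trend_animals = c("tested", "all"),
                       correlations = TRUE, cross_env = TRUE,
                       survival_glmm = TRUE, trends = TRUE) {
  trend_animals <- match.arg(trend_animals)
  ped <- if (is(pedigree, "Pedigree")) pedigree else readPedigree(pedigree)
  phen <- if (is.data.frame(phenotypes)) validatePhenotypes(phenotypes, ped)
          else readPhenotypes(phenotypes, ped)
  res <- list(seed = seed, errors = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  res$descriptives <- stage("descriptives", summarizePhenotypes(phen))

  fits <- list()
  uni <- list()
  for (env in environments) {
    for (tr in c(traits, "survival")) {
      key <- paste(env, tr, sep = ".")
      row <- stage(paste0("univariate.", key), {
        fit <- remlFit(phen, modelSpec(tr, environment = env,
                                       animal = TRUE, family = TRUE),
                       ped)
        fit0 <- remlFit(phen, modelSpec(tr, environment = env,
                                        animal = TRUE, family = FALSE),
                        ped, se = FALSE)
        lrt <- lrtVarianceComponent(fit, fit0)
        h <- heritability(fit); cc <- commonFullsibEffect(fit)
        fits[[key]] <- fit
        data.frame(environment = env, trait = tr,
                   V_A = fit@theta[["s2a"]], V_C = fit@theta[["s2c"]],
                   V_E = fit@theta[["s2e"]],
                   h2 = h$estimate, h2_se = h$se,
                   c2 = cc$estimate, c2_se = cc$se,
                   logLik = fit@logLik, converged = fit@converged,
                   lrt_c2_stat = lrt$statistic, lrt_c2_p = lrt$p_value)
      })
      if (!is.null(row)) uni[[key]] <- row
    }
  }
  res$univariate <- if (length(uni)) do.call(rbind, uni)

  if (correlations) {
    res$correlations <- list()
    for (env in environments) {
      res$correlations[[env]] <- stage(paste0("correlations.", env),
        correlationsWithinEnv(phen, ped, env, traits = traits, se = TRUE)
        [c("genetic", "genetic_se", "phenotypic", "phenotypic_se")])
    }
  }

  if (cross_env && all(c("pond", "cage") %in% environments)) {
    ce <- list()
    for (tr in traits) {
      ce[[tr]] <- stage(paste0("cross_env.", tr), {
        fit <- remlBivariateCrossEnv(phen, tr, ped)
        co <- geneticCorrelation(fit)
        fits[[paste0("cross.", tr)]] <- fit
        list(r_g = co$genetic$estimate, se = co$genetic$se,
             converged = fit@converged)
      })
    }
    res$cross_env <- ce
  }

  if (survival_glmm) {
    res$survival <- list()
    for (env in environments) {
      res$survival[[env]] <- stage(paste0("survival.", env), {
        gl <- fitLogitSireModel(phen, ped, environment = env)
        lin <- fits[[paste(env, "survival", sep = ".")]]
        h_obs <- if (!is.null(lin)) heritability(lin)$estimate else NA_real_
        list(p = gl$p, s2_sire = gl$s2s, s2_family = gl$s2c,
             h2_logit = gl$h2_logit,
             h2_observed = h_obs,
             h2_liability = if (is.finite(h_obs))
               observedLiabilityTransform(h_obs, gl$p,
                                          direction = liability_direction)
             else NA_real_,
             liability_direction = liability_direction,
             converged = gl$converged)
      })
    }
  }

  if (trends) {
    tl <- list()
    for (env in environments) {
      tl[[env]] <- list()
      for (tr in traits) {
        key <- paste(env, tr, sep = ".")
        tl[[env]][[tr]] <- stage(paste0("trend.", key), {
          fit <- fits[[key]]
          if (is.null(fit)) stop("no univariate fit for ", key)
          subset_ids <- if (trend_animals == "tested")
            phen$animal[phen$environment == env] else NULL
          geneticTrend(ebv(fit), ped, fit@theta[["s2a"]],
                       baseline = baseline, animals = subset_ids)
        })
      }
    }
    res$trends <- stage("trend.table", correlatedResponseTable(tl))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$univariate)) {
      utils::write.csv(res$univariate,
                       file.path(out_dir, "variance_components.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$trends)) {
      utils::write.csv(res$trends, file.path(out_dir, "genetic_trends.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$descriptives)) {
      utils::write.csv(res$descriptives,
                       file.path(out_dir, "descriptives.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  res
}

#' Render a plain-text analysis report
#'
#' Formats the output of [cmdAnalyze()] (or its serialized
#' `results.json`) as readable tables: descriptives, variance components
#' and ratios, correlations, cross-environment genetic correlations,
#' survival threshold results and genetic trends. Sections that were not
#' run render as "not run". Pure function of its input: rendering twice
#' gives identical text.
#'
#' @param results list from [cmdAnalyze()] or path to `results.json`.
#' @param file optional path to write the report to.
#' @return the report, invisibly, as a character vector of lines.
#' @export
cmdReport <- function(results, file = NULL) {
  if (is.character(results)) results <- jsonlite::read_json(results,
                                                            simplifyVector = TRUE)
  out <- character(0)
  say <- function(...) out <<- c(out, sprintf(...))
  hdr <- function(t) { say(""); say("== %s ==", t) }
  fmt_df <- function(df) c(utils::capture.output(print(df, row.names = FALSE,
                                                       digits = 4)))
  hdr("Descriptive statistics")
  if (!is.null(results$descriptives)) {
    out <- c(out, fmt_df(as.data.frame(results$descriptives)))
  } else say("not run")
  hdr("Variance components, h2 and c2")
  if (!is.null(results$univariate)) {
    out <- c(out, fmt_df(as.data.frame(results$univariate)))
  } else say("not run")
  hdr("Within-environment correlations (genetic below, SE in parens)")
  if (!is.null(results$correlations)) {
    for (env in names(results$correlations)) {
      say("-- %s", env)
      rg <- results$correlations[[env]]$genetic
      if (!is.null(rg)) out <- c(out, fmt_df(as.data.frame(rg))) else say("failed")
    }
  } else say("not run")
  hdr("Cross-environment genetic correlations")
  if (!is.null(results$cross_env)) {
    for (tr in names(results$cross_env)) {
      x <- results$cross_env[[tr]]
      if (!is.null(x$r_g)) say("%-8s r_g = %6.3f (SE %s)", tr, x$r_g,
                               ifelse(is.null(x$se) || !is.finite(x$se), "NA",
                                      sprintf("%.3f", x$se)))
    }
  } else say("not run")
  hdr("Survival (threshold model)")
  if (!is.null(results$survival)) {
    for (env in names(results$survival)) {
      x <- results$survival[[env]]
      say("%-5s p = %.3f  h2_logit = %.3f  h2_obs = %.3f  h2_liab = %.3f",
          env, x$p, x$h2_logit,
          ifelse(is.null(x$h2_observed), NA, x$h2_observed),
          ifelse(is.null(x$h2_liability), NA, x$h2_liability))
    }
  } else say("not run")
  hdr("Genetic trends (change from baseline cohort)")
  if (!is.null(results$trends)) {
    out <- c(out, fmt_df(as.data.frame(results$trends)))
  } else say("not run")
  if (length(results$errors)) {
    hdr("Stage errors")
    for (nm in names(results$errors)) say("%s: %s", nm, results$errors[[nm]])
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
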