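#' Read a phenotype table
#'
#' Columns: `animal, environment, weight, length, width, depth, survival,
#' age_days, stock_weight, sex, generation, family`; `"NA"` marks missing
#' values. Survival is coded 1 for fish present at harvest and 0 for fish
#' absent; body-trait measurements are expected only on survivors, while
#' survival itself is recorded for every stocked, tagged fish.
#'
#' @param path file path.
#' @param ped optional [Pedigree-class]; when supplied, every animal must
#'   have a pedigree record and appear in exactly one environment.
#' @param sep field separator.
#' @return a validated `data.frame`.
#' @export
readPhenotypes <- function(path, ped = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = "NA", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  validatePhenotypes(df, ped)
}

#' @rdname readPhenotypes
#' @param data a data.frame in the phenotype layout.
#' @export
validatePhenotypes <- function(data, ped = NULL) {
  need <- c("animal", "environment", "survival", "sex", "generation", "family")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  }
  data$animal <- as.character(data$animal)
  data$environment <- as.character(data$environment)
  if (!all(data$environment %in% c("pond", "cage"))) {
    stop("environment must be 'pond' or 'cage'")
  }
  if (!all(stats::na.omit(data$survival) %in% c(0, 1))) {
    stop("survival must be coded 0/1")
  }
  if (anyDuplicated(data$animal)) {
    stop(sprintf("animal '%s' has more than one record (tested twice?)",
                 data$animal[duplicated(data$animal)][1L]))
  }
  if (!is.null(ped)) {
    absent <- setdiff(data$animal, pedIds(ped))
    if (length(absent)) {
      stop(sprintf("animal '%s' has a phenotype but no pedigree record",
                   absent[1L]))
    }
  }
  data
}

#' Descriptive statistics per trait and environment
#'
#' n, mean, SD and CV% (`100 * SD / mean`) per trait within each
#' environment. The survival row reports the mean as a percentage and omits
#' the CV; a zero trait mean leaves CV missing.
#'
#' @param data phenotype `data.frame` (see [readPhenotypes()]).
#' @param traits trait columns to summarize.
#' @return `data.frame` with columns environment, trait, n, mean, sd, cv.
#' @export
summarizePhenotypes <- function(data,
                                traits = c("weight", "length", "width",
                                           "depth", "survival")) {
  traits <- intersect(traits, names(data))
  out <- do.call(rbind, lapply(split(data, data$environment), function(dd) {
    do.call(rbind, lapply(traits, function(tr) {
      x <- dd[[tr]]
      x <- x[!is.na(x)]
      n <- length(x)
      if (tr == "survival") {
        data.frame(environment = dd$environment[1L], trait = tr, n = n,
                   mean = 100 * mean(x), sd = 100 * stats::sd(x),
                   cv = NA_real_)
      } else {
        m <- mean(x); s <- stats::sd(x)
        data.frame(environment = dd$environment[1L], trait = tr, n = n,
                   mean = m, sd = s,
                   cv = if (isTRUE(all.equal(m, 0))) NA_real_ else 100 * s / m)
      }
    }))
  }))
  rownames(out) <- NULL
  out
}
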