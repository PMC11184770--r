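# Published baseline counts of the EpiSS GWAS subcohort, used to anchor the
# synthetic generator's covariate marginals and to recompute the headline
# cohort percentages.

#' Baseline categorical counts of the EpiSS GWAS subcohort
#'
#' Counts of the 1,684 genotyped participants by salt-sensitivity status
#' and by the categorical covariates the risk models adjust for. These are
#' the published cohort margins the synthetic generator emulates.
#'
#' @return data.frame `variable`, `level`, `count`.
#' @export
episs_baseline_counts <- function() {
  data.frame(
    variable = c("ssbp", "ssbp",
                 "sex", "sex",
                 "smoking", "smoking",
                 "diabetes", "diabetes",
                 "hypertension", "hypertension"),
    level = c("SR", "SS", "women", "men", "no", "yes", "no", "yes",
              "no", "yes"),
    count = c(1199L, 485L, 1237L, 447L, 1426L, 258L, 1414L, 270L,
              834L, 850L),
    stringsAsFactors = FALSE)
}

#' Recompute baseline percentages from the counts
#'
#' @param counts A counts data.frame as returned by
#'   [episs_baseline_counts()].
#' @param digits Rounding of the percentage (default 1, the reporting
#'   convention).
#' @return data.frame `variable`, `level`, `count`, `pct` where `pct` is
#'   the within-variable percentage.
#' @export
baseline_percentages <- function(counts = episs_baseline_counts(),
                                 digits = 1) {
  totals <- tapply(counts$count, counts$variable, sum)
  counts$pct <- round(100 * counts$count /
                        as.numeric(totals[counts$variable]), digits)
  counts
}
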