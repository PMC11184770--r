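#' Power of a one-stage case-control genetic association test
#'
#' Computes the power of the 1-df allele (or Cochran-Armitage trend) test for
#' a biallelic variant in a one-stage case-control design, following the
#' classical genetic-association power calculation: baseline penetrance is
#' solved from the disease prevalence, the disease allele frequency and the
#' genotype relative risk under a chosen mode of inheritance; genotype
#' frequencies in cases and controls are then derived by Bayes' rule under
#' Hardy-Weinberg equilibrium, and the power of the two-sided test at level
#' `alpha` follows from the normal approximation to the allele-frequency
#' difference.
#'
#' @param n_cases Number of cases.
#' @param n_controls Number of controls.
#' @param alpha Two-sided significance level.
#' @param daf Disease (risk) allele frequency in the population, in (0, 1).
#' @param prevalence Disease prevalence in the population, in (0, 1).
#' @param grr Genotype relative risk (per-allele risk ratio for the
#'   multiplicative model), > 0.
#' @param model Mode of inheritance: `"multiplicative"` (default),
#'   `"additive"`, `"dominant"` or `"recessive"`. Under the multiplicative
#'   model the heterozygote relative risk is `grr` and the risk-homozygote
#'   relative risk is `grr^2`; under the additive model it is `2*grr - 1`;
#'   dominant and recessive use `grr` for carrier / risk-homozygote only.
#' @param test `"allele"` (default; 2N alleles compared between groups) or
#'   `"trend"` (Cochran-Armitage trend test on genotype counts).
#'
#' @return A list of class `"gwas_power"` with elements `power`,
#'   `penetrance` (length-3 vector for 0/1/2 risk alleles), `geno_freq_cases`,
#'   `geno_freq_controls`, and the case/control risk-allele frequencies.
#' @examples
#' gwas_power(485, 1199, alpha = 1e-5, daf = 0.358,
#'            prevalence = 0.35, grr = 1.58)$power
#' @export
gwas_power <- function(n_cases, n_controls, alpha, daf, prevalence, grr,
                       model = c("multiplicative", "additive", "dominant",
                                 "recessive"),
                       test = c("allele", "trend")) {
  model <- match.arg(model)
  test <- match.arg(test)
  stopifnot(n_cases >= 1, n_controls >= 1)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (!(daf > 0 && daf < 1)) stop("daf must be in (0,1)")
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be in (0,1)")
  if (!(grr > 0)) stop("grr must be > 0")

  p <- daf
  g <- c((1 - p)^2, 2 * p * (1 - p), p^2)   # genotype freqs, 0/1/2 risk alleles
  rr <- switch(model,
    multiplicative = c(1, grr, grr^2),
    additive       = c(1, grr, 2 * grr - 1),
    dominant       = c(1, grr, grr),
    recessive      = c(1, 1, grr))
  f0 <- prevalence / sum(g * rr)
  f <- f0 * rr
  if (any(f <= 0) || any(f >= 1))
    stop("infeasible parameters: penetrance outside (0,1)")

  K <- prevalence
  gc_case <- f * g / K
  gc_ctrl <- (1 - f) * g / (1 - K)

  z <- stats::qnorm(1 - alpha / 2)
  if (test == "allele") {
    p1 <- gc_case[3] + gc_case[2] / 2    # risk-allele freq in cases
    p0 <- gc_ctrl[3] + gc_ctrl[2] / 2
    m1 <- 2 * n_cases
    m0 <- 2 * n_controls
    pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
    se0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m0))
    seA <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
    delta <- p1 - p0
  } else {
    # Cochran-Armitage trend with scores (0,1,2) on genotype proportions
    x <- c(0, 1, 2)
    mu1 <- sum(x * gc_case)
    mu0 <- sum(x * gc_ctrl)
    v1 <- sum(x^2 * gc_case) - mu1^2
    v0 <- sum(x^2 * gc_ctrl) - mu0^2
    w <- n_cases * n_controls / (n_cases + n_controls)
    gbar <- (n_cases * gc_case + n_controls * gc_ctrl) /
      (n_cases + n_controls)
    vbar <- sum(x^2 * gbar) - sum(x * gbar)^2
    se0 <- sqrt(vbar * (1 / n_cases + 1 / n_controls))
    seA <- sqrt(v1 / n_cases + v0 / n_controls)
    delta <- mu1 - mu0
    w # unused; kept for clarity of the pooled variance
  }
  pow <- stats::pnorm((delta - z * se0) / seA) +
    stats::pnorm((-delta - z * se0) / seA)
  structure(list(power = pow,
                 penetrance = f,
                 geno_freq_cases = gc_case,
                 geno_freq_controls = gc_ctrl,
                 allele_freq_cases = gc_case[3] + gc_case[2] / 2,
                 allele_freq_controls = gc_ctrl[3] + gc_ctrl[2] / 2,
                 model = model, test = test),
            class = "gwas_power")
}

#' @export
print.gwas_power <- function(x, ...) {
  cat(sprintf("Case-control association power (%s model, %s test)\n",
              x$model, x$test))
  cat(sprintf("  power: %.3f\n", x$power))
  cat(sprintf("  risk-allele freq cases/controls: %.4f / %.4f\n",
              x$allele_freq_cases, x$allele_freq_controls))
  invisible(x)
}
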