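# Genotype/sample quality control, additive-model case-control association,
# and greedy LD clumping.

#' Quality-control thresholds
#'
#' Defaults are the conventional chip-QC values for this study design: SNP
#' call rate >= 0.95, MAF >= 0.01, Hardy-Weinberg exact P >= 1e-4, sample
#' call rate >= 0.95, heterozygosity within mean +/- 6 SD, pairwise
#' PI_HAT <= 0.25, sex chromosomes dropped.
#'
#' @param snp_call_rate,maf_min,hwe_p_min,sample_call_rate,het_sd,pi_hat_max
#'   Numeric thresholds; see Description.
#' @param drop_sex_chromosomes Drop variants with chr outside 1-22.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, maf_min = 0.01,
                          hwe_p_min = 1e-4, sample_call_rate = 0.95,
                          het_sd = 6, pi_hat_max = 0.25,
                          drop_sex_chromosomes = TRUE) {
  thr <- list(snp_call_rate = snp_call_rate, maf_min = maf_min,
              hwe_p_min = hwe_p_min, sample_call_rate = sample_call_rate,
              het_sd = het_sd, pi_hat_max = pi_hat_max,
              drop_sex_chromosomes = isTRUE(drop_sex_chromosomes))
  with(thr, stopifnot(snp_call_rate >= 0, snp_call_rate <= 1,
                      maf_min >= 0, maf_min <= 0.5,
                      hwe_p_min >= 0, hwe_p_min <= 1,
                      sample_call_rate >= 0, sample_call_rate <= 1,
                      het_sd > 0, pi_hat_max >= 0, pi_hat_max <= 1))
  structure(thr, class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions: with allele
#' counts fixed, the P value is the sum of the probabilities of every
#' attainable heterozygote count whose probability does not exceed that of
#' the observed count (plain exact formulation, not mid-p).
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts.
#' @return P value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration: P = 1
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be > 0")
  n_minor <- 2 * n_hom_minor + n_het          # rarer-allele count wlog
  n_major <- 2 * n_hom_major + n_het
  if (n_minor > n_major) { tmp <- n_minor; n_minor <- n_major; n_major <- tmp }
  hets <- seq(n_minor %% 2, n_minor, by = 2)  # attainable het counts
  # log P(n_het = h | allele counts) up to a constant
  logp <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- n - h - aa
    h * log(2) - lfactorial(AA) - lfactorial(h) - lfactorial(aa)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant-level quality control
#'
#' Retains variants passing, in order: autosomal location, call rate, minor
#' allele frequency, and Hardy-Weinberg exact P. Each excluded variant is
#' reported with the first rule it failed.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param thr A [qc_thresholds()].
#' @return List with `geno` (filtered) and `report` (data.frame
#'   `variant_id`, `reason`).
#' @export
snp_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "ssbp_geno"))
  d <- geno$dosage
  if (ncol(d) == 0) stop("empty genotype matrix")
  n <- nrow(d)
  call_rate <- 1 - colSums(is.na(d)) / n
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  reason <- rep(NA_character_, ncol(d))
  if (thr$drop_sex_chromosomes)
    reason[!(geno$map$chr %in% 1:22)] <- "sex_chromosome"
  sel <- is.na(reason) & call_rate < thr$snp_call_rate
  reason[sel] <- "call_rate"
  sel <- is.na(reason) & maf < thr$maf_min
  reason[sel] <- "maf"
  todo <- which(is.na(reason))
  for (j in todo) {
    x <- d[, j]
    x <- x[!is.na(x)]
    p <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    if (p < thr$hwe_p_min) reason[j] <- "hwe"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("all variants excluded by QC: empty panel")
  report <- data.frame(variant_id = geno$map$variant_id[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  out <- geno
  out$dosage <- d[, keep, drop = FALSE]
  out$map <- geno$map[keep, , drop = FALSE]
  out$block <- geno$block[keep]
  list(geno = out, report = report)
}

# PLINK-style method-of-moments IBD estimation from IBS counts.
# Computed on variants with no missingness across the given samples;
# allele frequencies taken from those samples.
estimate_pi_hat <- function(dosage) {
  cc <- which(colSums(is.na(dosage)) == 0)
  d <- dosage[, cc, drop = FALSE]
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  M0 <- (d == 0) + 0; M1 <- (d == 1) + 0; M2 <- (d == 2) + 0
  ibs0 <- tcrossprod(M0, M2) + tcrossprod(M2, M0)
  ibs1 <- tcrossprod(M0, M1) + tcrossprod(M1, M0) +
    tcrossprod(M1, M2) + tcrossprod(M2, M1)
  ibs2 <- tcrossprod(M0, M0) + tcrossprod(M1, M1) + tcrossprod(M2, M2)
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_ibd1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_ibd1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  m <- length(p)
  P0 <- ibs0 / e0_ibd0
  P1 <- (ibs1 - P0 * e1_ibd0) / e1_ibd1
  P2 <- (ibs2 - P0 * e2_ibd0 - P1 * e2_ibd1) / m
  # only the final PI_HAT is clamped: truncating the per-state estimates at
  # zero would bias PI_HAT upward for unrelated pairs at moderate marker
  # counts
  pihat <- pmin(pmax(P1 / 2 + P2, 0), 1)
  diag(pihat) <- NA_real_
  dimnames(pihat) <- list(rownames(dosage), rownames(dosage))
  pihat
}

#' Sample-level quality control
#'
#' Removes samples failing call rate, samples whose heterozygosity rate is
#' more than `het_sd` SDs from the cohort mean, and, for every remaining
#' pair with method-of-moments PI_HAT above `pi_hat_max`, the member with
#' the lower call rate.
#'
#' @param geno An `"ssbp_geno"` object (ideally after [snp_qc()]).
#' @param thr A [qc_thresholds()].
#' @return List with `geno` (filtered) and `report` (data.frame
#'   `sample_id`, `reason`).
#' @export
sample_qc <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "ssbp_geno"))
  d <- geno$dosage
  if (nrow(d) < 2) stop("sample QC requires at least 2 samples")
  m <- ncol(d)
  call_rate <- 1 - rowSums(is.na(d)) / m
  het <- rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d))
  reason <- rep(NA_character_, nrow(d))
  reason[call_rate < thr$sample_call_rate] <- "call_rate"
  ok <- is.na(reason)
  mu <- mean(het[ok]); sdv <- stats::sd(het[ok])
  if (is.finite(sdv) && sdv > 0) {
    out_het <- ok & abs(het - mu) > thr$het_sd * sdv
    reason[out_het] <- "heterozygosity"
  }
  keep <- which(is.na(reason))
  if (length(keep) >= 2) {
    ph <- estimate_pi_hat(d[keep, , drop = FALSE])
    repeat {
      w <- which(ph > thr$pi_hat_max, arr.ind = TRUE)
      if (nrow(w) == 0) break
      pair <- keep[w[1, ]]
      drop_local <- w[1, which.min(call_rate[pair])]
      reason[keep[drop_local]] <- "relatedness"
      ph[drop_local, ] <- NA_real_
      ph[, drop_local] <- NA_real_
    }
  }
  keep <- is.na(reason)
  if (sum(keep) < 2) stop("fewer than 2 samples remain after QC")
  report <- data.frame(sample_id = rownames(d)[!keep],
                       reason = reason[!keep], stringsAsFactors = FALSE)
  out <- geno
  out$dosage <- d[keep, , drop = FALSE]
  list(geno = out, report = report)
}

#' Additive-model logistic association
#'
#' Per-variant logistic regression of case status on additive dosage plus
#' covariates, fitted by iteratively reweighted least squares. Missing
#' dosages are dropped per variant (complete case). Monomorphic variants
#' are skipped; separated or non-converged fits are flagged, not reported
#' as estimates.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param cohort Cohort data.frame with `sample_id`, the outcome column and
#'   the covariates.
#' @param covariate_names Character vector of covariate column names.
#' @param outcome Name of the binary outcome column; `"SS"`/`"SR"` or 0/1
#'   (default `"ssbp"`).
#' @return List with `summary`, a data.frame in GWAS summary layout
#'   (`variant_id`, `chr`, `bp`, `effect_allele`, `other_allele`, `beta`
#'   = ln OR per effect allele, `se`, `z`, `p` two-sided, `maf`, `n`), and
#'   `skipped` (data.frame `variant_id`, `reason`).
#' @export
assoc_additive <- function(geno, cohort,
                           covariate_names = c("age", "sex", "area",
                                               "hypertension", "fbg", "tg",
                                               "bmi"),
                           outcome = "ssbp") {
  stopifnot(inherits(geno, "ssbp_geno"))
  cohort <- cohort[match(rownames(geno$dosage), cohort$sample_id), ]
  if (any(is.na(cohort$sample_id)))
    stop("cohort does not cover all genotyped samples")
  y <- cohort[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.integer(y == "SS")
  if (length(unique(y)) < 2) stop("outcome must have both classes present")
  X0 <- stats::model.matrix(
    ~ ., data = cohort[, covariate_names, drop = FALSE])
  if (anyNA(X0)) stop("covariates must be complete")

  m <- ncol(geno$dosage)
  beta <- se <- rep(NA_real_, m)
  nn <- integer(m); maf <- rep(NA_real_, m)
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    g <- geno$dosage[, j]
    obs <- !is.na(g)
    gj <- as.numeric(g[obs])
    if (stats::var(gj) == 0) { reason[j] <- "zero variance"; next }
    X <- cbind(X0[obs, , drop = FALSE], dosage = gj)
    fit <- suppressWarnings(
      stats::glm.fit(X, y[obs], family = stats::binomial(),
                     control = list(epsilon = 1e-8, maxit = 50)))
    k <- ncol(X)
    cf <- fit$coefficients[k]
    vc <- tryCatch(chol2inv(chol(crossprod(
      X * sqrt(fit$weights)))), error = function(e) NULL)
    if (is.null(vc) || !fit$converged) { reason[j] <- "non-convergence"; next }
    sej <- sqrt(vc[k, k])
    if (!is.finite(cf) || abs(cf) > 15 || sej > 100) {
      reason[j] <- "separation"; next
    }
    beta[j] <- cf; se[j] <- sej
    nn[j] <- sum(obs)
    af <- mean(gj) / 2
    maf[j] <- min(af, 1 - af)
  }
  ok <- is.na(reason)
  summ <- data.frame(
    variant_id = geno$map$variant_id[ok],
    chr = geno$map$chr[ok], bp = geno$map$bp[ok],
    effect_allele = geno$map$a1[ok], other_allele = geno$map$a2[ok],
    beta = beta[ok], se = se[ok], z = beta[ok] / se[ok],
    p = 2 * stats::pnorm(-abs(beta[ok] / se[ok])),
    maf = maf[ok], n = nn[ok], stringsAsFactors = FALSE)
  skipped <- data.frame(variant_id = geno$map$variant_id[!ok],
                        reason = reason[!ok], stringsAsFactors = FALSE)
  list(summary = summ, skipped = skipped)
}

#' Greedy LD clumping of GWAS results
#'
#' Repeatedly takes the lowest-P unassigned variant with `p <= p_index` as
#' an index variant and assigns every unassigned variant within `window_kb`
#' on the same chromosome with dosage r-squared at least `r2_max` to its
#' clump.
#'
#' @param summary GWAS summary data.frame (needs `variant_id`, `chr`, `bp`,
#'   `p`).
#' @param geno_ref `"ssbp_geno"` LD reference sharing variant ids.
#' @param r2_max r-squared threshold for clump membership.
#' @param window_kb Window half-width in kilobases.
#' @param p_index Index-variant significance threshold.
#' @return data.frame `variant_id`, `index` (its clump's index variant),
#'   `is_index`; empty when nothing passes `p_index`.
#' @export
clump <- function(summary, geno_ref, r2_max = 0.5, window_kb = 250,
                  p_index = 1e-5) {
  stopifnot(inherits(geno_ref, "ssbp_geno"))
  if (!all(summary$variant_id %in% colnames(geno_ref$dosage)))
    stop("summary and LD reference must share variant ids")
  cand <- summary[order(summary$p), ]
  assigned <- character(0)
  rows <- list()
  d <- geno_ref$dosage
  repeat {
    avail <- cand[!(cand$variant_id %in% assigned) & cand$p <= p_index, ]
    if (nrow(avail) == 0) break
    idx <- avail[1, ]
    near <- summary[summary$chr == idx$chr &
                      abs(summary$bp - idx$bp) <= window_kb * 1000 &
                      !(summary$variant_id %in% assigned) &
                      summary$variant_id != idx$variant_id, ]
    members <- idx$variant_id
    if (nrow(near)) {
      r2 <- as.numeric(stats::cor(d[, idx$variant_id],
                                  d[, near$variant_id, drop = FALSE],
                                  use = "pairwise.complete.obs"))^2
      members <- c(members, near$variant_id[!is.na(r2) & r2 >= r2_max])
    }
    assigned <- c(assigned, members)
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = members, index = idx$variant_id,
      is_index = members == idx$variant_id, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(variant_id = character(0), index = character(0),
                      is_index = logical(0)))
  do.call(rbind, rows)
}
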