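# Synthetic cohort generators: genotypes, eQTL weight panels, expression,
# and the saline-loading phenotype with its SS/SR classification rule.

#' Classify salt sensitivity from a MAP triplet
#'
#' A participant is salt sensitive (SS) when mean arterial pressure rises by
#' at least 5 mmHg after acute saline loading (`map2 - map1 >= 5`) or falls
#' by at least 10 mmHg after diuresis (`map3 - map2 <= -10`); otherwise salt
#' resistant (SR).
#'
#' @param map1,map2,map3 Numeric vectors of mean arterial pressure (mmHg) at
#'   baseline, 2h post saline load, and 2h post diuresis.
#' @return Character vector of `"SS"` / `"SR"`.
#' @examples
#' classify_ssbp(90, 96, 95)    # "SS": rise of 6 mmHg
#' classify_ssbp(100, 103, 98)  # "SR"
#' @export
classify_ssbp <- function(map1, map2, map3) {
  n <- length(map1)
  if (length(map2) != n || length(map3) != n)
    stop("classification error: MAP vectors must have equal length")
  if (any(!is.finite(map1)) || any(!is.finite(map2)) || any(!is.finite(map3)))
    stop("classification error: missing or non-finite MAP value")
  ifelse((map2 - map1 >= 5) | (map3 - map2 <= -10), "SS", "SR")
}

# Standard bivariate normal lower-quadrant probability P(Z1 <= h, Z2 <= k)
# by numerical integration of the conditional normal; adequate for the
# copula calibration below (|error| << 1e-6).
pbinorm <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z)
    stats::dnorm(z) * stats::pnorm((k - rho * z) / s),
    lower = -8, upper = h, rel.tol = 1e-10)$value
}

# Latent Gaussian correlation such that two alleles thresholded at frequency
# maf have phi coefficient (= dosage correlation) equal to target_r.
calibrate_latent_rho <- function(maf, target_r) {
  if (target_r <= 0) return(0)
  t <- stats::qnorm(maf)
  phi_of <- function(rho)
    (pbinorm(t, t, rho) - maf^2) / (maf * (1 - maf)) - target_r
  # phi is increasing in rho, phi(1) = 1 for equal thresholds
  stats::uniroot(phi_of, c(1e-6, 1 - 1e-9), tol = 1e-8)$root
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Draws additive dosages in `{0, 1, 2}` under Hardy-Weinberg equilibrium.
#' Within each LD block of `cfg$ld_block_size` consecutive variants, the two
#' haplotypes of every sample are generated from an exchangeable Gaussian
#' copula whose latent correlation is calibrated so that realized pairwise
#' dosage correlation is close to `cfg$within_block_corr`; blocks are
#' mutually independent. Blocks never straddle chromosomes.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `"ssbp_geno"`: a list with `dosage`
#'   (samples x variants integer matrix, dimnames set) and `map`
#'   (data.frame: `variant_id`, `chr`, `bp` 1-based, `a1` counted/minor
#'   allele, `a2`).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 1L))
  n <- cfg$n_samples
  m <- cfg$n_variants
  bs <- cfg$ld_block_size
  n_block <- ceiling(m / bs)
  block_of <- rep(seq_len(n_block), each = bs)[seq_len(m)]

  # geometry: ~50 blocks per chromosome, 10 kb spacing
  blocks_per_chr <- 50L
  chr_of_block <- ((seq_len(n_block) - 1L) %/% blocks_per_chr) %% 22L + 1L
  chr <- chr_of_block[block_of]
  bp <- integer(m)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    bp[idx] <- seq_along(idx) * 10000L
  }

  # block-level MAF with mild jitter: variants in strong LD share allele
  # frequencies, and near-equal thresholds keep the copula calibration tight
  block_maf <- stats::runif(n_block, cfg$maf_range[1], cfg$maf_range[2])
  maf <- block_maf[block_of] * exp(stats::rnorm(m, 0, 0.05))
  maf <- pmin(pmax(maf, cfg$maf_range[1]), cfg$maf_range[2])
  dosage <- matrix(0L, n, m)
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), "")

  for (b in seq_len(n_block)) {
    idx <- which(block_of == b)
    k <- length(idx)
    r <- cfg$within_block_corr
    if (r > 0 && k > 1) {
      rho <- calibrate_latent_rho(mean(maf[idx]), r)
      sr <- sqrt(rho); se <- sqrt(1 - rho)
      hap <- function() {
        s <- stats::rnorm(n)
        z <- sr * s + se * matrix(stats::rnorm(n * k), n, k)
        sweep(z, 2, stats::qnorm(maf[idx]), "<=") + 0L
      }
    } else {
      hap <- function()
        sweep(matrix(stats::rnorm(n * k), n, k), 2,
              stats::qnorm(maf[idx]), "<=") + 0L
    }
    dosage[, idx] <- hap() + hap()
  }
  storage.mode(dosage) <- "integer"
  vid <- sprintf("snp%05d", seq_len(m))
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(n)), vid)
  map <- data.frame(variant_id = vid, chr = chr, bp = bp,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  structure(list(dosage = dosage, map = map, block = block_of),
            class = "ssbp_geno")
}

#' @export
print.ssbp_geno <- function(x, ...) {
  cat(sprintf("ssbp_geno: %d samples x %d variants (chr %s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(range(x$map$chr), collapse = "-")))
  invisible(x)
}

# contiguous cis windows for gene placement; errors when genes do not fit
gene_windows <- function(cfg) {
  win <- max(2L * cfg$cis_snps_per_gene, 4L)
  if (cfg$n_genes * win > cfg$n_variants)
    stop(sprintf(
      "cannot place %d genes: %d variants support at most %d loci of %d variants",
      cfg$n_genes, cfg$n_variants, cfg$n_variants %/% win, win))
  starts <- floor(seq(1, cfg$n_variants - win + 1, length.out = cfg$n_genes))
  data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
             first = as.integer(starts),
             last = as.integer(starts + win - 1L))
}

#' Simulate a sparse cis-eQTL weight panel
#'
#' Places `cfg$n_genes` genes on contiguous cis windows of the variant grid
#' and, for every (gene, tissue) pair, draws up to `cfg$cis_snps_per_gene`
#' nonzero variant weights from N(0, `effect_size_sd`^2), mimicking the
#' content of a FUSION-style per-tissue weight file. Each entry carries a
#' fitted-model label and a cross-validation R2.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param cfg The [sim_config()] used to generate it.
#' @return An object of class `"weight_panel"`: list with `weights`
#'   (data.frame: `gene_id`, `tissue`, `variant_id`, `effect_allele`,
#'   `weight`, `model`, `cv_r2`) and `genes` (data.frame: `gene_id`, `chr`,
#'   `start`, `end` in bp). Attribute `n_nonzero` records the generator's
#'   own count of nonzero weights.
#' @export
simulate_weight_panel <- function(geno, cfg) {
  stopifnot(inherits(geno, "ssbp_geno"))
  set.seed(sim_seed(cfg, 2L))
  gw <- gene_windows(cfg)
  map <- geno$map
  genes <- data.frame(gene_id = gw$gene_id,
                      chr = map$chr[gw$first],
                      start = map$bp[gw$first],
                      end = map$bp[gw$last])
  # keep each gene's window on one chromosome
  for (i in seq_len(nrow(gw))) {
    idx <- gw$first[i]:gw$last[i]
    idx <- idx[map$chr[idx] == map$chr[gw$first[i]]]
    gw$last[i] <- max(idx)
    genes$end[i] <- map$bp[gw$last[i]]
  }
  models <- c("top1", "lasso", "enet", "ridge")
  out <- vector("list", nrow(gw) * length(cfg$tissues))
  k <- 0L
  n_nonzero <- 0L
  for (i in seq_len(nrow(gw))) {
    window <- gw$first[i]:gw$last[i]
    for (tis in cfg$tissues) {
      nw <- min(cfg$cis_snps_per_gene, length(window))
      pick <- sort(sample(window, nw))
      w <- stats::rnorm(nw, 0, cfg$effect_size_sd)
      n_nonzero <- n_nonzero + sum(w != 0)
      k <- k + 1L
      out[[k]] <- data.frame(
        gene_id = gw$gene_id[i], tissue = tis,
        variant_id = map$variant_id[pick],
        effect_allele = map$a1[pick],
        weight = w,
        model = sample(models, 1L),
        cv_r2 = max(0, min(1, stats::rnorm(1, cfg$expr_h2, 0.05))),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(weights = do.call(rbind, out), genes = genes),
            class = "weight_panel", n_nonzero = n_nonzero)
}

#' @export
print.weight_panel <- function(x, ...) {
  cat(sprintf("weight_panel: %d genes x %d tissues, %d weight rows\n",
              nrow(x$genes), length(unique(x$weights$tissue)),
              nrow(x$weights)))
  invisible(x)
}

#' Simulate expression as cis-genetic component plus noise
#'
#' For every gene, expression is
#' `standardize(G w) * sqrt(h2) + e * sqrt(1 - h2)` with `e ~ N(0, 1)`, so
#' the realized genetic variance fraction approximates `cfg$expr_h2`. A gene
#' whose genetic component has zero variance gets pure noise.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param panel A `"weight_panel"`; weights of `tissue` are used.
#' @param cfg The [sim_config()].
#' @param tissue Tissue whose weights drive expression (default: first).
#' @return Numeric matrix, genes x samples, log-scale expression.
#' @export
simulate_expression <- function(geno, panel, cfg, tissue = cfg$tissues[1]) {
  stopifnot(inherits(geno, "ssbp_geno"), inherits(panel, "weight_panel"))
  h2 <- cfg$expr_h2
  if (!is.finite(h2) || h2 < 0 || h2 > 1) stop("expr_h2 must be in [0, 1]")
  set.seed(sim_seed(cfg, 3L))
  W <- panel$weights[panel$weights$tissue == tissue, , drop = FALSE]
  if (!all(W$variant_id %in% colnames(geno$dosage)))
    stop("panel variants must be a subset of genotype variants")
  gvals <- genetic_component(geno, W)
  n <- nrow(geno$dosage)
  expr <- matrix(NA_real_, nrow(panel$genes), n,
                 dimnames = list(panel$genes$gene_id, rownames(geno$dosage)))
  for (g in panel$genes$gene_id) {
    gc <- gvals[, g]
    s <- stats::sd(gc)
    gc <- if (s > 0) (gc - mean(gc)) / s else rep(0, n)
    expr[g, ] <- gc * sqrt(h2) + stats::rnorm(n) * sqrt(1 - h2)
  }
  expr
}

# samples x genes matrix of raw genetic components G w
genetic_component <- function(geno, weights) {
  genes <- unique(weights$gene_id)
  out <- matrix(0, nrow(geno$dosage), length(genes),
                dimnames = list(rownames(geno$dosage), genes))
  for (g in genes) {
    w <- weights[weights$gene_id == g, ]
    G <- geno$dosage[, w$variant_id, drop = FALSE]
    out[, g] <- as.numeric(G %*% w$weight)
  }
  out
}

#' Simulate the saline-loading phenotype and covariates
#'
#' Baseline MAP is drawn around 97.3 mmHg (SD 12). The two MAP deltas
#' (`map2 - map1` and `map3 - map2`) carry planted additive effects of
#' `cfg$n_causal_snps` variants and `cfg$n_causal_genes` gene expressions
#' plus Gaussian noise (`cfg$delta_sd`). The salt-load delta intercept is
#' calibrated by 1-D root finding so that the expected SS prevalence under
#' the classification rule equals `cfg$target_ss_prevalence` (tolerance
#' 1e-3). Covariates are drawn to match the source cohort's marginal
#' distributions (73.5% women, median age 59, etc.) and are independent of
#' genotype.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param expr Genes x samples expression matrix (may be `NULL` when
#'   `cfg$n_causal_genes == 0`).
#' @param cfg The [sim_config()].
#' @param delta1_intercept,delta2_intercept Optional fixed intercepts
#'   (mmHg); supplying `delta1_intercept` bypasses prevalence calibration.
#' @return A data.frame cohort with columns `sample_id`, `age`, `sex`
#'   (1 = female), `bmi`, `education` (ordinal 1 illiteracy .. 6
#'   postgraduate), `smoking`, `diabetes`, `hypertension`, `map1`, `map2`,
#'   `map3`, `ssbp`, plus `area` (study centre 1-11), `fbg`, `tg` used as
#'   association covariates. Attributes `causal_snps`, `causal_genes`,
#'   `snp_effects`, `gene_effects`, `delta_intercepts`.
#' @export
simulate_phenotype <- function(geno, expr, cfg,
                               delta1_intercept = NULL,
                               delta2_intercept = -2) {
  stopifnot(inherits(geno, "ssbp_geno"))
  set.seed(sim_seed(cfg, 4L))
  n <- nrow(geno$dosage)
  m <- ncol(geno$dosage)
  if (cfg$n_causal_snps > m)
    stop("n_causal_snps exceeds the number of variants")

  causal_snps <- if (cfg$n_causal_snps > 0)
    sort(sample(m, cfg$n_causal_snps)) else integer(0)
  beta_snp <- stats::rnorm(length(causal_snps), 0, cfg$effect_size_sd)
  g1 <- if (length(causal_snps))
    as.numeric(geno$dosage[, causal_snps, drop = FALSE] %*% beta_snp)
  else rep(0, n)

  causal_genes <- character(0)
  beta_gene <- numeric(0)
  if (cfg$n_causal_genes > 0) {
    if (is.null(expr)) stop("expression matrix required for causal genes")
    if (cfg$n_causal_genes > nrow(expr))
      stop("n_causal_genes exceeds the number of genes")
    causal_genes <- sort(sample(rownames(expr), cfg$n_causal_genes))
    beta_gene <- stats::rnorm(length(causal_genes), 0, cfg$effect_size_sd)
    g1 <- g1 + as.numeric(t(expr[causal_genes, , drop = FALSE]) %*% beta_gene)
  }
  g1 <- g1 - mean(g1)
  g2 <- -0.5 * g1   # diuresis response opposes the salt-load response

  sd1 <- cfg$delta_sd
  b2 <- delta2_intercept
  expected_prev <- function(a)
    mean(1 - stats::pnorm((5 - a - g1) / sd1) *
           stats::pnorm((b2 + g2 + 10) / sd1))
  if (is.null(delta1_intercept)) {
    lo <- -10 * sd1; hi <- 10 * sd1
    if (expected_prev(lo) > cfg$target_ss_prevalence ||
        expected_prev(hi) < cfg$target_ss_prevalence)
      stop("calibration error: target prevalence unattainable at this noise scale")
    delta1_intercept <- stats::uniroot(
      function(a) expected_prev(a) - cfg$target_ss_prevalence,
      c(lo, hi), tol = 1e-6)$root
    # calibration tolerance on expected prevalence: 1e-3
    stopifnot(abs(expected_prev(delta1_intercept) -
                    cfg$target_ss_prevalence) < 1e-3)
  }

  map1 <- stats::rnorm(n, 97.3, 12)
  d1 <- delta1_intercept + g1 + stats::rnorm(n, 0, sd1)
  d2 <- b2 + g2 + stats::rnorm(n, 0, sd1)
  map2 <- map1 + d1
  map3 <- map2 + d2
  stopifnot(all(map1 > 0), all(map2 > 0), all(map3 > 0))

  edu_prob <- c(0.010, 0.100, 0.391, 0.312, 0.152, 0.034)
  cohort <- data.frame(
    sample_id = rownames(geno$dosage),
    age = rnorm_trunc(n, 59, 7, 35, 70),
    sex = stats::rbinom(n, 1, 0.735),             # 1 = female
    bmi = rnorm_trunc(n, 25.9, 3.3, 15, 45),
    education = sample(1:6, n, replace = TRUE, prob = edu_prob),
    smoking = stats::rbinom(n, 1, 0.153),
    diabetes = stats::rbinom(n, 1, 0.160),
    hypertension = stats::rbinom(n, 1, 0.505),
    map1 = map1, map2 = map2, map3 = map3,
    stringsAsFactors = FALSE)
  cohort$ssbp <- classify_ssbp(cohort$map1, cohort$map2, cohort$map3)
  cohort$area <- sample(1:11, n, replace = TRUE)
  cohort$fbg <- exp(stats::rnorm(n, log(5.4), 0.12))
  cohort$tg <- exp(stats::rnorm(n, log(1.6), 0.4))
  attr(cohort, "causal_snps") <- colnames(geno$dosage)[causal_snps]
  attr(cohort, "causal_genes") <- causal_genes
  attr(cohort, "snp_effects") <- beta_snp
  attr(cohort, "gene_effects") <- beta_gene
  attr(cohort, "delta_intercepts") <- c(delta1_intercept, b2)
  cohort
}

# truncated normal draw by rejection (bounds several SD out, so cheap)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}
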