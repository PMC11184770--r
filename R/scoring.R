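# PRS and PTRS at serial P thresholds, PCA-weighted score combination and
# quartile binning.

#' Scoring configuration
#'
#' @param p_thresholds Strictly decreasing P-value thresholds defining the
#'   nested variant/gene subsets (default 0.05, 0.01, 0.001, 0.0001).
#' @param missing_policy `"mean_impute"` substitutes `2 * MAF` for a missing
#'   dosage; `"drop"` omits it from the sample's sum.
#' @param standardize_expression Standardize predicted expression per gene
#'   before use in the PTRS (default TRUE; predicted expression is on an
#'   arbitrary scale).
#' @return List of class `"score_config"`.
#' @export
score_config <- function(p_thresholds = c(0.05, 0.01, 0.001, 0.0001),
                         missing_policy = c("mean_impute", "drop"),
                         standardize_expression = TRUE) {
  if (any(diff(p_thresholds) >= 0))
    stop("p_thresholds must be strictly decreasing")
  structure(list(p_thresholds = p_thresholds,
                 missing_policy = match.arg(missing_policy),
                 standardize_expression = isTRUE(standardize_expression)),
            class = "score_config")
}

#' Select PRS variants from TWAS results
#'
#' For every (gene, tissue) with TWAS `p < threshold`, takes (a) the
#' lowest-P GWAS variant inside the gene's locus bounds and (b) the gene's
#' best eQTL, deduplicates variant ids across genes and tissues, and
#' attaches each variant's GWAS effect size (ln OR). Variants absent from
#' the genotype data are dropped and counted.
#'
#' @param twas TWAS results ([twas_assoc()] columns, incl. locus bounds and
#'   `best_eqtl_id`).
#' @param gwas GWAS summary data.frame.
#' @param threshold TWAS P threshold.
#' @param available_variants Optional character vector of genotyped variant
#'   ids; selected variants outside it are dropped with a logged count.
#' @return data.frame `variant_id`, `effect_allele`, `beta`, `maf`;
#'   attribute `n_dropped` counts unmatched variants.
#' @export
select_prs_snps <- function(twas, gwas, threshold,
                            available_variants = NULL) {
  hits <- twas[twas$p < threshold, , drop = FALSE]
  picks <- character(0)
  for (i in seq_len(nrow(hits))) {
    loc <- gwas[gwas$chr == hits$chr[i] & gwas$bp >= hits$start[i] &
                  gwas$bp <= hits$end[i], , drop = FALSE]
    if (nrow(loc) > 0)
      picks <- c(picks, loc$variant_id[which.min(loc$p)])
    picks <- c(picks, hits$best_eqtl_id[i])
  }
  picks <- unique(picks)
  in_gwas <- picks %in% gwas$variant_id
  n_dropped <- sum(!in_gwas)
  picks <- picks[in_gwas]
  if (!is.null(available_variants)) {
    avail <- picks %in% available_variants
    n_dropped <- n_dropped + sum(!avail)
    picks <- picks[avail]
  }
  idx <- match(picks, gwas$variant_id)
  out <- data.frame(variant_id = picks,
                    effect_allele = gwas$effect_allele[idx],
                    beta = gwas$beta[idx], maf = gwas$maf[idx],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

# align a dosage matrix to the requested effect alleles (2 - G on mismatch)
align_dosage <- function(geno, variant_id, effect_allele) {
  G <- geno$dosage[, variant_id, drop = FALSE]
  a1 <- geno$map$a1[match(variant_id, geno$map$variant_id)]
  flip <- which(a1 != effect_allele)
  if (length(flip)) G[, flip] <- 2L - G[, flip]
  G
}

#' Compute the polygenic risk score
#'
#' `PRS_j = sum_i beta_i * G_ij` over the selected variants, with dosage
#' counted on each variant's effect allele and `beta` the GWAS ln OR.
#'
#' @param geno `"ssbp_geno"` with the score variants.
#' @param snp_betas data.frame from [select_prs_snps()] (`variant_id`,
#'   `effect_allele`, `beta`, optionally `maf` for imputation).
#' @param cfg A [score_config()] governing missing-dosage handling.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_prs <- function(geno, snp_betas, cfg = score_config()) {
  if (nrow(snp_betas) == 0)
    stop("empty SNP set: no variant passes the requested threshold")
  if (any(!is.finite(snp_betas$beta))) stop("betas must be finite")
  miss <- setdiff(snp_betas$variant_id, colnames(geno$dosage))
  if (length(miss))
    stop(sprintf("variants absent from genotypes: %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  G <- align_dosage(geno, snp_betas$variant_id, snp_betas$effect_allele)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    if (cfg$missing_policy == "mean_impute") {
      fill <- if (!is.null(snp_betas$maf)) 2 * snp_betas$maf
        else colMeans(G, na.rm = TRUE)
      for (j in which(colSums(is.na(G)) > 0))
        G[is.na(G[, j]), j] <- fill[j]
    } else {
      G[is.na(G)] <- 0
    }
  }
  drop(G %*% snp_betas$beta)[rownames(geno$dosage)]
}

#' Predict individual-level expression from a weight panel
#'
#' `T_gj = sum_i w_gi * G_ij` with dosages standardized across samples (the
#' weights are trained on standardized dosages), optionally followed by
#' per-gene standardization of the prediction.
#'
#' @param geno `"ssbp_geno"` target genotypes.
#' @param panel A `"weight_panel"`.
#' @param cfg A [score_config()]; `standardize_expression` controls the
#'   per-gene standardization.
#' @param standardize_dosage Standardize dosages before applying weights
#'   (default TRUE).
#' @return Numeric matrix samples x (gene, tissue) columns, column names
#'   `"<gene_id>|<tissue>"`; attribute `dropped_genes` lists (gene, tissue)
#'   pairs with no genotyped variant.
#' @export
predict_expression <- function(geno, panel, cfg = score_config(),
                               standardize_dosage = TRUE) {
  stopifnot(inherits(panel, "weight_panel"))
  W <- panel$weights
  keys <- unique(W[, c("gene_id", "tissue")])
  n <- nrow(geno$dosage)
  out <- matrix(NA_real_, n, nrow(keys),
                dimnames = list(rownames(geno$dosage),
                                paste(keys$gene_id, keys$tissue, sep = "|")))
  dropped <- character(0)
  for (i in seq_len(nrow(keys))) {
    w <- W[W$gene_id == keys$gene_id[i] & W$tissue == keys$tissue[i], ]
    have <- w$variant_id %in% colnames(geno$dosage)
    if (!any(have)) {
      dropped <- c(dropped, colnames(out)[i]); next
    }
    w <- w[have, , drop = FALSE]
    G <- align_dosage(geno, w$variant_id, w$effect_allele)
    storage.mode(G) <- "double"
    if (standardize_dosage) {
      mu <- colMeans(G, na.rm = TRUE)
      sdv <- apply(G, 2, stats::sd, na.rm = TRUE)
      sdv[sdv == 0] <- 1
      G <- sweep(sweep(G, 2, mu), 2, sdv, "/")
    }
    G[is.na(G)] <- 0
    tg <- drop(G %*% w$weight)
    if (cfg$standardize_expression) {
      s <- stats::sd(tg)
      tg <- if (s > 0) (tg - mean(tg)) / s else tg * 0
    }
    out[, i] <- tg
  }
  keep <- !(colnames(out) %in% dropped)
  out <- out[, keep, drop = FALSE]
  attr(out, "dropped_genes") <- dropped
  out
}

#' Compute the polygenic transcriptome risk score
#'
#' `PTRS_j = sum_g z_g * T_gj` over genes with TWAS `p < threshold`, where
#' `z_g` is the gene's TWAS z and `T` the predicted expression. Scope
#' `"aggregate"` sums every qualifying (gene, tissue) contribution;
#' `"tissue"` restricts to one tissue; `"deg_set"` uses a supplied gene
#' list instead of the threshold.
#'
#' @param pred Predicted-expression matrix from [predict_expression()].
#' @param twas TWAS results (`gene_id`, `tissue`, `z`, `p`).
#' @param threshold TWAS P threshold (ignored for `scope = "deg_set"`).
#' @param scope `"aggregate"`, `"tissue"` or `"deg_set"`.
#' @param tissue Tissue label for `scope = "tissue"`.
#' @param deg_genes Gene ids for `scope = "deg_set"`.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_ptrs <- function(pred, twas, threshold = 0.05,
                         scope = c("aggregate", "tissue", "deg_set"),
                         tissue = NULL, deg_genes = NULL) {
  scope <- match.arg(scope)
  sel <- switch(scope,
    aggregate = twas[twas$p < threshold, , drop = FALSE],
    tissue = {
      if (is.null(tissue)) stop("tissue scope requires a tissue label")
      twas[twas$p < threshold & twas$tissue == tissue, , drop = FALSE]
    },
    deg_set = {
      if (is.null(deg_genes)) stop("deg_set scope requires deg_genes")
      twas[twas$p < threshold & twas$gene_id %in% deg_genes, , drop = FALSE]
    })
  cols <- paste(sel$gene_id, sel$tissue, sep = "|")
  have <- cols %in% colnames(pred)
  sel <- sel[have, , drop = FALSE]; cols <- cols[have]
  if (nrow(sel) == 0)
    stop(sprintf(
      "empty gene set for PTRS at threshold %g (scope %s)", threshold, scope))
  drop(pred[, cols, drop = FALSE] %*% sel$z)
}

#' Combine PRS and PTRS with PCA-derived weights
#'
#' Both scores are standardized and a principal component analysis of their
#' 2 x 2 correlation matrix supplies the combination weights: each
#' eigenvector's sign is fixed so its loading on the first score (the PRS)
#' is nonnegative, each variable's weight is the eigenvalue-share-weighted
#' average of its loadings, and the two weights are normalized to sum to 1.
#' For standardized scores with correlation `rho >= 0` this reduces to
#' `c1 = 1 / (1 + rho)`, `c2 = rho / (1 + rho)`. A negative correlation is
#' combined on `|rho|` with a warning.
#'
#' @param prs,ptrs Numeric vectors, same samples, both non-constant.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return List `combined` (c1 * scale(prs) + c2 * scale(ptrs)), `c1`,
#'   `c2`, `rho`, `variance_share` (eigenvalue shares).
#' @export
combine_scores <- function(prs, ptrs, cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  if (length(prs) != length(ptrs) || length(prs) < 3)
    stop("scores must have equal length >= 3")
  if (stats::sd(prs) == 0 || stats::sd(ptrs) == 0)
    stop("constant score vector")
  rho <- stats::cor(prs, ptrs, method = cor_method)
  if (rho < 0) {
    warning("negative PRS-PTRS correlation; combining on |rho|")
    rho <- abs(rho)
  }
  C <- matrix(c(1, rho, rho, 1), 2)
  eig <- eigen(C, symmetric = TRUE)
  A <- eig$vectors
  # sign convention: nonnegative loading on the first variable
  for (k in 1:2) if (A[1, k] < 0) A[, k] <- -A[, k]
  share <- eig$values / sum(eig$values)
  w <- as.numeric(A %*% share)
  cw <- w / sum(w)
  z1 <- as.numeric(scale(prs)); z2 <- as.numeric(scale(ptrs))
  list(combined = cw[1] * z1 + cw[2] * z2,
       c1 = cw[1], c2 = cw[2], rho = rho, variance_share = share)
}

#' Quartile binning of a score
#'
#' Bins by the empirical 25th, 50th and 75th percentiles
#' (linear-interpolation quantile definition); values tied with a cut point
#' go to the lower bin.
#'
#' @param score Numeric vector, `n >= 4`, non-constant.
#' @param cuts Optional pre-computed cut points (e.g. from a training set).
#' @return Integer vector of bins 1-4; attribute `cuts`.
#' @export
quartile_bin <- function(score, cuts = NULL) {
  if (is.null(cuts)) {
    if (length(score) < 4) stop("need at least 4 values")
    if (stats::sd(score) == 0) stop("constant score vector")
    cuts <- stats::quantile(score, c(0.25, 0.5, 0.75), type = 7,
                            names = FALSE)
  }
  bins <- 1L + (score > cuts[1]) + (score > cuts[2]) + (score > cuts[3])
  attr(bins, "cuts") <- cuts
  bins
}
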