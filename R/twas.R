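# Summary-statistic TWAS: eQTL weight training (top1 / lasso / elastic-net /
# ridge with 5-fold CV model selection), the gene-level association
# z = w'z / sqrt(w'Rw), serial P thresholding, and locus-level conditional
# analysis on the joint normal of gene z-scores.

#' Train per-gene eQTL weight models
#'
#' For every gene, cis-window dosages are standardized and four expression
#' prediction models are fitted: `top1` (single best marginal eQTL),
#' `lasso`, elastic-net (`enet`, alpha = 0.5) and `ridge` (alpha = 0, a
#' best-linear-unbiased-predictor surrogate). The model with the highest
#' 5-fold cross-validated R2 is retained (ties broken in the order
#' top1 < lasso < enet < ridge); its nonzero weights and CV R2 populate the
#' weight panel.
#'
#' @param geno_ref `"ssbp_geno"` reference genotypes (>= 50 samples).
#' @param expr_ref Genes x samples expression matrix for the same samples.
#' @param genes Gene annotation data.frame (`gene_id`, `chr`, `start`,
#'   `end`); defaults to all rows of `expr_ref` require an annotation.
#' @param cis_window_kb cis window padding in kb around `[start, end]`.
#' @param models Subset of `c("top1", "lasso", "enet", "ridge")`.
#' @param tissue Tissue label stored in the panel.
#' @param seed Seed fixing the CV folds.
#' @return A `"weight_panel"` (see [simulate_weight_panel()]); genes with no
#'   polymorphic cis variant are skipped and listed in attribute `skipped`.
#' @export
train_weights <- function(geno_ref, expr_ref, genes, cis_window_kb = 500,
                          models = c("top1", "lasso", "enet", "ridge"),
                          tissue = "trained", seed = 1L) {
  stopifnot(inherits(geno_ref, "ssbp_geno"))
  if (nrow(geno_ref$dosage) < 50)
    stop("weight training requires at least 50 reference samples")
  models <- match.arg(models, several.ok = TRUE)
  set.seed(seed)
  map <- geno_ref$map
  out <- list(); skipped <- list()
  folds <- sample(rep_len(1:5, nrow(geno_ref$dosage)))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    cis <- which(map$chr == genes$chr[i] &
                   map$bp >= genes$start[i] - cis_window_kb * 1000 &
                   map$bp <= genes$end[i] + cis_window_kb * 1000)
    if (length(cis) == 0) {
      skipped[[gid]] <- "no cis variant"; next
    }
    G <- geno_ref$dosage[, cis, drop = FALSE]
    sds <- apply(G, 2, stats::sd)
    cis <- cis[sds > 0]; G <- G[, sds > 0, drop = FALSE]
    if (ncol(G) == 0) { skipped[[gid]] <- "no polymorphic cis variant"; next }
    Gs <- scale(G)
    y <- as.numeric(expr_ref[gid, ])
    fitted <- fit_expression_models(Gs, y, models, folds)
    best <- fitted$best
    w <- fitted$weights[[best]]
    nz <- which(w != 0)
    if (length(nz) == 0) { skipped[[gid]] <- "all-zero weights"; next }
    out[[gid]] <- data.frame(
      gene_id = gid, tissue = tissue,
      variant_id = map$variant_id[cis][nz],
      effect_allele = map$a1[cis][nz],
      weight = w[nz], model = best, cv_r2 = fitted$cv_r2[best],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no gene yielded a weight model")
  genes_kept <- genes[genes$gene_id %in% names(out), , drop = FALSE]
  structure(list(weights = do.call(rbind, out), genes = genes_kept),
            class = "weight_panel",
            skipped = unlist(skipped))
}

# fit the four expression models on standardized dosages and report 5-fold
# CV R2 per model; in-sample refit on all data supplies the weights
fit_expression_models <- function(Gs, y, models, folds) {
  weights <- list(); cv_r2 <- c()
  order_rank <- c(top1 = 1, lasso = 2, enet = 3, ridge = 4)
  predict_m <- function(model, Gtr, ytr, Gte) {
    if (model == "top1") {
      b <- as.numeric(crossprod(Gtr, ytr - mean(ytr))) / nrow(Gtr)
      k <- which.max(abs(b))
      w <- numeric(ncol(Gtr)); w[k] <- b[k]
      list(w = w, pred = mean(ytr) + Gte %*% w)
    } else {
      alpha <- c(lasso = 1, enet = 0.5, ridge = 0)[[model]]
      fit <- glmnet::cv.glmnet(Gtr, ytr, alpha = alpha, nfolds = 5,
                               standardize = FALSE)
      w <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
      list(w = w, pred = as.numeric(stats::predict(
        fit, newx = Gte, s = "lambda.min")))
    }
  }
  for (model in models) {
    pred <- rep(NA_real_, length(y))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      pr <- tryCatch(
        predict_m(model, Gs[tr, , drop = FALSE], y[tr],
                  Gs[!tr, , drop = FALSE]),
        error = function(e) NULL)
      pred[!tr] <- if (is.null(pr)) mean(y[tr]) else pr$pred
    }
    cv_r2[model] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    full <- tryCatch(predict_m(model, Gs, y, Gs), error = function(e) NULL)
    weights[[model]] <- if (is.null(full)) numeric(ncol(Gs)) else full$w
  }
  usable <- names(cv_r2)[vapply(weights, function(w) any(w != 0), TRUE)]
  if (length(usable) == 0) usable <- names(cv_r2)
  best <- usable[order(-cv_r2[usable], order_rank[usable])][1]
  list(best = best, weights = weights, cv_r2 = cv_r2)
}

#' Gene-level TWAS association from GWAS summary z-scores
#'
#' Computes `z_gene = w'z / sqrt(w'R w)` where `w` are the panel weights,
#' `z` the per-variant GWAS z-scores aligned to the panel's effect alleles,
#' and `R` the dosage correlation matrix from the LD reference, regularized
#' as `(1 - lambda) R + lambda I`.
#'
#' @param gwas GWAS summary data.frame (`variant_id`, `effect_allele`, `z`;
#'   other columns ignored).
#' @param panel A `"weight_panel"`.
#' @param ld_ref `"ssbp_geno"` LD reference covering the panel variants.
#' @param lambda Ridge regularization of the LD matrix (default 0.05).
#' @param locus_pad_kb Padding added to the weight-variant span to define
#'   the gene's locus bounds.
#' @return data.frame of class rows: `gene_id`, `tissue`, `z`, `p`,
#'   `best_eqtl_id`, `chr`, `start`, `end`.
#' @export
twas_assoc <- function(gwas, panel, ld_ref, lambda = 0.05,
                       locus_pad_kb = 100) {
  stopifnot(inherits(panel, "weight_panel"), inherits(ld_ref, "ssbp_geno"))
  zmap <- gwas$z; names(zmap) <- gwas$variant_id
  amap <- gwas$effect_allele; names(amap) <- gwas$variant_id
  map <- ld_ref$map
  rownames(map) <- map$variant_id
  keys <- unique(panel$weights[, c("gene_id", "tissue")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    w <- panel$weights[panel$weights$gene_id == keys$gene_id[i] &
                         panel$weights$tissue == keys$tissue[i], ]
    if (!all(w$variant_id %in% names(zmap)) ||
        !all(w$variant_id %in% colnames(ld_ref$dosage)))
      stop("panel variants must be present in GWAS summary and LD reference")
    z <- zmap[w$variant_id]
    flip <- amap[w$variant_id] != w$effect_allele
    z[flip] <- -z[flip]
    R <- stats::cor(ld_ref$dosage[, w$variant_id, drop = FALSE],
                    use = "pairwise.complete.obs")
    R <- (1 - lambda) * R + lambda * diag(nrow(R))
    denom <- as.numeric(t(w$weight) %*% R %*% w$weight)
    if (denom <= 1e-8) stop(sprintf(
      "degenerate weights for gene %s: w'Rw <= 1e-8", keys$gene_id[i]))
    zg <- sum(w$weight * z) / sqrt(denom)
    best <- w$variant_id[which.max(abs(w$weight) * abs(z))]
    locus_bp <- map[w$variant_id, "bp"]
    out[[i]] <- data.frame(
      gene_id = keys$gene_id[i], tissue = keys$tissue[i],
      z = zg, p = 2 * stats::pnorm(-abs(zg)), best_eqtl_id = best,
      chr = map[w$variant_id[1], "chr"],
      start = min(locus_bp) - locus_pad_kb * 1000,
      end = max(locus_bp) + locus_pad_kb * 1000,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Serial P-value thresholding of TWAS results
#'
#' @param results TWAS result data.frame from [twas_assoc()].
#' @param p_thresholds Decreasing significance thresholds.
#' @return Named list (one element per threshold) of lists with
#'   `gene_tissue` (the qualifying rows) and `genes` (deduplicated gene
#'   ids). Subsets are nested by construction.
#' @export
threshold_genes <- function(results,
                            p_thresholds = c(0.05, 0.01, 0.001, 0.0001)) {
  if (nrow(results) == 0) stop("empty TWAS results")
  if (any(diff(p_thresholds) >= 0))
    stop("thresholds must be strictly decreasing")
  out <- lapply(p_thresholds, function(th) {
    sub <- results[results$p < th, , drop = FALSE]
    list(gene_tissue = sub, genes = unique(sub$gene_id))
  })
  names(out) <- as.character(p_thresholds)
  out
}

#' Locus-level conditional analysis of TWAS signals
#'
#' Stepwise selection on the joint multivariate normal of gene z-scores:
#' the most significant gene enters first; each remaining gene's statistic
#' is recomputed conditional on the selected set,
#' `z_cond = (z_j - rho_jS solve(rho_SS) z_S) / sqrt(1 - rho_jS solve(rho_SS) rho_Sj)`,
#' and genes keep entering while the best conditional P is below `alpha`.
#'
#' @param results TWAS rows sharing one locus (`gene_id`, `z`).
#' @param rho Predicted-expression correlation matrix (genes x genes,
#'   dimnames = gene ids), positive semi-definite.
#' @param alpha Entry threshold on the conditional P (default 0.05).
#' @return List with `selected` (gene ids in entry order) and `conditional`
#'   (data.frame `gene_id`, `z_cond`, `p_cond` for non-selected genes).
#' @export
conditional_analysis <- function(results, rho, alpha = 0.05) {
  genes <- results$gene_id
  if (anyDuplicated(genes)) stop("one row per gene required")
  rho <- rho[genes, genes, drop = FALSE]
  z <- results$z; names(z) <- genes
  cond_stat <- function(j, S) {
    if (length(S) == 0) return(z[j])
    Rss <- rho[S, S, drop = FALSE]
    sol <- tryCatch(solve(Rss, cbind(z[S], rho[S, j])),
                    error = function(e) NULL)
    if (is.null(sol)) return(NA_real_)
    num <- z[j] - sum(rho[j, S] * sol[, 1])
    v <- 1 - sum(rho[j, S] * sol[, 2])
    if (v <= 1e-12) return(0)
    num / sqrt(v)
  }
  selected <- character(0)
  remaining <- genes
  repeat {
    if (length(remaining) == 0) break
    zc <- vapply(remaining, cond_stat, 0, S = selected)
    if (all(is.na(zc))) break
    best <- remaining[which.max(abs(zc))]
    pbest <- 2 * stats::pnorm(-abs(zc[best]))
    if (is.na(pbest) || pbest >= alpha) break
    # a singular correlation with the selected set drops the later gene
    Rtry <- rho[c(selected, best), c(selected, best), drop = FALSE]
    if (length(selected) > 0 &&
        rcond_sym(Rtry) < 1e-10) {
      warning(sprintf(
        "gene %s is collinear with the selected set and was dropped", best))
      remaining <- setdiff(remaining, best)
      next
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  zc <- vapply(remaining, cond_stat, 0, S = selected)
  list(selected = selected,
       conditional = data.frame(
         gene_id = remaining, z_cond = unname(zc),
         p_cond = 2 * stats::pnorm(-abs(unname(zc))),
         stringsAsFactors = FALSE))
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}
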