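# End-to-end orchestration: synthetic cohort -> QC -> GWAS -> TWAS ->
# differential expression -> PRS/PTRS scoring -> risk-model evaluation.

#' Run the full SSBP genetic risk pipeline on a synthetic cohort
#'
#' Generates a cohort from `cfg`, applies variant and sample QC, runs the
#' additive-model GWAS, computes gene-level TWAS associations from the
#' summary statistics and the simulated weight panel, tests differential
#' expression between SS and SR, builds PRS and PTRS at the serial P
#' thresholds (plus a PTRS over the TWAS/DEG overlap), combines each PRS
#' with the most significant PTRS by PCA weights, and evaluates every score
#' in covariate-adjusted quartile logistic models on a stratified 70/30
#' split.
#'
#' @param cfg A [sim_config()]. Its master seed drives every stage.
#' @param score_cfg A [score_config()].
#' @param outdir Optional directory: when given, all tables are written as
#'   TSV (deterministically, enabling byte-identical re-runs).
#' @param qc A [qc_thresholds()].
#' @return List with `cohort`, `geno` (post-QC), `gwas`, `twas`, `de`,
#'   `overlap`, `scores` (per-sample score table), `combine` (PCA weights
#'   per combined pair), `evaluation` ([evaluate_scores()] output), `cv`
#'   (10-fold cross-validation of the best PRS model).
#' @export
run_ssbp_pipeline <- function(cfg = sim_config(),
                              score_cfg = score_config(),
                              outdir = NULL,
                              qc = qc_thresholds()) {
  geno <- simulate_genotypes(cfg)
  panel <- simulate_weight_panel(geno, cfg)
  expr <- simulate_expression(geno, panel, cfg)
  cohort <- simulate_phenotype(geno, expr, cfg)

  sq <- snp_qc(geno, qc)
  smq <- sample_qc(sq$geno, qc)
  geno_qc <- smq$geno
  keep <- rownames(geno_qc$dosage)
  cohort_qc <- cohort[match(keep, cohort$sample_id), ]
  expr_qc <- expr[, keep, drop = FALSE]

  gw <- assoc_additive(geno_qc, cohort_qc)
  # weights on variants lost to QC or skipped in association are dropped;
  # genes left without any weight are excluded from the TWAS
  panel_qc <- restrict_panel(panel, gw$summary$variant_id)
  tw <- twas_assoc(gw$summary, panel_qc, geno_qc)
  th <- threshold_genes(tw, score_cfg$p_thresholds)

  de <- de_test(expr_qc, cohort_qc$ssbp)
  ov <- overlap_with_twas(de, tw)

  pred <- predict_expression(geno_qc, panel, score_cfg)
  scores <- data.frame(sample_id = keep, stringsAsFactors = FALSE)
  selected <- list()
  for (tname in as.character(score_cfg$p_thresholds)) {
    thv <- as.numeric(tname)
    snps <- select_prs_snps(tw, gw$summary, thv,
                            available_variants = colnames(geno_qc$dosage))
    if (nrow(snps) > 0) {
      selected[[tname]] <- snps
      scores[[paste0("prs_", tname)]] <-
        compute_prs(geno_qc, snps, score_cfg)
    }
    ptrs <- tryCatch(compute_ptrs(pred, tw, thv, scope = "aggregate"),
                     error = function(e) NULL)
    if (!is.null(ptrs)) scores[[paste0("ptrs_", tname)]] <- ptrs
  }
  if (nrow(ov) > 0) {
    deg_ptrs <- tryCatch(
      compute_ptrs(pred, tw, 0.05, scope = "deg_set",
                   deg_genes = ov$gene_id),
      error = function(e) NULL)
    if (!is.null(deg_ptrs)) scores$ptrs_deg <- deg_ptrs
  }

  # combine each PRS with the PTRS it correlates with most strongly
  combine <- list()
  prs_cols <- grep("^prs_", colnames(scores), value = TRUE)
  ptrs_cols <- grep("^ptrs_", colnames(scores), value = TRUE)
  for (pc in prs_cols) {
    if (length(ptrs_cols) == 0) break
    cors <- vapply(ptrs_cols, function(qc2)
      abs(stats::cor(scores[[pc]], scores[[qc2]])), 0)
    mate <- ptrs_cols[which.max(cors)]
    cb <- suppressWarnings(combine_scores(scores[[pc]], scores[[mate]]))
    nm <- paste0("combined_", sub("^prs_", "", pc))
    scores[[nm]] <- cb$combined
    combine[[nm]] <- list(prs = pc, ptrs = mate, c1 = cb$c1, c2 = cb$c2,
                          rho = cb$rho)
  }

  split <- split_train_valid(cohort_qc, seed = cfg$seed)
  score_cols <- setdiff(colnames(scores), "sample_id")
  usable <- score_cols[vapply(score_cols,
                              function(sc) stats::sd(scores[[sc]]) > 0, TRUE)]
  ev <- evaluate_scores(cohort_qc, scores[, c("sample_id", usable)],
                        split = split, seed = cfg$seed)
  # quartile bins of each evaluated score for the score table
  for (sc in names(ev$reports))
    scores[[paste0("q_", sc)]] <-
      as.integer(quartile_bin(scores[[sc]],
                              cuts = ev$reports[[sc]]$cuts))

  best <- ev$comparison$score[1]
  bins <- factor(quartile_bin(scores[[best]],
                              cuts = ev$reports[[best]]$cuts), levels = 1:4)
  cv <- cross_validate(
    data.frame(quartile = bins,
               cohort_qc[, c("age", "sex", "bmi", "education", "smoking",
                             "diabetes", "hypertension")]),
    cohort_qc$ssbp, k = 10, seed = cfg$seed)

  res <- list(cohort = cohort_qc, geno = geno_qc, gwas = gw, twas = tw,
              thresholds = th, de = de, overlap = ov, scores = scores,
              selected_snps = selected, combine = combine, evaluation = ev,
              cv = cv, qc_reports = list(snp = sq$report,
                                         sample = smq$report))
  if (!is.null(outdir)) write_pipeline_outputs(res, cfg, outdir)
  res
}

write_pipeline_outputs <- function(res, cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_sim_config(cfg, p("config.yaml"))
  write_cohort_tsv(res$cohort, p("cohort.tsv"))
  write_gwas_tsv(res$gwas$summary, p("gwas_summary.tsv"))
  write_twas_tsv(res$twas, p("twas_results.tsv"))
  utils::write.table(res$de, p("de_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$overlap, p("twas_deg_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$scores, p("score_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$evaluation$comparison, p("model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Restrict a weight panel to a set of available variants
#'
#' Drops weight rows whose variant is unavailable and removes (gene,
#' tissue) entries left without any weight.
#'
#' @param panel A `"weight_panel"`.
#' @param variant_ids Character vector of usable variant ids.
#' @return A `"weight_panel"`.
#' @export
restrict_panel <- function(panel, variant_ids) {
  w <- panel$weights[panel$weights$variant_id %in% variant_ids, ,
                     drop = FALSE]
  if (nrow(w) == 0) stop("no panel variant is available")
  genes <- panel$genes[panel$genes$gene_id %in% w$gene_id, , drop = FALSE]
  structure(list(weights = w, genes = genes), class = "weight_panel")
}
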