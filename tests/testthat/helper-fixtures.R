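# Shared small synthetic cohort, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(seed = 11L) {
  sim_config(n_samples = 300, n_variants = 400, n_genes = 20,
             tissues = ssbp_tissues()[1:2], seed = seed)
}

fixture_small <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- small_cfg()
    geno <- simulate_genotypes(cfg)
    panel <- simulate_weight_panel(geno, cfg)
    expr <- simulate_expression(geno, panel, cfg)
    cohort <- simulate_phenotype(geno, expr, cfg)
    .fixtures$small <- list(cfg = cfg, geno = geno, panel = panel,
                            expr = expr, cohort = cohort)
  }
  .fixtures$small
}

fixture_pipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    cfg <- sim_config(n_samples = 400, n_variants = 400, n_genes = 20,
                      tissues = ssbp_tissues()[1:2], seed = 301L)
    .fixtures$pipeline <- suppressWarnings(run_ssbp_pipeline(cfg))
  }
  .fixtures$pipeline
}

# a tiny hand-built genotype object for QC and scoring edge cases
manual_geno <- function(dosage, chr = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("v%02d", seq_len(m))
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%03d", seq_len(nrow(dosage)))
  if (is.null(chr)) chr <- rep(1L, m)
  if (is.null(a1)) a1 <- rep("A", m)
  if (is.null(a2)) a2 <- rep("G", m)
  map <- data.frame(variant_id = colnames(dosage), chr = chr,
                    bp = seq_len(m) * 10000L, a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  structure(list(dosage = dosage, map = map, block = seq_len(m)),
            class = "ssbp_geno")
}
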