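# Text-format readers and writers: PLINK PED/MAP (text dialect), dosage
# TSV, cohort TSV, weight-panel and results TSVs, and the simulation
# configuration file.

#' Write genotypes as PLINK text PED/MAP
#'
#' MAP columns: chromosome, variant id, genetic distance (0), 1-based bp.
#' PED columns: FID IID PAT MAT SEX PHENO then two allele columns per
#' variant; missing dosage becomes `0 0`.
#'
#' @param geno An `"ssbp_geno"` object.
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @param cohort Optional cohort data.frame supplying sex (1 = female ->
#'   PED code 2) and SS/SR phenotype (PED 2/1).
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(geno, prefix, cohort = NULL) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chr, map$variant_id, 0L, map$bp),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  d <- geno$dosage
  n <- nrow(d); m <- ncol(d)
  a1 <- map$a1; a2 <- map$a2
  # allele pair strings per variant for dosage 0/1/2
  g0 <- paste(a2, a2); g1 <- paste(a1, a2); g2 <- paste(a1, a1)
  lines <- character(n)
  sex <- rep(0L, n); phe <- rep(-9L, n)
  if (!is.null(cohort)) {
    idx <- match(rownames(d), cohort$sample_id)
    sex <- ifelse(cohort$sex[idx] == 1, 2L, 1L)
    phe <- ifelse(cohort$ssbp[idx] == "SS", 2L, 1L)
  }
  for (i in seq_len(n)) {
    gi <- d[i, ]
    cells <- ifelse(is.na(gi), "0 0",
                    ifelse(gi == 0L, g0, ifelse(gi == 1L, g1, g2)))
    lines[i] <- paste(rownames(d)[i], rownames(d)[i], 0, 0, sex[i], phe[i],
                      paste(cells, collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK text PED/MAP into a genotype object
#'
#' Dosage counts the minor allele observed in the file (alphabetical
#' tie-break); `0 0` becomes `NA`.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return An `"ssbp_geno"` object.
#' @export
read_plink_text <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chr", "variant_id", "cm", "bp"),
                           colClasses = c("integer", "character",
                                          "integer", "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), colClasses = "character")
  m <- nrow(map)
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  stopifnot(ncol(al) == 2 * m)
  dosage <- matrix(NA_integer_, nrow(ped), m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x <- c(al[, 2 * j - 1], al[, 2 * j])
    obs <- x[x != "0"]
    alleles <- sort(unique(obs))
    counts <- table(factor(obs, levels = alleles))
    minor <- alleles[which.min(counts)]
    major <- if (length(alleles) > 1) alleles[alleles != minor][1] else "0"
    cnt <- (al[, 2 * j - 1] == minor) + (al[, 2 * j] == minor)
    cnt[al[, 2 * j - 1] == "0" | al[, 2 * j] == "0"] <- NA_integer_
    dosage[, j] <- cnt
    a1[j] <- minor; a2[j] <- major
  }
  dimnames(dosage) <- list(ids, map$variant_id)
  structure(list(dosage = dosage,
                 map = data.frame(variant_id = map$variant_id,
                                  chr = map$chr, bp = map$bp,
                                  a1 = a1, a2 = a2,
                                  stringsAsFactors = FALSE)),
            class = "ssbp_geno")
}

#' Write / read a plain dosage TSV
#'
#' Samples x variants; first column `sample_id`, header row of variant ids,
#' `NA` for missing.
#' @param geno An `"ssbp_geno"` object.
#' @param path Output file.
#' @return Invisibly `path`.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @param map Optional variant map (`variant_id`, `chr`, `bp`, `a1`, `a2`)
#'   to attach on read; defaults to a placeholder map.
#' @export
read_dosage_tsv <- function(path, map = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  ids <- df$sample_id
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  if (is.null(map))
    map <- data.frame(variant_id = colnames(d), chr = 1L,
                      bp = seq_len(ncol(d)), a1 = "A", a2 = "C",
                      stringsAsFactors = FALSE)
  structure(list(dosage = d, map = map), class = "ssbp_geno")
}

#' Write / read the cohort table as TSV
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a weight panel / TWAS results / GWAS summary as TSV
#'
#' Weight panel columns: GENE, TISSUE, MODEL, CVR2, SNP, A1, WEIGHT (one
#' row per nonzero weight). TWAS columns: GENE, TISSUE, ZSCORE, P,
#' BEST_EQTL, CHR, START, END.
#'
#' @param panel A `"weight_panel"`.
#' @param path File path.
#' @export
write_weight_panel_tsv <- function(panel, path) {
  w <- panel$weights
  out <- data.frame(GENE = w$gene_id, TISSUE = w$tissue, MODEL = w$model,
                    CVR2 = w$cv_r2, SNP = w$variant_id,
                    A1 = w$effect_allele, WEIGHT = w$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_panel_tsv
#' @param genes Gene annotation data.frame to re-attach on read.
#' @export
read_weight_panel_tsv <- function(path, genes = NULL) {
  w <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  weights <- data.frame(gene_id = w$GENE, tissue = w$TISSUE,
                        variant_id = w$SNP, effect_allele = w$A1,
                        weight = w$WEIGHT, model = w$MODEL, cv_r2 = w$CVR2,
                        stringsAsFactors = FALSE)
  if (is.null(genes))
    genes <- data.frame(gene_id = unique(weights$gene_id))
  structure(list(weights = weights, genes = genes), class = "weight_panel")
}

#' @rdname write_weight_panel_tsv
#' @param twas TWAS result data.frame.
#' @export
write_twas_tsv <- function(twas, path) {
  out <- data.frame(GENE = twas$gene_id, TISSUE = twas$tissue,
                    ZSCORE = twas$z, P = twas$p,
                    BEST_EQTL = twas$best_eqtl_id, CHR = twas$chr,
                    START = twas$start, END = twas$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_panel_tsv
#' @param summary GWAS summary data.frame.
#' @export
write_gwas_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read the simulation configuration
#'
#' A flat key-value YAML file mirroring [sim_config()].
#' @param cfg A `"sim_config"`.
#' @param path File path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
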