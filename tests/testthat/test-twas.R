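make_gwas_frame <- function(geno, z) {
  data.frame(variant_id = geno$map$variant_id, chr = geno$map$chr,
             bp = geno$map$bp, effect_allele = geno$map$a1,
             other_allele = geno$map$a2, z = z,
             p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
}

one_gene_panel <- function(geno, variant_ids, weights,
                           effect_allele = NULL, tissue = "Whole_Blood") {
  map <- geno$map
  if (is.null(effect_allele))
    effect_allele <- map$a1[match(variant_ids, map$variant_id)]
  w <- data.frame(gene_id = "geneA", tissue = tissue,
                  variant_id = variant_ids, effect_allele = effect_allele,
                  weight = weights, model = "lasso", cv_r2 = 0.3,
                  stringsAsFactors = FALSE)
  g <- data.frame(gene_id = "geneA",
                  chr = map$chr[match(variant_ids[1], map$variant_id)],
                  start = min(map$bp[match(variant_ids, map$variant_id)]),
                  end = max(map$bp[match(variant_ids, map$variant_id)]))
  structure(list(weights = w, genes = g), class = "weight_panel")
}

test_that("a single-variant gene inherits the variant z up to weight sign", {
  fx <- fixture_small()
  z <- rep(0, nrow(fx$geno$map)); z[3] <- 3.7
  gwas <- make_gwas_frame(fx$geno, z)
  vid <- fx$geno$map$variant_id[3]
  tw_pos <- twas_assoc(gwas, one_gene_panel(fx$geno, vid, 0.8), fx$geno)
  tw_neg <- twas_assoc(gwas, one_gene_panel(fx$geno, vid, -0.8), fx$geno)
  # with one variant, (1-lambda) R + lambda I = 1 and z_gene = sign(w) z
  expect_equal(tw_pos$z, 3.7, tolerance = 1e-12)
  expect_equal(tw_neg$z, -3.7, tolerance = 1e-12)
  expect_identical(tw_pos$best_eqtl_id, vid)
})

test_that("multi-variant gene z matches the quadratic-form oracle", {
  fx <- fixture_small()
  set.seed(8)
  z <- stats::rnorm(nrow(fx$geno$map))
  gwas <- make_gwas_frame(fx$geno, z)
  vids <- fx$geno$map$variant_id[11:13]   # one LD block, correlated
  w <- c(0.5, -0.3, 0.9)
  tw <- twas_assoc(gwas, one_gene_panel(fx$geno, vids, w), fx$geno,
                   lambda = 0.05)
  R <- stats::cor(fx$geno$dosage[, vids])
  R <- 0.95 * R + 0.05 * diag(3)
  zo <- sum(w * z[11:13]) / sqrt(drop(t(w) %*% R %*% w))
  expect_equal(tw$z, zo, tolerance = 1e-10)
  expect_equal(tw$p, 2 * stats::pnorm(-abs(zo)), tolerance = 1e-10)
})

test_that("allele-mismatched weights flip the z-score sign", {
  fx <- fixture_small()
  z <- rep(0, nrow(fx$geno$map)); z[3] <- 2.5
  gwas <- make_gwas_frame(fx$geno, z)
  vid <- fx$geno$map$variant_id[3]
  other <- fx$geno$map$a2[3]
  tw_a1 <- twas_assoc(gwas, one_gene_panel(fx$geno, vid, 0.8), fx$geno)
  tw_a2 <- twas_assoc(gwas, one_gene_panel(fx$geno, vid, 0.8,
                                           effect_allele = other), fx$geno)
  expect_equal(tw_a2$z, -tw_a1$z, tolerance = 1e-12)
})

test_that("missing reference variants and degenerate weights are rejected", {
  fx <- fixture_small()
  gwas <- make_gwas_frame(fx$geno, rep(0, nrow(fx$geno$map)))
  bad <- one_gene_panel(fx$geno, fx$geno$map$variant_id[1], 1)
  bad$weights$variant_id <- "absent"
  expect_error(twas_assoc(gwas, bad, fx$geno), "must be present")
  zero <- one_gene_panel(fx$geno, fx$geno$map$variant_id[1], 0)
  expect_error(twas_assoc(gwas, zero, fx$geno), "degenerate")
})

test_that("serial thresholding produces nested gene sets", {
  res <- data.frame(gene_id = sprintf("g%d", 1:6),
                    tissue = "Whole_Blood",
                    z = c(3.5, 2.8, 2.0, 1.2, 0.5, 4.2),
                    stringsAsFactors = FALSE)
  res$p <- 2 * stats::pnorm(-abs(res$z))
  th <- threshold_genes(res, c(0.05, 0.01, 0.001))
  expect_named(th, c("0.05", "0.01", "0.001"))
  expect_true(all(th[["0.01"]]$genes %in% th[["0.05"]]$genes))
  expect_true(all(th[["0.001"]]$genes %in% th[["0.01"]]$genes))
  expect_error(threshold_genes(res, c(0.01, 0.05)), "decreasing")
  expect_error(threshold_genes(res[0, ], c(0.05, 0.01)), "empty")
})

test_that("conditional analysis resolves a correlated gene pair", {
  res <- data.frame(gene_id = c("g1", "g2"), z = c(5, 4.6),
                    stringsAsFactors = FALSE)
  rho <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("g1", "g2"),
                                                      c("g1", "g2")))
  out <- conditional_analysis(res, rho)
  expect_identical(out$selected, "g1")
  # z_cond = (4.6 - 0.9 * 5) / sqrt(1 - 0.81)
  expect_equal(out$conditional$z_cond, 0.1 / sqrt(0.19), tolerance = 1e-10)
  expect_gt(out$conditional$p_cond, 0.05)
})

test_that("independent genes are all selected and collinear ones dropped", {
  res <- data.frame(gene_id = c("g1", "g2"), z = c(5, 4.6),
                    stringsAsFactors = FALSE)
  rho0 <- diag(2); dimnames(rho0) <- list(c("g1", "g2"), c("g1", "g2"))
  out <- conditional_analysis(res, rho0)
  expect_setequal(out$selected, c("g1", "g2"))
  # an exactly duplicated signal carries no conditional information
  rho1 <- matrix(1, 2, 2, dimnames = dimnames(rho0))
  out1 <- conditional_analysis(res, rho1)
  expect_identical(out1$selected, "g1")
  expect_equal(out1$conditional$z_cond, 0)
  # a near-singular but numerically explosive correlation is dropped with
  # a warning instead of entering on a spurious conditional statistic
  rho2 <- matrix(c(1, 1 - 1e-11, 1 - 1e-11, 1), 2,
                 dimnames = dimnames(rho0))
  expect_warning(out2 <- conditional_analysis(res, rho2), "collinear")
  expect_identical(out2$selected, "g1")
})

test_that("weight training recovers a planted eQTL architecture", {
  cfg <- sim_config(n_samples = 250, n_variants = 120, n_genes = 4,
                    tissues = ssbp_tissues()[1], seed = 55)
  geno <- simulate_genotypes(cfg)
  set.seed(56)
  genes <- data.frame(gene_id = c("gA", "gB"), chr = 1L,
                      start = c(10000L, 500000L), end = c(60000L, 550000L))
  causal <- c(gA = "snp00003", gB = "snp00052")
  y <- rbind(
    gA = as.numeric(scale(geno$dosage[, causal["gA"]])) +
      stats::rnorm(250, 0, 0.6),
    gB = as.numeric(scale(geno$dosage[, causal["gB"]])) +
      stats::rnorm(250, 0, 0.6))
  panel <- train_weights(geno, y, genes, cis_window_kb = 20, seed = 2)
  expect_s3_class(panel, "weight_panel")
  for (g in c("gA", "gB")) {
    w <- panel$weights[panel$weights$gene_id == g, ]
    expect_gt(w$cv_r2[1], 0.4)
    top <- w$variant_id[which.max(abs(w$weight))]
    # the top weight lands on the causal variant or an LD-block partner
    blk <- function(v) (match(v, geno$map$variant_id) - 1) %/%
      cfg$ld_block_size
    expect_identical(blk(top), blk(causal[[g]]))
  }
  expect_error(train_weights(geno, y, genes[0, , drop = FALSE]),
               "no gene yielded")
})

test_that("weight training demands a usable reference size", {
  fx <- fixture_small()
  small <- fx$geno
  small$dosage <- small$dosage[1:30, ]
  expect_error(train_weights(small, fx$expr[, 1:30], fx$panel$genes),
               "at least 50")
})
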