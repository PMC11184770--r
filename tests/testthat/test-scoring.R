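test_that("the PRS is the dosage-weighted sum on the effect alleles", {
  d <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L,
                1L, 1L, 1L), 3, 3, byrow = TRUE)
  geno <- manual_geno(d)
  betas <- data.frame(variant_id = c("v01", "v02", "v03"),
                      effect_allele = c("A", "A", "A"),
                      beta = c(0.5, -0.2, 0.1), stringsAsFactors = FALSE)
  prs <- compute_prs(geno, betas)
  expect_equal(unname(prs), as.numeric(d %*% betas$beta))
  # scoring the other allele mirrors the dosage
  betas2 <- betas; betas2$effect_allele <- "G"
  prs2 <- compute_prs(geno, betas2)
  expect_equal(unname(prs2), as.numeric((2 - d) %*% betas$beta))
})

test_that("missing dosages follow the configured policy", {
  d <- matrix(c(NA, 1L, 2L, 0L), 2, 2,
              dimnames = list(c("Sa", "Sb"), c("v01", "v02")))
  geno <- manual_geno(d)
  betas <- data.frame(variant_id = c("v01", "v02"),
                      effect_allele = "A", beta = c(1, 1),
                      maf = c(0.25, 0.4), stringsAsFactors = FALSE)
  prs_mean <- compute_prs(geno, betas, score_config())
  expect_equal(unname(prs_mean["Sa"]), 2 * 0.25 + 2)
  prs_drop <- compute_prs(geno, betas,
                          score_config(missing_policy = "drop"))
  expect_equal(unname(prs_drop["Sa"]), 2)
  expect_error(compute_prs(geno, betas[0, ], score_config()), "empty")
  bad <- betas; bad$variant_id[1] <- "nope"
  expect_error(compute_prs(geno, bad), "absent")
})

test_that("PRS variants come from the hit loci plus their best eQTLs", {
  twas <- data.frame(gene_id = c("g1", "g2"), tissue = "Whole_Blood",
                     z = c(4, 1), p = c(1e-4, 0.3),
                     best_eqtl_id = c("v07", "v09"),
                     chr = 1L, start = 5000L, end = 25000L,
                     stringsAsFactors = FALSE)
  gwas <- data.frame(variant_id = c("v01", "v02", "v07"),
                     chr = 1L, bp = c(10000L, 20000L, 600000L),
                     effect_allele = "A", p = c(0.2, 1e-6, 0.5),
                     beta = c(0.1, 0.8, -0.2), maf = 0.3,
                     stringsAsFactors = FALSE)
  snps <- select_prs_snps(twas, gwas, 0.05)
  # g1 qualifies: lowest-P locus variant v02 plus best eQTL v07; g2 does not
  expect_setequal(snps$variant_id, c("v02", "v07"))
  expect_identical(attr(snps, "n_dropped"), 0L)
  snps2 <- select_prs_snps(twas, gwas, 0.05, available_variants = "v02")
  expect_identical(snps2$variant_id, "v02")
  expect_identical(attr(snps2, "n_dropped"), 1L)
})

test_that("predicted expression equals the weighted standardized dosages", {
  fx <- fixture_small()
  pred <- predict_expression(fx$geno, fx$panel, score_config())
  key <- colnames(pred)[1]
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  w <- fx$panel$weights[fx$panel$weights$gene_id == parts[1] &
                          fx$panel$weights$tissue == parts[2], ]
  G <- fx$geno$dosage[, w$variant_id, drop = FALSE]
  storage.mode(G) <- "double"
  Gs <- scale(G)
  manual <- as.numeric(scale(Gs %*% w$weight))
  expect_equal(unname(pred[, key]), manual, tolerance = 1e-12)
  # every returned column is standardized
  expect_lt(max(abs(colMeans(pred))), 1e-12)
  expect_equal(unname(apply(pred, 2, stats::sd)), rep(1, ncol(pred)),
               tolerance = 1e-12)
})

test_that("the PTRS sums z-weighted predicted expression over hit genes", {
  pred <- cbind("g1|Whole_Blood" = c(1, -1, 0.5),
                "g2|Whole_Blood" = c(0, 2, -2))
  rownames(pred) <- c("Sa", "Sb", "Sc")
  twas <- data.frame(gene_id = c("g1", "g2"), tissue = "Whole_Blood",
                     z = c(3, -2), p = c(0.001, 0.2),
                     stringsAsFactors = FALSE)
  p1 <- compute_ptrs(pred, twas, 0.05)
  expect_equal(unname(p1), as.numeric(pred[, 1] * 3))
  p2 <- compute_ptrs(pred, twas, 0.5)
  expect_equal(unname(p2), as.numeric(pred %*% c(3, -2)))
  expect_error(compute_ptrs(pred, twas, 1e-6), "empty gene set")
  expect_error(compute_ptrs(pred, twas, 0.05, scope = "tissue"), "tissue")
  p3 <- compute_ptrs(pred, twas, 0.5, scope = "deg_set", deg_genes = "g2")
  expect_equal(unname(p3), as.numeric(pred[, 2] * -2))
})

test_that("PCA combination weights reduce to the closed form in rho", {
  set.seed(71)
  z <- stats::rnorm(500)
  prs <- z + stats::rnorm(500, 0, 0.8)
  ptrs <- z + stats::rnorm(500, 0, 1.2)
  cb <- combine_scores(prs, ptrs)
  rho <- stats::cor(prs, ptrs)
  expect_equal(cb$rho, rho, tolerance = 1e-12)
  expect_equal(cb$c1, 1 / (1 + rho), tolerance = 1e-10)
  expect_equal(cb$c2, rho / (1 + rho), tolerance = 1e-10)
  expect_equal(cb$c1 + cb$c2, 1)
  expect_equal(cb$combined,
               cb$c1 * as.numeric(scale(prs)) +
                 cb$c2 * as.numeric(scale(ptrs)), tolerance = 1e-12)
  expect_equal(sum(cb$variance_share), 1)
})

test_that("anti-correlated scores are combined on |rho| with a warning", {
  set.seed(72)
  a <- stats::rnorm(200)
  b <- -a + stats::rnorm(200, 0, 0.5)
  expect_warning(cb <- combine_scores(a, b), "negative")
  expect_gt(cb$rho, 0)
  expect_error(combine_scores(a, rep(1, 200)), "constant")
  expect_error(combine_scores(a, b[1:100]), "equal length")
})

test_that("quartile bins send cut-point ties to the lower bin", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- quartile_bin(x)
  expect_identical(as.integer(table(b)), rep(2L, 4))
  cuts <- attr(b, "cuts")
  expect_equal(cuts, stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                     names = FALSE))
  # a value equal to a cut stays below it
  expect_identical(as.integer(quartile_bin(cuts[1], cuts = cuts)), 1L)
  expect_identical(as.integer(quartile_bin(cuts[3], cuts = cuts)), 3L)
  # training cuts reused on new data
  b2 <- quartile_bin(c(-10, 100), cuts = cuts)
  expect_identical(as.integer(b2), c(1L, 4L))
  expect_error(quartile_bin(c(1, 2, 3)), "at least 4")
  expect_error(quartile_bin(rep(2, 10)), "constant")
})
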