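test_that("the Hardy-Weinberg exact test behaves at its landmarks", {
  # modal heterozygote configuration: nothing is less probable
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  # symmetric in the two homozygote counts
  expect_equal(hwe_exact_test(30, 10, 5), hwe_exact_test(5, 10, 30))
  # extreme excess homozygosity is highly significant
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  p <- hwe_exact_test(12, 3, 9)
  expect_gt(p, 0); expect_lte(p, 1)
  expect_error(hwe_exact_test(-1, 2, 3), "nonnegative")
  expect_error(hwe_exact_test(1.5, 2, 3), "nonnegative integers")
  expect_error(hwe_exact_test(0, 0, 0), "> 0")
})

test_that("the exact test agrees with the chi-square test asymptotically", {
  # large balanced table: exact and chi-square P converge
  n <- c(3600, 4800, 1700)   # mild departure from 3600/4800/1600
  p_exact <- hwe_exact_test(n[1], n[2], n[3])
  af <- (2 * n[1] + n[2]) / (2 * sum(n))
  e <- sum(n) * c(af^2, 2 * af * (1 - af), (1 - af)^2)
  p_chi <- stats::pchisq(sum((n - e)^2 / e), df = 1, lower.tail = FALSE)
  expect_equal(p_exact, p_chi, tolerance = 0.15)
})

test_that("variant QC excludes by rule priority and reports reasons", {
  set.seed(21)
  n <- 200
  d <- cbind(
    good   = stats::rbinom(n, 2, 0.3),
    sexchr = stats::rbinom(n, 2, 0.3),
    lowcall = stats::rbinom(n, 2, 0.3),
    raremaf = stats::rbinom(n, 2, 0.002),
    hwe_bad = rep(1L, n))
  d[1:20, "lowcall"] <- NA
  geno <- manual_geno(d, chr = c(1L, 23L, 2L, 3L, 4L))
  out <- snp_qc(geno)
  expect_identical(colnames(out$geno$dosage), "good")
  got <- out$report$reason[match(c("sexchr", "lowcall", "raremaf", "hwe_bad"),
                                 out$report$variant_id)]
  expect_identical(got, c("sex_chromosome", "call_rate", "maf", "hwe"))
  expect_identical(out$geno$map$variant_id, "good")
})

test_that("variant QC fails loudly when nothing survives", {
  d <- matrix(1L, 100, 2)
  expect_error(snp_qc(manual_geno(d)), "empty panel")
})

test_that("identity-by-descent estimates separate duplicates from strangers", {
  cfg <- sim_config(n_samples = 80, n_variants = 600, n_genes = 10,
                    tissues = ssbp_tissues()[1], within_block_corr = 0,
                    seed = 31)
  geno <- simulate_genotypes(cfg)
  d <- geno$dosage
  d[80, ] <- d[1, ]   # plant a duplicate pair
  ph <- ssbprisk:::estimate_pi_hat(d)
  expect_gt(ph[1, 80], 0.9)
  off <- ph[2:79, 2:79]
  expect_lt(mean(off[upper.tri(off)]), 0.08)
  expect_true(all(ph[upper.tri(ph)] >= 0 & ph[upper.tri(ph)] <= 1))
})

test_that("sample QC drops the lower-call-rate member of a related pair", {
  cfg <- sim_config(n_samples = 60, n_variants = 600, n_genes = 10,
                    tissues = ssbp_tissues()[1], within_block_corr = 0,
                    seed = 32)
  geno <- simulate_genotypes(cfg)
  geno$dosage[60, ] <- geno$dosage[1, ]          # duplicate of sample 1
  geno$dosage[60, 1:30] <- NA                    # with worse call rate
  geno$dosage[59, 1:200] <- NA                   # call-rate failure
  out <- sample_qc(geno)
  rep <- out$report
  expect_identical(rep$reason[rep$sample_id == "S0059"], "call_rate")
  expect_identical(rep$reason[rep$sample_id == "S0060"], "relatedness")
  expect_true("S0001" %in% rownames(out$geno$dosage))
})

test_that("additive association matches the glm oracle variant by variant", {
  fx <- fixture_small()
  gw <- assoc_additive(fx$geno, fx$cohort)
  expect_true(all(c("variant_id", "chr", "bp", "effect_allele",
                    "other_allele", "beta", "se", "z", "p", "maf", "n")
                  %in% colnames(gw$summary)))
  y <- as.integer(fx$cohort$ssbp == "SS")
  for (vid in gw$summary$variant_id[c(1, 57, 200, 311)]) {
    df <- data.frame(y = y, g = as.numeric(fx$geno$dosage[, vid]),
                     fx$cohort[, c("age", "sex", "area", "hypertension",
                                   "fbg", "tg", "bmi")])
    fit <- stats::glm(y ~ age + sex + area + hypertension + fbg + tg +
                        bmi + g, data = df, family = stats::binomial())
    row <- gw$summary[gw$summary$variant_id == vid, ]
    sm <- summary(fit)$coefficients
    expect_equal(row$beta, unname(sm["g", "Estimate"]), tolerance = 1e-6)
    expect_equal(row$se, unname(sm["g", "Std. Error"]), tolerance = 1e-6)
  }
  # two-sided p really is 2 * Phi(-|z|)
  expect_equal(gw$summary$p, 2 * stats::pnorm(-abs(gw$summary$z)))
})

test_that("monomorphic variants are skipped with a recorded reason", {
  fx <- fixture_small()
  geno <- fx$geno
  geno$dosage[, 5] <- 1L
  gw <- assoc_additive(geno, fx$cohort)
  vid <- geno$map$variant_id[5]
  expect_false(vid %in% gw$summary$variant_id)
  expect_identical(gw$skipped$reason[gw$skipped$variant_id == vid],
                   "zero variance")
})

test_that("a strongly planted variant is recovered with the right sign", {
  cfg <- sim_config(n_samples = 600, n_variants = 100, n_genes = 5,
                    tissues = ssbp_tissues()[1], within_block_corr = 0,
                    seed = 35)
  geno <- simulate_genotypes(cfg)
  set.seed(99)
  g <- as.numeric(geno$dosage[, 7])
  pr <- 1 / (1 + exp(-(-1.2 + 0.9 * g)))
  cohort <- data.frame(
    sample_id = rownames(geno$dosage),
    age = stats::rnorm(600, 59, 5), sex = stats::rbinom(600, 1, 0.7),
    area = sample(1:11, 600, TRUE), hypertension = stats::rbinom(600, 1, 0.5),
    fbg = stats::rnorm(600, 5.4, 0.5), tg = stats::rnorm(600, 1.6, 0.4),
    bmi = stats::rnorm(600, 26, 3),
    ssbp = ifelse(stats::rbinom(600, 1, pr) == 1, "SS", "SR"),
    stringsAsFactors = FALSE)
  gw <- assoc_additive(geno, cohort)
  row <- gw$summary[gw$summary$variant_id == geno$map$variant_id[7], ]
  expect_gt(row$beta, 0.5)
  expect_lt(row$p, 1e-6)
})

test_that("greedy clumping assigns correlated neighbours to one index", {
  summ <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    chr = c(1L, 1L, 1L, 1L),
    bp = c(10000L, 20000L, 30000L, 900000L),
    p = c(1e-8, 1e-6, 0.5, 1e-7), stringsAsFactors = FALSE)
  set.seed(3)
  base <- stats::rbinom(300, 2, 0.3)
  flip <- function(x, k) { i <- sample(300, k); x[i] <- 2 - x[i]; x }
  d <- cbind(v1 = base, v2 = flip(base, 15), v3 = stats::rbinom(300, 2, 0.3),
             v4 = stats::rbinom(300, 2, 0.3))
  geno <- manual_geno(d, chr = summ$chr)
  geno$map$bp <- summ$bp
  cl <- clump(summ, geno, r2_max = 0.5, window_kb = 250, p_index = 1e-5)
  expect_identical(cl$index[cl$variant_id == "v1"], "v1")
  expect_true(cl$is_index[cl$variant_id == "v1"])
  # v2 is in LD with v1 and within the window: absorbed, not an index
  expect_identical(cl$index[cl$variant_id == "v2"], "v1")
  # v4 is significant but 890 kb away: its own clump
  expect_identical(cl$index[cl$variant_id == "v4"], "v4")
  # v3 never reaches the index threshold and is uncorrelated
  expect_false("v3" %in% cl$variant_id)
})
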