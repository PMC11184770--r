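# Two-group differential expression: moderated t with empirical-Bayes
# variance shrinkage (Welch t as fallback) and the TWAS/DEG overlap.

#' Two-group differential expression test
#'
#' Per gene, compares mean log-expression between the two label groups.
#' In moderated mode an equal-variance t statistic is computed with the
#' per-gene variance shrunk toward an empirical-Bayes prior:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)` on `d0 + d` degrees of
#' freedom, with the prior `(d0, s0^2)` estimated by moment matching on
#' `log(s2)` across genes. In Welch mode each gene gets the ordinary
#' unequal-variance t test.
#'
#' @param expr Genes x samples matrix of log-scale expression.
#' @param labels Vector (length = samples) with two levels, e.g. "SS"/"SR";
#'   the first level in `sort(unique(labels))` is the reference, and
#'   `log_fc` is mean(level2) - mean(level1).
#' @param moderated Use empirical-Bayes shrinkage (default TRUE).
#' @return data.frame `gene_id`, `log_fc`, `t_stat`, `p`, `fdr_bh`;
#'   attributes `d0` and `s0_2` carry the estimated prior in moderated mode.
#' @export
de_test <- function(expr, labels, moderated = TRUE) {
  if (any(!is.finite(expr))) stop("expression must be finite")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("labels must have exactly two levels")
  i1 <- which(labels == lev[1]); i2 <- which(labels == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 samples")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(expr[, i2, drop = FALSE], 1, stats::var)
  lfc <- m2 - m1
  d0 <- Inf; s0_2 <- NA_real_
  if (moderated) {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0; s0_2 <- prior$s0_2
    s2_post <- if (is.finite(d0)) (d0 * s0_2 + d * s2) / (d0 + d)
      else rep(s0_2, length(s2))
    tt <- lfc / sqrt(s2_post * (1 / n1 + 1 / n2))
    df <- d0 + d
    p <- 2 * stats::pt(-abs(tt), df = df)
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- lfc / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
  }
  zerovar <- (v1 + v2) == 0
  tt[zerovar & lfc == 0] <- 0
  p[zerovar & lfc == 0] <- 1
  res <- data.frame(gene_id = rownames(expr), log_fc = lfc, t_stat = tt,
                    p = p, fdr_bh = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  res
}

# Empirical-Bayes prior for gene variances: moment matching of log(s2)
# against a scaled-F distribution (s2 ~ s0^2 F(d, d0)).
fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(d0 = Inf, s0_2 = stats::median(s2)))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    # no excess dispersion: infinite prior df, common variance
    s0_2 <- exp(mean(e))
    return(list(d0 = Inf, s0_2 = s0_2))
  }
  d0 <- 2 * trigamma_inverse(ev)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton inversion of trigamma (monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Overlap of differentially expressed genes with TWAS hits
#'
#' Intersects genes significant in the expression comparison with genes
#' significant in the TWAS, and reports per-gene provenance in the layout
#' gene / chromosome / locus bounds / tissue / TWAS z / TWAS P /
#' expression P.
#'
#' @param de [de_test()] result.
#' @param twas TWAS result data.frame ([twas_assoc()] columns).
#' @param de_p,twas_p Significance cutoffs (default 0.05 each).
#' @return data.frame with one row per overlapping (gene, tissue):
#'   `gene_id`, `chr`, `start`, `end`, `tissue`, `twas_z`, `twas_p`,
#'   `de_p`, ordered by `twas_p`.
#' @export
overlap_with_twas <- function(de, twas, de_p = 0.05, twas_p = 0.05) {
  de_hit <- de[de$p < de_p, , drop = FALSE]
  tw_hit <- twas[twas$p < twas_p, , drop = FALSE]
  common <- intersect(de_hit$gene_id, tw_hit$gene_id)
  tw <- tw_hit[tw_hit$gene_id %in% common, , drop = FALSE]
  # one row per gene: the most significant tissue (ties: first)
  tw <- tw[order(tw$p), ]
  tw <- tw[!duplicated(tw$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = tw$gene_id, chr = tw$chr,
                    start = tw$start, end = tw$end, tissue = tw$tissue,
                    twas_z = tw$z, twas_p = tw$p,
                    de_p = de_hit$p[match(tw$gene_id, de_hit$gene_id)],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$twas_p), , drop = FALSE]
}
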