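# Covariate-adjusted logistic risk models over score quartiles:
# stratified train/validation split, IRLS logistic fits with Wald CIs,
# ROC/AUC with DeLong variance, Nagelkerke pseudo-R2, stratified k-fold
# cross-validation, and the multi-score comparison report.

#' Stratified train/validation split
#'
#' Splits the cohort into a training fraction and its complement,
#' stratified by the binary outcome so the case fraction is nearly equal in
#' both parts.
#'
#' @param cohort data.frame with `sample_id` and the outcome column.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @param outcome Outcome column name (default `"ssbp"`, cases = `"SS"`).
#' @return List `train`, `valid` of sample ids.
#' @export
split_train_valid <- function(cohort, fraction = 0.7, seed = 1L,
                              outcome = "ssbp") {
  if (nrow(cohort) < 20) stop("need at least 20 samples to split")
  y <- cohort[[outcome]]
  set.seed(seed)
  train <- character(0)
  for (lev in unique(y)) {
    ids <- cohort$sample_id[y == lev]
    n_tr <- round(fraction * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  # per-class rounding can miss the overall target by one; rebalance from
  # the larger class
  want <- round(fraction * nrow(cohort))
  valid <- setdiff(cohort$sample_id, train)
  while (length(train) > want) {
    big <- names(which.max(table(y[match(train, cohort$sample_id)])))
    mv <- utils::tail(train[y[match(train, cohort$sample_id)] == big], 1)
    train <- setdiff(train, mv); valid <- c(valid, mv)
  }
  while (length(train) < want) {
    big <- names(which.max(table(y[match(valid, cohort$sample_id)])))
    mv <- utils::tail(valid[y[match(valid, cohort$sample_id)] == big], 1)
    valid <- setdiff(valid, mv); train <- c(train, mv)
  }
  ytr <- y[match(train, cohort$sample_id)]
  yva <- y[match(valid, cohort$sample_id)]
  if (length(unique(ytr)) < 2 || length(unique(yva)) < 2)
    stop("a class is absent from one split")
  list(train = sort(train), valid = sort(valid))
}

#' Logistic regression with odds ratios and Wald confidence intervals
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (deviance convergence 1e-8), reporting `exp(beta)` with 95% Wald
#' intervals. Rank-deficient designs and separated fits raise errors naming
#' the offending column.
#'
#' @param design data.frame or matrix of predictors (no intercept column;
#'   one is added). Factors are expanded via [stats::model.matrix()].
#' @param outcome Binary vector (0/1, logical, or `"SS"`/`"SR"`).
#' @return List of class `"ssbp_logit"`: `coef` (data.frame `term`,
#'   `beta`, `se`, `or`, `ci_lo`, `ci_hi`, `z`, `p`), `fit` (the glm
#'   object), `deviance`, `null_deviance`, `n`.
#' @export
fit_logistic <- function(design, outcome) {
  y <- outcome
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "SS")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome must have both classes present")
  df <- as.data.frame(design)
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: %s", paste(bad, collapse = ", ")))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) stop("IRLS did not converge")
  cf <- fit$coefficients
  sep <- which(abs(cf) > 15)
  if (length(sep))
    stop(sprintf("separation detected for column(s): %s",
                 paste(names(cf)[sep], collapse = ", ")))
  vc <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  se <- sqrt(diag(vc))
  z <- cf / se
  coef <- data.frame(term = names(cf), beta = unname(cf), se = se,
                     or = exp(unname(cf)),
                     ci_lo = exp(unname(cf) - 1.96 * se),
                     ci_hi = exp(unname(cf) + 1.96 * se),
                     z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coef = coef, fit = fit, X = X, y = y,
                 deviance = fit$deviance,
                 null_deviance = null_deviance_logit(y),
                 n = length(y)),
            class = "ssbp_logit")
}

null_deviance_logit <- function(y) {
  p <- mean(y)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @export
print.ssbp_logit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, deviance = %.2f (null %.2f)\n",
              x$n, x$deviance, x$null_deviance))
  print(x$coef, digits = 4)
  invisible(x)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney formulation (midranks; ties count one half) and
#' a 95% CI from the DeLong placement-value variance.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (1/`"SS"` = case).
#' @return List `auc`, `ci_lo`, `ci_hi`, `se`.
#' @export
roc_auc <- function(scores, labels) {
  y <- labels
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "SS")
  cases <- scores[y == 1]; controls <- scores[y == 0]
  n1 <- length(cases); n0 <- length(controls)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(c(cases, controls), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  v10 <- vapply(cases, function(x)
    mean((x > controls) + 0.5 * (x == controls)), 0)
  v01 <- vapply(controls, function(x)
    mean((cases > x) + 0.5 * (cases == x)), 0)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  list(auc = auc,
       ci_lo = max(0, auc - 1.96 * se),
       ci_hi = min(1, auc + 1.96 * se),
       se = se)
}

#' Nagelkerke pseudo-R2
#'
#' `R2 = (1 - exp((D_full - D_null) / n)) / (1 - exp(-D_null / n))`. With
#' `cox_snell = TRUE` the unrescaled numerator is returned instead.
#'
#' @param model An `"ssbp_logit"` fit.
#' @param cox_snell Return the Cox-Snell variant.
#' @return R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(model, cox_snell = FALSE) {
  if (is.null(model$null_deviance)) stop("null model deviance missing")
  cs <- 1 - exp((model$deviance - model$null_deviance) / model$n)
  if (cox_snell) return(cs)
  cs / (1 - exp(-model$null_deviance / model$n))
}

#' Stratified k-fold cross-validation of a logistic model
#'
#' Out-of-fold predicted probabilities are pooled across folds; accuracy is
#' evaluated at the 0.5 probability cutoff and AUC (with DeLong CI) on the
#' pooled predictions.
#'
#' @param design Predictor data.frame (as in [fit_logistic()]).
#' @param outcome Binary outcome vector.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List `accuracy`, `auc`, `ci_lo`, `ci_hi`, `pred` (pooled
#'   probabilities), `fold` (assignments).
#' @export
cross_validate <- function(design, outcome, k = 10, seed = 1L) {
  y <- outcome
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "SS")
  n <- length(y)
  if (n < 2 * k) stop("need at least 2k samples")
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  df <- as.data.frame(design)
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      stop("a fold lost a class despite stratification")
    X <- stats::model.matrix(~ ., data = df)
    fit <- suppressWarnings(
      stats::glm.fit(X[tr, , drop = FALSE], y[tr],
                     family = stats::binomial(),
                     control = list(epsilon = 1e-8, maxit = 100)))
    eta <- X[!tr, , drop = FALSE] %*% fit$coefficients
    pred[!tr] <- 1 / (1 + exp(-eta))
  }
  roc <- roc_auc(pred, y)
  list(accuracy = mean((pred >= 0.5) == (y == 1)),
       auc = roc$auc, ci_lo = roc$ci_lo, ci_hi = roc$ci_hi,
       pred = pred, fold = fold)
}

#' Evaluate a set of risk scores with quartile logistic models
#'
#' For every score column: quartile bins are computed from training-set cut
#' points, a logistic model `outcome ~ quartile + covariates` is fitted on
#' the training set, and AUC (train and validation), Nagelkerke R2 and
#' per-quartile odds ratios (Q1 reference) are reported, together with a
#' ranked comparison table.
#'
#' @param cohort Cohort data.frame (`sample_id`, outcome, covariates).
#' @param scores data.frame or matrix of score columns, rownames or a
#'   `sample_id` column aligning with the cohort.
#' @param covariates Covariate column names (default the risk-model set:
#'   age, sex, BMI, education, smoking, diabetes, hypertension).
#' @param split A [split_train_valid()] result; computed at `seed` when
#'   omitted.
#' @param seed Seed for the split.
#' @param outcome Outcome column (default `"ssbp"`).
#' @return List `reports` (per score: fit, quartile ORs, AUCs, R2) and
#'   `comparison` (data.frame ranked by validation AUC).
#' @export
evaluate_scores <- function(cohort, scores,
                            covariates = c("age", "sex", "bmi", "education",
                                           "smoking", "diabetes",
                                           "hypertension"),
                            split = NULL, seed = 1L, outcome = "ssbp") {
  scores <- as.data.frame(scores)
  if ("sample_id" %in% colnames(scores)) {
    rownames(scores) <- scores$sample_id
    scores$sample_id <- NULL
  }
  scores <- scores[match(cohort$sample_id, rownames(scores)), , drop = FALSE]
  if (anyNA(scores)) stop("scores and cohort are not aligned")
  if (is.null(split))
    split <- split_train_valid(cohort, seed = seed, outcome = outcome)
  tr <- cohort$sample_id %in% split$train
  y <- cohort[[outcome]]
  yb <- if (is.character(y) || is.factor(y))
    as.integer(as.character(y) == "SS") else as.numeric(y)

  reports <- list()
  rows <- list()
  for (sc in colnames(scores)) {
    s <- scores[[sc]]
    bins_tr <- tryCatch(quartile_bin(s[tr]), error = function(e) e)
    if (inherits(bins_tr, "error")) {
      warning(sprintf("score %s skipped: %s", sc,
                      conditionMessage(bins_tr)))
      next
    }
    cuts <- attr(bins_tr, "cuts")
    q <- factor(quartile_bin(s, cuts = cuts), levels = 1:4)
    design <- data.frame(quartile = q,
                         cohort[, covariates, drop = FALSE])
    # drop unused quartile levels (heavily tied scores can empty a bin);
    # a level absent from the training part makes the score unusable
    design$quartile <- droplevels(design$quartile)
    if (nlevels(droplevels(design$quartile[tr])) <
        nlevels(design$quartile)) {
      warning(sprintf("score %s skipped: quartile level absent in training",
                      sc))
      next
    }
    fit <- tryCatch(fit_logistic(design[tr, , drop = FALSE], yb[tr]),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("score %s skipped: %s", sc, conditionMessage(fit)))
      next
    }
    X <- stats::model.matrix(~ ., data = design)
    pr <- 1 / (1 + exp(-(X %*% fit$fit$coefficients)))
    auc_tr <- roc_auc(pr[tr], yb[tr])
    auc_va <- roc_auc(pr[!tr], yb[!tr])
    qor <- fit$coef[grepl("^quartile", fit$coef$term), , drop = FALSE]
    reports[[sc]] <- list(score = sc, fit = fit,
                          quartile_or = qor,
                          auc_train = auc_tr, auc_valid = auc_va,
                          r2 = nagelkerke_r2(fit), cuts = cuts)
    rows[[sc]] <- data.frame(score = sc,
                             auc_train = auc_tr$auc, auc_valid = auc_va$auc,
                             r2 = nagelkerke_r2(fit),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no score could be evaluated")
  comparison <- do.call(rbind, rows)
  comparison <- comparison[order(-comparison$auc_valid), , drop = FALSE]
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison, split = split)
}
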