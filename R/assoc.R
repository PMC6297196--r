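#' Mann-Whitney U test with group median difference
#'
#' Two-sided rank-sum comparison of two groups. The exact null distribution
#' is used when the smaller group has at most 8 observations and there are no
#' ties; otherwise the midrank normal approximation with tie and continuity
#' correction applies.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list with `U`, `median_diff` (`median(a) - median(b)`), `p`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), median_diff = median(a) - median(b),
       p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; p-value by the exact or
#' t-approximation branch of [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Covariate-adjusted logistic association of a feature with a binary outcome
#'
#' Maximum-likelihood logistic slope for the feature adjusting for the given
#' covariates, with a Wald p-value. Complete cases only. Complete or
#' quasi-complete separation is reported as an error rather than a silently
#' divergent estimate.
#'
#' @param feature numeric feature values (e.g. log10 concentrations).
#' @param outcome binary outcome (0/1, logical, or 2-level factor).
#' @param covariates optional data frame of covariates, rows aligned with
#'   `feature`.
#' @param test `"wald"` (default) or `"lrt"` for a likelihood-ratio p-value.
#' @return list with `beta`, `p`, `n`.
#' @export
logistic_assoc <- function(feature, outcome, covariates = NULL,
                           test = c("wald", "lrt")) {
  test <- match.arg(test)
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  df <- data.frame(.y = y, .feature = feature)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.y)) < 2)
    stop("both outcome classes must be present")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic regression did not converge after ", fit$iter, " iterations")
  eta <- predict(fit, type = "link")
  separated <- min(eta[df$.y == 1]) > max(eta[df$.y == 0]) ||
    max(eta[df$.y == 1]) < min(eta[df$.y == 0])
  if (sep_warn && (separated || abs(coef(fit)[".feature"]) > 15))
    stop("complete or quasi-complete separation detected for the feature")
  beta <- unname(coef(fit)[".feature"])
  p <- if (test == "wald") {
    summary(fit)$coefficients[".feature", "Pr(>|z|)"]
  } else {
    fit0 <- glm(.y ~ . - .feature, data = df, family = binomial())
    pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  list(beta = beta, p = p, n = nrow(df))
}

#' Covariate-adjusted linear association of an outcome with a feature
#'
#' Least-squares slope of the continuous outcome on the feature given the
#' covariates, with a t-test p-value. Complete cases only.
#'
#' @param feature numeric feature values.
#' @param outcome continuous outcome, aligned with `feature`.
#' @param covariates optional data frame of covariates.
#' @return list with `beta`, `p`, `n`.
#' @export
linear_assoc <- function(feature, outcome, covariates = NULL) {
  df <- data.frame(.y = outcome, .feature = feature)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(df) <= length(coef(fit)))
    stop("not enough complete cases for the number of parameters")
  sm <- summary(fit)$coefficients
  list(beta = unname(coef(fit)[".feature"]),
       p = sm[".feature", "Pr(>|t|)"], n = nrow(df))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values `q(i) = min over j >= i of m * p(j) / j`,
#' capped at 1 and returned in the input order.
#'
#' @param p p-values in `[0, 1]` (`NA` allowed; adjusted over non-missing).
#' @return q-values aligned with `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run the four-test univariate association battery
#'
#' Per feature: (1) covariate-adjusted logistic regression of the
#' dichotomized group on the feature, (2) unadjusted Mann-Whitney comparison
#' of groups, (3) covariate-adjusted linear regression of the continuous
#' endophenotype on the feature, (4) unadjusted Spearman rank correlation
#' with the endophenotype. The nonparametric tests are run unadjusted;
#' covariates enter the regression models only. BH q-values are computed per
#' test across features, and `n_sig` counts tests with `p < alpha`. Features
#' for which a test fails (e.g. separation) get `NA` for that test, with a
#' warning.
#'
#' @param mat feature x sample matrix (analysis scale, e.g. log10).
#' @param group per-sample group label; `"high"` is the positive class.
#' @param endophenotype per-sample continuous endophenotype.
#' @param covariates optional data frame of per-sample covariates.
#' @param alpha significance level for `n_sig` (default 0.05).
#' @return data frame with one row per feature: per-test effect size, p and
#'   q columns, and `n_sig`.
#' @export
run_battery <- function(mat, group, endophenotype, covariates = NULL,
                        alpha = 0.05) {
  stopifnot(is.matrix(mat), ncol(mat) == length(group),
            length(endophenotype) == length(group))
  grp <- factor(group)
  if (nlevels(grp) != 2) stop("group must have exactly two levels")
  if ("high" %in% levels(grp)) grp <- relevel(grp, setdiff(levels(grp), "high"))
  if (min(table(grp)) < 2) stop("need at least 2 samples per group")
  pos <- levels(grp)[2]

  one <- function(v) {
    lg <- tryCatch(logistic_assoc(v, grp == pos, covariates),
                   error = function(e) list(beta = NA_real_, p = NA_real_))
    mw <- tryCatch({
      ok <- !is.na(v)
      mann_whitney(v[ok & grp == pos], v[ok & grp != pos])
    }, error = function(e) list(U = NA_real_, median_diff = NA_real_,
                                p = NA_real_))
    ln <- tryCatch(linear_assoc(v, endophenotype, covariates),
                   error = function(e) list(beta = NA_real_, p = NA_real_))
    sp <- tryCatch(spearman(v, endophenotype),
                   error = function(e) list(rho = NA_real_, p = NA_real_))
    c(logistic_beta = lg$beta, logistic_p = lg$p,
      mw_median_diff = mw$median_diff, mw_U = mw$U, mw_p = mw$p,
      linear_beta = ln$beta, linear_p = ln$p,
      spearman_rho = sp$rho, spearman_p = sp$p)
  }
  res <- t(apply(mat, 1, one))
  out <- data.frame(feature = rownames(mat), res, stringsAsFactors = FALSE,
                    row.names = NULL)
  n_fail <- sum(is.na(out[c("logistic_p", "mw_p", "linear_p", "spearman_p")]))
  if (n_fail > 0)
    warning(n_fail, " test result(s) unavailable (errors recorded as NA)")
  out$logistic_q <- bh_adjust(out$logistic_p)
  out$mw_q <- bh_adjust(out$mw_p)
  out$linear_q <- bh_adjust(out$linear_p)
  out$spearman_q <- bh_adjust(out$spearman_p)
  pm <- as.matrix(out[c("logistic_p", "mw_p", "linear_p", "spearman_p")])
  out$n_sig <- rowSums(pm < alpha, na.rm = TRUE)
  out
}

#' Select replication candidates from battery results
#'
#' Applies the three replication-candidate criteria: (1) nominal significance
#' in at least one battery test, (2) quantification by at least `min_peptides`
#' peptides, (3) detection in the molecular-weight range of the native
#' protein. Each criterion can be toggled.
#'
#' @param table battery result from [run_battery()].
#' @param peptide_counts named integer vector, peptides per feature.
#' @param native_mw named logical vector, native-MW detection flag per
#'   feature.
#' @param alpha nominal significance level.
#' @param min_peptides minimum peptide support (default 2).
#' @param require character subset of
#'   `c("significance", "peptides", "native_mw")`.
#' @return character vector of selected feature ids.
#' @export
select_candidates <- function(table, peptide_counts, native_mw,
                              alpha = 0.05, min_peptides = 2L,
                              require = c("significance", "peptides",
                                          "native_mw")) {
  require <- match.arg(require, several.ok = TRUE)
  feats <- table$feature
  missing_ann <- c(
    if ("peptides" %in% require) feats[!feats %in% names(peptide_counts)],
    if ("native_mw" %in% require) feats[!feats %in% names(native_mw)])
  if (length(missing_ann))
    stop("missing annotation for feature(s): ",
         paste(unique(missing_ann), collapse = ", "))
  keep <- rep(TRUE, length(feats))
  if ("significance" %in% require) {
    pm <- as.matrix(table[c("logistic_p", "mw_p", "linear_p", "spearman_p")])
    keep <- keep & rowSums(pm < alpha, na.rm = TRUE) >= 1
  }
  if ("peptides" %in% require)
    keep <- keep & peptide_counts[feats] >= min_peptides
  if ("native_mw" %in% require)
    keep <- keep & native_mw[feats]
  feats[keep]
}
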