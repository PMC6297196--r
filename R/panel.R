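#' Residualize features on covariates
#'
#' Replaces each feature by its residuals from a least-squares regression on
#' the covariates (intercept included), so that downstream classifiers see
#' covariate-free variation. With no covariates this mean-centers each
#' feature. Residuals are orthogonal to every covariate column by
#' construction.
#'
#' @param mat feature x sample matrix, complete cases (no `NA`).
#' @param covariates optional data frame of per-sample covariates.
#' @return adjusted matrix with attribute `covariates` recording the design
#'   columns used.
#' @export
glm_adjust <- function(mat, covariates = NULL) {
  stopifnot(is.matrix(mat))
  if (anyNA(mat))
    stop("matrix contains missing values; restrict to complete cases first")
  X <- if (is.null(covariates)) matrix(1, ncol(mat), 1,
                                       dimnames = list(NULL, "(Intercept)"))
       else model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qx$rank)]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  adj <- t(qr.resid(qx, t(mat)))
  dimnames(adj) <- dimnames(mat)
  attr(adj, "covariates") <- colnames(X)
  adj
}

#' Rank features by first entry into the LASSO path
#'
#' Fits the L1-regularized logistic path (features standardized internally)
#' and orders features by the largest penalty at which each first obtains a
#' nonzero coefficient; features that never enter are appended in index
#' order.
#'
#' @param mat feature x sample matrix.
#' @param labels 2-level class labels per sample.
#' @param nlambda length of the penalty path.
#' @return character vector of feature ids, strongest-first.
#' @export
lasso_rank <- function(mat, labels, nlambda = 100L) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  sds <- apply(mat, 1, sd)
  if (all(sds == 0)) stop("all features are constant")
  fit <- glmnet::glmnet(x = t(mat), y = y, family = "binomial", alpha = 1,
                        nlambda = nlambda, standardize = TRUE)
  beta <- as.matrix(fit$beta)
  entry <- apply(beta != 0, 1, function(r) if (any(r)) which(r)[1] else Inf)
  rownames(mat)[order(entry, seq_along(entry))]
}

# Rank-based AUC (Mann-Whitney identity); pos is a logical vector.
rank_auc <- function(dv, pos) {
  r <- rank(dv)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Train a linear SVM on selected features and return held-out decision
# values oriented so that larger means more likely the positive class.
svm_decision <- function(xtr, ytr, xte, pos_level, cost) {
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, sd)
  sdv[sdv == 0] <- 1
  xtr <- scale(xtr, mu, sdv)
  xte <- scale(xte, mu, sdv)
  m <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost, scale = FALSE)
  pr <- predict(m, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (first == pos_level) as.numeric(dv) else -as.numeric(dv)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Cross-validated AUC across panel sizes
#'
#' For panel sizes `1..max_size`, trains a linear-kernel SVM on the top-n
#' LASSO-ranked features and scores held-out folds under repeated stratified
#' cross-validation, pooling each repeat's held-out decision values into one
#' AUC. The feature ranking is recomputed inside every training fold by
#' default, so that feature selection never sees held-out data;
#' `rank_once = TRUE` reproduces the optimistic variant that ranks once on
#' the full data.
#'
#' @param mat feature x sample matrix (typically covariate-adjusted).
#' @param labels 2-level class labels; the second factor level is the
#'   positive class.
#' @param max_size largest panel size to evaluate.
#' @param repeats number of cross-validation repeats (default 100).
#' @param folds folds per repeat (default 10).
#' @param seed master seed; one child seed is drawn per repeat.
#' @param rank_once rank features once on the full data instead of within
#'   each training fold (leaks; for comparison only).
#' @param cost SVM cost parameter.
#' @return object of class `panel_sweep`: list with `curve` (data frame of
#'   `size`, `mean_auc`, `sd_auc`), `auc` (repeats x sizes matrix), and
#'   `ranking` (full-data ranking, for reporting).
#' @export
cv_auc_sweep <- function(mat, labels, max_size = min(10L, nrow(mat)),
                         repeats = 100L, folds = 10L, seed = 1L,
                         rank_once = FALSE, cost = 1) {
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  n <- ncol(mat)
  if (folds > min(table(y)))
    stop("folds exceed the size of the smaller class")
  if (folds >= n)
    stop("leave-one-out folds are not supported: per-fold pooling needs >= 2",
         " samples per fold")
  pos_level <- levels(y)[2]
  full_rank <- lasso_rank(mat, y)
  global_rank <- if (rank_once) full_rank else NULL

  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max, repeats)
  auc <- matrix(NA_real_, repeats, max_size)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    fold <- stratified_folds(y, folds)
    dv <- matrix(NA_real_, n, max_size)
    for (f in seq_len(folds)) {
      tr <- fold != f
      ranking <- if (rank_once) global_rank else lasso_rank(mat[, tr], y[tr])
      for (s in seq_len(max_size)) {
        feats <- ranking[seq_len(s)]
        dv[!tr, s] <- svm_decision(t(mat[feats, tr, drop = FALSE]), y[tr],
                                   t(mat[feats, !tr, drop = FALSE]),
                                   pos_level, cost)
      }
    }
    auc[r, ] <- vapply(seq_len(max_size),
                       function(s) rank_auc(dv[, s], y == pos_level),
                       numeric(1))
  }
  curve <- data.frame(size = seq_len(max_size),
                      mean_auc = colMeans(auc),
                      sd_auc = apply(auc, 2, sd))
  structure(list(curve = curve, auc = auc, ranking = full_rank),
            class = "panel_sweep")
}

#' Choose the minimal panel size from a CV AUC curve
#'
#' Rule `"max"`: the smallest size whose mean AUC attains the curve maximum.
#' Rule `"one_se"`: the smallest size whose mean AUC is within one SD (of
#' the best size's repeats) of the maximum.
#'
#' @param sweep a `panel_sweep` object, or a data frame with columns `size`,
#'   `mean_auc`, `sd_auc`.
#' @param rule `"max"` or `"one_se"`.
#' @return list with `size`, `features` (`NULL` when only a curve was
#'   given), and `rule`.
#' @export
select_minimal_panel <- function(sweep, rule = c("max", "one_se")) {
  rule <- match.arg(rule)
  curve <- if (inherits(sweep, "panel_sweep")) sweep$curve else sweep
  if (!nrow(curve)) stop("empty panel curve")
  best <- which.max(curve$mean_auc)
  thr <- if (rule == "max") curve$mean_auc[best] - 1e-12
         else curve$mean_auc[best] - curve$sd_auc[best]
  size <- min(curve$size[curve$mean_auc >= thr])
  features <- if (inherits(sweep, "panel_sweep"))
    sweep$ranking[seq_len(size)] else NULL
  list(size = size, features = features, rule = rule)
}

#' Cross-validated operating metrics of a fixed panel
#'
#' Trains the linear SVM on the given panel under repeated stratified
#' cross-validation, pools all held-out decision values, picks the operating
#' threshold maximizing Youden's J on the pooled values, and reports AUC,
#' sensitivity, specificity, PPV and NPV from the pooled confusion counts.
#'
#' @param mat feature x sample matrix.
#' @param labels 2-level class labels; second level is positive.
#' @param panel character vector of feature ids.
#' @param repeats,folds,seed,cost as in [cv_auc_sweep()].
#' @return list with `auc`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `threshold`, and `roc` (data frame of pooled FPR/TPR).
#' @export
evaluate_panel <- function(mat, labels, panel, repeats = 100L, folds = 10L,
                           seed = 1L, cost = 1) {
  missing <- setdiff(panel, rownames(mat))
  if (length(missing))
    stop("panel features not in matrix: ", paste(missing, collapse = ", "))
  y <- factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  if (folds > min(table(y)))
    stop("folds exceed the size of the smaller class")
  pos_level <- levels(y)[2]
  n <- ncol(mat)

  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max, repeats)
  all_dv <- numeric(0); all_pos <- logical(0)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    fold <- stratified_folds(y, folds)
    dv <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      dv[!tr] <- svm_decision(t(mat[panel, tr, drop = FALSE]), y[tr],
                              t(mat[panel, !tr, drop = FALSE]),
                              pos_level, cost)
    }
    all_dv <- c(all_dv, dv)
    all_pos <- c(all_pos, y == pos_level)
  }
  auc <- rank_auc(all_dv, all_pos)
  thr_cand <- sort(unique(all_dv))
  cuts <- c(-Inf, (thr_cand[-1] + thr_cand[-length(thr_cand)]) / 2)
  stats <- vapply(cuts, function(tc) {
    pred <- all_dv > tc
    c(sens = sum(pred & all_pos) / sum(all_pos),
      spec = sum(!pred & !all_pos) / sum(!all_pos))
  }, numeric(2))
  j <- stats["sens", ] + stats["spec", ] - 1
  bi <- which.max(j)
  threshold <- cuts[bi]
  pred <- all_dv > threshold
  if (length(unique(pred)) == 1)
    warning("degenerate pooled predictions: all samples on one side of the ",
            "threshold")
  tp <- sum(pred & all_pos); fp <- sum(pred & !all_pos)
  fn <- sum(!pred & all_pos); tn <- sum(!pred & !all_pos)
  roc <- data.frame(fpr = 1 - stats["spec", ], tpr = stats["sens", ])
  list(auc = auc,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       threshold = threshold, roc = roc)
}
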