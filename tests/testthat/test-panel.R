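planted_data <- function(n = 120, p = 20, k = 3, effect = 1.2, seed = 1) {
  set.seed(seed)
  labels <- factor(rep(c("neg", "pos"), each = n / 2),
                   levels = c("neg", "pos"))
  mat <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("F%03d", seq_len(p)), NULL))
  mat[seq_len(k), labels == "pos"] <- mat[seq_len(k), labels == "pos"] + effect
  list(mat = mat, labels = labels)
}

test_that("covariate residualization is an orthogonal projection", {
  set.seed(40)
  n <- 50
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  mat <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("f", 1:5), NULL))
  adj <- glm_adjust(mat, covs)
  X <- model.matrix(~ ., covs)
  expect_lt(max(abs(adj %*% X)), 1e-9)

  # no covariates -> mean centering
  cen <- glm_adjust(mat)
  expect_equal(cen, mat - rowMeans(mat), ignore_attr = TRUE)

  # a feature equal to a covariate residualizes to zero
  mat2 <- rbind(mat, cov_copy = covs$age)
  adj2 <- glm_adjust(mat2, covs)
  expect_lt(max(abs(adj2["cov_copy", ])), 1e-9)

  expect_error(glm_adjust(mat, data.frame(a = covs$age, b = 2 * covs$age)),
               "rank deficient")
  mat[1, 1] <- NA
  expect_error(glm_adjust(mat, covs), "missing")
})

test_that("LASSO ranking puts planted features first", {
  hits <- 0L
  for (i in 1:100) {
    d <- planted_data(n = 80, p = 15, k = 1, effect = 2, seed = i)
    if (lasso_rank(d$mat, d$labels)[1] == "F001") hits <- hits + 1L
  }
  expect_gte(hits, 95)

  # a duplicated informative feature: the L1 path activates one of the
  # pair (which one is unspecified; the other may stay at zero throughout)
  d <- planted_data(n = 120, p = 20, k = 1, effect = 2, seed = 7)
  dup <- d$mat
  dup["F010", ] <- dup["F001", ] + rnorm(ncol(dup), 0, 1e-6)
  rk <- lasso_rank(dup, d$labels)
  expect_true(rk[1] %in% c("F001", "F010"))

  expect_error(lasso_rank(d$mat, rep("pos", ncol(d$mat))), "single class")
  const <- matrix(1, 3, 20, dimnames = list(paste0("c", 1:3), NULL))
  expect_error(lasso_rank(const, rep(c("a", "b"), 10)), "constant")
})

test_that("CV AUC is high for a separable feature and flat under the null", {
  d <- planted_data(n = 60, p = 5, k = 1, effect = 50, seed = 2)
  sw <- cv_auc_sweep(d$mat, d$labels, max_size = 2, repeats = 3, folds = 5,
                     seed = 1)
  expect_gte(sw$curve$mean_auc[1], 0.99)

  d0 <- planted_data(n = 80, p = 10, k = 0, seed = 3)
  sw0 <- cv_auc_sweep(d0$mat, d0$labels, max_size = 3, repeats = 5,
                      folds = 5, seed = 1)
  expect_true(all(abs(sw0$curve$mean_auc - 0.5) < 0.12))

  expect_error(cv_auc_sweep(d$mat, d$labels, folds = 60), "smaller class")
  expect_error(cv_auc_sweep(d$mat, d$labels, folds = 60, repeats = 1),
               "smaller class")
})

test_that("leave-one-out folds are rejected", {
  d <- planted_data(n = 20, p = 4, k = 1, seed = 4)
  lab <- factor(rep(c("neg", "pos"), 10), levels = c("neg", "pos"))
  expect_error(cv_auc_sweep(d$mat, lab, folds = 20, repeats = 1),
               "leave-one-out|smaller class")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  dv <- rnorm(60)
  pos <- rbinom(60, 1, 0.5) == 1
  ours <- endosig:::rank_auc(dv, pos)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = dv,
                                           levels = c(FALSE, TRUE),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
  # invariant under strictly monotone transforms of the decision values
  expect_equal(endosig:::rank_auc(exp(dv / 2), pos), ours)
})

test_that("minimal panel selection follows the stated rules", {
  curve <- data.frame(size = 1:4, mean_auc = c(0.6, 0.7, 0.7, 0.69),
                      sd_auc = c(0.05, 0.05, 0.05, 0.05))
  expect_equal(select_minimal_panel(curve, "max")$size, 2)
  flat <- data.frame(size = 1:4, mean_auc = rep(0.6, 4), sd_auc = rep(0, 4))
  expect_equal(select_minimal_panel(flat, "max")$size, 1)
  inc <- data.frame(size = 1:4, mean_auc = c(0.5, 0.6, 0.7, 0.8),
                    sd_auc = rep(0, 4))
  expect_equal(select_minimal_panel(inc, "max")$size, 4)
  ose <- data.frame(size = 1:3, mean_auc = c(0.68, 0.66, 0.70),
                    sd_auc = c(0.02, 0.02, 0.03))
  expect_equal(select_minimal_panel(ose, "one_se")$size, 1)
  expect_error(select_minimal_panel(flat[0, ]), "empty")
})

test_that("panel evaluation reports coherent operating metrics", {
  d <- planted_data(n = 60, p = 4, k = 1, effect = 50, seed = 5)
  ev <- evaluate_panel(d$mat, d$labels, "F001", repeats = 3, folds = 5,
                       seed = 1)
  expect_gte(ev$auc, 0.99)
  expect_gte(ev$sensitivity, 0.99)
  expect_gte(ev$specificity, 0.99)
  expect_gte(ev$ppv, 0.99)
  expect_gte(ev$npv, 0.99)

  # under the null the CV AUC centers on 0.5 (averaged over datasets to
  # tame per-dataset Monte-Carlo noise)
  auc0 <- mean(sapply(1:8, function(i) {
    d0 <- planted_data(n = 100, p = 4, k = 0, seed = 100 + i)
    evaluate_panel(d0$mat, d0$labels, c("F001", "F002"), repeats = 2,
                   folds = 5, seed = i)$auc
  }))
  expect_lt(abs(auc0 - 0.5), 0.08)
  expect_error(evaluate_panel(d$mat, d$labels, "nope"), "not in matrix")
})
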