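make_pq <- function(intensities, channels, peptides, plex = 1,
                    ref_channel = "131") {
  # one protein, one isoform; intensities indexed [peptide, channel]
  df <- expand.grid(peptide = peptides, channel = channels,
                    stringsAsFactors = FALSE)
  df$plex <- plex
  df$protein <- "P1"
  df$isoform <- "P1_iso1"
  df$intensity <- as.vector(intensities)
  df$sample <- ifelse(df$channel == ref_channel, NA_character_,
                      paste0("S_", df$channel))
  attr(df, "ref_channel") <- ref_channel
  df
}

test_that("median ratio normalization removes channel-level scale factors", {
  ref <- c(10, 20, 40)
  pq <- make_pq(cbind("126" = ref,          # identical to reference
                      "127" = ref * 2,      # globally scaled x2
                      "131" = ref),
                c("126", "127", "131"), paste0("pep", 1:3))
  out <- median_ratio_normalize(pq)
  expect_equal(out$log2_ratio[out$channel == "126"], rep(0, 3))
  expect_equal(out$log2_ratio[out$channel == "127"], rep(0, 3))
  expect_true(all(is.na(out$log2_ratio[out$channel == "131"])))

  # single peptide in a channel: median of one value is the value itself
  pq1 <- make_pq(cbind("126" = 5, "131" = 40), c("126", "131"), "pep1")
  out1 <- median_ratio_normalize(pq1)
  expect_equal(out1$log2_ratio[out1$channel == "126"], 0)
})

test_that("median ratio normalization is idempotent", {
  set.seed(1)
  pq <- make_pq(matrix(exp(rnorm(15, 3)), 5), c("126", "127", "131"),
                paste0("pep", 1:5))
  once <- median_ratio_normalize(pq)
  twice <- median_ratio_normalize(once)
  expect_equal(twice$intensity, once$intensity, tolerance = 1e-12)
  expect_equal(twice$log2_ratio, once$log2_ratio, tolerance = 1e-12)
})

test_that("normalization fails when a plex lacks the reference channel", {
  pq <- make_pq(cbind("126" = c(1, 2)), "126", paste0("pep", 1:2), plex = 7)
  expect_error(median_ratio_normalize(pq), "plex 7")
})

test_that("roll-up reproduces hand-computed medians and means", {
  # one isoform, three peptides with log2 ratios (0, 1, 2) and (0, 0, 3)
  mk <- function(lr) {
    pq <- make_pq(cbind("126" = 2^lr * 100, "131" = rep(100, 3)),
                  c("126", "131"), paste0("pep", 1:3))
    pqn <- median_ratio_normalize(pq)
    # undo the median-centering shift so the raw ratios are the target
    pqn$log2_ratio[pqn$channel == "126"] <- lr
    pqn
  }
  m_med <- rollup_isoforms(mk(c(0, 1, 2)), "median")
  m_mean <- rollup_isoforms(mk(c(0, 1, 2)), "mean")
  expect_equal(unname(m_med["P1_iso1", ]), 1)
  expect_equal(unname(m_mean["P1_iso1", ]), 1)
  expect_equal(unname(rollup_isoforms(mk(c(0, 0, 3)), "median")[1, ]), 0)
  expect_equal(unname(rollup_isoforms(mk(c(0, 0, 3)), "mean")[1, ]), 1)
  expect_error(rollup_isoforms(mk(c(0, 1, 2)), "trimmed"), "arg")
})

test_that("roll-up stays within the peptide range and handles singletons", {
  cfg <- tiny_config()
  s <- simulate_cohort(cfg)
  pqn <- median_ratio_normalize(simulate_tmt(s$proteins, cfg))
  med <- rollup_isoforms(pqn, "median")
  avg <- rollup_isoforms(pqn, "mean")
  study <- pqn[pqn$channel != "131" & !is.na(pqn$log2_ratio), ]
  key <- split(study$log2_ratio, paste(study$isoform, study$sample))
  for (k in sample(names(key), 50)) {
    parts <- strsplit(k, " ")[[1]]
    lo <- min(key[[k]]); hi <- max(key[[k]])
    expect_gte(med[parts[1], parts[2]] + 1e-12, lo)
    expect_lte(med[parts[1], parts[2]] - 1e-12, hi)
    expect_gte(avg[parts[1], parts[2]] + 1e-12, lo)
    expect_lte(avg[parts[1], parts[2]] - 1e-12, hi)
  }
})

test_that("detection filter uses an inclusive boundary over plexes", {
  m <- matrix(rnorm(30), 3, dimnames = list(c("a", "b", "c"), NULL))
  attr(m, "detection") <- c(a = 0.8, b = 0.7, c = 1.0)
  kept <- filter_detection(m, 0.8)
  expect_setequal(rownames(kept), c("a", "c")) # 8/10 kept, 7/10 dropped
  expect_equal(rownames(filter_detection(m, 0)), rownames(m))
  expect_error(filter_detection(m, 1.5), "0, 1")

  # detection fractions computed over plexes by the roll-up, not samples
  cfg <- tiny_config(n_subjects = 20, plex_missing_prob = 0.3)
  s <- simulate_cohort(cfg)
  iso <- rollup_isoforms(median_ratio_normalize(simulate_tmt(s$proteins,
                                                             cfg)))
  pq <- simulate_tmt(s$proteins, cfg)
  n_plex <- length(unique(pq$plex))
  brute <- tapply(pq$plex, pq$isoform, function(z) length(unique(z))) / n_plex
  expect_equal(unname(attr(iso, "detection")),
               as.numeric(brute[rownames(iso)]))
})

test_that("5PL fit recovers parameters and inverts in closed form", {
  truth <- list(a = 0.04, d = 2.8, c = 35, b = 1.4, g = 0.7)
  x <- 35 * 3^seq(-3.5, 3.5)
  y <- fivepl_forward(x, truth)
  fit <- fit_5pl(x, y)
  for (par in c("a", "d", "c", "b", "g"))
    expect_equal(fit[[par]] / truth[[par]], 1, tolerance = 1e-4)

  # midpoint identity: y(c) = d + (a - d) / 2^g, and its inversion
  y_mid <- truth$d + (truth$a - truth$d) / 2^truth$g
  expect_equal(fivepl_forward(truth$c, truth), y_mid)
  expect_equal(invert_5pl(truth, y_mid), truth$c)

  # round trip over the standard range
  xs <- seq(min(x), max(x), length.out = 40)
  expect_equal(invert_5pl(fit, fivepl_forward(xs, fit)) / xs,
               rep(1, 40), tolerance = 1e-8)

  # asymptotes are out of range, reported not clamped
  expect_error(invert_5pl(truth, truth$a), "out of range")
  expect_error(invert_5pl(truth, truth$d + 1), "out of range")
  expect_error(fit_5pl(x, rep(1, length(x))), "degenerate")
  expect_error(fit_5pl(x[1:4], y[1:4]), "6 standards")
})

test_that("a symmetric 4PL is recovered when the asymmetry is free", {
  truth <- list(a = 0.1, d = 2, c = 50, b = 1.2, g = 1)
  x <- 50 * 2^seq(-4, 4)
  fit <- fit_5pl(x, fivepl_forward(x, truth))
  expect_equal(fit$g, 1, tolerance = 1e-3)
})

test_that("coefficients of variation match hand-computed values", {
  dup <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                    value = c(10, 10, 9, 11))
  cv <- compute_cv(dup, control = data.frame(plate = 1:3, value = c(5, 5, 5)))
  expect_equal(unname(cv$per_sample["s1"]), 0)
  expect_equal(unname(cv$per_sample["s2"]), 100 * sqrt(2) / 10)
  expect_equal(cv$intra_cv, (0 + 14.14214) / 2, tolerance = 1e-4)
  expect_equal(cv$inter_cv, 0)
  expect_error(compute_cv(data.frame(sample = "s", value = c(1, -1))),
               "zero mean")
})

test_that("log10 transform plus IQR cleaning removes extreme outliers", {
  m <- matrix(c(1, 2, 3, 4, 100), 1,
              dimnames = list("f1", paste0("s", 1:5)))
  out <- log10_and_clean(m, iqr_multiplier = 3, scale = "raw")
  # Q1 = 2, Q3 = 4, fences [-4, 10]: only the 100 is removed
  expect_equal(out$removed$sample, "s5")
  expect_equal(out$removed$value, 100)
  expect_true(is.na(out$matrix["f1", "s5"]))
  expect_equal(out$matrix["f1", "s1"], 0)

  all_eq <- matrix(rep(7, 5), 1, dimnames = list("f", paste0("s", 1:5)))
  expect_equal(nrow(log10_and_clean(all_eq)$removed), 0)
  expect_equal(nrow(log10_and_clean(m, iqr_multiplier = Inf)$removed), 0)
  expect_error(log10_and_clean(matrix(c(-1, 2), 1)), "non-positive")
})
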