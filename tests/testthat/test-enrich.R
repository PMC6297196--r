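test_that("Fisher combination matches closed forms and the identity case", {
  expect_equal(combine_isoform_pvalues(0.05)$p, 0.05)
  r <- combine_isoform_pvalues(c(0.1, 0.1))
  expect_equal(r$X, -2 * (log(0.1) + log(0.1)))
  expect_equal(r$X, 9.21034, tolerance = 1e-5)
  # chi-squared(4) survival has closed form exp(-X/2) * (1 + X/2)
  expect_equal(r$p, exp(-r$X / 2) * (1 + r$X / 2))
  expect_equal(r$p, 0.056052, tolerance = 1e-5)
  expect_equal(combine_isoform_pvalues(c(1, 1))$p, 1)
  expect_error(combine_isoform_pvalues(c(0, 0.5)), "\\(0, 1\\]")
  expect_equal(combine_isoform_pvalues(c(0, 0.5), floor = 1e-10)$k, 2)
})

test_that("Fisher tail agrees with numerical integration for k <= 5", {
  set.seed(30)
  for (k in 1:5) {
    p <- runif(k, 0.005, 0.9)
    r <- combine_isoform_pvalues(p)
    expect_lt(abs(r$p - chisq_tail_integrate(r$X, 2 * k)), 1e-10)
  }
})

test_that("per-protein combination and score transform", {
  tbl <- data.frame(protein = c("A", "A", "B"), p = c(0.1, 0.1, 0.01))
  cb <- combine_by_protein(tbl)
  expect_equal(cb$k, c(2L, 1L))
  expect_equal(cb$p[2], 0.01)
  s <- transform_scores(cb)
  expect_equal(unname(s["B"]), 2)
  expect_equal(unname(transform_scores(c(X = 1))), 0)
  # monotone: score order reverses p order
  set.seed(31)
  p <- runif(20)
  expect_equal(order(transform_scores(p)), rev(order(p)))
})

test_that("network expansion averages measured neighbors above threshold", {
  scores <- c(A = 0.2, B = 0.4)
  net <- data.frame(node1 = c("A", "B", "A"),
                    node2 = c("U", "U", "V"),
                    confidence = c(0.9, 0.8, 0.4))
  out <- expand_network(scores, net, min_conf = 0.4)
  expect_equal(out$score[out$node == "U"], 0.3)
  # V is linked only by a confidence-0.4 edge: strictly excluded
  expect_false("V" %in% out$node)
  expect_equal(out$score[out$node == "A"], 0.2)
  expect_equal(out$provenance[out$node == "A"], "measured")
  expect_equal(out$provenance[out$node == "U"], "expanded")
  expect_error(expand_network(scores, net[0, ]), "empty network")

  # adding a sub-threshold edge never changes the output
  net2 <- rbind(net, data.frame(node1 = "B", node2 = "W",
                                confidence = 0.1))
  expect_equal(expand_network(scores, net2, 0.4), out)

  # overwrite mode replaces measured nodes that have measured neighbors
  net3 <- data.frame(node1 = "A", node2 = "B", confidence = 0.9)
  ow <- expand_network(scores, net3, overwrite_measured = TRUE)
  expect_equal(ow$score[ow$node == "A"], 0.4)
  expect_equal(ow$score[ow$node == "B"], 0.2)
})

test_that("KS statistic matches brute force and its invariances", {
  expect_equal(ks_enrichment(c(a = 0.9, b = 0.8, c = 0.2, d = 0.1),
                             c("a", "b"))$D, 1)
  s <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(ks_enrichment(s, c("a", "b"))$D, 0)
  expect_error(ks_enrichment(s, letters[1:4]), "outside")
  expect_error(ks_enrichment(s, "zz"), "inside")

  set.seed(32)
  for (i in 1:25) {
    sc <- setNames(rnorm(12), paste0("g", 1:12))
    set <- sample(names(sc), sample(2:10, 1))
    D <- ks_enrichment(sc, set)$D
    expect_equal(D, ks_brute(sc[names(sc) %in% set],
                             sc[!names(sc) %in% set]))
    # invariant under strictly monotone transforms of all scores
    expect_equal(ks_enrichment(exp(sc) + 3, set)$D, D)
  }
})

test_that("permutation p-values agree with exact enumeration on tiny universes", {
  set.seed(33)
  for (i in 1:5) {
    sc <- setNames(runif(8), paste0("g", 1:8))
    k <- sample(2:6, 1)
    set <- sample(names(sc), k)
    res <- permutation_correct(sc, setNames(list(set), "s1"),
                               B = 4000, seed = i)
    exact <- ks_perm_exact(unname(sc), k, res$D)
    mc_err <- 4 * sqrt(max(exact, 1 / 4000) * (1 - exact) / 4000) + 2 / 4001
    expect_lt(abs(res$p_perm - exact), mc_err + 1e-12)
  }
})

test_that("permutation p-values respect their structural bounds", {
  sc <- setNames(c(10, 9, 8, rep(0, 17)), paste0("g", 1:20))
  coll <- list(top = c("g1", "g2", "g3"))
  res <- permutation_correct(sc, coll, B = 500, seed = 1)
  # observed D = 1 can only be tied by the (rare) identical null subset
  expect_gte(res$p_perm, 1 / 501) # the add-one correction keeps p > 0
  expect_lt(res$p_perm, 0.02)
  expect_equal(res$D, 1)
  # an all-tied score vector gives D = 0 for any set -> p = 1
  flat <- setNames(rep(1, 10), paste0("g", 1:10))
  res0 <- permutation_correct(flat, list(s = paste0("g", 1:3)),
                              B = 200, seed = 1)
  expect_equal(res0$D, 0)
  expect_equal(res0$p_perm, 1)
  expect_error(permutation_correct(sc, coll, B = 50), "at least 100")
  expect_warning(res_e <- permutation_correct(sc, list(), B = 200),
                 "empty")
  expect_equal(nrow(res_e), 0)
})

test_that("the enrichment pipeline flags a planted set and reports sizes", {
  cfg <- tiny_config(n_subjects = 40, n_proteins = 60,
                     n_signal_proteins = 8, seed = 5)
  s <- simulate_cohort(cfg)
  subj <- s$subjects
  lp <- log10_and_clean(s$proteins)$matrix
  subj$group <- dichotomize(subj$pathology_score)
  batt <- run_battery(lp[, subj$subject], subj$group, subj$pathology_score)
  iso_p <- data.frame(protein = batt$feature, p = batt$spearman_p)
  net <- simulate_network(cfg, s$truth)
  sets <- simulate_gene_sets(cfg, s$truth, n_sets = 6, set_size = 12)
  enr <- enrich_pipeline(iso_p, net, sets, B = 2000, seed = 9)
  res <- enr$results[[1]]
  planted <- attr(sets, "enriched")
  expect_lte(res$p_perm[res$set == planted], 0.01)
  expect_equal(enr$report$n_proteins_combined, 60)
  expect_gt(enr$report$n_expanded_universe, 60) # unmeasured interactors added
})
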