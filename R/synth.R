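#' Simulation configuration
#'
#' Bundles the knobs of the synthetic cohort generator. The defaults emulate a
#' two-extreme CSF-pathology study arm: ~100 subjects, 200 plasma proteins of
#' which 10 carry a planted association with the CSF tau/amyloid pathology
#' score, negatively correlated CSF tTau and Abeta42, and TMT-style
#' multi-peptide, multi-isoform quantification with plex-level dropout.
#'
#' @param n_subjects number of subjects.
#' @param n_proteins number of proteins on the measured panel.
#' @param n_signal_proteins number of proteins with a true (nonzero) effect of
#'   the pathology score; must not exceed `n_proteins`.
#' @param effect_size standardized shift of log10 concentration per unit
#'   pathology z-score, in units of the residual SD `noise_sd`.
#' @param csf_corr correlation between log CSF tTau and log Abeta42, in
#'   `[-1, 0]` (biologically negative: more tau, less amyloid).
#' @param covariate_effects named numeric vector of per-covariate slopes on the
#'   log10 concentration scale; small nonzero defaults so covariate
#'   adjustment downstream is actually exercised.
#' @param peptides_per_protein peptides generated per protein isoform.
#' @param isoform_prob probability that a protein yields a second
#'   molecular-weight isoform.
#' @param plex_missing_prob probability that an isoform drops out of a given
#'   TMT plex entirely.
#' @param batch_sd SD of per-batch, per-protein shifts (log10 scale).
#' @param noise_sd residual SD of log10 concentrations; must be positive.
#' @param seed integer RNG seed; all generators are deterministic given the
#'   configuration and seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 100L, n_proteins = 200L,
                       n_signal_proteins = 10L, effect_size = 0.8,
                       csf_corr = -0.4,
                       covariate_effects = c(age = 0.005, sex = 0.05,
                                             apoe_e4 = 0.08,
                                             storage_years = 0.01,
                                             bmi = 0.003, diabetes = 0.04),
                       peptides_per_protein = 3L, isoform_prob = 0.2,
                       plex_missing_prob = 0.1, batch_sd = 0.1,
                       noise_sd = 0.3, seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_subjects < 1 || n_proteins < 1 || peptides_per_protein < 1)
    stop("invalid config: dimensions must be positive integers")
  if (n_signal_proteins < 0 || n_signal_proteins > n_proteins)
    stop("invalid config: n_signal_proteins must be in [0, n_proteins]")
  if (csf_corr < -1 || csf_corr > 0)
    stop("invalid config: csf_corr must lie in [-1, 0]")
  for (p in c(isoform_prob, plex_missing_prob))
    if (p < 0 || p > 1) stop("invalid config: probabilities must lie in [0, 1]")
  if (noise_sd <= 0) stop("invalid config: noise_sd must be positive")
  if (batch_sd < 0) stop("invalid config: batch_sd must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_proteins = as.integer(n_proteins),
                 n_signal_proteins = as.integer(n_signal_proteins),
                 effect_size = effect_size, csf_corr = csf_corr,
                 covariate_effects = covariate_effects,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 isoform_prob = isoform_prob,
                 plex_missing_prob = plex_missing_prob,
                 batch_sd = batch_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a stratified cohort with CSF measures and protein concentrations
#'
#' Draws subjects with demographic and technical covariates, bivariate
#' log-normal CSF tTau/Abeta42 with the configured (negative) correlation,
#' pTau proportional to tTau plus noise, and a protein concentration matrix in
#' which exactly `n_signal_proteins` proteins depend linearly (on the log10
#' scale) on the standardized CSF pathology score. PET amyloid status and
#' MCI-conversion status are derived noisily from the same score so that
#' classification endpoints exist.
#'
#' @param config a [sim_config()].
#' @return list with `subjects` (data frame), `proteins` (n_proteins x
#'   n_subjects matrix of raw concentrations), and `truth` (list with
#'   `signal_protein_ids` and named `true_effect` on the log10 scale).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  P <- config$n_proteins
  id <- sprintf("S%04d", seq_len(n))

  age <- rnorm(n, 67, 8)
  sex <- rbinom(n, 1, 0.5)
  apoe_e4 <- rbinom(n, 1, 0.35)
  storage_years <- runif(n, 1, 10)
  bmi <- rnorm(n, 26, 4)
  diabetes <- rbinom(n, 1, 0.08)
  center <- sample(c("Perugia", "Barcelona", "Milan"), n, replace = TRUE)
  batch <- sprintf("B%02d", ((seq_len(n) - 1L) %/% 10L) + 1L)

  # bivariate log-normal CSF: log tTau ~ N(log 400, 0.5), log Abeta42 ~ N(log 700, 0.4)
  sig <- matrix(c(0.5^2, config$csf_corr * 0.5 * 0.4,
                  config$csf_corr * 0.5 * 0.4, 0.4^2), 2, 2)
  lcsf <- MASS::mvrnorm(n, mu = c(log(400), log(700)), Sigma = sig)
  ttau <- exp(lcsf[, 1])
  abeta42 <- exp(lcsf[, 2])
  ptau <- pmax(0.2 * ttau + rnorm(n, 0, 5), 1)

  x <- pathology_score(ttau, abeta42)
  pathz <- as.numeric(scale(log(x)))
  pet_status <- as.integer(runif(n) < plogis(3 * (x - 1)))
  mci_converter <- as.integer(runif(n) < plogis(1.5 * pathz - 0.5))

  subjects <- data.frame(subject = id, age = age, sex = sex,
                         apoe_e4 = apoe_e4, storage_years = storage_years,
                         bmi = bmi, diabetes = diabetes, center = center,
                         batch = batch, abeta42 = abeta42, ttau = ttau,
                         ptau = ptau, pathology_score = x,
                         pathology_z = pathz, pet_status = pet_status,
                         mci_converter = mci_converter,
                         stringsAsFactors = FALSE)

  prot_id <- sprintf("P%04d", seq_len(P))
  signal_ids <- if (config$n_signal_proteins > 0)
    sort(sample(prot_id, config$n_signal_proteins)) else character(0)
  beta <- setNames(numeric(P), prot_id)
  if (length(signal_ids))
    beta[signal_ids] <- config$effect_size * config$noise_sd *
      sample(c(-1, 1), length(signal_ids), replace = TRUE)

  mu <- rnorm(P, 2, 0.5)
  covs <- cbind(age = scale(age)[, 1], sex = sex, apoe_e4 = apoe_e4,
                storage_years = scale(storage_years)[, 1],
                bmi = scale(bmi)[, 1], diabetes = diabetes)
  ce <- config$covariate_effects
  ce <- ce[intersect(names(ce), colnames(covs))]
  cov_term <- if (length(ce)) as.numeric(covs[, names(ce), drop = FALSE] %*% ce)
              else numeric(n)
  batches <- unique(batch)
  beff <- matrix(rnorm(P * length(batches), 0, config$batch_sd), P,
                 dimnames = list(prot_id, batches))

  log10conc <- matrix(mu, P, n) + outer(beta, pathz) +
    matrix(cov_term, P, n, byrow = TRUE) + beff[, batch, drop = FALSE] +
    matrix(rnorm(P * n, 0, config$noise_sd), P, n)
  proteins <- 10^log10conc
  dimnames(proteins) <- list(prot_id, id)

  list(subjects = subjects, proteins = proteins,
       truth = list(signal_protein_ids = signal_ids, true_effect = beta))
}

#' Simulate peptide-level TMT quantification
#'
#' Tiles subjects into TMT6plex runs of 5 study channels (126-130) plus a
#' reference channel (131) equal to the arithmetic mean of the plex's study
#' channels ("pooled" reference). Each protein is expanded into
#' `peptides_per_protein` peptides per molecular-weight isoform; with
#' probability `isoform_prob` a protein emits a second isoform carrying a
#' fixed share of its abundance. Whole isoforms drop out of a plex with
#' probability `plex_missing_prob`. Measurement noise is log-normal.
#'
#' @param proteins protein x subject matrix of raw concentrations.
#' @param config a [sim_config()].
#' @return data frame with columns `plex`, `channel`, `sample`, `protein`,
#'   `isoform`, `peptide`, `intensity` and attribute `ref_channel = "131"`.
#'   Reference-channel rows have `sample = NA`.
#' @export
simulate_tmt <- function(proteins, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(proteins))
  if (ncol(proteins) < 1) stop("need at least one subject")
  set.seed(config$seed + 1L)
  P <- nrow(proteins)
  prot_id <- rownames(proteins)
  samples <- colnames(proteins)
  n <- length(samples)
  n_plex <- ceiling(n / 5)
  channels <- c("126", "127", "128", "129", "130")

  n_iso <- 1L + rbinom(P, 1L, config$isoform_prob)
  share1 <- ifelse(n_iso == 2L, runif(P, 0.6, 0.9), 1)

  rows <- vector("list", n_plex)
  for (px in seq_len(n_plex)) {
    idx <- ((px - 1L) * 5L + 1L):min(px * 5L, n)
    plex_samples <- samples[idx]
    plex_channels <- channels[seq_along(idx)]
    out <- list()
    for (p in seq_len(P)) {
      for (iso in seq_len(n_iso[p])) {
        if (runif(1) < config$plex_missing_prob) next
        iso_id <- sprintf("%s_iso%d", prot_id[p], iso)
        share <- if (iso == 1L) share1[p] else 1 - share1[p]
        for (pep in seq_len(config$peptides_per_protein)) {
          pep_id <- sprintf("%s_pep%d", iso_id, pep)
          ion <- exp(rnorm(1, 0, 0.5))
          base <- proteins[p, plex_samples] * share * ion * 1e3
          inten <- base * 10^rnorm(length(idx), 0, config$noise_sd / 3)
          ref <- mean(inten)
          out[[length(out) + 1L]] <- data.frame(
            plex = px,
            channel = c(plex_channels, "131"),
            sample = c(plex_samples, NA_character_),
            protein = prot_id[p], isoform = iso_id, peptide = pep_id,
            intensity = c(inten, ref), stringsAsFactors = FALSE)
        }
      }
    }
    rows[[px]] <- do.call(rbind, out)
  }
  pq <- do.call(rbind, rows)
  rownames(pq) <- NULL
  attr(pq, "ref_channel") <- "131"
  pq
}

#' Simulate a scored protein-protein interaction network
#'
#' Generates an undirected edge list with confidence scores in `[0, 1]` over
#' the measured proteins plus `n_extra` unmeasured interactors (so that
#' network expansion has nodes to fill in). When `truth` is supplied, a dense
#' module over the signal proteins is planted: every within-module edge is
#' present with confidence at least 0.7.
#'
#' @param config a [sim_config()].
#' @param truth optional ground truth from [simulate_cohort()].
#' @param density background edge density in `[0, 1]`.
#' @param n_extra number of unmeasured nodes to add.
#' @param plant_module plant the signal-protein module? Defaults to `TRUE`
#'   when `truth` is supplied.
#' @return data frame with columns `node1`, `node2`, `confidence`.
#' @export
simulate_network <- function(config, truth = NULL, density = 0.02,
                             n_extra = ceiling(config$n_proteins / 2),
                             plant_module = !is.null(truth)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_proteins < 2) stop("need at least two proteins")
  set.seed(config$seed + 2L)
  nodes <- c(sprintf("P%04d", seq_len(config$n_proteins)),
             if (n_extra > 0) sprintf("N%04d", seq_len(n_extra)))
  nn <- length(nodes)
  n_edges <- round(density * nn * (nn - 1) / 2)
  edges <- NULL
  if (n_edges > 0) {
    i <- sample.int(nn, 2 * n_edges, replace = TRUE)
    j <- sample.int(nn, 2 * n_edges, replace = TRUE)
    keep <- i != j
    a <- pmin(i, j)[keep]; b <- pmax(i, j)[keep]
    dup <- duplicated(paste(a, b))
    a <- a[!dup][seq_len(min(n_edges, sum(!dup)))]
    b <- b[!dup][seq_len(min(n_edges, sum(!dup)))]
    edges <- data.frame(node1 = nodes[a], node2 = nodes[b],
                        confidence = runif(length(a), 0.05, 1),
                        stringsAsFactors = FALSE)
  }
  if (plant_module && length(truth$signal_protein_ids) >= 2) {
    sp <- sort(truth$signal_protein_ids)
    pairs <- t(combn(sp, 2))
    mod <- data.frame(node1 = pairs[, 1], node2 = pairs[, 2],
                      confidence = runif(nrow(pairs), 0.7, 1),
                      stringsAsFactors = FALSE)
    edges <- rbind(edges, mod)
  }
  if (is.null(edges))
    return(data.frame(node1 = character(0), node2 = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  # dedup unordered pairs, keep max confidence
  a <- pmin(edges$node1, edges$node2); b <- pmax(edges$node1, edges$node2)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$confidence)
  keep <- !duplicated(key[ord])
  out <- data.frame(node1 = a[ord][keep], node2 = b[ord][keep],
                    confidence = edges$confidence[ord][keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate gene-set collections with planted enrichment
#'
#' Builds a named list of gene sets over the measured protein universe:
#' `n_enriched` sets contain at least `overlap_fraction` signal proteins
#' (padded with random proteins to `set_size`), the rest are uniform random
#' ("null") sets. With no signal proteins all sets are null.
#'
#' @param config a [sim_config()].
#' @param truth ground truth from [simulate_cohort()].
#' @param n_sets total number of sets.
#' @param set_size genes per set; must not exceed the universe size.
#' @param n_enriched number of signal-loaded sets.
#' @param overlap_fraction target fraction of the enriched set made of signal
#'   proteins.
#' @param universe optional character vector of gene ids; defaults to the
#'   measured protein ids.
#' @return named list of character vectors, with attribute `enriched` naming
#'   the planted sets.
#' @export
simulate_gene_sets <- function(config, truth, n_sets = 10L, set_size = 20L,
                               n_enriched = 1L, overlap_fraction = 0.8,
                               universe = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  if (is.null(universe)) universe <- sprintf("P%04d", seq_len(config$n_proteins))
  if (set_size > length(universe))
    stop("requested set size exceeds the gene universe")
  sig <- intersect(truth$signal_protein_ids, universe)
  sets <- list()
  enriched_names <- character(0)
  for (i in seq_len(n_enriched)) {
    k_sig <- min(ceiling(overlap_fraction * set_size), length(sig))
    if (k_sig > 0) {
      members <- sample(sig, k_sig)
      pad <- sample(setdiff(universe, members), set_size - k_sig)
      nm <- sprintf("ENRICHED_%d", i)
      sets[[nm]] <- sort(c(members, pad))
      enriched_names <- c(enriched_names, nm)
    } else {
      sets[[sprintf("NULL_E%d", i)]] <- sort(sample(universe, set_size))
    }
  }
  for (i in seq_len(n_sets - length(sets)))
    sets[[sprintf("NULL_%d", i)]] <- sort(sample(universe, set_size))
  attr(sets, "enriched") <- enriched_names
  sets
}

#' Simulate an ELISA plate with duplicate wells and a 5PL standard curve
#'
#' Generates background-corrected absorbances from the forward five-parameter
#' logistic model plus Gaussian noise: a dilution series of standards
#' spanning the curve, duplicate wells for every sample, and (optionally) a
#' control sample repeated on each plate for inter-assay CV.
#'
#' @param true_conc named vector of true sample concentrations (must be > 0).
#' @param curve list with 5PL parameters `a`, `d`, `c`, `b`, `g`
#'   (see [fit_5pl()] for the parameterization); `b` must be nonzero.
#' @param noise_sd SD of additive absorbance noise.
#' @param seed RNG seed.
#' @param n_standards number of standards (>= 6).
#' @param dilution fold-dilution between consecutive standards.
#' @param n_plates number of plates; samples are split across plates.
#' @param control_conc concentration of the per-plate control sample, or
#'   `NULL` for none.
#' @return data frame with columns `type` (standard/sample/control),
#'   `sample`, `conc_true`, `replicate`, `plate`, `absorbance`.
#' @export
simulate_elisa_plate <- function(true_conc, curve = list(a = 0.05, d = 3,
                                                         c = 50, b = 1.3,
                                                         g = 1),
                                 noise_sd = 0.02, seed = 1L,
                                 n_standards = 8L, dilution = 3,
                                 n_plates = 1L, control_conc = NULL) {
  if (any(true_conc <= 0)) stop("concentrations must be positive")
  if (curve$b == 0) stop("curve shape parameter b must be nonzero")
  if (n_standards < 6) stop("need at least 6 standards")
  set.seed(seed)
  std_conc <- curve$c * dilution^(seq_len(n_standards) - (n_standards + 1) / 2)
  if (is.null(names(true_conc)))
    names(true_conc) <- sprintf("S%04d", seq_along(true_conc))
  plate_of <- rep(seq_len(n_plates), length.out = length(true_conc))

  mk <- function(type, sample, conc, plate) {
    do.call(rbind, lapply(1:2, function(rep_i)
      data.frame(type = type, sample = sample, conc_true = conc,
                 replicate = rep_i, plate = plate,
                 absorbance = fivepl_forward(conc, curve) +
                   rnorm(length(conc), 0, noise_sd),
                 stringsAsFactors = FALSE)))
  }
  out <- list()
  for (pl in seq_len(n_plates)) {
    out[[length(out) + 1L]] <- mk("standard",
                                  sprintf("STD%d_plate%d",
                                          seq_len(n_standards), pl),
                                  std_conc, pl)
    sel <- plate_of == pl
    if (any(sel))
      out[[length(out) + 1L]] <- mk("sample", names(true_conc)[sel],
                                    unname(true_conc[sel]), pl)
    if (!is.null(control_conc))
      out[[length(out) + 1L]] <- mk("control", "CONTROL", control_conc, pl)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
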