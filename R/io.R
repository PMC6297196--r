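#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are removed with a warning.
#'
#' @param path file path.
#' @return named list of character vectors with attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i,
           ": need at least 3 tab-separated fields")
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' (line ", i,
              ") removed")
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions") %||%
      setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored interaction network
#'
#' Three tab- or whitespace-separated columns: node, node, confidence. An
#' optional header line is detected. The edge list is made undirected and
#' deduplicated keeping the maximum confidence per pair; self-loops are
#' dropped with a warning; edges with confidence at or below `min_conf` are
#' dropped (strict threshold).
#'
#' @param path file path.
#' @param min_conf confidence threshold; default 0 keeps all positive-score
#'   edges.
#' @return data frame with columns `node1`, `node2`, `confidence`.
#' @export
read_network <- function(path, min_conf = 0) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(node1 = character(0), node2 = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "[\t ]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(parts[[1]][3])))) start <- 2L
  n1 <- character(0); n2 <- character(0); cf <- numeric(0)
  for (i in seq(start, length(parts))) {
    f <- parts[[i]]
    if (length(f) < 3)
      stop("network parse error at line ", i, ": need 3 columns")
    v <- suppressWarnings(as.numeric(f[3]))
    if (is.na(v))
      stop("network parse error at line ", i, ": non-numeric confidence '",
           f[3], "'")
    n1 <- c(n1, f[1]); n2 <- c(n2, f[2]); cf <- c(cf, v)
  }
  loops <- n1 == n2
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped")
  n1s <- pmin(n1, n2)[!loops]; n2s <- pmax(n1, n2)[!loops]; cf <- cf[!loops]
  key <- paste(n1s, n2s, sep = "\r")
  ord <- order(key, -cf)
  keep <- !duplicated(key[ord])
  out <- data.frame(node1 = n1s[ord][keep], node2 = n2s[ord][keep],
                    confidence = cf[ord][keep], stringsAsFactors = FALSE)
  out <- out[out$confidence > min_conf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network edge list
#'
#' @param network data frame with columns `node1`, `node2`, `confidence`.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  write.table(network, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature x sample matrix from TSV
#'
#' First column holds feature ids, the header row holds sample ids. Empty
#' cells and `NA` are missing. Duplicate feature ids and ragged rows are
#' errors.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty matrix file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  samples <- header[-1]
  nc <- length(header)
  feats <- character(length(parts) - 1L)
  vals <- matrix(NA_real_, length(parts) - 1L, length(samples))
  for (i in seq_along(parts)[-1]) {
    f <- parts[[i]]
    # trailing empty cells are dropped by strsplit; pad them back
    if (length(f) < nc) f <- c(f, rep("", nc - length(f)))
    if (length(f) != nc)
      stop("ragged row at line ", i, ": expected ", nc, " fields, got ",
           length(f))
    feats[i - 1L] <- f[1]
    v <- f[-1]
    v[v == ""] <- NA
    vals[i - 1L, ] <- suppressWarnings(as.numeric(v))
  }
  if (anyDuplicated(feats))
    stop("duplicate feature id(s): ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  dimnames(vals) <- list(feats, samples)
  vals
}

#' Write a feature x sample matrix to TSV
#'
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the feature id column (default `"feature"`).
#' @export
write_matrix <- function(mat, path, id_col = "feature") {
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    paste(c(rownames(mat)[i], ifelse(is.na(v), "", format(v, digits = 15,
                                                          trim = TRUE,
                                                          scientific = FALSE))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write a subject phenotype table (CSV)
#'
#' Thin wrappers over [utils::read.csv()]/[utils::write.csv()] fixing the
#' dialect used throughout the pipeline.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_subjects <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_subjects
#' @param subjects data frame of subjects.
#' @export
write_subjects <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full pipeline on synthetic data
#'
#' End-to-end orchestration: simulate a cohort with TMT quantification, a
#' network and gene sets; normalize, roll up and filter; compute the CSF
#' pathology endotype; run the four-test battery; run the enrichment chain;
#' select and evaluate a minimal classification panel. All inputs and
#' outputs are written under `out_dir` and a run report records seeds,
#' parameters and row counts at every filter step.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param rollup_method `"median"` or `"mean"`.
#' @param min_detect detection-fraction filter, default 0.8.
#' @param alpha nominal significance level.
#' @param min_conf network confidence threshold.
#' @param B permutation iterations for enrichment.
#' @param panel_repeats,panel_folds,panel_max_size cross-validation settings
#'   for the panel sweep.
#' @param seed master seed; defaults to the configuration seed.
#' @return invisibly, a list with the main stage outputs and the run report.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         rollup_method = "median", min_detect = 0.8,
                         alpha = 0.05, min_conf = 0.4, B = 2000L,
                         panel_repeats = 10L, panel_folds = 5L,
                         panel_max_size = 10L, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  report <- list(seed = config$seed, parameters = list(
    rollup_method = rollup_method, min_detect = min_detect, alpha = alpha,
    min_conf = min_conf, B = B, panel_repeats = panel_repeats,
    panel_folds = panel_folds))

  # synth
  sim <- simulate_cohort(config)
  pq <- simulate_tmt(sim$proteins, config)
  network <- simulate_network(config, sim$truth)
  sets <- simulate_gene_sets(config, sim$truth)
  write_subjects(sim$subjects, file.path(out_dir, "subjects.csv"))
  write_matrix(sim$proteins, file.path(out_dir, "proteins.tsv"))
  write_network(network, file.path(out_dir, "network.tsv"))
  write_gmt(sets, file.path(out_dir, "sets.gmt"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  # quantify
  pqn <- median_ratio_normalize(pq)
  iso <- rollup_isoforms(pqn, method = rollup_method)
  report$n_isoforms <- nrow(iso)
  iso_f <- filter_detection(iso, min_detect)
  report$n_isoforms_detected <- nrow(iso_f)
  write_matrix(iso_f, file.path(out_dir, "isoform_matrix.tsv"))

  # endotype
  subj <- sim$subjects
  subj$group <- dichotomize(subj$pathology_score)
  report$n_high <- sum(subj$group == "high")
  report$n_low <- sum(subj$group == "low")

  # assoc on the isoform matrix (discovery arm)
  covars <- subj[c("age", "sex", "apoe_e4", "storage_years")]
  m <- iso_f[, subj$subject, drop = FALSE]
  battery <- run_battery(m, subj$group, subj$pathology_score,
                         covariates = covars, alpha = alpha)
  write.table(battery, file.path(out_dir, "associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$n_features_tested <- nrow(battery)
  report$n_nominal <- sum(battery$n_sig >= 1, na.rm = TRUE)

  # enrich (isoform p's -> proteins -> network -> sets)
  iso_p <- data.frame(protein = sub("_iso\\d+$", "", battery$feature),
                      p = battery$spearman_p, stringsAsFactors = FALSE)
  iso_p <- iso_p[!is.na(iso_p$p), , drop = FALSE]
  enr <- enrich_pipeline(iso_p, network, list(simulated = sets),
                         min_conf = min_conf, B = B, seed = config$seed,
                         p_floor = 1e-300)
  write.table(enr$results$simulated,
              file.path(out_dir, "enrichment_simulated.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$enrich <- enr$report

  # panel on the log10 protein matrix against PET status
  lp <- log10_and_clean(sim$proteins)$matrix
  cc <- colSums(is.na(lp)) == 0
  adj <- glm_adjust(lp[, cc, drop = FALSE], covars[cc, , drop = FALSE])
  labels <- factor(subj$pet_status[cc], levels = c(0, 1),
                   labels = c("negative", "positive"))
  sweep <- cv_auc_sweep(adj, labels, max_size = panel_max_size,
                        repeats = panel_repeats, folds = panel_folds,
                        seed = config$seed)
  sel <- select_minimal_panel(sweep)
  metrics <- evaluate_panel(adj, labels, sel$features,
                            repeats = panel_repeats, folds = panel_folds,
                            seed = config$seed)
  write.table(sweep$curve, file.path(out_dir, "panel_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(size = sel$size, features = sel$features,
                            rule = sel$rule,
                            metrics = metrics[c("auc", "sensitivity",
                                                "specificity", "ppv",
                                                "npv", "threshold")]),
                       file.path(out_dir, "panel_result.json"),
                       auto_unbox = TRUE, digits = NA)
  report$panel_size <- sel$size
  report$panel_auc <- metrics$auc

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(battery = battery, enrichment = enr, sweep = sweep,
                 panel = sel, metrics = metrics, report = report))
}
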