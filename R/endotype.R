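#' CSF tau/amyloid pathology score
#'
#' Computes the discrimination-line score `x = (373 + 0.82 * tTau) / Abeta42`
#' from CSF total tau and Abeta42 (both in pg/mL). Higher values indicate a
#' more AD-like CSF profile; `x = 1` is the natural boundary of the
#' discrimination line.
#'
#' @param ttau CSF total tau, pg/mL (>= 0).
#' @param abeta42 CSF Abeta42, pg/mL (> 0).
#' @return dimensionless score(s).
#' @export
pathology_score <- function(ttau, abeta42) {
  if (any(abeta42 <= 0)) stop("abeta42 must be positive")
  if (any(ttau < 0)) stop("ttau must be non-negative")
  (373 + 0.82 * ttau) / abeta42
}

#' Dichotomize pathology scores
#'
#' Assigns `"high"` when the score strictly exceeds the threshold, else
#' `"low"` (a score exactly at the threshold is low).
#'
#' @param x pathology scores (> 0).
#' @param threshold boundary, default 1 (the discrimination line itself).
#' @return character vector of `"low"`/`"high"`.
#' @export
dichotomize <- function(x, threshold = 1) {
  if (any(x <= 0)) stop("pathology scores must be positive")
  ifelse(x > threshold, "high", "low")
}

#' Select extreme low- and high-score subjects
#'
#' Returns the `k` lowest and `k` highest scoring subject ids (the
#' extreme-phenotype design). Ties are broken by subject id order for
#' determinism; a tie crossing a selection boundary triggers a warning.
#'
#' @param scores named numeric vector of pathology scores.
#' @param k group size; `2 * k` must not exceed the number of subjects.
#' @return list with `low` and `high` character vectors of ids.
#' @export
select_extremes <- function(scores, k) {
  n <- length(scores)
  if (2 * k > n) stop("2 * k exceeds the number of subjects")
  if (is.null(names(scores))) names(scores) <- as.character(seq_len(n))
  ord <- order(scores, names(scores))
  ids <- names(scores)[ord]
  s <- scores[ord]
  if (k == 0) return(list(low = character(0), high = character(0)))
  if (k < n && s[k] == s[k + 1])
    warning("tie at the low-group boundary; broken by subject id order")
  if (k < n && s[n - k + 1] == s[n - k])
    warning("tie at the high-group boundary; broken by subject id order")
  list(low = ids[seq_len(k)], high = ids[seq(n - k + 1, n)])
}

#' Default per-cohort CSF cutoffs (pg/mL)
#'
#' Center-provided cutoff values for assigning high/low pathology in the
#' multi-center validation design: Perugia (Abeta42 800, tTau 300, pTau 60),
#' Barcelona (550, 350, 61) and Milan (600, 450, 61).
#'
#' @return data frame with columns `cohort`, `abeta42`, `ttau`, `ptau`.
#' @export
default_csf_cutoffs <- function() {
  data.frame(cohort = c("Perugia", "Barcelona", "Milan"),
             abeta42 = c(800, 550, 600),
             ttau = c(300, 350, 450),
             ptau = c(60, 61, 61), stringsAsFactors = FALSE)
}

#' Assign per-measure pathology labels from cohort-specific cutoffs
#'
#' Amyloid pathology is high when Abeta42 falls strictly below the cohort
#' cutoff (low CSF Abeta42 = more brain amyloid); tau/pTau pathology is high
#' when the measure strictly exceeds its cutoff. Values exactly at a cutoff
#' are labeled low.
#'
#' @param profile data frame with columns `cohort`, `abeta42`, `ttau`, and
#'   optionally `ptau`.
#' @param cutoffs cutoff table as from [default_csf_cutoffs()].
#' @return `profile` with added columns `amyloid_pathology`, `tau_pathology`
#'   and (if pTau present) `ptau_pathology`, each `"low"`/`"high"`.
#' @export
apply_cutoffs <- function(profile, cutoffs = default_csf_cutoffs()) {
  unknown <- setdiff(profile$cohort, cutoffs$cohort)
  if (length(unknown))
    stop("unknown cohort(s): ", paste(unknown, collapse = ", "))
  i <- match(profile$cohort, cutoffs$cohort)
  profile$amyloid_pathology <-
    ifelse(profile$abeta42 < cutoffs$abeta42[i], "high", "low")
  profile$tau_pathology <-
    ifelse(profile$ttau > cutoffs$ttau[i], "high", "low")
  if (!is.null(profile$ptau))
    profile$ptau_pathology <-
      ifelse(profile$ptau > cutoffs$ptau[i], "high", "low")
  profile
}

#' Harmonize a CSF measure across cohorts by within-cohort z-scoring
#'
#' Each cohort's values are standardized to mean 0 and SD 1 independently,
#' then combined into a single continuous variable, removing center-specific
#' assay scales.
#'
#' @param values numeric measurements.
#' @param cohort cohort label per value.
#' @return numeric vector of z-scores, aligned with `values`.
#' @export
harmonize_zscores <- function(values, cohort) {
  stopifnot(length(values) == length(cohort))
  z <- rep(NA_real_, length(values))
  for (co in unique(cohort)) {
    sel <- which(cohort == co & !is.na(values))
    if (length(sel) < 2)
      stop("cohort ", co, " has fewer than 2 subjects with values")
    s <- sd(values[sel])
    if (s == 0) stop("zero within-cohort sd in cohort ", co)
    z[sel] <- (values[sel] - mean(values[sel])) / s
  }
  z
}
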