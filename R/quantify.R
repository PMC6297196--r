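#' Forward five-parameter logistic curve
#'
#' Evaluates `y = d + (a - d) / (1 + (x / c)^b)^g`, where `a` is the
#' asymptote at zero concentration, `d` the asymptote at infinite
#' concentration, `c` the midpoint concentration, `b` the slope and `g` the
#' asymmetry.
#'
#' @param x concentrations (> 0).
#' @param curve list or `fivepl` object with elements `a`, `d`, `c`, `b`, `g`.
#' @return absorbances.
#' @export
fivepl_forward <- function(x, curve) {
  with(curve, d + (a - d) / (1 + (x / c)^b)^g)
}

#' Median-ratio normalize a peptide quantification set
#'
#' For every plex, peptide intensities are expressed as log2 ratios to the
#' matching reference-channel peptide, and each plex x channel is rescaled so
#' that the median of its log2 ratios is zero (multiplicative channel biases
#' such as loading differences cancel). The returned table carries both the
#' rescaled intensities and a `log2_ratio` column; missing entries are left
#' untouched. The operation is idempotent.
#'
#' @param pq data frame with columns `plex`, `channel`, `protein`, `isoform`,
#'   `peptide`, `intensity` (positive where present), and optionally
#'   `sample`.
#' @param ref_channel label of the reference channel; defaults to the
#'   `ref_channel` attribute of `pq`, else `"131"`.
#' @return `pq` with rescaled `intensity` and a `log2_ratio` column
#'   (`NA` for reference rows).
#' @export
median_ratio_normalize <- function(pq, ref_channel = NULL) {
  if (is.null(ref_channel))
    ref_channel <- attr(pq, "ref_channel") %||% "131"
  need <- c("plex", "channel", "protein", "isoform", "peptide", "intensity")
  if (!all(need %in% names(pq)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  for (px in unique(pq$plex))
    if (!any(pq$channel[pq$plex == px] == ref_channel))
      stop("plex ", px, " lacks reference channel ", ref_channel)

  is_ref <- pq$channel == ref_channel
  key <- paste(pq$plex, pq$peptide, sep = "\r")
  ref_int <- setNames(pq$intensity[is_ref], key[is_ref])
  lr <- log2(pq$intensity / ref_int[key])
  lr[is_ref] <- NA_real_

  grp <- paste(pq$plex, pq$channel, sep = "\r")
  med <- tapply(lr, grp, median, na.rm = TRUE)
  shift <- as.numeric(med[grp])
  shift[is_ref | is.na(shift)] <- 0
  pq$intensity <- pq$intensity / 2^shift
  pq$log2_ratio <- lr - ifelse(is_ref, 0, shift)
  pq$log2_ratio[is_ref] <- NA_real_
  attr(pq, "ref_channel") <- ref_channel
  pq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Roll peptides up to molecular-weight isoform values
#'
#' Aggregates normalized peptide log2 ratios into one value per isoform and
#' sample by the median or mean. Both methods are provided because analyses
#' are routinely run on both roll-ups. By default aggregation happens on the
#' log2 scale; `scale = "ratio"` aggregates raw ratios and reports their
#' log2.
#'
#' @param pq normalized peptide table (see [median_ratio_normalize()]).
#' @param method `"median"` or `"mean"`.
#' @param scale `"log2"` (default) or `"ratio"`.
#' @return isoform x sample matrix of log2 ratios with attributes
#'   `detection` (per-isoform fraction of plexes in which the isoform was
#'   observed) and `n_plex`.
#' @export
rollup_isoforms <- function(pq, method = c("median", "mean"),
                            scale = c("log2", "ratio")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  if (is.null(pq$log2_ratio))
    stop("input is not normalized; run median_ratio_normalize() first")
  ref_channel <- attr(pq, "ref_channel") %||% "131"
  study <- pq[pq$channel != ref_channel, , drop = FALSE]
  sample_id <- if (!is.null(study$sample) && !all(is.na(study$sample)))
    study$sample else paste(study$plex, study$channel, sep = "_")

  v <- study$log2_ratio
  if (scale == "ratio") v <- 2^v
  agg <- if (method == "median")
    function(z) median(z, na.rm = TRUE) else function(z) mean(z, na.rm = TRUE)
  tab <- tapply(v, list(study$isoform, sample_id), agg)
  m <- matrix(unlist(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  if (scale == "ratio") m <- log2(m)
  m[is.nan(m)] <- NA_real_

  n_plex <- length(unique(pq$plex))
  obs <- unique(pq[!is.na(pq$intensity), c("isoform", "plex")])
  det <- tapply(obs$plex, obs$isoform, function(z) length(unique(z))) / n_plex
  det <- det[rownames(m)]
  attr(m, "detection") <- setNames(as.numeric(det), rownames(m))
  attr(m, "n_plex") <- n_plex
  m
}

#' Filter isoforms by detection fraction across plexes
#'
#' Retains isoforms observed in at least `min_fraction` of the TMT plexes
#' (inclusive boundary: detection in exactly 80% of plexes passes the default
#' filter).
#'
#' @param m isoform matrix from [rollup_isoforms()], or any matrix with a
#'   `detection` attribute.
#' @param min_fraction minimum detection fraction in `[0, 1]`.
#' @return the filtered matrix, detection attribute subset accordingly.
#' @export
filter_detection <- function(m, min_fraction = 0.8) {
  if (min_fraction < 0 || min_fraction > 1)
    stop("min_fraction must lie in [0, 1]")
  det <- attr(m, "detection")
  if (is.null(det)) stop("matrix lacks a detection attribute")
  keep <- det >= min_fraction
  out <- m[keep, , drop = FALSE]
  attr(out, "detection") <- det[keep]
  attr(out, "n_plex") <- attr(m, "n_plex")
  out
}

#' Fit a five-parameter logistic standard curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x / c)^b)^g` to a standard
#' series by Levenberg-Marquardt. `a` is the zero-concentration asymptote.
#'
#' @param concentration standard concentrations (> 0, >= 6 points).
#' @param absorbance matching absorbances.
#' @return object of class `fivepl`: list with `a`, `d`, `c`, `b`, `g`,
#'   `resid_sd`, `fitted`.
#' @export
fit_5pl <- function(concentration, absorbance) {
  if (length(concentration) < 6)
    stop("need at least 6 standards spanning the curve")
  if (any(concentration <= 0)) stop("standard concentrations must be > 0")
  if (diff(range(absorbance)) < .Machine$double.eps^0.5)
    stop("degenerate standards: absorbance is constant")
  df <- data.frame(x = concentration, y = absorbance)
  ord <- order(df$x)
  rising <- df$y[ord][which.max(df$x)] > df$y[ord][1]
  start <- list(a = min(df$y) - 0.001, d = max(df$y) + 0.001,
                c = exp(mean(log(df$x))), b = if (rising) 1 else 1, g = 1)
  if (!rising) { start$a <- max(df$y) + 0.001; start$d <- min(df$y) - 0.001 }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b)^g, data = df,
                      start = start,
                      lower = c(a = -Inf, d = -Inf, c = 1e-12, b = -Inf,
                                g = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("5PL fit failed to converge (last state: ",
                             conditionMessage(e), ")", call. = FALSE))
  cf <- as.list(coef(fit))
  structure(c(cf, list(resid_sd = sqrt(mean(residuals(fit)^2)),
                       fitted = fitted(fit))),
            class = "fivepl")
}

#' @export
predict.fivepl <- function(object, newdata, ...) {
  fivepl_forward(newdata, object)
}

#' Invert a five-parameter logistic curve
#'
#' Closed-form inversion of the 5PL: for an absorbance strictly between the
#' two asymptotes, returns the unique concentration mapping to it. Values at
#' or beyond an asymptote are reported as out of range, never clamped.
#'
#' @param curve a `fivepl` object or parameter list.
#' @param absorbance absorbances to invert.
#' @return concentrations.
#' @export
invert_5pl <- function(curve, absorbance) {
  lo <- min(curve$a, curve$d); hi <- max(curve$a, curve$d)
  if (any(absorbance <= lo | absorbance >= hi))
    stop("absorbance out of range: must lie strictly between the asymptotes (",
         signif(lo, 6), ", ", signif(hi, 6), ")")
  with(curve, c * (((a - d) / (absorbance - d))^(1 / g) - 1)^(1 / b))
}

#' Intra- and inter-assay coefficients of variation
#'
#' Intra-assay CV is the mean over samples of `100 * sd / mean` of duplicate
#' wells; inter-assay CV is `100 * sd / mean` of a control sample measured
#' across plates.
#'
#' @param duplicates data frame with columns `sample`, `value` (>= 2 values
#'   per sample).
#' @param control optional data frame with columns `plate`, `value`
#'   (>= 2 plates).
#' @return list with `intra_cv` (%), `inter_cv` (% or `NA`), and
#'   `per_sample` (named vector of per-sample CVs).
#' @export
compute_cv <- function(duplicates, control = NULL) {
  stopifnot(all(c("sample", "value") %in% names(duplicates)))
  cv1 <- function(v) {
    m <- mean(v)
    if (m == 0) stop("zero mean in CV computation")
    100 * sd(v) / m
  }
  per <- tapply(duplicates$value, duplicates$sample, function(v) {
    if (length(v) < 2) stop("need >= 2 replicate measurements per sample")
    cv1(v)
  })
  inter <- NA_real_
  if (!is.null(control)) {
    stopifnot(all(c("plate", "value") %in% names(control)))
    if (nrow(control) < 2) stop("control must be measured on >= 2 plates")
    inter <- cv1(control$value)
  }
  list(intra_cv = mean(per), inter_cv = inter,
       per_sample = setNames(as.numeric(per), names(per)))
}

#' Log10-transform a concentration matrix and remove extreme outliers
#'
#' Values are log10-transformed; per feature, values outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` are set to missing and logged. By default
#' the fences are computed on the log10 scale (the scale the downstream
#' statistics use); `scale = "raw"` computes them on raw concentrations.
#' Quartiles use linear interpolation between order statistics (R type 7);
#' `quartile_type` selects an alternative convention.
#'
#' @param mat feature x sample matrix of positive concentrations (NA allowed).
#' @param iqr_multiplier fence multiplier `k` (default 3); `Inf` disables
#'   cleaning.
#' @param scale `"log10"` (default) or `"raw"`: scale on which fences are
#'   computed.
#' @param quartile_type quantile type passed to [stats::quantile()].
#' @return list with `matrix` (log10-transformed, outliers `NA`) and
#'   `removed` (data frame of feature, sample, value on the fence scale).
#' @export
log10_and_clean <- function(mat, iqr_multiplier = 3,
                            scale = c("log10", "raw"), quartile_type = 7) {
  scale <- match.arg(scale)
  if (iqr_multiplier < 0) stop("iqr_multiplier must be non-negative")
  if (any(mat <= 0, na.rm = TRUE))
    stop("non-positive values present; cannot log10 transform")
  logm <- log10(mat)
  basis <- if (scale == "log10") logm else mat
  removed <- list()
  for (i in seq_len(nrow(mat))) {
    v <- basis[i, ]
    if (all(is.na(v))) next
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, type = quartile_type,
                  names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - iqr_multiplier * iqr
    hi <- q[2] + iqr_multiplier * iqr
    out <- which(!is.na(v) & (v < lo | v > hi))
    if (length(out)) {
      removed[[length(removed) + 1L]] <- data.frame(
        feature = rownames(mat)[i] %||% as.character(i),
        sample = colnames(mat)[out] %||% as.character(out),
        value = unname(v[out]), stringsAsFactors = FALSE)
      logm[i, out] <- NA_real_
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(feature = character(0), sample = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  list(matrix = logm, removed = removed)
}
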