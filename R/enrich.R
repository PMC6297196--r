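#' Combine isoform p-values by Fisher's method
#'
#' Combines the p-values of a protein's molecular-weight isoforms into one
#' protein-level p-value: `X = -2 * sum(log(p))` is referred to a chi-squared
#' distribution with `2k` degrees of freedom. With a single p-value the
#' combination is the identity.
#'
#' @param p isoform p-values, all in `(0, 1]`.
#' @param floor optional lower floor applied to p-values (default none;
#'   `p = 0` is an error).
#' @return list with `k`, `X`, `df`, `p`.
#' @export
combine_isoform_pvalues <- function(p, floor = NULL) {
  if (!length(p)) stop("need at least one p-value")
  if (!is.null(floor)) p <- pmax(p, floor)
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]; got a value <= 0 or > 1")
  k <- length(p)
  X <- -2 * sum(log(p))
  list(k = k, X = X, df = 2L * k,
       p = pchisq(X, df = 2 * k, lower.tail = FALSE))
}

#' Combine isoform p-values per protein
#'
#' Applies [combine_isoform_pvalues()] to every protein in an isoform-level
#' p-value table.
#'
#' @param isoform_p data frame with columns `protein` and `p`.
#' @param floor optional lower floor applied to p-values before combining
#'   (guards against p-values that underflow to exactly 0).
#' @return data frame with columns `protein`, `k`, `X`, `df`, `p`.
#' @export
combine_by_protein <- function(isoform_p, floor = NULL) {
  stopifnot(all(c("protein", "p") %in% names(isoform_p)))
  parts <- split(isoform_p$p, isoform_p$protein)
  out <- do.call(rbind, lapply(names(parts), function(pr) {
    cb <- combine_isoform_pvalues(parts[[pr]], floor = floor)
    data.frame(protein = pr, k = cb$k, X = cb$X, df = cb$df, p = cb$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Transform combined p-values to node scores
#'
#' Node score `s = -log10(p)`: larger scores indicate stronger association.
#'
#' @param p combined p-values in `(0, 1]`, optionally named by protein, or a
#'   data frame from [combine_by_protein()].
#' @return named numeric vector of scores.
#' @export
transform_scores <- function(p) {
  if (is.data.frame(p)) p <- setNames(p$p, p$protein)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  -log10(p)
}

#' Expand node scores over an interaction network
#'
#' Every network node with at least one measured direct neighbor linked by an
#' edge with confidence strictly above `min_conf` receives the arithmetic
#' mean of its measured neighbors' scores. Measured nodes keep their own
#' score by default (`overwrite_measured = FALSE`); unmeasured nodes without
#' qualifying neighbors are absent from the output.
#'
#' @param scores named numeric vector of measured node scores.
#' @param network data frame with columns `node1`, `node2`, `confidence`.
#' @param min_conf confidence threshold (edges at exactly `min_conf` are
#'   excluded).
#' @param overwrite_measured if `TRUE`, measured nodes with measured
#'   neighbors are also replaced by the neighbor average.
#' @return data frame with columns `node`, `score`, `provenance`
#'   (`"measured"` or `"expanded"`).
#' @export
expand_network <- function(scores, network, min_conf = 0.4,
                           overwrite_measured = FALSE) {
  if (is.null(network) || nrow(network) == 0) stop("empty network")
  stopifnot(all(c("node1", "node2", "confidence") %in% names(network)))
  net <- network[network$confidence > min_conf, , drop = FALSE]
  measured <- names(scores)
  from <- c(net$node1, net$node2)
  to <- c(net$node2, net$node1)
  keep <- to %in% measured
  from <- from[keep]; to <- to[keep]
  nb_mean <- tapply(scores[to], from, mean)

  nodes <- union(measured, names(nb_mean))
  score <- setNames(rep(NA_real_, length(nodes)), nodes)
  prov <- setNames(rep("expanded", length(nodes)), nodes)
  score[names(nb_mean)] <- nb_mean
  if (overwrite_measured) {
    own_only <- setdiff(measured, names(nb_mean))
    score[own_only] <- scores[own_only]
    prov[own_only] <- "measured"
  } else {
    score[measured] <- scores
    prov[measured] <- "measured"
  }
  data.frame(node = nodes, score = unname(score),
             provenance = unname(prov), stringsAsFactors = FALSE,
             row.names = NULL)
}

# One-sided two-sample KS statistic D = max_t (F_out(t) - F_in(t)), floored
# at 0, evaluated only at tie-group boundaries so ties are handled exactly.
ks_stat <- function(in_scores, out_scores) {
  n_in <- length(in_scores); n_out <- length(out_scores)
  pooled <- c(in_scores, out_scores)
  memb <- rep(c(TRUE, FALSE), c(n_in, n_out))
  o <- order(pooled)
  s <- pooled[o]; m <- memb[o]
  cin <- cumsum(m)
  cout <- seq_along(s) - cin
  valid <- c(s[-length(s)] != s[-1], TRUE)
  max(0, max(cout[valid] / n_out - cin[valid] / n_in))
}

#' Kolmogorov-Smirnov enrichment statistic for one gene set
#'
#' One-sided two-sample KS statistic comparing the score distribution of
#' genes inside the set against those outside, under the "in-set scores are
#' larger" alternative: `D = max_t (F_out(t) - F_in(t))`, in `[0, 1]`.
#'
#' @param scores named numeric vector over the scored gene universe.
#' @param set character vector of gene ids.
#' @param set_name label used in error messages.
#' @return list with `D` and `n_overlap`.
#' @export
ks_enrichment <- function(scores, set, set_name = "gene set") {
  inside <- names(scores) %in% set
  if (!any(inside))
    stop("no scored genes inside ", set_name)
  if (all(inside))
    stop("no scored genes outside ", set_name)
  list(D = ks_stat(scores[inside], scores[!inside]),
       n_overlap = sum(inside))
}

# Null draws of the one-sided KS statistic for a random size-k subset of the
# N sorted scores; `valid` marks tie-group boundaries of the sorted scores.
ks_null_draws <- function(N, k, B, valid) {
  n_out <- N - k
  idx <- seq_len(N)
  vapply(seq_len(B), function(b) {
    memb <- logical(N)
    memb[sample.int(N, k)] <- TRUE
    cin <- cumsum(memb)
    d <- (idx - cin) / n_out - cin / k
    max(0, max(d[valid]))
  }, numeric(1))
}

#' Permutation-calibrated enrichment over a gene-set collection
#'
#' For every set, the observed KS statistic is compared with a null built by
#' shuffling the score-to-gene assignment over the scored universe
#' (equivalent, for the KS statistic, to drawing random sets of the same
#' overlap size). The permutation p-value uses the add-one correction
#' `p = (1 + #[D_null >= D_obs]) / (B + 1)`, so `p >= 1/(B+1)` always.
#' BH q-values are computed across the sets of the collection.
#'
#' @param scores named numeric vector over the scored gene universe.
#' @param collection named list of gene sets (character vectors).
#' @param B number of permutation iterations (>= 100; default 50,000).
#' @param seed RNG seed.
#' @return data frame with columns `set`, `D`, `p_perm`, `q`, `n_overlap`.
#'   Sets with empty in- or out-universe are dropped with a warning.
#' @export
permutation_correct <- function(scores, collection, B = 50000L, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  if (!length(collection)) {
    warning("empty gene-set collection")
    return(data.frame(set = character(0), D = numeric(0),
                      p_perm = numeric(0), q = numeric(0),
                      n_overlap = integer(0), stringsAsFactors = FALSE))
  }
  set.seed(seed)
  N <- length(scores)
  s <- sort(scores)
  valid <- c(s[-length(s)] != s[-1], TRUE)
  rows <- lapply(names(collection), function(nm) {
    obs <- tryCatch(ks_enrichment(scores, collection[[nm]], nm),
                    error = function(e) NULL)
    if (is.null(obs)) return(NULL)
    null_D <- ks_null_draws(N, obs$n_overlap, B, valid)
    data.frame(set = nm, D = obs$D,
               p_perm = (1 + sum(null_D >= obs$D)) / (B + 1),
               n_overlap = obs$n_overlap, stringsAsFactors = FALSE)
  })
  dropped <- names(collection)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("set(s) without scored genes on both sides dropped: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(0), D = numeric(0),
                      p_perm = numeric(0), q = numeric(0),
                      n_overlap = integer(0), stringsAsFactors = FALSE))
  out$q <- bh_adjust(out$p_perm)
  out[c("set", "D", "p_perm", "q", "n_overlap")]
}

#' Full enrichment pipeline: combine, transform, expand, test
#'
#' Runs the pathway-analysis chain on an isoform-level p-value table:
#' Fisher's-method combination per protein, `-log10` score transform,
#' neighbor-average expansion over the interaction network, then
#' permutation-calibrated KS enrichment per gene-set collection with BH FDR
#' within each collection.
#'
#' @param isoform_p data frame with columns `protein` and `p` (isoform rows).
#' @param network interaction edge list (`node1`, `node2`, `confidence`).
#' @param collections named list of collections, each a named list of gene
#'   sets; a single collection is also accepted.
#' @param min_conf network confidence threshold (strict), default 0.4.
#' @param B permutation iterations, default 50,000.
#' @param seed RNG seed.
#' @param overwrite_measured see [expand_network()].
#' @param p_floor optional lower floor for isoform p-values before Fisher
#'   combination (see [combine_by_protein()]).
#' @return list with `results` (named list of per-collection data frames)
#'   and `report` (universe sizes at each stage).
#' @export
enrich_pipeline <- function(isoform_p, network, collections,
                            min_conf = 0.4, B = 50000L, seed = 1L,
                            overwrite_measured = FALSE, p_floor = NULL) {
  combined <- combine_by_protein(isoform_p, floor = p_floor)
  scores <- transform_scores(combined)
  expanded <- expand_network(scores, network, min_conf = min_conf,
                             overwrite_measured = overwrite_measured)
  escores <- setNames(expanded$score, expanded$node)
  if (!is.list(collections[[1]]))
    collections <- list(collection = collections)
  results <- lapply(collections, function(cl)
    permutation_correct(escores, cl, B = B, seed = seed))
  list(results = results,
       report = list(n_isoform_p = nrow(isoform_p),
                     n_proteins_combined = nrow(combined),
                     n_expanded_universe = nrow(expanded),
                     n_collections = length(collections)))
}
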