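# Independent oracles used across the suite. These deliberately use brute
# force / enumeration / numerical integration, never the code paths they
# check.

# Exact two-sided Mann-Whitney p by full enumeration of all label
# assignments (no ties assumed).
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  U_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) # U for the first group
  }
  all_idx <- combn(length(pooled), n1)
  Uall <- apply(all_idx, 2, U_of)
  Uobs <- U_of(seq_len(n1))
  pl <- mean(Uall <= Uobs); pg <- mean(Uall >= Uobs)
  min(1, 2 * min(pl, pg))
}

# Chi-squared upper tail by adaptive numerical integration.
chisq_tail_integrate <- function(X, df) {
  integrate(function(t) dchisq(t, df), lower = X, upper = Inf,
            rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# One-sided two-sample KS statistic (F_out above F_in), brute force over a
# grid of all pooled values.
ks_brute <- function(in_s, out_s) {
  ts <- sort(unique(c(in_s, out_s)))
  d <- vapply(ts, function(t) mean(out_s <= t) - mean(in_s <= t), numeric(1))
  max(0, max(d))
}

# Exact enrichment p by enumerating every size-k subset of a small universe.
ks_perm_exact <- function(scores, k, D_obs) {
  N <- length(scores)
  subsets <- combn(N, k)
  Dall <- apply(subsets, 2, function(idx)
    ks_brute(scores[idx], scores[-idx]))
  mean(Dall >= D_obs)
}

# Closed-form log odds ratio of a 2x2 table (cells: exposed/unexposed x
# outcome yes/no).
log_or_2x2 <- function(n11, n10, n01, n00) {
  log((n11 * n00) / (n10 * n01))
}

# Small simulation configuration used by most tests.
tiny_config <- function(...) {
  defaults <- list(n_subjects = 25, n_proteins = 30, n_signal_proteins = 4,
                   peptides_per_protein = 2, seed = 42)
  do.call(sim_config, modifyList(defaults, list(...)))
}
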