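# Build a canonical probe-profile tibble from plain matrices.
# signals / detection: probes x samples matrices with sample column names.
make_profile <- function(signals, detection, probe_class = NULL,
                         probe_id = NULL) {
  n <- nrow(signals)
  if (is.null(probe_id)) probe_id <- sprintf("P%04d", seq_len(n))
  if (is.null(probe_class)) probe_class <- rep("regular", n)
  out <- tibble::tibble(PROBE_ID = probe_id, PROBE_CLASS = probe_class)
  for (s in colnames(signals)) {
    out[[paste0(s, ".AVG_Signal")]] <- signals[, s]
    out[[paste0(s, ".Detection_Pval")]] <- detection[, s]
  }
  out
}

# A desk-scale simulation configuration; the small probe count forces a
# smaller triple-unique fraction than the full-scale default so the planted
# sets fit among well-expressed probes.
small_cfg <- function(...) {
  defaults <- list(n_probes = 2000, n_negative_controls = 200,
                   frac_deg_per_group = 0.02, frac_triple_unique = 0.3,
                   seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Brute-force quantile normalization: sort each column, average the sorted
# vectors, map the averages back by within-column rank (ties get the mean of
# their tied target values).
qn_oracle <- function(m) {
  sorted_mean <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- vapply(r, function(ri) {
      if (ri == floor(ri)) sorted_mean[ri]
      else mean(sorted_mean[c(floor(ri), ceiling(ri))])
    }, numeric(1))
  }
  out
}

# Exact hypergeometric upper tail by enumeration: fix the first m ids as the
# DEG set, enumerate every n-subset of the universe, count overlaps >= k.
hyper_tail_oracle <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= m)
  mean(overlaps >= k)
}

# Do the member sets form a laminar family (pairwise nested or disjoint)?
is_laminar_sets <- function(member_sets) {
  k <- length(member_sets)
  if (k < 2) return(TRUE)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- member_sets[[i]]; b <- member_sets[[j]]
      ab <- length(intersect(a, b))
      if (ab != 0 && ab != min(length(a), length(b))) return(FALSE)
    }
  }
  TRUE
}
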