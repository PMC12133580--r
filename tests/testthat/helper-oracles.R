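# Independent brute-force oracles used across the test files. These are
# deliberately written from scratch (plain dnorm sums, O(n*m) interval
# loops) so they share no code with the package's implementation paths.

# Silverman / Scott bandwidth, re-derived independently
oracle_bandwidth <- function(x, rule = "silverman") {
  n <- length(x)
  s <- stats::sd(x)
  h <- if (rule == "silverman") {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    0.9 * min(s, (q[2] - q[1]) / 1.34) * n^(-0.2)
  } else 1.06 * s * n^(-0.2)
  if (!is.finite(h) || h < 1e-6) 1e-6 else h
}

# Leave-one-out KDE classifier: for every sample recompute both
# class-conditional kernel sums from scratch, holding the sample out of its
# own class. Tie predicts reference.
oracle_loo_kde <- function(values, is_case, loo = TRUE) {
  h_case <- oracle_bandwidth(values[is_case])
  h_ref <- oracle_bandwidth(values[!is_case])
  n <- length(values)
  pred <- logical(n)
  for (i in seq_len(n)) {
    keep <- rep(TRUE, n)
    if (loo) keep[i] <- FALSE
    xc <- values[is_case & keep]
    xr <- values[!is_case & keep]
    dc <- mean(stats::dnorm((values[i] - xc) / h_case)) / h_case
    dr <- mean(stats::dnorm((values[i] - xr) / h_ref)) / h_ref
    pred[i] <- dc > dr
  }
  pred
}

oracle_mcc <- function(pred, actual) {
  tp <- sum(pred & actual); tn <- sum(!pred & !actual)
  fp <- sum(pred & !actual); fn <- sum(!pred & actual)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
}

# O(n*m) interval intersection on 0-based half-open coordinates
oracle_bound_genes <- function(peaks_df, prom_df, min_overlap = 1) {
  bound <- character(0)
  for (g in seq_len(nrow(prom_df))) {
    for (p in seq_len(nrow(peaks_df))) {
      if (peaks_df$chrom[p] != prom_df$chrom[g]) next
      ov <- min(peaks_df$end0[p], prom_df$end0[g]) -
        max(peaks_df$start0[p], prom_df$start0[g])
      if (ov >= min_overlap) { bound <- c(bound, prom_df$gene_id[g]); break }
    }
  }
  sort(unique(bound))
}

gr_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             gene_id = if (!is.null(names(gr))) names(gr) else NA_character_,
             stringsAsFactors = FALSE)
}

# small labelled-vector generator for classifier tests
make_labelled <- function(n, n_case, shift, seed) {
  withr::with_seed(seed, {
    values <- c(rnorm(n_case, shift), rnorm(n - n_case, 0))
    list(values = values,
         is_case = c(rep(TRUE, n_case), rep(FALSE, n - n_case)))
  })
}

# vectorised brute force: still an all-pairs O(n*m) comparison per gene,
# independent of any interval-index structure
oracle_bound_genes_vec <- function(peaks_df, prom_df, min_overlap = 1) {
  hit <- vapply(seq_len(nrow(prom_df)), function(g) {
    same <- peaks_df$chrom == prom_df$chrom[g]
    ov <- pmin(peaks_df$end0, prom_df$end0[g]) -
      pmax(peaks_df$start0, prom_df$start0[g])
    any(same & ov >= min_overlap)
  }, logical(1))
  sort(unique(prom_df$gene_id[hit]))
}
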