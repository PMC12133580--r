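#' Construct a labelled expression matrix
#'
#' Container for log2-scale expression values (genes x samples) together
#' with a case/reference group label per sample. Missing values are
#' rejected: imputation is out of scope for this pipeline, upstream
#' quantification must deliver a complete matrix.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param groups Character vector of `"case"`/`"reference"`, either named by
#'   sample id or in column order.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids` and `groups` (named character vector).
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  if (anyNA(values))
    stop("expression matrix contains missing values; imputation is not supported")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene ids in expression matrix")
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("`groups` length does not match the number of samples")
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples missing a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("case", "reference"))
  if (length(bad))
    stop("group labels must be 'case' or 'reference', found: ",
         paste(bad, collapse = ", "))
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), groups = groups),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", sum(x$groups == "case"), " case / ",
      sum(x$groups == "reference"), " reference)\n", sep = "")
  invisible(x)
}

#' Differential-expression thresholds
#'
#' Default cutoffs used throughout: the kernel-MCC route calls a gene when
#' Kernel MCC > 0.105 and |l2fc| > 0.58; the classical route when the
#' two-sided p-value is below `alpha` and the fold change exceeds 1.5
#' (|l2fc| > log2(1.5) = 0.585).
#'
#' @param mcc_threshold Kernel-MCC cutoff, in \[-1, 1\].
#' @param l2fc_threshold Absolute log2 fold-change cutoff (>= 0).
#' @param alpha Significance level for the classical route, in (0, 1).
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(mcc_threshold = 0.105, l2fc_threshold = 0.58,
                          alpha = 0.05) {
  stopifnot(is.numeric(mcc_threshold), mcc_threshold >= -1, mcc_threshold <= 1,
            is.numeric(l2fc_threshold), l2fc_threshold >= 0,
            is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(mcc_threshold = mcc_threshold,
                 l2fc_threshold = l2fc_threshold, alpha = alpha),
            class = "de_thresholds")
}

# normalize labels to logical is_case
as_case_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("case", "reference"))
    if (length(bad)) stop("labels must be 'case'/'reference' or logical")
    return(labels == "case")
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be 'case'/'reference', logical, or 0/1")
}

# Bandwidth selectors with a floor for constant data. Silverman:
# 0.9 min(sd, IQR/1.34) n^(-1/5); Scott: 1.06 sd n^(-1/5).
kde_bandwidth <- function(values, rule = c("silverman", "scott"),
                          floor = 1e-6) {
  rule <- match.arg(rule)
  n <- length(values)
  if (n < 2) stop("bandwidth selection needs at least 2 points")
  s <- sd(values)
  h <- if (rule == "silverman") {
    iqr <- unname(diff(quantile(values, c(0.25, 0.75), names = FALSE,
                                type = 7)))
    0.9 * min(s, iqr / 1.34) * n^(-1 / 5)
  } else {
    1.06 * s * n^(-1 / 5)
  }
  if (!is.finite(h) || h < floor) floor else h
}

#' Gaussian kernel density estimate at query points
#'
#' Plain fixed-bandwidth Gaussian KDE; the bandwidth comes from Silverman's
#' (default) or Scott's rule with a floor of 1e-6 for constant data, so the
#' estimate is always defined.
#'
#' @param values Numeric vector of at least 2 observations.
#' @param query Numeric vector of evaluation points.
#' @param bandwidth_rule `"silverman"` or `"scott"`.
#' @param bandwidth Optional explicit bandwidth overriding the rule.
#' @return Numeric vector of densities at `query`.
#' @examples
#' kde_density(c(-1, 1), 0)
#' @export
kde_density <- function(values, query,
                        bandwidth_rule = c("silverman", "scott"),
                        bandwidth = NULL) {
  if (length(values) < 2)
    stop("insufficient data: kde_density needs at least 2 points")
  stopifnot(is.numeric(values), is.numeric(query), all(is.finite(values)))
  h <- if (is.null(bandwidth)) kde_bandwidth(values, bandwidth_rule)
       else bandwidth
  vapply(query, function(q) {
    mean(stats::dnorm((q - values) / h)) / h
  }, numeric(1))
}

#' Leave-one-out KDE classification of one gene's expression values
#'
#' For each sample, class-conditional Gaussian KDEs are evaluated at the
#' sample's value with that sample excluded from its own class's kernel sum,
#' and the class with the larger density wins. No class priors are applied:
#' with a handful of cases against hundreds of references, prior weighting
#' would force the trivial all-reference classifier. Ties predict reference.
#' Bandwidths are computed once per class on the full class (not per
#' holdout), which keeps the statistic smooth and deterministic.
#'
#' @param values Numeric vector of expression values (log2 scale).
#' @param labels Case/reference labels (see [expression_matrix()] coding).
#' @param bandwidth_rule `"silverman"` (default) or `"scott"`.
#' @param loo Use leave-one-out evaluation (default). `FALSE` gives
#'   resubstitution, for sensitivity analysis.
#' @return Logical vector: `TRUE` where the sample is predicted case.
#' @export
loo_kde_classify <- function(values, labels,
                             bandwidth_rule = c("silverman", "scott"),
                             loo = TRUE) {
  is_case <- as_case_labels(labels)
  stopifnot(length(values) == length(is_case))
  n_case <- sum(is_case); n_ref <- sum(!is_case)
  if (n_case < 3 || n_ref < 3)
    stop("insufficient data: both classes need at least 3 members ",
         "(so that 2 remain after holdout)")
  rule <- match.arg(bandwidth_rule)
  h_case <- kde_bandwidth(values[is_case], rule)
  h_ref <- kde_bandwidth(values[!is_case], rule)
  loo_kde_predict_c(as.numeric(values), is_case, h_case, h_ref, loo)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with the
#' convention that the value is 0 whenever any factor of the denominator is
#' zero (e.g. a constant prediction).
#'
#' @param predicted,actual Logical (or case/reference) vectors of equal
#'   length; `TRUE` = case.
#' @return A number in \[-1, 1\].
#' @examples
#' mcc(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
mcc <- function(predicted, actual) {
  p <- as_case_labels(predicted); a <- as_case_labels(actual)
  if (length(p) != length(a))
    stop("dimension error: predicted and actual differ in length")
  if (length(p) < 1) stop("empty vectors")
  tp <- sum(p & a); tn <- sum(!p & !a)
  fp <- sum(p & !a); fn <- sum(!p & a)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

#' Kernel MCC of a single gene
#'
#' The Matthews correlation coefficient of the leave-one-out KDE classifier:
#' `mcc(loo_kde_classify(values, labels), labels)`. This is the
#' rare-subgroup differential-expression statistic; values above 0.105
#' (together with |l2fc| > 0.58) flag a gene as differential.
#'
#' @inheritParams loo_kde_classify
#' @return A number in \[-1, 1\].
#' @export
kernel_mcc <- function(values, labels,
                       bandwidth_rule = c("silverman", "scott"),
                       loo = TRUE) {
  pred <- loo_kde_classify(values, labels, bandwidth_rule, loo)
  mcc(pred, labels)
}

#' Log2 fold change between case and reference
#'
#' Difference of group means on already-log2 values: mean(case) -
#' mean(reference). No pseudocount is applied because inputs are log scale.
#'
#' @inheritParams loo_kde_classify
#' @return Log2 fold change (case minus reference).
#' @export
log2_fold_change <- function(values, labels) {
  is_case <- as_case_labels(labels)
  stopifnot(length(values) == length(is_case))
  if (!any(is_case) || !any(!is_case))
    stop("insufficient data: both groups need at least 1 sample")
  mean(values[is_case]) - mean(values[!is_case])
}

#' Classical two-group test of one gene
#'
#' Welch's two-sample t-test on log2 values (two-sided). When both groups
#' are essentially constant the test is degenerate: equal means give p = 1,
#' distinct means are reported at the smallest representable p-value
#' (perfect separation).
#'
#' @inheritParams loo_kde_classify
#' @return Two-sided p-value in (0, 1].
#' @export
classic_test <- function(values, labels) {
  is_case <- as_case_labels(labels)
  stopifnot(length(values) == length(is_case))
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("insufficient data: both groups need at least 2 samples")
  x <- values[is_case]; y <- values[!is_case]
  res <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NULL)
  if (is.null(res) || !is.finite(res)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
    return(.Machine$double.xmin)
  }
  min(res, 1)
}

# Vectorised Welch test over matrix rows (same degenerate-row conventions as
# classic_test; agreement with stats::t.test is covered by tests).
welch_rows <- function(mat, is_case) {
  x <- mat[, is_case, drop = FALSE]; y <- mat[, !is_case, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- !is.finite(p)
  if (any(degen)) {
    eq <- abs(mx - my) <= 1e-12 * (abs(mx) + abs(my) + 1e-12)
    p[degen & eq] <- 1
    p[degen & !eq] <- .Machine$double.xmin
  }
  pmin(p, 1)
}

# Vectorised per-row bandwidths for one class submatrix
row_bandwidths <- function(sub, rule) {
  n <- ncol(sub)
  m <- rowMeans(sub)
  s <- sqrt(pmax(rowSums((sub - m)^2) / (n - 1), 0))
  h <- if (rule == "silverman") {
    qs <- t(apply(sub, 1, quantile, probs = c(0.25, 0.75), names = FALSE,
                  type = 7))
    0.9 * pmin(s, (qs[, 2] - qs[, 1]) / 1.34) * n^(-1 / 5)
  } else {
    1.06 * s * n^(-1 / 5)
  }
  list(h = ifelse(!is.finite(h) | h < 1e-6, 1e-6, h), sd = s)
}

#' Differential expression of a rare subgroup against a reference cohort
#'
#' Computes, per gene, the log2 fold change, the kernel-MCC statistic
#' (leave-one-out KDE classifier scored by MCC) and a Welch-test p-value,
#' and applies the two calling routes: `passes_kmcc` (Kernel MCC >
#' `mcc_threshold` and |l2fc| > `l2fc_threshold`) and `passes_classic`
#' (p < `alpha` and |l2fc| > log2(1.5)). Genes with zero spread in both
#' groups get kernel_mcc = 0 and p = 1.
#'
#' @param em An [expression_matrix()].
#' @param thresholds A [de_thresholds()] object.
#' @param route `"kmcc"` (default) or `"classic"`. The classical route skips
#'   the kernel-MCC computation (reported as `NA`), which is much faster on
#'   large cohorts; the kmcc route computes both statistics.
#' @param bandwidth_rule Bandwidth rule for the KDE classifier.
#' @param adjust Multiple-testing adjustment for the classical route p-values
#'   (`"none"`, default, or any [stats::p.adjust()] method such as `"BH"`).
#' @return A `data.frame` of class `de_table` with columns `gene_id`,
#'   `l2fc`, `kernel_mcc`, `p_value`, `passes_kmcc`, `passes_classic`,
#'   `direction`, sorted by decreasing |l2fc| (ties broken by gene id).
#'   Attribute `summary` holds pass/up/down counts and the analysis
#'   metadata (thresholds, route, bandwidth rule, test).
#' @export
differential_expression <- function(em, thresholds = de_thresholds(),
                                    route = c("kmcc", "classic"),
                                    bandwidth_rule = c("silverman", "scott"),
                                    adjust = "none") {
  stopifnot(inherits(em, "expr_matrix"), inherits(thresholds, "de_thresholds"))
  route <- match.arg(route)
  rule <- match.arg(bandwidth_rule)
  is_case <- em$groups == "case"
  n_case <- sum(is_case); n_ref <- sum(!is_case)
  if (n_case == 0 || n_ref == 0)
    stop("cohort error: both a case and a reference group are required")
  min_n <- if (route == "kmcc") 3 else 2
  if (n_case < min_n || n_ref < min_n)
    stop("cohort error: the ", route, " route needs at least ", min_n,
         " samples per group (found ", n_case, " case, ", n_ref,
         " reference)")
  mat <- em$values
  l2fc <- rowMeans(mat[, is_case, drop = FALSE]) -
    rowMeans(mat[, !is_case, drop = FALSE])
  p <- welch_rows(mat, is_case)
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  if (route == "kmcc") {
    bc <- row_bandwidths(mat[, is_case, drop = FALSE], rule)
    br <- row_bandwidths(mat[, !is_case, drop = FALSE], rule)
    degen <- bc$sd == 0 & br$sd == 0 & abs(l2fc) < 1e-12
    kmcc <- kernel_mcc_rows_c(mat, is_case, bc$h, br$h, degen)
    p[bc$sd == 0 & br$sd == 0 & abs(l2fc) < 1e-12] <- 1
  } else {
    kmcc <- rep(NA_real_, nrow(mat))
  }
  th <- thresholds
  passes_kmcc <- if (route == "kmcc") {
    kmcc > th$mcc_threshold & abs(l2fc) > th$l2fc_threshold
  } else rep(NA, nrow(mat))
  # fold cutoff is inclusive at the boundary (with float tolerance): a gene
  # at exactly 1.5-fold is called
  passes_classic <- p < th$alpha & abs(l2fc) >= log2(1.5) * (1 - 1e-12)
  out <- data.frame(
    gene_id = em$gene_ids, l2fc = l2fc, kernel_mcc = kmcc, p_value = p,
    passes_kmcc = passes_kmcc, passes_classic = passes_classic,
    direction = ifelse(l2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-abs(out$l2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  pass <- if (route == "kmcc") out$passes_kmcc else out$passes_classic
  attr(out, "summary") <- list(
    route = route, n_genes = nrow(out),
    n_pass = sum(pass), n_up = sum(pass & out$direction == "up"),
    n_down = sum(pass & out$direction == "down"),
    n_pass_classic = sum(out$passes_classic),
    thresholds = unclass(th), bandwidth_rule = rule,
    test = "Welch two-sample t (two-sided)", adjust = adjust,
    n_case = n_case, n_reference = n_ref)
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<de_table> ", s$n_genes, " genes, route = ", s$route, ": ",
      s$n_pass, " pass (", s$n_up, " up / ", s$n_down, " down)\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Summarise a DE table
#' @param object A `de_table`.
#' @param ... Unused.
#' @return The summary list stored on the table (counts, thresholds,
#'   metadata).
#' @method summary de_table
#' @export
summary.de_table <- function(object, ...) attr(object, "summary")
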