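#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (ec50/x)^hill)`
#' on log10 dose. Initialisation is a deterministic multi-start grid
#' (EC50 at each observed dose, Hill slope in 0.5/1/2) on the
#' variable-projection profile (bottom/top solved linearly), followed by
#' Levenberg-Marquardt refinement; the lowest-RSS fit wins. The curve is
#' constrained non-decreasing in dose (bottom <= top, hill > 0): a
#' decreasing trend, which for an inhibition assay is noise, collapses to
#' the flat fit. Responses are clamped to \[0, 100\] before fitting when
#' `clamp = TRUE` (raw values are an assay readout and can stray outside).
#'
#' @param doses Numeric vector of strictly positive concentrations (nM).
#' @param responses Numeric vector of % inhibition values.
#' @param clamp Clamp responses to \[0, 100\] before fitting (default TRUE).
#' @return A list of class `fourpl_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `rss`, `converged`, plus the dose window (`dose_min`, `dose_max`).
#' @examples
#' d <- 10^(0:4)
#' y <- 80 / (1 + (100 / d)^1)
#' fit_4pl(d, y)
#' @export
fit_4pl <- function(doses, responses, clamp = TRUE) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("doses must be finite and strictly positive")
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (length(unique(doses)) < 4)
    stop("at least 4 distinct doses are required for a 4PL fit")
  y <- if (clamp) pmin(pmax(responses, 0), 100) else responses
  res <- fit4pl_c(log10(doses), as.numeric(y))
  structure(
    list(bottom = res[1], top = res[2], ec50 = res[3], hill = res[4],
         rss = res[5], converged = res[6] == 1,
         dose_min = min(doses), dose_max = max(doses)),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> bottom=%.3g top=%.3g ec50=%.4g nM hill=%.3g rss=%.3g%s\n",
    x$bottom, x$top, x$ec50, x$hill, x$rss,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Drug sensitivity score from 4PL parameters (closed form)
#'
#' Normalised area of the fitted curve above an activity threshold over the
#' tested log10-dose window:
#' `DSS = 100 * A / ((100 - t) * (log10(dose_max) - log10(dose_min)))`
#' with `A = integral of max(y(x) - t, 0) d log10(x)`. The integral uses the
#' exact antiderivative of the logistic (softplus); the threshold crossing
#' is solved analytically. For scoring, bottom and top are clamped to
#' \[0, 100\] so the score is bounded in \[0, 100\].
#'
#' All arguments are vectorised over curves.
#'
#' @param bottom,top,ec50,hill 4PL parameters (top >= bottom, hill > 0).
#' @param dose_min,dose_max Integration window (same units as `ec50`).
#' @param activity_threshold Activity threshold t in %, default 10.
#' @return DSS values in \[0, 100\].
#' @export
dss_params <- function(bottom, top, ec50, hill, dose_min, dose_max,
                       activity_threshold = 10) {
  stopifnot(all(dose_min < dose_max), all(ec50 > 0), all(hill > 0),
            activity_threshold >= 0, activity_threshold < 100)
  n <- max(length(bottom), length(top), length(ec50), length(hill),
           length(dose_min), length(dose_max))
  b <- pmin(pmax(rep_len(bottom, n), 0), 100)
  t_ <- pmin(pmax(rep_len(top, n), 0), 100)
  m <- log10(rep_len(ec50, n))
  h <- rep_len(hill, n)
  s1 <- log10(rep_len(dose_min, n))
  s2 <- log10(rep_len(dose_max, n))
  t0 <- activity_threshold
  k <- h * log(10)
  softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  area <- numeric(n)
  flat <- abs(t_ - b) < 1e-12
  # flat curve: rectangle above threshold (if any)
  area[flat] <- pmax(b[flat] - t0, 0) * (s2[flat] - s1[flat])
  i <- which(!flat)
  if (length(i)) {
    bi <- b[i]; ti <- t_[i]; mi <- m[i]; ki <- k[i]
    a1 <- s1[i]; a2 <- s2[i]
    inc <- ti > bi
    # crossing point of y(s) = t0, solved analytically from the logistic;
    # r in (0,1) exactly when t0 lies between the two asymptotes
    r <- pmin(pmax((t0 - bi) / (ti - bi), 1e-300), 1 - 1e-16)
    scross <- pmin(pmax(mi + log(r / (1 - r)) / ki, a1), a2)
    # integration bounds of the region where y > t0: the upper tail for an
    # increasing curve, the lower tail for a decreasing one
    lo <- ifelse(inc, ifelse(bi >= t0, a1, scross), a1)
    hi <- ifelse(inc, a2, ifelse(ti >= t0, a2, scross))
    lo[inc & ti <= t0] <- a2[inc & ti <= t0]    # max(y) = t below threshold
    hi[!inc & bi <= t0] <- a1[!inc & bi <= t0]  # max(y) = b below threshold
    sp_hi <- softplus(ki * (hi - mi))
    sp_lo <- softplus(ki * (lo - mi))
    area[i] <- (bi - t0) * (hi - lo) + (ti - bi) * (sp_hi - sp_lo) / ki
    area[i] <- pmax(area[i], 0)
  }
  100 * area / ((100 - t0) * (s2 - s1))
}

#' Drug sensitivity score of a fitted curve
#'
#' @param fit A [fit_4pl()] result.
#' @param dose_min,dose_max Integration window; defaults to the fitted
#'   curve's own tested dose range.
#' @param activity_threshold Activity threshold in %, default 10.
#' @return DSS in \[0, 100\]. An unconverged fit scores 0 with a warning.
#' @export
dss <- function(fit, dose_min = fit$dose_min, dose_max = fit$dose_max,
                activity_threshold = 10) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (!isTRUE(fit$converged)) {
    warning("unconverged 4PL fit: DSS set to 0")
    return(0)
  }
  dss_params(fit$bottom, fit$top, fit$ec50, fit$hill,
             dose_min, dose_max, activity_threshold)
}

# numerical-quadrature counterpart of dss_params, used as an independent
# check in the test-suite and exposed for diagnostics
dss_quadrature <- function(bottom, top, ec50, hill, dose_min, dose_max,
                           activity_threshold = 10) {
  b <- min(max(bottom, 0), 100); t_ <- min(max(top, 0), 100)
  m <- log10(ec50)
  f <- function(s) {
    y <- b + (t_ - b) / (1 + 10^(hill * (m - s)))
    pmax(y - activity_threshold, 0)
  }
  # piecewise panels keep the quadrature from missing a narrow
  # above-threshold sliver near a window edge
  breaks <- seq(log10(dose_min), log10(dose_max), length.out = 65)
  a <- sum(vapply(seq_len(64), function(j) {
    stats::integrate(f, breaks[j], breaks[j + 1], subdivisions = 200L,
                     rel.tol = 1e-10, abs.tol = 1e-13)$value
  }, numeric(1)))
  100 * a / ((100 - activity_threshold) * (log10(dose_max) - log10(dose_min)))
}

#' Fit all dose-response series of a screening plate and score them
#'
#' Groups a long-format plate table by (drug, sample), fits each series with
#' the 4PL model and computes the DSS over that series' own tested dose
#' window (panels may differ per drug).
#'
#' @param plate `data.frame` with columns `drug_id`, `sample_id`, `dose_nM`,
#'   `response_pct`.
#' @param activity_threshold DSS activity threshold in %, default 10.
#' @return `data.frame` with one row per (drug, sample): 4PL parameters,
#'   `rss`, `converged`, `dss`.
#' @export
score_plate <- function(plate, activity_threshold = 10) {
  need <- c("drug_id", "sample_id", "dose_nM", "response_pct")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate is missing columns: ", paste(miss, collapse = ", "))
  if (any(plate$dose_nM <= 0)) stop("doses must be strictly positive")
  key <- paste(plate$drug_id, plate$sample_id, sep = "\r")
  ord <- order(key, plate$dose_nM, method = "radix")
  plate <- plate[ord, , drop = FALSE]
  key <- key[ord]
  runs <- rle(key)
  if (any(runs$lengths < 4))
    stop("every (drug, sample) series needs at least 4 doses; offending: ",
         paste(head(sub("\r", "/", runs$values[runs$lengths < 4]), 5),
               collapse = ", "))
  offsets <- c(0L, cumsum(runs$lengths))
  y <- pmin(pmax(plate$response_pct, 0), 100)
  fits <- fit4pl_batch_c(log10(plate$dose_nM), y, offsets)
  first <- offsets[-length(offsets)] + 1L
  last <- offsets[-1L]
  out <- data.frame(
    drug_id = plate$drug_id[first], sample_id = plate$sample_id[first],
    bottom = fits[, 1], top = fits[, 2], ec50 = fits[, 3], hill = fits[, 4],
    rss = fits[, 5], converged = fits[, 6] == 1,
    dose_min = plate$dose_nM[first], dose_max = plate$dose_nM[last],
    stringsAsFactors = FALSE)
  out$dss <- ifelse(
    out$converged,
    dss_params(out$bottom, out$top, out$ec50, out$hill,
               out$dose_min, out$dose_max, activity_threshold),
    0)
  out
}

#' Selective DSS relative to a reference cohort
#'
#' Centers each sample's DSS on the per-drug mean DSS of the reference
#' cohort: `sdss(drug, sample) = dss(drug, sample) - mean(reference dss)`.
#' Missing (drug, sample) cells are allowed (smaller panels); the reference
#' mean uses whatever reference cells exist for the drug. Drugs with no
#' reference coverage cannot be centered and are dropped with a warning.
#'
#' @param scores `data.frame` with columns `drug_id`, `sample_id`, `dss`
#'   (e.g. from [score_plate()]).
#' @param reference_sample_ids Character vector of reference sample ids.
#' @return The input with an `sdss` column added (uncovered drugs removed).
#' @export
sdss <- function(scores, reference_sample_ids) {
  stopifnot(all(c("drug_id", "sample_id", "dss") %in% names(scores)))
  is_ref <- scores$sample_id %in% reference_sample_ids
  if (!any(is_ref)) stop("no reference samples present in the score table")
  ref_mean <- tapply(scores$dss[is_ref], scores$drug_id[is_ref], mean)
  uncovered <- setdiff(unique(scores$drug_id), names(ref_mean))
  if (length(uncovered)) {
    warning(length(uncovered),
            " drug(s) without reference coverage excluded: ",
            paste(head(uncovered, 5), collapse = ", "))
    scores <- scores[!scores$drug_id %in% uncovered, , drop = FALSE]
  }
  scores$sdss <- scores$dss - unname(ref_mean[scores$drug_id])
  scores
}

#' Rank drugs by group selectivity
#'
#' Orders drugs by decreasing mean sDSS over the case samples (mean over
#' non-missing case cells). Ties are broken by decreasing mean case DSS,
#' then drug id. Drugs covered in fewer case samples than
#' `min_case_coverage` are flagged (`low_coverage`) but still ranked.
#'
#' @param scores `data.frame` with `drug_id`, `sample_id`, `dss`, `sdss`
#'   (from [sdss()]).
#' @param case_sample_ids Character vector of case sample ids.
#' @param min_case_coverage Minimum number of case cells for a fully
#'   trusted ranking entry (default 2).
#' @return `data.frame` with columns `drug_id`, `mean_case_sdss`,
#'   `mean_case_dss`, `n_case_covered`, `low_coverage`, `rank` (1 = most
#'   case-selective), ordered by rank.
#' @export
rank_selective <- function(scores, case_sample_ids, min_case_coverage = 2) {
  stopifnot(all(c("drug_id", "sample_id", "dss", "sdss") %in% names(scores)))
  cs <- scores[scores$sample_id %in% case_sample_ids, , drop = FALSE]
  if (nrow(cs) == 0) stop("cohort error: no case samples in the score table")
  agg <- do.call(rbind, lapply(split(cs, cs$drug_id), function(d) {
    data.frame(drug_id = d$drug_id[1], mean_case_sdss = mean(d$sdss),
               mean_case_dss = mean(d$dss), n_case_covered = nrow(d),
               stringsAsFactors = FALSE)
  }))
  agg$low_coverage <- agg$n_case_covered < min_case_coverage
  ord <- order(-agg$mean_case_sdss, -agg$mean_case_dss, agg$drug_id,
               method = "radix")
  agg <- agg[ord, , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}
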