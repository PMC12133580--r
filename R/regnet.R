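#' Build strand-aware promoter windows around TSSs
#'
#' The promoter of a gene on the + strand with TSS at 0-based position p is
#' the 0-based half-open interval `[p - upstream, p + downstream)`; on the
#' - strand it is the mirror `[p - downstream, p + upstream)`. Windows are
#' clipped at position 0. One promoter per gene id is required.
#'
#' @param tss `data.frame` with columns `chrom`, `tss` (0-based TSS
#'   coordinate), `strand` (`"+"`/`"-"`; missing or `"."` defaults to `"+"`
#'   with a warning) and `gene_id`, e.g. from
#'   [simulate_gene_annotation()] or a BED6 file read with [read_bed()].
#' @param upstream,downstream Window extents in bp (defaults 2000/500).
#' @return A named `GRanges` (1-based, names = gene ids) of promoter
#'   windows.
#' @examples
#' tss <- data.frame(chrom = "chr1", tss = 10000, strand = "+",
#'                   gene_id = "g1")
#' build_promoters(tss)  # 0-based [8000, 10500) -> GRanges 8001-10500
#' @export
build_promoters <- function(tss, upstream = 2000, downstream = 500) {
  need <- c("chrom", "tss", "gene_id")
  miss <- setdiff(need, names(tss))
  if (length(miss))
    stop("TSS annotation is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tss$gene_id))
    stop("one promoter per gene id required; duplicated: ",
         paste(head(unique(tss$gene_id[duplicated(tss$gene_id)]), 5),
               collapse = ", "))
  strand <- if ("strand" %in% names(tss)) as.character(tss$strand)
            else rep(NA_character_, nrow(tss))
  bad <- is.na(strand) | !strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " record(s) without usable strand; defaulting to '+'")
    strand[bad] <- "+"
  }
  p <- tss$tss
  start0 <- ifelse(strand == "+", p - upstream, p - downstream)
  end0 <- ifelse(strand == "+", p + downstream, p + upstream)
  start0 <- pmax(start0, 0)
  if (any(end0 <= start0)) stop("degenerate promoter window (end <= start)")
  gr <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(start0 + 1, end0), strand = strand)
  names(gr) <- tss$gene_id
  gr
}

check_chrom_harmony <- function(peaks, promoters, normalize_chr) {
  cp <- unique(as.character(GenomicRanges::seqnames(peaks)))
  cq <- unique(as.character(GenomicRanges::seqnames(promoters)))
  if (normalize_chr) {
    strip <- function(x) sub("^chr", "", x)
    GenomeInfoDb::seqlevels(peaks) <-
      paste0("chr", strip(GenomeInfoDb::seqlevels(peaks)))
    GenomeInfoDb::seqlevels(promoters) <-
      paste0("chr", strip(GenomeInfoDb::seqlevels(promoters)))
    return(list(peaks = peaks, promoters = promoters))
  }
  if (length(intersect(cp, cq)) == 0 &&
      length(intersect(sub("^chr", "", cp), sub("^chr", "", cq))) > 0)
    stop("chromosome naming mismatch between peaks (",
         paste(head(cp, 3), collapse = ", "), ") and promoters (",
         paste(head(cq, 3), collapse = ", "),
         "); set normalize_chr = TRUE to harmonise 'chr' prefixes")
  list(peaks = peaks, promoters = promoters)
}

#' Assign binding peaks to promoter-bound genes
#'
#' A gene is bound when at least one peak overlaps its promoter window by
#' `min_overlap` bp or more. Peaks and promoters use the same convention as
#' BED (0-based half-open on disk; 1-based closed as `GRanges`), so
#' intervals that merely touch do not overlap. Chromosome naming is strict
#' by default: if the two inputs share no chromosome but would after
#' removing a `"chr"` prefix, an error names the offending styles.
#'
#' @param peaks `GRanges` of binding peaks (e.g. [read_bed()]).
#' @param promoters Named `GRanges` from [build_promoters()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @param normalize_chr Harmonise `"chr"` prefixes instead of erroring.
#' @return Sorted character vector of bound gene ids.
#' @export
assign_peaks <- function(peaks, promoters, min_overlap = 1,
                         normalize_chr = FALSE) {
  stopifnot(methods::is(peaks, "GRanges"), methods::is(promoters, "GRanges"))
  if (is.null(names(promoters)))
    stop("promoters must be named by gene id")
  if (length(peaks) == 0 || length(promoters) == 0) return(character(0))
  h <- check_chrom_harmony(peaks, promoters, normalize_chr)
  hits <- GenomicRanges::findOverlaps(h$promoters, h$peaks,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  sort(unique(names(h$promoters)[S4Vectors::queryHits(hits)]))
}

#' Intersect promoter-bound genes with differentially expressed genes
#'
#' @param bound Character vector of bound gene ids (from [assign_peaks()]).
#' @param de_table A `de_table` from [differential_expression()].
#' @param route Which pass flag defines "differentially expressed":
#'   `"kmcc"` (default) or `"classic"`.
#' @return `data.frame` with columns `gene_id` and `direction` for the
#'   genes that are both bound and differentially expressed, sorted by
#'   gene id.
#' @export
intersect_bound_with_de <- function(bound, de_table,
                                    route = c("kmcc", "classic")) {
  route <- match.arg(route)
  flag <- if (route == "kmcc") de_table$passes_kmcc else de_table$passes_classic
  if (all(is.na(flag)))
    stop("the requested route was not computed in this DE table")
  de_genes <- de_table$gene_id[!is.na(flag) & flag]
  keep <- sort(intersect(bound, de_genes))
  idx <- match(keep, de_table$gene_id)
  data.frame(gene_id = keep, direction = de_table$direction[idx],
             stringsAsFactors = FALSE)
}

#' Genes whose promoter binding is lost after treatment
#'
#' @param vehicle_peaks,treated_peaks `GRanges` peak tracks from the same
#'   antibody under vehicle and treatment.
#' @param promoters Named `GRanges` from [build_promoters()].
#' @param ... Passed to [assign_peaks()] (e.g. `min_overlap`).
#' @return Sorted character vector: genes bound under vehicle but not under
#'   treatment.
#' @export
binding_lost <- function(vehicle_peaks, treated_peaks, promoters, ...) {
  before <- assign_peaks(vehicle_peaks, promoters, ...)
  after <- assign_peaks(treated_peaks, promoters, ...)
  sort(setdiff(before, after))
}

#' Relative expression from qPCR Ct values (delta-Ct method)
#'
#' Per (condition, target): `dCt = mean Ct(target) - mean over housekeeping
#' targets of their mean Ct`, relative expression `2^-dCt`. With a control
#' condition the quantities are re-normalised to it (delta-delta-Ct), so the
#' control condition maps to 1 and `1 - ratio` is the knockdown efficiency.
#'
#' @param ct_table `data.frame` with columns `condition`, `target_id`,
#'   `replicate`, `ct`.
#' @param housekeeping Character vector of housekeeping target ids that must
#'   be present in every condition (conditions where one is missing are
#'   skipped with a warning).
#' @param control_condition Optional condition id for delta-delta-Ct
#'   renormalisation.
#' @return `data.frame` with columns `condition`, `target_id`, `delta_ct`,
#'   `rel_expression` and, when a control is given, `rel_to_control`.
#' @export
delta_ct_expression <- function(ct_table, housekeeping,
                                control_condition = NULL) {
  need <- c("condition", "target_id", "replicate", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  out <- list()
  for (cond in unique(ct_table$condition)) {
    sub <- ct_table[ct_table$condition == cond, , drop = FALSE]
    hk_present <- housekeeping %in% sub$target_id
    if (!all(hk_present)) {
      warning("condition '", cond, "' skipped: missing housekeeping ",
              paste(housekeeping[!hk_present], collapse = ", "))
      next
    }
    mean_ct <- tapply(sub$ct, sub$target_id, mean)
    hk_ref <- mean(mean_ct[housekeeping])
    targets <- setdiff(names(mean_ct), housekeeping)
    dct <- mean_ct[targets] - hk_ref
    out[[cond]] <- data.frame(
      condition = cond, target_id = targets, delta_ct = unname(dct),
      rel_expression = unname(2^(-dct)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(control_condition)) {
    if (!control_condition %in% res$condition)
      stop("control condition '", control_condition, "' not in the table")
    ctrl <- res[res$condition == control_condition, ]
    ref <- stats::setNames(ctrl$rel_expression, ctrl$target_id)
    res$rel_to_control <- res$rel_expression / unname(ref[res$target_id])
  }
  res
}

#' Fold enrichment of chromatin-profiling qPCR tracks
#'
#' Per locus, the fold enrichment of each track relative to a designated
#' IgG control track: `fold = 2^(mean Ct(control track) - mean Ct(track))`.
#' The control track therefore maps to exactly 1 at every locus. Loci
#' without a control-track measurement are skipped with a warning.
#'
#' @param ct_table `data.frame` with columns `track`, `locus`, `replicate`,
#'   `ct`.
#' @param control_track Track id of the designated IgG control.
#' @return `data.frame` with columns `track`, `locus`, `fold_enrichment`.
#' @export
fold_enrichment <- function(ct_table, control_track) {
  need <- c("track", "locus", "replicate", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "))
  if (!control_track %in% ct_table$track)
    stop("control track '", control_track, "' not present in the table")
  out <- list()
  for (loc in unique(ct_table$locus)) {
    sub <- ct_table[ct_table$locus == loc, , drop = FALSE]
    if (!control_track %in% sub$track) {
      warning("locus '", loc, "' skipped: no control-track measurement")
      next
    }
    mean_ct <- tapply(sub$ct, sub$track, mean)
    ref <- mean_ct[[control_track]]
    out[[loc]] <- data.frame(
      track = names(mean_ct), locus = loc,
      fold_enrichment = unname(2^(ref - mean_ct)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify treatment-dependent ("rewired") genes
#'
#' Integrates four differential-expression tables and the promoter-binding
#' calls into one per-gene report. A gene is rewired when it is (i) up at
#' diagnosis in the case subgroup, (ii) significantly downregulated
#' (p < `alpha` and fold change < 1/`fc_threshold`) in treated case cells,
#' (iii) NOT downregulated by the same criterion in treated reference
#' cells, and (iv) NOT changed (two-sided criterion) under the control
#' drug. Binding information is annotated per gene (bound at promoter,
#' binding lost on treatment, bound-and-DE) but does not gate the rewired
#' call.
#'
#' @param de_diagnosis `de_table` of case vs reference at diagnosis.
#' @param de_treated_case,de_treated_reference,de_control_drug `de_table`s
#'   of treated vs vehicle (classic route on replicate-level data) in case
#'   cells, reference cells and case cells under the control drug.
#' @param bound Character vector of promoter-bound genes.
#' @param lost Character vector of genes losing promoter binding on
#'   treatment (see [binding_lost()]).
#' @param alpha Significance level for the treatment criteria.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param diagnosis_route Pass flag defining diagnosis DE: `"kmcc"`
#'   (default) or `"classic"`.
#' @return `data.frame` of class `rewiring_report`, one row per gene of the
#'   diagnosis table, with boolean columns `up_at_diagnosis`,
#'   `down_at_diagnosis`, `down_on_treatment_case`,
#'   `down_on_treatment_reference`, `changed_on_control_drug`,
#'   `bound_at_promoter`, `binding_lost_on_treatment`, `rewired`,
#'   `bound_and_de`. Attribute `summary` carries the headline counts.
#' @export
classify_rewiring <- function(de_diagnosis, de_treated_case,
                              de_treated_reference, de_control_drug,
                              bound, lost = character(0), alpha = 0.05,
                              fc_threshold = 1.5,
                              diagnosis_route = c("kmcc", "classic")) {
  diagnosis_route <- match.arg(diagnosis_route)
  genes <- de_diagnosis$gene_id
  for (nm in c("de_treated_case", "de_treated_reference",
               "de_control_drug")) {
    tab <- get(nm)
    missing <- setdiff(genes, tab$gene_id)
    if (length(missing))
      stop("gene namespace mismatch: ", nm, " lacks ",
           length(missing), " gene(s): ",
           paste(head(missing, 5), collapse = ", "))
  }
  l2fc_cut <- log2(fc_threshold)
  flag <- if (diagnosis_route == "kmcc") de_diagnosis$passes_kmcc
          else de_diagnosis$passes_classic
  up_dx <- !is.na(flag) & flag & de_diagnosis$direction == "up"
  down_dx <- !is.na(flag) & flag & de_diagnosis$direction == "down"
  down_in <- function(tab) {
    i <- match(genes, tab$gene_id)
    tab$p_value[i] < alpha & tab$l2fc[i] < -l2fc_cut
  }
  changed_in <- function(tab) {
    i <- match(genes, tab$gene_id)
    tab$p_value[i] < alpha & abs(tab$l2fc[i]) > l2fc_cut
  }
  down_case <- down_in(de_treated_case)
  down_ref <- down_in(de_treated_reference)
  changed_ctrl <- changed_in(de_control_drug)
  bound_f <- genes %in% bound
  lost_f <- genes %in% lost
  rewired <- up_dx & down_case & !down_ref & !changed_ctrl
  bound_and_de <- bound_f & (up_dx | down_dx)
  rep <- data.frame(
    gene_id = genes, up_at_diagnosis = up_dx, down_at_diagnosis = down_dx,
    down_on_treatment_case = down_case,
    down_on_treatment_reference = down_ref,
    changed_on_control_drug = changed_ctrl,
    bound_at_promoter = bound_f, binding_lost_on_treatment = lost_f,
    rewired = rewired, bound_and_de = bound_and_de,
    stringsAsFactors = FALSE)
  rep <- rep[order(rep$gene_id), , drop = FALSE]
  rownames(rep) <- NULL
  stopifnot(all(rep$rewired <= rep$up_at_diagnosis),
            all(rep$bound_and_de <= rep$bound_at_promoter))
  attr(rep, "summary") <- list(
    n_up_at_diagnosis = sum(up_dx), n_down_at_diagnosis = sum(down_dx),
    n_rewired = sum(rewired), n_bound = sum(bound_f),
    n_bound_and_de = sum(bound_and_de), n_binding_lost = sum(lost_f),
    alpha = alpha, fc_threshold = fc_threshold,
    diagnosis_route = diagnosis_route)
  class(rep) <- c("rewiring_report", "data.frame")
  rep
}

#' @export
print.rewiring_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<rewiring_report> ", nrow(x), " genes: ", s$n_up_at_diagnosis,
      " up at diagnosis, ", s$n_rewired, " rewired, ", s$n_bound,
      " bound, ", s$n_bound_and_de, " bound & DE\n", sep = "")
  invisible(x)
}

#' Summarise a rewiring report
#' @param object A `rewiring_report`.
#' @param ... Unused.
#' @return The headline-count list stored on the report.
#' @method summary rewiring_report
#' @export
summary.rewiring_report <- function(object, ...) attr(object, "summary")
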