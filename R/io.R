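#' Read an expression matrix with sample annotation
#'
#' @param expression_file TSV/CSV: first column gene ids, remaining columns
#'   one per sample (header row = sample ids), log2-scale values.
#' @param annotation_file CSV with columns `sample_id`, `group`
#'   (`"case"`/`"reference"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expression_file, annotation_file) {
  for (f in c(expression_file, annotation_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  sep <- if (grepl("\\.csv$", expression_file, ignore.case = TRUE)) ","
         else "\t"
  tab <- utils::read.table(expression_file, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  storage.mode(mat) <- "double"
  ann <- utils::read.csv(annotation_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ann)))
    stop("annotation must have columns sample_id and group: ",
         annotation_file)
  expression_matrix(mat, stats::setNames(ann$group, ann$sample_id))
}

#' Write an expression matrix and its annotation
#'
#' @param em An [expression_matrix()].
#' @param expression_file Output TSV path (genes x samples).
#' @param annotation_file Output CSV path (`sample_id`, `group`).
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(em, expression_file, annotation_file) {
  stopifnot(inherits(em, "expr_matrix"))
  tab <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE)
  utils::write.table(tab, expression_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(sample_id = em$sample_ids,
                              group = unname(em$groups)),
                   annotation_file, row.names = FALSE, quote = FALSE)
  invisible(c(expression_file, annotation_file))
}

#' Read a drug-screen plate table
#'
#' @param plate_file Long-format CSV with columns `drug_id`, `sample_id`,
#'   `dose_nM`, `response_pct`.
#' @return `data.frame` as stored.
#' @export
read_plate <- function(plate_file) {
  if (!file.exists(plate_file)) stop("input file not found: ", plate_file)
  plate <- utils::read.csv(plate_file, stringsAsFactors = FALSE)
  need <- c("drug_id", "sample_id", "dose_nM", "response_pct")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate file missing columns: ", paste(miss, collapse = ", "))
  plate
}

#' Read / write genomic intervals as BED
#'
#' Thin wrappers around `rtracklayer` that keep the package's interval
#' convention (BED on disk is 0-based half-open; in memory `GRanges` are
#' 1-based closed).
#'
#' @param file Path to a BED (or narrowPeak; columns beyond 6 ignored) file.
#' @return `read_bed()`: a `GRanges` (with `name` metadata if present).
#' @export
read_bed <- function(file) {
  if (!file.exists(file)) stop("input file not found: ", file)
  # narrowPeak files carry 10 columns; import the first 6 as BED
  first <- readLines(file, n = 1L)
  ncol <- length(strsplit(first, "\t")[[1]])
  if (ncol > 6) {
    tab <- utils::read.table(file, sep = "\t", stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      tab[[1]], IRanges::IRanges(tab[[2]] + 1, tab[[3]]),
      strand = if (ncol >= 6) ifelse(tab[[6]] %in% c("+", "-"),
                                     tab[[6]], "*") else "*")
    if (ncol >= 4) gr$name <- tab[[4]]
    gr
  } else {
    rtracklayer::import(file, format = "BED")
  }
}

#' @rdname read_bed
#' @param gr A `GRanges` to write.
#' @return `write_bed()`: the path, invisibly.
#' @export
write_bed <- function(gr, file) {
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
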