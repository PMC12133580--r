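#' Assemble a pipeline run configuration
#'
#' Collects every option of the end-to-end analysis in one validated list.
#' In `"simulate"` mode the inputs are generated by the synthetic-data
#' module under `seed`; in `"user-data"` mode they are read from the paths
#' given in `paths`.
#'
#' @param mode `"simulate"` or `"user-data"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; mandatory in simulate mode.
#' @param sim Named list of overrides passed to [sim_config()] for the
#'   expression/peaks/qPCR generators.
#' @param screen_n_case,screen_n_reference Cohort sizes of the simulated
#'   drug screen (the screened cohort is typically smaller than the
#'   expression cohort).
#' @param thresholds A [de_thresholds()].
#' @param dss_threshold DSS activity threshold in % (default 10).
#' @param promoter_upstream,promoter_downstream Promoter window in bp.
#' @param paths Named list of input files for user-data mode; recognised
#'   names: `expression`, `annotation`, `plate`, `tss`, `peaks_vehicle`,
#'   `peaks_treated`, and optional treated expression pairs
#'   `treated_case`/`treated_case_annotation` (likewise
#'   `treated_reference*`, `control_drug*`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "user-data"),
                       out_dir = tempfile("raresig_run_"),
                       seed = 1L, sim = list(),
                       screen_n_case = 4L, screen_n_reference = 145L,
                       thresholds = de_thresholds(), dss_threshold = 10,
                       promoter_upstream = 2000, promoter_downstream = 500,
                       paths = list()) {
  mode <- match.arg(mode)
  if (mode == "simulate" && (is.null(seed) || !is.finite(seed)))
    stop("configuration error: seed is mandatory in simulate mode")
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              sim = sim, screen_n_case = as.integer(screen_n_case),
              screen_n_reference = as.integer(screen_n_reference),
              thresholds = thresholds, dss_threshold = dss_threshold,
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream, paths = paths)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML file whose top-level keys match the arguments of
#'   [run_config()] (`thresholds` given as a mapping of
#'   `mcc_threshold`/`l2fc_threshold`/`alpha`).
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  y <- yaml::read_yaml(file)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(de_thresholds,
                                                      y$thresholds)
  do.call(run_config, y)
}

#' Validate pipeline inputs without running the analysis
#'
#' Structural checks only: file existence, matrix/annotation consistency,
#' dose-ladder completeness, BED coordinate sanity, shared gene namespace.
#'
#' @param config A [run_config()].
#' @return `data.frame` with columns `check`, `status`
#'   (`"pass"`/`"fail"`), `detail`; one row per check performed.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- list()
  add <- function(check, ok, detail = "") {
    res[[length(res) + 1]] <<- data.frame(
      check = check, status = if (ok) "pass" else "fail",
      detail = detail, stringsAsFactors = FALSE)
  }
  if (config$mode == "simulate") {
    ok <- tryCatch({
      do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                            config$sim))
      TRUE
    }, error = function(e) e)
    add("sim_config", isTRUE(ok),
        if (isTRUE(ok)) "" else conditionMessage(ok))
    return(do.call(rbind, res))
  }
  p <- config$paths
  for (nm in names(p))
    add(paste0("file_exists:", nm), file.exists(p[[nm]]), p[[nm]])
  if (!is.null(p$expression) && !is.null(p$annotation) &&
      file.exists(p$expression) && file.exists(p$annotation)) {
    em <- tryCatch(read_expression(p$expression, p$annotation),
                   error = function(e) e)
    if (inherits(em, "error")) {
      add("expression_annotation_consistent", FALSE, conditionMessage(em))
    } else {
      add("expression_annotation_consistent", TRUE,
          paste0(nrow(em$values), " genes x ", ncol(em$values), " samples"))
      add("two_groups_present",
          all(c("case", "reference") %in% em$groups), "")
      add("min_group_size", min(table(em$groups)) >= 3,
          paste(table(em$groups), collapse = "/"))
    }
  }
  if (!is.null(p$plate) && file.exists(p$plate)) {
    plate <- tryCatch(read_plate(p$plate), error = function(e) e)
    if (inherits(plate, "error")) {
      add("plate_readable", FALSE, conditionMessage(plate))
    } else {
      add("plate_readable", TRUE, paste0(nrow(plate), " wells"))
      add("doses_positive", all(plate$dose_nM > 0), "")
      ndose <- tapply(plate$dose_nM, paste(plate$drug_id, plate$sample_id),
                      function(d) length(unique(d)))
      bad <- names(ndose)[ndose < 4]
      add("dose_ladder_complete", length(bad) == 0,
          if (length(bad)) paste("series with <4 doses:",
                                 paste(head(bad, 3), collapse = "; "))
          else "")
    }
  }
  for (nm in intersect(c("peaks_vehicle", "peaks_treated"), names(p))) {
    if (!file.exists(p[[nm]])) next
    tab <- tryCatch(utils::read.table(p[[nm]], sep = "\t",
                                      stringsAsFactors = FALSE),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      add(paste0("bed_readable:", nm), FALSE, conditionMessage(tab))
    } else {
      bad <- which(tab[[2]] >= tab[[3]])
      add(paste0("bed_coordinates:", nm), length(bad) == 0,
          if (length(bad)) paste("start >= end at line(s):",
                                 paste(head(bad, 5), collapse = ", "))
          else "")
    }
  }
  do.call(rbind, res)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in order: data simulation (or ingestion), rare-subgroup
#' differential expression, drug-screen scoring and selective ranking,
#' promoter construction, peak-to-promoter assignment, treatment DE and
#' rewiring classification, and qPCR quantities. All intermediate tables
#' are written under `config$out_dir` together with `report.json` and a
#' frozen copy of the resolved configuration; a rerun with the same
#' configuration and seed is bit-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report` with the headline counts, the
#'   top-of-ranking table, per-stage output paths and metadata.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- character(0)
  note <- function(f) { paths <<- c(paths, f); f }
  th <- config$thresholds
  sim_mode <- config$mode == "simulate"
  truth <- NULL

  # --- stage 1: expression cohort -------------------------------------
  if (sim_mode) {
    scfg <- do.call(sim_config, utils::modifyList(
      list(seed = config$seed), config$sim))
    sim <- simulate_expression(scfg)
    em <- sim$expr; truth <- sim$truth
    write_expression(em, note(out("expression.tsv")),
                     note(out("annotation.csv")))
  } else {
    p <- config$paths
    for (nm in c("expression", "annotation"))
      if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
        stop("pipeline stage 'ingest': missing input '", nm, "' (",
             if (is.null(p[[nm]])) "no path configured" else p[[nm]],
             "); provide paths$", nm)
    em <- read_expression(p$expression, p$annotation)
  }

  # --- stage 2: diagnosis differential expression ---------------------
  de_dx <- differential_expression(em, th, route = "kmcc")
  utils::write.csv(as.data.frame(de_dx), note(out("de_diagnosis.csv")),
                   row.names = FALSE)
  de_sum <- summary(de_dx)

  # --- stage 3: drug screen -------------------------------------------
  if (sim_mode) {
    screen_cfg <- do.call(sim_config, utils::modifyList(
      utils::modifyList(list(seed = config$seed), config$sim),
      list(n_samples_group = config$screen_n_case,
           n_samples_reference = config$screen_n_reference)))
    screen <- simulate_dose_response(screen_cfg)
    plate <- screen$plate
    screen_ann <- screen$annotation
    utils::write.csv(plate, note(out("plate.csv")), row.names = FALSE)
  } else {
    plate <- if (!is.null(config$paths$plate))
      read_plate(config$paths$plate) else NULL
    screen_ann <- if (!is.null(plate))
      utils::read.csv(config$paths$annotation, stringsAsFactors = FALSE)
  }
  ranking <- NULL
  if (!is.null(plate)) {
    scores <- score_plate(plate, activity_threshold = config$dss_threshold)
    ref_ids <- screen_ann$sample_id[screen_ann$group == "reference"]
    case_ids <- screen_ann$sample_id[screen_ann$group == "case"]
    scores <- sdss(scores, ref_ids)
    utils::write.csv(
      scores[, c("drug_id", "sample_id", "dss", "sdss")],
      note(out("drug_scores.csv")), row.names = FALSE)
    ranking <- rank_selective(scores, case_ids)
    utils::write.csv(ranking, note(out("drug_ranking.csv")),
                     row.names = FALSE)
  }

  # --- stage 4: promoters and binding ---------------------------------
  bound <- character(0); lost <- character(0); promoters <- NULL
  if (sim_mode) {
    tss <- simulate_gene_annotation(scfg)
  } else if (!is.null(config$paths$tss)) {
    gr <- read_bed(config$paths$tss)
    tss <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      tss = GenomicRanges::start(gr) - 1L,
                      strand = as.character(GenomicRanges::strand(gr)),
                      gene_id = gr$name, stringsAsFactors = FALSE)
  } else tss <- NULL
  if (!is.null(tss)) {
    promoters <- build_promoters(tss, config$promoter_upstream,
                                 config$promoter_downstream)
    write_bed(promoters, note(out("promoters.bed")))
    if (sim_mode) {
      pk <- simulate_peaks(scfg, promoters, truth)
      truth <- pk$truth
      for (nm in names(pk$tracks))
        write_bed(pk$tracks[[nm]], note(out(paste0("peaks_", nm, ".bed"))))
      peaks_vehicle <- pk$tracks$antibody_vehicle
      peaks_treated <- pk$tracks$antibody_treated
    } else {
      peaks_vehicle <- if (!is.null(config$paths$peaks_vehicle))
        read_bed(config$paths$peaks_vehicle) else NULL
      peaks_treated <- if (!is.null(config$paths$peaks_treated))
        read_bed(config$paths$peaks_treated) else NULL
    }
    if (!is.null(peaks_vehicle)) {
      bound <- assign_peaks(peaks_vehicle, promoters)
      writeLines(bound, note(out("bound_genes.txt")))
      if (!is.null(peaks_treated))
        lost <- binding_lost(peaks_vehicle, peaks_treated, promoters)
    }
  }
  bound_de <- intersect_bound_with_de(bound, de_dx, route = "kmcc")

  # --- stage 5: treatment DE and rewiring ------------------------------
  rewiring <- NULL
  treat_tables <- NULL
  if (sim_mode) {
    tr <- simulate_treatment_expression(scfg, truth)
    treat_tables <- lapply(tr[c("treated_case", "treated_reference",
                                "control_drug")], function(e)
      differential_expression(e, th, route = "classic"))
  } else {
    p <- config$paths
    trio <- c("treated_case", "treated_reference", "control_drug")
    if (all(trio %in% names(p))) {
      treat_tables <- lapply(trio, function(nm)
        differential_expression(
          read_expression(p[[nm]], p[[paste0(nm, "_annotation")]]),
          th, route = "classic"))
      names(treat_tables) <- trio
    }
  }
  if (!is.null(treat_tables)) {
    rewiring <- classify_rewiring(
      de_dx, treat_tables$treated_case, treat_tables$treated_reference,
      treat_tables$control_drug, bound = bound, lost = lost,
      alpha = th$alpha)
    utils::write.csv(as.data.frame(rewiring),
                     note(out("rewiring_report.csv")), row.names = FALSE)
  }

  # --- stage 6: qPCR quantities ----------------------------------------
  qpcr <- NULL
  if (sim_mode) {
    q <- simulate_qpcr(scfg)
    rel <- delta_ct_expression(q$expression_ct, q$housekeeping,
                               q$control_condition)
    fe <- fold_enrichment(q$enrichment_ct, q$control_track)
    utils::write.csv(rel, note(out("qpcr_relative_expression.csv")),
                     row.names = FALSE)
    utils::write.csv(fe, note(out("qpcr_fold_enrichment.csv")),
                     row.names = FALSE)
    qpcr <- list(relative_expression = rel, fold_enrichment = fe)
  }

  # --- report -----------------------------------------------------------
  rew_sum <- if (!is.null(rewiring)) summary(rewiring) else NULL
  report <- list(
    de = list(n_genes = de_sum$n_genes, n_pass = de_sum$n_pass,
              n_up = de_sum$n_up, n_down = de_sum$n_down,
              n_pass_classic = de_sum$n_pass_classic),
    drugs = if (!is.null(ranking)) list(
      n_drugs = nrow(ranking),
      top5 = ranking[seq_len(min(5, nrow(ranking))),
                     c("drug_id", "mean_case_sdss", "rank")]),
    binding = list(n_bound = length(bound),
                   n_bound_and_de = nrow(bound_de),
                   n_binding_lost = length(lost)),
    rewiring = if (!is.null(rew_sum)) list(
      n_up_at_diagnosis = rew_sum$n_up_at_diagnosis,
      n_rewired = rew_sum$n_rewired,
      rewired_genes = rewiring$gene_id[rewiring$rewired]),
    qpcr = if (!is.null(qpcr)) list(
      knockdown_relative_expression =
        qpcr$relative_expression$rel_to_control[
          qpcr$relative_expression$condition != "scramble"][1]),
    metadata = list(
      package_version = as.character(utils::packageVersion("raresig")),
      mode = config$mode, seed = config$seed,
      thresholds = unclass(th), dss_threshold = config$dss_threshold,
      promoter_window = c(upstream = config$promoter_upstream,
                          downstream = config$promoter_downstream),
      bandwidth_rule = "silverman",
      classic_test = "Welch two-sample t (two-sided)"),
    outputs = paths)
  write_json_report(report, out("report.json"))
  yaml::write_yaml(
    utils::modifyList(unclass(config),
                      list(thresholds = unclass(th))),
    out("resolved_config.yaml"))
  if (sim_mode) report$truth <- truth
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  DE: ", x$de$n_pass, " pass (", x$de$n_up, " up / ", x$de$n_down,
      " down) of ", x$de$n_genes, " genes\n", sep = "")
  if (!is.null(x$drugs))
    cat("  drugs: ", x$drugs$n_drugs, " ranked; top: ",
        paste(x$drugs$top5$drug_id, collapse = ", "), "\n", sep = "")
  cat("  binding: ", x$binding$n_bound, " bound promoters, ",
      x$binding$n_bound_and_de, " bound & DE, ",
      x$binding$n_binding_lost, " lost on treatment\n", sep = "")
  if (!is.null(x$rewiring))
    cat("  rewiring: ", x$rewiring$n_rewired, " of ",
        x$rewiring$n_up_at_diagnosis, " up-at-diagnosis genes\n", sep = "")
  invisible(x)
}
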