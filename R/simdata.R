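#' Configuration of the synthetic study generator
#'
#' Holds the design constants of the emulated study: a large reference
#' cohort with a handful of fusion-positive cases, spiked differential
#' genes at a given log2 effect size, a drug panel with a few
#' group-selective compounds, and promoter binding that is partly lost
#' under treatment. Defaults mirror the emulated design: 7 cases against
#' 741 references, 104 up- and 62 down-spiked genes at mean |l2fc| 1.5,
#' a 527-compound panel with 4 selective drugs, 36 rewired genes, 801
#' promoter-bound genes of which 10 overlap the spiked set.
#'
#' @param seed Integer seed; fixes every generated artifact bit-identically.
#' @param n_genes Number of genes.
#' @param n_samples_reference,n_samples_group Reference / case cohort sizes.
#' @param n_up_spiked,n_down_spiked Numbers of up-/down-spiked genes.
#' @param effect_l2fc_mean,effect_l2fc_sd Mean and SD of the spiked log2
#'   effect (the draw is centred at `+mean` for up, `-mean` for down genes).
#' @param noise_sd Gaussian log2 noise SD shared by all samples.
#' @param n_drugs,n_selective_drugs Size of the drug panel and number of
#'   case-selective compounds within it.
#' @param n_rewired Number of up-spiked genes whose case overexpression is
#'   lost under the treatment (must be <= `n_up_spiked`).
#' @param n_bound_genes Number of promoter-bound genes.
#' @param n_bound_and_de Number of bound genes drawn from the spiked set.
#' @param replicates_per_condition Replicates per (sample, treatment) in the
#'   treatment experiment.
#' @param n_treated_samples Samples per cohort in the treatment experiment
#'   (columns per condition = samples x replicates).
#' @param response_noise_sd SD (in % inhibition) of plate response noise.
#' @param dose_min,dose_max,n_doses Dose ladder: `n_doses` log10-spaced
#'   points over \[`dose_min`, `dose_max`\] nM (default 5 points over a
#'   10,000-fold range).
#' @param n_background_peaks Background (non-promoter) intervals per track.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_reference = 741L,
                       n_samples_group = 7L,
                       n_up_spiked = 104L,
                       n_down_spiked = 62L,
                       effect_l2fc_mean = 1.5,
                       effect_l2fc_sd = 0.25,
                       noise_sd = 0.5,
                       n_drugs = 527L,
                       n_selective_drugs = 4L,
                       n_rewired = 36L,
                       n_bound_genes = 801L,
                       n_bound_and_de = 10L,
                       replicates_per_condition = 5L,
                       n_treated_samples = 2L,
                       response_noise_sd = 4,
                       dose_min = 1,
                       dose_max = 1e4,
                       n_doses = 5L,
                       n_background_peaks = 200L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_reference = as.integer(n_samples_reference),
              n_samples_group = as.integer(n_samples_group),
              n_up_spiked = as.integer(n_up_spiked),
              n_down_spiked = as.integer(n_down_spiked),
              effect_l2fc_mean = effect_l2fc_mean,
              effect_l2fc_sd = effect_l2fc_sd, noise_sd = noise_sd,
              n_drugs = as.integer(n_drugs),
              n_selective_drugs = as.integer(n_selective_drugs),
              n_rewired = as.integer(n_rewired),
              n_bound_genes = as.integer(n_bound_genes),
              n_bound_and_de = as.integer(n_bound_and_de),
              replicates_per_condition = as.integer(replicates_per_condition),
              n_treated_samples = as.integer(n_treated_samples),
              response_noise_sd = response_noise_sd,
              dose_min = dose_min, dose_max = dose_max,
              n_doses = as.integer(n_doses),
              n_background_peaks = as.integer(n_background_peaks))
  counts <- cfg[c("n_genes", "n_samples_reference", "n_samples_group",
                  "n_up_spiked", "n_down_spiked", "n_drugs",
                  "n_selective_drugs", "n_rewired", "n_bound_genes",
                  "n_bound_and_de", "replicates_per_condition",
                  "n_treated_samples", "n_doses", "n_background_peaks")]
  neg <- names(counts)[vapply(counts, function(x) x < 0, logical(1))]
  if (length(neg))
    stop("configuration error: counts must be >= 0, violated by: ",
         paste(neg, collapse = ", "))
  if (cfg$n_up_spiked + cfg$n_down_spiked > cfg$n_genes)
    stop("configuration error: n_up_spiked + n_down_spiked (",
         cfg$n_up_spiked + cfg$n_down_spiked, ") exceeds n_genes (",
         cfg$n_genes, ")")
  if (cfg$n_rewired > cfg$n_up_spiked)
    stop("configuration error: n_rewired (", cfg$n_rewired,
         ") exceeds n_up_spiked (", cfg$n_up_spiked, ")")
  if (cfg$n_bound_and_de >
      min(cfg$n_bound_genes, cfg$n_up_spiked + cfg$n_down_spiked))
    stop("configuration error: n_bound_and_de (", cfg$n_bound_and_de,
         ") exceeds min(n_bound_genes, n_up_spiked + n_down_spiked)")
  if (cfg$n_bound_genes > cfg$n_genes)
    stop("configuration error: n_bound_genes (", cfg$n_bound_genes,
         ") exceeds n_genes (", cfg$n_genes, ")")
  if (cfg$n_selective_drugs > cfg$n_drugs)
    stop("configuration error: n_selective_drugs (", cfg$n_selective_drugs,
         ") exceeds n_drugs (", cfg$n_drugs, ")")
  if (cfg$noise_sd < 0 || cfg$effect_l2fc_sd < 0 || cfg$response_noise_sd < 0)
    stop("configuration error: noise SDs must be >= 0")
  if (cfg$dose_min <= 0 || cfg$dose_min >= cfg$dose_max)
    stop("configuration error: need 0 < dose_min < dose_max")
  if (cfg$n_doses < 4)
    stop("configuration error: n_doses must be >= 4 for curve fitting")
  if (cfg$replicates_per_condition < 1)
    stop("configuration error: replicates_per_condition must be >= 1")
  structure(cfg, class = "sim_config")
}

gene_ids_of <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

# Per-gene baselines and truth labels shared by all generators; drawn under
# a seed offset of the config seed so each generator is independently
# reproducible while staying mutually consistent.
sim_truth <- function(cfg) {
  genes <- gene_ids_of(cfg)
  withr::with_seed(cfg$seed, {
    baseline <- stats::setNames(runif(cfg$n_genes, 3, 10), genes)
    spiked <- sample(genes, cfg$n_up_spiked + cfg$n_down_spiked)
    spiked_up <- sort(spiked[seq_len(cfg$n_up_spiked)])
    spiked_down <- sort(setdiff(spiked, spiked_up))
    effect <- stats::setNames(numeric(cfg$n_genes), genes)
    effect[spiked_up] <- cfg$effect_l2fc_mean +
      rnorm(cfg$n_up_spiked, 0, cfg$effect_l2fc_sd)
    effect[spiked_down] <- -(cfg$effect_l2fc_mean +
      rnorm(cfg$n_down_spiked, 0, cfg$effect_l2fc_sd))
    rewired <- sort(sample(spiked_up, cfg$n_rewired))
    bound_de <- sort(sample(c(spiked_up, spiked_down), cfg$n_bound_and_de))
    pool <- setdiff(genes, c(spiked_up, spiked_down))
    bound_bg <- sort(sample(pool, cfg$n_bound_genes - cfg$n_bound_and_de))
    structure(
      list(spiked_up = spiked_up, spiked_down = spiked_down,
           rewired_genes = rewired,
           bound_genes = sort(c(bound_de, bound_bg)),
           bound_and_de = bound_de,
           true_l2fc = effect, baseline = baseline,
           selective_drugs = character(0), true_dss = NULL),
      class = "ground_truth")
  })
}

#' Simulate a diagnosis expression cohort with known ground truth
#'
#' Draws a genes x samples log2 expression matrix: every gene has a uniform
#' baseline on \[3, 10\] plus Gaussian log2 noise; spiked genes are shifted
#' in the case group by an effect drawn around +/- `effect_l2fc_mean`. The
#' returned truth records the spiked sets, the per-gene true l2fc, and the
#' downstream labels (rewired, promoter-bound) used by the other
#' generators, so that all simulated artifacts are mutually consistent.
#'
#' @param config A [sim_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`
#'   (class `ground_truth`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- sim_truth(config)
  genes <- gene_ids_of(config)
  n_case <- config$n_samples_group
  n_ref <- config$n_samples_reference
  samples <- c(sprintf("case_%03d", seq_len(n_case)),
               sprintf("ref_%03d", seq_len(n_ref)))
  groups <- stats::setNames(rep(c("case", "reference"), c(n_case, n_ref)),
                            samples)
  mat <- withr::with_seed(config$seed + 1L, {
    m <- matrix(rnorm(config$n_genes * length(samples), 0, config$noise_sd),
                config$n_genes, length(samples),
                dimnames = list(genes, samples))
    m <- m + truth$baseline
    if (n_case > 0)
      m[, seq_len(n_case)] <- m[, seq_len(n_case), drop = FALSE] +
        truth$true_l2fc
    m
  })
  list(expr = expression_matrix(mat, groups), truth = truth)
}

#' Simulate replicate-level treatment expression experiments
#'
#' Emulates the three treated-vs-vehicle comparisons needed to classify
#' treatment-dependent rewiring: case cells under the study drug, reference
#' cells under the study drug, and case cells under a control drug. Each
#' condition has `n_treated_samples * replicates_per_condition` replicate
#' columns. Rewired genes lose their case overexpression under the study
#' drug (their treated mean returns to the reference baseline); all other
#' genes, and all genes under the control drug or in reference cells, keep
#' their condition mean.
#'
#' @param config A [sim_config()].
#' @param truth Optional `ground_truth` from [simulate_expression()];
#'   regenerated from `config` if omitted.
#' @return List of three [expression_matrix()] objects (`treated_case`,
#'   `treated_reference`, `control_drug`), each labelling treated columns
#'   `"case"` and vehicle columns `"reference"`, plus `truth`.
#' @export
simulate_treatment_expression <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- sim_truth(config)
  genes <- gene_ids_of(config)
  nrep <- config$replicates_per_condition * config$n_treated_samples
  base_ref <- truth$baseline
  base_case <- truth$baseline + truth$true_l2fc
  treated_case_mean <- base_case
  treated_case_mean[truth$rewired_genes] <- base_ref[truth$rewired_genes]
  one <- function(mean_ctrl, mean_trt, seed_off) {
    cols <- c(sprintf("trt_%02d", seq_len(nrep)),
              sprintf("veh_%02d", seq_len(nrep)))
    withr::with_seed(config$seed + seed_off, {
      m <- matrix(rnorm(config$n_genes * 2 * nrep, 0, config$noise_sd),
                  config$n_genes, 2 * nrep, dimnames = list(genes, cols))
      m[, seq_len(nrep)] <- m[, seq_len(nrep)] + mean_trt
      m[, nrep + seq_len(nrep)] <- m[, nrep + seq_len(nrep)] + mean_ctrl
      expression_matrix(m, rep(c("case", "reference"), each = nrep))
    })
  }
  list(treated_case = one(base_case, treated_case_mean, 2L),
       treated_reference = one(base_ref, base_ref, 3L),
       control_drug = one(base_case, base_case, 4L),
       truth = truth)
}

#' Simulate a TSS annotation for the synthetic genes
#'
#' Genes are laid out on four chromosomes, 50 kb apart, with random strand.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with columns `chrom`, `tss` (0-based coordinate),
#'   `strand`, `gene_id`.
#' @export
simulate_gene_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- gene_ids_of(config)
  n <- config$n_genes
  i <- seq_len(n) - 1L
  withr::with_seed(config$seed + 5L, {
    data.frame(
      chrom = paste0("chr", 1L + i %% 4L),
      tss = 20000L + (i %/% 4L) * 50000L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      gene_id = genes, stringsAsFactors = FALSE)
  })
}

random_background_peaks <- function(n, promoters, chroms, max_pos) {
  # rejection-sample intervals that overlap no promoter
  got <- GenomicRanges::GRanges()
  tries <- 0L
  while (length(got) < n && tries < 50L) {
    k <- max(2L * (n - length(got)), 10L)
    width <- round(runif(k, 200, 1000))
    start <- round(runif(k, 1, max_pos))
    cand <- GenomicRanges::GRanges(sample(chroms, k, replace = TRUE),
                                   IRanges::IRanges(start, width = width))
    hit <- IRanges::overlapsAny(cand, promoters)
    got <- c(got, cand[!hit])
    tries <- tries + 1L
  }
  out <- got[seq_len(min(n, length(got)))]
  names(out) <- NULL
  out
}

#' Simulate antibody/IgG binding-peak tracks under vehicle and treatment
#'
#' Produces four peak tracks (antibody and IgG control, each under vehicle
#' and under treatment). Every promoter-bound gene gets a 200-1000 bp peak
#' overlapping its promoter by at least 1 bp in the antibody/vehicle track;
#' genes whose binding is treatment-dependent (the rewired, bound genes)
#' lose that peak in the antibody/treated track. IgG tracks carry only
#' background intervals that overlap no promoter, as do the antibody tracks
#' on top of their true peaks.
#'
#' @param config A [sim_config()].
#' @param promoters Named `GRanges` of promoter windows (one per gene), e.g.
#'   from [build_promoters()].
#' @param truth Optional `ground_truth`; regenerated from `config` if
#'   omitted. Its `bound_genes` must all have a promoter.
#' @return List with `tracks` (named list of `GRanges`: `antibody_vehicle`,
#'   `antibody_treated`, `igg_vehicle`, `igg_treated`) and `truth` (with
#'   `lost_genes` added: bound genes whose peak disappears on treatment).
#' @export
simulate_peaks <- function(config, promoters, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(promoters) == 0) stop("promoters must be non-empty")
  if (is.null(names(promoters)) || anyDuplicated(names(promoters)))
    stop("promoters must be uniquely named by gene id")
  if (config$n_bound_genes > length(promoters))
    stop("configuration error: n_bound_genes (", config$n_bound_genes,
         ") exceeds the number of promoters (", length(promoters), ")")
  withr::with_seed(config$seed + 6L, {
    if (is.null(truth)) truth <- sim_truth(config)
    bound <- intersect(truth$bound_genes, names(promoters))
    if (length(bound) < length(truth$bound_genes))
      stop("bound genes missing from the promoter map: ",
           paste(head(setdiff(truth$bound_genes, names(promoters)), 5),
                 collapse = ", "))
    lost <- intersect(truth$rewired_genes, bound)
    prom <- promoters[bound]
    width <- round(runif(length(bound), 200, 1000))
    # any start in [prom_start - width + 1, prom_end] overlaps by >= 1 bp
    start <- floor(runif(length(bound),
                         GenomicRanges::start(prom) - width + 1,
                         GenomicRanges::end(prom) + 1))
    start <- pmax(start, 1)
    peaks <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(prom),
      IRanges::IRanges(start, width = width), name = bound)
    names(peaks) <- NULL
    chroms <- unique(as.character(GenomicRanges::seqnames(promoters)))
    max_pos <- max(GenomicRanges::end(promoters)) + 100000
    bg <- function() {
      g <- random_background_peaks(config$n_background_peaks, promoters,
                                   chroms, max_pos)
      if (length(g)) g$name <- "background"
      g
    }
    tracks <- list(
      antibody_vehicle = c(peaks, bg()),
      antibody_treated = c(peaks[!peaks$name %in% lost], bg()),
      igg_vehicle = bg(),
      igg_treated = bg())
    tracks <- lapply(tracks, GenomicRanges::sort)
    truth$lost_genes <- sort(lost)
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a dose-response screening plate with known selective drugs
#'
#' Every drug gets 4PL parameters (bottom 0, top uniform on \[10, 90\],
#' EC50 log-uniform inside the dose window, Hill slope uniform on
#' \[0.8, 2.5\]) shared by both groups; the selective drugs additionally
#' get an elevated top asymptote (+40%, capped at 100) and a 10-fold lower
#' EC50 in the case group only. Responses are the group curve evaluated on
#' the dose ladder plus Gaussian noise (`response_noise_sd`). True DSS per
#' (drug, group) is computed from the generating parameters.
#'
#' @param config A [sim_config()]; `n_samples_group` / `n_samples_reference`
#'   set the screened cohort sizes.
#' @return List with `plate` (long `data.frame`: `drug_id`, `sample_id`,
#'   `dose_nM`, `response_pct`), `annotation` (sample -> group), and
#'   `truth` (`selective_drugs`, `true_dss`, generating `params`).
#' @export
simulate_dose_response <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nd <- config$n_drugs
  drugs <- sprintf("drug_%03d", seq_len(nd))
  n_case <- config$n_samples_group
  n_ref <- config$n_samples_reference
  samples <- c(sprintf("case_%03d", seq_len(n_case)),
               sprintf("ref_%03d", seq_len(n_ref)))
  group <- rep(c("case", "reference"), c(n_case, n_ref))
  doses <- 10^seq(log10(config$dose_min), log10(config$dose_max),
                  length.out = config$n_doses)
  withr::with_seed(config$seed + 7L, {
    top_ref <- runif(nd, 10, 90)
    lm10 <- log10(config$dose_min); lM10 <- log10(config$dose_max)
    ec50_ref <- 10^runif(nd, lm10 + 0.5, lM10 - 0.5)
    hill <- runif(nd, 0.8, 2.5)
    selective <- sort(sample(drugs, config$n_selective_drugs))
    is_sel <- drugs %in% selective
    top_case <- ifelse(is_sel, pmin(top_ref + 40, 100), top_ref)
    ec50_case <- ifelse(is_sel, ec50_ref / 10, ec50_ref)
    params <- data.frame(
      drug_id = drugs, bottom = 0, top_reference = top_ref,
      top_case = top_case, ec50_reference = ec50_ref,
      ec50_case = ec50_case, hill = hill, stringsAsFactors = FALSE)
    true_dss <- rbind(
      data.frame(drug_id = drugs, group = "case",
                 dss = dss_params(0, top_case, ec50_case, hill,
                                  config$dose_min, config$dose_max)),
      data.frame(drug_id = drugs, group = "reference",
                 dss = dss_params(0, top_ref, ec50_ref, hill,
                                  config$dose_min, config$dose_max)))
    # long plate: drug x sample x dose
    grid <- expand.grid(dose_i = seq_along(doses),
                        sample_i = seq_along(samples),
                        drug_i = seq_len(nd))
    g_case <- group[grid$sample_i] == "case"
    top_g <- ifelse(g_case, top_case[grid$drug_i], top_ref[grid$drug_i])
    ec50_g <- ifelse(g_case, ec50_case[grid$drug_i], ec50_ref[grid$drug_i])
    h_g <- hill[grid$drug_i]
    d_g <- doses[grid$dose_i]
    y <- top_g / (1 + (ec50_g / d_g)^h_g)
    if (config$response_noise_sd > 0)
      y <- y + rnorm(length(y), 0, config$response_noise_sd)
    plate <- data.frame(
      drug_id = drugs[grid$drug_i], sample_id = samples[grid$sample_i],
      dose_nM = d_g, response_pct = y, stringsAsFactors = FALSE)
    truth <- list(selective_drugs = selective, true_dss = true_dss,
                  params = params)
    list(plate = plate,
         annotation = data.frame(sample_id = samples, group = group,
                                 stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate qPCR Ct tables with encoded truth
#'
#' Two tables are produced. The expression table emulates a knockdown
#' experiment quantified against two housekeeping genes: the knockdown
#' condition's target Ct is raised by `-log2(1 - knockdown_efficiency)`
#' cycles over the control condition. The enrichment table emulates
#' chromatin-profiling qPCR: each track's Ct at each locus is lowered below
#' the control IgG track by `log2(fold)` cycles, where `fold` is that
#' track's encoded enrichment.
#'
#' @param config A [sim_config()]; `replicates_per_condition` sets the
#'   number of technical replicates.
#' @param knockdown_efficiency Fraction of target expression removed in the
#'   knockdown condition (0.5 = 50% remaining).
#' @param enrichment_folds Named numeric vector: encoded fold enrichment of
#'   each track relative to the control IgG track.
#' @param ct_noise_sd Gaussian Ct noise (cycles); 0 gives exact tables.
#' @return List with `expression_ct` (`condition`, `target_id`, `replicate`,
#'   `ct`), `enrichment_ct` (`track`, `locus`, `replicate`, `ct`),
#'   `housekeeping`, `control_condition`, `control_track` and `truth`.
#' @export
simulate_qpcr <- function(config, knockdown_efficiency = 0.5,
                          enrichment_folds = c(antibody_case = 8,
                                               igg_case = 1,
                                               antibody_control = 1.2,
                                               igg_control = 0.9),
                          ct_noise_sd = 0) {
  stopifnot(inherits(config, "sim_config"),
            knockdown_efficiency >= 0, knockdown_efficiency < 1)
  nrep <- config$replicates_per_condition
  withr::with_seed(config$seed + 8L, {
    hk <- c(GAPDH = 18, RN18S = 10)
    base_target <- 24
    dct_shift <- -log2(1 - knockdown_efficiency)
    rows <- expand.grid(replicate = seq_len(nrep),
                        target_id = c("target", names(hk)),
                        condition = c("scramble", "knockdown"),
                        stringsAsFactors = FALSE)
    ct0 <- ifelse(rows$target_id == "target",
                  base_target +
                    ifelse(rows$condition == "knockdown", dct_shift, 0),
                  hk[rows$target_id])
    expr_ct <- data.frame(rows[c("condition", "target_id", "replicate")],
                          ct = ct0 + rnorm(nrow(rows), 0, ct_noise_sd))
    loci <- c("locus_A", "locus_B")
    igg_ct <- c(locus_A = 28, locus_B = 30)
    rows2 <- expand.grid(replicate = seq_len(nrep), locus = loci,
                         track = names(enrichment_folds),
                         stringsAsFactors = FALSE)
    ct2 <- igg_ct[rows2$locus] - log2(enrichment_folds[rows2$track])
    enr_ct <- data.frame(rows2[c("track", "locus", "replicate")],
                         ct = ct2 + rnorm(nrow(rows2), 0, ct_noise_sd))
    list(expression_ct = expr_ct, enrichment_ct = enr_ct,
         housekeeping = names(hk), control_condition = "scramble",
         control_track = "igg_case",
         truth = list(
           knockdown_efficiency = knockdown_efficiency,
           relative_expression_knockdown = 1 - knockdown_efficiency,
           enrichment_folds = enrichment_folds))
  })
}
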