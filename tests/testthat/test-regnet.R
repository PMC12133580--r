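test_that("build_promoters applies the strand-aware window arithmetic", {
  tss <- data.frame(chrom = "chr1", tss = c(10000, 10000, 100),
                    strand = c("+", "-", "+"),
                    gene_id = c("gp", "gm", "gc"))
  pr <- build_promoters(tss)
  df <- gr_to_df0(pr)
  # + strand: [TSS-2000, TSS+500)
  expect_equal(unlist(df[df$gene_id == "gp", c("start0", "end0")]),
               c(start0 = 8000, end0 = 10500))
  # - strand mirror: [TSS-500, TSS+2000)
  expect_equal(unlist(df[df$gene_id == "gm", c("start0", "end0")]),
               c(start0 = 9500, end0 = 12000))
  # clipped at 0
  expect_equal(unlist(df[df$gene_id == "gc", c("start0", "end0")]),
               c(start0 = 0, end0 = 600))
  # strand mirror property: reflection about the TSS
  p <- df[df$gene_id == "gp", ]; m <- df[df$gene_id == "gm", ]
  expect_equal(10000 - p$start0, m$end0 - 10000)
  expect_equal(p$end0 - 10000, 10000 - m$start0)
  # missing strand defaults to + with a warning
  expect_warning(pr2 <- build_promoters(
    data.frame(chrom = "chr1", tss = 5000, strand = ".", gene_id = "gx")),
    "strand")
  expect_equal(GenomicRanges::start(pr2), 3001)
  expect_error(build_promoters(tss[c(1, 1), ]), "duplicated")
})

test_that("assign_peaks honours half-open overlap semantics", {
  prom <- build_promoters(data.frame(chrom = "chr1", tss = 10000,
                                     strand = "+", gene_id = "g1"))
  mk <- function(start0, end0) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start0 + 1, end0))
  expect_equal(assign_peaks(mk(8100, 8300), prom), "g1")
  # touching half-open intervals do not overlap
  expect_length(assign_peaks(mk(10500, 10700), prom), 0)
  expect_length(assign_peaks(mk(7000, 8000), prom), 0)
  expect_equal(assign_peaks(mk(7000, 8001), prom), "g1")
  # min_overlap raises the bar
  expect_length(assign_peaks(mk(7000, 8005), prom, min_overlap = 10), 0)
  expect_equal(assign_peaks(mk(7000, 8010), prom, min_overlap = 10), "g1")
})

test_that("assign_peaks equals the brute-force oracle on random intervals", {
  for (seed in 1:5) {
    dat <- withr::with_seed(seed, {
      prom <- build_promoters(data.frame(
        chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
        tss = sample(5000:200000, 40), strand = sample(c("+", "-"), 40, TRUE),
        gene_id = sprintf("g%02d", 1:40)))
      start0 <- sample(0:210000, 150, replace = TRUE)
      peaks <- GenomicRanges::GRanges(
        sample(c("chr1", "chr2"), 150, replace = TRUE),
        IRanges::IRanges(start0 + 1, width = sample(50:1500, 150, TRUE)))
      list(prom = prom, peaks = peaks)
    })
    expect_identical(assign_peaks(dat$peaks, dat$prom),
                     oracle_bound_genes(gr_to_df0(dat$peaks),
                                        gr_to_df0(dat$prom)))
  }
})

test_that("chromosome-name mismatches are caught and harmonisable", {
  prom <- build_promoters(data.frame(chrom = "chr1", tss = 10000,
                                     strand = "+", gene_id = "g1"))
  peaks <- GenomicRanges::GRanges("1", IRanges::IRanges(8101, 8300))
  expect_error(assign_peaks(peaks, prom), "chromosome naming mismatch")
  expect_equal(assign_peaks(peaks, prom, normalize_chr = TRUE), "g1")
})

test_that("intersect_bound_with_de and binding_lost behave set-wise", {
  m <- withr::with_seed(3, matrix(rnorm(60), 10, 6,
      dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6))))
  m["g01", 1:3] <- m["g01", 1:3] + 5  # clear up gene
  em <- expression_matrix(m, rep(c("case", "reference"), each = 3))
  de <- differential_expression(em)
  expect_equal(nrow(intersect_bound_with_de(character(0), de)), 0)
  hit <- intersect_bound_with_de(c("g01", "g09"), de)
  expect_true("g01" %in% hit$gene_id)
  expect_equal(hit$direction[hit$gene_id == "g01"], "up")
  # bound subset of DE returns bound
  de_genes <- de$gene_id[de$passes_kmcc]
  expect_equal(intersect_bound_with_de(de_genes, de)$gene_id,
               sort(de_genes))
  # binding_lost trivials
  prom <- build_promoters(data.frame(chrom = "chr1", tss = 10000,
                                     strand = "+", gene_id = "g1"))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8101, 8300))
  none <- GenomicRanges::GRanges()
  expect_length(binding_lost(pk, pk, prom), 0)
  expect_equal(binding_lost(pk, none, prom), "g1")
})

test_that("delta-Ct quantification reproduces hand-computed values", {
  ct <- expand.grid(condition = c("scramble", "knockdown"),
                    target_id = c("tgt", "hk1", "hk2"), replicate = 1:2,
                    stringsAsFactors = FALSE)
  base <- c(tgt = 25, hk1 = 20, hk2 = 22)
  ct$ct <- base[ct$target_id] + ifelse(
    ct$condition == "knockdown" & ct$target_id == "tgt", 1, 0)
  res <- delta_ct_expression(ct, c("hk1", "hk2"), "scramble")
  scr <- res[res$condition == "scramble", ]
  # housekeeping pair (20, 22), target 25 -> dCt 4, rel 2^-4
  expect_equal(scr$delta_ct, 4)
  expect_equal(scr$rel_expression, 2^-4)
  expect_equal(scr$rel_to_control, 1)   # control condition maps to 1
  kd <- res[res$condition == "knockdown", ]
  expect_equal(kd$rel_to_control, 0.5)  # one extra cycle = 50% remaining
  # target Ct equal to the housekeeping average -> relative expression 1
  ct2 <- data.frame(condition = "c", target_id = c("t", "hk1", "hk2"),
                    replicate = 1, ct = c(21, 20, 22))
  expect_equal(delta_ct_expression(ct2, c("hk1", "hk2"))$rel_expression, 1)
  # missing housekeeping skips the condition with a warning
  expect_warning(
    out <- delta_ct_expression(ct[ct$target_id != "hk2" |
                                    ct$condition != "knockdown", ],
                               c("hk1", "hk2")),
    "skipped")
  expect_false("knockdown" %in% out$condition)
})

test_that("fold enrichment is relative to the control IgG track", {
  ct <- expand.grid(track = c("ab", "igg"), locus = "L", replicate = 1:2,
                    stringsAsFactors = FALSE)
  ct$ct <- ifelse(ct$track == "igg", 28, 26)
  fe <- fold_enrichment(ct, "igg")
  # control track maps to exactly 1; two cycles below IgG = fold 4
  expect_equal(fe$fold_enrichment[fe$track == "igg"], 1)
  expect_equal(fe$fold_enrichment[fe$track == "ab"], 4)
  # replicate means: IgG 28.0 vs antibody 24.5 -> 2^3.5
  ct2 <- data.frame(track = rep(c("ab", "igg"), each = 2), locus = "L",
                    replicate = c(1, 2, 1, 2), ct = c(24, 25, 27.5, 28.5))
  fe2 <- fold_enrichment(ct2, "igg")
  expect_equal(fe2$fold_enrichment[fe2$track == "ab"], 2^3.5)
  expect_error(fold_enrichment(ct2, "nope"), "control track")
})

test_that("classify_rewiring applies the selectivity rule", {
  mk_de <- function(l2fc, p) {
    data.frame(gene_id = names(l2fc), l2fc = unname(l2fc),
               kernel_mcc = NA_real_, p_value = unname(p),
               passes_kmcc = NA, passes_classic = p < 0.05 &
                 abs(l2fc) >= log2(1.5),
               direction = ifelse(l2fc >= 0, "up", "down"),
               stringsAsFactors = FALSE)
  }
  genes <- c("gA", "gB", "gC", "gD")
  dx <- mk_de(c(gA = 2, gB = 2, gC = 2, gD = -2),
              c(gA = 1e-5, gB = 1e-5, gC = 1e-5, gD = 1e-5))
  # gA: selective loss (rewired); gB: lost in both cohorts (not rewired);
  # gC: also responds to the control drug (not rewired)
  trt_case <- mk_de(c(gA = -2, gB = -2, gC = -2, gD = 0),
                    c(gA = 0.001, gB = 0.001, gC = 0.001, gD = 0.9))
  trt_ref <- mk_de(c(gA = 0, gB = -2, gC = 0, gD = 0),
                   c(gA = 0.8, gB = 0.001, gC = 0.8, gD = 0.9))
  ctrl <- mk_de(c(gA = 0, gB = 0, gC = -2, gD = 0),
                c(gA = 0.9, gB = 0.9, gC = 0.001, gD = 0.9))
  rep <- classify_rewiring(dx, trt_case, trt_ref, ctrl,
                           bound = c("gA", "gD"), lost = "gA",
                           diagnosis_route = "classic")
  expect_equal(rep$gene_id[rep$rewired], "gA")
  expect_false(rep$rewired[rep$gene_id == "gB"])  # selectivity violated
  expect_false(rep$rewired[rep$gene_id == "gC"])  # control drug responds
  expect_true(all(rep$rewired <= rep$up_at_diagnosis))
  expect_setequal(rep$gene_id[rep$bound_and_de], c("gA", "gD"))
  expect_true(all(rep$bound_and_de <= rep$bound_at_promoter))
  s <- summary(rep)
  expect_equal(s$n_rewired, 1)
  expect_equal(s$n_bound_and_de, 2)
  # namespace mismatch is an explicit error
  expect_error(classify_rewiring(dx, trt_case[1:3, ], trt_ref, ctrl,
                                 bound = character(0)),
               "namespace mismatch")
})
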