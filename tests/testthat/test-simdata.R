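test_that("sim_config validates its bounds with informative errors", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 100L, n_up_spiked = 80L,
                          n_down_spiked = 40L, n_bound_genes = 50L),
               "n_up_spiked \\+ n_down_spiked")
  expect_error(sim_config(n_up_spiked = 10L, n_down_spiked = 0L,
                          n_rewired = 11L, n_bound_and_de = 5L),
               "n_rewired")
  expect_error(sim_config(n_bound_and_de = 500L), "n_bound_and_de")
  expect_error(sim_config(n_selective_drugs = 600L), "n_selective_drugs")
  expect_error(sim_config(n_doses = 3L), "n_doses")
  expect_error(sim_config(noise_sd = -1), "noise SDs")
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 99L, n_genes = 120L, n_samples_reference = 30L,
                    n_samples_group = 5L, n_up_spiked = 8L,
                    n_down_spiked = 4L, n_drugs = 15L,
                    n_selective_drugs = 2L, n_rewired = 3L,
                    n_bound_genes = 30L, n_bound_and_de = 4L)
  a <- simulate_expression(cfg); b <- simulate_expression(cfg)
  expect_identical(a, b)
  expect_identical(simulate_dose_response(cfg), simulate_dose_response(cfg))
  prom <- build_promoters(simulate_gene_annotation(cfg))
  expect_identical(simulate_peaks(cfg, prom), simulate_peaks(cfg, prom))
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  expect_identical(simulate_treatment_expression(cfg),
                   simulate_treatment_expression(cfg))
  # a different seed changes the data
  cfg2 <- sim_config(seed = 100L, n_genes = 120L,
                     n_samples_reference = 30L, n_samples_group = 5L,
                     n_up_spiked = 8L, n_down_spiked = 4L, n_drugs = 15L,
                     n_selective_drugs = 2L, n_rewired = 3L,
                     n_bound_genes = 30L, n_bound_and_de = 4L)
  expect_false(identical(simulate_expression(cfg2)$expr$values,
                         a$expr$values))
})

test_that("null design carries no effect and truth sets are consistent", {
  cfg <- sim_config(seed = 5L, n_genes = 100L, n_samples_reference = 20L,
                    n_samples_group = 4L, effect_l2fc_mean = 0,
                    n_up_spiked = 0L, n_down_spiked = 0L, n_rewired = 0L,
                    n_bound_genes = 10L, n_bound_and_de = 0L)
  sim <- simulate_expression(cfg)
  expect_true(all(abs(sim$truth$true_l2fc) == 0))
  expect_length(sim$truth$spiked_up, 0)
  # truth-set containment on a spiked design
  cfg2 <- sim_config(seed = 6L, n_genes = 200L, n_samples_reference = 20L,
                     n_samples_group = 4L, n_up_spiked = 20L,
                     n_down_spiked = 10L, n_rewired = 7L,
                     n_bound_genes = 40L, n_bound_and_de = 6L)
  tr <- simulate_expression(cfg2)$truth
  genes <- rownames(simulate_expression(cfg2)$expr$values)
  expect_true(all(tr$rewired_genes %in% tr$spiked_up))
  expect_length(intersect(tr$spiked_up, tr$spiked_down), 0)
  expect_true(all(tr$bound_genes %in% genes))
  expect_length(tr$bound_genes, 40)
  expect_setequal(intersect(tr$bound_genes,
                            c(tr$spiked_up, tr$spiked_down)),
                  tr$bound_and_de)
})

test_that("spiked-gene group means recover the programmed effect", {
  cfg <- sim_config(seed = 17L, n_genes = 2000L, n_up_spiked = 104L,
                    n_down_spiked = 62L, effect_l2fc_mean = 1.5,
                    effect_l2fc_sd = 0, noise_sd = 0.5)
  sim <- simulate_expression(cfg)
  is_case <- sim$expr$groups == "case"
  m <- sim$expr$values
  l2fc <- rowMeans(m[, is_case]) - rowMeans(m[, !is_case])
  up_mean <- mean(l2fc[sim$truth$spiked_up])
  # SE of the mean over 104 genes at noise 0.5, 7 vs 741 samples
  se <- 0.5 * sqrt(1 / 7 + 1 / 741) / sqrt(104)
  expect_lt(abs(up_mean - 1.5), 3 * se)
  down_mean <- mean(l2fc[sim$truth$spiked_down])
  expect_lt(abs(down_mean + 1.5), 3 * se)
})

test_that("selective drugs are more sensitive in the case group by design", {
  cfg <- sim_config(seed = 23L, n_drugs = 20L, n_selective_drugs = 3L,
                    n_samples_group = 3L, n_samples_reference = 4L,
                    response_noise_sd = 0)
  dr <- simulate_dose_response(cfg)
  tru <- dr$truth$true_dss
  for (d in dr$truth$selective_drugs) {
    expect_gt(tru$dss[tru$drug_id == d & tru$group == "case"],
              tru$dss[tru$drug_id == d & tru$group == "reference"])
  }
  nonsel <- setdiff(unique(tru$drug_id), dr$truth$selective_drugs)
  same <- tru$dss[tru$group == "case"][match(nonsel, tru$drug_id[tru$group == "case"])] -
    tru$dss[tru$group == "reference"][match(nonsel, tru$drug_id[tru$group == "reference"])]
  expect_lt(max(abs(same)), 1e-12)
  # the dose ladder is 5 log-spaced points over a 10,000-fold range
  doses <- sort(unique(dr$plate$dose_nM))
  expect_length(doses, 5)
  expect_equal(max(doses) / min(doses), 1e4)
  expect_equal(diff(log10(doses)), rep(1, 4), tolerance = 1e-12)
})

test_that("peak tracks respect the bound/lost truth by construction", {
  cfg <- sim_config(seed = 41L, n_genes = 150L, n_up_spiked = 12L,
                    n_down_spiked = 6L, n_rewired = 5L,
                    n_bound_genes = 30L, n_bound_and_de = 6L,
                    n_samples_reference = 10L, n_samples_group = 4L)
  prom <- build_promoters(simulate_gene_annotation(cfg))
  pk <- simulate_peaks(cfg, prom)
  tr <- pk$truth
  # every bound gene has a vehicle antibody peak overlapping its promoter
  # (verified against the brute-force interval oracle)
  ab <- gr_to_df0(pk$tracks$antibody_vehicle)
  ab$chrom <- ab$chrom  # peaks carry no gene names in the oracle frame
  bound_oracle <- oracle_bound_genes(ab, gr_to_df0(prom))
  expect_setequal(bound_oracle, tr$bound_genes)
  # treated antibody track lost exactly the rewired&bound genes
  trt <- oracle_bound_genes(gr_to_df0(pk$tracks$antibody_treated),
                            gr_to_df0(prom))
  expect_setequal(setdiff(bound_oracle, trt), tr$lost_genes)
  expect_setequal(tr$lost_genes, intersect(tr$rewired_genes, tr$bound_genes))
  # IgG tracks never touch a promoter
  for (nm in c("igg_vehicle", "igg_treated")) {
    expect_length(oracle_bound_genes(gr_to_df0(pk$tracks[[nm]]),
                                     gr_to_df0(prom)), 0)
  }
  # no bound genes -> antibody track is all background
  cfg0 <- sim_config(seed = 42L, n_genes = 50L, n_up_spiked = 0L,
                     n_down_spiked = 0L, n_rewired = 0L,
                     n_bound_genes = 0L, n_bound_and_de = 0L,
                     n_samples_reference = 10L, n_samples_group = 4L)
  prom0 <- build_promoters(simulate_gene_annotation(cfg0))
  pk0 <- simulate_peaks(cfg0, prom0)
  expect_true(all(pk0$tracks$antibody_vehicle$name == "background"))
  expect_error(
    simulate_peaks(cfg, prom[1:10]),
    "n_bound_genes")
})

test_that("qPCR tables encode knockdown and enrichment exactly", {
  cfg <- sim_config(seed = 51L, replicates_per_condition = 3L)
  q <- simulate_qpcr(cfg, knockdown_efficiency = 0.5, ct_noise_sd = 0)
  ct <- q$expression_ct
  tgt <- tapply(ct$ct[ct$target_id == "target"],
                ct$condition[ct$target_id == "target"], mean)
  # 50% knockdown = exactly one extra cycle on the target
  expect_equal(unname(tgt["knockdown"] - tgt["scramble"]), 1)
  # encoded fold enrichment 8 = 3 cycles below the control IgG
  e <- q$enrichment_ct
  m <- tapply(e$ct, list(e$track, e$locus), mean)
  expect_equal(unname(m["igg_case", "locus_A"] -
                        m["antibody_case", "locus_A"]), 3)
})
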