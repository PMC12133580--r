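# raresig

Rare cytogenetic subgroups — a handful of fusion-positive patients inside
a cohort of hundreds — break the usual differential-expression toolbox:
per-group variance estimates are unstable and fold changes are dominated
by single samples. `raresig` implements an analysis pipeline built for
this regime, for computational biologists working on subtype
characterisation and ex vivo drug screening in leukemia (or any rare
subgroup vs large cohort design):

* **Kernel-MCC differential expression.** Per gene, a leave-one-out
  classifier built from class-conditional Gaussian kernel density
  estimates predicts each sample's group; the Matthews correlation
  coefficient of those predictions,

  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,

  is the significance statistic. A gene is called when Kernel MCC > 0.105
  and |l2fc| > 0.58 (i.e. beyond a 1.5-fold change). A classical Welch-test
  route (p < 0.05, fold change ≥ 1.5) runs alongside.
* **Drug-sensitivity scoring.** Four-parameter logistic fits
  (`y = b + (t−b)/(1+(EC50/x)^h)`, deterministic multi-start least
  squares in C++), DSS (closed-form normalised area above a 10% activity
  threshold over the tested log-dose window), reference-centered
  selective DSS, and group-selectivity ranking of a compound panel.
* **Promoter binding & rewiring.** Strand-aware promoter windows (2 kb
  up / 500 bp down of the TSS), peak-to-promoter assignment with
  half-open BED semantics, overlap of bound genes with the DE signature,
  ΔCt / ΔΔCt qPCR quantification and fold enrichment, and classification
  of *rewired* genes — up at diagnosis, selectively lost on treatment in
  case cells but not reference cells nor under a control drug.
* **Synthetic-data generator** with known ground truth mirroring the
  whole design (7 cases vs 741 references, 104/62 spiked genes, a
  527-compound panel with 4 selective drugs, 801 bound promoters, 36
  rewired genes), so every stage is testable end to end without access
  to patient data.

## Worked example

```r
library(raresig)

cfg <- sim_config(seed = 42, n_genes = 400L, n_samples_reference = 120L,
                  n_samples_group = 6L, n_up_spiked = 12L, n_down_spiked = 6L,
                  n_rewired = 4L, n_drugs = 30L, n_selective_drugs = 2L,
                  n_bound_genes = 40L, n_bound_and_de = 5L)
sim <- simulate_expression(cfg)
sim$expr
#> <expr_matrix> 400 genes x 126 samples (6 case / 120 reference)

de <- differential_expression(sim$expr)
head(as.data.frame(de)[, c("gene_id", "l2fc", "kernel_mcc", "p_value",
                           "passes_kmcc")], 5)
#>   gene_id      l2fc kernel_mcc      p_value passes_kmcc
#> 1   g0356  2.152278  1.0000000 4.817114e-07        TRUE
#> 2   g0348  2.004943  0.7615773 3.769537e-05        TRUE
#> 3   g0352 -1.997947  0.9219544 1.077825e-04        TRUE
#> 4   g0225  1.810231  1.0000000 1.183318e-07        TRUE
#> 5   g0379  1.808903  0.5622441 1.094986e-04        TRUE
unlist(summary(de)[c("n_pass", "n_up", "n_down")])
#> n_pass   n_up n_down
#>     20     13      7
```

The table is sorted by |l2fc|; `kernel_mcc = 1` means the leave-one-out
classifier separated the 6 cases from the 120 references perfectly on
that gene alone. Of 400 genes, 20 pass both thresholds (18 were truly
spiked). The screen side:

```r
dr <- simulate_dose_response(cfg)
sc <- sdss(score_plate(dr$plate),
           dr$annotation$sample_id[dr$annotation$group == "reference"])
rk <- rank_selective(sc, dr$annotation$sample_id[dr$annotation$group == "case"])
head(rk, 4)
#>    drug_id mean_case_sdss mean_case_dss n_case_covered low_coverage rank
#> 1 drug_010      42.753931      94.23354              6        FALSE    1
#> 2 drug_003      41.408175      61.87562              6        FALSE    2
#> 3 drug_013       2.953260      11.47741              6        FALSE    3
#> 4 drug_014       2.742122      41.70179              6        FALSE    4
dr$truth$selective_drugs
#> [1] "drug_003" "drug_010"
```

The two programmed case-selective compounds occupy ranks 1–2 with mean
case sDSS ≈ 40 points above the reference cohort, while the best
non-selective drug sits at ≈ 3. `run_pipeline(run_config(...))`
orchestrates all stages (simulated or user-supplied data), writes every
intermediate table plus `report.json`, and is bit-identical under a fixed
seed; `validate_inputs()` checks user files before any analysis runs.

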