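test_that("kde_density matches the closed-form kernel sum", {
  # two symmetric points, query at the midpoint
  v <- c(-1, 1)
  h <- raresig:::kde_bandwidth(v, "silverman")
  expected <- (1 / (2 * h * sqrt(2 * pi))) * 2 * exp(-1 / (2 * h^2))
  expect_equal(kde_density(v, 0), expected, tolerance = 1e-12)
  # translation equivariance
  v2 <- withr::with_seed(11, rnorm(9))
  expect_equal(kde_density(v2, 0.3), kde_density(v2 + 5, 0.3 + 5),
               tolerance = 1e-12)
  # constant data: floor bandwidth concentrates all mass at the point
  expect_gt(kde_density(rep(0, 4), 0), 1e3 * kde_density(rep(0, 4), 10))
  expect_error(kde_density(1, 0), "insufficient")
})

test_that("kde_density integrates to 1", {
  v <- withr::with_seed(7, rnorm(15, 2, 1.5))
  int <- integrate(function(q) kde_density(v, q), -Inf, Inf)$value
  expect_equal(int, 1, tolerance = 1e-6)
})

test_that("loo_kde_classify handles separation, ties and degenerate data", {
  v <- c(rep(10, 4), rep(0, 7))
  lab <- c(rep("case", 4), rep("reference", 7))
  expect_equal(loo_kde_classify(v, lab), c(rep(TRUE, 4), rep(FALSE, 7)))
  # all values identical: tie everywhere -> reference
  expect_equal(loo_kde_classify(rep(1, 10), c(rep(TRUE, 4), rep(FALSE, 6))),
               rep(FALSE, 10))
  expect_error(loo_kde_classify(1:6, c(TRUE, TRUE, rep(FALSE, 4))),
               "insufficient")
})

test_that("loo_kde_classify equals the brute-force oracle", {
  cases <- expand.grid(n = c(6, 8, 10, 12), n_case = 3:4,
                       shift = c(0, 1, 3), seed = 1:5)
  cases <- cases[cases$n - cases$n_case >= 3, ]
  for (k in seq_len(nrow(cases))) {
    with(cases[k, ], {
      d <- make_labelled(n, n_case, shift, seed + 100 * k)
      got <- loo_kde_classify(d$values, d$is_case)
      expect_identical(got, oracle_loo_kde(d$values, d$is_case))
    })
  }
  # interleaved duplicated values exercise exact ties
  v <- c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2)
  lab <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_identical(loo_kde_classify(v, lab), oracle_loo_kde(v, lab))
})

test_that("mcc reproduces the confusion-matrix formula", {
  a <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(mcc(a, a), 1)
  expect_equal(mcc(!a, a), -1)
  # TP=2 TN=5 FP=2 FN=1 -> 8/sqrt(504)
  pred <- c(TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 5))
  act <- c(TRUE, TRUE, TRUE, FALSE, FALSE, rep(FALSE, 5))
  expect_equal(mcc(pred, act), 8 / sqrt(504), tolerance = 1e-12)
  # constant prediction -> 0 by convention
  expect_equal(mcc(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_error(mcc(c(TRUE, FALSE), TRUE), "dimension")
})

test_that("kernel_mcc is 1 under perfect separation and ~0 under the null", {
  v <- withr::with_seed(12, c(rnorm(5, 100), rnorm(20, 0)))
  lab <- c(rep(TRUE, 5), rep(FALSE, 20))
  expect_equal(kernel_mcc(v, lab), 1)
  # permutation null: mean over 200 shuffles close to 0
  vals <- withr::with_seed(42, rnorm(40))
  perms <- withr::with_seed(43, replicate(200, {
    kernel_mcc(vals, sample(c(rep(TRUE, 8), rep(FALSE, 32))))
  }))
  expect_lt(abs(mean(perms)), 0.05)
  expect_true(all(perms >= -1 & perms <= 1))
})

test_that("log2_fold_change is the difference of group means", {
  lab <- c(rep(TRUE, 3), rep(FALSE, 3))
  expect_equal(log2_fold_change(c(8, 8, 8, 2, 2, 2), lab), 6)
  expect_equal(log2_fold_change(c(1, 2, 3, 1, 2, 3), lab), 0)
  # antisymmetry under label swap
  v <- withr::with_seed(5, rnorm(6))
  expect_equal(log2_fold_change(v, lab), -log2_fold_change(v, !lab))
  # a 1.5-linear-fold shift exceeds the 0.58 cutoff
  expect_gt(log2(1.5), 0.58)
  expect_equal(log2_fold_change(c(rep(5 + log2(1.5), 3), rep(5, 3)), lab),
               log2(1.5))
})

test_that("classic_test gives calibrated Welch p-values", {
  lab <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(classic_test(rep(c(1, 1), each = 10), lab), 1)
  v <- withr::with_seed(2, c(rnorm(10, 5), rnorm(10, 0)))
  expect_lt(classic_test(v, lab), 1e-6)
  # matches stats::t.test
  v2 <- withr::with_seed(3, rnorm(20))
  expect_equal(classic_test(v2, lab), t.test(v2[1:10], v2[11:20])$p.value)
})

test_that("vectorised Welch route equals per-gene t.test", {
  m <- withr::with_seed(8, matrix(rnorm(50 * 12), 50, 12))
  is_case <- c(rep(TRUE, 5), rep(FALSE, 7))
  p_fast <- raresig:::welch_rows(m, is_case)
  p_ref <- apply(m, 1, function(r)
    t.test(r[is_case], r[!is_case])$p.value)
  expect_equal(unname(p_fast), unname(p_ref), tolerance = 1e-12)
})

test_that("differential_expression applies both routes and sorts output", {
  cfg <- sim_config(seed = 21, n_genes = 300L, n_samples_reference = 60L,
                    n_samples_group = 6L, n_up_spiked = 10L,
                    n_down_spiked = 5L, n_rewired = 0L,
                    n_bound_genes = 20L, n_bound_and_de = 0L)
  sim <- simulate_expression(cfg)
  de <- differential_expression(sim$expr)
  expect_s3_class(de, "de_table")
  expect_equal(nrow(de), 300)
  # pass flags equal the brute-force filter at the thresholds
  th <- de_thresholds()
  expect_equal(de$passes_kmcc,
               de$kernel_mcc > th$mcc_threshold &
                 abs(de$l2fc) > th$l2fc_threshold)
  expect_equal(de$passes_classic,
               de$p_value < th$alpha &
                 abs(de$l2fc) >= log2(1.5) * (1 - 1e-12))
  expect_equal(de$direction, ifelse(de$l2fc >= 0, "up", "down"))
  # sorted by |l2fc| descending, gene id as tie-break
  expect_true(all(diff(abs(de$l2fc)) <= 1e-15))
  s <- summary(de)
  expect_equal(s$n_pass, sum(de$passes_kmcc))
  expect_equal(s$n_up + s$n_down, s$n_pass)
  # matrix fast path agrees with the single-gene composition
  is_case <- sim$expr$groups == "case"
  for (g in c(1, 50, 300)) {
    gene <- de$gene_id[g]
    expect_equal(de$kernel_mcc[g],
                 kernel_mcc(sim$expr$values[gene, ], is_case))
  }
})

test_that("differential_expression validates cohorts and routes", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  em_one_group <- expression_matrix(m, rep("reference", 4))
  expect_error(differential_expression(em_one_group), "cohort")
  em_small <- expression_matrix(m, c("case", "case", "reference",
                                     "reference"))
  expect_error(differential_expression(em_small, route = "kmcc"),
               "at least 3")
  de <- differential_expression(em_small, route = "classic")
  expect_true(all(is.na(de$kernel_mcc)))
  expect_false(any(is.na(de$p_value)))
})

test_that("expression_matrix rejects malformed input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  storage.mode(m) <- "double"
  expect_error(expression_matrix(m, c("case", "weird")), "case")
  m[1, 1] <- NA
  expect_error(expression_matrix(m, c("case", "reference")), "missing")
})
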