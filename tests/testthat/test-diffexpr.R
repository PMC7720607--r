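# Small count tables with unit factor tables let tests control the pooled
# totals exactly (equal effective library sizes, pi = 1/2 for 1 vs 1).

make_counts <- function(yA, yB) {
  tibble::tibble(gene = paste0("g", seq_along(yA)), A = yA, B = yB)
}

test_that("symmetric null gives p = 1 and zero fold change", {
  counts <- make_counts(c(5L, 0L), c(5L, 0L))
  f <- unit_factors(c("A", "B"))
  for (mode in c("binomial", "nb")) {
    de <- exact_test(counts, "A", "B", mode = mode, dispersion = 0.1,
                     factors = f)
    expect_equal(de$pvalue, c(1, 1))
    expect_equal(de$log2fc, c(0, 0))
  }
})

test_that("extreme binomial split has the enumerated exact p-value", {
  de <- exact_test(make_counts(0L, 10L), "A", "B", mode = "binomial",
                   factors = unit_factors(c("A", "B")))
  expect_equal(de$pvalue, 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(de$pvalue, 0.001953125, tolerance = 1e-12)
  expect_lt(de$log2fc, 0)
})

test_that("nb mode with zero dispersion equals binomial mode", {
  set.seed(31)
  n <- 50
  yA <- as.integer(rpois(n, 60) + rbinom(n, 1, 0.3) * rpois(n, 200))
  yB <- as.integer(rpois(n, 60))
  counts <- make_counts(yA, yB)
  f <- unit_factors(c("A", "B"))
  p_bin <- exact_test(counts, "A", "B", mode = "binomial", factors = f)$pvalue
  p_nb <- exact_test(counts, "A", "B", mode = "nb", dispersion = 0,
                     factors = f)$pvalue
  expect_equal(p_nb, p_bin, tolerance = 1e-9)
})

test_that("group swap negates log2fc and preserves p exactly", {
  set.seed(32)
  sim <- simulate_counts(sim_config(n_genes = 300, seed = 33))
  a <- sim$metadata$sample_id[sim$metadata$condition == "AO_untreated"]
  b <- sim$metadata$sample_id[sim$metadata$condition == "NM_untreated"]
  f <- tmm_factors(sim$counts)
  for (mode in c("binomial", "nb")) {
    ab <- exact_test(sim$counts, a, b, mode = mode, dispersion = 0.1,
                     factors = f)
    ba <- exact_test(sim$counts, b, a, mode = mode, dispersion = 0.1,
                     factors = f)
    expect_identical(ab$pvalue, ba$pvalue)
    expect_identical(ab$log2fc, -ba$log2fc)
  }
})

test_that("nb mode agrees with the reference exact test implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulate_counts(sim_config(n_genes = 1000, seed = 35))
  a <- sim$metadata$sample_id[sim$metadata$condition == "AO_untreated"]
  b <- sim$metadata$sample_id[sim$metadata$condition == "NM_untreated"]
  mine <- exact_test(sim$counts, a, b, mode = "nb", dispersion = 0.1)
  m <- as.matrix(sim$counts[-1])[, c(a, b)]
  rownames(m) <- sim$counts$gene
  dge <- edgeR::calcNormFactors(edgeR::DGEList(m, group = rep(c("A", "B"), each = 2)))
  et <- edgeR::exactTest(dge, pair = c("B", "A"), dispersion = 0.1)
  # different pooling details, so agreement is statistical, not bitwise
  expect_gt(cor(log10(mine$pvalue + 1e-300),
                log10(et$table$PValue + 1e-300)), 0.999)
  expect_gt(cor(mine$log2fc, et$table$logFC), 0.999)
})

test_that("windowed enumeration matches full enumeration for large totals", {
  counts <- make_counts(c(14000L, 11000L), c(10000L, 12500L))
  f <- unit_factors(c("A", "B"))
  full <- exact_test(counts, "A", "B", mode = "nb", dispersion = 0.05,
                     factors = f, enum_limit = 1e7)$pvalue
  windowed <- exact_test(counts, "A", "B", mode = "nb", dispersion = 0.05,
                         factors = f, enum_limit = 1000)$pvalue
  expect_equal(windowed, full, tolerance = 1e-9)
})

test_that("type-I error is nominal on Poisson null data", {
  cfg <- sim_config(n_genes = 10000, n_reps = 2, dispersion = 0,
                    lib_size_cv = 0, class_fractions = c(background = 1),
                    seed = 11)
  sim <- simulate_counts(cfg)
  a <- sim$metadata$sample_id[sim$metadata$condition == "AO_untreated"]
  b <- sim$metadata$sample_id[sim$metadata$condition == "NM_untreated"]
  de <- exact_test(sim$counts, a, b, mode = "binomial")
  frac <- mean(de$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(de))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("dispersion estimation recovers the truth and floors at zero", {
  pois <- simulate_counts(sim_config(n_genes = 5000, dispersion = 0,
                                     baseline_logmean_mu = log(100),
                                     baseline_logmean_sigma = 0,
                                     baseline_min = 0, lib_size_cv = 0,
                                     class_fractions = c(background = 1),
                                     seed = 41))
  expect_lt(estimate_common_dispersion(pois$counts, pois$metadata), 0.02)

  nb <- simulate_counts(sim_config(n_genes = 5000, dispersion = 0.2,
                                   baseline_logmean_mu = log(100),
                                   baseline_logmean_sigma = 0,
                                   baseline_min = 0, lib_size_cv = 0,
                                   class_fractions = c(background = 1),
                                   seed = 42))
  phi <- estimate_common_dispersion(nb$counts, nb$metadata)
  expect_gt(phi, 0.15); expect_lt(phi, 0.25)

  # constant counts across replicates: s^2 - mu < 0 everywhere -> floor 0
  const <- tibble::tibble(gene = paste0("g", 1:3),
                          a1 = c(10L, 20L, 30L), a2 = c(10L, 20L, 30L))
  expect_equal(estimate_common_dispersion(const, list(A = c("a1", "a2"))), 0)

  expect_warning(
    phi0 <- estimate_common_dispersion(const, list(A = "a1", B = "a2")),
    "replicates")
  expect_equal(phi0, 0)
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.5, 0.5, 0.5)
  expect_equal(bh_adjust(p), p)

  set.seed(51)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- round(runif(n), 3)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }

  # monotone in p-rank
  set.seed(52)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance rule is strict on both thresholds", {
  de <- de_table(paste0("g", 1:3), c(1.2, 1.0, -3), c(0.005, 0.001, 0.02))
  out <- classify_de(de)
  expect_equal(out$label, c("up", "ns", "ns"))
  g <- glance(out)
  expect_equal(c(g$n_up, g$n_down, g$n_ns), c(1L, 0L, 2L))
  expect_error(classify_de(de, lfc_threshold = 0), "positive")
})

test_that("fold-change profiles recover planted signal and symmetry", {
  cfg <- sim_config(n_genes = 2000, lib_size_cv = 0, seed = 61)
  sim <- simulate_counts(cfg)
  prof <- fold_change_to_reference(sim$counts, sim$metadata)
  expect_equal(names(prof), c("gene", ll_profile_conditions()))

  ao_cols <- c("AO_12hpt", "AO_24hpt", "AO_untreated")
  nm_cols <- c("NM_12hpt", "NM_24hpt", "NM_untreated")
  ao_idx <- sim$truth$class == "ao_specific"
  bg_idx <- sim$truth$class == "background"
  expect_equal(mean(as.matrix(prof[ao_idx, ao_cols])), 2, tolerance = 0.15)
  expect_equal(mean(as.matrix(prof[ao_idx, nm_cols])), 0, tolerance = 0.15)
  expect_equal(mean(as.matrix(prof[bg_idx, -1])), 0, tolerance = 0.1)

  # relabeling AO <-> NM swaps the two profile halves exactly
  meta_sw <- sim$metadata
  meta_sw$condition <- ifelse(meta_sw$condition == "EP", "EP",
                              ifelse(grepl("^AO", meta_sw$condition),
                                     sub("AO", "NM", meta_sw$condition),
                                     sub("NM", "AO", meta_sw$condition)))
  prof_sw <- fold_change_to_reference(sim$counts, meta_sw)
  expect_identical(prof_sw[ao_cols], setNames(prof[nm_cols], ao_cols))
  expect_identical(prof_sw[nm_cols], setNames(prof[ao_cols], nm_cols))

  meta_bad <- sim$metadata[sim$metadata$condition != "NM_24hpt", ]
  expect_error(
    fold_change_to_reference(sim$counts[c("gene", meta_bad$sample_id)],
                             meta_bad),
    "NM_24hpt")
})
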