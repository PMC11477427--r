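# Coefficient sums and the three risk-assignment algorithms.

mini_screen <- function(gene_id, beta, mode = "deep_amp") {
  tibble::tibble(gene_id = gene_id, mode = mode,
                 n_altered = 4L, statistic = 1, score = sign(beta),
                 p_value = 0.01, fdr = 0.01, beta = beta, se = 0.1,
                 direction = ifelse(beta > 0, "high_risk", "low_risk"),
                 monotone = FALSE)
}

mini_am <- function(ind, mode = "deep_amp") {
  structure(list(mode = mode, gene_ids = rownames(ind),
                 sample_ids = colnames(ind), indicator = ind),
            class = "alteration_matrix")
}

test_that("coefficient sums follow the carried genes", {
  ind <- rbind(gA = c(1L, 1L, 0L), gB = c(1L, 0L, 0L), gC = c(1L, 0L, 1L))
  colnames(ind) <- c("s1", "s2", "s3")
  screen <- mini_screen(c("gA", "gB", "gC"), c(0.5, 0.7, -0.3))
  sc <- score_samples(screen, mini_am(ind))
  # s1 carries both high-risk genes and the low-risk gene
  expect_equal(sc$sum_beta_high, c(1.2, 0.5, 0))
  expect_equal(sc$sum_beta_low, c(0.3, 0, 0.3))   # |beta| for low-risk
  # carrying every screened gene gives each direction's total
  expect_equal(sc$sum_beta_high[1], 0.5 + 0.7)
})

test_that("single-data labels implement the greater-sum rule with NA ties", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                       sum_beta_high = c(1.2, 0.4, 0, 0.1),
                       sum_beta_low = c(0.3, 0.4, 0, 0.6))
  lab <- assign_single(sc)
  expect_identical(lab$label, c("H", "NA", "NA", "L"))
  # near-ties within relative tolerance collapse to NA
  sc2 <- tibble::tibble(sample_id = "x", sum_beta_high = 1,
                        sum_beta_low = 1 + 1e-12)
  expect_identical(assign_single(sc2)$label, "NA")
})

test_that("MaxSum compares the pooled directional totals", {
  amp <- tibble::tibble(sample_id = c("a", "b"),
                        sum_beta_high = c(1.0, 0.5),
                        sum_beta_low = c(0, 0.5))
  del <- tibble::tibble(sample_id = c("a", "b"),
                        sum_beta_high = c(0, 0),
                        sum_beta_low = c(1.5, 0))
  lab <- assign_maxsum(amp, del)
  expect_identical(lab$label, c("L", "NA"))   # (1.0 vs 1.5) -> L; tie -> NA
})

test_that("Combinations crosses amp and del labels into at most 9 groups", {
  amp <- tibble::tibble(sample_id = c("a", "b", "c"),
                        label = c("H", "NA", "L"))
  del <- tibble::tibble(sample_id = c("a", "b", "c"),
                        label = c("L", "NA", "NA"))
  comb <- assign_combinations(amp, del)
  expect_identical(comb$label, c("H/L", "NA/NA", "L/NA"))
  expect_lte(dplyr::n_distinct(comb$label), 9)
})

test_that("a cohort with only deep deletions planted localizes its signal", {
  cfg <- simulation_config(
    planted = tibble::tibble(mode = "deep_del", beta = 1.2,
                             carrier_frac = 0.1, .rows = 4),
    n_samples = 250, n_genes = 120, seed = 404)
  ms <- build_all_models(as_cohort(simulate_cohort(cfg)),
                         engine = "asymptotic", seed = 404)
  lab_amp <- dplyr::filter(ms$assignments, model_id == "single_deep_amp")$label
  lab_del <- dplyr::filter(ms$assignments, model_id == "single_deep_del")$label
  # deep-del model assigns real risk labels; deep-amp picks up at most noise
  expect_gt(mean(lab_del != "NA"), mean(lab_amp != "NA"))
  expect_gt(sum(lab_del == "H"), 0)
})

test_that("build_all_models emits exactly 8 models with bounded label counts", {
  sim <- simulate_cohort(simulation_config(n_samples = 200, n_genes = 100,
                                           seed = 2))
  ms <- build_all_models(as_cohort(sim), engine = "asymptotic", seed = 2)
  expect_equal(nrow(ms$reports), 8)
  expect_setequal(as.character(unique(ms$assignments$model_id)),
                  c("single_soft_del", "single_soft_amp", "single_deep_del",
                    "single_deep_amp", "maxsum_soft", "maxsum_deep",
                    "combinations_soft", "combinations_deep"))
  counts <- ms$assignments |>
    dplyr::group_by(model_id) |>
    dplyr::summarise(k = dplyr::n_distinct(label),
                     n = dplyr::n(), .groups = "drop")
  expect_true(all(counts$n == 200))   # exactly one label per sample per model
  single_maxsum <- !grepl("combinations", counts$model_id)
  expect_true(all(counts$k[single_maxsum] <= 3))
  expect_true(all(counts$k[!single_maxsum] <= 9))
  # group sizes in every report sum to the cohort size
  for (g in ms$reports$groups) expect_equal(sum(g$n), 200)
})

test_that("assignments are deterministic and order-equivariant", {
  sim <- simulate_cohort(simulation_config(n_samples = 150, n_genes = 80,
                                           seed = 31))
  coh <- as_cohort(sim)
  a1 <- build_all_models(coh, engine = "permutation", n_perm = 200,
                         seed = 9)$assignments
  a2 <- build_all_models(coh, engine = "permutation", n_perm = 200,
                         seed = 9)$assignments
  expect_identical(a1, a2)
  # permuting sample order permutes assignments identically
  perm <- withr::with_seed(8, sample.int(coh$n))
  coh2 <- structure(
    list(cna = cna_matrix(coh$cna$values[, perm],
                          gene_ids = coh$cna$gene_ids,
                          sample_ids = coh$cna$sample_ids[perm]),
         clinical = coh$clinical[perm, ], n = coh$n),
    class = "cna_cohort")
  a3 <- build_all_models(coh2, engine = "permutation", n_perm = 200,
                         seed = 9)$assignments
  merged <- dplyr::inner_join(a1, a3, by = c("sample_id", "model_id"))
  expect_identical(merged$label.x, merged$label.y)
})

test_that("MaxSum is consistent with one-sided single assignments", {
  # if the deletion side contributes nothing, MaxSum reduces to the amp rule
  amp <- tibble::tibble(sample_id = c("a", "b", "c"),
                        sum_beta_high = c(2, 0, 1),
                        sum_beta_low = c(0.5, 0, 1))
  del <- tibble::tibble(sample_id = c("a", "b", "c"),
                        sum_beta_high = 0, sum_beta_low = 0)
  expect_identical(assign_maxsum(amp, del)$label, assign_single(amp)$label)
})
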