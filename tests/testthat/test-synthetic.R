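test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(n_mirna = 0), "count >= 1")
  expect_error(simulation_config(catalog_density = 0), "catalog_density")
  expect_error(simulation_config(planted_shared_mirnas = 2), ">= 3")
  expect_error(simulation_config(decoupling_fraction = 1.2),
               "decoupling_fraction")
  expect_error(simulation_config(n_planted_pairs = 100, n_lncrna = 10),
               "exceeds")
})

test_that("catalog generation is deterministic and honors density extremes", {
  cfg <- simulation_config(n_mirna = 20, n_mrna = 15, n_lncrna = 8,
                           n_planted_pairs = 3, planted_shared_mirnas = 4,
                           catalog_density = 0.2, seed = 7)
  c1 <- simulate_catalog(cfg)
  c2 <- simulate_catalog(cfg)
  expect_identical(c1, c2)

  # density 1: every miRNA targets everything; every pair shares all miRNAs
  cfg_full <- simulation_config(n_mirna = 10, n_mrna = 4, n_lncrna = 3,
                                n_planted_pairs = 2, catalog_density = 1,
                                seed = 1)
  cat_full <- simulate_catalog(cfg_full)
  expect_equal(nrow(cat_full$mrna), 10 * 4)
  expect_length(shared_mirnas(cat_full, "mRNA-0003", "lnc-0002"), 10)

  # planted sharing cannot exceed the miRNA universe
  cfg_bad <- simulation_config(n_mirna = 3, planted_shared_mirnas = 5,
                               n_mrna = 10, n_lncrna = 10,
                               n_planted_pairs = 2)
  expect_error(simulate_catalog(cfg_bad), "universe too small")
})

test_that("planted pairs are guaranteed their shared miRNAs", {
  cfg <- simulation_config(n_mirna = 50, n_mrna = 30, n_lncrna = 12,
                           n_planted_pairs = 10, planted_shared_mirnas = 6,
                           catalog_density = 0.01, seed = 3)
  cat_ <- simulate_catalog(cfg)
  for (i in 1:10)
    expect_gte(length(shared_mirnas(cat_, sprintf("mRNA-%04d", i),
                                    sprintf("lnc-%04d", i))), 6)
})

test_that("planted-pair correlation is calibrated to coexpression_strength", {
  cfg <- simulation_config(n_samples_per_condition = 200,
                           coexpression_strength = 0.9, seed = 11)
  cat_ <- simulate_catalog(cfg)
  sim <- simulate_expression(cat_, cfg)
  smp <- names(sim$labels)[sim$labels == "normal"]
  rs <- vapply(seq_len(nrow(sim$truth$planted_pairs)), function(i)
    cor(sim$expr[sim$truth$planted_pairs$mrna[i], smp],
        sim$expr[sim$truth$planted_pairs$lncrna[i], smp]), numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.1)
})

test_that("zero noise with a pure shared factor gives r = 1 exactly", {
  cfg <- simulation_config(n_mirna = 10, n_mrna = 5, n_lncrna = 5,
                           n_planted_pairs = 3, planted_shared_mirnas = 3,
                           noise_sd = 0, repression_gain = 0,
                           n_samples_per_condition = 10,
                           decoupling_fraction = 0, seed = 2)
  sim <- simulate_expression(simulate_catalog(cfg), cfg)
  expect_equal(cor(sim$expr["mRNA-0001", ], sim$expr["lnc-0001", ]), 1)
})

test_that("decoupling_fraction = 0 leaves disease correlations intact", {
  cfg <- simulation_config(decoupling_fraction = 0,
                           n_samples_per_condition = 150, seed = 5)
  sim <- simulate_expression(simulate_catalog(cfg), cfg)
  expect_equal(nrow(sim$truth$decoupled_pairs), 0)
  r_by_cond <- sapply(c("normal", "disease"), function(cond) {
    smp <- names(sim$labels)[sim$labels == cond]
    mean(vapply(seq_len(nrow(sim$truth$planted_pairs)), function(i)
      cor(sim$expr[sim$truth$planted_pairs$mrna[i], smp],
          sim$expr[sim$truth$planted_pairs$lncrna[i], smp]), numeric(1)))
  })
  expect_lt(abs(r_by_cond["normal"] - r_by_cond["disease"]), 0.1)
})

test_that("expression generation is deterministic and rejects tiny cohorts", {
  cfg <- simulation_config(n_mirna = 15, n_mrna = 10, n_lncrna = 6,
                           n_planted_pairs = 3, catalog_density = 0.1,
                           n_samples_per_condition = 5, seed = 9)
  cat_ <- simulate_catalog(cfg)
  expect_identical(simulate_expression(cat_, cfg),
                   simulate_expression(cat_, cfg))
  cfg2 <- cfg; cfg2$n_samples_per_condition <- 2L
  expect_error(simulate_expression(cat_, cfg2), "3 samples")
})

test_that("probe fixtures embed recoverable probes and honest decoys", {
  fix <- simulate_probe_data(n_transcripts = 4, probes_per_transcript = 12,
                             probe_length = 25, n_decoy_probes = 3,
                             transcript_length = 400, seed = 13)
  expect_length(fix$probes, 4 * 12 + 3)
  tx <- as.character(fix$transcripts)
  for (i in seq_len(nrow(fix$truth))) {
    p <- as.character(fix$probes[[fix$truth$probe[i]]])
    if (is.na(fix$truth$transcript[i])) {
      expect_false(any(vapply(tx, grepl, logical(1), pattern = p,
                              fixed = TRUE)))
    } else {
      expect_true(grepl(p, tx[fix$truth$transcript[i]], fixed = TRUE))
    }
  }
  expect_identical(fix, simulate_probe_data(4, 12, 25, 3, 400, seed = 13))
  expect_error(simulate_probe_data(2, 20, 25, 0, transcript_length = 100),
               "non-overlapping")
})

test_that("marker cohort plants signal only in the informative markers", {
  mc <- simulate_marker_cohort(n_markers = 9, n_informative = 5,
                               effect_size = 1.5, n_per_condition = 300,
                               seed = 4)
  d <- names(mc$labels)[mc$labels == "disease"]
  n <- names(mc$labels)[mc$labels == "normal"]
  shifts <- rowMeans(mc$expr[, d]) - rowMeans(mc$expr[, n])
  expect_true(all(shifts[mc$informative] > 1))
  expect_true(all(abs(shifts[setdiff(rownames(mc$expr), mc$informative)]) <
                    0.5))
})
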