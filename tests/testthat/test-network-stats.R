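test_that("degree distribution handles stars, matchings and degree sums", {
  star <- data.frame(mrna = "hub", lncrna = paste0("l", 1:6))
  dd <- degree_distribution(star)
  expect_equal(unname(dd$degree["hub"]), 6)
  expect_true(all(dd$degree[paste0("l", 1:6)] == 1))
  expect_equal(sum(dd$histogram$n_nodes), 7)
  expect_equal(sum(dd$degree), 2 * nrow(star))

  matching <- data.frame(mrna = paste0("g", 1:5), lncrna = paste0("l", 1:5))
  dm <- degree_distribution(matching)
  expect_equal(nrow(dm$histogram), 1)
  expect_true(is.na(dm$loglog_slope))
  expect_error(degree_distribution(matching[0, ]), "empty")
})

test_that("heavy-tailed synthetic networks fit a negative log-log slope", {
  # preferential-attachment-flavoured bipartite edges: many degree-1 nodes,
  # few hubs
  set.seed(7)
  hubs <- sample(paste0("g", 1:8), 120, replace = TRUE,
                 prob = 1 / seq_len(8))
  net <- unique(data.frame(mrna = hubs,
                           lncrna = paste0("l", sample(120))))
  dd <- degree_distribution(net)
  expect_lt(dd$loglog_slope, 0)
})

test_that("degree vs co-expression reports the planted positive association", {
  # hub mRNA with strongly coupled partners; leaves weakly coupled
  set.seed(11)
  n <- 80
  samples <- paste0("s", 1:n)
  labels <- stats::setNames(rep("normal", n), samples)
  z <- rnorm(n)
  # two hub mRNAs, each strongly coupled to six shared lncRNAs (degree 2),
  # plus weakly coupled leaf pairs (degree 1): degree tracks coupling
  rows <- list(hub1 = z + 0.3 * rnorm(n), hub2 = z + 0.3 * rnorm(n))
  net <- NULL
  for (i in 1:6) {
    rows[[paste0("hl", i)]] <- z + 0.3 * rnorm(n)
    net <- rbind(net,
                 data.frame(mrna = c("hub1", "hub2"),
                            lncrna = paste0("hl", i)))
  }
  for (i in 1:8) {  # leaf pairs, weak coupling
    w <- rnorm(n)
    rows[[paste0("lg", i)]] <- w + 3 * rnorm(n)
    rows[[paste0("ll", i)]] <- w + 3 * rnorm(n)
    net <- rbind(net, data.frame(mrna = paste0("lg", i),
                                 lncrna = paste0("ll", i)))
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- samples
  res <- degree_vs_coexpression(net, expr, labels, "normal")
  expect_gt(res$association$estimate, 0)
  expect_lt(res$association$p_value, 0.05)
  expect_equal(sum(res$per_node$degree), 2 * nrow(net))
})

test_that("constant co-expression degrades to a null association", {
  n <- 20
  samples <- paste0("s", 1:n)
  labels <- stats::setNames(rep("normal", n), samples)
  set.seed(3)
  x <- rnorm(n)
  expr <- rbind(g1 = x, l1 = x, g2 = -x, l2 = -x, l3 = -x)
  colnames(expr) <- samples
  net <- data.frame(mrna = c("g1", "g2", "g2"), lncrna = c("l1", "l2", "l3"))
  res <- degree_vs_coexpression(net, expr, labels, "normal")
  expect_equal(res$association$estimate, 0)  # all edge r identical (= 1)
  expect_equal(res$association$p_value, 1)
  one_pair <- data.frame(mrna = "g1", lncrna = "l1")
  expect_error(degree_vs_coexpression(one_pair[0, ], expr, labels, "normal"),
               "empty")
})

test_that("shared-miRNA count associates with planted monotone coupling", {
  set.seed(19)
  n <- 100
  samples <- paste0("s", 1:n)
  labels <- stats::setNames(rep("normal", n), samples)
  shared_counts <- 3:10
  rows <- list(); cand <- NULL
  for (i in seq_along(shared_counts)) {
    r_target <- shared_counts[i] / 12
    z <- rnorm(n)
    rows[[paste0("g", i)]] <- sqrt(r_target) * z +
      sqrt(1 - r_target) * rnorm(n)
    rows[[paste0("l", i)]] <- sqrt(r_target) * z +
      sqrt(1 - r_target) * rnorm(n)
    cand <- rbind(cand, data.frame(mrna = paste0("g", i),
                                   lncrna = paste0("l", i),
                                   shared_count = shared_counts[i]))
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- samples
  res <- shared_count_vs_coexpression(cand, expr, labels, "normal")
  expect_gt(res$association$estimate, 0)
  expect_error(shared_count_vs_coexpression(cand[0, ], expr, labels,
                                            "normal"), "empty")
  expect_error(shared_count_vs_coexpression(cand[, 1:2], expr, labels,
                                            "normal"), "shared_count")
})

test_that("Dicer stratification exposes repression-gain-driven coupling", {
  # high repression gain: planted pairs couple mostly through the shared,
  # Dicer-scaled repression term, so coupling should be stronger in
  # high-Dicer samples
  cfg <- simulation_config(n_samples_per_condition = 200,
                           coexpression_strength = 0.05,
                           planted_shared_mirnas = 6,
                           repression_gain = 4, decoupling_fraction = 0,
                           seed = 29)
  cat_ <- simulate_catalog(cfg)
  sim <- simulate_expression(cat_, cfg)
  net <- data.frame(mrna = sim$truth$planted_pairs$mrna,
                    lncrna = sim$truth$planted_pairs$lncrna)
  res <- dicer_stratified_coexpression(net, sim$expr, sim$labels, "normal",
                                       sim$truth$dicer_proxy_id)
  expect_gt(mean(res$high_r), mean(res$low_r))
  expect_lt(res$p_value, 0.05)
})

test_that("Dicer analysis rejects degenerate strata and shows no effect at zero gain", {
  cfg <- simulation_config(n_samples_per_condition = 100,
                           repression_gain = 0, decoupling_fraction = 0,
                           seed = 37)
  sim <- simulate_expression(simulate_catalog(cfg), cfg)
  net <- data.frame(mrna = sim$truth$planted_pairs$mrna,
                    lncrna = sim$truth$planted_pairs$lncrna)
  res <- dicer_stratified_coexpression(net, sim$expr, sim$labels, "normal",
                                       sim$truth$dicer_proxy_id)
  expect_lt(abs(mean(res$high_r) - mean(res$low_r)), 0.1)
  # constant Dicer: strata ill-defined
  sim$expr[sim$truth$dicer_proxy_id, ] <- 5
  expect_error(dicer_stratified_coexpression(net, sim$expr, sim$labels,
                                             "normal",
                                             sim$truth$dicer_proxy_id),
               "constant")
})
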