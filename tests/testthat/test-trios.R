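# Paired miRNA + target fixture: miR-1, miR-2, gene-A and lnc-A all load on
# one latent factor in the normal condition only, so every (planted miRNA,
# planted target) pair is differentially correlated between conditions.
# miR-3, gene-B, lnc-B and gene-C are independent noise throughout.
make_trio_fixture <- function(n_per_condition = 80, seed = 1L) {
  set.seed(seed)
  n_tot <- 2L * n_per_condition
  samples <- sprintf("S%03d", seq_len(n_tot))
  labels <- stats::setNames(rep(c("normal", "disease"),
                                each = n_per_condition), samples)
  nrm <- labels == "normal"
  z <- rnorm(n_tot)
  member <- function(planted) {
    x <- rnorm(n_tot)
    if (planted) x[nrm] <- sqrt(0.85) * z[nrm] + sqrt(0.15) * rnorm(sum(nrm))
    x
  }
  expr <- rbind("miR-1" = member(TRUE), "miR-2" = member(TRUE),
                "miR-3" = member(FALSE),
                "gene-A" = member(TRUE), "gene-B" = member(FALSE),
                "gene-C" = member(FALSE), "lnc-A" = member(TRUE),
                "lnc-B" = member(FALSE))
  colnames(expr) <- samples
  list(expr = expr + 8, labels = labels)
}

split_fixture <- function(fix) {
  mir <- fix$expr[grep("^miR", rownames(fix$expr)), , drop = FALSE]
  tgt <- fix$expr[grep("^miR", rownames(fix$expr), invert = TRUE), ,
                  drop = FALSE]
  list(mir = mir, tgt = tgt)
}

test_that("miRNA-target dysregulation requires a paired design", {
  fx <- split_fixture(make_trio_fixture(seed = 2))
  expect_error(
    mirna_target_dysregulation(fx$mir, fx$tgt[, 1:10],
                               data.frame(mirna = "miR-1",
                                          target = "gene-A"),
                               rep("normal", 10)),
    "same samples")
})

test_that("planted miRNA-target decoupling is flagged, null pairs are not", {
  fix <- make_trio_fixture(seed = 7)
  fx <- split_fixture(fix)
  inter <- data.frame(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-2", "miR-3", "miR-3"),
    target = c("gene-A", "lnc-A", "gene-A", "lnc-A", "gene-B", "lnc-B"))
  dys <- mirna_target_dysregulation(fx$mir, fx$tgt, inter, fix$labels,
                                    alpha = 0.01, n_perm = 400, seed = 3)
  keys <- paste(dys$mirna, dys$target)
  expect_true(all(c("miR-1 gene-A", "miR-1 lnc-A", "miR-2 gene-A",
                    "miR-2 lnc-A") %in% keys))
  expect_false(any(grepl("miR-3", keys)))
  # alpha = 1 returns every catalog-supported pair
  all_pairs <- mirna_target_dysregulation(fx$mir, fx$tgt, inter, fix$labels,
                                          alpha = 1, n_perm = 50, seed = 3)
  expect_equal(nrow(all_pairs), nrow(inter))
  # expression mode flags differentially expressed miRNAs instead
  mir2 <- fx$mir
  mir2["miR-3", fix$labels == "disease"] <-
    mir2["miR-3", fix$labels == "disease"] + 3
  de <- mirna_target_dysregulation(mir2, fx$tgt, inter, fix$labels,
                                   alpha = 0.01, n_perm = 10, seed = 3,
                                   mode = "expression")
  expect_true(all(grepl("^miR-3", de$mirna)))
  expect_true(all(de$direction == "up_in_disease"))
})

test_that("ternary network keeps pairs whose shared miRNAs are dysregulated", {
  dys_mm <- data.frame(mirna = c("m1", "m2", "m3"),
                       target = c("g1", "g1", "g2"))
  dys_ml <- data.frame(mirna = c("m1", "m2", "m9"),
                       target = c("l1", "l1", "l2"))
  ce <- data.frame(mrna = c("g1", "g2", "g3"), lncrna = c("l1", "l2", "l3"))
  trios <- build_ternary_network(dys_mm, dys_ml, ce)
  expect_equal(nrow(trios), 1)  # only (g1, l1) shares dysregulated miRNAs
  expect_equal(trios$n_shared, 2)
  expect_equal(trios$shared_mirnas, "m1,m2")
  # the ">1 shared" filtered sub-network
  filtered <- build_ternary_network(dys_mm, dys_ml, ce, min_shared = 2)
  expect_equal(nrow(filtered), 1)
  dys_mm1 <- dys_mm[1, ]
  expect_equal(nrow(build_ternary_network(dys_mm1, dys_ml, ce,
                                          min_shared = 2)), 0)
})

test_that("planted trios are recovered with high precision end to end", {
  fix <- make_trio_fixture(n_per_condition = 80, seed = 13)
  fx <- split_fixture(fix)
  inter_m <- data.frame(
    mirna = c("miR-1", "miR-2", "miR-3", "miR-1", "miR-2"),
    target = c("gene-A", "gene-A", "gene-B", "gene-C", "gene-C"))
  inter_l <- data.frame(
    mirna = c("miR-1", "miR-2", "miR-3"),
    target = c("lnc-A", "lnc-A", "lnc-B"))
  dys_mm <- mirna_target_dysregulation(fx$mir, fx$tgt, inter_m, fix$labels,
                                       n_perm = 400, seed = 5)
  dys_ml <- mirna_target_dysregulation(fx$mir, fx$tgt, inter_l, fix$labels,
                                       n_perm = 400, seed = 5)
  ce <- data.frame(mrna = c("gene-A", "gene-B", "gene-C"),
                   lncrna = c("lnc-A", "lnc-B", "lnc-B"))
  trios <- build_ternary_network(dys_mm, dys_ml, ce, min_shared = 2)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$mrna, "gene-A")
  expect_equal(trios$shared_mirnas, "miR-1,miR-2")
  # shared sets stay inside the catalog-shared sets
  expect_true(all(strsplit(trios$shared_mirnas, ",")[[1]] %in%
                    intersect(inter_m$mirna[inter_m$target == "gene-A"],
                              inter_l$mirna[inter_l$target == "lnc-A"])))
})

test_that("shared-count histogram conserves pairs and fractions", {
  recs <- data.frame(mrna = paste0("g", 1:10), lncrna = paste0("l", 1:10),
                     n_shared = c(rep(1L, 7), rep(2L, 3)),
                     shared_mirnas = "x")
  d <- shared_count_distribution(recs)
  expect_equal(d$fraction_single, 0.7)
  expect_equal(sum(d$histogram$n_pairs), 10)
  expect_equal(sum(d$histogram$fraction), 1)
  all1 <- recs; all1$n_shared <- 1L
  expect_equal(shared_count_distribution(all1)$fraction_single, 1)
  expect_error(shared_count_distribution(recs[0, ]), "no trio")
  # independent recount
  expect_equal(d$histogram$n_pairs[d$histogram$n_shared == 2],
               sum(recs$n_shared == 2))
})
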