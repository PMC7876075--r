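#' Dysregulated miRNA-target pairs from paired expression profiles
#'
#' For each catalog-supported (miRNA, target) interaction with both members
#' measured, applies the same label-permutation differential-correlation
#' test used for mRNA-lncRNA pairs to the miRNA and target expression
#' vectors (default mode), or -- behind the `"expression"` mode -- flags
#' pairs whose miRNA is differentially expressed between conditions
#' (Student's t-test). Requires a paired design: both matrices must cover
#' the same samples.
#'
#' @param mirna_expr miRNAs x samples expression matrix.
#' @param target_expr Targets x samples expression matrix (same samples).
#' @param interactions data.frame with `mirna`, `target` columns (one
#'   target class of an `interaction_catalog`).
#' @param labels Named condition vector.
#' @param alpha Retention cutoff (`<=` on the p-value; `alpha = 1` keeps
#'   every catalog-supported pair).
#' @param n_perm,seed,conditions See [permutation_test()].
#' @param mode `"correlation"` (default) or `"expression"`.
#' @param negative_only Keep only pairs with negative miRNA-target
#'   correlation in the normal condition (off by default; repression
#'   direction is reported, not enforced).
#' @return data.frame: `mirna`, `target`, `r_normal`, `r_disease`,
#'   `delta_r`, `p_value`, `direction` (correlation mode fields are NA in
#'   expression mode).
#' @export
mirna_target_dysregulation <- function(mirna_expr, target_expr, interactions,
                                       labels, alpha = 0.05, n_perm = 1000,
                                       seed = 1L,
                                       conditions = c("normal", "disease"),
                                       mode = c("correlation", "expression"),
                                       negative_only = FALSE) {
  mode <- match.arg(mode)
  check_expression(mirna_expr, "miRNA expression matrix")
  check_expression(target_expr, "target expression matrix")
  if (!setequal(colnames(mirna_expr), colnames(target_expr)))
    stop("miRNA and target matrices must cover the same samples ",
         "(paired design)", call. = FALSE)
  target_expr <- target_expr[, colnames(mirna_expr), drop = FALSE]
  keep <- interactions$mirna %in% rownames(mirna_expr) &
    interactions$target %in% rownames(target_expr)
  inter <- unique(interactions[keep, c("mirna", "target"), drop = FALSE])
  if (!nrow(inter))
    return(data.frame(mirna = character(0), target = character(0),
                      r_normal = numeric(0), r_disease = numeric(0),
                      delta_r = numeric(0), p_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  combined <- rbind(mirna_expr[unique(inter$mirna), , drop = FALSE],
                    target_expr[unique(inter$target), , drop = FALSE])
  labels <- check_labels(labels, combined)
  smp_n <- colnames(combined)[labels == conditions[1]]
  smp_d <- colnames(combined)[labels == conditions[2]]
  recs <- lapply(seq_len(nrow(inter)), function(i) {
    mi <- inter$mirna[i]; tg <- inter$target[i]
    if (mode == "correlation") {
      rec <- permutation_test(mi, tg, combined, labels, n_perm = n_perm,
                              seed = seed, conditions = conditions)
      names(rec)[names(rec) %in% c("mrna", "lncrna")] <- c("mirna", "target")
      rec
    } else {
      tt <- t.test(mirna_expr[mi, smp_d], mirna_expr[mi, smp_n])
      data.frame(mirna = mi, target = tg, r_normal = NA_real_,
                 r_disease = NA_real_, delta_r = NA_real_,
                 p_value = tt$p.value,
                 direction = if (tt$estimate[1] > tt$estimate[2])
                   "up_in_disease" else "down_in_disease",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, recs)
  if (negative_only && mode == "correlation")
    out <- out[!is.na(out$r_normal) & out$r_normal < 0, , drop = FALSE]
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the ternary mRNA-miRNA-lncRNA network
#'
#' For each ceRNA pair, its shared dysregulated miRNAs are the miRNAs
#' found dysregulated against BOTH the pair's mRNA and its lncRNA. Pairs
#' with at least one shared dysregulated miRNA form the ternary network;
#' `min_shared = 2` gives the filtered sub-network of pairs with more than
#' one shared dysregulated miRNA.
#'
#' @param dys_mrna_mirna Output of [mirna_target_dysregulation()] run on
#'   mRNA targets.
#' @param dys_mirna_lncrna Likewise for lncRNA targets.
#' @param ce_pairs data.frame with `mrna`, `lncrna` columns.
#' @param min_shared Minimum shared dysregulated miRNA count (default 1).
#' @return data.frame of trio records: `mrna`, `lncrna`, `n_shared`,
#'   `shared_mirnas` (comma-joined ids).
#' @export
build_ternary_network <- function(dys_mrna_mirna, dys_mirna_lncrna, ce_pairs,
                                  min_shared = 1) {
  mir_by_mrna <- split(dys_mrna_mirna$mirna, dys_mrna_mirna$target)
  mir_by_lnc <- split(dys_mirna_lncrna$mirna, dys_mirna_lncrna$target)
  recs <- lapply(seq_len(nrow(ce_pairs)), function(i) {
    shared <- sort(intersect(mir_by_mrna[[ce_pairs$mrna[i]]],
                             mir_by_lnc[[ce_pairs$lncrna[i]]]))
    if (length(shared) < min_shared) return(NULL)
    data.frame(mrna = ce_pairs$mrna[i], lncrna = ce_pairs$lncrna[i],
               n_shared = length(shared),
               shared_mirnas = paste(shared, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(mrna = character(0), lncrna = character(0),
                      n_shared = integer(0), shared_mirnas = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Distribution of shared dysregulated miRNA counts
#'
#' Exact histogram of the per-pair shared dysregulated miRNA count, plus
#' the fraction of pairs containing only one dysregulated miRNA.
#'
#' @param records Trio records from [build_ternary_network()].
#' @return List with `histogram` (data.frame n_shared, n_pairs, fraction)
#'   and `fraction_single` (fraction of pairs at count 1).
#' @export
shared_count_distribution <- function(records) {
  if (!nrow(records)) stop("no trio records", call. = FALSE)
  tab <- table(records$n_shared)
  histogram <- data.frame(n_shared = as.integer(names(tab)),
                          n_pairs = as.integer(tab))
  histogram$fraction <- histogram$n_pairs / sum(histogram$n_pairs)
  single <- histogram$fraction[histogram$n_shared == 1L]
  list(histogram = histogram,
       fraction_single = if (length(single)) single else 0)
}
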