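#' Intersection of two condition-specific ceRNA networks
#'
#' The mRNA-lncRNA pairs present in both edge sets; symmetric in its
#' arguments. Per-network correlations are carried along when available.
#'
#' @param net_a,net_b `cerna_network` objects (or data.frames with `mrna`,
#'   `lncrna` columns).
#' @return data.frame with `mrna`, `lncrna` and, when present, `r_a`, `r_b`.
#' @export
network_intersection <- function(net_a, net_b) {
  key_a <- paste(net_a$mrna, net_a$lncrna, sep = "\r")
  key_b <- paste(net_b$mrna, net_b$lncrna, sep = "\r")
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a)
  out <- data.frame(mrna = net_a$mrna[ia], lncrna = net_a$lncrna[ia],
                    stringsAsFactors = FALSE)
  if (!is.null(net_a$r)) out$r_a <- net_a$r[ia]
  if (!is.null(net_b$r)) out$r_b <- net_b$r[match(common, key_b)]
  out <- out[order(out$mrna, out$lncrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Difference in Pearson correlation of (x, y) between two sample index sets,
# optionally on the Fisher z scale. Returns NA when a group is degenerate.
delta_r_stat <- function(x, y, idx1, idx2, fisher_z = FALSE) {
  if (sd(x[idx1]) == 0 || sd(y[idx1]) == 0 ||
      sd(x[idx2]) == 0 || sd(y[idx2]) == 0) return(NA_real_)
  r1 <- cor(x[idx1], y[idx1])
  r2 <- cor(x[idx2], y[idx2])
  if (fisher_z) {
    z <- atanh(pmin(pmax(c(r1, r2), -1 + 1e-12), 1 - 1e-12))
    return(z[2] - z[1])
  }
  r2 - r1
}

#' Label-permutation test for differential co-expression of one pair
#'
#' The observed statistic is the absolute difference between the Pearson
#' correlations of the pair computed in the disease and the normal samples.
#' The null distribution is built by randomly permuting the condition
#' labels over samples `n_perm` times and recomputing the statistic; the
#' p-value uses the add-one estimator (1 + #\{null >= observed\}) /
#' (n_perm + 1). Samples are processed in sorted sample-id order so the
#' result does not depend on the column order of `expr`. Permutations
#' producing a zero-variance group are redrawn (with a cap).
#'
#' @param mrna,lncrna Feature ids of the pair.
#' @param expr Features x samples expression matrix.
#' @param labels Named condition vector over samples.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param conditions Length-2 character: reference (normal) then disease
#'   condition.
#' @param fisher_z Difference correlations on the Fisher z scale instead of
#'   the raw r scale.
#' @return One-row data.frame: `mrna`, `lncrna`, `r_normal`, `r_disease`,
#'   `delta_r` (disease minus normal), `p_value`, `direction` (sign of the
#'   pair members' mean differential expression, disease minus normal;
#'   `discordant` when the members disagree).
#' @export
permutation_test <- function(mrna, lncrna, expr, labels, n_perm = 1000,
                             seed = 1L, conditions = c("normal", "disease"),
                             fisher_z = FALSE) {
  check_expression(expr)
  labels <- check_labels(labels, expr)
  if (!all(conditions %in% labels))
    stop("labels must contain both conditions: ",
         paste(conditions, collapse = ", "), call. = FALSE)
  for (f in c(mrna, lncrna))
    if (!f %in% rownames(expr))
      stop("feature absent from expression matrix: ", f, call. = FALSE)
  ord <- order(colnames(expr))
  keep <- labels[ord] %in% conditions
  smp <- colnames(expr)[ord][keep]
  lab <- labels[smp]
  x <- expr[mrna, smp]
  y <- expr[lncrna, smp]
  idx_norm <- which(lab == conditions[1])
  idx_dis <- which(lab == conditions[2])
  if (length(idx_norm) < 3L || length(idx_dis) < 3L)
    stop("need >= 3 samples per condition", call. = FALSE)

  obs <- delta_r_stat(x, y, idx_norm, idx_dis, fisher_z)
  if (is.na(obs))
    stop("zero-variance feature in a condition: correlation undefined for ",
         mrna, " / ", lncrna, call. = FALSE)

  n <- length(smp)
  n1 <- length(idx_norm)
  null <- numeric(n_perm)
  redraws <- 0L
  with_seed(substream_seed(seed, paste("perm", mrna, lncrna)), {
    b <- 1L
    while (b <= n_perm) {
      perm <- sample.int(n)
      d <- delta_r_stat(x, y, perm[seq_len(n1)], perm[-seq_len(n1)], fisher_z)
      if (is.na(d)) {
        redraws <- redraws + 1L
        if (redraws > 100L + 10L * n_perm)
          stop("too many degenerate permutations (zero-variance groups)",
               call. = FALSE)
        next
      }
      null[b] <- d
      b <- b + 1L
    }
  })
  if (redraws > 0L)
    message(redraws, " degenerate permutation(s) redrawn for ",
            mrna, " / ", lncrna)
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)

  d_m <- mean(expr[mrna, names(lab)[idx_dis]]) -
    mean(expr[mrna, names(lab)[idx_norm]])
  d_l <- mean(expr[lncrna, names(lab)[idx_dis]]) -
    mean(expr[lncrna, names(lab)[idx_norm]])
  direction <- if (d_m > 0 && d_l > 0) "up_in_disease"
               else if (d_m < 0 && d_l < 0) "down_in_disease"
               else "discordant"

  r_n <- cor(x[idx_norm], y[idx_norm])
  r_d <- cor(x[idx_dis], y[idx_dis])
  data.frame(mrna = mrna, lncrna = lncrna, r_normal = r_n, r_disease = r_d,
             delta_r = r_d - r_n, p_value = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' Dysregulated mRNA-lncRNA pairs between conditions
#'
#' Runs the label-permutation differential-correlation test on each pair
#' and returns those with p-value at or below `alpha`. Each pair's
#' permutation stream is derived from the global seed and the pair's ids,
#' so results are independent of pair order.
#'
#' @param pairs data.frame with `mrna`, `lncrna` columns (candidate pairs
#'   or a network intersection).
#' @param expr,labels,conditions,n_perm,seed,fisher_z See
#'   [permutation_test()].
#' @param alpha Retention cutoff on the permutation p-value (`<=`);
#'   `alpha = 1` keeps every record.
#' @param adjust Additionally BH-adjust the permutation p-values and filter
#'   on the adjusted values instead.
#' @param direction_method `"expression"` (default; sign of the members'
#'   mean differential expression) or `"delta_r"` (sign of the correlation
#'   change).
#' @return data.frame of dysregulation records (see [permutation_test()]),
#'   sorted by p-value.
#' @export
dysregulated_pairs <- function(pairs, expr, labels, alpha = 0.05,
                               n_perm = 1000, seed = 1L,
                               conditions = c("normal", "disease"),
                               adjust = FALSE, fisher_z = FALSE,
                               direction_method = c("expression", "delta_r")) {
  direction_method <- match.arg(direction_method)
  if (!nrow(pairs)) {
    out <- data.frame(mrna = character(0), lncrna = character(0),
                      r_normal = numeric(0), r_disease = numeric(0),
                      delta_r = numeric(0), p_value = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  recs <- lapply(seq_len(nrow(pairs)), function(i)
    permutation_test(pairs$mrna[i], pairs$lncrna[i], expr, labels,
                     n_perm = n_perm, seed = seed, conditions = conditions,
                     fisher_z = fisher_z))
  out <- do.call(rbind, recs)
  if (direction_method == "delta_r")
    out$direction <- ifelse(out$delta_r > 0, "up_in_disease",
                            "down_in_disease")
  if (adjust) {
    out$q_value <- bh_fdr(out$p_value)
    out <- out[out$q_value <= alpha, , drop = FALSE]
  } else {
    out <- out[out$p_value <= alpha, , drop = FALSE]
  }
  out <- out[order(out$p_value, out$mrna, out$lncrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split-half stability of the dysregulation analysis
#'
#' Randomly splits the samples into two halves (stratified by condition),
#' runs [dysregulated_pairs()] independently on each half and on the full
#' cohort, and reports the three pair lists together with their pairwise
#' Jaccard overlaps.
#'
#' @inheritParams dysregulated_pairs
#' @return List with `half1`, `half2`, `full` (dysregulation records),
#'   `jaccard_halves`, `jaccard_half1_full`, `jaccard_half2_full`, and the
#'   sample assignment (`samples_half1`, `samples_half2`).
#' @export
split_half_stability <- function(pairs, expr, labels, alpha = 0.05,
                                 n_perm = 1000, seed = 1L,
                                 conditions = c("normal", "disease")) {
  check_expression(expr)
  labels <- check_labels(labels, expr)
  split_idx <- with_seed(substream_seed(seed, "split-half"), {
    unlist(lapply(conditions, function(cond) {
      smp <- sort(colnames(expr)[labels == cond])
      if (length(smp) < 6L)
        stop("need >= 6 samples per condition to stratify a half-split",
             call. = FALSE)
      sample(smp, floor(length(smp) / 2))
    }))
  })
  half1 <- sort(split_idx)
  half2 <- sort(setdiff(colnames(expr), half1))
  run <- function(smp)
    dysregulated_pairs(pairs, expr[, smp, drop = FALSE], labels[smp],
                       alpha = alpha, n_perm = n_perm, seed = seed,
                       conditions = conditions)
  res1 <- run(half1); res2 <- run(half2); full <- run(colnames(expr))
  jac <- function(a, b) {
    ka <- paste(a$mrna, a$lncrna); kb <- paste(b$mrna, b$lncrna)
    if (!length(ka) && !length(kb)) return(1)
    length(intersect(ka, kb)) / length(union(ka, kb))
  }
  list(half1 = res1, half2 = res2, full = full,
       jaccard_halves = jac(res1, res2),
       jaccard_half1_full = jac(res1, full),
       jaccard_half2_full = jac(res2, full),
       samples_half1 = half1, samples_half2 = half2)
}
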