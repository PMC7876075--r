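#' Upper-tail hypergeometric probability of miRNA sharing
#'
#' Probability of observing at least `r` shared miRNAs between an mRNA and
#' a lncRNA when the lncRNA's `n` targeting miRNAs are drawn without
#' replacement from a universe of `m` miRNAs of which `t` target the mRNA:
#' \deqn{p = 1 - \sum_{k=0}^{r-1} \binom{t}{k}\binom{m-t}{n-k} / \binom{m}{n}.}
#' Evaluated in log space (via the hypergeometric distribution function) so
#' it is numerically stable for universes up to at least 1e4 miRNAs.
#'
#' @param m miRNA universe size.
#' @param t Number of miRNAs targeting the mRNA.
#' @param n Number of miRNAs targeting the lncRNA.
#' @param r Observed shared count. All arguments vectorized.
#' @return Upper-tail probability in [0, 1]; `r = 0` gives 1 exactly.
#' @export
hypergeom_pvalue <- function(m, t, n, r) {
  len <- max(length(m), length(t), length(n), length(r))
  m <- rep_len(m, len); t <- rep_len(t, len)
  n <- rep_len(n, len); r <- rep_len(r, len)
  bad <- t > m | n > m | r > pmin(t, n) | r < 0 | m < 0
  if (any(bad))
    stop("invalid hypergeometric parameters: need 0 <= r <= min(t, n), ",
         "t <= m, n <= m (first offending index ", which(bad)[1], ")",
         call. = FALSE)
  # P(X >= r) with X ~ Hypergeometric(white = t, black = m - t, drawn = n)
  p <- phyper(r - 1, t, m - t, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjusted q-values, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Candidate ceRNA pairs by the hypergeometric miRNA-sharing test
#'
#' Evaluates every (mRNA, lncRNA) pair in the catalog; the shared-miRNA
#' count is scored against the hypergeometric null, q-values are computed
#' by BH over all evaluated pairs, and a pair is retained when it shares at
#' least `min_shared` miRNAs and its q-value is below `fdr_threshold`.
#'
#' @param catalog An `interaction_catalog`.
#' @param min_shared Minimum shared-miRNA count (default 3).
#' @param fdr_threshold FDR cutoff (default 0.05; strict `<`).
#' @return data.frame of class `candidate_pairs` with columns `mrna`,
#'   `lncrna`, `shared_count`, `p_value`, `q_value`, sorted by q then ids.
#' @export
candidate_pairs <- function(catalog, min_shared = 3, fdr_threshold = 0.05) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  if (!nrow(catalog$mrna) || !nrow(catalog$lncrna))
    stop("catalog has no interactions for one of the target classes",
         call. = FALSE)
  M <- catalog_incidence(catalog, "mrna")
  L <- catalog_incidence(catalog, "lncrna")
  m <- length(catalog$mirnas)
  shared <- as.matrix(Matrix::crossprod(M, L))  # mRNA x lncRNA shared counts
  t_counts <- Matrix::colSums(M)
  n_counts <- Matrix::colSums(L)
  grid <- expand.grid(mrna = colnames(M), lncrna = colnames(L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- data.frame(
    mrna = grid$mrna, lncrna = grid$lncrna,
    shared_count = as.vector(shared),
    p_value = hypergeom_pvalue(m, t_counts[grid$mrna], n_counts[grid$lncrna],
                               as.vector(shared)),
    stringsAsFactors = FALSE)
  res$q_value <- bh_fdr(res$p_value)
  res <- res[res$shared_count >= min_shared & res$q_value < fdr_threshold, ,
             drop = FALSE]
  res <- res[order(res$q_value, res$mrna, res$lncrna), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_pairs", "data.frame")
  res
}

# Pearson correlation p-value via the t-distribution on n - 2 df.
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

#' Build a condition-specific ceRNA network by co-expression pruning
#'
#' For each candidate pair, the Pearson correlation of the two members is
#' computed over the samples of one condition; correlation p-values (t
#' approximation on n-2 df) are BH-adjusted across candidates, and an edge
#' is kept when r strictly exceeds `r_threshold` (signed, positive
#' co-expression) and its q-value is below `fdr_threshold`. Zero-variance
#' features skip the pair with a warning rather than aborting.
#'
#' @param candidates A `candidate_pairs` data.frame (or any data.frame with
#'   `mrna`, `lncrna` columns).
#' @param expr Features x samples expression matrix.
#' @param labels Named condition vector.
#' @param condition Condition whose samples define the network.
#' @param r_threshold Correlation cutoff (strict `>`; default 0.25).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Object of class `cerna_network`: data.frame with `mrna`,
#'   `lncrna`, `r`, `p_value`, `q_value`; attribute `condition`.
#' @export
build_condition_network <- function(candidates, expr, labels, condition,
                                    r_threshold = 0.25,
                                    fdr_threshold = 0.05) {
  check_expression(expr)
  smp <- condition_samples(expr, labels, condition)
  if (length(smp) < 3L)
    stop("need >= 3 samples in condition '", condition, "'", call. = FALSE)
  missing <- setdiff(unique(c(candidates$mrna, candidates$lncrna)),
                     rownames(expr))
  if (length(missing))
    stop("candidate feature(s) absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  sub <- expr[, smp, drop = FALSE]
  sds <- apply(sub, 1, sd)
  flat <- unique(c(candidates$mrna, candidates$lncrna))
  flat <- flat[sds[flat] == 0]
  keep <- !(candidates$mrna %in% flat | candidates$lncrna %in% flat)
  if (any(!keep))
    warning(sum(!keep), " pair(s) skipped: zero-variance feature in ",
            "condition '", condition, "'", call. = FALSE)
  cand <- candidates[keep, , drop = FALSE]
  r <- vapply(seq_len(nrow(cand)), function(i)
    cor(sub[cand$mrna[i], ], sub[cand$lncrna[i], ]), numeric(1))
  p <- cor_pvalue(r, length(smp))
  q <- bh_fdr(p)
  sel <- r > r_threshold & q < fdr_threshold
  net <- data.frame(mrna = cand$mrna[sel], lncrna = cand$lncrna[sel],
                    r = r[sel], p_value = p[sel], q_value = q[sel],
                    stringsAsFactors = FALSE)
  net <- net[order(net$mrna, net$lncrna), , drop = FALSE]
  rownames(net) <- NULL
  attr(net, "condition") <- condition
  class(net) <- c("cerna_network", "data.frame")
  net
}
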