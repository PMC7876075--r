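#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line -- name, description, then tab-separated
#' member gene ids. Parsed with `fgsea::gmtPathways` when available,
#' otherwise by a minimal reader with identical semantics.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors (set name -> member ids).
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (highest expression gets
#' the largest rank; ties broken deterministically by feature-id order) and
#' walked in decreasing order. The enrichment score is the sum, over all
#' positions of the ranked list, of the difference between the weighted
#' in-set cumulative distribution (weights = rank^`weight_exponent`) and
#' the unweighted out-of-set cumulative distribution. Scores are rank-based
#' and therefore invariant to strictly monotone transforms of a sample's
#' values. A set covering every gene has a degenerate out-of-set
#' distribution; its score is defined as 0 by convention.
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param weight_exponent Rank-weight exponent tau (default 0.25; 0 gives
#'   the unweighted Kolmogorov-Smirnov-like running sum).
#' @param normalize Divide all scores by the range of scores across the
#'   whole matrix (off by default).
#' @return Sets x samples numeric score matrix. Sets with no gene in
#'   `expr` are dropped with a warning; an error is raised if none survive.
#' @export
ssgsea_scores <- function(expr, sets, weight_exponent = 0.25,
                          normalize = FALSE) {
  check_expression(expr)
  genes <- rownames(expr)
  sets <- lapply(sets, function(s) intersect(s, genes))
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " gene set(s) with no gene in the ",
            "expression matrix: ",
            paste(head(names(sets)[empty], 5), collapse = ", "),
            call. = FALSE)
    sets <- sets[!empty]
  }
  if (!length(sets))
    stop("no gene set overlaps the expression matrix", call. = FALSE)
  n <- length(genes)
  id_order <- order(genes)  # deterministic tie-break by feature id
  scores <- matrix(0, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  set_ind <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    # decreasing expression; ties resolved by feature-id order
    ord <- id_order[order(expr[id_order, j], decreasing = TRUE)]
    w <- (n:1)^weight_exponent  # rank weight of position i in the walk
    for (k in seq_along(sets)) {
      ind <- set_ind[[k]][ord]
      n_in <- sum(ind)
      n_out <- n - n_in
      if (n_out == 0L) { scores[k, j] <- 0; next }
      p_in <- cumsum(w * ind) / sum(w * ind)
      p_out <- cumsum(!ind) / n_out
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Associate lncRNA expression with pathway enrichment scores
#'
#' Pearson correlation between each lncRNA's expression and each gene
#' set's per-sample enrichment score; associations exceeding the threshold
#' are retained (signed r by default; `use_absolute = TRUE` retains on
#' |r|). The full correlation matrix is returned alongside for
#' clustering/heatmap use.
#'
#' @param scores Sets x samples score matrix from [ssgsea_scores()].
#' @param lncrna_expr lncRNAs x samples expression matrix (same samples).
#' @param threshold Correlation cutoff (strict `>`; default 0.5).
#' @param use_absolute Threshold on |r| instead of signed r.
#' @return List with `associations` (data.frame lncrna, gene_set, r) and
#'   `correlation_matrix` (lncRNAs x sets).
#' @export
lncrna_pathway_association <- function(scores, lncrna_expr, threshold = 0.5,
                                       use_absolute = FALSE) {
  check_expression(lncrna_expr, "lncRNA expression matrix")
  if (!setequal(colnames(scores), colnames(lncrna_expr)))
    stop("score matrix and lncRNA matrix must cover the same samples",
         call. = FALSE)
  scores <- scores[, colnames(lncrna_expr), drop = FALSE]
  cm <- cor(t(lncrna_expr), t(scores))
  crit <- if (use_absolute) abs(cm) > threshold else cm > threshold
  w <- which(crit, arr.ind = TRUE)
  associations <- data.frame(lncrna = rownames(cm)[w[, 1]],
                             gene_set = colnames(cm)[w[, 2]],
                             r = cm[w], stringsAsFactors = FALSE)
  associations <- associations[order(-abs(associations$r)), , drop = FALSE]
  rownames(associations) <- NULL
  list(associations = associations, correlation_matrix = cm)
}
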