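#' Degree distribution of a ceRNA network
#'
#' Node degrees over the bipartite mRNA-lncRNA edge set, the degree
#' histogram, and a least-squares slope of log10(count) on log10(degree) as
#' a descriptive summary of the distribution's tail (no formal power-law
#' test is attempted).
#'
#' @param net A `cerna_network` (or data.frame with `mrna`, `lncrna`).
#' @return List with `degree` (named integer), `histogram` (data.frame
#'   degree, n_nodes), `loglog_slope` and `loglog_r2` (NA when fewer than
#'   two distinct degrees).
#' @export
degree_distribution <- function(net) {
  if (!nrow(net)) stop("empty network", call. = FALSE)
  nodes <- c(net$mrna, net$lncrna)
  degree <- table(nodes)
  degree <- setNames(as.integer(degree), names(degree))
  hist_tab <- table(degree)
  histogram <- data.frame(degree = as.integer(names(hist_tab)),
                          n_nodes = as.integer(hist_tab))
  slope <- r2 <- NA_real_
  if (nrow(histogram) >= 2L) {
    fit <- stats::lm(log10(n_nodes) ~ log10(degree), data = histogram)
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  list(degree = degree, histogram = histogram,
       loglog_slope = slope, loglog_r2 = r2)
}

#' Node degree versus mean edge co-expression
#'
#' For every node of the network, the mean Pearson correlation over its
#' incident edges (computed in the requested condition's samples), and the
#' association between node degree and that mean.
#'
#' @param net A `cerna_network`.
#' @param expr,labels,condition Expression matrix, condition labels and
#'   the condition whose samples are used.
#' @return List with `per_node` (data.frame node, degree, mean_r) and
#'   `association` (estimate, p_value). A constant response reports
#'   estimate 0 with p-value 1.
#' @export
degree_vs_coexpression <- function(net, expr, labels, condition) {
  if (!nrow(net)) stop("empty network", call. = FALSE)
  check_expression(expr)
  smp <- condition_samples(expr, labels, condition)
  sub <- expr[, smp, drop = FALSE]
  edge_r <- vapply(seq_len(nrow(net)), function(i)
    cor(sub[net$mrna[i], ], sub[net$lncrna[i], ]), numeric(1))
  deg <- degree_distribution(net)$degree
  if (length(deg) < 2L)
    stop("network has fewer than two nodes; association undefined",
         call. = FALSE)
  nodes <- names(deg)
  mean_r <- vapply(nodes, function(v)
    mean(edge_r[net$mrna == v | net$lncrna == v]), numeric(1))
  per_node <- data.frame(node = nodes, degree = unname(deg[nodes]),
                         mean_r = unname(mean_r), stringsAsFactors = FALSE)
  assoc <- safe_pearson_assoc(per_node$degree, per_node$mean_r)
  list(per_node = per_node, association = assoc)
}

# Pearson association that degrades gracefully on constant inputs.
safe_pearson_assoc <- function(x, y) {
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0)
    return(list(estimate = 0, p_value = 1))
  ct <- cor.test(x, y, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Shared-miRNA count versus pair co-expression
#'
#' Association between the number of miRNAs shared by each candidate pair
#' and the pair's Pearson co-expression in one condition.
#'
#' @param candidates A `candidate_pairs` data.frame (needs `shared_count`).
#' @param expr,labels,condition As in [degree_vs_coexpression()].
#' @return List with `per_pair` (data.frame mrna, lncrna, shared_count, r)
#'   and `association` (estimate, p_value).
#' @export
shared_count_vs_coexpression <- function(candidates, expr, labels,
                                         condition) {
  if (!nrow(candidates)) stop("empty candidate set", call. = FALSE)
  if (is.null(candidates$shared_count))
    stop("candidates must carry a shared_count column", call. = FALSE)
  check_expression(expr)
  smp <- condition_samples(expr, labels, condition)
  sub <- expr[, smp, drop = FALSE]
  r <- vapply(seq_len(nrow(candidates)), function(i)
    cor(sub[candidates$mrna[i], ], sub[candidates$lncrna[i], ]), numeric(1))
  per_pair <- data.frame(mrna = candidates$mrna, lncrna = candidates$lncrna,
                         shared_count = candidates$shared_count, r = r,
                         stringsAsFactors = FALSE)
  list(per_pair = per_pair,
       association = safe_pearson_assoc(per_pair$shared_count, per_pair$r))
}

#' Co-expression stratified by Dicer expression
#'
#' Splits the condition's samples at the median expression of the Dicer
#' proxy feature, recomputes every edge correlation within the low and the
#' high stratum, and compares the two correlation lists with Student's
#' t-test. Because Dicer governs global miRNA processing, stronger
#' miRNA-mediated coupling is expected in the high stratum.
#'
#' @param net A `cerna_network`.
#' @param expr,labels,condition As in [degree_vs_coexpression()].
#' @param dicer_id Feature id of the Dicer proxy.
#' @return List with `low_r`, `high_r` (edge correlation vectors),
#'   `p_value` (two-sided t-test), and the stratum sample ids.
#' @export
dicer_stratified_coexpression <- function(net, expr, labels, condition,
                                          dicer_id) {
  if (!nrow(net)) stop("empty network", call. = FALSE)
  check_expression(expr)
  if (!dicer_id %in% rownames(expr))
    stop("Dicer proxy feature absent from expression matrix: ", dicer_id,
         call. = FALSE)
  smp <- condition_samples(expr, labels, condition)
  d <- expr[dicer_id, smp]
  if (sd(d) == 0)
    stop("Dicer proxy is constant in condition '", condition,
         "'; strata are ill-defined", call. = FALSE)
  med <- median(d)
  low <- smp[d <= med]
  high <- smp[d > med]
  if (length(low) < 3L || length(high) < 3L)
    stop("fewer than 3 samples in a Dicer stratum", call. = FALSE)
  edge_cor <- function(s) {
    sub <- expr[, s, drop = FALSE]
    vapply(seq_len(nrow(net)), function(i)
      cor(sub[net$mrna[i], ], sub[net$lncrna[i], ]), numeric(1))
  }
  low_r <- edge_cor(low)
  high_r <- edge_cor(high)
  p <- t.test(high_r, low_r)$p.value
  list(low_r = low_r, high_r = high_r, p_value = p,
       samples_low = low, samples_high = high)
}
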