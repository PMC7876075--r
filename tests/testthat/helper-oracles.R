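# Exhaustive-enumeration oracle for the upper-tail miRNA-sharing
# probability: draw all size-n subsets of an m-element universe whose first
# t elements are "mRNA-interacting" and count subsets overlapping in >= r.
# Independent of the distribution-function path used by the package.
enum_hypergeom <- function(m, t, n, r) {
  if (r == 0) return(1)
  subsets <- combn(m, n)
  mean(apply(subsets, 2, function(s) sum(s <= t) >= r))
}

# All valid (m, t, n, r) parameter combinations with m <= m_max.
hypergeom_grid <- function(m_max) {
  g <- expand.grid(m = 1:m_max, t = 0:m_max, n = 0:m_max, r = 0:m_max)
  g[g$t <= g$m & g$n <= g$m & g$r <= pmin(g$t, g$n), ]
}

# Two-condition expression fixture with a chosen set of feature pairs
# correlated at r_normal in the normal samples and r_disease in the
# disease samples (shared latent factor with loading sqrt(r)).
make_diffcor_fixture <- function(pair_names_a, pair_names_b, r_normal,
                                 r_disease, n_per_condition, seed = 1L) {
  stopifnot(length(pair_names_a) == length(pair_names_b))
  set.seed(seed)
  n_tot <- 2L * n_per_condition
  samples <- sprintf("S%03d", seq_len(n_tot))
  labels <- stats::setNames(rep(c("normal", "disease"),
                                each = n_per_condition), samples)
  gen_member <- function(z, r, n) sqrt(r) * z + sqrt(1 - r) * rnorm(n)
  rows <- list()
  for (i in seq_along(pair_names_a)) {
    zn <- rnorm(n_per_condition)
    zd <- rnorm(n_per_condition)
    a <- c(gen_member(zn, r_normal, n_per_condition),
           gen_member(zd, r_disease, n_per_condition))
    b <- c(gen_member(zn, r_normal, n_per_condition),
           gen_member(zd, r_disease, n_per_condition))
    rows[[pair_names_a[i]]] <- a
    rows[[pair_names_b[i]]] <- b
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- samples
  list(expr = expr + 8, labels = labels,
       pairs = data.frame(mrna = pair_names_a, lncrna = pair_names_b,
                          stringsAsFactors = FALSE))
}
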