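#' Construct a miRNA-target interaction catalog
#'
#' An interaction catalog is the bipartite mapping from miRNAs to their
#' targets, kept separately for the two target classes (mRNA and lncRNA).
#' It defines the miRNA universe over which the hypergeometric
#' miRNA-sharing test is evaluated.
#'
#' @param mrna_edges data.frame with columns `mirna`, `target` listing
#'   miRNA-mRNA interactions.
#' @param lncrna_edges data.frame with columns `mirna`, `target` listing
#'   miRNA-lncRNA interactions.
#' @return An object of class `interaction_catalog`: a list with the
#'   deduplicated edge tables (`mrna`, `lncrna`), the miRNA universe
#'   (`mirnas`), and per-feature targeting-miRNA lookups.
#' @export
interaction_catalog <- function(mrna_edges, lncrna_edges) {
  clean <- function(df, what) {
    if (!is.data.frame(df) || !all(c("mirna", "target") %in% names(df)))
      stop(what, " edges must be a data.frame with columns mirna, target",
           call. = FALSE)
    df <- unique(data.frame(mirna = as.character(df$mirna),
                            target = as.character(df$target),
                            stringsAsFactors = FALSE))
    df <- df[order(df$mirna, df$target), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  mrna_edges <- clean(mrna_edges, "mRNA")
  lncrna_edges <- clean(lncrna_edges, "lncRNA")
  cat <- list(
    mrna = mrna_edges,
    lncrna = lncrna_edges,
    mirnas = sort(unique(c(mrna_edges$mirna, lncrna_edges$mirna))),
    mirnas_by_mrna = split(mrna_edges$mirna, mrna_edges$target),
    mirnas_by_lncrna = split(lncrna_edges$mirna, lncrna_edges$target)
  )
  class(cat) <- "interaction_catalog"
  cat
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat("interaction_catalog:", length(x$mirnas), "miRNAs;",
      length(x$mirnas_by_mrna), "mRNAs (", nrow(x$mrna), "interactions );",
      length(x$mirnas_by_lncrna), "lncRNAs (", nrow(x$lncrna),
      "interactions )\n")
  invisible(x)
}

#' miRNAs shared by an mRNA and a lncRNA
#'
#' The set intersection of the miRNAs targeting the mRNA and those
#' targeting the lncRNA -- the quantity the hypergeometric sharing test
#' scores.
#'
#' @param catalog An `interaction_catalog`.
#' @param mrna,lncrna Feature identifiers present in the catalog.
#' @return Character vector of shared miRNA ids (possibly empty).
#' @export
shared_mirnas <- function(catalog, mrna, lncrna) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  a <- catalog$mirnas_by_mrna[[mrna]]
  if (is.null(a)) stop("unknown mRNA id: ", mrna, call. = FALSE)
  b <- catalog$mirnas_by_lncrna[[lncrna]]
  if (is.null(b)) stop("unknown lncRNA id: ", lncrna, call. = FALSE)
  sort(intersect(a, b))
}

# Sparse miRNA x target incidence matrix for one target class.
catalog_incidence <- function(catalog, class = c("mrna", "lncrna")) {
  class <- match.arg(class)
  edges <- catalog[[class]]
  targets <- sort(unique(edges$target))
  Matrix::sparseMatrix(
    i = match(edges$mirna, catalog$mirnas),
    j = match(edges$target, targets),
    x = 1,
    dims = c(length(catalog$mirnas), length(targets)),
    dimnames = list(catalog$mirnas, targets)
  )
}
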