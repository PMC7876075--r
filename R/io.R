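#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds feature ids and
#' whose header row holds sample ids; all cells numeric and complete.
#'
#' @param path Path to the TSV file.
#' @return Features x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a feature-id column plus >= 1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric or missing value at row '", ids[bad[1]],
           "', column '", names(vals)[j], "'", call. = FALSE)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  check_expression(m)
}

#' Write an expression matrix as TSV
#'
#' @param expr Features x samples numeric matrix.
#' @param path Output path.
#' @param id_column Name of the feature-id column (default "feature").
#' @export
write_expression <- function(expr, path, id_column = "feature") {
  check_expression(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write per-sample condition labels (two-column TSV)
#'
#' @param path Path to a TSV with columns `sample`, `condition`.
#' @return Named character vector (names = sample ids).
#' @export
read_labels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop("labels TSV must have columns 'sample' and 'condition'",
         call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in labels file", call. = FALSE)
  setNames(as.character(df$condition), as.character(df$sample))
}

#' @rdname read_labels
#' @param labels Named condition vector.
#' @export
write_labels <- function(labels, path) {
  write.table(data.frame(sample = names(labels),
                         condition = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction catalog from two-column TSVs
#'
#' Each file is a starBase-like two-column table (miRNA id, target id) with
#' a header row; rows are deduplicated.
#'
#' @param mrna_path Path for miRNA-mRNA interactions.
#' @param lncrna_path Path for miRNA-lncRNA interactions.
#' @return An `interaction_catalog`.
#' @export
read_catalog <- function(mrna_path, lncrna_path) {
  read_edges <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      stop("interaction TSV '", path, "' must have two columns ",
           "(miRNA, target)", call. = FALSE)
    bad <- which(!nzchar(df[[1]]) | !nzchar(df[[2]]) |
                   is.na(df[[1]]) | is.na(df[[2]]))
    if (length(bad))
      stop("malformed interaction row at line ", bad[1] + 1L, " of '",
           path, "'", call. = FALSE)
    data.frame(mirna = as.character(df[[1]]), target = as.character(df[[2]]),
               stringsAsFactors = FALSE)
  }
  interaction_catalog(read_edges(mrna_path), read_edges(lncrna_path))
}

#' Write an interaction catalog as two two-column TSVs
#'
#' @param catalog An `interaction_catalog`.
#' @param mrna_path,lncrna_path Output paths per target class.
#' @export
write_catalog <- function(catalog, mrna_path, lncrna_path) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  write.table(catalog$mrna, mrna_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(catalog$lncrna, lncrna_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(mrna_path, lncrna_path))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
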