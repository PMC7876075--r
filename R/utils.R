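#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test median p.adjust phyper pt rnorm runif sd t.test setNames predict
#' @importFrom utils combn write.table read.delim head
NULL

# Derive a per-stage RNG seed from the global seed. Keeps substreams for
# different pipeline stages independent while remaining a pure function of
# (seed, stage). Result stays inside the 32-bit integer range.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 7919 * h) %% .Machine$integer.max)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library users' random streams are untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Validate an expression matrix: numeric, finite, named rows (features) and
# columns (samples), no duplicated ids.
check_expression <- function(expr, what = "expression matrix") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop(what, " must be a numeric matrix (features x samples)", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop(what, " must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate feature ids in ", what, call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample ids in ", what, call. = FALSE)
  if (any(!is.finite(expr)))
    stop(what, " contains missing or non-finite values", call. = FALSE)
  invisible(expr)
}

# Validate condition labels against an expression matrix; returns the labels
# reordered to match the matrix columns.
check_labels <- function(labels, expr) {
  if (is.null(names(labels)))
    stop("labels must be a named vector (names = sample ids)", call. = FALSE)
  labels <- setNames(as.character(labels), names(labels))
  missing <- setdiff(colnames(expr), names(labels))
  if (length(missing))
    stop("no condition label for sample(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  labels[colnames(expr)]
}

# Samples belonging to one condition, in matrix column order.
condition_samples <- function(expr, labels, condition) {
  labels <- check_labels(labels, expr)
  smp <- colnames(expr)[labels == condition]
  if (!length(smp))
    stop("no samples with condition '", condition, "'", call. = FALSE)
  smp
}
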