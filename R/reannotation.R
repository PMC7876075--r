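#' Map array probes to transcripts by exact sequence match
#'
#' A probe maps to a transcript when it occurs as an exact substring of the
#' transcript sequence (mismatches fixed at 0). U is normalized to T before
#' matching. By default the given strand only is searched; set
#' `reverse_complement = TRUE` to also match a probe's reverse complement.
#'
#' @param probes,transcripts [Biostrings::DNAStringSet] (or named character
#'   vectors) of probe and transcript sequences.
#' @param max_mismatch Allowed mismatches; only 0 is supported.
#' @param reverse_complement Also match reverse-complemented probes.
#' @return An object of class `probe_map`: list with `matches` (data.frame
#'   probe, feature), `probe_to_features` (named list), `support` (named
#'   integer: unambiguous supporting-probe count per feature) and
#'   `ambiguous` (probe ids matching more than one feature).
#' @export
map_probes <- function(probes, transcripts, max_mismatch = 0,
                       reverse_complement = FALSE) {
  if (max_mismatch != 0)
    stop("only exact matching (max_mismatch = 0) is supported", call. = FALSE)
  as_dss <- function(x, what) {
    if (!length(x)) stop("empty ", what, " set", call. = FALSE)
    nm <- names(x)
    x <- Biostrings::DNAStringSet(gsub("U", "T", toupper(as.character(x))))
    if (!is.null(nm)) names(x) <- nm
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, " sequences must be named", call. = FALSE)
    x
  }
  probes <- as_dss(probes, "probe")
  transcripts <- as_dss(transcripts, "transcript")

  hit <- matrix(FALSE, length(probes), length(transcripts),
                dimnames = list(names(probes), names(transcripts)))
  for (i in seq_along(probes)) {
    hit[i, ] <- Biostrings::vcountPattern(probes[[i]], transcripts,
                                          fixed = FALSE) > 0
    if (reverse_complement) {
      rc <- Biostrings::reverseComplement(probes[[i]])
      hit[i, ] <- hit[i, ] |
        Biostrings::vcountPattern(rc, transcripts, fixed = FALSE) > 0
    }
  }
  w <- which(hit, arr.ind = TRUE)
  matches <- data.frame(probe = rownames(hit)[w[, 1]],
                        feature = colnames(hit)[w[, 2]],
                        stringsAsFactors = FALSE)
  matches <- matches[order(matches$probe, matches$feature), , drop = FALSE]
  rownames(matches) <- NULL
  probe_to_features <- split(matches$feature, matches$probe)
  n_per_probe <- lengths(probe_to_features)
  ambiguous <- names(n_per_probe)[n_per_probe > 1L]
  unamb <- matches[!(matches$probe %in% ambiguous), , drop = FALSE]
  support <- table(factor(unamb$feature, levels = colnames(hit)))
  out <- list(matches = matches, probe_to_features = probe_to_features,
              support = setNames(as.integer(support), names(support)),
              ambiguous = ambiguous)
  class(out) <- "probe_map"
  out
}

#' Select transcripts with sufficient unambiguous probe support
#'
#' A transcript is considered successfully re-annotated only when at least
#' `min_probes` unambiguous probes match it (default 11, the conventional
#' support threshold for array re-annotation).
#'
#' @param map A `probe_map` from [map_probes()].
#' @param min_probes Minimum supporting probe count.
#' @return Character vector of feature ids, sorted.
#' @export
select_supported_features <- function(map, min_probes = 11) {
  stopifnot(inherits(map, "probe_map"))
  sort(names(map$support)[map$support >= min_probes])
}

#' Collapse probe-level expression to feature-level expression
#'
#' Probes mapping to more than one feature are excluded outright; for each
#' remaining feature, its expression in every sample is the median over its
#' surviving probes (even counts: mean of the two central order
#' statistics). Output features are exactly those retaining at least one
#' probe.
#'
#' @param probe_expr Probes x samples numeric matrix.
#' @param probe_to_feature Either a `probe_map` or a named list/character
#'   vector mapping probe id -> feature id(s).
#' @return Features x samples numeric matrix.
#' @export
collapse_to_features <- function(probe_expr, probe_to_feature) {
  check_expression(probe_expr, "probe expression matrix")
  if (inherits(probe_to_feature, "probe_map"))
    probe_to_feature <- probe_to_feature$probe_to_features
  if (is.character(probe_to_feature))
    probe_to_feature <- as.list(probe_to_feature)
  if (is.null(names(probe_to_feature)))
    stop("probe_to_feature must be named by probe id", call. = FALSE)
  absent <- setdiff(names(probe_to_feature), rownames(probe_expr))
  if (length(absent))
    stop("probe(s) absent from expression matrix: ",
         paste(head(absent, 5), collapse = ", "), call. = FALSE)
  # multi-feature probes are dropped, not shared out
  keep <- names(probe_to_feature)[lengths(probe_to_feature) == 1L]
  feature_of <- vapply(probe_to_feature[keep], `[[`, character(1), 1L)
  by_feature <- split(keep, feature_of)
  out <- t(vapply(by_feature, function(pr)
    apply(probe_expr[pr, , drop = FALSE], 2, median),
    numeric(ncol(probe_expr))))
  colnames(out) <- colnames(probe_expr)
  out[order(rownames(out)), , drop = FALSE]
}
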