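#' Area under the ROC curve (Mann-Whitney construction)
#'
#' AUC is the probability that a randomly chosen positive sample outranks
#' a randomly chosen negative one, ties counting one half -- computed from
#' midranks, equivalent to the normalized Mann-Whitney U statistic.
#'
#' @param scores Numeric per-sample scores (higher = more disease-like).
#' @param labels Binary labels, same length; see `positive`.
#' @param positive The label value treated as the positive (disease) class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "disease") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  ranks <- rank(scores)  # midranks handle ties as 1/2
  (sum(ranks[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Enumerate all marker panels of a minimum size
#'
#' All subsets of the marker list with at least `min_size` members, in a
#' canonical deterministic order: increasing size, then lexicographic in
#' the input marker order. For `min_size = 2` the count is
#' 2^k - k - 1 (e.g. 9 markers give 502 panels).
#'
#' @param markers Character vector of distinct marker ids.
#' @param min_size Smallest panel size (default 2).
#' @return List of character vectors.
#' @export
enumerate_panels <- function(markers, min_size = 2) {
  if (anyDuplicated(markers)) stop("markers must be distinct", call. = FALSE)
  k <- length(markers)
  if (k < min_size) return(list())
  unlist(lapply(seq(min_size, k), function(s)
    combn(markers, s, simplify = FALSE)), recursive = FALSE)
}

panel_metrics <- function(predicted, truth, positive, negative) {
  tp <- sum(predicted == positive & truth == positive)
  tn <- sum(predicted == negative & truth == negative)
  fp <- sum(predicted == positive & truth == negative)
  fn <- sum(predicted == negative & truth == positive)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_correct = tp + tn, n_samples = length(truth))
}

# Stratified k-fold assignment: samples of each class are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, k, seed) {
  with_seed(substream_seed(seed, "folds"), {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Fit a linear-kernel SVM on z-scored training features and return a
# prediction closure; standardization parameters come from the training
# data only.
fit_svm_model <- function(train_x, train_y, cost = 1) {
  mu <- colMeans(train_x)
  sdev <- apply(train_x, 2, sd)
  sdev[sdev == 0] <- 1
  scale_x <- function(x) sweep(sweep(x, 2, mu), 2, sdev, "/")
  fit <- e1071::svm(scale_x(train_x), factor(train_y), kernel = "linear",
                    cost = cost, scale = FALSE)
  list(predict = function(x)
    as.character(predict(fit, scale_x(x))), fit = fit)
}

#' Cross-validated evaluation of one marker panel
#'
#' Trains a linear-kernel support-vector machine per stratified fold
#' (features z-scored with training-fold statistics only) and pools the
#' out-of-fold predictions into accuracy, sensitivity (disease recall) and
#' specificity (normal recall).
#'
#' @param expr Features x samples expression matrix containing the panel.
#' @param labels Named condition vector.
#' @param panel Character vector of marker ids.
#' @param k Number of folds (default 10).
#' @param seed Integer seed governing the fold assignment.
#' @param conditions Length-2 character: normal then disease condition.
#' @param cost SVM regularization constant (default 1).
#' @return Object of class `panel_evaluation`: list with `panel`,
#'   `accuracy`, `sensitivity`, `specificity`, `n_correct`, `n_samples`,
#'   `predictions`, `seed`.
#' @export
crossval_panel <- function(expr, labels, panel, k = 10, seed = 1L,
                           conditions = c("normal", "disease"), cost = 1) {
  check_expression(expr)
  labels <- check_labels(labels, expr)
  missing <- setdiff(panel, rownames(expr))
  if (length(missing))
    stop("panel marker(s) absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  smp <- colnames(expr)[labels %in% conditions]
  x <- t(expr[panel, smp, drop = FALSE])
  y <- labels[smp]
  fold <- stratified_folds(y, k, seed)
  pred <- character(length(y))
  for (f in seq_len(k)) {
    train <- fold != f
    if (length(unique(y[train])) < 2L)
      stop("a training fold contains a single class; use a smaller k",
           call. = FALSE)
    if (!any(!train)) next
    model <- fit_svm_model(x[train, , drop = FALSE], y[train], cost)
    pred[!train] <- model$predict(x[!train, , drop = FALSE])
  }
  m <- panel_metrics(pred, y, positive = conditions[2],
                     negative = conditions[1])
  out <- c(list(panel = panel), m,
           list(predictions = setNames(pred, smp), seed = seed))
  class(out) <- "panel_evaluation"
  out
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("panel [%s]: accuracy %.3f, sensitivity %.3f, specificity %.3f (%d/%d correct)\n",
              paste(x$panel, collapse = ";"), x$accuracy, x$sensitivity,
              x$specificity, x$n_correct, x$n_samples))
  invisible(x)
}

#' Rank panel evaluations by cross-validated accuracy
#'
#' Best first; ties broken by smaller panel size, then by canonical
#' (enumeration) order, i.e. stable with the input order.
#'
#' @param evaluations List of `panel_evaluation` objects.
#' @return The same list, reordered.
#' @export
rank_panels <- function(evaluations) {
  if (!length(evaluations)) stop("no evaluations to rank", call. = FALSE)
  acc <- vapply(evaluations, `[[`, numeric(1), "accuracy")
  size <- vapply(evaluations, function(e) length(e$panel), integer(1))
  evaluations[order(-acc, size, seq_along(evaluations))]
}

#' Validate a marker panel on an external cohort
#'
#' Refits the panel's SVM on the full training cohort and applies it
#' unchanged (including the training standardization) to the validation
#' cohort.
#'
#' @param panel Character vector of marker ids.
#' @param expr,labels Training expression matrix and condition labels.
#' @param expr2,labels2 Validation expression matrix and condition labels.
#' @param conditions,cost See [crossval_panel()].
#' @return List with `accuracy`, `sensitivity`, `specificity`, `n_correct`,
#'   `n_samples`, `predictions`.
#' @export
external_validation <- function(panel, expr, labels, expr2, labels2,
                                conditions = c("normal", "disease"),
                                cost = 1) {
  check_expression(expr, "training matrix")
  check_expression(expr2, "validation matrix")
  labels <- check_labels(labels, expr)
  labels2 <- check_labels(labels2, expr2)
  missing <- setdiff(panel, rownames(expr2))
  if (length(missing))
    stop("marker(s) missing from validation matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  smp <- colnames(expr)[labels %in% conditions]
  model <- fit_svm_model(t(expr[panel, smp, drop = FALSE]), labels[smp], cost)
  smp2 <- colnames(expr2)[labels2 %in% conditions]
  pred <- model$predict(t(expr2[panel, smp2, drop = FALSE]))
  m <- panel_metrics(pred, labels2[smp2], positive = conditions[2],
                     negative = conditions[1])
  c(m, list(predictions = setNames(pred, smp2)))
}
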