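#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns) for
#' 0-based integer class indices.
#'
#' @param y_true,y_pred equal-length integer vectors with values in
#'   `0:(K-1)`.
#' @param K number of classes.
#' @return `K x K` integer matrix; entry `(t, p)` counts samples of true
#'   class `t - 1` predicted as class `p - 1`.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) &&
      (min(y_true, y_pred) < 0 || max(y_true, y_pred) >= K))
    stop("class indices out of range [0, K)")
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  cm
}

#' Per-fold metrics from a confusion matrix
#'
#' Accuracy is trace over total. Sensitivity (recall), specificity and
#' precision are computed one-vs-rest per class and macro-averaged with
#' equal class weight, then expressed as percentages — the unweighted
#' macro average keeps minority-class performance visible. A class whose
#' denominator is zero (e.g. precision for a never-predicted class)
#' contributes nothing to that metric's macro mean, with a warning.
#'
#' @param confusion square integer matrix, rows = true class.
#' @return List of class `fold_metrics`: `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision` (percent).
#' @export
summarize_confusion <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  macro <- function(num, den, what) {
    ok <- den > 0
    if (!all(ok))
      warning(sprintf("%s undefined for class(es) %s; excluded from macro mean",
                      what, paste(which(!ok) - 1L, collapse = ", ")))
    mean(num[ok] / den[ok]) * 100
  }
  structure(
    list(confusion = cm,
         accuracy = sum(tp) / total * 100,
         sensitivity = macro(tp, tp + fn, "sensitivity"),
         specificity = macro(tn, tn + fp, "specificity"),
         precision = macro(tp, tp + fp, "precision")),
    class = "fold_metrics"
  )
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%%\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision))
  invisible(x)
}

#' Row-normalised confusion matrix
#'
#' Each row divided by its sum (rows with no samples stay zero), so rows
#' of occupied classes sum to 1.
#' @param confusion square count matrix.
#' @export
normalize_confusion <- function(confusion) {
  cm <- as.matrix(confusion)
  rs <- rowSums(cm)
  cm / ifelse(rs > 0, rs, 1)
}

#' Aggregate per-fold metrics as mean and SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' each metric across folds; a single fold reports SD 0 with a warning.
#'
#' @param results list of `fold_metrics`.
#' @return Object of class `cv_summary`: `folds` (the input), `mean` and
#'   `sd` (named vectors over the four metrics), `pooled_confusion`.
#' @export
aggregate_folds <- function(results) {
  if (length(results) == 0) stop("no fold results to aggregate")
  metrics <- c("accuracy", "sensitivity", "specificity", "precision")
  tab <- sapply(metrics, function(m)
    vapply(results, function(r) r[[m]], numeric(1)))
  tab <- matrix(tab, nrow = length(results),
                dimnames = list(NULL, metrics))
  sds <- if (nrow(tab) == 1) {
    warning("single fold: SD reported as 0")
    stats::setNames(rep(0, length(metrics)), metrics)
  } else apply(tab, 2, stats::sd)
  pooled <- Reduce(`+`, lapply(results, `[[`, "confusion"))
  structure(
    list(folds = results, per_fold = tab,
         mean = colMeans(tab), sd = sds,
         pooled_confusion = pooled),
    class = "cv_summary"
  )
}

#' @export
print.cv_summary <- function(x, digits = 2, ...) {
  cat(sprintf("%d-fold cross-validation summary\n", length(x$folds)))
  tab <- rbind(x$per_fold,
               `Mean` = x$mean,
               `SD` = x$sd)
  rownames(tab)[seq_len(nrow(x$per_fold))] <-
    paste("Fold", seq_len(nrow(x$per_fold)))
  print(round(tab, digits))
  invisible(x)
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)` for `N` samples over `K` classes with `N_c`
#' samples in class `c`; balanced classes give weight 1 everywhere and
#' `sum(N_c * w_c) = N` always. Used to scale the per-sample training
#' loss so a minority class is not drowned out.
#'
#' @param labels vector (factor, character or integer) of class tags.
#' @param classes the full configured class set; defaults to the distinct
#'   values present. Every configured class must occur at least once.
#' @return Named numeric vector of weights, one per class.
#' @export
class_weights <- function(labels, classes = sort(unique(labels))) {
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0))
    stop("class(es) with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  N <- length(labels)
  K <- length(classes)
  w <- N / (K * as.numeric(counts))
  stats::setNames(w, classes)
}
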