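#' Stratified (optionally subject-grouped) fold assignment
#'
#' Epoch-level grouping deals each class's samples round-robin into `k`
#' folds after shuffling, so per-fold class proportions stay within one
#' sample of the global proportions. Subject-level grouping deals whole
#' subjects the same way, guaranteeing that no subject's epochs span a
#' fold boundary (no subject leakage).
#'
#' @param y 0-based integer class labels per sample.
#' @param k number of folds.
#' @param subjects subject identifier per sample (required for
#'   `grouping = "subject"`).
#' @param grouping `"epoch"` or `"subject"`.
#' @param seed integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
make_folds <- function(y, k = 10, subjects = NULL,
                       grouping = c("epoch", "subject"), seed = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(seed)) set.seed(seed)
  y <- as.integer(y)
  n <- length(y)
  fold <- integer(n)
  if (grouping == "epoch") {
    if (k > n) stop("k exceeds the number of samples")
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    if (is.null(subjects)) stop("subject grouping requires `subjects`")
    subjects <- as.character(subjects)
    subj <- unique(subjects)
    if (k > length(subj)) stop("k exceeds the number of subjects")
    subj_class <- vapply(subj, function(s) y[match(s, subjects)], integer(1))
    subj_fold <- integer(length(subj))
    for (cl in unique(subj_class)) {
      idx <- sample(which(subj_class == cl))
      subj_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold <- subj_fold[match(subjects, subj)]
  }
  fold
}

#' k-fold cross-validation of the correlation-matrix CNN
#'
#' The reference protocol: the data are split into `k` stratified folds;
#' at each iteration one fold is the test set, one of the remaining folds
#' (drawn at random under the run seed) is held out as the validation set
#' for checkpointing, and the rest train the model. The checkpointed
#' (best-validation) weights evaluate the test fold. Metrics per fold are
#' the confusion matrix, accuracy, and macro one-vs-rest sensitivity,
#' specificity and precision.
#'
#' @param x `H x W x N` array of correlation matrices.
#' @param y 0-based integer class labels.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param subjects,grouping see [make_folds()]; `grouping = "subject"`
#'   keeps all epochs of a subject on one side of every split.
#' @param seed master seed; fold assignment, validation-fold draws,
#'   weight initialisation and training randomness all derive from it.
#' @param epochs,batch_size,learning_rate,class_weight forwarded to
#'   [fit.cdnet()].
#' @param restart_below validation-accuracy floor for the optimisation
#'   guard: if a fold's checkpointed validation accuracy ends at or below
#'   this value the fit is considered a failed optimisation run
#'   (collapsed to near-chance) and is retried with a fresh derived seed,
#'   at most `max_restarts` times, keeping the best-validation model.
#'   Restarts look only at validation data, never at the test fold.
#'   Default 0.5; set to 0 to disable.
#' @param max_restarts maximum refits per fold under `restart_below`.
#' @param keep_models keep each fold's trained model (for later
#'   Grad-CAM inspection of its test subjects).
#' @param verbose print a line per fold.
#' @return Object of class `cdnet_cv`: `summary` (a
#'   [aggregate_folds()] `cv_summary`), `results` (per-fold
#'   `fold_metrics`), `fold` (assignment vector), `val_fold` (validation
#'   fold per iteration), `predictions` (0-based predicted label per
#'   sample, from the fold where it was in the test set) and optionally
#'   `models`.
#' @export
cross_validate <- function(x, y, spec, k = 10, subjects = NULL,
                           grouping = c("epoch", "subject"), seed = 1,
                           epochs = spec$epochs,
                           batch_size = spec$batch_size,
                           learning_rate = spec$learning_rate,
                           class_weight = TRUE, restart_below = 0.5,
                           max_restarts = 2, keep_models = FALSE,
                           verbose = FALSE) {
  grouping <- match.arg(grouping)
  x <- as_input_cube(x, spec$input_shape)
  y <- as.integer(y)
  n <- dim(x)[3]
  stopifnot(length(y) == n)
  if (k < 3)
    stop("k must be at least 3: each iteration needs disjoint train, ",
         "validation and test folds")
  set.seed(seed)
  fold <- make_folds(y, k, subjects, grouping)
  fold_seeds <- sample.int(.Machine$integer.max, k)
  results <- vector("list", k)
  models <- if (keep_models) vector("list", k)
  val_fold <- integer(k)
  predictions <- integer(n)
  for (i in seq_len(k)) {
    others <- setdiff(seq_len(k), i)
    set.seed(fold_seeds[i])
    val_fold[i] <- sample(others, 1)
    train_idx <- which(!fold %in% c(i, val_fold[i]))
    val_idx <- which(fold == val_fold[i])
    test_idx <- which(fold == i)
    fit_once <- function(s) {
      fit(cdnet(spec, seed = s), x[, , train_idx, drop = FALSE],
          y[train_idx], x[, , val_idx, drop = FALSE], y[val_idx],
          epochs = epochs, batch_size = batch_size,
          learning_rate = learning_rate, class_weight = class_weight,
          seed = s)
    }
    model <- fit_once(fold_seeds[i])
    attempts <- 0
    while (model$checkpoint$val_accuracy <= restart_below &&
           attempts < max_restarts) {
      attempts <- attempts + 1
      if (verbose)
        message(sprintf(
          "fold %d: validation accuracy %.2f <= %.2f, restart %d",
          i, model$checkpoint$val_accuracy, restart_below, attempts))
      retry <- fit_once((fold_seeds[i] + 104729 * attempts) %%
                          .Machine$integer.max)
      if (retry$checkpoint$val_accuracy > model$checkpoint$val_accuracy)
        model <- retry
    }
    pred <- predict(model, x[, , test_idx, drop = FALSE], type = "class")
    predictions[test_idx] <- pred
    results[[i]] <- summarize_confusion(
      confusion_matrix(y[test_idx], pred, spec$n_classes))
    if (keep_models) models[[i]] <- model
    if (verbose)
      message(sprintf("fold %2d/%d: test acc %.1f%% (checkpoint epoch %d)",
                      i, k, results[[i]]$accuracy, model$checkpoint$epoch))
  }
  structure(
    list(summary = aggregate_folds(results), results = results,
         fold = fold, val_fold = val_fold, predictions = predictions,
         grouping = grouping, k = k, seed = seed,
         models = models),
    class = "cdnet_cv"
  )
}

#' @export
print.cdnet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s-level folds, seed %d)\n",
              x$k, x$grouping, x$seed))
  print(x$summary)
  invisible(x)
}
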