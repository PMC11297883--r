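#' Grad-CAM heatmap for one correlation matrix
#'
#' Gradient-weighted class activation mapping on the final convolutional
#' layer: feature-map weights are the spatially averaged gradients of the
#' target-class logit with respect to the final conv activations, the
#' weighted feature-map sum is rectified (ReLU), bilinearly upsampled to
#' the model input size, and min–max normalised to \[0, 1\]. An all-zero
#' pre-normalisation map is returned as all zeros with a warning.
#'
#' @param model a [cdnet()] (checkpoint weights used when available).
#' @param x a single `H x W` correlation matrix (the model input).
#' @param target_class 0-based class whose evidence is mapped; defaults
#'   to the model's predicted class for `x`.
#' @param use `"checkpoint"` or `"final"` weights.
#' @return Object of class `gradcam_heatmap`: list with `values`
#'   (`H x W` matrix in \[0, 1\]), `target_class`, `predicted_class` and
#'   `probs`.
#' @export
gradcam <- function(model, x, target_class = NULL,
                    use = c("checkpoint", "final")) {
  stopifnot(inherits(model, "cdnet"))
  use <- match.arg(use)
  par <- model_parameters(model, use)
  x <- as.matrix(x)
  H <- model$spec$input_shape[1]
  if (nrow(x) != H || ncol(x) != H)
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 nrow(x), ncol(x), H, H))
  if (is.null(target_class)) {
    probs <- drop(cnn_predict_probs(array(x, dim = c(H, H, 1)),
                                    par$weights, par$bn_mean, par$bn_var))
    target_class <- which.max(probs) - 1L
  }
  if (target_class < 0 || target_class >= model$spec$n_classes)
    stop("target_class out of range [0, K)")
  raw <- cnn_gradcam_raw(x, par$weights, par$bn_mean, par$bn_var,
                         as.integer(target_class))
  alpha <- apply(raw$dA, 3, mean)              # spatially averaged gradients
  cam <- matrix(0, dim(raw$A)[1], dim(raw$A)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * raw$A[, , k]
  cam[cam < 0] <- 0
  up <- EBImage::resize(cam, w = H, h = H)     # bilinear upsampling
  up[up < 0] <- 0
  mx <- max(up)
  if (mx > 0) up <- up / mx
  else warning("Grad-CAM map is identically zero for this input/class")
  structure(
    list(values = up, target_class = as.integer(target_class),
         predicted_class = which.max(raw$probs) - 1L,
         probs = drop(raw$probs)),
    class = "gradcam_heatmap"
  )
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap %dx%d for class %d (predicted %d)\n",
              nrow(x$values), ncol(x$values), x$target_class,
              x$predicted_class))
  invisible(x)
}

#' Aggregate a heatmap into channel-pair attributions
#'
#' The correlation-matrix input has block structure: rows/columns
#' `[i*n, (i+1)*n)` belong to channel `i`'s `n` scales, so the heatmap
#' block `(i, j)` measures how much the correlations between channels `i`
#' and `j` drove the prediction. Each unordered pair (self-pairs
#' included) is scored by the block statistic symmetrised over `(i, j)`
#' and `(j, i)`, and pairs are ranked by descending score with ties
#' broken lexicographically.
#'
#' @param heatmap a [gradcam()] result or plain square matrix.
#' @param montage channel labels; side length must be
#'   `length(montage) * n_scales`.
#' @param n_scales scales per channel.
#' @param statistic `"mean"` (default) or `"max"` over the block.
#' @return Object of class `pair_attribution`: data.frame with columns
#'   `channel_i`, `channel_j` (labels, i <= j in montage order), `score`,
#'   sorted by rank; the score matrix is attached as attribute
#'   `"score_matrix"`.
#' @export
pair_attribution <- function(heatmap, montage = DEFAULT_MONTAGE,
                             n_scales = NULL,
                             statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  hm <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$values else
    as.matrix(heatmap)
  C <- length(montage)
  if (is.null(n_scales)) n_scales <- nrow(hm) %/% C
  if (nrow(hm) != ncol(hm) || nrow(hm) != C * n_scales)
    stop(sprintf("heatmap side %d does not equal channels (%d) x scales (%d)",
                 nrow(hm), C, n_scales))
  stat <- if (statistic == "mean") mean else max
  block <- function(i, j)
    stat(hm[((i - 1) * n_scales + 1):(i * n_scales),
            ((j - 1) * n_scales + 1):(j * n_scales)])
  pairs <- which(upper.tri(diag(C), diag = TRUE), arr.ind = TRUE)
  score <- apply(pairs, 1, function(p)
    (block(p[1], p[2]) + block(p[2], p[1])) / 2)
  out <- data.frame(
    channel_i = montage[pairs[, 1]],
    channel_j = montage[pairs[, 2]],
    i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
    score = score
  )
  # descending score; ties broken by (i, j) lexicographic order
  out <- out[order(-out$score, out$i, out$j), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  S <- matrix(NA_real_, C, C, dimnames = list(montage, montage))
  S[cbind(out$i + 1, out$j + 1)] <- out$score
  S[cbind(out$j + 1, out$i + 1)] <- out$score
  structure(out, score_matrix = S, n_scales = n_scales,
            class = c("pair_attribution", "data.frame"))
}

#' Explain one subject's epochs
#'
#' Applies Grad-CAM to every epoch of a subject, aggregates each heatmap
#' into channel-pair attributions, and forms a consensus ranking: each
#' pair's consensus score is its mean rank across epochs (smaller =
#' more consistently important), ranked ascending with lexicographic
#' tie-break.
#'
#' @param model a trained [cdnet()].
#' @param epochs_x `H x W x n_epochs` array (or list) of the subject's
#'   correlation matrices.
#' @param target_class 0-based class to explain; `NULL` explains each
#'   epoch's predicted class.
#' @param montage,n_scales,statistic see [pair_attribution()].
#' @return Object of class `subject_explanation`: list with
#'   `per_epoch` (list of `pair_attribution`), `consensus` (data.frame
#'   with mean rank and consensus rank per pair) and `heatmaps`.
#' @export
explain_subject <- function(model, epochs_x, target_class = NULL,
                            montage = DEFAULT_MONTAGE, n_scales = NULL,
                            statistic = "mean") {
  x <- as_input_cube(epochs_x, model$spec$input_shape)
  n_ep <- dim(x)[3]
  if (n_ep == 0) stop("no epochs to explain")
  heatmaps <- vector("list", n_ep)
  attrs <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    heatmaps[[e]] <- gradcam(model, x[, , e], target_class)
    attrs[[e]] <- pair_attribution(heatmaps[[e]], montage, n_scales,
                                   statistic)
  }
  base <- attrs[[1]][order(attrs[[1]]$i, attrs[[1]]$j), ]
  ranks <- sapply(attrs, function(a) {
    a <- a[order(a$i, a$j), ]
    a$rank
  })
  ranks <- matrix(ranks, nrow = nrow(base))
  consensus <- data.frame(
    channel_i = base$channel_i, channel_j = base$channel_j,
    i = base$i, j = base$j,
    mean_rank = rowMeans(ranks),
    mean_score = rowMeans(sapply(attrs, function(a) {
      a <- a[order(a$i, a$j), ]; a$score
    }))
  )
  consensus <- consensus[order(consensus$mean_rank, consensus$i, consensus$j), ]
  consensus$rank <- seq_len(nrow(consensus))
  rownames(consensus) <- NULL
  structure(
    list(per_epoch = attrs, consensus = consensus, heatmaps = heatmaps),
    class = "subject_explanation"
  )
}

#' @export
print.subject_explanation <- function(x, n = 5, ...) {
  cat(sprintf("Grad-CAM explanation over %d epoch(s); top pairs:\n",
              length(x$per_epoch)))
  print(utils::head(x$consensus[, c("channel_i", "channel_j", "mean_rank",
                                    "mean_score")], n), row.names = FALSE)
  invisible(x)
}

#' Render a heatmap PNG with channel-block gridlines
#'
#' Writes the heatmap with gridlines every `n_scales` rows/columns and
#' montage labels on both axes, the reading aid for locating channel-pair
#' blocks by eye.
#'
#' @param heatmap a [gradcam()] result or square matrix.
#' @param path output PNG path.
#' @param montage channel labels.
#' @param n_scales scales per channel block.
#' @export
plot_heatmap <- function(heatmap, path, montage = DEFAULT_MONTAGE,
                         n_scales = NULL) {
  hm <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$values else
    as.matrix(heatmap)
  C <- length(montage)
  if (is.null(n_scales)) n_scales <- nrow(hm) %/% C
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(5, 5, 2, 1))   # device-local; dies with dev.off()
  # image() draws x right, y up; flip rows so row 1 is at the top
  graphics::image(seq_len(ncol(hm)), seq_len(nrow(hm)),
                  t(hm[rev(seq_len(nrow(hm))), ]),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "", ylab = "", axes = FALSE, useRaster = TRUE)
  at <- (seq_len(C) - 0.5) * n_scales
  graphics::axis(1, at = at, labels = montage, las = 2, tick = FALSE)
  graphics::axis(2, at = rev(at), labels = montage, las = 1, tick = FALSE)
  graphics::abline(v = seq(0, C) * n_scales + 0.5,
                   h = seq(0, C) * n_scales + 0.5, col = "grey40")
  invisible(path)
}
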