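#' Fit a model
#'
#' Generic; see [fit.cdnet()].
#' @param object model object.
#' @param ... passed to methods.
#' @export
fit <- function(object, ...) UseMethod("fit")

# Adam moment state matching the weight structure
adam_state <- function(w) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(w), v = zero_like(w), t = 0L)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  upd <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- list(w = w, m = m, v = v)
      for (nm in names(w)) {
        r <- upd(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$w[[nm]] <- r$w; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      if (is.null(names(w))) {          # unnamed list (conv blocks)
        for (i in seq_along(w)) {
          r <- upd(w[[i]], g[[i]], m[[i]], v[[i]])
          out$w[[i]] <- r$w; out$m[[i]] <- r$m; out$v[[i]] <- r$v
        }
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(w = w - lr * (m / corr1) / (sqrt(v / corr2) + eps), m = m, v = v)
    }
  }
  r <- upd(w, g, st$m, st$v)
  list(w = r$w, state = list(m = r$m, v = r$v, t = st$t))
}

as_input_cube <- function(x, input_shape) {
  if (is.list(x)) x <- simplify2array(lapply(x, unclass))
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  if (dim(x)[1] != input_shape[1] || dim(x)[2] != input_shape[2])
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 dim(x)[1], dim(x)[2], input_shape[1], input_shape[2]))
  x
}

#' Train a correlation-matrix CNN
#'
#' Minibatch Adam on class-weighted sparse categorical cross-entropy,
#' with per-epoch evaluation on a held-out validation set and
#' checkpointing of the best validation weights (highest validation
#' accuracy, ties broken by lower validation loss). Class weights default
#' to inverse-frequency weights of the training labels
#' (`w_c = N / (K N_c)`).
#'
#' @param object an untrained or trained [cdnet()].
#' @param x training inputs: `H x W x N` array of correlation matrices,
#'   or a list of matrices.
#' @param y 0-based integer class labels (length N).
#' @param x_val,y_val validation set (required, non-empty, disjoint from
#'   the training set by construction of the caller's folds).
#' @param epochs,batch_size,learning_rate override the spec's budget.
#' @param class_weight `TRUE` (inverse-frequency), `FALSE` (all 1), or a
#'   numeric vector of length `n_classes`.
#' @param seed integer seed controlling shuffling, dropout and (if the
#'   model is untrained) its weight initialisation.
#' @param verbose print one line per `verbose` epochs (0 = quiet).
#' @param ... unused.
#' @return The trained `cdnet`, with `$history` (per-epoch train/val loss
#'   and accuracy) and `$checkpoint` (best validation weights).
#' @export
fit.cdnet <- function(object, x, y, x_val, y_val,
                      epochs = object$spec$epochs,
                      batch_size = object$spec$batch_size,
                      learning_rate = object$spec$learning_rate,
                      class_weight = TRUE, seed = NULL, verbose = 0, ...) {
  x <- as_input_cube(x, object$spec$input_shape)
  y <- as.integer(y)
  n <- dim(x)[3]
  if (n == 0 || length(y) != n) stop("empty training set or label mismatch")
  if (missing(x_val) || is.null(x_val))
    stop("a non-empty validation set is required for checkpointing")
  x_val <- as_input_cube(x_val, object$spec$input_shape)
  y_val <- as.integer(y_val)
  if (dim(x_val)[3] == 0) stop("validation set is empty")
  K <- object$spec$n_classes
  if (max(c(y, y_val)) >= K || min(c(y, y_val)) < 0)
    stop("labels out of range [0, K)")
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(class_weight)) {
    cw <- class_weights(y, classes = 0:(K - 1))
  } else if (isFALSE(class_weight)) {
    cw <- rep(1, K)
  } else {
    stopifnot(length(class_weight) == K)
    cw <- as.numeric(class_weight)
  }
  nfeat <- object$engine$conv_filters[length(object$engine$conv_filters)]
  p_drop <- object$engine$dropout_rate
  w <- object$weights
  bn_mean <- object$bn_mean
  bn_var <- object$bn_var
  momentum <- 0.99
  adam <- adam_state(w)
  hist <- matrix(NA_real_, epochs, 4,
                 dimnames = list(NULL, c("loss", "accuracy",
                                         "val_loss", "val_accuracy")))
  best <- list(val_accuracy = -Inf, val_loss = Inf)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      nb <- length(idx)
      mask <- matrix((stats::runif(nfeat * nb) >= p_drop) / (1 - p_drop),
                     nfeat, nb)
      res <- cnn_batch(x[, , idx, drop = FALSE], y[idx], w,
                       bn_mean, bn_var, mask, cw[y[idx] + 1],
                       TRUE, TRUE)
      st <- adam_step(w, res$grads, adam, learning_rate)
      w <- st$w; adam <- st$state
      bn_mean <- momentum * bn_mean + (1 - momentum) * res$bn_mean
      bn_var <- momentum * bn_var + (1 - momentum) * res$bn_var
      ep_loss <- ep_loss + res$loss * nb
      ep_correct <- ep_correct + sum(max.col(t(res$probs), "first") - 1 == y[idx])
    }
    val <- evaluate_probs(cnn_predict_probs(x_val, w, bn_mean, bn_var), y_val)
    hist[ep, ] <- c(ep_loss / n, ep_correct / n, val$loss, val$accuracy)
    if (val$accuracy > best$val_accuracy ||
        (val$accuracy == best$val_accuracy && val$loss < best$val_loss)) {
      best <- list(weights = w, bn_mean = bn_mean, bn_var = bn_var,
                   epoch = ep, val_accuracy = val$accuracy,
                   val_loss = val$loss)
    }
    if (verbose > 0 && (ep %% verbose == 0 || ep == epochs))
      message(sprintf("epoch %3d/%d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                      ep, epochs, hist[ep, 1], hist[ep, 2],
                      hist[ep, 3], hist[ep, 4]))
  }
  object$weights <- w
  object$bn_mean <- bn_mean
  object$bn_var <- bn_var
  object$history <- as.data.frame(hist)
  object$checkpoint <- best
  object$class_weights <- cw
  object$trained <- TRUE
  object
}

# mean unweighted cross-entropy and accuracy from a K x N probability matrix
evaluate_probs <- function(probs, y) {
  n <- ncol(probs)
  picked <- probs[cbind(y + 1, seq_len(n))]
  list(loss = mean(-log(pmax(picked, 1e-300))),
       accuracy = mean(max.col(t(probs), "first") - 1 == y))
}

#' Predict from a correlation-matrix CNN
#'
#' @param object a [cdnet()].
#' @param x `H x W x N` array (or single matrix, or list of matrices).
#' @param type `"prob"` for the N x K probability matrix, `"class"` for
#'   0-based argmax labels (ties to the lowest class index).
#' @param use `"checkpoint"` (default; best validation weights when the
#'   model was trained) or `"final"` weights.
#' @param ... unused.
#' @export
predict.cdnet <- function(object, x, type = c("prob", "class"),
                          use = c("checkpoint", "final"), ...) {
  type <- match.arg(type)
  use <- match.arg(use)
  par <- model_parameters(object, use)
  x <- as_input_cube(x, object$spec$input_shape)
  probs <- t(cnn_predict_probs(x, par$weights, par$bn_mean, par$bn_var))
  colnames(probs) <- paste0("class", 0:(object$spec$n_classes - 1))
  if (type == "prob") probs else max.col(probs, "first") - 1L
}

# resolve checkpoint vs final parameter set
model_parameters <- function(object, use = "checkpoint") {
  if (use == "checkpoint" && !is.null(object$checkpoint$weights)) {
    list(weights = object$checkpoint$weights,
         bn_mean = object$checkpoint$bn_mean,
         bn_var = object$checkpoint$bn_var)
  } else {
    list(weights = object$weights, bn_mean = object$bn_mean,
         bn_var = object$bn_var)
  }
}

#' Plot training history
#'
#' Loss and accuracy per epoch for the training and validation sets, with
#' the checkpointed epoch marked.
#' @param x a trained [cdnet()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cdnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(cbind(h$accuracy, h$val_accuracy), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", ...)
  if (!is.null(x$checkpoint))
    graphics::abline(v = x$checkpoint$epoch, lty = 3)
  invisible(x)
}
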