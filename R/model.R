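#' Single layer specification
#'
#' One row of a network description. Supported kinds: `conv2d` (needs
#' `filters`, `kernel`), `maxpool2d` (needs `pool`), `globalmaxpool2d`,
#' `dropout` (needs `rate`), `dense` (needs `units`), `batchnorm`,
#' `softmax_dense` (needs `units`).
#'
#' @param kind layer kind (see above).
#' @param filters,kernel,pool,units,rate kind-specific parameters.
#' @return Object of class `layer_spec`.
#' @export
layer_spec <- function(kind = c("conv2d", "maxpool2d", "globalmaxpool2d",
                                "dropout", "dense", "batchnorm",
                                "softmax_dense"),
                       filters = NULL, kernel = NULL, pool = NULL,
                       units = NULL, rate = NULL) {
  kind <- match.arg(kind)
  need <- function(x, nm)
    if (is.null(x)) stop(sprintf("layer kind '%s' requires `%s`", kind, nm))
  switch(kind,
    conv2d = { need(filters, "filters"); need(kernel, "kernel") },
    maxpool2d = need(pool, "pool"),
    dropout = need(rate, "rate"),
    dense = , softmax_dense = need(units, "units"),
    NULL)
  structure(list(kind = kind, filters = filters, kernel = kernel,
                 pool = pool, units = units, rate = rate),
            class = "layer_spec")
}

#' Default layer stack
#'
#' The reference 15-layer architecture: five conv(3x3, 'same') + maxpool
#' (2x2, stride 2) blocks with 8/16/32/64/128 filters, global max
#' pooling, dropout, a 32-unit ReLU dense layer, batch normalisation and
#' a softmax output. On a 360x360x1 input the spatial trace is
#' 360-180-90-45-22-11 and the pooled feature vector has length 128.
#'
#' @param conv_filters filter counts of the conv blocks.
#' @param kernel odd conv kernel size.
#' @param dense_units hidden dense width.
#' @param n_classes softmax output width.
#' @param dropout_rate dropout fraction before the dense layers.
#' @return List of [layer_spec()] rows.
#' @export
default_layers <- function(conv_filters = c(8, 16, 32, 64, 128), kernel = 3,
                           dense_units = 32, n_classes = 3,
                           dropout_rate = 0.2) {
  layers <- list()
  for (f in conv_filters) {
    layers <- c(layers, list(
      layer_spec("conv2d", filters = f, kernel = kernel),
      layer_spec("maxpool2d", pool = 2)))
  }
  c(layers, list(
    layer_spec("globalmaxpool2d"),
    layer_spec("dropout", rate = dropout_rate),
    layer_spec("dense", units = dense_units),
    layer_spec("batchnorm"),
    layer_spec("softmax_dense", units = n_classes)))
}

#' Layer-by-layer output shape trace
#'
#' Pure shape arithmetic over a layer list: 'same'-padded convolution
#' preserves the spatial size, 2x2 pooling floor-divides it, global max
#' pooling flattens to the channel count. Errors if a layer is
#' inconsistent with its input (e.g. dense before flattening).
#'
#' @param layers list of [layer_spec()].
#' @param input_shape `(H, W, C)` of the input image.
#' @return data.frame with one row per layer: `no`, `layer` and `output`
#'   (shape string); the full shapes are in attribute `"shapes"`.
#' @export
shape_trace <- function(layers, input_shape = c(360, 360, 1)) {
  shp <- as.integer(input_shape)
  rows <- character(length(layers))
  kinds <- character(length(layers))
  shapes <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    kinds[i] <- l$kind
    shp <- switch(l$kind,
      conv2d = {
        if (length(shp) != 3) stop("conv2d needs a 3-d input, layer ", i)
        if (l$kernel %% 2 != 1) stop("conv kernel must be odd, layer ", i)
        c(shp[1], shp[2], l$filters)
      },
      maxpool2d = {
        if (length(shp) != 3) stop("maxpool2d needs a 3-d input, layer ", i)
        if (shp[1] < l$pool || shp[2] < l$pool)
          stop("pool window exceeds feature map, layer ", i)
        c(shp[1] %/% l$pool, shp[2] %/% l$pool, shp[3])
      },
      globalmaxpool2d = {
        if (length(shp) != 3) stop("globalmaxpool2d needs a 3-d input, layer ", i)
        shp[3]
      },
      dropout = shp,
      batchnorm = shp,
      dense = ,
      softmax_dense = {
        if (length(shp) != 1) stop("dense needs a flat input, layer ", i)
        l$units
      })
    shp <- as.integer(shp)
    shapes[[i]] <- shp
    rows[i] <- paste(shp, collapse = " x ")
  }
  out <- data.frame(no = seq_along(layers), layer = kinds, output = rows)
  attr(out, "shapes") <- shapes
  out
}

#' Model specification
#'
#' Aggregates the layer stack and the training hyperparameters. Defaults
#' reproduce the reference configuration: the [default_layers()] stack on
#' a 360x360x1 input, Adam with learning rate 1e-4, sparse categorical
#' cross-entropy, 700 epochs, batch size 15, dropout 0.2, three classes.
#' Scaled-down studies pass smaller `input_shape`, `conv_filters`,
#' `epochs` etc.
#'
#' @param input_shape `(H, W, 1)`; H must equal W.
#' @param conv_filters,kernel,dense_units,dropout_rate architecture knobs
#'   forwarded to [default_layers()]; ignored when `layers` is given.
#' @param layers explicit layer list overriding the default stack.
#' @param n_classes number of classes.
#' @param learning_rate,epochs,batch_size Adam training budget.
#' @return Object of class `cdnet_spec`.
#' @export
model_spec <- function(input_shape = c(360, 360, 1),
                       conv_filters = c(8, 16, 32, 64, 128), kernel = 3,
                       dense_units = 32, dropout_rate = 0.2, n_classes = 3,
                       layers = NULL, learning_rate = 1e-4, epochs = 700,
                       batch_size = 15) {
  if (length(input_shape) == 2) input_shape <- c(input_shape, 1)
  stopifnot(length(input_shape) == 3, input_shape[1] == input_shape[2],
            input_shape[3] == 1, dropout_rate >= 0, dropout_rate < 1)
  if (is.null(layers))
    layers <- default_layers(conv_filters, kernel, dense_units, n_classes,
                             dropout_rate)
  trace <- shape_trace(layers, input_shape)   # validates the stack
  last <- layers[[length(layers)]]
  if (last$kind != "softmax_dense")
    stop("final layer must be softmax_dense")
  structure(
    list(input_shape = as.integer(input_shape), layers = layers,
         n_classes = last$units,
         loss = "sparse_categorical_crossentropy",
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), trace = trace),
    class = "cdnet_spec"
  )
}

#' @export
print.cdnet_spec <- function(x, ...) {
  cat(sprintf("CNN spec on %s input, %d classes\n",
              paste(x$input_shape, collapse = "x"), x$n_classes))
  print(x$trace, row.names = FALSE)
  cat(sprintf("Adam lr %g, %s, %d epochs, batch %d\n",
              x$learning_rate, x$loss, x$epochs, x$batch_size))
  invisible(x)
}

# Decompose a layer list into the compact engine form:
# (conv_filters, kernel, dropout_rate, dense_units, n_classes).
# The engine supports the conv+pool blocks -> GMP -> dropout -> dense ->
# batchnorm -> softmax family; anything else errors here.
engine_config <- function(layers) {
  kinds <- vapply(layers, `[[`, "", "kind")
  n <- length(kinds)
  tail_kinds <- c("globalmaxpool2d", "dropout", "dense", "batchnorm",
                  "softmax_dense")
  if (n < 7 || !identical(kinds[(n - 4):n], tail_kinds))
    stop("unsupported architecture: expected conv/pool blocks followed by ",
         paste(tail_kinds, collapse = ", "))
  body <- kinds[seq_len(n - 5)]
  if (length(body) %% 2 != 0 ||
      !all(body[c(TRUE, FALSE)] == "conv2d") ||
      !all(body[c(FALSE, TRUE)] == "maxpool2d"))
    stop("unsupported architecture: body must alternate conv2d / maxpool2d")
  convs <- layers[which(kinds == "conv2d")]
  kernels <- vapply(convs, `[[`, numeric(1), "kernel")
  if (length(unique(kernels)) != 1 || kernels[1] %% 2 != 1)
    stop("conv kernels must share one odd size")
  pools <- vapply(layers[which(kinds == "maxpool2d")], `[[`, numeric(1), "pool")
  if (any(pools != 2)) stop("only 2x2 pooling is supported")
  list(conv_filters = vapply(convs, `[[`, numeric(1), "filters"),
       kernel = kernels[1],
       dropout_rate = layers[[n - 3]]$rate,
       dense_units = layers[[n - 2]]$units,
       n_classes = layers[[n]]$units)
}

# He-normal weight initialisation from the current R RNG stream
init_weights <- function(cfg) {
  k <- cfg$kernel
  cin <- 1
  conv <- vector("list", length(cfg$conv_filters))
  for (l in seq_along(cfg$conv_filters)) {
    cout <- cfg$conv_filters[l]
    conv[[l]] <- list(
      W = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                dim = c(k, k, cin, cout)),
      b = numeric(cout))
    cin <- cout
  }
  nfeat <- cin
  list(conv = conv,
       W1 = matrix(stats::rnorm(cfg$dense_units * nfeat,
                                sd = sqrt(2 / nfeat)),
                   cfg$dense_units, nfeat),
       b1 = numeric(cfg$dense_units),
       gamma = rep(1, cfg$dense_units),
       beta = numeric(cfg$dense_units),
       W2 = matrix(stats::rnorm(cfg$n_classes * cfg$dense_units,
                                sd = sqrt(2 / cfg$dense_units)),
                   cfg$n_classes, cfg$dense_units),
       b2 = numeric(cfg$n_classes))
}

#' Build an (untrained) correlation-matrix CNN
#'
#' Instantiates the network described by a [model_spec()]: validates the
#' layer stack against the engine's architecture family, traces shapes,
#' and draws He-normal initial weights from the current RNG stream. The
#' returned model already predicts (softmax probabilities from the
#' random weights); call [fit()] to train it.
#'
#' @param spec a [model_spec()].
#' @param seed optional integer seed for the weight initialisation.
#' @return Object of class `cdnet`.
#' @examples
#' m <- cdnet(model_spec(input_shape = c(96, 96, 1),
#'                       conv_filters = c(4, 8)), seed = 1)
#' m
#' @export
cdnet <- function(spec = model_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cdnet_spec"))
  cfg <- engine_config(spec$layers)
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(spec = spec, engine = cfg,
         weights = init_weights(cfg),
         bn_mean = numeric(cfg$dense_units),
         bn_var = rep(1, cfg$dense_units),
         history = NULL, checkpoint = NULL, trained = FALSE),
    class = "cdnet"
  )
}

#' @export
print.cdnet <- function(x, ...) {
  npar <- sum(rapply(x$weights, length, how = "unlist"))
  cat(sprintf("<cdnet> %strained CNN, input %s, %d classes, %d parameters\n",
              if (x$trained) "" else "un",
              paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_classes, npar))
  if (!is.null(x$history)) {
    h <- x$history
    best <- if (!is.null(x$checkpoint)) x$checkpoint$epoch else nrow(h)
    cat(sprintf("  %d epochs trained; checkpoint at epoch %d (val acc %.3f)\n",
                nrow(h), best,
                if (!is.null(x$checkpoint)) x$checkpoint$val_accuracy else NA))
  }
  invisible(x)
}

#' @export
summary.cdnet <- function(object, ...) {
  print(object)
  print(object$spec$trace, row.names = FALSE)
  invisible(object)
}

#' @export
coef.cdnet <- function(object, ...) object$weights
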