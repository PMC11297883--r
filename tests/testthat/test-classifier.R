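test_that("the default network's shape trace matches the reference table", {
  tr <- shape_trace(default_layers(), c(360, 360, 1))
  expect_equal(tr$output, c(
    "360 x 360 x 8", "180 x 180 x 8",
    "180 x 180 x 16", "90 x 90 x 16",
    "90 x 90 x 32", "45 x 45 x 32",
    "45 x 45 x 64", "22 x 22 x 64",
    "22 x 22 x 128", "11 x 11 x 128",
    "128", "128", "32", "32", "3"))
  # pooled feature vector after global max pooling has length 128
  expect_equal(attr(tr, "shapes")[[11]], 128L)
})

test_that("shape arithmetic generalises to other input sizes", {
  tr <- shape_trace(default_layers(), c(96, 96, 1))
  spatial <- vapply(attr(tr, "shapes")[seq(2, 10, 2)], `[[`, 0L, 1)
  expect_equal(spatial, c(48L, 24L, 12L, 6L, 3L))
  expect_equal(attr(tr, "shapes")[[11]], 128L)
})

test_that("inconsistent layer stacks fail at construction", {
  expect_error(shape_trace(list(layer_spec("dense", units = 4)),
                           c(8, 8, 1)), "flat input")
  expect_error(
    shape_trace(c(default_layers(), list(layer_spec("conv2d", filters = 2,
                                                    kernel = 3))),
                c(360, 360, 1)), "3-d input")
  expect_error(layer_spec("conv2d", filters = 4), "kernel")
  bad <- default_layers()
  bad[[15]] <- layer_spec("dense", units = 3)
  expect_error(model_spec(layers = bad, input_shape = c(64, 64, 1)),
               "softmax_dense")
})

test_that("inverse-frequency class weights satisfy their identities", {
  labs <- rep(c("CD", "ADHD", "ADHD+CD"), c(128, 360, 496))
  w <- class_weights(labs)
  expect_equal(unname(w["CD"]), 2.5625)                  # 984 / (3 * 128)
  expect_equal(unname(w["ADHD"]), 984 / 1080)            # 0.9111...
  expect_equal(unname(w["ADHD+CD"]), 984 / 1488)         # 0.6613...
  counts <- table(labs)[names(w)]
  expect_equal(sum(as.numeric(counts) * w), length(labs))
  expect_equal(unname(class_weights(rep(0:2, 5))), rep(1, 3))
  expect_error(class_weights(c("a", "a"), classes = c("a", "b")), "b")
})

test_that("an untrained model emits normalised probabilities", {
  m <- cdnet(tiny_spec(), seed = 1)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  p <- predict(m, x)
  expect_equal(dim(p), c(3, 3))
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-6)
  expect_error(predict(m, array(0, c(8, 8, 1))), "expects")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  m <- cdnet(tiny_spec(side = 12), seed = 7)
  N <- 4
  X <- array(rnorm(12 * 12 * N), c(12, 12, N))
  y <- c(0L, 1L, 2L, 1L)
  mask <- matrix(1, 4, N)
  sw <- c(1.3, 0.8, 1.1, 0.8)
  res <- cwtnet:::cnn_batch(X, y, m$weights, m$bn_mean, m$bn_var, mask, sw,
                            TRUE, TRUE)
  lossfn <- function(w) cwtnet:::cnn_batch(X, y, w, m$bn_mean, m$bn_var,
                                           mask, sw, TRUE, FALSE)$loss
  eps <- 1e-6
  numdiff <- function(bump) {
    (lossfn(bump(m$weights, eps)) - lossfn(bump(m$weights, -eps))) / (2 * eps)
  }
  checks <- list(
    list(bump = function(w, e) { w$conv[[1]]$W[14] <- w$conv[[1]]$W[14] + e; w },
         g = res$grads$conv[[1]]$W[14]),
    list(bump = function(w, e) { w$conv[[2]]$W[50] <- w$conv[[2]]$W[50] + e; w },
         g = res$grads$conv[[2]]$W[50]),
    list(bump = function(w, e) { w$W1[7] <- w$W1[7] + e; w },
         g = res$grads$W1[7]),
    list(bump = function(w, e) { w$gamma[2] <- w$gamma[2] + e; w },
         g = res$grads$gamma[2]),
    list(bump = function(w, e) { w$beta[4] <- w$beta[4] + e; w },
         g = res$grads$beta[4]),
    list(bump = function(w, e) { w$W2[5] <- w$W2[5] + e; w },
         g = res$grads$W2[5]),
    list(bump = function(w, e) { w$b2[3] <- w$b2[3] + e; w },
         g = res$grads$b2[3]))
  for (ch in checks) expect_equal(ch$g, numdiff(ch$bump), tolerance = 1e-5)
})

test_that("per-sample weights of one reproduce the unweighted loss exactly", {
  set.seed(5)
  m <- cdnet(tiny_spec(), seed = 2)
  X <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  y <- rep(0:2, 2)
  mask <- matrix(1, 4, 6)
  a <- cwtnet:::cnn_batch(X, y, m$weights, m$bn_mean, m$bn_var, mask,
                          rep(1, 6), TRUE, TRUE)
  manual <- mean(-log(a$probs[cbind(y + 1, 1:6)]))
  expect_identical(a$loss, manual)
  # and class_weight = FALSE vs explicit unit weights give identical fits
  f1 <- fit(cdnet(tiny_spec(epochs = 2), seed = 3), X[, , 1:4], y[1:4],
            X[, , 5:6], y[5:6], class_weight = FALSE, seed = 11)
  f2 <- fit(cdnet(tiny_spec(epochs = 2), seed = 3), X[, , 1:4], y[1:4],
            X[, , 5:6], y[5:6], class_weight = c(1, 1, 1), seed = 11)
  expect_identical(f1$history, f2$history)
})

test_that("training separates constant-block toy classes", {
  set.seed(21)
  mk <- function(cls) {
    m <- matrix(0, 16, 16)
    if (cls == 0) m[1:6, 1:6] <- 1 else m[11:16, 11:16] <- 1
    m + matrix(rnorm(256, sd = 0.05), 16)
  }
  y <- rep(0:1, each = 12)
  X <- simplify2array(lapply(y, mk))
  spec <- model_spec(input_shape = c(16, 16, 1), conv_filters = c(4, 8),
                     dense_units = 8, n_classes = 2, epochs = 30,
                     batch_size = 6, learning_rate = 1e-3)
  tr <- c(1:9, 13:21)
  val <- c(10:12, 22:24)
  m <- fit(cdnet(spec, seed = 4), X[, , tr], y[tr], X[, , val], y[val],
           seed = 8)
  # trained network classifies its training data perfectly (eval mode)
  expect_equal(mean(predict(m, X[, , tr], type = "class",
                            use = "final") == y[tr]), 1.0)
  expect_equal(utils::tail(m$history$val_accuracy, 1), 1.0)
  # checkpointed weights reproduce the recorded best validation metric
  val_probs <- predict(m, X[, , val], use = "checkpoint")
  expect_equal(mean(max.col(val_probs, "first") - 1 == y[val]),
               m$checkpoint$val_accuracy)
})

test_that("fitting is deterministic under a fixed seed", {
  set.seed(77)
  X <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y <- rep(0:1, 4)
  spec <- tiny_spec(K = 2, epochs = 3)
  m1 <- fit(cdnet(spec, seed = 5), X[, , 1:6], y[1:6], X[, , 7:8], y[7:8],
            seed = 9)
  m2 <- fit(cdnet(spec, seed = 5), X[, , 1:6], y[1:6], X[, , 7:8], y[7:8],
            seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$checkpoint$val_loss, m2$checkpoint$val_loss)
  expect_error(fit(cdnet(spec, seed = 5), X, y, NULL, NULL), "validation")
})

test_that("fold assignment is an exact stratified cover", {
  set.seed(13)
  y <- rep(0:2, c(40, 30, 30))
  fold <- make_folds(y, k = 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(unname(table(fold)), rep(10L, 10), ignore_attr = TRUE)
  # stratification within one sample of the global class proportions
  for (f in 1:10) {
    counts <- table(factor(y[fold == f], levels = 0:2))
    expect_true(all(abs(counts - c(4, 3, 3)) <= 1))
  }
  expect_error(make_folds(rep(0, 5), k = 10), "exceeds")
})

test_that("subject-grouped folds never split a subject", {
  y <- rep(rep(0:1, each = 6), each = 4)        # 12 subjects x 4 epochs
  subj <- rep(sprintf("s%02d", 1:12), each = 4)
  fold <- make_folds(y, k = 4, subjects = subj, grouping = "subject",
                     seed = 6)
  per_subj <- tapply(fold, subj, function(f) length(unique(f)))
  expect_true(all(per_subj == 1))
  expect_equal(sort(unique(fold)), 1:4)
  expect_error(make_folds(y, k = 13, subjects = subj, grouping = "subject"),
               "exceeds")
})
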