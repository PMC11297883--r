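# a small trained-ish model for Grad-CAM structural tests
gradcam_model <- function() {
  set.seed(31)
  spec <- model_spec(input_shape = c(24, 24, 1), conv_filters = c(3, 4),
                     dense_units = 6, n_classes = 3, epochs = 2,
                     batch_size = 4, learning_rate = 1e-3)
  X <- array(rnorm(24 * 24 * 8), c(24, 24, 8))
  y <- rep(0:2, length.out = 8)
  fit(cdnet(spec, seed = 2), X[, , 1:6], y[1:6], X[, , 7:8], y[7:8],
      seed = 3)
}

test_that("gradcam is deterministic, normalised and correctly shaped", {
  m <- gradcam_model()
  set.seed(32)
  x <- matrix(rnorm(24 * 24), 24)
  h1 <- gradcam(m, x, target_class = 1)
  h2 <- gradcam(m, x, target_class = 1)
  expect_identical(h1$values, h2$values)
  expect_equal(dim(h1$values), c(24, 24))
  expect_gte(min(h1$values), 0)
  expect_equal(max(h1$values), 1)
  expect_error(gradcam(m, x, target_class = 5), "range")
  expect_error(gradcam(m, matrix(0, 10, 10)), "expects")
})

test_that("gradcam gradients match finite differences through the head", {
  m <- gradcam_model()
  set.seed(33)
  x <- matrix(rnorm(24 * 24), 24)
  par <- cwtnet:::model_parameters(m, "checkpoint")
  raw <- cwtnet:::cnn_gradcam_raw(x, par$weights, par$bn_mean, par$bn_var, 2L)
  f <- function(A) cwtnet:::cnn_logits_from_conv(A, par$weights, par$bn_mean,
                                                 par$bn_var)[3]
  eps <- 1e-5
  hits <- which(raw$dA != 0)[1:5]
  for (q in hits[!is.na(hits)]) {
    A2 <- raw$A; A2[q] <- A2[q] + eps
    A3 <- raw$A; A3[q] <- A3[q] - eps
    expect_equal(raw$dA[q], (f(A2) - f(A3)) / (2 * eps), tolerance = 1e-4)
  }
  # the weighted, rectified combination matches a hand computation
  alpha <- apply(raw$dA, 3, mean)
  cam <- matrix(0, dim(raw$A)[1], dim(raw$A)[2])
  for (k in seq_along(alpha)) cam <- cam + alpha[k] * raw$A[, , k]
  cam[cam < 0] <- 0
  up <- EBImage::resize(cam, 24, 24)
  up[up < 0] <- 0
  hm <- gradcam(m, x, target_class = 2)
  expect_equal(hm$values, up / max(up), tolerance = 1e-12)
})

test_that("pair attribution scores blocks and ranks with tie-breaks", {
  C <- 12; n <- 30
  ones <- matrix(1, C * n, C * n)
  pa <- pair_attribution(ones, DEFAULT_MONTAGE, n)
  expect_equal(nrow(pa), C * (C + 1) / 2)
  expect_true(all(pa$score == 1))
  # pure tie-break order: (0,0), (0,1), ..., (0,11), (1,1), ...
  expect_equal(pa$channel_i[1:3], c("Fp1", "Fp1", "Fp1"))
  expect_equal(pa$channel_j[1:2], c("Fp1", "Fp2"))
  expect_equal(pa$i[pa$rank == 13], 1L)   # after Fp1's 12 pairs comes (1,1)

  # block support on rows 31..60 x cols 151..180 -> channels (Fp2, P4)
  hm <- matrix(0, 360, 360)
  hm[31:60, 151:180] <- 1
  top <- pair_attribution(hm, DEFAULT_MONTAGE, 30)
  expect_equal(c(top$channel_i[1], top$channel_j[1]), c("Fp2", "P4"))

  # diagonal-only support ranks self-pairs first
  dg <- matrix(0, 360, 360)
  for (c0 in 0:11) dg[c0 * 30 + 1:30, c0 * 30 + 1:30] <- 1
  pd <- pair_attribution(dg, DEFAULT_MONTAGE, 30)
  expect_true(all(pd$channel_i[1:12] == pd$channel_j[1:12]))

  expect_error(pair_attribution(matrix(0, 100, 100), DEFAULT_MONTAGE, 30),
               "does not equal")
})

test_that("pair attribution is symmetrisation-invariant and conserves mass", {
  set.seed(34)
  C <- 4; n <- 5
  hm <- matrix(runif(C * n * C * n), C * n)
  labs <- c("a", "b", "c", "d")
  p1 <- pair_attribution(hm, labs, n)
  p2 <- pair_attribution((hm + t(hm)) / 2, labs, n)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
  expect_equal(p1$rank, p2$rank)
  # sum over ordered blocks of block mean x block area == total mass
  S <- attr(p1, "score_matrix")
  expect_equal(sum(S * n * n), sum(hm), tolerance = 1e-8)
  # max statistic is also available
  pm <- pair_attribution(hm, labs, n, statistic = "max")
  expect_true(all(pm$score >= p1$score - 1e-12))
})

test_that("consensus ranking over epochs behaves at its fixed points", {
  m <- gradcam_model()
  set.seed(35)
  x <- matrix(rnorm(24 * 24), 24)
  labs <- c("c1", "c2", "c3", "c4")
  one <- explain_subject(m, array(x, c(24, 24, 1)), target_class = 1,
                         montage = labs, n_scales = 6)
  pa <- pair_attribution(gradcam(m, x, 1), labs, 6)
  expect_equal(one$consensus$rank[order(one$consensus$i, one$consensus$j)],
               pa$rank[order(pa$i, pa$j)])
  # identical epochs give the common ranking and integer mean ranks
  rep8 <- explain_subject(m, array(rep(x, 8), c(24, 24, 8)),
                          target_class = 1, montage = labs, n_scales = 6)
  expect_equal(rep8$consensus$mean_rank, rep8$consensus$rank)
  expect_error(explain_subject(m, array(0, c(24, 24, 0))), "no epochs")
})
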