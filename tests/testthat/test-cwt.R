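test_that("scalogram shape and zero-linearity are exact", {
  cfg <- cwt_config()
  expect_equal(length(cfg$scales), 30)
  z <- cwt_scalogram(numeric(512), cfg)
  expect_equal(dim(z$coefficients), c(30, 512))
  expect_true(all(z$coefficients == 0))
  expect_error(cwt_scalogram(c(1, NA, 3), cfg), "non-finite")
  expect_error(cwt_config(scales = c(2, 1)), "increasing")
})

test_that("the engine reproduces the brute-force CWT discretisation", {
  set.seed(7)
  f <- rnorm(60)
  scales <- c(1, 2.5, 4)
  got <- cwt_scalogram(f, cwt_config(6, scales))$coefficients
  expect_lt(max(abs(got - oracle_cwt(f, scales, 6))), 1e-10)
  # and for another derivative order
  got3 <- cwt_scalogram(f, cwt_config(3, scales))$coefficients
  expect_lt(max(abs(got3 - oracle_cwt(f, scales, 3))), 1e-10)
})

test_that("CWT is linear", {
  set.seed(8)
  x <- rnorm(256); y <- rnorm(256)
  cfg <- cwt_config(6, c(2, 5, 9))
  lhs <- cwt_scalogram(3 * x - 2 * y, cfg)$coefficients
  rhs <- 3 * cwt_scalogram(x, cfg)$coefficients -
         2 * cwt_scalogram(y, cfg)$coefficients
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
})

test_that("a sinusoid peaks at the scale nearest its frequency", {
  cfg <- cwt_config()
  fc <- wavelet_center_frequency(6)
  # With the 1/sqrt(a) family normalisation the scalogram energy of a pure
  # tone peaks where a * |psi_hat(2 pi a f0)|^2 is maximal; for the p-th
  # Gaussian derivative (spectrum ~ w^p exp(-w^2/4)) that is
  # a* = sqrt(2 p + 1) / (2 pi f0), one half-step above the centre
  # frequency sqrt(2 p) / (2 pi f0).
  for (f0 in c(0.03, 0.05, 0.12)) {
    x <- sin(2 * pi * f0 * seq_len(4096))
    energy <- rowMeans(cwt_scalogram(x, cfg)$coefficients^2)
    a_energy <- sqrt(13) / (2 * pi * f0)
    expect_equal(which.max(energy), which.min(abs(cfg$scales - a_energy)))
    # and lands within one grid step of the centre-frequency prediction
    expect_lte(abs(which.max(energy) - which.min(abs(fc / cfg$scales - f0))),
               1)
  }
})

test_that("stacking is channel-major with a faithful row index", {
  cfg <- cwt_config(6, c(1, 2, 3))
  s1 <- cwt_scalogram(rnorm(100), cfg, "chA")
  s2 <- cwt_scalogram(rnorm(100), cfg, "chB")
  st <- stack_scalograms(list(s1, s2))
  expect_equal(dim(st$matrix), c(6, 100))
  expect_identical(st$matrix[1:3, ], s1$coefficients)
  expect_identical(st$matrix[4:6, ], s2$coefficients)
  expect_equal(st$row_index$channel, rep(0:1, each = 3))
  expect_equal(st$row_index$scale, rep(1:3, 2))
  expect_error(stack_scalograms(list()), "no scalograms")
  s3 <- cwt_scalogram(rnorm(50), cfg, "chC")
  expect_error(stack_scalograms(list(s1, s3)), "mismatch")
})

test_that("pearson_matrix matches the element-wise oracle and conventions", {
  set.seed(9)
  x <- matrix(rnorm(8 * 50), 8, 50)
  R <- pearson_matrix(x)
  expect_lt(max(abs(unclass(R) - oracle_pearson(x))), 1e-10)
  expect_lt(max(abs(R - t(R))), 1e-10)
  expect_true(all(R >= -1 - 1e-12 & R <= 1 + 1e-12))
  expect_equal(unname(diag(R)), rep(1, 8))

  # positive affine maps and sign flips
  y <- rbind(x[1, ], 2 * x[1, ] + 5, c(1, 2, 3, rep(0, 47)),
             c(3, 2, 1, rep(0, 47)))
  Ry <- pearson_matrix(y)
  expect_equal(Ry[1, 2], 1)
  expect_equal(unclass(Ry[3, 4]), cor(y[3, ], y[4, ]))

  # zero-variance rows: 0 off-diagonal, 1 on the diagonal
  z <- rbind(x[1:2, ], rep(4, 50))
  Rz <- pearson_matrix(z)
  expect_equal(unname(Rz[3, ]), c(0, 0, 1))

  # invariance to positive row rescaling
  xs <- x * matrix(runif(8, 0.1, 10), 8, 50)
  expect_lt(max(abs(pearson_matrix(xs) - R)), 1e-10)
})

test_that("transform_epoch composes the two stages and is deterministic", {
  set.seed(10)
  epoch <- matrix(rnorm(2 * 80), 2, 80,
                  dimnames = list(c("A", "B"), NULL))
  cfg <- cwt_config(6, c(2, 4))
  got <- transform_epoch(epoch, cfg)
  expect_equal(dim(got), c(4, 4))
  chained <- oracle_pearson(rbind(oracle_cwt(epoch[1, ], c(2, 4)),
                                  oracle_cwt(epoch[2, ], c(2, 4))))
  expect_lt(max(abs(unclass(got) - chained)), 1e-10)
  expect_identical(unclass(got), unclass(transform_epoch(epoch, cfg)))

  # identical channels: same-scale cross-channel correlations are 1
  epoch2 <- rbind(A = epoch[1, ], B = epoch[1, ], C = epoch[1, ])
  R <- transform_epoch(epoch2, cfg)
  n <- 2
  for (s in 1:n) expect_equal(unname(R[s, s + n]), 1, tolerance = 1e-12)
})

test_that("default 12-channel transform gives the 360-square matrix", {
  set.seed(11)
  epoch <- matrix(rnorm(12 * 10625), 12, 10625,
                  dimnames = list(DEFAULT_MONTAGE, NULL))
  sc <- cwt_scalogram(epoch[1, ])
  expect_equal(dim(sc$coefficients), c(30, 10625))
  R <- transform_epoch(epoch)
  expect_equal(dim(R), c(360, 360))
})
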