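# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own vectorised implementations.

# direct double-loop discretisation of the CWT integral
oracle_cwt <- function(signal, scales, p = 6) {
  psi <- gaus_wavelet(p)
  L <- length(signal)
  W <- matrix(0, length(scales), L)
  for (s in seq_along(scales)) {
    a <- scales[s]
    J <- ceiling(5 * a)
    for (b in seq_len(L)) {
      j <- seq(-J, J)
      t <- b + j
      ok <- t >= 1 & t <= L
      W[s, b] <- sum(signal[t[ok]] * psi(j[ok] / a) / sqrt(a))
    }
  }
  W
}

# per-pair Pearson correlation from the covariance definition
oracle_pearson <- function(x) {
  R <- matrix(NA_real_, nrow(x), nrow(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(nrow(x))) {
      xi <- x[i, ] - mean(x[i, ])
      xj <- x[j, ] - mean(x[j, ])
      R[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  R
}

# textbook binary-classification metrics from a 2x2 confusion matrix,
# one-vs-rest for class 1 and class 2, macro averaged
oracle_binary_metrics <- function(cm) {
  per_class <- function(c) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- sum(cm) - tp - fn - fp
    c(sens = tp / (tp + fn), spec = tn / (tn + fp), prec = tp / (tp + fp))
  }
  m <- rbind(per_class(1), per_class(2))
  list(accuracy = sum(diag(cm)) / sum(cm) * 100,
       sensitivity = mean(m[, "sens"], na.rm = TRUE) * 100,
       specificity = mean(m[, "spec"], na.rm = TRUE) * 100,
       precision = mean(m[, "prec"], na.rm = TRUE) * 100)
}

# small recording factory
make_recording <- function(C = 3, L = 100, fs = 50, seed = 1,
                           labels = paste0("ch", seq_len(C))) {
  set.seed(seed)
  recording(matrix(rnorm(C * L), C, L, dimnames = list(labels, NULL)),
            fs = fs, channel_names = labels, subject_id = "sub1",
            label = "A")
}

# tiny model spec for engine tests
tiny_spec <- function(side = 16, filters = c(3, 4), units = 5, K = 3,
                      epochs = 5, lr = 1e-3)
  model_spec(input_shape = c(side, side, 1), conv_filters = filters,
             dense_units = units, n_classes = K, epochs = epochs,
             batch_size = 4, learning_rate = lr)
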