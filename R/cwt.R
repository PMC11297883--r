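#' CWT configuration
#'
#' Settings for the continuous wavelet transform applied per EEG channel:
#' the Gaussian-derivative order of the mother wavelet and the grid of
#' scales. Defaults are derivative order 6 ("gaus6") and integer scales
#' 1..30, the configuration used throughout the package for 500 Hz
#' recordings.
#'
#' @param wavelet_order derivative order `p` of the Gaussian-derivative
#'   mother wavelet (default 6).
#' @param scales strictly positive, strictly increasing numeric vector of
#'   scale values `a` (default `1:30`).
#' @return An object of class `cwt_config`.
#' @export
cwt_config <- function(wavelet_order = 6, scales = 1:30) {
  stopifnot(length(scales) >= 1, all(is.finite(scales)), all(scales > 0))
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing")
  structure(
    list(wavelet_order = as.integer(wavelet_order),
         scales = as.numeric(scales)),
    class = "cwt_config"
  )
}

#' @export
print.cwt_config <- function(x, ...) {
  cat(sprintf("CWT config: gaus%d wavelet, %d scales (%g .. %g)\n",
              x$wavelet_order, length(x$scales),
              min(x$scales), max(x$scales)))
  invisible(x)
}

# Precompute the frequency-domain kernels for one (config, signal length)
# pair. The CWT at scale a and translation b is discretised as
#   W[a, b] = sum_j f[b + j] * psi(j / a) / sqrt(a),  j in [-J, J],
# with J = ceil(support * a), i.e. a cross-correlation of the signal with
# the scaled, unit-spacing-sampled wavelet; samples outside the recording
# are treated as zero (same-length output, zero-padded edges). Kernels are
# embedded circularly in a padded length M so one FFT of the signal plus
# one inverse FFT per scale yields all translations.
cwt_plan <- function(cfg, L) {
  psi <- gaus_wavelet(cfg$wavelet_order)
  Jmax <- ceiling(WAVELET_SUPPORT * max(cfg$scales))
  M <- stats::nextn(L + 2 * Jmax + 1)
  K <- matrix(0, M, length(cfg$scales))
  for (s in seq_along(cfg$scales)) {
    a <- cfg$scales[s]
    J <- ceiling(WAVELET_SUPPORT * a)
    j <- seq(-J, J)
    k <- psi(j / a) / sqrt(a)
    idx <- ifelse(j >= 0, j + 1, M + j + 1)   # circular placement
    K[idx, s] <- k
  }
  list(M = M, L = L, kspec = Conj(stats::mvfft(K)))
}

# small memo so repeated epochs of identical length reuse the kernel FFTs
.cwt_plan_cache <- new.env(parent = emptyenv())

cwt_plan_cached <- function(cfg, L) {
  key <- paste(cfg$wavelet_order, paste(cfg$scales, collapse = ","), L,
               sep = "|")
  plan <- .cwt_plan_cache[[key]]
  if (is.null(plan)) {
    plan <- cwt_plan(cfg, L)
    # keep the cache tiny: drop everything when a new length shows up
    if (length(ls(.cwt_plan_cache)) >= 4) {
      rm(list = ls(.cwt_plan_cache), envir = .cwt_plan_cache)
    }
    .cwt_plan_cache[[key]] <- plan
  }
  plan
}

#' Continuous wavelet transform scalogram of one channel
#'
#' Correlates the signal with scaled, translated copies of the
#' Gaussian-derivative mother wavelet, with the \eqn{1/\sqrt{a}}
#' normalisation of the wavelet family, producing an
#' `n_scales x length(signal)` coefficient matrix (rows = scales, columns
#' = time points). Translations sweep every sample; samples beyond the
#' signal ends are taken as zero, so edge columns carry partial-support
#' coefficients.
#'
#' @param signal numeric vector, finite values.
#' @param cfg a [cwt_config()].
#' @param channel_label optional channel name attached to the result.
#' @return Object of class `cwt_scalogram`: list with `coefficients`
#'   (matrix `n_scales x L`), `scales`, and `channel_label`.
#' @examples
#' sc <- cwt_scalogram(sin(2 * pi * 0.05 * (1:512)), cwt_config())
#' dim(sc$coefficients)  # 30 x 512
#' @export
cwt_scalogram <- function(signal, cfg = cwt_config(), channel_label = NA_character_) {
  signal <- as.numeric(signal)
  if (!all(is.finite(signal)))
    stop("signal contains non-finite values")
  L <- length(signal)
  plan <- cwt_plan_cached(cfg, L)
  f <- complex(length.out = plan$M)
  f[seq_len(L)] <- signal
  Fs <- stats::fft(f)
  coef <- Re(stats::mvfft(Fs * plan$kspec, inverse = TRUE)) / plan$M
  structure(
    list(coefficients = t(coef[seq_len(L), , drop = FALSE]),
         scales = cfg$scales,
         channel_label = channel_label),
    class = "cwt_scalogram"
  )
}

#' Stack per-channel scalograms channel-major
#'
#' Vertically concatenates scalograms in montage order: all scales of the
#' first channel, then all scales of the second, and so on. A 12-channel
#' epoch with 30 scales stacks to a 360-row matrix.
#'
#' @param scalograms list of `cwt_scalogram` objects sharing the same
#'   scale grid and epoch length, in montage order.
#' @return Object of class `cwt_stack`: list with `matrix`
#'   ((C*n_scales) x L) and `row_index` (data.frame mapping each row to
#'   its channel and scale).
#' @export
stack_scalograms <- function(scalograms) {
  if (length(scalograms) == 0) stop("no scalograms to stack")
  dims <- vapply(scalograms, function(s) dim(s$coefficients), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("scalograms have mismatching shapes and cannot be stacked")
  for (s in scalograms[-1]) {
    if (!isTRUE(all.equal(s$scales, scalograms[[1]]$scales)))
      stop("scalograms have mismatching scale grids")
  }
  n <- dims[1, 1]
  labels <- vapply(scalograms, function(s) as.character(s$channel_label),
                   character(1))
  row_index <- data.frame(
    channel = rep(seq_along(scalograms) - 1L, each = n),
    channel_label = rep(labels, each = n),
    scale = rep(scalograms[[1]]$scales, length(scalograms))
  )
  structure(
    list(matrix = do.call(rbind, lapply(scalograms, `[[`, "coefficients")),
         row_index = row_index,
         n_scales = n),
    class = "cwt_stack"
  )
}

#' Row-wise Pearson correlation of a stacked scalogram
#'
#' Correlates every pair of scale-channel rows, giving the square
#' channel-wise CWT correlation matrix that serves as the classifier
#' input (360 x 360 for 12 channels x 30 scales). Rows with zero variance
#' (e.g. from an all-zero channel) get 0 off-diagonal and 1 on the
#' diagonal instead of NaN.
#'
#' @param stacked a `cwt_stack` (or plain numeric matrix, rows = series).
#' @return Object of class `cwt_corr`: the correlation matrix with
#'   attributes `row_index` and `n_scales` when available.
#' @export
pearson_matrix <- function(stacked) {
  x <- if (inherits(stacked, "cwt_stack")) stacked$matrix else as.matrix(stacked)
  if (ncol(x) < 2) stop("need at least 2 time points for correlation")
  sds <- apply(x, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  R <- suppressWarnings(stats::cor(t(x)))
  if (any(degenerate)) {
    R[degenerate, ] <- 0
    R[, degenerate] <- 0
  }
  diag(R) <- 1
  structure(
    R,
    row_index = if (inherits(stacked, "cwt_stack")) stacked$row_index,
    n_scales = if (inherits(stacked, "cwt_stack")) stacked$n_scales,
    class = c("cwt_corr", "matrix")
  )
}

#' @export
print.cwt_corr <- function(x, ...) {
  n <- attr(x, "n_scales")
  cat(sprintf("Channel-wise CWT correlation matrix %d x %d%s\n",
              nrow(x), ncol(x),
              if (!is.null(n)) sprintf(" (%d channels x %d scales)",
                                       nrow(x) / n, n) else ""))
  invisible(x)
}

#' Transform one epoch into its channel-wise CWT correlation matrix
#'
#' Composition of the three preprocessing stages: per-channel CWT
#' scalogram, channel-major stacking, row-wise Pearson correlation. A
#' 12-channel, 10,625-sample epoch under the default configuration yields
#' a 360 x 360 matrix.
#'
#' @param epoch an `eeg_epoch` (see [segment_recording()]) or a plain
#'   channels-by-samples numeric matrix.
#' @param cfg a [cwt_config()].
#' @return A `cwt_corr` correlation matrix.
#' @export
transform_epoch <- function(epoch, cfg = cwt_config()) {
  data <- if (inherits(epoch, "eeg_epoch")) epoch$data else as.matrix(epoch)
  labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  scalos <- lapply(seq_len(nrow(data)), function(i) {
    cwt_scalogram(data[i, ], cfg, channel_label = labels[i])
  })
  pearson_matrix(stack_scalograms(scalos))
}
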