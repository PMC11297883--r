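#' Class specification for the synthetic EEG generator
#'
#' A synthetic class is defined by the channel pair that shares a
#' band-limited oscillatory latent and by the coupling strength. With
#' coupling \eqn{\rho}, each planted channel is
#' \eqn{\sqrt{1-\rho^2}\,\epsilon_i + \rho\, z} for independent unit-variance
#' noise \eqn{\epsilon_i} and a shared unit-variance latent \eqn{z}, so the
#' expected Pearson correlation between the planted channels is
#' \eqn{\rho^2}; all other channels are pure noise.
#'
#' @param label class tag.
#' @param planted_pair character vector of two distinct montage labels.
#' @param coupling \eqn{\rho \in [0, 1]}, the fraction of planted-channel
#'   amplitude drawn from the shared latent.
#' @param latent_band numeric `(f_lo, f_hi)` Hz band of the latent
#'   oscillation; the default 8–12 Hz mimics an alpha-band rhythm.
#' @return Object of class `class_spec`.
#' @export
class_spec <- function(label, planted_pair, coupling = 0.85,
                       latent_band = c(8, 12)) {
  stopifnot(length(planted_pair) == 2, is.numeric(coupling),
            coupling >= 0, coupling <= 1,
            length(latent_band) == 2, latent_band[1] < latent_band[2])
  if (planted_pair[1] == planted_pair[2])
    stop("planted_pair channels must be distinct")
  structure(
    list(label = label, planted_pair = as.character(planted_pair),
         coupling = coupling, latent_band = as.numeric(latent_band)),
    class = "class_spec"
  )
}

#' Default three-class specification
#'
#' Three classes named after the clinical groups the package emulates,
#' each planting its latent in a distinct channel pair (frontal–parietal
#' for ADHD, prefrontal–frontal pairs for the others).
#' @param coupling coupling strength shared by all three classes.
#' @export
default_classes <- function(coupling = 0.85) {
  list(
    class_spec("ADHD", c("Fp2", "P4"), coupling),
    class_spec("ADHD+CD", c("F3", "O2"), coupling),
    class_spec("CD", c("Fp1", "F8"), coupling)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the structure of a 12-channel, 500 Hz, 3-minute
#' resting-state montage: each simulated recording then segments into 8
#' epochs of 21.25 s.
#'
#' @param montage ordered channel labels.
#' @param fs sampling rate (Hz).
#' @param duration recording duration (seconds).
#' @param n_per_class recordings (subjects) per class.
#' @param classes list of [class_spec()] objects.
#' @param noise_spectrum `"pink"` (1/f power, qualitatively EEG-like;
#'   default) or `"white"` background noise.
#' @param seed integer master seed; per-recording substreams are derived
#'   deterministically from `(seed, subject index)`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(montage = DEFAULT_MONTAGE, fs = 500, duration = 180,
                       n_per_class = 10, classes = default_classes(),
                       noise_spectrum = c("pink", "white"), seed = 1L) {
  noise_spectrum <- match.arg(noise_spectrum)
  stopifnot(fs > 0, duration > 0, n_per_class >= 1, length(classes) >= 1)
  for (cl in classes) {
    absent <- setdiff(cl$planted_pair, montage)
    if (length(absent))
      stop("planted channel(s) absent from montage: ",
           paste(absent, collapse = ", "))
  }
  structure(
    list(montage = montage, fs = fs, duration = duration,
         n_per_class = n_per_class, classes = classes,
         noise_spectrum = noise_spectrum, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# standardise to zero mean, unit (population) sd
standardise <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s > 0) x / s else x
}

# coloured noise by FFT amplitude shaping: power spectrum ~ 1/f for pink
coloured_noise <- function(L, spectrum = c("pink", "white")) {
  spectrum <- match.arg(spectrum)
  w <- stats::rnorm(L)
  if (spectrum == "white") return(standardise(w))
  W <- stats::fft(w)
  f <- c(1, seq_len(L - 1))                  # avoid 1/0 at DC
  f <- pmin(f, L - f + 1)                    # symmetric frequency index
  W <- W / sqrt(f)
  W[1] <- 0
  standardise(Re(stats::fft(W, inverse = TRUE)) / L)
}

# band-limited noise: brick-wall FFT bandpass of white noise
bandlimited_noise <- function(L, fs, band) {
  w <- stats::rnorm(L)
  W <- stats::fft(w)
  f <- (seq_len(L) - 1) / L * fs
  f <- pmin(f, fs - f)                       # two-sided frequencies
  W[f < band[1] | f > band[2]] <- 0
  standardise(Re(stats::fft(W, inverse = TRUE)) / L)
}

#' Simulate one labelled recording
#'
#' Every channel carries independent unit-variance background noise; the
#' class's planted pair additionally shares a band-limited latent
#' oscillation at coupling `rho`, mixed as
#' \eqn{\sqrt{1-\rho^2}\,\epsilon + \rho z} so channel variance stays at
#' one. The coupling is injected in the time domain, before any wavelet
#' transform, so planted structure must survive the full preprocessing
#' chain to be recoverable downstream.
#'
#' @param spec a [class_spec()].
#' @param cfg a [sim_config()]; `spec` need not be among `cfg$classes`.
#' @param seed integer seed for this recording (substream).
#' @param subject_id identifier for the returned recording.
#' @return An [recording()].
#' @export
simulate_recording <- function(spec, cfg, seed = cfg$seed,
                               subject_id = "sim") {
  stopifnot(inherits(spec, "class_spec"), inherits(cfg, "sim_config"))
  absent <- setdiff(spec$planted_pair, cfg$montage)
  if (length(absent))
    stop("planted channel(s) absent from montage: ",
         paste(absent, collapse = ", "))
  L <- floor(cfg$duration * cfg$fs)
  rho <- spec$coupling
  old_seed <- .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  latent <- bandlimited_noise(L, cfg$fs, spec$latent_band)
  data <- matrix(0, length(cfg$montage), L,
                 dimnames = list(cfg$montage, NULL))
  planted <- cfg$montage %in% spec$planted_pair
  for (i in seq_along(cfg$montage)) {
    eps <- coloured_noise(L, cfg$noise_spectrum)
    data[i, ] <- if (planted[i]) sqrt(1 - rho^2) * eps + rho * latent else eps
  }
  recording(data, fs = cfg$fs, channel_names = cfg$montage,
            subject_id = subject_id, label = spec$label)
}

#' Simulate a labelled dataset
#'
#' Generates `n_per_class` recordings per class with distinct subject ids.
#' Each recording uses a seed derived deterministically from the master
#' seed and the global subject index, so regeneration is reproducible and
#' order-independent.
#'
#' @param cfg a [sim_config()].
#' @return List of [recording()] objects,
#'   `length(cfg$classes) * cfg$n_per_class` in total.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  recs <- list()
  idx <- 0L
  for (cl in cfg$classes) {
    for (j in seq_len(cfg$n_per_class)) {
      idx <- idx + 1L
      sub_seed <- (cfg$seed + 7919L * idx) %% .Machine$integer.max
      sid <- sprintf("S%03d_%s", idx, cl$label)
      recs[[idx]] <- simulate_recording(cl, cfg, seed = sub_seed,
                                        subject_id = sid)
    }
  }
  recs
}
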