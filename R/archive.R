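# On-disk containers for intermediate pipeline artifacts. Epoch sets and
# correlation-matrix sets are stored as single RDS archives holding the
# data arrays plus labels, subjects, epoch indices and the resolved
# configuration (for cache invalidation and provenance).

#' Write an epoch archive
#'
#' @param epochs list of `eeg_epoch` (see [segment_recording()]), all of
#'   identical shape.
#' @param path output `.rds` path.
#' @param config optional resolved configuration to embed.
#' @export
write_epoch_archive <- function(epochs, path, config = NULL) {
  if (length(epochs) == 0) stop("no epochs to write")
  dims <- dim(epochs[[1]]$data)
  arr <- array(NA_real_, c(dims, length(epochs)))
  for (i in seq_along(epochs)) arr[, , i] <- epochs[[i]]$data
  obj <- list(
    epochs = arr,
    channel_names = rownames(epochs[[1]]$data),
    fs = epochs[[1]]$fs,
    labels = vapply(epochs, function(e) as.character(e$label), ""),
    subjects = vapply(epochs, function(e) as.character(e$source_subject), ""),
    epoch_index = vapply(epochs, function(e) e$index, integer(1)),
    config = config
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read an epoch archive back into a list of epochs
#' @param path archive path written by [write_epoch_archive()].
#' @return List with `epochs` (list of `eeg_epoch`), `labels`,
#'   `subjects`, `config`.
#' @export
read_epoch_archive <- function(path) {
  obj <- readRDS(path)
  eps <- lapply(seq_along(obj$labels), function(i) {
    data <- obj$epochs[, , i]
    rownames(data) <- obj$channel_names
    structure(list(data = data, fs = obj$fs,
                   source_subject = obj$subjects[i],
                   index = obj$epoch_index[i],
                   label = obj$labels[i]),
              class = "eeg_epoch")
  })
  list(epochs = eps, labels = obj$labels, subjects = obj$subjects,
       config = obj$config)
}

#' Write a correlation-matrix archive
#'
#' @param corr `H x H x N` array of correlation matrices.
#' @param labels,subjects,epoch_index per-matrix metadata.
#' @param montage,n_scales block structure of the matrices.
#' @param path output path.
#' @param config resolved configuration to embed.
#' @export
write_corr_archive <- function(corr, labels, subjects, epoch_index,
                               montage, n_scales, path, config = NULL) {
  saveRDS(list(corr = corr, labels = labels, subjects = subjects,
               epoch_index = epoch_index, montage = montage,
               n_scales = n_scales, config = config), path)
  invisible(path)
}

#' Read a correlation-matrix archive
#' @param path archive path.
#' @export
read_corr_archive <- function(path) readRDS(path)
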