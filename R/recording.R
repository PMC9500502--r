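#' Multichannel recording container
#'
#' A `recording` holds a channels-by-samples numeric matrix together with its
#' sampling rate and channel labels. Every stage of the pipeline consumes and
#' emits this container. Values are interpreted as microvolts for EEG data,
#' but nothing downstream depends on the unit.
#'
#' @param data numeric matrix, M channels x N samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of M unique labels. Defaults to the
#'   first M names of the packaged 32-channel 10-20 montage.
#' @param reference_note free-text description of the reference scheme.
#' @return An object of class `recording` with elements `data`, `fs`,
#'   `channel_labels`, `reference_note`.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 256), 2), fs = 128)
#' n_channels(rec)
#' @export
recording <- function(data, fs, channel_labels = NULL,
                      reference_note = "unspecified") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  M <- nrow(data)
  if (M < 2) stop("a recording needs at least 2 channels")
  if (!all(is.finite(data))) stop("recording data contain NaN/Inf")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(channel_labels)) channel_labels <- montage_1020_32()[seq_len(M)]
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != M) stop("need one label per channel")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 reference_note = reference_note),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(head(x$channel_labels, 8), collapse = " "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname recording
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Standard 32-channel 10-20 montage labels
#'
#' Electrode names for a 32-channel cap laid out on the international 10-20
#' system, in cap order.
#'
#' @return Character vector of length 32.
#' @export
montage_1020_32 <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}

#' Read and write recordings as plain-text matrix + JSON sidecar
#'
#' A recording is stored as a tab-separated channels-by-samples matrix
#' (`<stem>.tsv`, one row per channel, no header) with a JSON sidecar
#' (`<stem>.json`) carrying the sampling rate, channel labels and reference
#' note.
#'
#' @param rec a [recording()].
#' @param stem file path without extension.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(format(rec$data, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = rec$channel_labels,
               reference_note = rec$reference_note)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                     header = FALSE))
  dimnames(dat) <- NULL
  recording(dat, fs = meta$fs, channel_labels = meta$channel_labels,
            reference_note = meta$reference_note)
}
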