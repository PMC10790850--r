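#' Continuous EEG recording container
#'
#' Holds a channel-by-sample matrix in microvolts together with the sampling
#' rate, channel labels, unit-sphere channel positions, the current reference
#' and the set of channels flagged as bad.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate_hz sampling rate (Hz).
#' @param labels character vector of channel labels (unique, one per row).
#' @param positions numeric matrix (channels x 3) of unit-norm xyz positions,
#'   or a montage data.frame containing the labels.
#' @param reference label of the recording reference, or `"linked-mastoid"`.
#' @param bads character vector of bad-channel labels.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, srate_hz, labels,
                          positions = NULL, reference = "Fz",
                          bads = character(0)) {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (is.data.frame(positions) && "label" %in% names(positions)) {
    idx <- match(labels, positions$label)
    if (anyNA(idx)) stop_fmt("positions montage is missing channels: %s",
                             paste(labels[is.na(idx)], collapse = ", "))
    positions <- as.matrix(positions[idx, c("x", "y", "z")])
  }
  if (!is.null(positions)) dimnames(positions) <- NULL
  rec <- structure(list(data = data, srate_hz = srate_hz,
                        labels = as.character(labels),
                        positions = positions, reference = reference,
                        bads = as.character(bads)),
                   class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (nrow(rec$data) != length(rec$labels))
    stop_fmt("recording has %d data rows but %d labels",
             nrow(rec$data), length(rec$labels))
  if (anyDuplicated(rec$labels))
    stop_fmt("channel labels must be unique")
  if (!is.finite(rec$srate_hz) || rec$srate_hz <= 0)
    stop_fmt("sampling rate must be positive")
  if (!all(is.finite(rec$data)))
    stop_fmt("recording data must be finite")
  if (!is.null(rec$positions)) {
    if (nrow(rec$positions) != length(rec$labels))
      stop_fmt("recording has %d channels but %d positions",
               length(rec$labels), nrow(rec$positions))
    nrm <- sqrt(rowSums(rec$positions^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop_fmt("channel positions must be unit-norm")
  }
  if (!all(rec$bads %in% rec$labels))
    stop_fmt("bad-channel labels not in montage: %s",
             paste(setdiff(rec$bads, rec$labels), collapse = ", "))
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate_hz,
              ncol(x$data) / x$srate_hz))
  cat(sprintf("  reference: %s; bads: %s\n", x$reference,
              if (length(x$bads)) paste(x$bads, collapse = ", ") else "none"))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$srate_hz

#' Read / write a recording (matrix + JSON sidecar)
#'
#' The on-disk form is a tab-separated sample-by-channel matrix (one header
#' row of channel labels) next to a JSON sidecar `<stem>.json` holding the
#' sampling rate, labels, unit-sphere positions, reference and bad-channel
#' set. The pair round-trips losslessly up to the 15 significant digits of the
#' text representation.
#'
#' @param path path of the data TSV; the sidecar is `<path without ext>.json`.
#' @return `read_recording` returns an `eeg_recording`.
#' @export
read_recording <- function(path) {
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  if (!file.exists(sidecar)) stop_fmt("missing JSON sidecar '%s'", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  mat <- t(as.matrix(dt))
  labels <- meta$labels %||% rownames(mat)
  if (!identical(as.character(colnames(dt)), as.character(labels)))
    stop_fmt("sidecar labels disagree with data header")
  positions <- NULL
  if (!is.null(meta$positions)) {
    positions <- matrix(unlist(meta$positions), ncol = 3, byrow = FALSE)
    if (nrow(positions) != length(labels))
      stop_fmt("sidecar lists %d positions for %d channels",
               nrow(positions), length(labels))
  }
  new_recording(mat, meta$srate_hz, labels, positions,
                reference = meta$reference %||% "Fz",
                bads = unlist(meta$bads) %||% character(0))
}

#' @rdname read_recording
#' @param rec an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$labels)
  data.table::fwrite(dt, path, sep = "\t")
  sidecar <- paste0(sub("\\.[^.]*$", "", path), ".json")
  meta <- list(srate_hz = rec$srate_hz, labels = rec$labels,
               reference = rec$reference, bads = rec$bads)
  if (!is.null(rec$positions)) meta$positions <- unname(as.data.frame(rec$positions))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Subset channels by label, preserving metadata.
pick_channels <- function(rec, labels) {
  idx <- match(labels, rec$labels)
  if (anyNA(idx)) stop_fmt("channels not in recording: %s",
                           paste(labels[is.na(idx)], collapse = ", "))
  new_recording(rec$data[idx, , drop = FALSE], rec$srate_hz, rec$labels[idx],
                rec$positions[idx, , drop = FALSE], rec$reference,
                intersect(rec$bads, labels))
}
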