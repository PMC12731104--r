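#' Epoched EEG container
#'
#' Trials x channels x samples array with per-trial class labels, sampling
#' rate and channel names. Labels are integer class ids in 0..(n_classes-1)
#' (0-based, matching the usual motor-imagery convention: 0 = left hand,
#' 1 = right hand, 2 = feet, 3 = tongue).
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param labels integer vector, one class id per trial.
#' @param channel_names character vector matching the channel dimension.
#' @param class_names optional class labels (character).
#' @return An object of class `lpggnet_epochs`.
#' @export
epoched_eeg <- function(data, fs, labels, channel_names,
                        class_names = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop_validation("data must be a 3-d array: trials x channels x samples")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop_validation("epoch data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_validation("fs must be a single positive number")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    stop_validation(sprintf(
      "labels length (%d) must equal trial count (%d)",
      length(labels), dim(data)[1L]))
  if (any(labels < 0L))
    stop_validation("labels must be nonnegative 0-based class ids")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2L])
    stop_validation(sprintf(
      "channel_names length (%d) must equal channel dimension (%d)",
      length(channel_names), dim(data)[2L]))
  if (anyDuplicated(channel_names))
    stop_validation("channel names must be unique")
  if (is.null(class_names))
    class_names <- as.character(sort(unique(labels)))
  structure(list(data = data, fs = as.numeric(fs), labels = labels,
                 channel_names = channel_names,
                 class_names = as.character(class_names)),
            class = "lpggnet_epochs")
}

#' @export
print.lpggnet_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lpggnet_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  tb <- table(x$labels)
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.lpggnet_epochs <- function(x) dim(x$data)

#' Number of trials
#' @param epochs an `lpggnet_epochs`.
#' @return integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1L]

#' Subset epochs by channel
#'
#' @param epochs an `lpggnet_epochs`.
#' @param channels channel names to keep, in the requested order.
#' @return An `lpggnet_epochs` restricted to `channels`.
#' @export
select_channels <- function(epochs, channels) {
  missing <- setdiff(channels, epochs$channel_names)
  if (length(missing))
    stop_validation(sprintf("unknown channel(s): %s",
                            paste(missing, collapse = ", ")))
  idx <- match(channels, epochs$channel_names)
  epoched_eeg(epochs$data[, idx, , drop = FALSE], epochs$fs, epochs$labels,
              channels, epochs$class_names)
}

#' Drop channels by label (e.g. EOG channels)
#'
#' Artifact channels are removed by name rather than by component-based
#' correction: recordings that carry dedicated ocular channels simply
#' exclude them before decoding.
#'
#' @param epochs an `lpggnet_epochs`.
#' @param channels labels to drop; labels absent from the montage are
#'   silently ignored.
#' @return An `lpggnet_epochs` without the dropped channels.
#' @export
drop_channels <- function(epochs, channels) {
  keep <- setdiff(epochs$channel_names, channels)
  if (length(keep) < 2L)
    stop_validation("dropping these channels would leave fewer than 2")
  select_channels(epochs, keep)
}

#' Subset epochs by trial
#' @param epochs an `lpggnet_epochs`.
#' @param trials integer trial indices.
#' @return An `lpggnet_epochs` with the selected trials.
#' @export
select_trials <- function(epochs, trials) {
  epoched_eeg(epochs$data[trials, , , drop = FALSE], epochs$fs,
              epochs$labels[trials], epochs$channel_names, epochs$class_names)
}
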