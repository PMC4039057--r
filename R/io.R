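#' Write an epoched recording to a single-file container
#'
#' One self-describing file per subject: named datasets `data`, `labels`,
#' `block_of`, `channels`, `periocular`, and scalar attributes `fs`,
#' `pre_stim_ms`, `subject_id`, `group`, serialised with R's native format.
#' Single-file subjects keep leave-one-subject-out workflows trivially
#' file-parallel.
#'
#' @param recording an [epoched_recording].
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_epoched <- function(recording, path) {
  stopifnot(inherits(recording, "epoched_recording"))
  payload <- list(
    format = "oddballEEG-epoched", version = 1L,
    data = recording$data,
    labels = as.character(recording$labels),
    block_of = recording$block_of,
    channels = recording$channels,
    periocular = recording$periocular,
    fs = recording$fs,
    pre_stim_ms = recording$pre_stim_ms,
    subject_id = recording$subject_id,
    group = recording$group,
    baselined = recording$baselined)
  saveRDS(payload, path)
  invisible(path)
}

#' Read an epoched recording from its container
#'
#' Validates the container layout and field shapes; a malformed container
#' fails with an error naming the missing field.
#'
#' @param path path written by [write_epoched()].
#' @return A validated [epoched_recording] (units microvolts).
#' @export
read_epoched <- function(path) {
  if (!file.exists(path)) stop("no such container: ", path)
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "oddballEEG-epoched"))
    stop("not an oddballEEG epoched container: ", path)
  required <- c("data", "labels", "block_of", "channels", "fs",
                "pre_stim_ms", "subject_id")
  missing <- setdiff(required, names(payload))
  if (length(missing))
    stop("malformed container: missing field(s) ",
         paste(missing, collapse = ", "))
  rec <- epoched_recording(
    data = payload$data, fs = payload$fs, pre_stim_ms = payload$pre_stim_ms,
    labels = payload$labels, block_of = payload$block_of,
    channels = payload$channels,
    periocular = if (is.null(payload$periocular)) character() else payload$periocular,
    subject_id = payload$subject_id,
    group = if (is.null(payload$group)) NA_character_ else payload$group)
  rec$baselined <- isTRUE(payload$baselined)
  rec
}

#' Epoch a continuous multichannel signal around stimulus events
#'
#' Cuts half-open windows `[onset - pre, onset + post)` out of a continuous
#' `channels x samples` array. Event sample indices are 0-based; epoch `e`
#' sample `k` equals the signal at sample `onset_e - pre_samples + k`.
#'
#' @param signal numeric `C x N` matrix, microvolts.
#' @param events data frame with columns `sample` (0-based stimulus onset)
#'   and `label` (`"standard"`/`"deviant"`); an optional `block` column gives
#'   per-event block indices.
#' @param fs sampling rate, Hz.
#' @param pre_stim_ms,post_stim_ms window extent around each onset, ms.
#' @param ... passed to [epoched_recording()] (channels, periocular,
#'   subject_id, group).
#' @return An [epoched_recording] with `E = nrow(events)` epochs.
#' @export
epoch_continuous <- function(signal, events, fs, pre_stim_ms, post_stim_ms,
                             ...) {
  if (!is.matrix(signal)) stop("`signal` must be a C x N matrix")
  if (!all(c("sample", "label") %in% names(events)))
    stop("`events` needs columns `sample` and `label`")
  C <- nrow(signal); N <- ncol(signal)
  pre_n <- as.integer(round(pre_stim_ms * fs / 1000))
  post_n <- as.integer(round(post_stim_ms * fs / 1000))
  T <- pre_n + post_n
  onset <- as.integer(events$sample)
  first <- onset - pre_n               # 0-based first sample of each window
  last <- onset + post_n - 1L          # 0-based last sample (inclusive)
  bad <- which(first < 0L | last >= N)
  if (length(bad))
    stop("event window out of bounds for event(s) at sample(s) ",
         paste(onset[bad], collapse = ", "))
  E <- length(onset)
  data <- array(0, c(C, E, T))
  for (e in seq_len(E))
    data[, e, ] <- signal[, (first[e] + 1L):(last[e] + 1L), drop = FALSE]
  epoched_recording(data, fs = fs, pre_stim_ms = pre_stim_ms,
                    labels = events$label,
                    block_of = if ("block" %in% names(events)) events$block else NULL,
                    ...)
}
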