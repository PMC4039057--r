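#' Epoched EEG recording
#'
#' The core container for a single subject's epoched EEG: a
#' `channels x epochs x samples` array in microvolts together with per-epoch
#' stimulus labels (`standard`/`deviant`), block indices, and montage
#' metadata. Time indexing is 0-based and epoch windows are half-open
#' `[onset - pre, onset + post)`, so an epoch holds
#' `T = round((pre_stim_ms + post_stim_ms) * fs / 1000)` samples.
#'
#' @param data numeric 3-D array `[C, E, T]`, microvolts.
#' @param fs sampling rate in Hz.
#' @param pre_stim_ms pre-stimulus baseline duration, ms.
#' @param labels per-epoch stimulus class, `"standard"` or `"deviant"`,
#'   length `E` (character or factor).
#' @param block_of per-epoch block index, length `E`; defaults to a single
#'   block.
#' @param channels ordered channel identifiers, length `C`; defaults to
#'   `"E001"`, `"E002"`, ...
#' @param periocular subset of `channels` flagged as periocular/frontal
#'   (blink-sensitive) sites.
#' @param subject_id opaque subject identifier.
#' @param group optional diagnostic group, `"ASD"` or `"TD"`.
#'
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, pre_stim_ms, labels,
                              block_of = NULL, channels = NULL,
                              periocular = character(),
                              subject_id = "S001", group = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [channels x epochs x samples]")
  storage.mode(data) <- "double"
  d <- dim(data)
  C <- d[1L]; E <- d[2L]; T <- d[3L]
  if (C < 1L || E < 1L || T < 1L) stop("all dimensions must be >= 1")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  if (!is.numeric(pre_stim_ms) || pre_stim_ms < 0) stop("`pre_stim_ms` must be >= 0")
  labels <- as.character(labels)
  if (length(labels) != E)
    stop(sprintf("length(labels) = %d but E = %d", length(labels), E))
  if (!all(labels %in% c("standard", "deviant")))
    stop("labels must be 'standard' or 'deviant'")
  labels <- factor(labels, levels = c("standard", "deviant"))
  if (is.null(block_of)) block_of <- rep(1L, E)
  block_of <- as.integer(block_of)
  if (length(block_of) != E)
    stop(sprintf("length(block_of) = %d but E = %d", length(block_of), E))
  if (is.null(channels)) channels <- sprintf("E%03d", seq_len(C))
  channels <- as.character(channels)
  if (length(channels) != C)
    stop(sprintf("length(channels) = %d but C = %d", length(channels), C))
  if (anyDuplicated(channels)) stop("channel identifiers must be unique")
  periocular <- as.character(periocular)
  if (!all(periocular %in% channels))
    stop("every periocular channel must be a member of `channels`")
  post_stim_ms <- T * 1000 / fs - pre_stim_ms
  if (post_stim_ms < 0) stop("pre_stim_ms longer than the epoch itself")
  if (!is.na(group) && !group %in% c("ASD", "TD"))
    stop("group must be 'ASD', 'TD' or NA")
  structure(
    list(data = data, fs = fs, pre_stim_ms = pre_stim_ms,
         post_stim_ms = post_stim_ms, labels = labels, block_of = block_of,
         channels = channels, periocular = periocular,
         subject_id = as.character(subject_id), group = group,
         baselined = FALSE),
    class = "epoched_recording")
}

#' @exportS3Method print epoched_recording
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> subject %s%s\n", x$subject_id,
              if (is.na(x$group)) "" else paste0(" (", x$group, ")")))
  cat(sprintf("  %d channels x %d epochs x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  window -%g..+%g ms; %d deviant / %d standard; %d block(s)\n",
              x$pre_stim_ms, x$post_stim_ms,
              sum(x$labels == "deviant"), sum(x$labels == "standard"),
              length(unique(x$block_of))))
  if (length(x$periocular))
    cat(sprintf("  periocular: %s\n", paste(x$periocular, collapse = ", ")))
  invisible(x)
}

#' @rdname epoched_recording
#' @param x an `epoched_recording`.
#' @export
n_channels <- function(x) dim(x$data)[1L]

#' @rdname epoched_recording
#' @export
n_epochs <- function(x) dim(x$data)[2L]

#' @rdname epoched_recording
#' @export
n_samples <- function(x) dim(x$data)[3L]

#' @rdname epoched_recording
#' @export
time_ms <- function(x) {
  (seq_len(n_samples(x)) - 1) * 1000 / x$fs - x$pre_stim_ms
}

# Number of samples in the pre-stimulus baseline.
pre_samples <- function(x) as.integer(round(x$pre_stim_ms * x$fs / 1000))

# View the data cube as a (C*E) x T matrix of epoch-channel vectors; the row
# for cell (c, e) is (e - 1) * C + c.
cell_matrix <- function(x) {
  d <- dim(x$data)
  matrix(x$data, d[1L] * d[2L], d[3L])
}

cell_row <- function(x, c, e) (e - 1L) * n_channels(x) + c

#' Clean-cell mask from channel-by-epoch rejection
#'
#' Holds the set of retained (channel, epoch) pairs as a boolean
#' `channels x epochs` grid, with a per-cell log of which criterion rejected
#' each discarded cell (`"threshold"`, `"trendline"`, `"both"`, `"none"`).
#'
#' @param keep logical `C x E` matrix, `TRUE` for retained cells.
#' @param criteria_log character `C x E` matrix; defaults to `"none"` where
#'   kept and `"threshold"` where rejected.
#' @return An object of class `clean_mask`.
#' @export
clean_mask <- function(keep, criteria_log = NULL) {
  if (!is.matrix(keep) || !is.logical(keep)) stop("`keep` must be a logical matrix")
  if (is.null(criteria_log)) {
    criteria_log <- matrix("none", nrow(keep), ncol(keep))
    criteria_log[!keep] <- "threshold"
  }
  if (!identical(dim(criteria_log), dim(keep)))
    stop("criteria_log shape must match keep")
  if (any((criteria_log == "none") != keep))
    stop("keep[c,e] must be FALSE exactly when criteria_log[c,e] != 'none'")
  structure(list(keep = keep, criteria_log = criteria_log), class = "clean_mask")
}

#' @exportS3Method print clean_mask
print.clean_mask <- function(x, ...) {
  cat(sprintf("<clean_mask> %d x %d cells, %d rejected (%.1f%%)\n",
              nrow(x$keep), ncol(x$keep), sum(!x$keep),
              100 * mean(!x$keep)))
  invisible(x)
}

check_mask_shape <- function(recording, mask) {
  if (!identical(dim(mask$keep), dim(recording$data)[1:2]))
    stop("mask shape does not match recording [channels x epochs]")
  invisible(TRUE)
}

#' Study-level collection of recordings
#'
#' Bundles one [epoched_recording] per subject with per-subject group labels
#' and optional sex metadata, mirroring a two-group case/control cohort.
#'
#' @param recordings list of [epoched_recording] objects.
#' @param group per-subject group (`"ASD"`/`"TD"`); taken from the recordings
#'   when omitted.
#' @param sex optional per-subject sex (`"M"`/`"F"`).
#' @return An object of class `study_set`.
#' @export
study_set <- function(recordings, group = NULL, sex = NULL) {
  if (!length(recordings)) {
    return(structure(list(recordings = list(),
                          group = factor(character(), c("ASD", "TD")),
                          sex = if (is.null(sex)) NULL else character()),
                     class = "study_set"))
  }
  stopifnot(all(vapply(recordings, inherits, TRUE, "epoched_recording")))
  if (is.null(group))
    group <- vapply(recordings, function(r) r$group, character(1))
  if (length(group) != length(recordings))
    stop("one group label per recording is required")
  group <- factor(as.character(group), levels = c("ASD", "TD"))
  if (anyNA(group)) stop("group labels must be 'ASD' or 'TD'")
  if (!is.null(sex)) {
    sex <- as.character(sex)
    if (length(sex) != length(recordings))
      stop("sex, when present, must have one entry per recording")
    if (!all(sex %in% c("M", "F"))) stop("sex entries must be 'M' or 'F'")
  }
  structure(list(recordings = recordings, group = group, sex = sex),
            class = "study_set")
}

#' @exportS3Method print study_set
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %d subjects (%d ASD / %d TD)%s\n",
              length(x$recordings), sum(x$group == "ASD"),
              sum(x$group == "TD"),
              if (is.null(x$sex)) "" else
                sprintf("; sex: %d M / %d F", sum(x$sex == "M"),
                        sum(x$sex == "F"))))
  invisible(x)
}

#' @rdname study_set
#' @param study a `study_set`.
#' @export
n_subjects <- function(study) length(study$recordings)

#' Restrict a study to one sex
#'
#' Supports sex-stratified reruns (e.g. a males-only analysis to rule out a
#' classifier keying on the cohort's sex imbalance). Subject order is
#' preserved.
#'
#' @param study a [study_set] with sex metadata.
#' @param sex `"M"` or `"F"`.
#' @return A [study_set] containing only the matching subjects.
#' @export
subset_by_sex <- function(study, sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (is.null(study$sex)) stop("study has no sex metadata")
  idx <- which(study$sex == sex)
  study_set(study$recordings[idx], group = as.character(study$group[idx]),
            sex = study$sex[idx])
}
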