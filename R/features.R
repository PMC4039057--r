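#' Pooled median standard and deviant waveforms
#'
#' Pools every retained (channel, epoch) vector of each stimulus class —
#' regardless of channel or epoch — and takes the elementwise median at each
#' time sample, yielding the subject's typical standard response `s_bar`,
#' typical deviant response `d_bar`, and difference `delta = d_bar - s_bar`.
#' Noisier channels contribute fewer clean cells and so are implicitly
#' down-weighted; the median itself is robust to the outliers that survive
#' rejection. Even-count medians average the two middle values.
#'
#' @param recording a baseline-corrected [epoched_recording].
#' @param mask a [clean_mask]; defaults to keeping everything.
#' @return List of class `median_waveforms`: `s_bar`, `d_bar`, `delta`
#'   (length-`T` microvolt vectors), `n_standard_vectors`,
#'   `n_deviant_vectors`, plus the recording's `fs` and `pre_stim_ms`.
#' @export
median_waveforms <- function(recording, mask = NULL) {
  if (is.null(mask))
    mask <- clean_mask(matrix(TRUE, n_channels(recording), n_epochs(recording)))
  check_mask_shape(recording, mask)
  m <- cell_matrix(recording)
  is_dev <- matrix(rep(recording$labels == "deviant",
                       each = n_channels(recording)),
                   n_channels(recording), n_epochs(recording))
  s_rows <- which(as.vector(mask$keep & !is_dev))
  d_rows <- which(as.vector(mask$keep & is_dev))
  if (!length(s_rows)) stop("no clean standard epoch-channels (S is empty)")
  if (!length(d_rows)) stop("no clean deviant epoch-channels (D is empty)")
  s_bar <- col_medians(m[s_rows, , drop = FALSE])
  d_bar <- col_medians(m[d_rows, , drop = FALSE])
  structure(list(s_bar = s_bar, d_bar = d_bar, delta = d_bar - s_bar,
                 n_standard_vectors = length(s_rows),
                 n_deviant_vectors = length(d_rows),
                 fs = recording$fs, pre_stim_ms = recording$pre_stim_ms),
            class = "median_waveforms")
}

#' @exportS3Method print median_waveforms
print.median_waveforms <- function(x, ...) {
  cat(sprintf("<median_waveforms> T = %d samples @ %g Hz (%d standard / %d deviant vectors pooled)\n",
              length(x$s_bar), x$fs, x$n_standard_vectors, x$n_deviant_vectors))
  invisible(x)
}

partition_bounds <- function(T, n_partitions) {
  if (T %% n_partitions != 0)
    stop(sprintf("T = %d is not divisible into %d equal partitions", T,
                 n_partitions))
  w <- T %/% n_partitions
  list(width = w, start = (seq_len(n_partitions) - 1L) * w + 1L)
}

#' Sum-of-signed-differences features
#'
#' Partitions the difference waveform into `n_partitions` contiguous
#' equal-length segments (50 ms each at the default geometry) and sums the
#' signed difference in each, i.e. the area under the difference curve per
#' region: `SSD_i = sum_{j = w(i-1)+1}^{wi} delta_j` with `w = T /
#' n_partitions`. A positive value means the deviant response sat above the
#' standard response in that region.
#'
#' @param delta length-`T` difference vector (or a [median_waveforms]).
#' @param n_partitions number of equal segments.
#' @return Numeric vector of `n_partitions` partition sums.
#' @export
ssd_features <- function(delta, n_partitions = 24) {
  if (inherits(delta, "median_waveforms")) delta <- delta$delta
  pb <- partition_bounds(length(delta), n_partitions)
  as.numeric(colSums(matrix(delta, pb$width, n_partitions)))
}

#' Partitioned variance features
#'
#' Sample variance (unbiased, `n - 1` divisor) of the difference waveform in
#' `n_partitions` contiguous equal-length segments:
#' `v_i = var{delta_j : w(i-1)+1 <= j <= wi}`. Fewer, wider partitions than
#' the SSD so each variance sees more data.
#'
#' @param delta length-`T` difference vector (or a [median_waveforms]).
#' @param n_partitions number of equal segments (partition length >= 2).
#' @return Numeric vector of `n_partitions` partition variances.
#' @export
variance_features <- function(delta, n_partitions = 12) {
  if (inherits(delta, "median_waveforms")) delta <- delta$delta
  pb <- partition_bounds(length(delta), n_partitions)
  if (pb$width < 2) stop("partition length must be >= 2 for a variance")
  m <- matrix(delta, pb$width, n_partitions)
  mc <- m - rep(colMeans(m), each = pb$width)
  as.numeric(colSums(mc^2)) / (pb$width - 1)
}

#' Select the classification feature subset
#'
#' Drops the four pre-stimulus SSD partitions (the first 200 ms of the
#' window precedes the stimulus), keeping SSD partitions 5..24, and keeps
#' variance partitions 4..6, concatenating them into the 23-dimensional
#' vector used for classification.
#'
#' @param ssd 24 SSD values.
#' @param variance 12 partition variances.
#' @return Numeric vector of length 23 (`ssd05`..`ssd24`, `var04`..`var06`).
#' @export
select_features <- function(ssd, variance) {
  if (length(ssd) != 24) stop("expected 24 SSD values, got ", length(ssd))
  if (length(variance) != 12) stop("expected 12 variance values, got ",
                                   length(variance))
  out <- c(ssd[5:24], variance[4:6])
  names(out) <- c(sprintf("ssd%02d", 5:24), sprintf("var%02d", 4:6))
  out
}

# Sample index range (1-based) covering post-stimulus interval [a, b) ms.
interval_samples <- function(fs, pre_stim_ms, from_ms, to_ms, T) {
  pre_n <- round(pre_stim_ms * fs / 1000)
  i0 <- pre_n + round(from_ms * fs / 1000) + 1
  i1 <- pre_n + round(to_ms * fs / 1000)
  if (i0 < 1 || i1 > T)
    stop(sprintf("interval %g-%g ms lies outside the epoch", from_ms, to_ms))
  i0:i1
}

#' Signed-difference sums over named post-stimulus intervals
#'
#' Sums the difference waveform over arbitrary post-stimulus millisecond
#' intervals (half-open `[from, to)`), the form used for interval-level
#' group testing (0--150, 150--250, 250--400, 400--1000 ms).
#'
#' @param delta length-`T` difference vector (or a [median_waveforms], in
#'   which case `fs` and `pre_stim_ms` are taken from it).
#' @param fs sampling rate, Hz.
#' @param pre_stim_ms baseline duration, ms.
#' @param intervals list of `c(from_ms, to_ms)` pairs.
#' @return Named numeric vector of interval sums.
#' @export
interval_ssd <- function(delta, fs = NULL, pre_stim_ms = NULL,
                         intervals = list(c(0, 150), c(150, 250),
                                          c(250, 400), c(400, 1000))) {
  if (inherits(delta, "median_waveforms")) {
    fs <- delta$fs; pre_stim_ms <- delta$pre_stim_ms; delta <- delta$delta
  }
  out <- vapply(intervals, function(iv) {
    sum(delta[interval_samples(fs, pre_stim_ms, iv[1], iv[2], length(delta))])
  }, numeric(1))
  names(out) <- vapply(intervals, function(iv)
    sprintf("ssd_%g_%g", iv[1], iv[2]), character(1))
  out
}

welch_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  tryCatch(t.test(x, y)$p.value, error = function(e) 1)
}

#' Group comparison of interval sums across a study
#'
#' Computes per-subject interval sums from a matrix of difference waveforms
#' and tests each interval for a group difference with a Welch two-sample
#' t-test. Degenerate (constant) intervals return p = 1.
#'
#' @param deltas `n_subjects x T` matrix of difference waveforms.
#' @param group per-subject factor (`ASD`/`TD`).
#' @inheritParams interval_ssd
#' @return List with `sums` (`n_subjects x n_intervals`) and `p_values`.
#' @export
interval_ssd_groups <- function(deltas, group, fs, pre_stim_ms,
                                intervals = list(c(0, 150), c(150, 250),
                                                 c(250, 400), c(400, 1000))) {
  sums <- t(apply(deltas, 1, interval_ssd, fs = fs,
                  pre_stim_ms = pre_stim_ms, intervals = intervals))
  p <- apply(sums, 2, function(col)
    welch_p(col[group == "ASD"], col[group == "TD"]))
  list(sums = sums, p_values = p)
}

#' Coarse-grain a series for multiscale entropy
#'
#' Default mode replaces the series by non-overlapping window means of
#' width `scale` (output length `floor(N / scale)`); the `"moving"` mode
#' uses a sliding window (output length `N - scale + 1`).
#'
#' @param x numeric series.
#' @param scale integer window width (>= 1).
#' @param mode `"nonoverlap"` or `"moving"`.
#' @return The coarse-grained series.
#' @export
coarse_grain <- function(x, scale, mode = c("nonoverlap", "moving")) {
  mode <- match.arg(mode)
  scale <- as.integer(scale)
  if (scale < 1) stop("scale must be >= 1")
  if (length(x) < scale) stop("series shorter than scale")
  if (scale == 1L) return(as.numeric(x))
  if (mode == "nonoverlap") {
    n <- length(x) %/% scale
    as.numeric(colMeans(matrix(x[seq_len(n * scale)], scale, n)))
  } else {
    as.numeric(stats::filter(x, rep(1 / scale, scale),
                             sides = 1)[scale:length(x)])
  }
}

#' Sample entropy
#'
#' `-ln(A / B)` where `B` counts template pairs (i != j) of length `m`
#' matching within tolerance `r` under the Chebyshev distance, and `A` the
#' same pairs still matching at length `m + 1`; self-matches are excluded.
#' Low values mean regularity (a matched template predicts its next point);
#' white noise scores high. A constant series returns 0; if no template pair
#' matches at either length the value is `NaN` with a warning.
#'
#' @param x numeric series, length > `m + 1`.
#' @param m embedding (template) length.
#' @param r tolerance; defaults to `0.15 * sd(x)`.
#' @return Scalar entropy (dimensionless).
#' @export
sample_entropy <- function(x, m = 2, r = 0.15 * sd(x)) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short for embedding length m")
  counts <- sampen_counts(x, as.integer(m), r)
  B <- counts[1]; A <- counts[2]
  if (B == 0 || A == 0) {
    if (length(unique(x)) == 1L) return(0)
    warning("no matching templates at tolerance r; sample entropy undefined")
    return(NaN)
  }
  -log(A / B)
}

#' Modified multiscale entropy features
#'
#' Complexity profile of each subject's EEG: every other channel in montage
#' order is kept (64 of a 128-channel net); for each kept channel the
#' earliest clean epochs are concatenated, resampled to the 250 Hz working
#' rate (integer decimation after an order-8 low-pass) until
#' `target_samples` contiguous samples are accumulated (20 s at 250 Hz),
#' then sample entropy is computed on coarse-grained copies at scales
#' `1..n_scales` with the tolerance fixed from the scale-1 series. Output is
#' channel-major (`channel 1` scales `1..n`, then `channel 2`, ...), length
#' `floor(C / 2) * n_scales` — 1,280 for a 128-channel recording.
#'
#' If a channel has fewer clean samples than requested, all of its clean
#' data are used (with a warning); a channel with no clean epochs
#' contributes zeros (with a warning).
#'
#' @param recording a baseline-corrected [epoched_recording].
#' @param mask a [clean_mask]; defaults to keeping everything.
#' @param n_scales number of timescales.
#' @param target_samples samples per channel at the working rate.
#' @param working_fs working sampling rate, Hz; `fs` must be an integer
#'   multiple.
#' @param m,r_factor sample-entropy embedding length and tolerance factor.
#' @return Named numeric vector of `floor(C/2) * n_scales` entropy values.
#' @export
mmse_features <- function(recording, mask = NULL, n_scales = 20,
                          target_samples = 5000, working_fs = 250,
                          m = 2, r_factor = 0.15) {
  if (is.null(mask))
    mask <- clean_mask(matrix(TRUE, n_channels(recording), n_epochs(recording)))
  check_mask_shape(recording, mask)
  C <- n_channels(recording)
  q <- recording$fs / working_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs must be an integer multiple of the working rate")
  q <- as.integer(round(q))
  kept <- seq(2, C, by = 2)
  ord <- order(recording$block_of, seq_len(n_epochs(recording)))
  T <- n_samples(recording)
  need_raw <- target_samples * q
  out <- numeric(length(kept) * n_scales)
  names(out) <- paste0(rep(recording$channels[kept], each = n_scales),
                       "_s", rep(seq_len(n_scales), length(kept)))
  short <- character(0)
  for (ci in seq_along(kept)) {
    c <- kept[ci]
    eps <- ord[mask$keep[c, ord]]
    if (!length(eps)) {
      warning("channel ", recording$channels[c],
              " has no clean epochs; mMSE set to 0")
      next
    }
    n_ep <- min(length(eps), ceiling(need_raw / T))
    x <- as.numeric(recording$data[c, eps[seq_len(n_ep)], ])
    if (length(x) < need_raw && length(eps) <= n_ep)
      short <- c(short, recording$channels[c])
    if (q > 1L) x <- signal::decimate(x, q, n = 8)
    if (length(x) > target_samples) x <- x[seq_len(target_samples)]
    r <- r_factor * sd(x)
    for (s in seq_len(n_scales)) {
      xs <- coarse_grain(x, s)
      out[(ci - 1) * n_scales + s] <-
        if (length(xs) > m + 1) sample_entropy(xs, m = m, r = r) else 0
    }
  }
  if (length(short))
    warning("insufficient clean data on channel(s) ",
            paste(short, collapse = ", "), "; used all available samples")
  out
}

#' Per-subject feature extraction
#'
#' Runs the feature stage end to end for one subject: baseline correction,
#' channel-by-epoch rejection (threshold + trend line), pooled median
#' waveforms, SSD and variance partitions, and the 23-dimensional selected
#' vector; optionally the multiscale-entropy block.
#'
#' @param recording an [epoched_recording].
#' @param reject_cfg a [rejection_config].
#' @param variance_source `"delta"` computes the partition variances on the
#'   difference waveform (the printed formula); `"standard"` uses the
#'   typical standard waveform instead (the prose reading), kept as an
#'   option.
#' @param include_mmse compute the multiscale-entropy block as well.
#' @param mmse_args list of arguments forwarded to [mmse_features()].
#' @return List of class `subject_features`: `waveforms`, `mask`, `ssd`
#'   (24), `variance` (12), `selected` (23), and optionally `mmse`.
#' @export
subject_features <- function(recording, reject_cfg = rejection_config(),
                             variance_source = c("delta", "standard"),
                             include_mmse = FALSE, mmse_args = list()) {
  variance_source <- match.arg(variance_source)
  if (!recording$baselined) recording <- baseline_correct(recording)
  mask <- reject_cells(recording, reject_cfg)
  mw <- median_waveforms(recording, mask)
  ssd <- ssd_features(mw$delta, 24)
  vsrc <- if (variance_source == "delta") mw$delta else mw$s_bar
  v <- variance_features(vsrc, 12)
  out <- list(waveforms = mw, mask = mask, ssd = ssd, variance = v,
              selected = select_features(ssd, v))
  if (include_mmse)
    out$mmse <- do.call(mmse_features,
                        c(list(recording = recording, mask = mask), mmse_args))
  class(out) <- "subject_features"
  out
}

#' @exportS3Method print subject_features
print.subject_features <- function(x, ...) {
  cat(sprintf("<subject_features> 24 SSD + 12 variance -> %d selected%s\n",
              length(x$selected),
              if (is.null(x$mmse)) "" else
                sprintf(" (+ %d mMSE)", length(x$mmse))))
  invisible(x)
}
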