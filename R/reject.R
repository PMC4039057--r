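#' Rejection criteria bundle
#'
#' Amplitude, trend-line and kurtosis bounds used by the artifact-rejection
#' stage. Defaults follow common practice for paediatric high-density nets:
#' a +/-100 microvolt amplitude bound after baselining, a 50 microvolt/epoch
#' trend slope with a 0.3 coefficient-of-determination floor, and a
#' 5-standard-deviation kurtosis screen for channels.
#'
#' @param threshold_uv amplitude bound, microvolts.
#' @param trend_slope_uv trend slope bound, microvolts per epoch duration.
#' @param trend_min_r2 minimum R^2 for a trend fit to count.
#' @param kurtosis_z channel-rejection bound in SD units.
#' @return A `rejection_config` list.
#' @export
rejection_config <- function(threshold_uv = 100, trend_slope_uv = 50,
                             trend_min_r2 = 0.3, kurtosis_z = 5) {
  if (any(c(threshold_uv, trend_slope_uv, trend_min_r2, kurtosis_z) <= 0))
    stop("all rejection bounds must be > 0")
  structure(list(threshold_uv = threshold_uv, trend_slope_uv = trend_slope_uv,
                 trend_min_r2 = trend_min_r2, kurtosis_z = kurtosis_z),
            class = "rejection_config")
}

#' Baseline-correct every epoch-channel
#'
#' Subtracts the mean of the pre-stimulus samples from each (channel, epoch)
#' vector, so the pre-stimulus mean of every cell is zero and post-stimulus
#' shape is preserved up to that constant.
#'
#' @param recording an [epoched_recording] with a non-empty baseline.
#' @return The baseline-corrected [epoched_recording].
#' @export
baseline_correct <- function(recording) {
  pre_n <- pre_samples(recording)
  if (pre_n == 0) stop("recording has no pre-stimulus baseline to correct against")
  d <- dim(recording$data)
  m <- rowMeans(matrix(recording$data[, , seq_len(pre_n)], d[1] * d[2], pre_n))
  recording$data <- recording$data - array(m, d)
  recording$baselined <- TRUE
  recording
}

#' Amplitude-threshold rejection, channel by epoch
#'
#' A cell (channel, epoch) is rejected when any sample of its
#' baseline-corrected signal deviates from baseline by strictly more than
#' `threshold_uv` in absolute value; a sample exactly at the bound is kept.
#' Rejection of a cell is independent of every other channel in that epoch.
#'
#' @param recording a baseline-corrected [epoched_recording].
#' @param threshold_uv amplitude bound, microvolts.
#' @return A [clean_mask].
#' @export
reject_threshold <- function(recording, threshold_uv = 100) {
  mx <- cell_absmax(as.numeric(recording$data), n_channels(recording),
                    n_epochs(recording), n_samples(recording))
  keep <- mx <= threshold_uv
  log <- matrix("none", nrow(keep), ncol(keep))
  log[!keep] <- "threshold"
  clean_mask(keep, log)
}

# Closed-form least-squares slope and R^2 of every cell against time
# normalised to one epoch unit. Returns list(slope, r2), each C x E.
cell_trend_fit <- function(recording) {
  m <- cell_matrix(recording)
  T <- ncol(m)
  if (T < 3) stop("trend-line rejection needs at least 3 samples")
  t <- (seq_len(T) - 1) / (T - 1)
  tc <- t - mean(t)
  St <- sum(tc^2)
  slope <- as.numeric(m %*% tc) / St
  Sxx <- rowSums(m^2) - rowSums(m)^2 / T
  r2 <- ifelse(Sxx > 0, slope^2 * St / Sxx, 0)
  d <- dim(recording$data)
  list(slope = matrix(slope, d[1], d[2]), r2 = matrix(r2, d[1], d[2]))
}

#' Trend-line rejection, channel by epoch
#'
#' Fits an ordinary least-squares line to each cell's samples against time
#' (the epoch duration normalised to one unit, so the slope is in microvolts
#' per epoch) and rejects the cell when the absolute slope exceeds
#' `slope_bound` and the fit's R^2 is at least `r2_min`.
#'
#' @param recording an [epoched_recording] with `T >= 3`.
#' @param slope_bound slope bound, microvolts per epoch duration.
#' @param r2_min coefficient-of-determination floor.
#' @return A [clean_mask].
#' @export
reject_trendline <- function(recording, slope_bound = 50, r2_min = 0.3) {
  fit <- cell_trend_fit(recording)
  reject <- abs(fit$slope) > slope_bound & fit$r2 >= r2_min
  log <- matrix("none", nrow(reject), ncol(reject))
  log[reject] <- "trendline"
  clean_mask(!reject, log)
}

#' Combine two rejection masks
#'
#' A cell is discarded if either mask rejects it, or both; criterion logs
#' are merged (`"both"` when each mask names a different criterion).
#'
#' @param a,b [clean_mask] objects of identical shape.
#' @return A [clean_mask].
#' @export
combine_masks <- function(a, b) {
  if (!identical(dim(a$keep), dim(b$keep))) stop("mask shapes differ")
  keep <- a$keep & b$keep
  log <- matrix("none", nrow(keep), ncol(keep))
  only_a <- !a$keep & b$keep
  only_b <- a$keep & !b$keep
  both <- !a$keep & !b$keep
  log[only_a] <- a$criteria_log[only_a]
  log[only_b] <- b$criteria_log[only_b]
  log[both] <- ifelse(a$criteria_log[both] == b$criteria_log[both],
                      a$criteria_log[both], "both")
  clean_mask(keep, log)
}

#' Full channel-by-epoch rejection
#'
#' Convenience wrapper: baseline correction (if needed) followed by the
#' amplitude-threshold and trend-line criteria combined.
#'
#' @param recording an [epoched_recording].
#' @param config a [rejection_config].
#' @return A [clean_mask].
#' @export
reject_cells <- function(recording, config = rejection_config()) {
  if (!recording$baselined) recording <- baseline_correct(recording)
  combine_masks(reject_threshold(recording, config$threshold_uv),
                reject_trendline(recording, config$trend_slope_uv,
                                 config$trend_min_r2))
}

#' Kurtosis channel screening
#'
#' Flags spiky channels per block: the excess (Fisher) kurtosis of each
#' channel's pooled samples across the block's epochs is standardised across
#' the block's channels, and a channel is rejected when its |z| exceeds
#' `z_bound`. Used by the traditional whole-epoch comparator.
#'
#' @param recording an [epoched_recording] with at least two channels.
#' @param z_bound rejection bound in SD units.
#' @return Named list, one character vector of rejected channel ids per
#'   block.
#' @export
reject_channels_kurtosis <- function(recording, z_bound = 5) {
  C <- n_channels(recording)
  if (C < 2) stop("kurtosis screening needs at least 2 channels")
  blocks <- sort(unique(recording$block_of))
  out <- vector("list", length(blocks))
  names(out) <- paste0("block", blocks)
  for (i in seq_along(blocks)) {
    eb <- which(recording$block_of == blocks[i])
    x <- matrix(recording$data[, eb, ], C, length(eb) * n_samples(recording))
    mu <- rowMeans(x)
    xc <- x - mu
    m2 <- rowMeans(xc^2)
    m4 <- rowMeans(xc^4)
    kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
    s <- sd(kurt)
    if (!is.finite(s) || s == 0) {
      warning("kurtosis identical across channels in block ", blocks[i],
              "; no channels rejected")
      out[[i]] <- character(0)
    } else {
      z <- (kurt - mean(kurt)) / s
      out[[i]] <- recording$channels[abs(z) > z_bound]
    }
  }
  out
}

#' Traditional whole-epoch rejection
#'
#' The comparator scheme: an epoch is kept only if every non-blacklisted
#' channel passes the amplitude criterion in that epoch, i.e. the epoch's
#' entire column of the channel-by-epoch mask must be clean.
#'
#' @param recording a baseline-corrected [epoched_recording].
#' @param threshold_uv amplitude bound, microvolts.
#' @param channel_blacklist channel ids excluded from the criterion (e.g.
#'   the kurtosis-screened set).
#' @return Integer vector of kept epoch indices, with the full logical
#'   keep vector in attribute `"keep"`.
#' @export
traditional_reject <- function(recording, threshold_uv = 100,
                               channel_blacklist = character()) {
  mask <- reject_threshold(recording, threshold_uv)
  rows <- which(!recording$channels %in% channel_blacklist)
  keep_epoch <- apply(mask$keep[rows, , drop = FALSE], 2, all)
  structure(which(keep_epoch), keep = keep_epoch)
}

#' Retention as a function of rejection threshold
#'
#' For each threshold and block, the proportion of data retained by the
#' channel-by-epoch scheme (clean cells / all cells) and by the traditional
#' scheme (clean epochs / all epochs), summarised across blocks by median
#' and quartiles. Because a traditionally kept epoch must be clean on every
#' channel, the cell-wise retention dominates the traditional one at every
#' threshold.
#'
#' @param recording a baseline-corrected [epoched_recording].
#' @param thresholds vector of amplitude bounds, microvolts.
#' @param channel_blacklist channels excluded from the traditional
#'   criterion.
#' @return A data frame of class `retention_curve` with columns
#'   `threshold`, `method`, `median`, `q25`, `q75`.
#' @export
retention_curve <- function(recording, thresholds = seq(100, 1000, by = 100),
                            channel_blacklist = character()) {
  mx <- cell_absmax(as.numeric(recording$data), n_channels(recording),
                    n_epochs(recording), n_samples(recording))
  rows <- which(!recording$channels %in% channel_blacklist)
  blocks <- sort(unique(recording$block_of))
  res <- expand.grid(threshold = thresholds,
                     method = c("channel_by_epoch", "traditional"),
                     stringsAsFactors = FALSE)
  cell_p <- matrix(NA_real_, length(blocks), length(thresholds))
  trad_p <- matrix(NA_real_, length(blocks), length(thresholds))
  for (i in seq_along(blocks)) {
    eb <- which(recording$block_of == blocks[i])
    mb <- mx[, eb, drop = FALSE]
    for (j in seq_along(thresholds)) {
      keep <- mb <= thresholds[j]
      cell_p[i, j] <- mean(keep)
      trad_p[i, j] <- mean(apply(keep[rows, , drop = FALSE], 2, all))
    }
  }
  summarise <- function(p) {
    data.frame(median = apply(p, 2, median),
               q25 = apply(p, 2, quantile, 0.25),
               q75 = apply(p, 2, quantile, 0.75))
  }
  out <- rbind(cbind(threshold = thresholds, method = "channel_by_epoch",
                     summarise(cell_p)),
               cbind(threshold = thresholds, method = "traditional",
                     summarise(trad_p)))
  rownames(out) <- NULL
  class(out) <- c("retention_curve", "data.frame")
  out
}

#' @export
plot.retention_curve <- function(x, ...) {
  cols <- c(channel_by_epoch = "blue", traditional = "red")
  graphics::plot(NA, xlim = range(x$threshold), ylim = c(0, 1),
                 xlab = "rejection threshold (uV)",
                 ylab = "proportion retained per block", ...)
  for (m in unique(x$method)) {
    s <- x[x$method == m, ]
    graphics::lines(s$threshold, s$median, col = cols[[m]], lwd = 2)
    graphics::lines(s$threshold, s$q25, col = cols[[m]], lty = 2)
    graphics::lines(s$threshold, s$q75, col = cols[[m]], lty = 2)
  }
  graphics::legend("bottomright", legend = names(cols), col = cols, lwd = 2)
  invisible(x)
}

kw_pvalue <- function(x, g) {
  if (length(unique(x)) == 1L) return(list(statistic = 0, p.value = 1))
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Rejection topography and periocular group comparison
#'
#' Totals the rejected epochs per channel across a study and, for the
#' flagged periocular channels, compares the per-subject rejection
#' proportions between groups with a Kruskal-Wallis rank test — the pattern
#' expected when one group blinks more is a frontal excess of rejections.
#'
#' @param study a [study_set].
#' @param masks list of [clean_mask] objects, one per subject.
#' @return List of class `rejection_topography`: `channel_counts` (named
#'   total rejections per channel) and `periocular` (data frame with group
#'   medians and p-value per periocular channel).
#' @export
rejection_topography <- function(study, masks) {
  if (length(masks) != n_subjects(study))
    stop("one mask per subject is required")
  if (!all(levels(study$group) %in% as.character(unique(study$group))))
    stop("both groups must have at least one subject")
  channels <- study$recordings[[1]]$channels
  counts <- numeric(length(channels))
  prop <- matrix(NA_real_, n_subjects(study), length(channels))
  for (i in seq_len(n_subjects(study))) {
    rej <- !masks[[i]]$keep
    counts <- counts + rowSums(rej)
    prop[i, ] <- rowMeans(rej)
  }
  names(counts) <- channels
  peri <- study$recordings[[1]]$periocular
  tab <- do.call(rbind, lapply(peri, function(ch) {
    j <- match(ch, channels)
    kw <- kw_pvalue(prop[, j], study$group)
    data.frame(channel = ch,
               median_asd = median(prop[study$group == "ASD", j]),
               median_td = median(prop[study$group == "TD", j]),
               statistic = kw$statistic, p_value = kw$p.value)
  }))
  structure(list(channel_counts = counts, periocular = tab),
            class = "rejection_topography")
}

#' @exportS3Method print rejection_topography
print.rejection_topography <- function(x, ...) {
  cat("<rejection_topography>\n")
  cat(sprintf("  most-rejected channels: %s\n",
              paste(names(sort(x$channel_counts, decreasing = TRUE))[1:5],
                    collapse = ", ")))
  print(x$periocular, row.names = FALSE)
  invisible(x)
}
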