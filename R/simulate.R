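#' Configuration for the synthetic oddball-EEG generator
#'
#' Defines a simulated auditory-oddball cohort: a high-density net recording
#' blocks of epochs with an 85/15 standard/deviant split, event-related
#' responses built from Gaussian components, pink (1/f) background noise with
#' a shared across-channel component, and injected blink/drift/spike
#' artifacts. The deviant template of the ASD group is made more positive in
#' the early (0--200 ms) and late (400--1000 ms) post-stimulus windows, and
#' blink probability is group-dependent and elevated after deviant stimuli
#' (novelty-evoked blinks), so that blink rate can reach the
#' deviant-minus-standard features exactly as a real ocular confound would.
#'
#' @param n_asd,n_td subject counts per group.
#' @param C number of channels.
#' @param fs sampling rate, Hz.
#' @param pre_stim_ms,post_stim_ms epoch window, ms.
#' @param blocks_per_subject,epochs_per_block recording structure.
#' @param deviant_fraction proportion of deviant stimuli per block.
#' @param min_gap minimum number of standards flanking every deviant.
#' @param n_periocular number of flagged periocular channels.
#' @param erp_components data frame (`latency_ms`, `width_ms`,
#'   `amplitude_uv`, `profile`) of Gaussian components shared by both
#'   stimulus classes; profiles are `"central"`, `"frontal"` or `"uniform"`.
#' @param deviant_components additional components evoked by deviants only
#'   (novelty response), same format.
#' @param asd_deviant_boost amplitude (microvolts) added to the ASD deviant
#'   template in the 0--200 and 400--1000 ms post-stimulus windows.
#' @param subject_scale_sd log-scale SD of the per-subject multiplicative
#'   amplitude jitter applied to the templates (between-subject variability).
#' @param noise_sd pink-noise RMS per channel, microvolts.
#' @param noise_shared proportion of noise variance shared across channels
#'   (induces the inter-channel correlation blind source separation needs).
#' @param blink_rate_asd,blink_rate_td per-epoch blink probability after a
#'   standard stimulus, by group.
#' @param blink_deviant_multiplier multiplier on the blink probability after
#'   deviant stimuli (capped at 1).
#' @param blink_amplitude_uv blink peak amplitude at the periocular sites.
#' @param blink_latency_ms,blink_width_ms centre and SD of the positive
#'   blink lobe (post-stimulus ms).
#' @param drift_prob,drift_slope_uv per-cell probability and magnitude of a
#'   linear drift spanning the epoch.
#' @param spike_prob,spike_amplitude_uv per-cell probability and magnitude
#'   of a brief spike artifact.
#' @param asd_male_fraction,td_male_fraction deterministic male fractions
#'   used to assign sex metadata.
#' @param seed integer study seed; per-subject substreams are derived from
#'   it, so equal seeds give identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_asd = 19, n_td = 30,
                       C = 128, fs = 1000,
                       pre_stim_ms = 200, post_stim_ms = 1000,
                       blocks_per_subject = 1, epochs_per_block = 400,
                       deviant_fraction = 0.15, min_gap = 4,
                       n_periocular = 8,
                       erp_components = default_erp_components(),
                       deviant_components = default_deviant_components(),
                       asd_deviant_boost = 3,
                       subject_scale_sd = 0.2,
                       noise_sd = 10, noise_shared = 0.3,
                       blink_rate_asd = 0.30, blink_rate_td = 0.10,
                       blink_deviant_multiplier = 3,
                       blink_amplitude_uv = 150,
                       blink_latency_ms = 300, blink_width_ms = 50,
                       drift_prob = 0.02, drift_slope_uv = 80,
                       spike_prob = 0.01, spike_amplitude_uv = 150,
                       asd_male_fraction = 16 / 19,
                       td_male_fraction = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(deviant_fraction, blink_rate_asd, blink_rate_td, drift_prob,
             spike_prob, noise_shared)
  if (any(probs < 0 | probs > 1))
    stop("fractions and probabilities must lie in [0, 1]")
  amps <- c(asd_deviant_boost, noise_sd, blink_amplitude_uv, drift_slope_uv,
            spike_amplitude_uv, erp_components$amplitude_uv,
            deviant_components$amplitude_uv)
  if (!all(is.finite(amps))) stop("amplitudes must be finite")
  if (cfg$n_periocular >= cfg$C) stop("n_periocular must be < C")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_erp_components <- function() {
  data.frame(latency_ms = c(100, 170, 280),
             width_ms = c(30, 40, 60),
             amplitude_uv = c(4, -6, 5),
             profile = c("central", "central", "central"))
}

#' @rdname sim_config
#' @export
default_deviant_components <- function() {
  data.frame(latency_ms = 350, width_ms = 120, amplitude_uv = 4,
             profile = "central")
}

# Scalar "frontality" coordinate per channel: periocular sites at 1, the
# rest graded front-to-back. Stands in for net geometry at the
# frontal/central/posterior grouping level only.
montage_frontality <- function(C, n_periocular) {
  f <- numeric(C)
  f[seq_len(n_periocular)] <- 1
  rest <- C - n_periocular
  if (rest > 0) f[(n_periocular + 1):C] <- seq(0.9, 0, length.out = rest)
  f
}

blink_topography <- function(frontality) exp(-3 * (1 - frontality))

profile_weight <- function(profile, frontality) {
  switch(profile,
         central = exp(-((frontality - 0.45)^2) / (2 * 0.25^2)),
         frontal = frontality,
         uniform = rep(1, length(frontality)),
         stop("unknown scalp profile: ", profile))
}

# Sum-of-Gaussian-bumps template, C x T, for one component table.
component_template <- function(components, t_post_ms, frontality) {
  C <- length(frontality); T <- length(t_post_ms)
  out <- matrix(0, C, T)
  for (i in seq_len(nrow(components))) {
    bump <- exp(-((t_post_ms - components$latency_ms[i])^2) /
                  (2 * components$width_ms[i]^2))
    w <- profile_weight(components$profile[i], frontality)
    out <- out + components$amplitude_uv[i] * (w %o% bump)
  }
  out
}

# Noise-free class templates for one group (list: standard, deviant).
group_templates <- function(config, group) {
  t_ms <- (seq_len(round((config$pre_stim_ms + config$post_stim_ms) *
                           config$fs / 1000)) - 1) * 1000 / config$fs -
    config$pre_stim_ms
  frontality <- montage_frontality(config$C, config$n_periocular)
  std <- component_template(config$erp_components, t_ms, frontality)
  dev <- std + component_template(config$deviant_components, t_ms, frontality)
  if (group == "ASD" && config$asd_deviant_boost != 0) {
    win <- (t_ms >= 0 & t_ms < 200) | (t_ms >= 400 & t_ms < 1000)
    w <- profile_weight("central", frontality)
    dev <- dev + config$asd_deviant_boost * (w %o% as.numeric(win))
  }
  list(standard = std, deviant = dev)
}

#' Pseudo-randomised oddball stimulus schedule
#'
#' Draws a standard/deviant sequence with exactly
#' `round(n_epochs * deviant_fraction)` deviants in which every deviant is
#' preceded and followed by at least `min_gap` standards (including the
#' block boundaries). Uses the current RNG stream.
#'
#' @param n_epochs block length.
#' @param deviant_fraction proportion of deviants.
#' @param min_gap minimum run of standards flanking each deviant.
#' @return Factor of length `n_epochs` with levels `standard`, `deviant`.
#' @export
make_schedule <- function(n_epochs, deviant_fraction, min_gap = 4) {
  n_dev <- round(n_epochs * deviant_fraction)
  if (n_dev == 0)
    return(factor(rep("standard", n_epochs), levels = c("standard", "deviant")))
  n_std <- n_epochs - n_dev
  slots <- n_dev + 1L
  extras <- n_std - min_gap * slots
  if (extras < 0)
    stop(sprintf("no schedule with %d deviants and gap %d fits in %d epochs",
                 n_dev, min_gap, n_epochs))
  extra <- tabulate(sample.int(slots, extras, replace = TRUE), nbins = slots)
  gaps <- min_gap + extra
  lab <- character(0)
  for (i in seq_len(n_dev))
    lab <- c(lab, rep("standard", gaps[i]), "deviant")
  lab <- c(lab, rep("standard", gaps[slots]))
  factor(lab, levels = c("standard", "deviant"))
}

# Pink noise: spectrally shaped white noise (power ~ 1/f), unit-SD columns.
pink_noise <- function(T, n) {
  white <- matrix(rnorm(T * n), T, n)
  if (T < 4) return(white)
  k <- 0:(T - 1)
  f <- pmin(k, T - k)
  amp <- c(0, 1 / sqrt(f[-1]))
  X <- Re(mvfft(mvfft(white) * amp, inverse = TRUE)) / T
  sds <- sqrt(colMeans(X^2) - colMeans(X)^2)
  sds[sds == 0] <- 1
  sweep(X, 2, sds, "/")
}

#' Simulate one subject's oddball recording
#'
#' Builds `signal = class template + pink noise + injected artifacts` and a
#' ground-truth record of every injection, enabling recovery tests of the
#' rejection, feature and blink-counting stages.
#'
#' @param config a [sim_config].
#' @param group `"ASD"` or `"TD"`.
#' @param seed integer seed for this subject's substream.
#' @param subject_id identifier stored in the recording.
#' @return A list with components `recording` (an [epoched_recording]) and
#'   `truth` (blink epochs, per-cell artifact kinds, the subject's noise-free
#'   templates, and the template scale factor).
#' @export
simulate_subject <- function(config, group = c("TD", "ASD"), seed = config$seed,
                             subject_id = "S001") {
  group <- match.arg(group)
  with_seed(seed, {
    fs <- config$fs
    T <- as.integer(round((config$pre_stim_ms + config$post_stim_ms) * fs / 1000))
    C <- config$C
    E <- config$blocks_per_subject * config$epochs_per_block
    frontality <- montage_frontality(C, config$n_periocular)
    btopo <- blink_topography(frontality)
    scale <- exp(rnorm(1, 0, config$subject_scale_sd))
    tpl <- group_templates(config, group)
    tpl$standard <- tpl$standard * scale
    tpl$deviant <- tpl$deviant * scale
    t_post_ms <- (seq_len(T) - 1) * 1000 / fs - config$pre_stim_ms
    blink_lobe <- exp(-((t_post_ms - config$blink_latency_ms)^2) /
                        (2 * config$blink_width_ms^2))
    t_norm <- if (T > 1) (seq_len(T) - 1) / (T - 1) else 0

    labels <- factor(character(E), levels = c("standard", "deviant"))
    block_of <- integer(E)
    data <- array(0, c(C, E, T))
    blink_epochs <- integer(0)
    artifacts <- matrix("none", C, E)
    rate <- if (group == "ASD") config$blink_rate_asd else config$blink_rate_td

    e0 <- 0L
    for (b in seq_len(config$blocks_per_subject)) {
      sched <- make_schedule(config$epochs_per_block, config$deviant_fraction,
                             config$min_gap)
      for (j in seq_len(config$epochs_per_block)) {
        e <- e0 + j
        labels[e] <- sched[j]
        block_of[e] <- b
        x <- if (sched[j] == "standard") tpl$standard else tpl$deviant
        if (config$noise_sd > 0) {
          nz <- pink_noise(T, C + 1L)
          own <- t(nz[, seq_len(C), drop = FALSE])
          shared <- rep(1, C) %o% nz[, C + 1L]
          x <- x + config$noise_sd *
            (sqrt(1 - config$noise_shared) * own +
               sqrt(config$noise_shared) * shared)
        }
        p_blink <- min(1, rate * if (sched[j] == "deviant")
          config$blink_deviant_multiplier else 1)
        if (p_blink > 0 && runif(1) < p_blink) {
          x <- x + config$blink_amplitude_uv * (btopo %o% blink_lobe)
          blink_epochs <- c(blink_epochs, e)
        }
        if (config$drift_prob > 0) {
          hit <- which(runif(C) < config$drift_prob)
          for (c in hit) {
            x[c, ] <- x[c, ] + sample(c(-1, 1), 1) * config$drift_slope_uv *
              (t_norm - 0.5)
            artifacts[c, e] <- "drift"
          }
        }
        if (config$spike_prob > 0) {
          hit <- which(runif(C) < config$spike_prob)
          for (c in hit) {
            at <- sample.int(T, 1)
            idx <- intersect(at + (-1:1), seq_len(T))
            x[c, idx] <- x[c, idx] + sample(c(-1, 1), 1) *
              config$spike_amplitude_uv * c(0.5, 1, 0.5)[seq_along(idx)]
            artifacts[c, e] <- if (artifacts[c, e] == "drift") "both" else "spike"
          }
        }
        data[, e, ] <- x
      }
      e0 <- e0 + config$epochs_per_block
    }
    rec <- epoched_recording(
      data, fs = fs, pre_stim_ms = config$pre_stim_ms, labels = labels,
      block_of = block_of, periocular = sprintf("E%03d", seq_len(config$n_periocular)),
      subject_id = subject_id, group = group)
    truth <- list(blink_epochs = blink_epochs, artifacts = artifacts,
                  templates = tpl, scale = scale, seed = seed)
    list(recording = rec, truth = truth)
  })
}

#' Simulate a two-group oddball study
#'
#' Generates `n_asd + n_td` subjects with per-subject seeds derived
#' deterministically from `config$seed`. Sex metadata is assigned
#' deterministically from the configured male fractions.
#'
#' @param config a [sim_config].
#' @param subject_fn optional function `(recording, truth) -> value`; when
#'   supplied, each subject's recording is replaced by `subject_fn`'s return
#'   value immediately after generation (memory-lean cohort processing) and
#'   the function returns a list of those values instead of a [study_set].
#' @return When `subject_fn` is `NULL`: a list with `study` (a [study_set])
#'   and `truth` (one ground-truth record per subject). Otherwise a list
#'   with `values`, `group`, `sex`, `truth`.
#' @export
simulate_study <- function(config, subject_fn = NULL) {
  n <- config$n_asd + config$n_td
  group <- c(rep("ASD", config$n_asd), rep("TD", config$n_td))
  n_asd_m <- round(config$n_asd * config$asd_male_fraction)
  n_td_m <- round(config$n_td * config$td_male_fraction)
  sex <- c(rep(c("M", "F"), c(n_asd_m, config$n_asd - n_asd_m)),
           rep(c("M", "F"), c(n_td_m, config$n_td - n_td_m)))
  truth <- vector("list", n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    res <- simulate_subject(config, group[i], seed = derive_seed(config$seed, i),
                            subject_id = sprintf("S%03d", i))
    truth[[i]] <- res$truth
    out[[i]] <- if (is.null(subject_fn)) res$recording
                else subject_fn(res$recording, res$truth)
  }
  if (is.null(subject_fn))
    list(study = study_set(out, group = group, sex = sex), truth = truth)
  else
    list(values = out, group = factor(group, c("ASD", "TD")), sex = sex,
         truth = truth)
}
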