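# Synthetic cohort drivers shared by the acceptance-style tests. Problem
# sizes follow the package's desk-scale study conditions: 19 ASD / 30 TD
# subjects, a 32-channel montage and one 150-epoch block per subject at
# 1 kHz (the full feature geometry, reduced spatially).

recovery_cohort_cfg <- function(seed) {
  sim_config(n_asd = 19, n_td = 30, C = 32, epochs_per_block = 150,
             seed = seed)
}

confound_cohort_cfg <- function(seed) {
  cfg <- recovery_cohort_cfg(seed)
  cfg$asd_deviant_boost <- 0   # blink rate is the only group difference
  cfg
}

# Simulate the recovery cohort; per subject: reject, features, and (when
# requested) ICA blink counting against the injected ground truth.
run_recovery_cohort <- function(seed, count_blinks = TRUE) {
  cfg <- recovery_cohort_cfg(seed)
  i <- 0
  res <- simulate_study(cfg, subject_fn = function(rec, truth) {
    i <<- i + 1
    rec <- baseline_correct(rec)
    out <- list(selected = subject_features(rec)$selected,
                injected = length(truth$blink_epochs))
    if (count_blinks) {
      dec <- decompose_block(rec, k = 10, seed = truth$seed)
      out$counted <- count_blinks(rec, dec)$n_blinks
    }
    out
  })
  X <- do.call(rbind, lapply(res$values, `[[`, "selected"))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(X = X, y = res$group,
       injected = vapply(res$values, `[[`, numeric(1), "injected"),
       counted = if (count_blinks)
         vapply(res$values, `[[`, numeric(1), "counted"))
}

# Simulate the blink-confound cohort; per subject compute the selected
# features twice: blinks retained vs ICA blink components removed.
run_confound_cohort <- function(seed) {
  cfg <- confound_cohort_cfg(seed)
  res <- simulate_study(cfg, subject_fn = function(rec, truth) {
    rec <- baseline_correct(rec)
    kept <- subject_features(rec)$selected
    dec <- decompose_block(rec, k = 10, seed = truth$seed)
    removed <- subject_features(remove_blinks(rec, dec))$selected
    list(kept = kept, removed = removed)
  })
  Xk <- do.call(rbind, lapply(res$values, `[[`, "kept"))
  Xr <- do.call(rbind, lapply(res$values, `[[`, "removed"))
  rownames(Xk) <- rownames(Xr) <- sprintf("S%03d", seq_len(nrow(Xk)))
  list(X_kept = Xk, X_removed = Xr, y = res$group)
}
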