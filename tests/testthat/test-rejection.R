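test_that("baseline correction zeroes the pre-stimulus mean", {
  # constant epoch collapses to zero
  rec <- tiny_recording(C = 2, E = 3, T = 100, fs = 500, pre_stim_ms = 40,
                        data = array(5, c(2, 3, 100)))
  bc <- baseline_correct(rec)
  expect_equal(max(abs(bc$data)), 0)

  # random epochs match the direct-mean oracle and have ~0 pre-stim mean
  rec <- tiny_recording(C = 3, E = 4, T = 100, fs = 500, pre_stim_ms = 40,
                        seed = 2)
  bc <- baseline_correct(rec)
  pre_n <- round(40 * 500 / 1000)
  for (c in 1:3) for (e in 1:4) {
    m <- mean(rec$data[c, e, 1:pre_n])
    expect_equal(bc$data[c, e, ], rec$data[c, e, ] - m)
    expect_lt(abs(mean(bc$data[c, e, 1:pre_n])), 1e-9)
  }

  rec0 <- tiny_recording(pre_stim_ms = 0)
  expect_error(baseline_correct(rec0), "baseline")
})

test_that("threshold rejection is cellwise with a strict bound", {
  rec <- tiny_recording(C = 8, E = 20, T = 50, data = array(0, c(8, 20, 50)))
  expect_true(all(reject_threshold(rec, 100)$keep))

  # one offending sample rejects exactly that cell; the bound itself is kept
  rec$data[3, 7, 25] <- 100.5
  rec$data[5, 9, 10] <- 100       # exactly at the bound
  mask <- reject_threshold(rec, 100)
  expect_false(mask$keep[3, 7])
  expect_equal(sum(!mask$keep), 1)
  expect_equal(mask$criteria_log[3, 7], "threshold")

  # exhaustive-scan oracle on random data
  rec <- tiny_recording(C = 6, E = 15, T = 40, seed = 9)
  rec$data <- rec$data * 60
  mask <- reject_threshold(rec, 100)
  for (c in 1:6) for (e in 1:15)
    expect_identical(mask$keep[c, e], max(abs(rec$data[c, e, ])) <= 100)
})

test_that("trend-line rejection matches a least-squares oracle", {
  T <- 200
  t_norm <- (0:(T - 1)) / (T - 1)
  flat <- tiny_recording(C = 1, E = 1, T = T, data = array(3, c(1, 1, T)))
  expect_true(all(reject_trendline(flat, 50, 0.3)$keep))

  # an exact line rising 60 uV across the epoch is rejected (R^2 = 1)
  line <- tiny_recording(C = 1, E = 1, T = T,
                         data = array(60 * t_norm, c(1, 1, T)))
  expect_false(any(reject_trendline(line, 50, 0.3)$keep))

  # noisy ramps at slopes 30 / 49 / 51 / 80: kept, kept, rejected, rejected
  slopes <- c(30, 49, 51, 80)
  d <- array(0, c(4, 1, T))
  noise <- with_test_seed(4, rnorm(4 * T, sd = 1))
  for (i in 1:4) d[i, 1, ] <- slopes[i] * t_norm + noise[(i - 1) * T + 1:T]
  ramps <- tiny_recording(C = 4, E = 1, T = T, data = d,
                          labels = "standard")
  mask <- reject_trendline(ramps, 50, 0.3)
  expect_identical(as.vector(mask$keep), c(TRUE, TRUE, FALSE, FALSE))

  # slope and R^2 agree with lm() to 1e-9 on random epochs
  rec <- tiny_recording(C = 3, E = 5, T = 60, seed = 12)
  fit <- oddballEEG:::cell_trend_fit(rec)
  tn <- (0:59) / 59
  for (c in 1:3) for (e in 1:5) {
    lmfit <- lm(rec$data[c, e, ] ~ tn)
    expect_equal(fit$slope[c, e], unname(coef(lmfit)[2]), tolerance = 1e-9)
    expect_equal(fit$r2[c, e], summary(lmfit)$r.squared, tolerance = 1e-9)
  }
})

test_that("mask combination is a cellwise AND with merged logs", {
  keep_a <- with_test_seed(5, matrix(runif(60) > 0.3, 6, 10))
  keep_b <- with_test_seed(6, matrix(runif(60) > 0.3, 6, 10))
  la <- matrix("none", 6, 10); la[!keep_a] <- "threshold"
  lb <- matrix("none", 6, 10); lb[!keep_b] <- "trendline"
  a <- clean_mask(keep_a, la); b <- clean_mask(keep_b, lb)
  ab <- combine_masks(a, b)
  expect_identical(ab$keep, keep_a & keep_b)
  expect_true(all(ab$criteria_log[!keep_a & !keep_b] == "both"))
  expect_true(all(ab$criteria_log[!keep_a & keep_b] == "threshold"))
  expect_true(all(ab$criteria_log[keep_a & !keep_b] == "trendline"))

  all_keep <- clean_mask(matrix(TRUE, 6, 10))
  expect_identical(combine_masks(a, all_keep)$keep, a$keep)
  expect_identical(combine_masks(a, a)$keep, a$keep)
  expect_error(combine_masks(a, clean_mask(matrix(TRUE, 2, 2))), "shape")
})

test_that("kurtosis screening flags only genuinely spiky channels", {
  C <- 32; E <- 20; T <- 100
  d <- with_test_seed(8, array(rnorm(C * E * T), c(C, E, T)))
  rec <- tiny_recording(C = C, E = E, T = T, data = d)
  expect_length(reject_channels_kurtosis(rec, 5)$block1, 0)

  # contaminate one channel with heavy sparse spikes until its kurtosis z
  # stands out, then verify against a direct kurtosis computation
  d[17, , 1] <- d[17, , 1] + 40
  rec2 <- tiny_recording(C = C, E = E, T = T, data = d)
  rej <- reject_channels_kurtosis(rec2, 5)$block1
  expect_identical(rej, rec2$channels[17])
  kurt <- apply(matrix(d, C, E * T), 1, function(x) {
    xc <- x - mean(x); mean(xc^4) / mean(xc^2)^2 - 3
  })
  z <- (kurt - mean(kurt)) / sd(kurt)
  expect_gt(abs(z[17]), 5)

  # identical channels: degenerate SD path warns and rejects nothing
  same <- tiny_recording(C = 2, E = 4, T = 50,
                         data = array(rep(sin(1:50), each = 8), c(2, 4, 50)))
  expect_warning(out <- reject_channels_kurtosis(same, 5), "identical")
  expect_length(out$block1, 0)
})

test_that("traditional rejection keeps an epoch only if all channels pass", {
  rec <- tiny_recording(C = 5, E = 12, T = 30, data = array(0, c(5, 12, 30)))
  expect_equal(as.integer(traditional_reject(rec, 100)), 1:12)

  # every epoch has one offending channel: traditional keeps nothing while
  # the channel-by-epoch mask retains all clean cells
  for (e in 1:12) rec$data[((e - 1) %% 5) + 1, e, 3] <- 150
  kept <- traditional_reject(rec, 100)
  expect_length(kept, 0)
  mask <- reject_threshold(rec, 100)
  expect_equal(sum(mask$keep), 5 * 12 - 12)

  # column-conjunction oracle on random contamination
  rec <- tiny_recording(C = 6, E = 20, T = 40, seed = 13)
  rec$data <- rec$data * 55
  mask <- reject_threshold(rec, 100)
  kept <- attr(traditional_reject(rec, 100), "keep")
  expect_identical(kept, apply(mask$keep, 2, all))

  # blacklisted channels are exempt from the criterion
  rec$data[2, , 1] <- 500
  expect_length(traditional_reject(rec, 100), 0)
  kept_bl <- traditional_reject(rec, 100, channel_blacklist = "E002")
  expect_identical(as.vector(kept_bl),
                   which(apply(mask$keep[-2, ], 2, all)))
})

test_that("retention curves are monotone and cellwise dominates traditional", {
  rec <- tiny_recording(C = 8, E = 30, T = 50, seed = 21,
                        block_of = rep(1:3, each = 10))
  rec$data <- rec$data * 80
  rc <- retention_curve(rec, thresholds = c(50, 100, 200, 400))
  cbe <- rc[rc$method == "channel_by_epoch", ]
  trad <- rc[rc$method == "traditional", ]
  expect_true(all(diff(cbe$median) >= 0))
  expect_true(all(diff(trad$median) >= 0))
  expect_true(all(cbe$median >= trad$median))
  expect_true(all(rc$median >= 0 & rc$median <= 1))

  clean <- tiny_recording(C = 4, E = 10, T = 20,
                          data = array(0, c(4, 10, 20)))
  rc0 <- retention_curve(clean, thresholds = c(100, 200))
  expect_true(all(rc0$median == 1))
})

test_that("cells kept at a threshold are kept at every larger threshold", {
  rec <- tiny_recording(C = 10, E = 25, T = 60, seed = 22)
  rec$data <- rec$data * 70
  prev <- reject_threshold(rec, 60)$keep
  for (thr in c(90, 130, 200, 500)) {
    cur <- reject_threshold(rec, thr)$keep
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("rejection topography compares periocular channels across groups", {
  recs <- lapply(1:6, function(i)
    tiny_recording(C = 4, E = 10, T = 20, periocular = c("E001", "E002"),
                   subject_id = sprintf("S%02d", i),
                   group = if (i <= 3) "ASD" else "TD"))
  st <- study_set(recs)

  # identical masks in both groups: every p-value is 1
  same_mask <- clean_mask(matrix(c(FALSE, rep(TRUE, 39)), 4, 10))
  topo <- rejection_topography(st, rep(list(same_mask), 6))
  expect_true(all(topo$periocular$p_value == 1))
  expect_equal(unname(topo$channel_counts["E001"]), 6)

  # hand-built masks: ASD rejects 8/10, 7/10, 6/10 on E001; TD 2, 1, 0.
  # Kruskal-Wallis on ranks 4,5,6 vs 1,2,3: H = 12 * (3*(5-3.5)^2 +
  # 3*(2-3.5)^2) / (6*7) = 27/7
  masks <- lapply(c(8, 7, 6, 2, 1, 0), function(n) {
    keep <- matrix(TRUE, 4, 10)
    if (n > 0) keep[1, seq_len(n)] <- FALSE
    clean_mask(keep)
  })
  topo <- rejection_topography(st, masks)
  row <- topo$periocular[topo$periocular$channel == "E001", ]
  expect_equal(row$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(row$median_asd, 0.7)
  expect_equal(row$median_td, 0.1)
  expect_equal(row$p_value, kruskal.test(c(8, 7, 6, 2, 1, 0) / 10,
                                         st$group)$p.value)
})

test_that("group-dependent blink rates surface as frontal rejection excess", {
  cfg <- quick_cfg(n_asd = 4, n_td = 4, blink_rate_asd = 0.5,
                   blink_rate_td = 0.05, seed = 17)
  res <- simulate_study(cfg, subject_fn = function(rec, truth)
    reject_cells(baseline_correct(rec)))
  recs <- lapply(seq_along(res$values), function(i)
    tiny_recording(C = cfg$C, E = cfg$epochs_per_block, T = 10,
                   periocular = sprintf("E%03d", 1:3),
                   group = as.character(res$group[i])))
  st <- study_set(recs)
  topo <- rejection_topography(st, res$values)
  expect_true(all(topo$periocular$median_asd > topo$periocular$median_td))
})
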