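test_that("pooled medians match a sort-based oracle and resist outliers", {
  # a single retained cell per class is returned verbatim
  d <- array(rnorm(2 * 2 * 30), c(2, 2, 30))
  rec <- tiny_recording(C = 2, E = 2, T = 30, data = d,
                        labels = c("standard", "deviant"))
  keep <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  mw <- median_waveforms(rec, clean_mask(keep))
  expect_equal(mw$s_bar, d[1, 1, ])
  expect_equal(mw$d_bar, d[2, 2, ])
  expect_equal(mw$delta, d[2, 2, ] - d[1, 1, ])

  # odd-count median ignores one extreme outlier entirely
  d <- array(0, c(3, 2, 10))
  d[1, 1, ] <- 1; d[2, 1, ] <- 2; d[3, 1, ] <- 1e6
  d[, 2, ] <- 5
  rec <- tiny_recording(C = 3, E = 2, T = 10, data = d,
                        labels = c("standard", "deviant"))
  mw <- median_waveforms(rec)
  expect_equal(mw$s_bar, rep(2, 10))

  # random pools match an apply/median oracle (even and odd counts)
  for (E in c(4, 5)) {
    d <- with_test_seed(E, array(rnorm(6 * E * 20), c(6, E, 20)))
    rec <- tiny_recording(C = 6, E = E, T = 20, data = d,
                          labels = rep("standard", E))
    rec$labels[E] <- "deviant"
    mw <- median_waveforms(rec)
    pool <- matrix(d, 6 * E, 20)[as.vector(
      matrix(rep(rec$labels == "standard", each = 6), 6, E)), ]
    expect_equal(mw$s_bar, apply(pool, 2, median), tolerance = 1e-12)
  }
})

test_that("median waveforms fail informatively on empty pools", {
  rec <- tiny_recording(C = 2, E = 4, T = 10, labels = rep("standard", 4))
  expect_error(median_waveforms(rec), "D is empty")
  keep <- matrix(FALSE, 2, 4)
  rec$labels[1] <- "deviant"
  expect_error(median_waveforms(rec, clean_mask(keep)), "S is empty")
})

test_that("SSD partition sums match a brute-force oracle", {
  expect_equal(ssd_features(numeric(1200)), numeric(24))
  expect_equal(ssd_features(rep(1, 1200)), rep(50, 24))

  with_test_seed(3, {
    for (i in 1:50) {
      delta <- rnorm(1200)
      got <- ssd_features(delta)
      oracle <- vapply(1:24, function(i)
        sum(delta[(50 * (i - 1) + 1):(50 * i)]), numeric(1))
      expect_equal(got, oracle, tolerance = 1e-12)
      expect_equal(sum(got), sum(delta), tolerance = 1e-9)
    }
  })
  expect_error(ssd_features(numeric(1000)), "divisible")
})

test_that("partition variances match a two-pass oracle", {
  expect_equal(variance_features(rep(3, 1200)), numeric(12))
  alt <- rep(c(1, -1), 600)
  expect_equal(variance_features(alt), rep(100 / 99, 12))
  with_test_seed(4, {
    for (i in 1:50) {
      delta <- rnorm(1200, sd = 10)
      got <- variance_features(delta)
      oracle <- vapply(1:12, function(i)
        var(delta[(100 * (i - 1) + 1):(100 * i)]), numeric(1))
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  })
  expect_error(variance_features(numeric(30), 30), ">= 2")
})

test_that("feature selection keeps SSD 5..24 and variance 4..6", {
  out <- select_features(1:24, 1:12)
  expect_equal(unname(out), c(5:24, 4:6))
  expect_length(out, 23)
  expect_equal(names(out)[1], "ssd05")
  expect_equal(names(out)[21:23], c("var04", "var05", "var06"))
  expect_equal(unname(select_features(numeric(24), numeric(12))), numeric(23))
  expect_error(select_features(1:23, 1:12), "24")
  expect_error(select_features(1:24, 1:11), "12")
})

test_that("interval sums cover exactly the requested post-stimulus samples", {
  # at 1 kHz with a 200 ms baseline, 0-150 ms is samples 201..350
  delta <- seq_len(1200)
  got <- interval_ssd(delta, fs = 1000, pre_stim_ms = 200,
                      intervals = list(c(0, 150)))
  expect_equal(unname(got), sum(201:350))
  got4 <- interval_ssd(delta, fs = 1000, pre_stim_ms = 200)
  expect_equal(unname(got4["ssd_400_1000"]), sum(601:1200))
  expect_error(interval_ssd(delta, 1000, 200, list(c(0, 1500))), "outside")

  # degenerate all-zero groups give p = 1
  D <- matrix(0, 6, 1200)
  g <- factor(rep(c("ASD", "TD"), each = 3), c("ASD", "TD"))
  res <- interval_ssd_groups(D, g, fs = 1000, pre_stim_ms = 200)
  expect_true(all(res$p_values == 1))
})

test_that("coarse graining matches a windowed-mean oracle in both modes", {
  x <- c(1, 2, 3, 4)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(x, 2), c(1.5, 3.5))
  with_test_seed(5, {
    x <- rnorm(103)
    for (s in c(2, 5, 10)) {
      n <- length(x) %/% s
      oracle <- vapply(seq_len(n), function(i)
        mean(x[((i - 1) * s + 1):(i * s)]), numeric(1))
      expect_equal(coarse_grain(x, s), oracle, tolerance = 1e-12)
      mov <- vapply(s:length(x), function(i) mean(x[(i - s + 1):i]), numeric(1))
      expect_equal(coarse_grain(x, s, "moving"), mov, tolerance = 1e-12)
    }
  })
  expect_error(coarse_grain(1:10, 0), "scale")
})

test_that("sample entropy equals the brute-force template-count oracle", {
  expect_equal(sample_entropy(rep(2, 50)), 0)

  # strictly periodic series with period <= m and a small tolerance
  per <- rep(c(0, 1), 100)
  expect_lt(sample_entropy(per, m = 2, r = 0.1), 1e-9)

  with_test_seed(6, {
    x <- rnorm(500)
    r <- 0.15 * sd(x)
    expect_identical(sample_entropy(x, 2, r), sampen_oracle(x, 2, r))
    y <- rnorm(120)
    for (m in c(1, 2, 3)) {
      r <- 0.2 * sd(y)
      expect_identical(sample_entropy(y, m, r), sampen_oracle(y, m, r))
    }
  })
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "short")
  expect_warning(s <- sample_entropy(seq_len(50), m = 2, r = 1e-12), "undefined")
  expect_true(is.nan(s))
})

test_that("a noisy sine is less entropic than white noise at scale 1", {
  with_test_seed(7, {
    noise <- rnorm(1000)
    sine <- sin(2 * pi * (1:1000) / 40) + 0.05 * rnorm(1000)
    expect_lt(sample_entropy(sine), sample_entropy(noise))
  })
})

test_that("multiscale entropy has the printed geometry and scale trend", {
  # constant recording: every entry 0
  rec <- tiny_recording(C = 8, E = 6, T = 250, fs = 250,
                        data = array(1, c(8, 6, 250)))
  mm <- mmse_features(rec, n_scales = 5, target_samples = 1000)
  expect_length(mm, 4 * 5)
  expect_true(all(mm == 0))

  # white-noise recording: entropy decreases with scale on average because
  # coarse-graining shrinks variance relative to the scale-1 tolerance
  rec <- tiny_recording(C = 8, E = 8, T = 250, fs = 250, seed = 8)
  mm <- mmse_features(rec, n_scales = 10, target_samples = 1500)
  m <- matrix(mm, nrow = 10)
  expect_gt(mean(m[1, ]), mean(m[5, ]))
  expect_gt(mean(m[5, ]), mean(m[10, ]))

  # 1 kHz input is decimated to the 250 Hz working rate
  rec2 <- tiny_recording(C = 4, E = 10, T = 1200, fs = 1000, seed = 9)
  mm2 <- mmse_features(rec2, n_scales = 3, target_samples = 500)
  expect_length(mm2, 2 * 3)
  expect_true(all(is.finite(mm2)))
  expect_named(mm2, c("E002_s1", "E002_s2", "E002_s3",
                      "E004_s1", "E004_s2", "E004_s3"))

  # insufficient clean data triggers the per-channel fallback warning
  keep <- matrix(TRUE, 4, 10)
  keep[2, 2:10] <- FALSE
  expect_warning(mmse_features(rec2, clean_mask(keep), n_scales = 2,
                               target_samples = 4000), "insufficient")
})

test_that("subject_features assembles the documented dimensions", {
  res <- simulate_subject(quick_cfg(), "TD", seed = 3)
  f <- subject_features(res$recording)
  expect_length(f$ssd, 24)
  expect_length(f$variance, 12)
  expect_length(f$selected, 23)
  expect_s3_class(f$mask, "clean_mask")
  # variance_source switch changes the variance block only
  f2 <- subject_features(res$recording, variance_source = "standard")
  expect_equal(f2$ssd, f$ssd)
  expect_false(identical(f2$variance, f$variance))
})
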