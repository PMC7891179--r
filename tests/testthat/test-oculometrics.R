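test_that("saccade detection finds injected events at the right times", {
  expect_equal(nrow(detect_saccades(rep(3, 200), fs = 100)), 0)

  seg <- synthesize_saccade(0, 10, onset_ms = 300, fs = 100, total_ms = 1000)
  ev <- detect_saccades(seg$pos_deg, fs = 100)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 300), 10)              # within one sample
  expect_equal(ev$amplitude, 10, tolerance = 0.1)

  # two saccades 500 ms apart, returned in order
  t <- seq(0, 1990, by = 10)
  pos <- oculomark:::saccade_profile(t, 0, 10, 300) +
    oculomark:::saccade_profile(t, 0, -6, 800)
  ev2 <- detect_saccades(pos, fs = 100)
  expect_equal(nrow(ev2), 2)
  expect_lt(abs(ev2$onset_ms[1] - 300), 10)
  expect_lt(abs(ev2$onset_ms[2] - 800), 10)
  expect_equal(ev2$direction, c(1, -1))

  # all-invalid trace: empty result with a warning
  expect_warning(out <- detect_saccades(pos, fs = 100,
                                        valid = rep(FALSE, length(pos))),
                 "valid")
  expect_equal(nrow(out), 0)
})

test_that("detection agrees with a brute-force oracle on noise-free traces", {
  set.seed(11)
  for (rep in 1:15) {
    n_sac <- sample(1:3, 1)
    onsets <- sort(runif(n_sac, 200, 2600))
    while (any(diff(onsets) < 300)) onsets <- sort(runif(n_sac, 200, 2600))
    amps <- runif(n_sac, 2, 15) * sample(c(-1, 1), n_sac, replace = TRUE)
    t <- seq(0, 2990, by = 10)
    pos <- rep(0, length(t))
    cur <- 0
    for (k in seq_len(n_sac)) {
      pos <- pos + oculomark:::saccade_profile(t, 0, amps[k], onsets[k])
    }
    mine <- detect_saccades(pos, fs = 100)
    oracle <- brute_saccades(pos, fs = 100)
    expect_equal(nrow(mine), nrow(oracle))
    expect_true(all(abs(mine$onset_ms - oracle$onset_ms) <= 20))
    expect_true(all(abs(mine$amplitude - oracle$amplitude) <= 0.5))
  }
})

test_that("response latency applies the anticipatory floor and counts early saccades", {
  seg <- synthesize_saccade(0, 10, onset_ms = 1300, fs = 100, total_ms = 2500)
  ev <- detect_saccades(seg$pos_deg, fs = 100)
  rl <- response_latency(ev, go_ms = 1000)
  expect_equal(rl$latency, 300, tolerance = 10)
  expect_equal(rl$early, 0)

  # saccade exactly at go-time: early, latency absent
  seg2 <- synthesize_saccade(0, 10, onset_ms = 1000, fs = 100, total_ms = 2500)
  ev2 <- detect_saccades(seg2$pos_deg, fs = 100)
  rl2 <- response_latency(ev2, go_ms = 1000)
  expect_equal(rl2$early, 1)
  expect_true(is.na(rl2$latency))
})

test_that("signed endpoint error follows the overshoot-positive convention", {
  expect_equal(endpoint_error(10, 10), 0)
  expect_equal(endpoint_error(8.5, 10), -1.5)    # hypometric
  expect_equal(endpoint_error(-12, -10), 2)      # leftward overshoot
})

test_that("antisaccade and memory outcome classification matches the generating truth", {
  pf <- load_group_profiles()
  coh <- generate_cohort(pf, sizes = c(control = 3, bvFTD = 3), seed = 17,
                         blink_rate = 0)          # no censoring
  lat_diff <- err_diff <- numeric(0)
  for (id in names(coh$records)) {
    rec <- coh$records[[id]]
    tru <- coh$truths[[id]]$trials
    for (par in c("antisaccade", "memory")) {
      trials <- rec$recordings[[par]]$trials
      tt <- tru[tru$paradigm == par, ]
      for (j in seq_along(trials)) {
        got <- oculomark:::trial_metrics(trials[[j]])
        expect_equal(got$outcome, tt$outcome[j],
                     label = paste(id, par, "trial", j))
        if (!is.na(tt$latency[j]) && !is.na(got$latency))
          lat_diff <- c(lat_diff, got$latency - tt$latency[j])
        if (par == "antisaccade" && !is.na(tt$corrected_latency[j]))
          lat_diff <- c(lat_diff, got$corrected_latency - tt$corrected_latency[j])
        if (!is.na(tt$error[j]) && !is.na(got$error))
          err_diff <- c(err_diff, got$error - tt$error[j])
      }
    }
  }
  # latencies recovered to within about one sample, with no systematic bias
  expect_lt(max(abs(lat_diff)), 12)
  expect_lt(abs(mean(lat_diff)), 2)
  # landing positions are medians over ~3 noisy samples (SD 0.3 deg), so
  # per-trial errors carry ~0.2 deg zero-mean measurement noise
  expect_lt(abs(mean(err_diff)), 0.06)
  expect_lt(quantile(abs(err_diff), 0.95), 0.6)
  expect_lt(max(abs(err_diff)), 1.2)
})

test_that("pursuit metrics match closed forms on analytic sinusoids", {
  A <- 20
  still <- make_pursuit_trial(2000, A, 0.25, function(tg) rep(0, length(tg)))
  pm <- pursuit_metrics(still)
  expect_equal(pm$gain, 0, tolerance = 1e-6)
  expect_equal(pm$error, (2 / pi) * A, tolerance = 1e-6)

  low <- make_pursuit_trial(2000, A, 0.25, function(tg) 0.8 * tg)
  pm2 <- pursuit_metrics(low)
  expect_equal(pm2$gain, 0.8, tolerance = 1e-6)
  expect_equal(pm2$error, 0.2 * (2 / pi) * A, tolerance = 1e-6)

  ideal <- make_pursuit_trial(2000, A, 0.25, function(tg) tg)
  pm3 <- pursuit_metrics(ideal)
  expect_equal(pm3$gain, 1, tolerance = 1e-6)
  expect_equal(pm3$error, 0, tolerance = 1e-6)

  # < 50% valid samples: trial excluded
  bad <- make_pursuit_trial(100, A, 0.25, function(tg) tg)
  bad$trace$valid[seq_len(ceiling(nrow(bad$trace) * 0.6))] <- FALSE
  expect_null(pursuit_metrics(bad))
})

test_that("subject aggregation uses the published success-rate arithmetic", {
  mk <- function(outcome, n) data.frame(
    paradigm = "antisaccade", plane = "horizontal", eccentricity = 10,
    outcome = outcome, latency = 300, return_latency = NA,
    corrected_latency = NA, error = NA, gain = NA, pursuit_error = NA,
    early = 0L)[rep(1, n), ]
  m <- rbind(mk("correct", 5), mk("corrected", 12), mk("uncorrected", 3))
  agg <- aggregate_subject(m)
  expect_equal(agg$pct_correct_anti, 25)
  expect_equal(agg$pct_corrected_anti, 80)
  expect_equal(agg$pct_successful_anti, 85)

  # all correct: corrected denominator empty -> unavailable, never zero
  agg2 <- aggregate_subject(mk("correct", 20))
  expect_equal(agg2$pct_correct_anti, 100)
  expect_equal(agg2$pct_successful_anti, 100)
  expect_true(is.na(agg2$pct_corrected_anti))

  # no corrections: successful equals correct
  agg3 <- aggregate_subject(rbind(mk("correct", 5), mk("uncorrected", 15)))
  expect_equal(agg3$pct_successful_anti, agg3$pct_correct_anti)

  # empty denominators propagate as missing
  agg4 <- aggregate_subject(mk("unknown", 5))
  expect_true(is.na(agg4$pct_correct_anti))
})
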