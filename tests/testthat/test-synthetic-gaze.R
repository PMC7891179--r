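test_that("subject-level latents reproduce the group distribution", {
  pf <- load_group_profiles()
  lat <- with_seed(1, vapply(seq_len(10000), function(i)
    sample_subject_truth(pf, "control")$latents[["pro_latency_h"]], 0))
  # 3 SE band around the published mean (truncation bounds are > 3 SD away)
  se <- 52.24 / sqrt(10000)
  expect_lt(abs(mean(lat) - 257.50), 3 * se)
})

test_that("degenerate profiles give identical subjects and seeds reproduce cohorts", {
  pf <- load_group_profiles()
  # SDs -> 0 limit: every subject collapses onto the group means
  pf0 <- pf
  for (p in names(pf0$groups$control$params))
    pf0$groups$control$params[[p]][2] <- 1e-9
  t1 <- with_seed(2, sample_subject_truth(pf0, "control"))
  t2 <- with_seed(9, sample_subject_truth(pf0, "control"))
  expect_equal(t1$latents, t2$latents, tolerance = 1e-6)

  c1 <- generate_cohort(pf, sizes = c(control = 2, AD = 1), seed = 7)
  c2 <- generate_cohort(pf, sizes = c(control = 2, AD = 1), seed = 7)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truths, c2$truths)
  expect_equal(length(c1$records), 3)
  expect_setequal(names(c1$records[[1]]$recordings),
                  c("prosaccade", "antisaccade", "memory", "pursuit"))
})

test_that("synthesized saccades follow the main-sequence kinematics", {
  # zero-amplitude: flat trace
  seg0 <- synthesize_saccade(5, 5, onset_ms = 100, fs = 100, total_ms = 500)
  expect_true(all(seg0$pos_deg == 5))

  # 10-degree saccade completes within d0 + 10 k = 40 ms (+- one sample)
  seg <- synthesize_saccade(0, 10, onset_ms = 300, fs = 100, total_ms = 800)
  done <- seg$t_ms[which(seg$pos_deg >= 10 - 1e-9)[1]]
  expect_lte(done, 300 + 40 + 10)
  expect_true(all(diff(seg$pos_deg) >= 0))          # monotone displacement
  expect_true(all(seg$pos_deg[seg$t_ms <= 300] == 0))

  # peak velocity strictly increases with amplitude
  vmax <- vapply(c(5, 10, 20), function(a) {
    s <- synthesize_saccade(0, a, onset_ms = 200, fs = 1000, total_ms = 600)
    max(abs(diff(s$pos_deg))) * 1000
  }, 0)
  expect_true(all(diff(vmax) > 0))
  expect_error(synthesize_saccade(0, 50, 100), "45 deg")
})

test_that("trial synthesis respects the commanded outcome class", {
  # correct antisaccade at a known latency: first movement is mirror-directed
  tru <- manual_truth(c(pro_latency_h = 340), p_correct_anti = 1)
  st <- with_seed(3, synthesize_trial("antisaccade", "horizontal", 10, tru,
                                      noise_sd = 0, blink_rate = 0))
  evs <- detect_saccades(st$trial$trace$x_deg, 100)
  expect_gte(nrow(evs), 1)
  expect_equal(evs$direction[1], -1)                 # mirror side of +10
  expect_lt(abs((evs$onset_ms[1] - st$trial$go_ms) - st$truth$latency), 15)

  # uncorrected error: the trace never crosses to the mirror side
  tru2 <- manual_truth(c(pro_latency_h = 250), p_correct_anti = 0,
                       p_corrected_anti = 0)
  st2 <- with_seed(4, synthesize_trial("antisaccade", "horizontal", 10, tru2,
                                       noise_sd = 0, blink_rate = 0))
  expect_true(all(st2$trial$trace$x_deg > -1))
  expect_equal(st2$truth$outcome, "uncorrected")

  # corrected error: crosses the midline after the erroneous saccade
  tru3 <- manual_truth(c(pro_latency_h = 250, anti_corrected_latency_h = 900),
                       p_correct_anti = 0, p_corrected_anti = 1)
  st3 <- with_seed(5, synthesize_trial("antisaccade", "horizontal", 10, tru3,
                                       noise_sd = 0, blink_rate = 0))
  x <- st3$trial$trace$x_deg
  expect_gt(max(x), 5)                               # first went to target
  expect_lt(min(x), -5)                              # then crossed to mirror

  # pursuit with gain 1 and zero requested error reproduces the target
  tru4 <- manual_truth(c(pursuit_gain_h = 1, pursuit_error_h = 0))
  st4 <- with_seed(6, synthesize_trial("pursuit", "horizontal", 20, tru4,
                                       noise_sd = 0, blink_rate = 0))
  expect_equal(st4$trial$trace$x_deg, st4$trial$target$pos_deg,
               tolerance = 1e-10)
  expect_equal(st4$truth$pursuit_error, 0)

  # infeasible (gain, error) pair: the feasibility floor is synthesized and
  # recorded as the realized truth
  tru5 <- manual_truth(c(pursuit_gain_h = 0.5, pursuit_error_h = 1))
  st5 <- with_seed(7, synthesize_trial("pursuit", "horizontal", 20, tru5,
                                       noise_sd = 0, blink_rate = 0))
  expect_gt(st5$truth$pursuit_error, 1)   # floor ~ (2/pi) * 0.5 * 20
})

test_that("generated traces satisfy the gaze-sample invariants", {
  pf <- load_group_profiles()
  coh <- generate_cohort(pf, sizes = c(AD = 2), seed = 13)
  for (rec in coh$records) for (rc in rec$recordings) for (tr in rc$trials) {
    expect_true(all(diff(tr$trace$t_ms) > 0))
    expect_equal(length(unique(round(diff(tr$trace$t_ms), 9))), 1)
    ok <- tr$trace$valid
    expect_true(all(abs(tr$trace$x_deg[ok]) <= 40))
    expect_true(all(abs(tr$trace$y_deg[ok]) <= 40))
  }
  # every synthesized trial has exactly one truth entry
  n_trials <- sum(vapply(coh$records[[1]]$recordings,
                         function(rc) length(rc$trials), 0))
  expect_equal(nrow(coh$truths[[1]]$trials), n_trials)
})
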