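test_that("protocols have the published trial counts and cover all eccentricities", {
  p <- build_protocol("prosaccade", seed = 1)
  expect_equal(p$n_horizontal, 12)
  expect_equal(p$n_vertical, 8)
  h <- p$schedule$eccentricity[p$schedule$plane == "horizontal"]
  v <- p$schedule$eccentricity[p$schedule$plane == "vertical"]
  expect_setequal(unique(h), c(-20, -10, -5, 5, 10, 20))
  expect_setequal(unique(v), c(-12, -5, 5, 12))

  for (par in c("antisaccade", "memory")) {
    q <- build_protocol(par, seed = 3)
    expect_equal(c(q$n_horizontal, q$n_vertical), c(12, 8))
  }
  pp <- build_protocol("pursuit", seed = 1)
  expect_equal(c(pp$n_horizontal, pp$n_vertical), c(6, 6))
})

test_that("protocol generation is a pure function of paradigm and seed", {
  a <- build_protocol("memory", seed = 42)
  b <- build_protocol("memory", seed = 42)
  expect_identical(a, b)
  c2 <- build_protocol("memory", seed = 43)
  expect_false(identical(a$schedule, c2$schedule))
  expect_error(build_protocol("smooth", seed = 1), "unknown paradigm")
})

test_that("saccadic trial phases are contiguous, non-overlapping and memory has a blank window", {
  for (par in c("prosaccade", "antisaccade", "memory")) {
    ph <- oculomark:::trial_phases(par, 10, "horizontal", default_timing(par))
    expect_true(all(ph$onset_ms < ph$offset_ms))
    expect_equal(ph$onset_ms[-1], ph$offset_ms[-nrow(ph)])
  }
  ph <- oculomark:::trial_phases("memory", 10, "horizontal", default_timing("memory"))
  expect_false(ph$visible[nrow(ph)])
})

test_that("gaze tables round-trip exactly and validate on read", {
  pf <- load_group_profiles()
  rec <- with_seed(5, sample_subject(pf, "control", "c1"))$record
  path <- tempfile(fileext = ".csv")
  write_gaze_table(rec, path)
  back <- read_gaze_table(path)
  expect_equal(back$id, "c1")
  for (par in names(rec$recordings)) {
    for (j in seq_along(rec$recordings[[par]]$trials)) {
      a <- rec$recordings[[par]]$trials[[j]]
      b <- back$recordings[[par]]$trials[[j]]
      expect_equal(b$trace$t_ms, a$trace$t_ms)
      expect_equal(b$trace$x_deg, a$trace$x_deg)
      expect_equal(b$trace$y_deg, a$trace$y_deg)
      expect_equal(b$trace$valid, a$trace$valid)
      expect_equal(b$eccentricity, a$eccentricity)
      expect_equal(b$go_ms, a$go_ms)
    }
  }

  # corrupt: decreasing time names the offending row
  d <- read.csv(path)
  i <- 5
  d$t_ms[i] <- d$t_ms[i - 1] - 1
  bad <- tempfile(fileext = ".csv")
  write.csv(d, bad, row.names = FALSE)
  expect_error(read_gaze_table(bad), "non-monotonic")

  # missing required column
  d2 <- read.csv(path)
  d2$x_deg <- NULL
  bad2 <- tempfile(fileext = ".csv")
  write.csv(d2, bad2, row.names = FALSE)
  expect_error(read_gaze_table(bad2), "missing columns: x_deg")

  # unknown paradigm
  d3 <- read.csv(path)
  d3$paradigm[1] <- "vergence"
  bad3 <- tempfile(fileext = ".csv")
  write.csv(d3, bad3, row.names = FALSE)
  expect_error(read_gaze_table(bad3), "unknown paradigm")

  # empty trial trace rejected at write time
  rec2 <- rec
  rec2$recordings$prosaccade$trials[[1]]$trace <-
    rec2$recordings$prosaccade$trials[[1]]$trace[0, ]
  expect_error(write_gaze_table(rec2, tempfile(fileext = ".csv")),
               "empty trace")
})

test_that("the packaged profile fixture resolves every published cell", {
  pf <- load_group_profiles()
  expect_equal(unname(profile_param(pf, "control", "pro_latency_h")),
               c(257.50, 52.24))
  expect_equal(unname(profile_param(pf, "AD", "pct_successful_anti")),
               c(36.44, 30.77))
  expect_equal(profile_param(pf, "svPPA", "n"), 7)
  expect_equal(vapply(pf$groups, function(g) g$n, 0),
               c(control = 29, AD = 18, bvFTD = 18, svPPA = 7))
  # completeness: every parameter any downstream stage asks for resolves,
  # for every group
  needed <- c(profile_params(pf), "age", "sedatives", "mmse")
  for (g in names(pf$groups)) for (p in needed)
    expect_silent(profile_param(pf, g, p))
  expect_true(all(classifier_features(pf) %in% profile_params(pf)))
  expect_error(profile_param(pf, "control", "no_such_param"),
               "unknown parameter")
  expect_error(load_group_profiles("no_such_fixture"), "unknown profile fixture")
})

test_that("truncated-normal sampler matches closed-form moments", {
  x <- with_seed(1, rtnorm(2e5, 10, 4, lower = 8, upper = 20))
  expect_true(all(x >= 8 & x <= 20))
  expect_equal(mean(x), tnorm_mean(10, 4, 8, 20), tolerance = 0.005)
  expect_equal(sd(x), tnorm_sd(10, 4, 8, 20), tolerance = 0.01)
  expect_equal(tnorm_mean(0, 1, lower = 0), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(rtnorm(3, 5, 0, 0, 10), rep(5, 3))   # degenerate point mass
})
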