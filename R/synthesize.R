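# Synthetic gaze recordings. Each diagnostic group's profile (means/SDs of
# every oculomotor parameter plus success probabilities) acts as the
# generative model: subject-level latent parameters are drawn from truncated
# normals around the group values, and trials are synthesized so that the
# oculometric extraction stage recovers those latents. SubjectTruth records
# the values actually used (after any feasibility truncation), providing the
# oracle for parameter-recovery tests.

clipv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Main-sequence saccade duration
#'
#' Linear amplitude-duration rule `d0 + k * |amplitude|`; with the defaults
#' (20 ms + 2 ms/deg) a 10-degree saccade lasts 40 ms and peak velocity
#' (`pi * amplitude / (2 * duration)`) grows, saturating, with amplitude.
#'
#' @param amplitude saccade amplitude in degrees.
#' @param d0,k intercept (ms) and slope (ms/deg).
#' @return duration in ms.
#' @export
saccade_duration <- function(amplitude, d0 = 20, k = 2) d0 + k * abs(amplitude)

# Raised-cosine position profile: smooth, monotone, continuous velocity,
# constant before onset and after offset.
saccade_profile <- function(t_ms, from, to, onset_ms, d0 = 20, k = 2) {
  amp <- to - from
  if (amp == 0) return(rep(from, length(t_ms)))
  dur <- saccade_duration(amp, d0, k)
  s <- clipv((t_ms - onset_ms) / dur, 0, 1)
  from + amp * (1 - cos(pi * s)) / 2
}

#' Synthesize a single saccade segment
#'
#' @param start_deg,end_deg start and end gaze positions (deg);
#'   `|end - start|` must be at most 45 deg.
#' @param onset_ms saccade onset (ms from segment start).
#' @param fs sampling rate (Hz).
#' @param total_ms segment length (ms); defaults to onset + duration +
#'   100 ms.
#' @param d0,k main-sequence parameters, see [saccade_duration()].
#' @return data frame with `t_ms` and `pos_deg`.
#' @examples
#' seg <- synthesize_saccade(0, 10, onset_ms = 300, fs = 100)
#' range(seg$pos_deg)
#' @export
synthesize_saccade <- function(start_deg, end_deg, onset_ms, fs = 100,
                               total_ms = NULL, d0 = 20, k = 2) {
  stopifnot(is.finite(start_deg), is.finite(end_deg), is.finite(onset_ms))
  if (abs(end_deg - start_deg) > 45) stop("saccade amplitude exceeds 45 deg")
  if (is.null(total_ms))
    total_ms <- onset_ms + saccade_duration(end_deg - start_deg, d0, k) + 100
  t <- seq(0, total_ms, by = 1000 / fs)
  data.frame(t_ms = t,
             pos_deg = saccade_profile(t, start_deg, end_deg, onset_ms, d0, k))
}

# Generator-side truncation bounds. Latencies are additionally capped so the
# response fits inside its phase window; see the methods vignette.
gen_bounds <- function(param) {
  if (grepl("^pro_latency", param)) return(c(80, 1250))
  if (grepl("^return_latency", param)) return(c(80, 1150))
  if (grepl("^anti_corrected_latency", param)) return(c(260, 3000))
  if (grepl("^mem_latency", param)) return(c(80, 2500))
  if (grepl("pos_error", param)) return(c(0, 15))
  if (grepl("neg_error", param)) return(c(-15, 0))
  if (grepl("gain", param)) return(c(0, 1.5))
  if (grepl("^pursuit_error", param)) return(c(0.2, 15))
  if (startsWith(param, "pct_")) return(c(0, 100))
  c(-Inf, Inf)
}

#' Draw one subject's latent oculomotor parameters
#'
#' Subject-level means are drawn from the group's truncated normals
#' (latencies at least 80 ms and capped to the trial response window,
#' percentages in \[0, 100\], gains in \[0, 1.5\], signed errors keeping
#' their sign); trial-level values are then produced around these latents by
#' [synthesize_trial()].
#'
#' @param profiles a `group_profiles` object.
#' @param group group label.
#' @return named list with `latents` (named numeric vector over the profile
#'   parameters), success probabilities, `early_rate` and demographic draws.
#' @export
sample_subject_truth <- function(profiles, group) {
  gr <- profiles$groups[[group]]
  if (is.null(gr)) stop("unknown group: ", group)
  pars <- names(gr$params)
  latents <- vapply(pars, function(p) {
    ms <- gr$params[[p]]
    b <- gen_bounds(p)
    rtnorm(1, ms[1], ms[2], b[1], b[2])
  }, 0)
  dem <- gr$demographics
  np <- gr$neuropsych
  dur <- if (is.null(dem$disease_duration)) NA_real_ else
    rtnorm(1, dem$disease_duration[1], dem$disease_duration[2], 0.5, 25)
  list(
    group = group,
    latents = latents,
    p_correct_anti = latents[["pct_correct_anti"]] / 100,
    p_corrected_anti = latents[["pct_corrected_anti"]] / 100,
    p_correct_memory = latents[["pct_correct_memory"]] / 100,
    early_rate = gr$early_rate %||% 0.05,
    age = rtnorm(1, dem$age[1], dem$age[2], 45, 95),
    sex = if (runif(1) < dem$pct_female / 100) "F" else "M",
    sedatives = round(rtnorm(1, dem$sedatives[1], dem$sedatives[2], 0, 8)),
    disease_duration = dur,
    mmse = round(rtnorm(1, np$mmse[1], np$mmse[2], 0, 30), 1),
    rocft_copy = round(rtnorm(1, np$rocft_copy[1], np$rocft_copy[2], 0, 36), 1),
    symbol_digit = round(rtnorm(1, np$symbol_digit[1], np$symbol_digit[2], 0, 110), 1)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lat_key <- function(stem, plane)
  paste0(stem, if (plane == "horizontal") "_h" else "_v")

# Draw a per-trial endpoint error around the subject latents: an overshoot
# coin picks the positive or negative latent, clipped to the geometric bounds
# of the trial eccentricity.
draw_error <- function(truth, stem, plane, lo, hi = 15) {
  pos <- runif(1) < 0.5
  key <- paste0(stem, if (pos) "_pos_error" else "_neg_error",
                if (plane == "horizontal") "_h" else "_v")
  list(value = clipv(truth$latents[[key]], lo, hi), positive = pos)
}

new_trial <- function(paradigm, plane, ecc, fs, end_ms, go_ms, go2_ms = NA,
                      phases = NULL, amp = NA, freq = NA) {
  list(paradigm = paradigm, plane = plane, eccentricity = ecc, fs = fs,
       end_ms = end_ms, go_ms = go_ms, go2_ms = go2_ms, phases = phases,
       amp = amp, freq = freq)
}

# Assemble an axis trace from an ordered list of saccade events
# (list(onset, from, to)); later events override from their onset onward.
assemble_axis <- function(t, events, d0 = 20, k = 2) {
  pos <- rep(if (length(events)) events[[1]]$from else 0, length(t))
  for (ev in events) {
    idx <- t >= ev$onset
    pos[idx] <- saccade_profile(t[idx], ev$from, ev$to, ev$onset, d0, k)
  }
  pos
}

finalize_trial <- function(trial, t, axis_pos, noise_sd, blink_rate,
                           target = NULL) {
  n <- length(t)
  other <- rnorm(n, 0, noise_sd)
  axis <- axis_pos + rnorm(n, 0, noise_sd)
  valid <- rep(TRUE, n)
  dur_s <- t[n] / 1000
  nb <- rpois(1, blink_rate * dur_s)
  if (nb > 0) for (i in seq_len(nb)) {
    len <- runif(1, 100, 250)
    start <- runif(1, 0, max(t[n] - len, 1))
    idx <- which(t >= start & t <= start + len)
    if (length(idx)) {
      valid[idx] <- FALSE
      axis[idx] <- axis[max(idx[1] - 1, 1)]
      other[idx] <- other[max(idx[1] - 1, 1)]
    }
  }
  if (trial$plane == "horizontal") {
    x <- axis; y <- other
  } else {
    x <- other; y <- axis
  }
  trial$trace <- structure(list(t_ms = t, x_deg = x, y_deg = y,
                                valid = valid),
                           class = "data.frame", row.names = seq_along(t))
  if (!is.null(target)) trial$target <- target
  structure(trial, class = "gaze_trial")
}

#' Synthesize one trial from subject truth
#'
#' Builds the raw gaze trace of a single trial. Prosaccade trials inject the
#' subject's latency and signed endpoint error plus a return saccade;
#' antisaccade trials sample an outcome class (correct / corrected error /
#' uncorrected error) from the subject's probabilities, with erroneous trials
#' containing a target-directed saccade and corrected trials a later
#' mirror-crossing saccade at the corrected latency; memory trials contain
#' the visually-guided approach, the re-fixation, and a response saccade
#' after blank onset that lands at the remembered location when correct and
#' in the opposite direction otherwise; pursuit trials follow
#' `gain * target` plus a piecewise offset with saccadic transitions solved
#' so the realized noise-free positional error matches the subject's truth
#' value. Gaussian positional noise and blink spans (invalid samples) are
#' added throughout.
#'
#' @param paradigm paradigm name.
#' @param plane `"horizontal"` or `"vertical"`.
#' @param eccentricity signed target eccentricity (deg); pursuit amplitude
#'   for pursuit trials.
#' @param truth subject truth from [sample_subject_truth()].
#' @param fs sampling rate (Hz).
#' @param timing phase timing ([default_timing()]).
#' @param noise_sd white positional noise SD (deg).
#' @param blink_rate blink insertions per second.
#' @return list with `trial` (a `gaze_trial`) and `truth` (one-row data
#'   frame of the realized per-trial generating values).
#' @export
synthesize_trial <- function(paradigm, plane, eccentricity, truth, fs = 100,
                             timing = default_timing(paradigm),
                             noise_sd = 0.3, blink_rate = 0.1) {
  paradigm <- match.arg(paradigm, .paradigms)
  switch(paradigm,
    prosaccade = synth_pro(plane, eccentricity, truth, fs, timing, noise_sd, blink_rate),
    antisaccade = synth_anti(plane, eccentricity, truth, fs, timing, noise_sd, blink_rate),
    memory = synth_mem(plane, eccentricity, truth, fs, timing, noise_sd, blink_rate),
    pursuit = synth_pursuit(plane, eccentricity, truth, fs, timing, noise_sd, blink_rate)
  )
}

truth_row <- function(paradigm, plane, ecc, outcome = NA, latency = NA,
                      return_latency = NA, corrected_latency = NA,
                      error = NA, error_positive = NA, gain = NA,
                      pursuit_error = NA, early = 0L) {
  structure(list(paradigm = paradigm, plane = plane, eccentricity = ecc,
                 outcome = outcome, latency = as.numeric(latency),
                 return_latency = as.numeric(return_latency),
                 corrected_latency = as.numeric(corrected_latency),
                 error = as.numeric(error),
                 error_positive = error_positive, gain = as.numeric(gain),
                 pursuit_error = as.numeric(pursuit_error), early = early),
            class = "data.frame", row.names = 1L)
}

# Optionally prepend an anticipatory (early) saccade: a small 2-deg movement
# toward the target starting before go + 80 ms.
maybe_early <- function(events, truth, go, sgn) {
  if (runif(1) >= truth$early_rate) return(list(events = events, early = 0L,
                                                floor_ms = 0))
  onset <- runif(1, go - 140, go + 50)
  from <- if (length(events)) events[[length(events)]]$to else 0
  events[[length(events) + 1]] <- list(onset = onset, from = from,
                                       to = from + 2 * sgn)
  list(events = events, early = 1L, floor_ms = onset + 24 + 40)
}

synth_pro <- function(plane, ecc, truth, fs, timing, noise_sd, blink_rate) {
  go <- timing$fixation_ms
  go2 <- go + timing$target_ms
  end <- go2 + timing$return_ms
  t <- seq(0, end - 1000 / fs, by = 1000 / fs)
  sgn <- sign(ecc)
  events <- list()
  ee <- maybe_early(events, truth, go, sgn)
  L1 <- rtnorm(1, truth$latents[[lat_key("pro_latency", plane)]], 40, 80, 1250)
  L1 <- max(L1, ee$floor_ms - go)
  err <- draw_error(truth, "pro", plane, lo = -(abs(ecc) - 1.5))
  landing <- sgn * (abs(ecc) + err$value)
  from1 <- if (ee$early) 2 * sgn else 0
  events <- ee$events
  events[[length(events) + 1]] <- list(onset = go + L1, from = from1, to = landing)
  Lr <- rtnorm(1, truth$latents[[lat_key("return_latency", plane)]], 40, 80, 1150)
  events[[length(events) + 1]] <- list(onset = go2 + Lr, from = landing,
                                       to = clipv(rnorm(1, 0, 0.4), -1, 1))
  trial <- new_trial("prosaccade", plane, ecc, fs, end, go, go2,
                     phases = trial_phases("prosaccade", ecc, plane, timing))
  list(trial = finalize_trial(trial, t, assemble_axis(t, events), noise_sd, blink_rate),
       truth = truth_row("prosaccade", plane, ecc, outcome = "response",
                         latency = L1, return_latency = Lr, error = err$value,
                         error_positive = err$positive, early = ee$early))
}

synth_anti <- function(plane, ecc, truth, fs, timing, noise_sd, blink_rate) {
  go <- timing$fixation_ms
  end <- go + timing$target_ms
  t <- seq(0, end - 1000 / fs, by = 1000 / fs)
  sgn <- sign(ecc)
  ee <- maybe_early(list(), truth, go, sgn)
  events <- ee$events
  from1 <- if (ee$early) 2 * sgn else 0
  pro_lat <- truth$latents[[lat_key("pro_latency", plane)]]
  correct <- runif(1) < truth$p_correct_anti
  err <- draw_error(truth, "anti", plane, lo = -(abs(ecc) - 1.5))
  mirror_landing <- -sgn * (abs(ecc) + err$value)
  if (correct) {
    Lc <- rtnorm(1, pro_lat + 60, 50, 100, 1300)
    Lc <- max(Lc, ee$floor_ms - go)
    events[[length(events) + 1]] <- list(onset = go + Lc, from = from1,
                                         to = mirror_landing)
    out <- "correct"; Lcorr <- NA; errv <- err$value; errp <- err$positive
    L1 <- Lc
  } else {
    Le <- rtnorm(1, pro_lat, 40, 80, 1000)
    Le <- max(Le, ee$floor_ms - go)
    target_landing <- sgn * abs(ecc) * runif(1, 0.65, 1.0)
    events[[length(events) + 1]] <- list(onset = go + Le, from = from1,
                                         to = target_landing)
    corrected <- runif(1) < truth$p_corrected_anti
    if (corrected) {
      Lcorr <- rtnorm(1, truth$latents[[lat_key("anti_corrected_latency", plane)]],
                      60, Le + 180, 3300)
      events[[length(events) + 1]] <- list(onset = go + Lcorr,
                                           from = target_landing,
                                           to = mirror_landing)
      out <- "corrected"; errv <- err$value; errp <- err$positive
    } else {
      out <- "uncorrected"; Lcorr <- NA; errv <- NA; errp <- NA
    }
    L1 <- Le
  }
  trial <- new_trial("antisaccade", plane, ecc, fs, end, go,
                     phases = trial_phases("antisaccade", ecc, plane, timing))
  list(trial = finalize_trial(trial, t, assemble_axis(t, events), noise_sd, blink_rate),
       truth = truth_row("antisaccade", plane, ecc, outcome = out,
                         latency = L1, corrected_latency = Lcorr,
                         error = errv, error_positive = errp,
                         early = ee$early))
}

synth_mem <- function(plane, ecc, truth, fs, timing, noise_sd, blink_rate) {
  t_target <- timing$fixation_ms
  t_center <- t_target + timing$target_ms
  go <- t_center + timing$center_ms       # blank onset = go event
  end <- go + timing$blank_ms
  t <- seq(0, end - 1000 / fs, by = 1000 / fs)
  sgn <- sign(ecc)
  events <- list()
  # visually-guided approach and re-fixation (not scored)
  L1 <- rtnorm(1, truth$latents[[lat_key("pro_latency", plane)]], 40, 80, 1250)
  near <- sgn * abs(ecc) + rnorm(1, 0, 0.3)
  events[[1]] <- list(onset = t_target + L1, from = 0, to = near)
  Lr <- rtnorm(1, truth$latents[[lat_key("return_latency", plane)]], 40, 80, 750)
  back <- clipv(rnorm(1, 0, 0.3), -0.8, 0.8)
  events[[2]] <- list(onset = t_center + Lr, from = near, to = back)
  ee <- maybe_early(events, truth, go, sgn)
  events <- ee$events
  from1 <- if (ee$early) back + 2 * sgn else back
  Lm <- rtnorm(1, truth$latents[[lat_key("mem_latency", plane)]], 60, 80, 2700)
  Lm <- max(Lm, ee$floor_ms - go)
  correct <- runif(1) < truth$p_correct_memory
  if (correct) {
    err <- draw_error(truth, "mem", plane,
                      lo = -min(0.4 * abs(ecc), abs(ecc) - 1.5))
    landing <- sgn * (abs(ecc) + err$value)
    out <- "correct"; errv <- err$value; errp <- err$positive
  } else {
    landing <- -sgn * 0.7 * abs(ecc)
    out <- "incorrect"; errv <- NA; errp <- NA
  }
  events[[length(events) + 1]] <- list(onset = go + Lm, from = from1, to = landing)
  trial <- new_trial("memory", plane, ecc, fs, end, go,
                     phases = trial_phases("memory", ecc, plane, timing))
  list(trial = finalize_trial(trial, t, assemble_axis(t, events), noise_sd, blink_rate),
       truth = truth_row("memory", plane, ecc, outcome = out, latency = Lm,
                         error = errv, error_positive = errp,
                         early = ee$early))
}

# Smooth pursuit: eye = gain * target + offset(t) + noise. offset(t) is a
# random-sign piecewise-constant level c with raised-cosine (saccade-like)
# transitions; c is solved so that the noise-free mean absolute positional
# error over non-transition samples equals the subject's truth value. When
# the drawn error is below its feasibility floor (2/pi)|1-gain|A the floor is
# synthesized and recorded as the realized truth.
synth_pursuit <- function(plane, amp, truth, fs, timing, noise_sd, blink_rate) {
  freq <- timing$freq_hz
  dur_ms <- timing$cycles / freq * 1000
  t <- seq(0, dur_ms - 1000 / fs, by = 1000 / fs)
  n <- length(t)
  target <- amp * sin(2 * pi * freq * t / 1000)
  g <- truth$latents[[lat_key("pursuit_gain", plane)]]
  e_want <- truth$latents[[lat_key("pursuit_error", plane)]]
  # random-sign segments, ~2 s each, with 30 ms raised-cosine transitions
  seg_ms <- 2000
  bounds <- seq(runif(1, 200, seg_ms), dur_ms, by = seg_ms)
  sgn <- rep(sample(c(-1, 1), 1), n)
  seg_sign <- sample(c(-1, 1), length(bounds) + 1, replace = TRUE)
  shape <- rep(seg_sign[1], n)
  trans_ms <- 30
  in_trans <- rep(FALSE, n)
  for (i in seq_along(bounds)) {
    b <- bounds[i]
    after <- t >= b
    shape[after] <- seg_sign[i + 1]
    idx <- which(t >= b - trans_ms / 2 & t <= b + trans_ms / 2)
    if (length(idx) && seg_sign[i + 1] != seg_sign[i]) {
      s <- (t[idx] - (b - trans_ms / 2)) / trans_ms
      shape[idx] <- seg_sign[i] + (seg_sign[i + 1] - seg_sign[i]) *
        (1 - cos(pi * clipv(s, 0, 1))) / 2
      in_trans[idx] <- TRUE
    }
  }
  mask <- !in_trans
  # pad the mask one sample on each side of a transition
  mask <- mask & c(TRUE, mask[-n]) & c(mask[-1], TRUE)
  resid0 <- (g - 1) * target
  f <- function(cc) mean(abs(resid0 + cc * shape)[mask]) - e_want
  if (f(0) >= 0) {
    cc <- 0
  } else {
    cc <- uniroot(f, c(0, e_want + abs(1 - g) * amp + 2), tol = 1e-8)$root
  }
  e_real <- mean(abs(resid0 + cc * shape)[mask])
  axis <- g * target + cc * shape
  trial <- new_trial("pursuit", plane, amp, fs, dur_ms, 0, amp = amp, freq = freq)
  out <- finalize_trial(trial, t, axis, noise_sd, blink_rate,
                        target = data.frame(t_ms = t, pos_deg = target))
  list(trial = out,
       truth = truth_row("pursuit", plane, amp, outcome = "pursuit",
                         gain = g, pursuit_error = e_real))
}

#' Synthesize one subject's full four-test recording
#'
#' @param profiles a `group_profiles` object.
#' @param group group label.
#' @param id subject identifier.
#' @param fs sampling rate (Hz).
#' @param noise_sd,blink_rate trace noise parameters, see
#'   [synthesize_trial()].
#' @return list with `record` (a `subject_record`: demographics plus one
#'   recording per paradigm) and `truth` (latents and the per-trial realized
#'   generating values).
#' @export
sample_subject <- function(profiles, group, id, fs = 100, noise_sd = 0.3,
                           blink_rate = 0.1) {
  truth <- sample_subject_truth(profiles, group)
  proto_seeds <- sample.int(2^30, length(.paradigms))
  recordings <- list()
  trial_truths <- list()
  for (i in seq_along(.paradigms)) {
    par <- .paradigms[i]
    proto <- build_protocol(par, proto_seeds[i], fs = fs)
    trials <- vector("list", nrow(proto$schedule))
    for (j in seq_len(nrow(proto$schedule))) {
      st <- synthesize_trial(par, proto$schedule$plane[j],
                             proto$schedule$eccentricity[j], truth, fs = fs,
                             timing = proto$timing, noise_sd = noise_sd,
                             blink_rate = blink_rate)
      trials[[j]] <- st$trial
      st$truth$trial <- j
      trial_truths[[length(trial_truths) + 1]] <- st$truth
    }
    recordings[[par]] <- list(protocol = proto, trials = trials)
  }
  record <- structure(list(
    id = id, group = group, age = truth$age, sex = truth$sex,
    sedatives = truth$sedatives, disease_duration = truth$disease_duration,
    mmse = truth$mmse, rocft_copy = truth$rocft_copy,
    symbol_digit = truth$symbol_digit, recordings = recordings
  ), class = "subject_record")
  truth$id <- id
  truth$trials <- do.call(rbind, trial_truths)
  list(record = record, truth = truth)
}

#' Generate a synthetic multi-group cohort
#'
#' @param profiles a `group_profiles` object.
#' @param sizes named integer vector of subjects per group; defaults to the
#'   profile group sizes.
#' @param seed integer seed; the same seed yields the identical cohort.
#' @param fs sampling rate (Hz).
#' @param noise_sd,blink_rate trace noise parameters.
#' @return object of class `gaze_cohort`: list with `records`, `truths` and
#'   the generation settings.
#' @examples
#' pf <- load_group_profiles()
#' coh <- generate_cohort(pf, sizes = c(control = 2, AD = 1), seed = 7)
#' length(coh$records)
#' @export
generate_cohort <- function(profiles, sizes = NULL, seed, fs = 100,
                            noise_sd = 0.3, blink_rate = 0.1) {
  if (is.null(sizes))
    sizes <- vapply(profiles$groups, function(g) g$n, 0)
  stopifnot(!is.null(names(sizes)), all(sizes >= 0))
  set.seed(seed)
  records <- list()
  truths <- list()
  for (g in names(sizes)) {
    ng <- sizes[[g]]
    if (ng < 1) next
    for (i in seq_len(ng)) {
      id <- sprintf("%s_%03d", g, i)
      st <- sample_subject(profiles, g, id, fs = fs, noise_sd = noise_sd,
                           blink_rate = blink_rate)
      records[[id]] <- st$record
      truths[[id]] <- st$truth
    }
  }
  structure(list(records = records, truths = truths, seed = seed, fs = fs,
                 noise_sd = noise_sd, blink_rate = blink_rate),
            class = "gaze_cohort")
}

#' @export
print.gaze_cohort <- function(x, ...) {
  groups <- vapply(x$records, function(r) r$group, "")
  cat("<gaze_cohort> ", length(x$records), " subjects (",
      paste(sprintf("%s: %d", names(table(groups)), table(groups)),
            collapse = ", "), "), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Subject-level feature means implied by the generating truth
#'
#' Aggregates the realized per-trial generating values of a cohort with the
#' same rules as [aggregate_subject()] applies to extracted trial metrics.
#' This is the oracle against which parameter recovery is judged.
#'
#' @param cohort a `gaze_cohort`.
#' @return data frame, one row per subject, columns as in
#'   [extract_features()].
#' @export
truth_features <- function(cohort) {
  rows <- lapply(cohort$truths, function(tr) {
    d <- tr$trials
    pick <- function(par, pl) d[d$paradigm == par & d$plane == pl, ]
    m <- function(x) if (length(x[!is.na(x)])) mean(x, na.rm = TRUE) else NA_real_
    err_mean <- function(dd, positive) {
      v <- dd$error[!is.na(dd$error) & dd$error_positive == positive]
      if (positive) v <- v[v >= 0] else v <- v[v <= 0]
      m(v)
    }
    out <- list(id = tr$id, group = tr$group)
    for (pl in c("horizontal", "vertical")) {
      sfx <- if (pl == "horizontal") "_h" else "_v"
      pro <- pick("prosaccade", pl); anti <- pick("antisaccade", pl)
      mem <- pick("memory", pl); pur <- pick("pursuit", pl)
      out[[paste0("pro_latency", sfx)]] <- m(pro$latency)
      out[[paste0("return_latency", sfx)]] <- m(pro$return_latency)
      out[[paste0("pro_pos_error", sfx)]] <- err_mean(pro, TRUE)
      out[[paste0("pro_neg_error", sfx)]] <- err_mean(pro, FALSE)
      out[[paste0("anti_corrected_latency", sfx)]] <- m(anti$corrected_latency)
      out[[paste0("anti_pos_error", sfx)]] <- err_mean(anti, TRUE)
      out[[paste0("anti_neg_error", sfx)]] <- err_mean(anti, FALSE)
      out[[paste0("mem_latency", sfx)]] <- m(mem$latency)
      out[[paste0("mem_pos_error", sfx)]] <- err_mean(mem, TRUE)
      out[[paste0("mem_neg_error", sfx)]] <- err_mean(mem, FALSE)
      out[[paste0("pursuit_gain", sfx)]] <- m(pur$gain)
      out[[paste0("pursuit_error", sfx)]] <- m(pur$pursuit_error)
    }
    anti <- d[d$paradigm == "antisaccade", ]
    n_corr <- sum(anti$outcome == "correct")
    n_fixed <- sum(anti$outcome == "corrected")
    n_unc <- sum(anti$outcome == "uncorrected")
    att <- n_corr + n_fixed + n_unc
    out$pct_correct_anti <- if (att) 100 * n_corr / att else NA_real_
    out$pct_corrected_anti <- if (n_fixed + n_unc)
      100 * n_fixed / (n_fixed + n_unc) else NA_real_
    out$pct_successful_anti <- if (att) 100 * (n_corr + n_fixed) / att else NA_real_
    mem <- d[d$paradigm == "memory", ]
    out$pct_correct_memory <- if (nrow(mem))
      100 * sum(mem$outcome == "correct") / nrow(mem) else NA_real_
    out$early_saccades <- sum(d$early, na.rm = TRUE)
    as.data.frame(out)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
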