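# Oculomotor parameters: per-trial metrics from detected saccade events and
# their aggregation to one feature vector per subject.

axis_trace <- function(trial) {
  tr <- trial$trace
  pos <- if (trial$plane == "horizontal") tr$x_deg else tr$y_deg
  list(t = tr$t_ms, pos = pos, valid = tr$valid)
}

#' Default detection parameters
#'
#' Velocity threshold 30 deg/s, minimum amplitude 1 deg, minimum duration
#' 10 ms and an 80 ms anticipatory latency floor: standard video-oculography
#' conventions, all configurable.
#' @return named list.
#' @export
default_detection_params <- function() {
  list(velocity_threshold = 30, min_amplitude = 1, min_duration_ms = 10,
       anticipatory_floor_ms = 80, corrective_window_ms = 100,
       corrected_latency_ref = "go", pursuit_excision_threshold = 60)
}

#' Response latency and early-saccade count
#'
#' Latency is the onset of the first qualifying saccade (amplitude at least
#' `min_amplitude` along the trial axis) minus the go-time. Saccades starting
#' before the go event or within the anticipatory floor (80 ms) are counted
#' as early and excluded from the latency statistic.
#'
#' @param events event table from [detect_saccades()].
#' @param go_ms go-event time (target onset; blank onset for memory trials).
#' @param floor_ms anticipatory floor (ms).
#' @param window_start_ms,window_end_ms events outside this window are
#'   ignored (earlier stimulus phases have their own responses).
#' @return list with `latency` (NA if no qualifying response), `early`
#'   (count) and `event` (row index of the response event, or NA).
#' @export
response_latency <- function(events, go_ms, floor_ms = 80,
                             window_start_ms = go_ms - 150,
                             window_end_ms = Inf) {
  if (!nrow(events))
    return(list(latency = NA_real_, early = 0L, event = NA_integer_))
  inwin <- events$onset_ms >= window_start_ms & events$onset_ms <= window_end_ms
  early <- sum(inwin & events$onset_ms < go_ms + floor_ms)
  cand <- which(inwin & events$onset_ms >= go_ms + floor_ms)
  if (!length(cand))
    return(list(latency = NA_real_, early = early, event = NA_integer_))
  list(latency = events$onset_ms[cand[1]] - go_ms, early = early,
       event = cand[1])
}

# Final gaze position of a response: the event's end position, chaining any
# immediately following corrective saccade (onset within `window` ms of the
# previous offset).
final_position <- function(events, i, window = 100) {
  repeat {
    nxt <- which(events$onset_ms > events$offset_ms[i] &
                 events$onset_ms <= events$offset_ms[i] + window)
    if (!length(nxt)) return(list(pos = events$end_pos[i], event = i))
    i <- nxt[1]
  }
}

#' Signed endpoint error
#'
#' Deviation of the final gaze position from the reference location, signed
#' along the movement axis: overshoot (hypermetria) positive, undershoot
#' (hypometria) negative, i.e. `|final| - |reference|`.
#'
#' @param final_pos final gaze position (deg).
#' @param reference_pos reference location (target, remembered location, or
#'   mirror location for antisaccades), deg.
#' @return signed error in degrees.
#' @examples
#' endpoint_error(8.5, 10)    # hypometric: -1.5
#' endpoint_error(-12, -10)   # leftward overshoot: +2
#' @export
endpoint_error <- function(final_pos, reference_pos) {
  abs(final_pos) - abs(reference_pos)
}

#' Classify an antisaccade trial
#'
#' The first qualifying saccade after the go event decides the outcome:
#' directed to the mirror side = correct; to the target side = erroneous. An
#' erroneous trial followed by a saccade crossing the midline to the mirror
#' side before trial end is a corrected error (successful = correct or
#' corrected). The corrected latency is referenced to the go event by
#' default, or to the erroneous saccade's offset with `latency_ref =
#' "error_offset"`. A trial with invalid (blink) samples after the primary
#' response is censored: a blink there could hide a corrective saccade, so
#' the outcome is reported as `unknown` and the trial is excluded from
#' every outcome percentage — uniformly, whatever was observed, so the
#' censoring cannot bias the correct/corrected proportions. Its latency and
#' error measurements are still returned.
#'
#' @param events event table from [detect_saccades()].
#' @param go_ms go time (target onset).
#' @param eccentricity signed target eccentricity (deg).
#' @param valid,t_ms trace validity flags and sample times (used for the
#'   unknown-status rule).
#' @param floor_ms anticipatory floor (ms).
#' @param latency_ref `"go"` or `"error_offset"`.
#' @return list with `outcome` (`correct`, `corrected`, `uncorrected`,
#'   `unknown`, `no_response`), `latency`, `corrected_latency`, `error`
#'   (signed endpoint error vs the mirror location, mirror-side landings
#'   only) and `early`.
#' @export
classify_antisaccade <- function(events, go_ms, eccentricity, valid, t_ms,
                                 floor_ms = 80, latency_ref = c("go", "error_offset")) {
  latency_ref <- match.arg(latency_ref)
  sgn <- sign(eccentricity)
  rl <- response_latency(events, go_ms, floor_ms)
  res <- list(outcome = "no_response", latency = NA_real_,
              corrected_latency = NA_real_, error = NA_real_,
              early = rl$early)
  if (is.na(rl$event)) return(res)
  i <- rl$event
  res$latency <- rl$latency
  # censor on blinks after the primary response (could hide a correction)
  # and on blinks between go and the response (the observed response might
  # not have been the first); both are independent of the true outcome
  censored <- any(!valid[t_ms > events$offset_ms[i]]) ||
    any(!valid[t_ms >= go_ms - 150 & t_ms <= events$onset_ms[i]])
  if (events$direction[i] == -sgn) {
    fin <- final_position(events, i)
    res$outcome <- "correct"
    res$error <- endpoint_error(fin$pos, -eccentricity)
  } else {
    # erroneous: search for a mirror-crossing correction
    later <- which(events$onset_ms > events$offset_ms[i] &
                   events$end_pos * sgn < 0 & abs(events$end_pos) >= 1)
    if (length(later)) {
      j <- later[1]
      fin <- final_position(events, j)
      res$outcome <- "corrected"
      res$corrected_latency <- if (latency_ref == "go")
        events$onset_ms[j] - go_ms else events$onset_ms[j] - events$offset_ms[i]
      res$error <- endpoint_error(fin$pos, -eccentricity)
    } else {
      res$outcome <- "uncorrected"
    }
  }
  if (censored) res$outcome <- "unknown"
  res
}

#' Classify a memory-guided saccade trial
#'
#' The go event is the disappearance of the central target (blank onset). The
#' trial is correct iff the first qualifying response saccade is in the
#' remembered direction and lands with at least 50% of the target
#' eccentricity. A trial with no detected response counts as incorrect
#' unless blinks obliterated the response window, in which case it is
#' invalid.
#'
#' @inheritParams classify_antisaccade
#' @return list with `outcome` (`correct`, `incorrect`, `invalid`),
#'   `latency`, `error` (signed endpoint error, correct trials only) and
#'   `early`.
#' @export
classify_memory_saccade <- function(events, go_ms, eccentricity, valid, t_ms,
                                    floor_ms = 80) {
  sgn <- sign(eccentricity)
  rl <- response_latency(events, go_ms, floor_ms)
  res <- list(outcome = "incorrect", latency = NA_real_, error = NA_real_,
              early = rl$early)
  if (is.na(rl$event)) {
    if (any(!valid[t_ms >= go_ms])) res$outcome <- "invalid"
    return(res)
  }
  i <- rl$event
  res$latency <- rl$latency
  fin <- final_position(events, i)
  if (events$direction[i] == sgn && abs(fin$pos) >= 0.5 * abs(eccentricity)) {
    res$outcome <- "correct"
    res$error <- endpoint_error(fin$pos, eccentricity)
  }
  res
}

#' Smooth-pursuit gain and positional error
#'
#' Saccadic intrusions are detected on the eye-minus-target residual (the
#' target itself moves faster than the saccade threshold at peak sinusoid
#' velocity) with the dedicated `pursuit_excision_threshold` (60 deg/s
#' default) and excised together with invalid samples. Gain is the robust
#' median of the ratio of smoothed eye velocity to target velocity over
#' samples where the target moves faster than 20% of its peak velocity;
#' pursuit error is the mean absolute eye-target positional difference over
#' the retained samples (`error_type = "rms"` gives the root-mean-square
#' alternative).
#'
#' @param trial a pursuit `gaze_trial` (with its `target` trace).
#' @param params detection parameters ([default_detection_params()]).
#' @param error_type `"mad"` (mean absolute deviation, default) or `"rms"`.
#' @return list with `gain`, `error` and `valid_fraction`; NULL (trial
#'   excluded) when fewer than 50% of samples are valid.
#' @export
pursuit_metrics <- function(trial, params = default_detection_params(),
                            error_type = c("mad", "rms")) {
  error_type <- match.arg(error_type)
  ax <- axis_trace(trial)
  if (mean(ax$valid) < 0.5) return(NULL)
  fs <- trial$fs
  target <- trial$target$pos_deg
  resid <- ax$pos - target
  # excision threshold sits well above both smooth-pursuit residual
  # velocity (<= |1 - gain| * peak target velocity) and velocity noise, but
  # far below genuine saccadic intrusions
  evs <- detect_saccades(resid, fs, valid = NULL, t_ms = ax$t,
                         velocity_threshold = params$pursuit_excision_threshold %||% 60,
                         min_amplitude = 0, min_duration_ms = 0,
                         keep_small = TRUE)
  keep <- ax$valid
  pad <- 20
  if (nrow(evs)) for (k in seq_len(nrow(evs)))
    keep[ax$t >= evs$onset_ms[k] - pad & ax$t <= evs$offset_ms[k] + pad] <- FALSE
  nw <- max(3, round(50 * fs / 1000) + !(round(50 * fs / 1000) %% 2))
  half <- (nw - 1) / 2
  nk <- length(keep)
  keep[c(seq_len(half + 1), (nk - half):nk)] <- FALSE  # filter edge region
  sm <- sg_filter(ax$pos, n = nw, p = 2)
  dev <- (sm - target)[keep]
  err <- if (error_type == "mad") mean(abs(dev)) else sqrt(mean(dev^2))
  ve <- gaze_velocity(ax$pos, fs)
  vt <- gaze_velocity(target, fs)
  strong <- abs(vt) > 0.2 * max(abs(vt))
  gain <- median((ve / vt)[keep & strong])
  list(gain = gain, error = err, valid_fraction = mean(ax$valid))
}

# Per-trial metrics dispatch. Returns a one-row data frame.
trial_metrics <- function(trial, params = default_detection_params()) {
  base <- structure(list(paradigm = trial$paradigm, plane = trial$plane,
                         eccentricity = trial$eccentricity, outcome = NA,
                         latency = NA_real_, return_latency = NA_real_,
                         corrected_latency = NA_real_, error = NA_real_,
                         gain = NA_real_, pursuit_error = NA_real_,
                         early = 0L),
                    class = "data.frame", row.names = 1L)
  if (trial$paradigm == "pursuit") {
    pm <- pursuit_metrics(trial, params)
    if (is.null(pm)) { base$outcome <- "invalid"; return(base) }
    base$outcome <- "pursuit"; base$gain <- pm$gain
    base$pursuit_error <- pm$error
    return(base)
  }
  ax <- axis_trace(trial)
  evs <- detect_saccades(ax$pos, trial$fs, valid = ax$valid, t_ms = ax$t,
                         velocity_threshold = params$velocity_threshold,
                         min_amplitude = params$min_amplitude,
                         min_duration_ms = params$min_duration_ms)
  floorms <- params$anticipatory_floor_ms
  if (trial$paradigm == "prosaccade") {
    rl <- response_latency(evs, trial$go_ms, floorms,
                           window_end_ms = trial$go2_ms)
    base$early <- rl$early
    if (is.na(rl$event)) {
      base$outcome <- if (any(!ax$valid[ax$t >= trial$go_ms & ax$t < trial$go2_ms]))
        "invalid" else "no_response"
    } else {
      base$outcome <- "response"
      base$latency <- rl$latency
      fin <- final_position(evs, rl$event, params$corrective_window_ms)
      base$error <- endpoint_error(fin$pos, trial$eccentricity)
    }
    r2 <- response_latency(evs, trial$go2_ms, floorms,
                           window_start_ms = trial$go2_ms)
    base$return_latency <- r2$latency
  } else if (trial$paradigm == "antisaccade") {
    cls <- classify_antisaccade(evs, trial$go_ms, trial$eccentricity,
                                ax$valid, ax$t, floorms,
                                params$corrected_latency_ref)
    if (cls$outcome == "no_response" &&
        any(!ax$valid[ax$t >= trial$go_ms])) cls$outcome <- "invalid"
    base$outcome <- cls$outcome
    base$latency <- cls$latency
    base$corrected_latency <- cls$corrected_latency
    base$error <- cls$error
    base$early <- cls$early
  } else if (trial$paradigm == "memory") {
    window_start <- trial$go_ms - 150
    evs_w <- evs[evs$onset_ms >= window_start, , drop = FALSE]
    cls <- classify_memory_saccade(evs_w, trial$go_ms, trial$eccentricity,
                                   ax$valid, ax$t, floorms)
    base$outcome <- cls$outcome
    base$latency <- cls$latency
    base$error <- cls$error
    base$early <- cls$early
  }
  base
}

#' Aggregate trial metrics into a subject feature vector
#'
#' Time and accuracy parameters are averaged within plane (positive and
#' negative endpoint errors separately, over trials of each sign); success
#' parameters are pooled over planes: % correct antisaccades =
#' correct/attempted, % corrected = corrected errors/erroneous, % successful
#' = (correct + corrected)/attempted. A parameter with an empty denominator
#' is carried as missing, never as zero.
#'
#' @param metrics data frame of per-trial metrics (rows from
#'   `trial_metrics()`).
#' @return one-row data frame of oculomotor features.
#' @export
aggregate_subject <- function(metrics) {
  m <- function(x) { x <- x[!is.na(x)]; if (length(x)) mean(x) else NA_real_ }
  out <- list()
  for (pl in c("horizontal", "vertical")) {
    sfx <- if (pl == "horizontal") "_h" else "_v"
    pro <- metrics[metrics$paradigm == "prosaccade" & metrics$plane == pl, ]
    anti <- metrics[metrics$paradigm == "antisaccade" & metrics$plane == pl, ]
    mem <- metrics[metrics$paradigm == "memory" & metrics$plane == pl, ]
    pur <- metrics[metrics$paradigm == "pursuit" & metrics$plane == pl, ]
    out[[paste0("pro_latency", sfx)]] <- m(pro$latency)
    out[[paste0("return_latency", sfx)]] <- m(pro$return_latency)
    out[[paste0("pro_pos_error", sfx)]] <- m(pro$error[pro$error > 0])
    out[[paste0("pro_neg_error", sfx)]] <- m(pro$error[pro$error <= 0])
    out[[paste0("anti_corrected_latency", sfx)]] <- m(anti$corrected_latency)
    out[[paste0("anti_pos_error", sfx)]] <- m(anti$error[anti$error > 0])
    out[[paste0("anti_neg_error", sfx)]] <- m(anti$error[anti$error <= 0])
    out[[paste0("mem_latency", sfx)]] <- m(mem$latency)
    out[[paste0("mem_pos_error", sfx)]] <- m(mem$error[mem$error > 0])
    out[[paste0("mem_neg_error", sfx)]] <- m(mem$error[mem$error <= 0])
    out[[paste0("pursuit_gain", sfx)]] <- m(pur$gain)
    out[[paste0("pursuit_error", sfx)]] <- m(pur$pursuit_error)
  }
  anti <- metrics[metrics$paradigm == "antisaccade", ]
  n_c <- sum(anti$outcome == "correct", na.rm = TRUE)
  n_f <- sum(anti$outcome == "corrected", na.rm = TRUE)
  n_u <- sum(anti$outcome == "uncorrected", na.rm = TRUE)
  att <- n_c + n_f + n_u            # censored ("unknown") trials excluded
  out$pct_correct_anti <- if (att) 100 * n_c / att else NA_real_
  out$pct_corrected_anti <- if (n_f + n_u) 100 * n_f / (n_f + n_u) else NA_real_
  out$pct_successful_anti <- if (att) 100 * (n_c + n_f) / att else NA_real_
  mem <- metrics[metrics$paradigm == "memory", ]
  n_att <- sum(mem$outcome %in% c("correct", "incorrect"), na.rm = TRUE)
  out$pct_correct_memory <- if (n_att)
    100 * sum(mem$outcome == "correct", na.rm = TRUE) / n_att else NA_real_
  out$early_saccades <- sum(metrics$early, na.rm = TRUE)
  as.data.frame(out)
}

#' Extract oculomotor features from a cohort of recordings
#'
#' Runs saccade detection and per-trial metric computation on every trial of
#' every subject and aggregates to one feature vector per subject
#' ([aggregate_subject()]), prefixed with the subject metadata columns.
#'
#' @param x a `gaze_cohort`, or a list of `subject_record`s.
#' @param params detection parameters ([default_detection_params()]).
#' @return data frame, one row per subject: `id`, `group`, demographics,
#'   then the oculomotor features.
#' @export
extract_features <- function(x, params = default_detection_params()) {
  records <- if (inherits(x, "gaze_cohort")) x$records else x
  rows <- lapply(records, function(rec) {
    tm <- do.call(rbind, lapply(rec$recordings, function(rc)
      do.call(rbind, lapply(rc$trials, trial_metrics, params = params))))
    meta <- data.frame(id = rec$id, group = rec$group, age = rec$age,
                       sex = rec$sex, sedatives = rec$sedatives,
                       disease_duration = rec$disease_duration %||% NA_real_,
                       mmse = rec$mmse %||% NA_real_,
                       rocft_copy = rec$rocft_copy %||% NA_real_,
                       symbol_digit = rec$symbol_digit %||% NA_real_)
    cbind(meta, aggregate_subject(tm))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
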