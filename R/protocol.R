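# Test protocols: trial counts, eccentricity schedules and phase timing for
# the four oculomotor paradigms.

.h_eccentricities <- c(-20, -10, -5, 5, 10, 20)
.v_eccentricities <- c(-12, -5, 5, 12)

#' Default phase timing for a paradigm
#'
#' Durations in ms of the stimulus phases of one trial. The eye tracker's
#' protocol publishes trial counts and target amplitudes but not phase
#' durations, so these are declared package defaults (see the methods
#' vignette): 1,000 ms central fixation; 1,500 ms eccentric target and a
#' 1,500 ms return phase for prosaccades; a long 3,500 ms eccentric phase for
#' antisaccades so that late corrective saccades fall inside the trial;
#' 1,500 ms eccentric + 1,000 ms re-fixation + 3,000 ms blank response window
#' for memory trials; and a ±20 deg (horizontal) / ±12 deg (vertical)
#' 0.25 Hz sinusoid lasting two full cycles for pursuit.
#'
#' @param paradigm one of `"prosaccade"`, `"antisaccade"`, `"memory"`,
#'   `"pursuit"`.
#' @return named list of durations (ms) and, for pursuit, amplitude (deg) and
#'   frequency (Hz).
#' @export
default_timing <- function(paradigm) {
  paradigm <- match.arg(paradigm, .paradigms)
  switch(paradigm,
    prosaccade = list(fixation_ms = 1000, target_ms = 1500, return_ms = 1500),
    antisaccade = list(fixation_ms = 1000, target_ms = 3500),
    memory = list(fixation_ms = 1000, target_ms = 1500, center_ms = 1000,
                  blank_ms = 3000),
    pursuit = list(amp_h = 20, amp_v = 12, freq_hz = 0.25, cycles = 2)
  )
}

#' Build a seeded test protocol
#'
#' Saccadic tests (prosaccade, antisaccade, memory) comprise 12 horizontal
#' trials followed by 8 vertical trials; horizontal targets appear at 5, 10 or
#' 20 degrees left or right and vertical targets at 5 or 12 degrees up or
#' down. The pursuit test has 6 horizontal and 6 vertical trials. The
#' eccentricity schedule is a seeded random permutation in which every allowed
#' eccentricity appears (twice per plane for saccadic tests), so the same
#' `(paradigm, seed)` pair always yields the identical protocol.
#'
#' @param paradigm paradigm name.
#' @param seed integer seed for the amplitude schedule.
#' @param fs sampling rate in Hz (default 100).
#' @param timing phase timing, as from [default_timing()].
#' @return an object of class `test_protocol`: a list with the paradigm,
#'   sampling rate, trial counts, the trial `schedule` (data frame with
#'   `plane` and `eccentricity`) and the phase `timing`.
#' @examples
#' p <- build_protocol("prosaccade", seed = 1)
#' table(p$schedule$plane)
#' @export
build_protocol <- function(paradigm, seed, fs = 100,
                           timing = default_timing(paradigm)) {
  if (length(paradigm) != 1 || !paradigm %in% .paradigms)
    stop("unknown paradigm: ", paste(paradigm, collapse = ", "),
         " (expected one of ", paste(.paradigms, collapse = ", "), ")")
  stopifnot(is.numeric(seed), length(seed) == 1, fs > 0)
  if (paradigm == "pursuit") {
    sched <- data.frame(
      plane = rep(c("horizontal", "vertical"), each = 6),
      eccentricity = rep(c(timing$amp_h, timing$amp_v), each = 6)
    )
  } else {
    sched <- with_seed(seed, {
      h <- sample(rep(.h_eccentricities, 2))
      v <- sample(rep(.v_eccentricities, 2))
      data.frame(
        plane = rep(c("horizontal", "vertical"), c(12, 8)),
        eccentricity = c(h, v)
      )
    })
  }
  structure(list(
    paradigm = paradigm, fs = fs, seed = seed,
    n_horizontal = sum(sched$plane == "horizontal"),
    n_vertical = sum(sched$plane == "vertical"),
    schedule = sched, timing = timing
  ), class = "test_protocol")
}

#' @export
print.test_protocol <- function(x, ...) {
  cat(sprintf("<test_protocol> %s: %d horizontal + %d vertical trials, fs = %g Hz\n",
              x$paradigm, x$n_horizontal, x$n_vertical, x$fs))
  invisible(x)
}

#' Stimulus phase table of one saccadic trial
#'
#' @param paradigm paradigm name (saccadic paradigms only).
#' @param eccentricity signed target eccentricity (deg).
#' @param plane `"horizontal"` or `"vertical"`.
#' @param timing phase timing list.
#' @return data frame with `onset_ms`, `offset_ms`, `target_x_deg`,
#'   `target_y_deg` and `visible` (FALSE for the blank memory-response
#'   window), contiguous and non-overlapping.
#' @keywords internal
trial_phases <- function(paradigm, eccentricity, plane, timing) {
  tx <- function(e) if (plane == "horizontal") e else 0
  ty <- function(e) if (plane == "vertical") e else 0
  mk <- function(durs, eccs, vis) {
    off <- cumsum(durs)
    data.frame(onset_ms = c(0, head(off, -1)), offset_ms = off,
               target_x_deg = vapply(eccs, tx, 0),
               target_y_deg = vapply(eccs, ty, 0), visible = vis)
  }
  switch(paradigm,
    prosaccade = mk(c(timing$fixation_ms, timing$target_ms, timing$return_ms),
                    c(0, eccentricity, 0), c(TRUE, TRUE, TRUE)),
    antisaccade = mk(c(timing$fixation_ms, timing$target_ms),
                     c(0, eccentricity), c(TRUE, TRUE)),
    memory = mk(c(timing$fixation_ms, timing$target_ms, timing$center_ms,
                  timing$blank_ms),
                c(0, eccentricity, 0, 0), c(TRUE, TRUE, TRUE, FALSE)),
    stop("trial_phases: not defined for paradigm ", paradigm)
  )
}
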