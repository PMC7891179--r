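# Velocity-threshold saccade detection on a smoothed derivative.

# Savitzky-Golay smoothing / differentiation via the central row of the
# signal::sgolay projection matrix, applied as a symmetric FIR filter with
# edge replication. m = 0 smooths, m = 1 differentiates (per sample).
.sg_cache <- new.env(parent = emptyenv())

sg_coefs <- function(n, p, m) {
  key <- paste(n, p, m, sep = "_")
  w <- .sg_cache[[key]]
  if (is.null(w)) {
    h <- (n + 1) / 2
    w <- as.numeric(signal::sgolay(p = p, n = n, m = m)[h, ])
    .sg_cache[[key]] <- w
  }
  w
}

sg_filter <- function(x, n = 5, p = 2, m = 0) {
  if (length(x) < n) return(if (m == 0) x else rep(0, length(x)))
  h <- (n + 1) / 2
  w <- sg_coefs(n, p, m)
  pad <- rep_len(h - 1, 2)
  xp <- c(rep(x[1], pad[1]), x, rep(x[length(x)], pad[2]))
  y <- stats::filter(xp, rev(w), sides = 2)
  as.numeric(y[h:(h + length(x) - 1)])
}

#' Smoothed gaze velocity
#'
#' Centered Savitzky-Golay differentiation (quadratic fit) over a window of
#' about 50 ms at the given sampling rate.
#'
#' @param pos position samples (deg).
#' @param fs sampling rate (Hz).
#' @param window_ms smoothing window (ms); rounded to an odd sample count.
#' @return velocity in deg/s, same length as `pos`.
#' @export
gaze_velocity <- function(pos, fs, window_ms = 50) {
  n <- max(3, round(window_ms * fs / 1000))
  if (n %% 2 == 0) n <- n + 1
  sg_filter(pos, n = n, p = 2, m = 1) * fs
}

# Sub-sample crossing time of `level` on the rising edge between samples
# i and i+1 (linear interpolation); returns time in ms.
.cross_time <- function(t, v, i, level) {
  if (i < 1 || i >= length(v)) return(t[max(i, 1)])
  dv <- v[i + 1] - v[i]
  if (dv == 0) return(t[i])
  t[i] + (level - v[i]) / dv * (t[i + 1] - t[i])
}

# Velocity-edge refinement (fallback): the rising edge of the (smoothed)
# velocity pulse between 20% and 80% of its peak is extrapolated linearly to
# zero velocity; the offset is refined symmetrically on the falling edge.
# Smoothing widens the pulse, so this estimator runs early by several ms;
# the position-based quartile estimator below is preferred when usable.
.refine_edge <- function(t, av, from, peak_idx, rising = TRUE) {
  pk <- av[peak_idx]
  lo <- 0.2 * pk; hi <- 0.8 * pk
  idx <- if (rising) from:peak_idx else peak_idx:from
  if (rising) {
    i_lo <- idx[which(av[idx] >= lo)[1]]
    i_hi <- idx[which(av[idx] >= hi)[1]]
    if (is.na(i_lo) || is.na(i_hi)) return(t[from])
    t_lo <- .cross_time(t, av, max(i_lo - 1, 1), lo)
    t_hi <- .cross_time(t, av, max(i_hi - 1, 1), hi)
    if (t_hi <= t_lo) return(t_lo)
    t_lo - (t_hi - t_lo) / 3          # extend 0.2->0.8 slope down to 0
  } else {
    below <- which(av[idx] <= lo)
    i_lo <- if (length(below)) idx[below[1]] else from
    above <- which(av[idx] >= hi)
    i_hi <- if (length(above)) idx[tail(above, 1)] else peak_idx
    t_lo <- .cross_time(t, -av, max(i_lo - 1, 1), -lo)
    t_hi <- .cross_time(t, -av, max(i_hi - 1, 1), -hi)
    if (t_lo <= t_hi) return(t[i_lo])
    t_lo + (t_lo - t_hi) / 3
  }
}

# Position-based boundary estimator. For a saccade with a symmetric
# (odd-about-centre) displacement profile the crossing of the halfway
# position is the temporal centre of the movement and is invariant under
# symmetric smoothing and sampling; onset and offset are then placed half a
# main-sequence duration (d0 + k * |amplitude|) either side of that centre.
# Returns NULL when the crossing cannot be bracketed (fallback to the
# velocity-edge estimator).
.refine_position <- function(t_ms, pos, i1, i2, d0 = 20, k = 2) {
  lo <- max(i1 - 2, 1); hi <- min(i2 + 2, length(pos))
  idx <- lo:hi
  sp <- pos[lo]; ep <- pos[hi]
  amp <- ep - sp
  if (abs(amp) < 1e-6) return(NULL)
  lev <- sp + amp / 2
  s <- sign(amp)
  above <- (pos[idx] - lev) * s >= 0
  j <- which(above)[1]
  if (is.na(j) || j == 1) return(NULL)
  t50 <- .cross_time(t_ms, s * pos, idx[j] - 1, s * lev)
  dur <- d0 + k * abs(amp)
  list(onset = t50 - dur / 2, offset = t50 + dur / 2)
}

#' Detect saccades in a 1-D gaze trace
#'
#' Velocity-threshold detection on a Savitzky-Golay smoothed derivative:
#' samples whose absolute smoothed velocity exceeds `velocity_threshold`
#' seed candidate events, event boundaries are extended to the surrounding
#' low-velocity samples, and onset/offset are refined to sub-sample
#' precision from the position trace: the mid-transition crossing gives the
#' movement centre (invariant under symmetric smoothing) and the
#' main-sequence rule `d0 + k * |amplitude|` its duration, falling back to
#' linear extrapolation of the velocity-pulse edges. Events
#' shorter than `min_duration_ms`, smaller than `min_amplitude` or
#' overlapping invalid (blink) samples are discarded.
#'
#' @param pos position along the trial axis (deg).
#' @param fs sampling rate (Hz).
#' @param valid logical vector of sample validity (default all valid).
#' @param t_ms sample times (default regular grid from `fs`).
#' @param velocity_threshold detection threshold (deg/s, default 30).
#' @param min_amplitude minimum event amplitude (deg, default 1).
#' @param min_duration_ms minimum event duration (ms, default 10).
#' @param main_sequence `c(d0, k)` of the amplitude-duration rule used by
#'   the position-based boundary refinement (ms and ms/deg).
#' @param keep_small keep sub-amplitude events (used internally for
#'   excision masks).
#' @return data frame of events sorted by onset: `onset_ms`, `offset_ms`,
#'   `start_pos`, `end_pos`, `amplitude` (signed), `peak_velocity`,
#'   `direction` (sign of the amplitude), and the sample index range
#'   `i_start`, `i_end`.
#' @examples
#' seg <- synthesize_saccade(0, 10, onset_ms = 300, fs = 250, total_ms = 800)
#' detect_saccades(seg$pos_deg, fs = 250)
.event_df <- function(onset, offset, sp, ep, pk, i1, i2) {
  structure(list(onset_ms = onset, offset_ms = offset, start_pos = sp,
                 end_pos = ep, amplitude = ep - sp, peak_velocity = pk,
                 direction = sign(ep - sp), i_start = i1, i_end = i2),
            class = "data.frame",
            row.names = if (length(onset)) seq_along(onset) else integer(0))
}

#' @export
detect_saccades <- function(pos, fs, valid = NULL, t_ms = NULL,
                            velocity_threshold = 30, min_amplitude = 1,
                            min_duration_ms = 10, main_sequence = c(20, 2),
                            keep_small = FALSE) {
  n <- length(pos)
  empty <- .event_df(numeric(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), integer(0), integer(0))
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(t_ms)) t_ms <- (seq_len(n) - 1) * 1000 / fs
  if (sum(valid) < 3) {
    warning("detect_saccades: fewer than 3 valid samples")
    return(empty)
  }
  # interpolate across invalid spans for the derivative only
  p <- pos
  if (any(!valid)) {
    ok <- which(valid)
    p <- approx(t_ms[ok], pos[ok], xout = t_ms, rule = 2)$y
  }
  v <- gaze_velocity(p, fs)
  av <- abs(v)
  above <- av >= velocity_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  evs <- list()
  last_end <- -1
  for (k in seq_len(nrow(runs))) {
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    pk_i <- i1 - 1 + which.max(av[i1:i2])
    lo <- max(velocity_threshold * 0.2, 0.05 * av[pk_i])
    while (i1 > 1 && av[i1 - 1] >= lo) i1 <- i1 - 1
    while (i2 < n && av[i2 + 1] >= lo) i2 <- i2 + 1
    if (i1 <= last_end) {            # merged with previous extended run
      prev <- evs[[length(evs)]]
      prev$i2 <- max(prev$i2, i2)
      if (av[pk_i] > av[prev$pk]) prev$pk <- pk_i
      evs[[length(evs)]] <- prev
    } else {
      evs[[length(evs) + 1]] <- list(i1 = i1, i2 = i2, pk = pk_i)
    }
    last_end <- i2
  }
  # lightly smoothed position for sub-sample crossing localisation: a
  # symmetric 3-point kernel preserves the mid-transition crossing time
  psm <- if (n >= 3) {
    y <- stats::filter(p, c(0.25, 0.5, 0.25), sides = 2)
    y[1] <- p[1]; y[n] <- p[n]
    as.numeric(y)
  } else p

  med3 <- function(idx) {
    k <- length(idx)
    if (k >= 3) median(pos[idx[(k - 2):k]]) else pos[idx[k]]
  }
  onset_v <- offset_v <- sp_v <- ep_v <- pk_v <- numeric(0)
  i1_v <- i2_v <- integer(0)
  for (ev in evs) {
    ref <- .refine_position(t_ms, psm, ev$i1, ev$i2,
                            main_sequence[1], main_sequence[2])
    if (is.null(ref)) {
      onset <- .refine_edge(t_ms, av, ev$i1, ev$pk, rising = TRUE)
      offset <- .refine_edge(t_ms, av, ev$i2, ev$pk, rising = FALSE)
    } else {
      onset <- ref$onset; offset <- ref$offset
    }
    if (offset - onset < min_duration_ms) next
    # robust positions just outside the event
    pre <- which(t_ms <= onset)
    post <- which(t_ms >= offset)
    if (!length(pre) || !length(post)) next
    sp <- med3(pre)
    k <- length(post)
    epos <- if (k >= 3) median(pos[post[1:3]]) else pos[post[1]]
    if (!keep_small && abs(epos - sp) < min_amplitude) next
    if (any(!valid[ev$i1:ev$i2])) next
    onset_v <- c(onset_v, onset); offset_v <- c(offset_v, offset)
    sp_v <- c(sp_v, sp); ep_v <- c(ep_v, epos); pk_v <- c(pk_v, av[ev$pk])
    i1_v <- c(i1_v, ev$i1); i2_v <- c(i2_v, ev$i2)
  }
  if (!length(onset_v)) return(empty)
  o <- order(onset_v)
  .event_df(onset_v[o], offset_v[o], sp_v[o], ep_v[o], pk_v[o],
            i1_v[o], i2_v[o])
}
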