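# Gaze-table I/O: a documented comma-delimited dialect for raw recordings.
#
# One row per sample. Required columns: subject, paradigm, trial, t_ms,
# x_deg, y_deg, valid. Additional metadata columns written by the package
# (group, plane, eccentricity, go_ms, go2_ms, amp, freq) make a written
# cohort re-extractable; readers require only the seven documented columns
# and tolerate extras.

.gaze_required_cols <- c("subject", "paradigm", "trial", "t_ms", "x_deg",
                         "y_deg", "valid")

#' Write a subject recording to a gaze CSV
#'
#' @param record a `subject_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(record, path) {
  blocks <- list()
  for (par in names(record$recordings)) {
    trials <- record$recordings[[par]]$trials
    for (j in seq_along(trials)) {
      tr <- trials[[j]]
      n <- nrow(tr$trace)
      if (!n) stop("empty trace: ", par, " trial ", j)
      blocks[[length(blocks) + 1]] <- data.frame(
        subject = record$id, group = record$group, paradigm = par, trial = j,
        plane = tr$plane, eccentricity = tr$eccentricity,
        go_ms = tr$go_ms, go2_ms = tr$go2_ms %||% NA_real_,
        amp = tr$amp, freq = tr$freq,
        t_ms = tr$trace$t_ms, x_deg = tr$trace$x_deg, y_deg = tr$trace$y_deg,
        valid = as.integer(tr$trace$valid)
      )
    }
  }
  d <- do.call(rbind, blocks)
  for (col in c("t_ms", "x_deg", "y_deg", "go_ms", "go2_ms", "amp", "freq",
                "eccentricity"))
    d[[col]] <- format(d[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a subject recording from a gaze CSV
#'
#' Validates the documented dialect on read: the required columns must be
#' present, each trial trace must be non-empty with strictly increasing
#' sample times, and the paradigm must be known; violations raise an error
#' naming the offending row.
#'
#' @param path gaze CSV written by [write_gaze_table()].
#' @return a `subject_record` (trace-level fields only; stimulus phase
#'   tables are reconstructed from the stored go times and eccentricities).
#' @export
read_gaze_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.gaze_required_cols, names(d))
  if (length(missing))
    stop("gaze table ", path, ": missing columns: ",
         paste(missing, collapse = ", "))
  bad <- which(!d$paradigm %in% .paradigms)
  if (length(bad))
    stop("gaze table row ", bad[1] + 1, ": unknown paradigm '",
         d$paradigm[bad[1]], "'")
  recs <- list()
  for (par in unique(d$paradigm)) {
    dp <- d[d$paradigm == par, ]
    trials <- list()
    for (j in sort(unique(dp$trial))) {
      dt <- dp[dp$trial == j, ]
      if (!nrow(dt)) stop("empty trace for ", par, " trial ", j)
      dec <- which(diff(dt$t_ms) <= 0)
      if (length(dec)) {
        row_in_file <- which(d$paradigm == par & d$trial == j)[dec[1] + 1] + 1
        stop("gaze table row ", row_in_file,
             ": non-monotonic t_ms in ", par, " trial ", j)
      }
      fs <- 1000 / median(diff(dt$t_ms))
      valid <- as.logical(dt$valid)
      oob <- which(valid & (abs(dt$x_deg) > 40 | abs(dt$y_deg) > 40))
      if (length(oob)) {
        row_in_file <- which(d$paradigm == par & d$trial == j)[oob[1]] + 1
        stop("gaze table row ", row_in_file, ": gaze angle out of range")
      }
      tr <- new_trial(par, dt$plane[1] %||% "horizontal",
                      dt$eccentricity[1] %||% NA_real_, fs,
                      end_ms = max(dt$t_ms), go_ms = dt$go_ms[1] %||% NA_real_,
                      go2_ms = dt$go2_ms[1] %||% NA_real_,
                      amp = dt$amp[1] %||% NA_real_,
                      freq = dt$freq[1] %||% NA_real_)
      tr$trace <- data.frame(t_ms = dt$t_ms, x_deg = dt$x_deg,
                             y_deg = dt$y_deg, valid = valid)
      if (par == "pursuit" && is.finite(tr$amp) && is.finite(tr$freq))
        tr$target <- data.frame(
          t_ms = dt$t_ms,
          pos_deg = tr$amp * sin(2 * pi * tr$freq * dt$t_ms / 1000))
      trials[[j]] <- structure(tr, class = "gaze_trial")
    }
    recs[[par]] <- list(trials = trials)
  }
  structure(list(id = d$subject[1], group = d$group[1] %||% NA_character_,
                 age = NA_real_, sex = NA_character_, sedatives = NA_real_,
                 disease_duration = NA_real_, mmse = NA_real_,
                 recordings = recs),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s): %s\n", x$id, x$group,
              paste(names(x$recordings), collapse = ", ")))
  invisible(x)
}
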