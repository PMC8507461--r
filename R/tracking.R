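# Operator position traces ---------------------------------------------------
#
# Timestamped 3D positions of the operator's dosemeter point in the room
# frame (meters), as produced by an indoor positioning system. The
# position used for an irradiation event is the one held at the event
# start (hold-last-value); movement during long image acquisitions can be
# handled by subdividing the event into frames.

#' Read / write an operator position trace
#'
#' CSV columns `t,x,y,z[,valid]`: time in epoch seconds (same time base
#' as the event log after the clock offset), position in meters in the
#' room frame, `valid` an optional 0/1 flag for dropout samples. Invalid
#' samples are kept and flagged, never interpolated at load time.
#'
#' @param path CSV file.
#' @param trace an `irs_trace`.
#' @return `read_trace()`: data.frame of class `irs_trace` with columns
#'   `t`, `x`, `y`, `z`, `valid`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("cannot read trace: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty position trace: ", path)
  position_trace(df)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @param df data.frame with columns `t,x,y,z[,valid]`.
#' @export
position_trace <- function(df) {
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df))) stop("trace needs columns t,x,y,z")
  if (is.null(df$valid)) df$valid <- 1L
  df$valid <- as.integer(df$valid != 0)
  dup <- which(diff(df$t) <= 0)
  if (length(dup)) {
    stop(sprintf("trace timestamps must be strictly increasing (row %d)", dup[1] + 1L))
  }
  bad <- df$valid == 1L & !is.finite(df$x + df$y + df$z)
  if (any(bad)) {
    stop(sprintf("non-finite position in valid trace sample (row %d)", which(bad)[1]))
  }
  df <- df[, c("t", "x", "y", "z", "valid")]
  class(df) <- c("irs_trace", "data.frame")
  df
}

#' Operator position at a given time
#'
#' Hold-last-value lookup: the latest valid sample at or before `t`. If
#' the nearest valid sample is further away than `max_gap` seconds the
#' position is unknown (`NA`s).
#'
#' @param trace an `irs_trace`.
#' @param t query time, epoch seconds.
#' @param max_gap maximum tolerated age of the held sample, s.
#' @return length-3 numeric (m) or `c(NA, NA, NA)` when unknown.
#' @export
position_at <- function(trace, t, max_gap = 5) {
  ok <- trace$valid == 1L & trace$t <= t
  if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_))
  i <- max(which(ok))
  if (t - trace$t[i] > max_gap) return(c(NA_real_, NA_real_, NA_real_))
  c(trace$x[i], trace$y[i], trace$z[i])
}

#' Operator position at the start of an irradiation event
#'
#' The operator position is fixed at the beginning of the irradiation
#' event, assuming no movement during the event (see [subdivide_event()]
#' for the movement-corrected treatment).
#'
#' @param trace an `irs_trace`.
#' @param event 1-row event data.frame (see [irradiation_event()]).
#' @param clock_offset seconds added to the event clock to reach the
#'   trace clock.
#' @param max_gap see [position_at()].
#' @return length-3 numeric (m) or `NA`s when position-unknown.
#' @export
position_at_event_start <- function(trace, event, clock_offset = 0, max_gap = 5) {
  position_at(trace, event$t_start + clock_offset, max_gap = max_gap)
}

#' Subdivide an event to follow operator movement
#'
#' Splits one irradiation event into `n_frames` equal-duration sub-events,
#' apportioning the kerma-area product and reference-point kerma uniformly
#' (acquisitions run at constant pulse rate) and assigning each sub-event
#' the trace position at its own start. Used to correct the dose of long
#' image acquisitions during which the operator moves away.
#'
#' @param event 1-row event data.frame with `duration > 0`.
#' @param trace an `irs_trace`.
#' @param n_frames number of frames (>= 1); reduced with a warning when
#'   the trace has fewer samples inside the event window.
#' @param clock_offset,max_gap see [position_at_event_start()].
#' @param interpolate if `TRUE`, positions are linearly interpolated at
#'   frame starts instead of held from the last sample.
#' @return list with `events` (data.frame of sub-events, `p_ka` and
#'   `k_air_ref` summing exactly to the parent's) and `positions`
#'   (n_frames x 3 matrix, rows may be `NA` when position-unknown).
#' @export
subdivide_event <- function(event, trace, n_frames, clock_offset = 0,
                            max_gap = 5, interpolate = FALSE) {
  stopifnot(n_frames >= 1, event$duration > 0)
  t0 <- event$t_start + clock_offset
  in_window <- sum(trace$valid == 1L & trace$t >= t0 &
                     trace$t <= t0 + event$duration)
  if (n_frames > max(in_window, 1L)) {
    n_frames <- max(in_window, 1L)
    warning(sprintf("event '%s': fewer trace samples than frames, using %d frames",
                    event$event_id, n_frames))
  }
  dt <- event$duration / n_frames
  subs <- event[rep(1L, n_frames), ]
  subs$event_id <- if (n_frames == 1) event$event_id else
    sprintf("%s#%d", event$event_id, seq_len(n_frames))
  subs$t_start <- event$t_start + (seq_len(n_frames) - 1) * dt
  subs$duration <- dt
  subs$p_ka <- event$p_ka / n_frames
  subs$k_air_ref <- event$k_air_ref / n_frames
  rownames(subs) <- NULL
  pos <- matrix(NA_real_, n_frames, 3)
  for (i in seq_len(n_frames)) {
    ti <- subs$t_start[i] + clock_offset
    pos[i, ] <- if (interpolate) .interp_position(trace, ti, max_gap)
                else position_at(trace, ti, max_gap = max_gap)
  }
  list(events = subs, positions = pos)
}

.interp_position <- function(trace, t, max_gap) {
  v <- trace[trace$valid == 1L, ]
  if (!nrow(v)) return(c(NA_real_, NA_real_, NA_real_))
  if (t <= v$t[1]) {
    return(if (v$t[1] - t <= max_gap) c(v$x[1], v$y[1], v$z[1])
           else c(NA_real_, NA_real_, NA_real_))
  }
  if (t >= v$t[nrow(v)]) return(position_at(trace, t, max_gap))
  c(stats::approx(v$t, v$x, t)$y, stats::approx(v$t, v$y, t)$y,
    stats::approx(v$t, v$z, t)$y)
}
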