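# Synthetic procedure generator ----------------------------------------------
#
# Emulates complete interventional procedures (event log + operator trace
# + room + detector points) with the exposure-parameter envelopes of four
# reference scenarios: A an experimental single-exposure set-up, B a long
# abdominal-artery treatment behind a ceiling shield, C a short low-dose
# extremity-artery investigation, D a long renal-artery treatment with
# the operator walking around and occasionally leaving the room. Per-event
# kerma-area products are drawn log-normally and rescaled so their sum
# matches the case total exactly; traces are deterministic waypoint
# scripts plus seeded jitter at 5 Hz with dropout gaps.

#' Case profiles for the synthetic generator
#'
#' Returns the parameter envelope of one of the built-in cases (event
#' count, technique-factor ranges, output totals, shield use, operator
#' movement script).
#'
#' @param name `"A"`, `"B"`, `"C"` or `"D"`.
#' @return list of class `irs_case_profile`.
#' @export
case_profile <- function(name = c("A", "B", "C", "D")) {
  name <- match.arg(name)
  p <- switch(name,
    A = list(n_events = 1L, n_acquisitions = 0L, kvp_range = c(79, 79),
             filtration_set = 0.3, field_range = c(835, 835),
             ang_range = c(0, 0), total_pka = 4.1, total_kair = 17.6,
             duration_s = 60, shield = FALSE, operator_script = "static_near"),
    B = list(n_events = 115L, n_acquisitions = 17L, kvp_range = c(70, 86),
             filtration_set = c(0.1, 0.2, 0.3, 0.6, 0.9),
             field_range = c(457, 1091), ang_range = c(0, 38),
             total_pka = 163, total_kair = 679, duration_s = 8640,
             shield = TRUE, operator_script = "moves_away_once"),
    C = list(n_events = 19L, n_acquisitions = 7L, kvp_range = c(66, 82),
             filtration_set = c(0.3, 0.6, 0.9), field_range = c(325, 825),
             ang_range = c(0, 0), total_pka = 0.06, total_kair = 0.3,
             duration_s = 780, shield = FALSE, operator_script = "static_near"),
    D = list(n_events = 186L, n_acquisitions = 10L, kvp_range = c(68, 85),
             filtration_set = c(0.2, 0.3, 0.6, 0.9), field_range = c(54, 630),
             ang_range = c(-35, 26), total_pka = 10.5, total_kair = 200,
             duration_s = 8040, shield = FALSE,
             operator_script = "walks_and_leaves"))
  p$name <- name
  structure(p, class = "irs_case_profile")
}

# operator base position: standing at the patient's right side at chest
# dosemeter height (room frame, isocenter origin)
.OPERATOR_BASE <- c(-0.7, 0.1, 0.3)

#' Generate a synthetic procedure
#'
#' Draws an event log, an operator position trace, a room model and a
#' detector-point set from a [case_profile()], reproducibly for a given
#' seed. Event kerma-area products sum to the profile total to within
#' 0.1% (exact up to rounding); acquisitions carry 60% of the total
#' output. The trace runs at 5 Hz with seeded 3 cm jitter and short
#' dropout gaps.
#'
#' @param profile an [case_profile()].
#' @param seed integer seed.
#' @return list with `log` (an `irs_log`), `trace` (an `irs_trace`),
#'   `room` (an `irs_room`), `points` (an `irs_points`; offsets from the
#'   tracked position) and `profile`.
#' @export
generate_case <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "irs_case_profile"))
  if (profile$n_events < 1 && profile$total_pka > 0) {
    stop("infeasible profile: zero events with positive total output")
  }
  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(event_seed(seed, paste0("case", profile$name)))

  n <- profile$n_events
  n_acq <- profile$n_acquisitions
  type <- rep("fluoroscopy", n)
  if (n_acq > 0) type[sort(sample.int(n, n_acq))] <- "acquisition"

  t0 <- 1.7e9  # arbitrary epoch anchor
  starts <- t0 + sort(stats::runif(n, 0, profile$duration_s))
  dur <- ifelse(type == "acquisition", 7,
                pmax(2, stats::rgamma(n, shape = 2, scale = 12)))

  # log-normal output shapes rescaled to the exact case totals,
  # with a 40/60 fluoroscopy/acquisition split
  raw <- stats::rlnorm(n, 0, 1)
  pka <- raw
  if (n_acq > 0 && n_acq < n) {
    acq <- type == "acquisition"
    pka[acq] <- raw[acq] / sum(raw[acq]) * 0.6 * profile$total_pka
    pka[!acq] <- raw[!acq] / sum(raw[!acq]) * 0.4 * profile$total_pka
  } else {
    pka <- raw / sum(raw) * profile$total_pka
  }
  kair <- pka / sum(pka) * profile$total_kair

  events <- data.frame(
    event_id = sprintf("ev%03d", seq_len(n)),
    t_start = starts, duration = dur, event_type = type,
    kvp = round(stats::runif(n, profile$kvp_range[1], profile$kvp_range[2])),
    filtration_cu = sample(rep(profile$filtration_set, 2), n, replace = TRUE),
    filtration_al = 0,
    ang_primary = round(stats::runif(n, profile$ang_range[1], profile$ang_range[2])),
    ang_secondary = 0,
    field_area = round(stats::runif(n, profile$field_range[1], profile$field_range[2])),
    p_ka = pka, k_air_ref = kair, table_height = NA_real_)
  log <- procedure_log(events, source_format = "csv", clock_offset = 0)

  trace <- .operator_trace(profile, events)

  shield <- if (profile$shield) {
    shield_model(center = c(-0.45, 0.1, 0.45), u = c(0, 1, 0), v = c(0, 0, 1),
                 width = 0.6, height = 0.6, pb_mm = 0.5)
  } else NULL
  room <- room_model(phantom = bomab_phantom(), shield = shield)

  points <- detector_points(data.frame(
    point_id = c("chest", "shoulder_l"),
    x = c(0, 0.12), y = c(0, 0), z = c(0, 0.25),
    label = c("chest dosemeter", "left shoulder")))

  list(log = log, trace = trace, room = room, points = points,
       profile = profile)
}

.operator_trace <- function(profile, events) {
  t_lo <- min(events$t_start) - 10
  t_hi <- max(events$t_start + events$duration) + 10
  t <- seq(t_lo, t_hi, by = 0.2)          # 5 Hz
  nt <- length(t)
  base <- .OPERATOR_BASE
  pos <- matrix(base, nt, 3, byrow = TRUE)

  if (profile$operator_script == "moves_away_once") {
    acq <- events[events$event_type == "acquisition", ]
    if (nrow(acq)) {
      ev <- acq[which.max(acq$duration), ]
      rel <- (t - ev$t_start) / ev$duration
      inwin <- rel >= 0 & rel <= 1
      pos[inwin, 1] <- base[1] - 0.8 * pmin(rel[inwin] * 1.4, 1)
      after <- rel > 1 & rel < 3
      pos[after, 1] <- base[1] - 0.8 * pmax(1 - (rel[after] - 1) / 2, 0)
    }
  } else if (profile$operator_script == "walks_and_leaves") {
    phase <- floor((t - t_lo) / 600) %% 4
    pos[phase == 1, 1] <- base[1] - 0.5
    pos[phase == 1, 2] <- base[2] + 0.8
    pos[phase == 3, 1] <- -2.5
    pos[phase == 3, 2] <- 1.5
  }

  jitter <- matrix(stats::rnorm(nt * 3, 0, 0.03), nt, 3)
  pos <- pos + jitter
  valid <- rep(1L, nt)
  # short dropout gaps (~1 per 100 s, 0.6 s long)
  n_gap <- max(0L, round((t_hi - t_lo) / 100))
  if (n_gap > 0) {
    gs <- sample.int(nt, n_gap)
    for (g in gs) valid[g:min(g + 2, nt)] <- 0L
  }
  if (profile$operator_script == "walks_and_leaves") {
    valid[floor((t - t_lo) / 600) %% 4 == 3] <- 0L  # out of camera view
  }
  position_trace(data.frame(t = t, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                            valid = valid))
}

#' Generate a single movement event with a receding trace
#'
#' One image acquisition during which the operator recedes monotonically
#' from `distance_start` to `distance_end` from the patient, sampled at
#' the frame starts; used to study the movement-correction mechanism.
#'
#' @param distance_start,distance_end operator distance from the
#'   isocenter at the start/end, m.
#' @param duration acquisition duration, s.
#' @param n_frames number of frames.
#' @param t_start event start time, epoch s.
#' @return list with `event` (1-row data.frame), `trace` (an
#'   `irs_trace` sampled at the frame starts).
#' @export
generate_movement_event <- function(distance_start, distance_end,
                                    duration = 7, n_frames = 7,
                                    t_start = 1.7e9) {
  stopifnot(duration > 0, n_frames >= 1)
  event <- irradiation_event("move01", t_start, duration, "acquisition",
                             kvp = 80, filtration_cu = 0.3, field_area = 600,
                             p_ka = 1, k_air_ref = 4)
  ts <- t_start + (seq_len(n_frames) - 1) * duration / n_frames
  dist <- seq(distance_start, distance_end, length.out = n_frames)
  trace <- position_trace(data.frame(
    t = ts, x = -dist, y = .OPERATOR_BASE[2], z = .OPERATOR_BASE[3],
    valid = 1L))
  list(event = event, trace = trace)
}

#' Write a synthetic case to a directory
#'
#' Writes `events.csv`, `trace.csv`, `room.yaml` and `points.csv`.
#'
#' @param case a [generate_case()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(case$log, file.path(dir, "events.csv"), "csv")
  write_trace(case$trace, file.path(dir, "trace.csv"))
  write_room(case$room, file.path(dir, "room.yaml"))
  write_points(case$points, file.path(dir, "points.csv"))
  invisible(dir)
}
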