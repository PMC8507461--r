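# Procedure-level orchestration ----------------------------------------------
#
# Combines the irradiation-event log, the operator position trace and the
# room geometry into per-event and per-procedure Hp(10) at every detector
# point. When a position trace is supplied the detector points are
# interpreted as offsets (m) from the tracked operator reference position,
# so the dosemeter point follows the operator; without a trace the points
# are absolute room coordinates (experimental set-ups).

.fnv32 <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Simulate and normalise a single irradiation event
#'
#' Convenience wrapper: runs the Monte-Carlo simulation of one event and
#' converts/normalises the result at every detector point.
#'
#' @param event 1-row event data.frame.
#' @param room an [room_model()].
#' @param detectors an [detector_points()] data.frame (absolute room
#'   coordinates).
#' @param n_histories photon histories for the event.
#' @param seed integer seed.
#' @param mode normalisation mode, `"pka"` or `"kair"`.
#' @return data.frame with one row per point: `point_id`, `hp10_uSv`,
#'   `u_stat_uSv` (1 sigma), `U_k2_uSv` (expanded).
#' @export
simulate_single_event <- function(event, room, detectors, n_histories = 1e5,
                                  seed = 1L, mode = c("pka", "kair")) {
  mode <- match.arg(mode)
  tally <- run_event_simulation(event, room, detectors, n_histories, seed)
  norm <- if (mode == "pka") tally$simulated_pka else tally$simulated_kair
  out <- lapply(detectors$point_id, function(pid) {
    hp <- fluence_to_hp10(tally, pid)
    d <- normalize_event(hp$hp10_rel, norm, event, mode = mode,
                         u_stat_rel = hp$u_stat_rel)
    data.frame(point_id = pid, hp10_uSv = d$hp10, u_stat_uSv = d$u_stat,
               U_k2_uSv = combine_uncertainty(d))
  })
  do.call(rbind, out)
}

#' Reconstruct operator Hp(10) for a whole procedure
#'
#' For every irradiation event: resolve the operator position from the
#' trace (fixed at the event start, or subdivided into movement frames
#' for the event ids listed in `subdivide`), run the Monte-Carlo
#' simulation with the detector points anchored at that position, convert
#' the fluence spectra to Hp(10) and normalise with the machine-reported
#' output; then aggregate per point over the procedure. Events whose
#' position is unknown contribute no dose and are counted, never
#' silently dropped. Deterministic for a fixed seed and invariant to
#' event order.
#'
#' @param log an `irs_log` from [read_events()].
#' @param trace an `irs_trace` or `NULL` (then `detectors` are absolute).
#' @param room an [room_model()].
#' @param detectors an [detector_points()] data.frame; offsets from the
#'   tracked position when `trace` is given.
#' @param n_histories total photon-history budget for the procedure,
#'   allocated to events proportionally to their kerma-area product.
#' @param min_histories per-event history floor.
#' @param seed integer seed (per-event streams derive from it).
#' @param mode normalisation mode, `"pka"` or `"kair"`.
#' @param clock_offset seconds added to event clocks to reach the trace
#'   clock; defaults to the log's stored offset.
#' @param max_gap maximum position-sample age, s (see [position_at()]).
#' @param subdivide named integer vector `c(event_id = n_frames)` of
#'   events given the movement-corrected treatment.
#' @param chest_height if not `NULL`, replaces the tracked z coordinate
#'   (planar traces) with this dosemeter height, m.
#' @return object of class `irs_report`; see [write_report()].
#' @export
run_procedure <- function(log, trace, room, detectors, n_histories = 1e6,
                          min_histories = 1e4, seed = 1L,
                          mode = c("pka", "kair"),
                          clock_offset = NULL, max_gap = 5,
                          subdivide = NULL, chest_height = NULL) {
  mode <- match.arg(mode)
  events <- as.data.frame(log)
  if (is.null(clock_offset)) clock_offset <- attr(log, "clock_offset") %||% 0
  det <- as.data.frame(detectors)
  npts <- nrow(det)
  measured_col <- if (mode == "pka") "p_ka" else "k_air_ref"

  per_event <- list()
  counts <- c(events_total = nrow(events), simulated = 0L,
              position_unknown = 0L, movement_corrected = 0L,
              zero_output = 0L)
  totals <- stats::setNames(numeric(npts), det$point_id)
  u_stat2 <- stats::setNames(numeric(npts), det$point_id)

  # history allocation proportional to event output
  pka_w <- events$p_ka
  if (nrow(events) && sum(pka_w) <= 0) pka_w <- rep(1, nrow(events))

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    measured <- ev[[measured_col]]
    if (ev$p_ka == 0 && ev$k_air_ref == 0) {
      counts["zero_output"] <- counts["zero_output"] + 1L
      next
    }
    nf <- if (!is.null(subdivide) && ev$event_id %in% names(subdivide)) {
      as.integer(subdivide[[ev$event_id]])
    } else 1L
    if (nf > 1 && !is.null(trace) && ev$duration > 0) {
      sub <- subdivide_event(ev, trace, nf, clock_offset = clock_offset,
                             max_gap = max_gap)
      counts["movement_corrected"] <- counts["movement_corrected"] + 1L
      sub_events <- sub$events; sub_pos <- sub$positions
      moved <- TRUE
    } else {
      sub_events <- ev
      sub_pos <- if (is.null(trace)) matrix(0, 1, 3) else
        matrix(position_at_event_start(trace, ev, clock_offset, max_gap), 1, 3)
      moved <- FALSE
    }
    n_ev <- max(min_histories,
                round(n_histories * pka_w[i] / sum(pka_w)))
    n_sub <- max(100, round(n_ev / nrow(sub_events)))

    for (s in seq_len(nrow(sub_events))) {
      sev <- sub_events[s, ]
      pos <- sub_pos[s, ]
      if (!is.null(trace) && any(!is.finite(pos))) {
        counts["position_unknown"] <- counts["position_unknown"] + 1L
        per_event[[length(per_event) + 1L]] <- data.frame(
          event_id = sev$event_id, point_id = det$point_id,
          hp10_uSv = NA_real_, u_stat_uSv = NA_real_,
          position_unknown = TRUE, movement_corrected = moved)
        next
      }
      if (!is.null(trace) && !is.null(chest_height)) pos[3] <- chest_height
      pts <- det
      if (!is.null(trace)) {
        pts$x <- det$x + pos[1]; pts$y <- det$y + pos[2]; pts$z <- det$z + pos[3]
      }
      tally <- run_event_simulation(sev, room, detector_points(pts),
                                    n_sub, seed)
      norm <- if (mode == "pka") tally$simulated_pka else tally$simulated_kair
      counts["simulated"] <- counts["simulated"] + 1L
      hp <- vapply(det$point_id, function(pid) {
        unlist(fluence_to_hp10(tally, pid))
      }, numeric(2))
      d_abs <- measured_sub <- if (mode == "pka") sev$p_ka else sev$k_air_ref
      scale <- measured_sub / norm * 1e-6
      hp_abs <- hp[1, ] * scale
      u_abs <- hp[2, ] * scale
      totals <- totals + hp_abs
      u_stat2 <- u_stat2 + u_abs^2
      per_event[[length(per_event) + 1L]] <- data.frame(
        event_id = sev$event_id, point_id = det$point_id,
        hp10_uSv = as.numeric(hp_abs), u_stat_uSv = as.numeric(u_abs),
        position_unknown = FALSE, movement_corrected = moved)
    }
  }

  per_event_df <- if (length(per_event)) do.call(rbind, per_event) else
    data.frame(event_id = character(0), point_id = character(0),
               hp10_uSv = numeric(0), u_stat_uSv = numeric(0),
               position_unknown = logical(0), movement_corrected = logical(0))
  rownames(per_event_df) <- NULL

  # expanded per-point uncertainty: MC statistics + correlated 10% (k=2)
  # normalisation term
  U_point <- 2 * sqrt(u_stat2 + (U_NORM_REL_DEFAULT / 2 * totals)^2)
  mean_hp <- if (npts) mean(totals) else 0
  u_mean <- if (npts) sqrt(sum(U_point^2)) / npts else 0

  per_point <- data.frame(point_id = det$point_id, label = det$label,
                          hp10_uSv = as.numeric(totals),
                          U_k2_uSv = as.numeric(U_point))
  rownames(per_point) <- NULL

  provenance <- list(
    package_version = as.character(utils::packageVersion("irscatter")),
    seed = seed, n_histories = n_histories, min_histories = min_histories,
    mode = mode, clock_offset = clock_offset,
    config_hash = .fnv32(paste(yaml::as.yaml(room[c("d_source_iso",
      "d_iso_detector", "d_iso_reference", "table_aleq_mm")]),
      room$phantom$kind, paste(det$point_id, collapse = ","))),
    tables = c("xs/: bundled attenuation tables",
               "air_muen.txt: air mass energy-absorption",
               "hp10_slab.txt: ICRU-slab Hp(10) conversion"))

  structure(list(schema = "irscatter-report/1",
                 per_point = per_point, per_event = per_event_df,
                 mean_hp10_uSv = mean_hp, u_mean_k2_uSv = u_mean,
                 counts = counts, provenance = provenance),
            class = "irs_report")
}

#' @export
print.irs_report <- function(x, ...) {
  cat("<irs_report>\n")
  print(x$per_point)
  cat(sprintf("mean over points: %.3g +/- %.2g uSv (k=2)\n",
              x$mean_hp10_uSv, x$u_mean_k2_uSv))
  cat(sprintf("events: %d total, %d simulated, %d position-unknown, %d zero-output\n",
              x$counts[["events_total"]], x$counts[["simulated"]],
              x$counts[["position_unknown"]], x$counts[["zero_output"]]))
  invisible(x)
}

#' Write / read a procedure report
#'
#' JSON (schema-versioned, numbers at full precision, round-trippable
#' with `read_report()`) or CSV (one row per point-event pair, one total
#' row per point and one procedure-mean row; provenance as `#` comment
#' lines).
#'
#' @param report an `irs_report`.
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                         na = "null", pretty = TRUE)
  } else {
    pe <- report$per_event
    rows <- data.frame(record = "point_event", point_id = pe$point_id,
                       event_id = pe$event_id, hp10_uSv = pe$hp10_uSv,
                       u_uSv = pe$u_stat_uSv)
    pp <- report$per_point
    rows <- rbind(rows, data.frame(record = "point_total",
                                   point_id = pp$point_id, event_id = "",
                                   hp10_uSv = pp$hp10_uSv, u_uSv = pp$U_k2_uSv))
    rows <- rbind(rows, data.frame(record = "procedure_mean", point_id = "",
                                   event_id = "", hp10_uSv = report$mean_hp10_uSv,
                                   u_uSv = report$u_mean_k2_uSv))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", names(report$provenance), ": ",
                      vapply(report$provenance, function(x)
                        paste(format(x), collapse = "; "), character(1))), con)
    utils::write.table(rows, con, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$counts <- unlist(x$counts)
  structure(x, class = "irs_report")
}
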