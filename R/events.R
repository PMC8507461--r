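# Irradiation-event logs -----------------------------------------------------
#
# One irradiation event is one continuous fluoroscopy run or image
# acquisition with fixed technique parameters, as logged by the machine's
# radiation dose structured report (RDSR). The package carries events as a
# data.frame with one row per event using the documented CSV/JSON dialect
# columns; timestamps are epoch seconds.

EVENT_COLS <- c("event_id", "t_start", "duration", "event_type", "kvp",
                "filtration_cu", "filtration_al", "ang_primary",
                "ang_secondary", "field_area", "p_ka", "k_air_ref",
                "table_height")

EVENT_TYPES <- c("fluoroscopy", "acquisition")

#' Construct one irradiation event
#'
#' @param event_id unique event identifier.
#' @param t_start event start, epoch seconds.
#' @param duration event duration, s (>= 0).
#' @param event_type `"fluoroscopy"` or `"acquisition"`.
#' @param kvp tube voltage, kV, in `[40, 150]`.
#' @param filtration_cu added copper filtration, mm (>= 0).
#' @param filtration_al added aluminium filtration, mm (default 0; the
#'   tube's inherent filtration is a spectrum-model configuration).
#' @param ang_primary primary C-arm angulation, degrees (+RAO / -LAO).
#' @param ang_secondary secondary (cranio-caudal) angulation, degrees.
#' @param field_area collimated field size at the image-receptor plane, cm2.
#' @param p_ka air kerma-area product for the event, Gy cm2.
#' @param k_air_ref air kerma at the interventional reference point, mGy.
#' @param table_height table height, cm (optional, `NA` if unknown).
#' @return 1-row data.frame in the event dialect.
#' @export
irradiation_event <- function(event_id, t_start, duration, event_type, kvp,
                              filtration_cu, filtration_al = 0,
                              ang_primary = 0, ang_secondary = 0,
                              field_area = 100, p_ka = 0, k_air_ref = 0,
                              table_height = NA_real_) {
  ev <- data.frame(event_id = as.character(event_id), t_start = t_start,
                   duration = duration, event_type = event_type, kvp = kvp,
                   filtration_cu = filtration_cu, filtration_al = filtration_al,
                   ang_primary = ang_primary, ang_secondary = ang_secondary,
                   field_area = field_area, p_ka = p_ka,
                   k_air_ref = k_air_ref, table_height = table_height,
                   stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

validate_events <- function(events) {
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    fail <- function(field, why) {
      stop(sprintf("event '%s': field '%s' %s", ev$event_id, field, why),
           call. = FALSE)
    }
    if (is.na(ev$duration) || ev$duration < 0) fail("duration", "must be >= 0")
    if (is.na(ev$kvp) || ev$kvp < 40 || ev$kvp > 150) fail("kvp", "must be in [40, 150]")
    if (is.na(ev$filtration_cu) || ev$filtration_cu < 0) fail("filtration_cu", "must be >= 0")
    if (is.na(ev$field_area) || ev$field_area <= 0) fail("field_area", "must be > 0")
    if (is.na(ev$p_ka) || ev$p_ka < 0) fail("p_ka", "must be >= 0")
    if (is.na(ev$k_air_ref) || ev$k_air_ref < 0) fail("k_air_ref", "must be >= 0")
    if (!ev$event_type %in% EVENT_TYPES) {
      fail("event_type", sprintf("must be one of %s", paste(EVENT_TYPES, collapse = ", ")))
    }
  }
  invisible(events)
}

#' Procedure log of irradiation events
#'
#' Orders events by start time (ties broken by `event_id`), validates
#' every event and attaches the source format and clock offset.
#'
#' @param events data.frame of events (see [irradiation_event()]).
#' @param source_format `"csv"`, `"json"` or `"rdsr_dicom"`.
#' @param clock_offset seconds added to event timestamps to align them
#'   with the position-trace clock (user supplied; no automatic sync).
#' @return object of class `irs_log` (a data.frame).
#' @export
procedure_log <- function(events, source_format = "csv", clock_offset = 0) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    missing_cols <- setdiff(c("event_id", "t_start", "duration", "event_type",
                              "kvp", "filtration_cu", "field_area", "p_ka",
                              "k_air_ref"), names(events))
    if (length(missing_cols)) {
      stop("missing mandatory event fields: ", paste(missing_cols, collapse = ", "))
    }
    if (is.null(events$filtration_al)) events$filtration_al <- 0
    if (is.null(events$ang_primary)) events$ang_primary <- 0
    if (is.null(events$ang_secondary)) events$ang_secondary <- 0
    if (is.null(events$table_height)) events$table_height <- NA_real_
    events$event_id <- as.character(events$event_id)
    for (col in setdiff(EVENT_COLS, c("event_id", "event_type"))) {
      events[[col]] <- as.numeric(events[[col]])
    }
    events$ang_secondary[is.na(events$ang_secondary)] <- 0
    events$filtration_al[is.na(events$filtration_al)] <- 0
    if (anyDuplicated(events$event_id)) {
      stop("event_ids must be unique (duplicated: ",
           paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", "), ")")
    }
    events <- events[order(events$t_start, events$event_id), EVENT_COLS]
    rownames(events) <- NULL
    validate_events(events)
  } else {
    events <- stats::setNames(
      as.data.frame(lapply(EVENT_COLS, function(x) numeric(0))), EVENT_COLS)
    events$event_id <- character(0)
    events$event_type <- character(0)
  }
  structure(events, class = c("irs_log", "data.frame"),
            source_format = source_format, clock_offset = clock_offset)
}

#' Read an irradiation-event log
#'
#' Reads the package's CSV or JSON event dialect into a validated
#' [procedure_log()]. The CSV dialect has the header
#' `event_id,t_start,duration,event_type,kvp,filtration_cu,filtration_al,`
#' `ang_primary,ang_secondary,field_area,p_ka,k_air_ref,table_height`
#' (UTF-8, dot decimal separator); the JSON dialect is an array of event
#' objects with the same keys. Units are fixed at the boundary: Gy cm2
#' for the kerma-area product, mGy for the reference-point air kerma
#' (convert vendor dGy cm2 exports before ingestion). Binary DICOM RDSR
#' ingestion is not provided; export the irradiation events of the RDSR
#' to this dialect upstream.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"json"` (`"rdsr_dicom"` is recognised but
#'   unsupported and raises an error pointing at the text dialects).
#' @param clock_offset seconds, stored on the log.
#' @return an `irs_log`.
#' @export
read_events <- function(path, dialect = c("csv", "json", "rdsr_dicom"),
                        clock_offset = 0) {
  dialect <- match.arg(dialect)
  if (dialect == "rdsr_dicom") {
    stop("binary DICOM RDSR reading is not supported; export the ",
         "irradiation events to the documented CSV/JSON dialect upstream")
  }
  if (!file.exists(path)) stop("cannot read event log: ", path)
  events <- if (dialect == "csv") {
    out <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) stop("malformed CSV event log: ",
                                             conditionMessage(e), call. = FALSE))
    out
  } else {
    out <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) stop("malformed JSON event log: ",
                                             conditionMessage(e), call. = FALSE))
    if (length(out) == 0) out <- data.frame()
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  procedure_log(events, source_format = dialect, clock_offset = clock_offset)
}

#' Write an irradiation-event log
#'
#' Writes the CSV or JSON event dialect such that
#' `read_events(write_events(log))` reproduces the log field-for-field.
#'
#' @param log an `irs_log`.
#' @param path output file.
#' @param dialect `"csv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_events <- function(log, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(log)
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, digits = NA, na = "null")
  }
  invisible(path)
}

#' Summarise a procedure log
#'
#' Per-procedure ranges of technique factors, totals of the output
#' quantities and counts by event type.
#'
#' @param log an `irs_log`.
#' @return list with `n_events`, `counts` (by event type), `ranges`
#'   (min/max of kvp, filtration_cu, field_area, angulation), `total_pka`
#'   (Gy cm2), `total_kair` (mGy) and `duration_s` (span of the log).
#' @export
summarize_events <- function(log) {
  df <- as.data.frame(log)
  if (!nrow(df)) {
    return(list(n_events = 0L, counts = c(fluoroscopy = 0L, acquisition = 0L),
                ranges = NULL, total_pka = 0, total_kair = 0, duration_s = 0))
  }
  rng <- function(x) c(min = min(x), max = max(x))
  list(n_events = nrow(df),
       counts = c(fluoroscopy = sum(df$event_type == "fluoroscopy"),
                  acquisition = sum(df$event_type == "acquisition")),
       ranges = list(kvp = rng(df$kvp), filtration_cu = rng(df$filtration_cu),
                     field_area = rng(df$field_area),
                     ang_primary = rng(df$ang_primary)),
       total_pka = sum(df$p_ka), total_kair = sum(df$k_air_ref),
       duration_s = max(df$t_start + df$duration) - min(df$t_start))
}
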