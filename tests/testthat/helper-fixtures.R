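# shared fixtures built in code

fix_event <- function(event_id = "e1", kvp = 80, filtration_cu = 0.3,
                      field_area = 835, p_ka = 4.1, k_air_ref = 17.6,
                      ang_primary = 0, t_start = 0, duration = 10,
                      event_type = "fluoroscopy") {
  irradiation_event(event_id, t_start, duration, event_type, kvp = kvp,
                    filtration_cu = filtration_cu, ang_primary = ang_primary,
                    field_area = field_area, p_ka = p_ka,
                    k_air_ref = k_air_ref)
}

fix_room <- function(...) room_model(phantom = bomab_phantom(), ...)

fix_chest_point <- function(x = -0.7, y = 0, z = 0.3) {
  detector_points(data.frame(point_id = "p1", x = x, y = y, z = z,
                             label = "operator chest"))
}

# a small event log data.frame with n events
fix_log_df <- function(n, p_ka = rep(1, n)) {
  data.frame(event_id = sprintf("ev%02d", seq_len(n)),
             t_start = seq_len(n) * 30, duration = 10,
             event_type = "fluoroscopy", kvp = 80, filtration_cu = 0.3,
             filtration_al = 0, ang_primary = 0, ang_secondary = 0,
             field_area = 600, p_ka = p_ka, k_air_ref = p_ka * 4,
             table_height = NA_real_)
}

# monoenergetic single-bin spectrum at `energy` keV (1 keV bins, 10-150)
mono_spectrum <- function(energy) {
  edges <- seq(10, 150, 1)
  w <- numeric(length(edges) - 1)
  w[findInterval(energy, edges)] <- 1
  spectrum(edges, w, kvp = energy + 0.5)
}
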