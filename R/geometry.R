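# Room / C-arm / phantom geometry -------------------------------------------
#
# Room frame: right-handed, origin at the isocenter, x = patient left,
# y = patient cranial, z = up, all coordinates in meters. Phantom segment
# dimensions are supplied in cm (the usual phantom convention) and stored
# in meters. Path lengths are reported in cm because attenuation
# coefficients are 1/cm.

unit3 <- function(v) v / sqrt(sum(v^2))

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
}

#' Patient phantoms
#'
#' `bomab_phantom()` builds the standard adult BOMAB-type segment set
#' (head ellipsoid; neck, chest, gut and pelvis elliptical cylinders; two
#' arms, two thighs and two calves as circular cylinders), soft-tissue
#' material, lying supine along +y (cranial) with the abdomen at the
#' isocenter. `prism_phantom()` builds a simple soft-tissue box.
#'
#' @param scaling per-axis scale factors `c(x, y, z)` (width, length,
#'   thickness) applied to every segment.
#' @param dims_cm prism dimensions `c(x, y, z)` in cm.
#' @param center_cm position of the phantom (prism) center, cm.
#' @param material phantom material (default `"soft_tissue"`; `"water"`
#'   for benchmark slabs).
#' @return object of class `irs_phantom`.
#' @export
bomab_phantom <- function(scaling = c(1, 1, 1), material = "soft_tissue") {
  ecyl <- function(cx, cy, a, b, len) {
    list(kind = "ecyl", center = c(cx, cy, 0) / 100,
         a = a / 100, b = b / 100, half = len / 200)
  }
  segs <- list(
    pelvis = ecyl(0, -20, 17, 10, 20),
    gut    = ecyl(0,   0, 17, 10, 20),
    chest  = ecyl(0,  30, 15, 10, 40),
    neck   = ecyl(0,  55, 6.5, 6.5, 10),
    head   = list(kind = "ellipsoid", center = c(0, 70, 0) / 100,
                  semi = c(8, 10, 7) / 100),
    arm_l  = ecyl( 21, 25, 5, 5, 60),
    arm_r  = ecyl(-21, 25, 5, 5, 60),
    thigh_l = ecyl( 8.5, -50, 7.5, 7.5, 40),
    thigh_r = ecyl(-8.5, -50, 7.5, 7.5, 40),
    calf_l  = ecyl( 8.5, -90, 6, 6, 40),
    calf_r  = ecyl(-8.5, -90, 6, 6, 40))
  sc <- scaling
  segs <- lapply(segs, function(s) {
    s$center <- s$center * sc
    if (s$kind == "ellipsoid") s$semi <- s$semi * sc
    else { s$a <- s$a * sc[1]; s$b <- s$b * sc[3]; s$half <- s$half * sc[2] }
    s
  })
  structure(list(kind = "bomab", segments = segs,
                 material = match.arg(material, MATERIALS),
                 scaling = sc), class = "irs_phantom")
}

#' @rdname bomab_phantom
#' @export
prism_phantom <- function(dims_cm = c(30, 60, 20), center_cm = c(0, 0, 0),
                          material = "soft_tissue") {
  stopifnot(all(dims_cm > 0))
  segs <- list(body = list(kind = "box", center = center_cm / 100,
                           half3 = dims_cm / 200))
  structure(list(kind = "prism", segments = segs,
                 material = match.arg(material, MATERIALS),
                 scaling = c(1, 1, 1)), class = "irs_phantom")
}

# analytic total volume, m^3
phantom_volume <- function(phantom) {
  sum(vapply(phantom$segments, function(s) {
    switch(s$kind,
           ecyl = pi * s$a * s$b * 2 * s$half,
           ellipsoid = 4 / 3 * pi * prod(s$semi),
           box = prod(2 * s$half3))
  }, numeric(1)))
}

#' Ceiling-suspended protective shield
#'
#' A rectangular lead-equivalent shield, described by its center, two
#' orthogonal in-plane unit axes and its width/height along them.
#'
#' @param center shield center, m, room frame.
#' @param u,v orthogonal in-plane axis vectors (normalised internally).
#' @param width,height extent along `u` / `v`, m.
#' @param pb_mm lead equivalence, mm Pb (>= 0).
#' @return object of class `irs_shield`.
#' @export
shield_model <- function(center, u, v, width, height, pb_mm) {
  u <- unit3(u); v <- unit3(v)
  if (abs(sum(u * v)) > 1e-9) stop("shield axes must be orthogonal")
  if (pb_mm < 0) stop("pb_mm must be >= 0")
  structure(list(center = center, u = u, v = v, normal = crossp(u, v),
                 width = width, height = height, pb_mm = pb_mm),
            class = "irs_shield")
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Room model
#'
#' Geometry of the interventional room: C-arm distances, patient phantom,
#' table and optional ceiling shield. The under-table tube points up
#' through the patient at zero angulation.
#'
#' @param d_source_iso focal spot to isocenter distance, m.
#' @param d_iso_detector isocenter to image receptor distance, m.
#' @param d_iso_reference isocenter to interventional reference point
#'   distance, m, toward the tube (must be `< d_source_iso`).
#' @param phantom an `irs_phantom`, see [bomab_phantom()].
#' @param table_aleq_mm aluminium-equivalent thickness of the patient
#'   table crossed by the primary beam, mm (0 disables it).
#' @param shield optional [shield_model()].
#' @return object of class `irs_room`.
#' @export
room_model <- function(d_source_iso = 0.75, d_iso_detector = 0.35,
                       d_iso_reference = 0.15, phantom = bomab_phantom(),
                       table_aleq_mm = 1.5, shield = NULL) {
  if (d_source_iso <= 0 || d_iso_detector <= 0) stop("C-arm distances must be > 0")
  if (d_iso_reference <= 0 || d_iso_reference >= d_source_iso) {
    stop("d_iso_reference must lie in (0, d_source_iso)")
  }
  if (!is.null(shield) && !inherits(shield, "irs_shield")) {
    stop("shield must be a shield_model() or NULL")
  }
  structure(list(isocenter = c(0, 0, 0), d_source_iso = d_source_iso,
                 d_iso_detector = d_iso_detector,
                 d_iso_reference = d_iso_reference, phantom = phantom,
                 table_aleq_mm = table_aleq_mm, shield = shield),
            class = "irs_room")
}

#' C-arm focal spot position for an angulation
#'
#' The under-table tube is rotated about the isocenter: the primary
#' angulation rotates about the patient longitudinal axis (y; +RAO swings
#' the tube toward the patient's left, the image receptor toward the
#' patient's right), the secondary (cranio-caudal) about the lateral
#' axis (x).
#'
#' @param room an [room_model()].
#' @param ang_primary,ang_secondary angulation, degrees, `|ang| <= 120`.
#' @return focal spot position, length-3 numeric, m.
#' @export
source_position <- function(room, ang_primary, ang_secondary = 0) {
  if (abs(ang_primary) > 120 || abs(ang_secondary) > 120) {
    stop("angulation must satisfy |ang| <= 120 degrees")
  }
  R <- rot_y(ang_primary * pi / 180) %*% rot_x(ang_secondary * pi / 180)
  as.numeric(room$isocenter + R %*% c(0, 0, -room$d_source_iso))
}

#' Beam geometry for an irradiation event
#'
#' Square-aperture beam from the focal spot through the isocenter whose
#' projected area at the image-receptor plane equals the event's logged
#' field size.
#'
#' @param room an [room_model()].
#' @param event one irradiation event (1-row data.frame or list with
#'   `ang_primary`, `ang_secondary`, `field_area`).
#' @return list with `apex`, `axis`, in-plane unit vectors `e1`, `e2`,
#'   `d_sd` (focal spot to receptor distance, m), `half_side` (m, at the
#'   receptor plane) and `half_angle` (radians).
#' @export
beam_cone <- function(room, event) {
  if (event$field_area <= 0) stop("field_area must be > 0")
  apex <- source_position(room, event$ang_primary, event$ang_secondary)
  axis <- unit3(room$isocenter - apex)
  d_sd <- room$d_source_iso + room$d_iso_detector
  half_side <- sqrt(event$field_area) / 100 / 2
  half_angle <- atan(half_side / d_sd)
  if (half_angle >= pi / 2) stop("beam aperture exceeds 90 degree half-angle")
  e1 <- if (abs(axis[2]) < 0.999) unit3(crossp(axis, c(0, 1, 0))) else c(1, 0, 0)
  e2 <- crossp(axis, e1)
  list(apex = apex, axis = axis, e1 = e1, e2 = e2, d_sd = d_sd,
       half_side = half_side, half_angle = half_angle)
}

# --- ray / segment intersections (vectorised over n rays) -------------------

as_mat3 <- function(x, n) {
  if (is.matrix(x)) x else matrix(x, n, 3, byrow = TRUE)
}

# each returns list(tin, tout) length-n vectors, NA on miss
.iv_ecyl <- function(s, o, d) {
  ox <- o[, 1] - s$center[1]; oz <- o[, 3] - s$center[3]
  A <- (d[, 1] / s$a)^2 + (d[, 3] / s$b)^2
  B <- 2 * (ox * d[, 1] / s$a^2 + oz * d[, 3] / s$b^2)
  C <- (ox / s$a)^2 + (oz / s$b)^2 - 1
  t1 <- rep(NA_real_, nrow(o)); t2 <- t1
  par <- A < 1e-14
  disc <- B^2 - 4 * A * C
  hit <- !par & disc >= 0
  sq <- sqrt(pmax(disc[hit], 0))
  t1[hit] <- (-B[hit] - sq) / (2 * A[hit])
  t2[hit] <- (-B[hit] + sq) / (2 * A[hit])
  inside_par <- par & C < 0
  t1[inside_par] <- -Inf; t2[inside_par] <- Inf
  # clip to the segment's y extent
  oy <- o[, 2] - s$center[2]; dy <- d[, 2]
  ylo <- -s$half; yhi <- s$half
  ta <- ifelse(abs(dy) > 1e-14, (ylo - oy) / dy, ifelse(oy >= ylo & oy <= yhi, -Inf, NA))
  tb <- ifelse(abs(dy) > 1e-14, (yhi - oy) / dy, ifelse(oy >= ylo & oy <= yhi, Inf, NA))
  ylo_t <- pmin(ta, tb); yhi_t <- pmax(ta, tb)
  tin <- pmax(t1, ylo_t); tout <- pmin(t2, yhi_t)
  bad <- is.na(tin) | is.na(tout) | tin >= tout
  tin[bad] <- NA; tout[bad] <- NA
  list(tin = tin, tout = tout)
}

.iv_ellipsoid <- function(s, o, d) {
  os <- sweep(o, 2, s$center)
  os <- sweep(os, 2, s$semi, "/")
  ds <- sweep(d, 2, s$semi, "/")
  A <- rowSums(ds^2); B <- 2 * rowSums(os * ds); C <- rowSums(os^2) - 1
  disc <- B^2 - 4 * A * C
  t1 <- rep(NA_real_, nrow(o)); t2 <- t1
  hit <- disc >= 0
  sq <- sqrt(pmax(disc[hit], 0))
  t1[hit] <- (-B[hit] - sq) / (2 * A[hit])
  t2[hit] <- (-B[hit] + sq) / (2 * A[hit])
  list(tin = t1, tout = t2)
}

.iv_box <- function(s, o, d) {
  tin <- rep(-Inf, nrow(o)); tout <- rep(Inf, nrow(o))
  ok <- rep(TRUE, nrow(o))
  for (ax in 1:3) {
    oa <- o[, ax] - s$center[ax]; da <- d[, ax]; h <- s$half3[ax]
    par <- abs(da) < 1e-14
    ta <- (-h - oa) / da; tb <- (h - oa) / da
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    tin <- ifelse(par, tin, pmax(tin, lo))
    tout <- ifelse(par, tout, pmin(tout, hi))
    ok <- ok & (!par | abs(oa) <= h)
  }
  bad <- !ok | tin >= tout
  tin[bad] <- NA; tout[bad] <- NA
  list(tin = tin, tout = tout)
}

# n x nseg interval matrices for all segments
phantom_intervals <- function(phantom, o, d) {
  n <- nrow(o)
  k <- length(phantom$segments)
  tin <- matrix(NA_real_, n, k); tout <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    s <- phantom$segments[[j]]
    iv <- switch(s$kind, ecyl = .iv_ecyl(s, o, d),
                 ellipsoid = .iv_ellipsoid(s, o, d), box = .iv_box(s, o, d))
    tin[, j] <- iv$tin; tout[, j] <- iv$tout
  }
  list(tin = tin, tout = tout)
}

#' Total in-phantom chord length along a ray
#'
#' Sum of entry-exit chord lengths across all phantom segments along the
#' ray from `origin` in `direction`, optionally truncated at parameter
#' `t_max` (m). Returns 0 when the ray misses the phantom.
#'
#' @param phantom an `irs_phantom`.
#' @param origin ray origin(s), length-3 vector or n x 3 matrix, m.
#' @param direction unit direction(s), same shape as `origin`.
#' @param t_max optional truncation distance, m (e.g. distance to a
#'   detector point).
#' @return chord length(s) in cm, numeric vector.
#' @export
path_length <- function(phantom, origin, direction, t_max = Inf) {
  n <- if (is.matrix(origin)) nrow(origin) else if (is.matrix(direction)) nrow(direction) else 1L
  o <- as_mat3(origin, n); d <- as_mat3(direction, n)
  iv <- phantom_intervals(phantom, o, d)
  lo <- pmax(iv$tin, 0); hi <- pmin(iv$tout, t_max)
  len <- pmax(hi - lo, 0)
  len[is.na(len)] <- 0
  rowSums(len) * 100
}

#' Shield transmission factor along a segment
#'
#' Transmission through the ceiling shield for a photon travelling from
#' `origin` to `target`: `exp(-mu_Pb(E) * t)` if the segment crosses the
#' shield rectangle, else 1.
#'
#' @param shield an [shield_model()] or `NULL` (always 1).
#' @param energy photon energy, keV (scalar or length-n).
#' @param origin,target segment endpoints, length-3 vectors or n x 3
#'   matrices, m.
#' @return transmission factor(s) in `[0, 1]`.
#' @export
shield_transmission <- function(shield, energy, origin, target) {
  n <- max(if (is.matrix(origin)) nrow(origin) else 1L,
           if (is.matrix(target)) nrow(target) else 1L, length(energy))
  if (is.null(shield)) return(rep(1, n))
  o <- as_mat3(origin, n); p <- as_mat3(target, n)
  d <- p - o
  nv <- shield$normal
  denom <- d %*% nv
  tnum <- sweep(-o, 2, shield$center, "+") %*% nv
  t <- ifelse(abs(denom) > 1e-14, tnum / denom, NA)
  hitpt <- o + d * as.numeric(t)
  rel <- sweep(hitpt, 2, shield$center)
  uu <- rel %*% shield$u; vv <- rel %*% shield$v
  crosses <- !is.na(t) & t > 0 & t < 1 &
    abs(uu) <= shield$width / 2 & abs(vv) <= shield$height / 2
  tr <- rep(1, n)
  if (any(crosses) && shield$pb_mm > 0) {
    e <- if (length(energy) == 1) rep(energy, n) else energy
    tr[crosses] <- exp(-mu_total("lead", e[crosses]) * shield$pb_mm / 10)
  }
  tr
}

# --- room config & detector point I/O ---------------------------------------

#' Detector points
#'
#' Points of interest at which scattered fluence and Hp(10) are scored,
#' e.g. the operator's chest dosemeter position. `read_points()` reads the
#' CSV dialect `point_id,x,y,z,label` (m, room frame).
#'
#' @param df data.frame with columns `point_id`, `x`, `y`, `z` and
#'   optionally `label`.
#' @param path CSV file path.
#' @return data.frame of class `irs_points`.
#' @export
detector_points <- function(df) {
  need <- c("point_id", "x", "y", "z")
  if (!all(need %in% names(df))) stop("points need columns point_id,x,y,z")
  if (anyDuplicated(df$point_id)) stop("point_id values must be unique")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("point coordinates must be finite")
  }
  df$point_id <- as.character(df$point_id)
  if (is.null(df$label)) df$label <- ""
  class(df) <- c("irs_points", "data.frame")
  df
}

#' @rdname detector_points
#' @export
read_points <- function(path) {
  detector_points(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname detector_points
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a room configuration file
#'
#' YAML room description: C-arm distances, phantom kind/scaling/dims,
#' table aluminium equivalence and optional shield block (`center`, `u`,
#' `v`, `width`, `height`, `pb_mm`).
#'
#' @param path YAML file.
#' @param room an [room_model()].
#' @return `read_room()`: an `irs_room`; `write_room()`: the path.
#' @export
read_room <- function(path) {
  cfg <- yaml::read_yaml(path)
  phantom <- if (identical(cfg$phantom$kind, "prism")) {
    prism_phantom(dims_cm = as.numeric(cfg$phantom$dims_cm),
                  center_cm = as.numeric(cfg$phantom$center_cm %||% c(0, 0, 0)))
  } else {
    bomab_phantom(scaling = as.numeric(cfg$phantom$scaling %||% c(1, 1, 1)))
  }
  sh <- NULL
  if (!is.null(cfg$shield)) {
    sh <- shield_model(center = as.numeric(cfg$shield$center),
                       u = as.numeric(cfg$shield$u), v = as.numeric(cfg$shield$v),
                       width = cfg$shield$width, height = cfg$shield$height,
                       pb_mm = cfg$shield$pb_mm)
  }
  room_model(d_source_iso = cfg$d_source_iso %||% 0.75,
             d_iso_detector = cfg$d_iso_detector %||% 0.35,
             d_iso_reference = cfg$d_iso_reference %||% 0.15,
             phantom = phantom, table_aleq_mm = cfg$table_aleq_mm %||% 1.5,
             shield = sh)
}

#' @rdname read_room
#' @export
write_room <- function(room, path) {
  ph <- room$phantom
  cfg <- list(d_source_iso = room$d_source_iso,
              d_iso_detector = room$d_iso_detector,
              d_iso_reference = room$d_iso_reference,
              table_aleq_mm = room$table_aleq_mm,
              phantom = if (ph$kind == "prism") {
                list(kind = "prism",
                     dims_cm = as.numeric(ph$segments[[1]]$half3 * 200),
                     center_cm = as.numeric(ph$segments[[1]]$center * 100))
              } else {
                list(kind = "bomab", scaling = as.numeric(ph$scaling))
              })
  if (!is.null(room$shield)) {
    s <- room$shield
    cfg$shield <- list(center = as.numeric(s$center), u = as.numeric(s$u),
                       v = as.numeric(s$v), width = s$width,
                       height = s$height, pb_mm = s$pb_mm)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
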