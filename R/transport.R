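# Monte-Carlo photon transport with next-event estimation ---------------------
#
# Photons are sampled from the event's tube spectrum within the collimated
# beam, attenuated through the table, transported analog through the
# patient phantom (photoelectric absorption, free-electron Klein-Nishina
# Compton scattering, Thomson-shaped coherent scattering) and, at every
# interaction, a next-event (point-detector) estimate of the scattered
# fluence is scored at each point of interest: the probability density of
# scattering toward the point per steradian, attenuated along the exit
# path through phantom and shield, divided by the squared distance.
# Histories are run in batches; the batch spread provides the statistical
# uncertainty of every tallied quantity. The operator body itself is not
# modelled: Hp(10) is later derived from the point fluence spectrum via
# ICRU-slab conversion coefficients.

TALLY_EDGES <- seq(10, 150, by = 1)
N_BINS <- length(TALLY_EDGES) - 1L
ENERGY_CUT <- 10        # keV, photons below are absorbed on the spot
RR_THRESHOLD <- 1e-3    # Russian-roulette weight threshold
RR_SURVIVAL <- 10       # weight multiplier on survival

tally_bin <- function(energy) {
  pmin(pmax(floor(energy - TALLY_EDGES[1]) + 1L, 1L), N_BINS)
}

# deterministic per-event RNG seed below 2^31
event_seed <- function(seed, event_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(event_id))) h <- (h * 31 + ch) %% 2147480017
  as.integer((seed %% 2147483647) * 7919 + h) %% 2147483587L
}

#' Klein-Nishina cross-sections
#'
#' `klein_nishina_total()` is the total free-electron Compton
#' cross-section per electron (cm2); `klein_nishina_dcs()` the
#' differential cross-section per steradian at scattering angle
#' `cos_theta` (cm2/sr). Both are exact closed forms.
#'
#' @param energy photon energy, keV.
#' @param cos_theta cosine of the scattering angle.
#' @return numeric vector.
#' @export
klein_nishina_total <- function(energy) {
  re2 <- (2.8179403262e-13)^2
  eps <- energy / 511.0
  2 * pi * re2 * ((1 + eps) / eps^2 *
                    (2 * (1 + eps) / (1 + 2 * eps) - log(1 + 2 * eps) / eps) +
                    log(1 + 2 * eps) / (2 * eps) - (1 + 3 * eps) / (1 + 2 * eps)^2)
}

#' @rdname klein_nishina_total
#' @export
klein_nishina_dcs <- function(energy, cos_theta) {
  re2 <- (2.8179403262e-13)^2
  k <- energy / 511.0
  eps <- 1 / (1 + k * (1 - cos_theta))      # E'/E
  re2 / 2 * eps^2 * (eps + 1 / eps - (1 - cos_theta^2))
}

#' Sample the interaction type at an energy
#'
#' Draws photoelectric / compton / rayleigh with probabilities
#' proportional to the partial attenuation coefficients of the material
#' at each energy, using the current RNG state.
#'
#' @param energy photon energies, keV (vectorised).
#' @param material material name, see [xs_table()].
#' @return character vector of interaction types.
#' @export
sample_interaction <- function(energy, material) {
  mp <- mu_partial(material, energy)
  u <- stats::runif(length(energy)) * mp$total
  ifelse(u < mp$pe, "photoelectric",
         ifelse(u < mp$pe + mp$compton, "compton", "rayleigh"))
}

#' Sample a Compton scatter
#'
#' Samples scattered energy and polar angle from the free-electron
#' Klein-Nishina differential cross-section (composition-rejection
#' sampling); `energy_out` and `cos_theta` are consistent through the
#' Compton relation.
#'
#' @param energy incident photon energies, keV (vectorised).
#' @return list with `energy_out` (keV) and `cos_theta`.
#' @export
sample_compton <- function(energy) {
  n <- length(energy)
  k <- energy / 511.0
  e0 <- 1 / (1 + 2 * k)
  a1 <- -log(e0)
  a2 <- (1 - e0^2) / 2
  eps <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    e0t <- e0[todo]
    epst <- ifelse(u1 < a1[todo] / (a1[todo] + a2[todo]),
                   exp(-u2 * a1[todo]),
                   sqrt(e0t^2 + (1 - e0t^2) * u2))
    tt <- (1 - epst) / (k[todo] * epst)
    g <- 1 - epst * tt * (2 - tt) / (1 + epst^2)
    acc <- u3 <= g
    eps[todo[acc]] <- epst[acc]
    todo <- todo[!acc]
  }
  list(energy_out = energy * eps, cos_theta = 1 - (1 - eps) / (k * eps))
}

# Thomson-shaped coherent scattering angle: pdf 3/8 (1 + mu^2)
sample_rayleigh_cos <- function(n) {
  mu <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    cand <- stats::runif(m, -1, 1)
    acc <- stats::runif(m) <= (1 + cand^2) / 2
    mu[todo[acc]] <- cand[acc]
    todo <- todo[!acc]
  }
  mu
}

# rotate unit rows of d by polar angle (cost) and azimuth phi
rotate_dirs <- function(d, cost, phi) {
  sint <- sqrt(pmax(1 - cost^2, 0))
  hx <- ifelse(abs(d[, 3]) < 0.99, 0, 1)
  hz <- 1 - hx
  # u = normalize(d x h), h = (hx, 0, hz)
  ux <- d[, 2] * hz
  uy <- d[, 3] * hx - d[, 1] * hz
  uz <- -d[, 2] * hx
  un <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / un; uy <- uy / un; uz <- uz / un
  # v = d x u
  vx <- d[, 2] * uz - d[, 3] * uy
  vy <- d[, 3] * ux - d[, 1] * uz
  vz <- d[, 1] * uy - d[, 2] * ux
  cp <- cos(phi); sp <- sin(phi)
  out <- cbind(d[, 1] * cost + (ux * cp + vx * sp) * sint,
               d[, 2] * cost + (uy * cp + vy * sp) * sint,
               d[, 3] * cost + (uz * cp + vz * sp) * sint)
  out / sqrt(rowSums(out^2))
}

point_in_phantom <- function(phantom, p) {
  for (s in phantom$segments) {
    inside <- switch(s$kind,
      ecyl = ((p[1] - s$center[1]) / s$a)^2 + ((p[3] - s$center[3]) / s$b)^2 < 1 &&
        abs(p[2] - s$center[2]) < s$half,
      ellipsoid = sum(((p - s$center) / s$semi)^2) < 1,
      box = all(abs(p - s$center) < s$half3))
    if (inside) return(TRUE)
  }
  FALSE
}

#' Next-event fluence contribution of one interaction
#'
#' Deterministic point-detector estimate: the probability density (per
#' steradian) of scattering from the interaction site toward the detector
#' point, attenuated along the exit path through the phantom and shield,
#' divided by the squared distance (cm2). With `kind = "isotropic"` the
#' angular density is `1/(4 pi)`, which in vacuum reduces to the
#' closed-form point-source fluence `1/(4 pi r^2)`.
#'
#' @param energy photon energy at the interaction, keV.
#' @param position interaction site, length-3 m.
#' @param direction incident flight direction (unit), length-3.
#' @param detector_pos detector point, length-3 m.
#' @param kind `"compton"`, `"rayleigh"` or `"isotropic"`.
#' @param room an [room_model()] or `NULL` for vacuum.
#' @return list with `energy_out` (keV) and `fluence` (per cm2, per
#'   scattering event of that kind).
#' @export
next_event_contribution <- function(energy, position, direction, detector_pos,
                                    kind = c("compton", "rayleigh", "isotropic"),
                                    room = NULL) {
  kind <- match.arg(kind)
  dv <- detector_pos - position
  r_m <- sqrt(sum(dv^2))
  u <- dv / r_m
  ct <- sum(direction * u)
  if (kind == "compton") {
    k <- energy / 511
    e_out <- energy / (1 + k * (1 - ct))
    pdf <- klein_nishina_dcs(energy, ct) / klein_nishina_total(energy)
  } else if (kind == "rayleigh") {
    e_out <- energy
    pdf <- 3 / (16 * pi) * (1 + ct^2)
  } else {
    e_out <- energy
    pdf <- 1 / (4 * pi)
  }
  att <- 1
  if (!is.null(room)) {
    tis <- path_length(room$phantom, position, u, t_max = r_m)
    att <- exp(-mu_total(room$phantom$material, pmax(e_out, ENERGY_CUT)) * tis) *
      shield_transmission(room$shield, e_out, position, detector_pos)
  }
  list(energy_out = e_out, fluence = pdf * att / (r_m * 100)^2)
}

# weighted accumulation of vals into nb bins
.bin_acc <- function(bins, vals, nb) {
  out <- numeric(nb)
  if (length(bins)) {
    rs <- rowsum(vals, bins)
    out[as.integer(rownames(rs))] <- rs
  }
  out
}

# one batch of histories; returns list(tally ndet x nbins, pka, kair)
.transport_batch <- function(n, spec, room, det_mat, cone, max_steps = 80) {
  ndet <- nrow(det_mat)
  phantom <- room$phantom
  mat <- phantom$material
  tal <- matrix(0, ndet, N_BINS)
  if (n == 0) return(list(tally = tal, pka = 0, kair = 0, uncollided = 0))

  E <- sample_spectrum(spec, n)
  # machine output per source photon, upstream of the table
  pka <- sum(air_kerma_per_fluence(E)) / n                      # Gy cm2
  r_ref <- room$d_source_iso - room$d_iso_reference
  side_ref_cm <- 2 * cone$half_side * (r_ref / cone$d_sd) * 100
  kair <- mean(air_kerma_per_fluence(E)) / side_ref_cm^2 * 1e3  # mGy

  # beam directions: uniform over the square aperture at the receptor plane
  u <- stats::runif(n, -cone$half_side, cone$half_side)
  v <- stats::runif(n, -cone$half_side, cone$half_side)
  tgt <- matrix(cone$apex, n, 3, byrow = TRUE) +
    outer(rep(cone$d_sd, n), cone$axis) + outer(u, cone$e1) + outer(v, cone$e2)
  pos <- matrix(cone$apex, n, 3, byrow = TRUE)
  dir <- tgt - pos
  dir <- dir / sqrt(rowSums(dir^2))

  # table: aluminium-equivalent slab crossed by the primary beam only
  w <- if (room$table_aleq_mm > 0) {
    exp(-mu_total("aluminium", E) * room$table_aleq_mm / 10)
  } else rep(1, n)

  # primary fluence at detectors lying inside the beam
  for (d in seq_len(ndet)) {
    dv <- sweep(-pos, 2, det_mat[d, ], "+")[1, ]  # same for all rows
    t_ax <- sum(dv * cone$axis)
    if (t_ax <= 0) next
    uu <- sum(dv * cone$e1); vv <- sum(dv * cone$e2)
    half_here <- cone$half_side * t_ax / cone$d_sd
    if (abs(uu) <= half_here && abs(vv) <= half_here) {
      r2_cm2 <- (2 * half_here * 100)^2  # beam cross-section area, cm2
      dpos <- det_mat[d, ]
      udir <- unit3(dpos - cone$apex)
      tis <- path_length(phantom, cone$apex, udir, t_max = sqrt(sum((dpos - cone$apex)^2)))
      sh <- shield_transmission(room$shield, E, matrix(cone$apex, 1, 3),
                                matrix(dpos, 1, 3))
      contrib <- w * exp(-mu_total(mat, E) * tis) * sh / r2_cm2 / n
      tal[d, ] <- tal[d, ] + .bin_acc(tally_bin(E), contrib, N_BINS)
    }
  }

  alive <- rep(TRUE, n)
  nseg <- length(phantom$segments)
  uncollided <- n   # photons escaping without any interaction
  step <- 0
  while (any(alive) && step < max_steps) {
    step <- step + 1
    idx <- which(alive)
    o <- pos[idx, , drop = FALSE]; dd <- dir[idx, , drop = FALSE]
    Ei <- E[idx]
    iv <- phantom_intervals(phantom, o, dd)
    tin <- iv$tin; tout <- iv$tout
    if (nseg > 1) {
      key <- tin; key[is.na(key)] <- Inf
      ord <- order(row(key), key)
      tin <- matrix(tin[ord], ncol = nseg, byrow = TRUE)
      tout <- matrix(tout[ord], ncol = nseg, byrow = TRUE)
    }
    lo <- pmax(tin, 0)
    len <- pmax(tout - lo, 0); len[is.na(len)] <- 0
    cum <- len
    if (nseg > 1) for (j in 2:nseg) cum[, j] <- cum[, j - 1] + len[, j]
    total_t <- cum[, nseg]

    mu_t <- mu_total(mat, Ei)
    s_m <- stats::rexp(length(idx)) / mu_t / 100
    interacts <- s_m < total_t & total_t > 0
    alive[idx[!interacts]] <- FALSE
    if (step == 1) uncollided <- sum(!interacts)
    if (!any(interacts)) next

    ii <- which(interacts)
    gidx <- idx[ii]
    cum_i <- cum[ii, , drop = FALSE]
    lo_i <- lo[ii, , drop = FALSE]
    si <- s_m[ii]
    j <- rowSums(cum_i < si) + 1L
    cum_prev <- rep(0, length(ii))
    sel <- j > 1
    if (any(sel)) cum_prev[sel] <- cum_i[cbind(which(sel), j[sel] - 1L)]
    t_int <- lo_i[cbind(seq_along(ii), j)] + (si - cum_prev)
    newpos <- o[ii, , drop = FALSE] + dd[ii, , drop = FALSE] * t_int

    Eint <- Ei[ii]
    wi <- w[gidx]
    ddi <- dd[ii, , drop = FALSE]
    mp <- mu_partial(mat, Eint)
    pC <- mp$compton / mp$total
    pR <- mp$rayleigh / mp$total

    # next-event scoring at every detector
    kk <- Eint / 511
    knt <- klein_nishina_total(Eint)
    for (d in seq_len(ndet)) {
      dv <- sweep(-newpos, 2, det_mat[d, ], "+")
      r_m <- sqrt(rowSums(dv^2))
      udet <- dv / r_m
      ct <- rowSums(ddi * udet)
      tis <- path_length(phantom, newpos, udet, t_max = r_m)
      r_cm2 <- (r_m * 100)^2
      # Compton branch
      e_out <- Eint / (1 + kk * (1 - ct))
      okC <- e_out >= ENERGY_CUT
      if (any(okC)) {
        pdfC <- klein_nishina_dcs(Eint[okC], ct[okC]) / knt[okC]
        attC <- exp(-mu_total(mat, e_out[okC]) * tis[okC]) *
          shield_transmission(room$shield, e_out[okC], newpos[okC, , drop = FALSE],
                              matrix(det_mat[d, ], sum(okC), 3, byrow = TRUE))
        fc <- wi[okC] * pC[okC] * pdfC * attC / r_cm2[okC] / n
        tal[d, ] <- tal[d, ] + .bin_acc(tally_bin(e_out[okC]), fc, N_BINS)
      }
      # Rayleigh branch (Thomson-shaped, elastic)
      pdfR <- 3 / (16 * pi) * (1 + ct^2)
      attR <- exp(-mu_total(mat, Eint) * tis) *
        shield_transmission(room$shield, Eint, newpos,
                            matrix(det_mat[d, ], length(ii), 3, byrow = TRUE))
      fr <- wi * pR * pdfR * attR / r_cm2 / n
      tal[d, ] <- tal[d, ] + .bin_acc(tally_bin(Eint), fr, N_BINS)
    }

    # analog branching
    u_br <- stats::runif(length(ii)) * mp$total
    absorbed <- u_br < mp$pe
    compton <- !absorbed & u_br < mp$pe + mp$compton
    cost <- numeric(length(ii))
    Enew <- Eint
    if (any(compton)) {
      sc <- sample_compton(Eint[compton])
      Enew[compton] <- sc$energy_out
      cost[compton] <- sc$cos_theta
    }
    ray <- !absorbed & !compton
    if (any(ray)) cost[ray] <- sample_rayleigh_cos(sum(ray))
    phi <- stats::runif(length(ii), 0, 2 * pi)
    scat <- !absorbed
    newdir <- ddi
    if (any(scat)) {
      newdir[scat, ] <- rotate_dirs(ddi[scat, , drop = FALSE], cost[scat], phi[scat])
    }
    dead <- absorbed | Enew < ENERGY_CUT
    # Russian roulette on low weights (weights stay 1 in analog mode but
    # the guard keeps any biased extension unbiased)
    low <- !dead & wi < RR_THRESHOLD
    if (any(low)) {
      die <- stats::runif(sum(low)) > 1 / RR_SURVIVAL
      wlow <- which(low)
      dead[wlow[die]] <- TRUE
      wi[wlow[!die]] <- wi[wlow[!die]] * RR_SURVIVAL
    }
    alive[gidx[dead]] <- FALSE
    keep <- !dead
    if (any(keep)) {
      gi <- gidx[keep]
      pos[gi, ] <- newpos[keep, , drop = FALSE]
      dir[gi, ] <- newdir[keep, , drop = FALSE]
      E[gi] <- Enew[keep]
      w[gi] <- wi[keep]
    }
  }
  list(tally = tal, pka = pka, kair = kair, uncollided = uncollided)
}

#' Monte-Carlo simulation of one irradiation event
#'
#' Samples source photons from the event's tube spectrum within the
#' collimated beam, transports them through the table and patient phantom
#' and scores the scattered (plus in-beam primary) fluence spectrum at
#' every detector point with next-event estimation, together with the
#' simulated kerma-area product and reference-point air kerma per source
#' photon used for normalisation. Deterministic for a fixed seed: the
#' per-event RNG stream is keyed on `(seed, event_id)`, so event order
#' (or parallel execution over events) never changes results.
#'
#' @param event 1-row event data.frame (see [irradiation_event()]).
#' @param room an [room_model()].
#' @param detectors an [detector_points()] data.frame.
#' @param n_histories number of photon histories (>= 1).
#' @param seed integer seed.
#' @param n_batches number of statistical batches (default 20).
#' @param spec optional [spectrum()] overriding the spectrum generated
#'   from the event's technique factors (e.g. a monoenergetic line for
#'   benchmark runs).
#' @return object of class `irs_tally`: energy-binned fluence per cm2 per
#'   source photon at every point (`fluence`, points x bins), its batch
#'   array, per-bin variance of the mean, `simulated_pka` (Gy cm2 per
#'   photon), `simulated_kair` (mGy per photon), the uncollided primary
#'   fraction `uncollided_frac` and bookkeeping fields.
#' @export
run_event_simulation <- function(event, room, detectors, n_histories,
                                 seed = 1L, n_batches = 20L, spec = NULL) {
  stopifnot(n_histories >= 1)
  if (!nrow(detectors)) stop("detectors must be non-empty")
  det_mat <- as.matrix(as.data.frame(detectors)[, c("x", "y", "z")])
  for (d in seq_len(nrow(det_mat))) {
    if (point_in_phantom(room$phantom, det_mat[d, ])) {
      stop("detector point '", detectors$point_id[d], "' lies inside the phantom")
    }
  }
  if (is.null(spec)) {
    spec <- generate_spectrum(event$kvp, filtration_cu = event$filtration_cu,
                              filtration_al = event$filtration_al %||% 0)
  }
  stopifnot(inherits(spec, "irs_spectrum"))
  cone <- beam_cone(room, event)
  n_batches <- max(2L, min(n_batches, n_histories))
  nb <- diff(round(seq(0, n_histories, length.out = n_batches + 1)))

  old_seed <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(event_seed(seed, event$event_id))

  ndet <- nrow(det_mat)
  batch <- array(0, c(n_batches, ndet, N_BINS))
  pka_b <- numeric(n_batches); kair_b <- numeric(n_batches)
  unc <- 0
  for (b in seq_len(n_batches)) {
    res <- .transport_batch(nb[b], spec, room, det_mat, cone)
    batch[b, , ] <- res$tally
    pka_b[b] <- res$pka; kair_b[b] <- res$kair
    unc <- unc + res$uncollided
  }
  wts <- nb / sum(nb)
  fl <- apply(batch * wts, c(2, 3), sum)
  var_mean <- apply(batch, c(2, 3), stats::var) / n_batches
  structure(list(point_id = detectors$point_id, energy_edges = TALLY_EDGES,
                 fluence = fl, batch = batch, batch_w = wts,
                 var_mean = var_mean,
                 simulated_pka = sum(pka_b * wts),
                 simulated_kair = sum(kair_b * wts),
                 uncollided_frac = unc / sum(nb),
                 u_pka = stats::sd(pka_b) / sqrt(n_batches),
                 n_histories = n_histories, n_batches = n_batches,
                 seed = seed, event_id = event$event_id),
            class = "irs_tally")
}

#' @export
print.irs_tally <- function(x, ...) {
  cat(sprintf("<irs_tally> event '%s': %d points, %g histories (%d batches)\n",
              x$event_id, length(x$point_id), x$n_histories, x$n_batches))
  invisible(x)
}
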