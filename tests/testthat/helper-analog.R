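# Independent analog estimator used as the oracle for the next-event
# point-detector estimator: photons are transported analog through the
# phantom and the fluence at a point is estimated from the track length
# inside a sphere around it (track-length estimator, no deterministic
# scoring). Shares only the sampling/geometry primitives, which have
# their own closed-form oracles.

analog_sphere_fluence <- function(spec, room, center, radius_m, n_histories,
                                  seed, n_batches = 10, max_steps = 60) {
  set.seed(seed)
  phantom <- room$phantom
  mat <- phantom$material
  nb <- diff(round(seq(0, n_histories, length.out = n_batches + 1)))
  vol_cm3 <- 4 / 3 * pi * (radius_m * 100)^3
  batch_fl <- numeric(n_batches)

  for (b in seq_len(n_batches)) {
    n <- nb[b]
    cone <- irscatter:::beam_cone(room, list(ang_primary = 0, ang_secondary = 0,
                                             field_area = 1))
    E <- irscatter:::sample_spectrum(spec, n)
    pos <- matrix(cone$apex, n, 3, byrow = TRUE)
    dir <- matrix(cone$axis, n, 3, byrow = TRUE)
    scattered <- rep(FALSE, n)
    alive <- rep(TRUE, n)
    track_cm <- 0
    step <- 0
    while (any(alive) && step < max_steps) {
      step <- step + 1
      idx <- which(alive)
      o <- pos[idx, , drop = FALSE]; dd <- dir[idx, , drop = FALSE]
      Ei <- E[idx]
      iv <- irscatter:::phantom_intervals(phantom, o, dd)
      nseg <- ncol(iv$tin)
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
      s_m <- stats::rexp(length(idx)) / mu_total(mat, Ei) / 100
      interacts <- s_m < total_t & total_t > 0
      # geometric end of this flight segment (10 m for escapes)
      t_end <- rep(10, length(idx))
      if (any(interacts)) {
        ii <- which(interacts)
        cum_i <- cum[ii, , drop = FALSE]; lo_i <- lo[ii, , drop = FALSE]
        si <- s_m[ii]
        j <- rowSums(cum_i < si) + 1L
        cum_prev <- rep(0, length(ii))
        sel <- j > 1
        if (any(sel)) cum_prev[sel] <- cum_i[cbind(which(sel), j[sel] - 1L)]
        t_end[ii] <- lo_i[cbind(seq_along(ii), j)] + (si - cum_prev)
      }
      # track length inside the sphere, scattered flights only
      sc <- scattered[idx]
      if (any(sc)) {
        os <- o[sc, , drop = FALSE]; ds <- dd[sc, , drop = FALSE]
        cp <- sweep(-os, 2, center, "+")
        q <- rowSums(cp * ds)
        d2 <- rowSums(cp^2) - q^2
        h2 <- radius_m^2 - d2
        hit <- h2 > 0
        if (any(hit)) {
          h <- sqrt(h2[hit])
          a <- pmax(q[hit] - h, 0)
          bnd <- pmin(q[hit] + h, t_end[sc][hit])
          track_cm <- track_cm + sum(pmax(bnd - a, 0)) * 100
        }
      }
      # advance / branch
      alive[idx[!interacts]] <- FALSE
      if (!any(interacts)) next
      gidx <- idx[interacts]
      newpos <- o[interacts, , drop = FALSE] +
        dd[interacts, , drop = FALSE] * t_end[which(interacts)]
      Eint <- E[gidx]
      kind <- sample_interaction(Eint, mat)
      dead <- kind == "photoelectric"
      cost <- numeric(length(gidx))
      Enew <- Eint
      isC <- kind == "compton"
      if (any(isC)) {
        scmp <- sample_compton(Eint[isC])
        Enew[isC] <- scmp$energy_out
        cost[isC] <- scmp$cos_theta
      }
      isR <- kind == "rayleigh"
      if (any(isR)) cost[isR] <- irscatter:::sample_rayleigh_cos(sum(isR))
      phi <- stats::runif(length(gidx), 0, 2 * pi)
      nd <- irscatter:::rotate_dirs(dd[interacts, , drop = FALSE], cost, phi)
      dead <- dead | Enew < 10
      alive[gidx[dead]] <- FALSE
      keep <- !dead
      if (any(keep)) {
        gi <- gidx[keep]
        pos[gi, ] <- newpos[keep, , drop = FALSE]
        dir[gi, ] <- nd[keep, , drop = FALSE]
        E[gi] <- Enew[keep]
        scattered[gi] <- TRUE
      }
    }
    batch_fl[b] <- track_cm / vol_cm3 / n
  }
  list(fluence = mean(batch_fl),
       u = stats::sd(batch_fl) / sqrt(n_batches))
}
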