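# Fluence to Hp(10) conversion and normalisation ------------------------------
#
# The simulated quantity is a relative fluence spectrum per source photon;
# converting with ICRU-slab coefficients gives a relative Hp(10) that is
# scaled to absolute dose with the machine-reported output (kerma-area
# product or reference-point air kerma) of the event. The backscatter of
# the wearer's body is carried implicitly by the slab-phantom definition
# of the conversion coefficients. A 10% (k = 2) uncertainty on the
# output normalisation is attached to every event dose.

U_NORM_REL_DEFAULT <- 0.10  # expanded (k = 2) relative normalisation uncertainty

#' Convert a tallied fluence spectrum to relative Hp(10)
#'
#' Folds the tallied fluence spectrum at one point with the ICRU-slab
#' conversion coefficients: `sum_bins fluence(E) * hp10_per_fluence(E_mid)`.
#' The statistical uncertainty is taken from the batch spread of the
#' folded sum (bins from one history are correlated, so the fold is
#' applied per batch before the variance is formed).
#'
#' @param tally an `irs_tally` from [run_event_simulation()].
#' @param point_id detector point id present in the tally.
#' @return list with `hp10_rel` (pSv per source photon) and `u_stat_rel`
#'   (1 sigma, same unit).
#' @export
fluence_to_hp10 <- function(tally, point_id) {
  d <- match(point_id, tally$point_id)
  if (is.na(d)) stop("unknown detector point: ", point_id)
  mids <- (tally$energy_edges[-1] + tally$energy_edges[-length(tally$energy_edges)]) / 2
  h <- hp10_per_fluence(mids)
  hp <- sum(tally$fluence[d, ] * h)
  per_batch <- as.numeric(tally$batch[, d, ] %*% h)
  u <- stats::sd(per_batch) / sqrt(tally$n_batches)
  list(hp10_rel = hp, u_stat_rel = u)
}

#' Normalise a simulated event dose to absolute Hp(10)
#'
#' Scales the relative per-source-photon Hp(10) with the machine-reported
#' output of the event: `hp10_abs = hp10_rel * p_ka / simulated_pka` in
#' `"pka"` mode (analogous with the reference-point air kerma in
#' `"kair"` mode), and attaches the expanded (k = 2) relative
#' normalisation uncertainty.
#'
#' @param hp10_rel relative Hp(10), pSv per source photon.
#' @param simulated_norm simulated normalisation quantity per source
#'   photon: Gy cm2 (`"pka"` mode) or mGy (`"kair"` mode); must be > 0.
#' @param event 1-row event data.frame.
#' @param mode `"pka"` or `"kair"`.
#' @param u_stat_rel statistical uncertainty of `hp10_rel` (1 sigma, pSv).
#' @param u_norm_rel expanded (k = 2) relative normalisation uncertainty.
#' @param position_used optional length-3 operator position, m.
#' @param movement_corrected logical bookkeeping flag.
#' @return object of class `irs_event_dose`: list with `event_id`,
#'   `hp10` (uSv), `u_stat` (uSv, 1 sigma), `u_norm_rel`,
#'   `position_used`, `movement_corrected`.
#' @export
normalize_event <- function(hp10_rel, simulated_norm, event,
                            mode = c("pka", "kair"), u_stat_rel = 0,
                            u_norm_rel = U_NORM_REL_DEFAULT,
                            position_used = c(NA_real_, NA_real_, NA_real_),
                            movement_corrected = FALSE) {
  mode <- match.arg(mode)
  if (!is.finite(simulated_norm) || simulated_norm <= 0) {
    stop("cannot normalise: simulated ", mode, " per photon is not positive")
  }
  measured <- if (mode == "pka") event$p_ka else event$k_air_ref
  scale <- measured / simulated_norm * 1e-6   # pSv -> uSv
  structure(list(event_id = event$event_id,
                 hp10 = hp10_rel * scale,
                 u_stat = u_stat_rel * scale,
                 u_norm_rel = u_norm_rel,
                 mode = mode,
                 position_used = position_used,
                 movement_corrected = movement_corrected),
            class = "irs_event_dose")
}

#' Expanded uncertainty of an event dose
#'
#' Combines the Monte-Carlo statistical uncertainty with the output
#' normalisation uncertainty in quadrature and expands with coverage
#' factor k = 2: `U = 2 * hp10 * sqrt((u_stat/hp10)^2 + (u_norm_rel/2)^2)`
#' for `hp10 > 0`, and 0 for a zero dose.
#'
#' @param d an `irs_event_dose` from [normalize_event()].
#' @return expanded uncertainty U (k = 2), uSv.
#' @export
combine_uncertainty <- function(d) {
  if (d$hp10 <= 0) return(0)
  2 * d$hp10 * sqrt((d$u_stat / d$hp10)^2 + (d$u_norm_rel / 2)^2)
}
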