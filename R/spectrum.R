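# X-ray tube spectra --------------------------------------------------------

#' Binned photon fluence spectrum
#'
#' Container for a binned photon energy-fluence distribution. Bin edges are
#' uniform and ascending; weights are relative photon fluence per bin.
#'
#' @param energy_edges ascending, uniformly spaced bin edges, keV.
#' @param weights non-negative fluence weights, one per bin.
#' @param kvp tube voltage, kV; every bin whose lower edge is at or above
#'   `kvp` must have zero weight.
#' @return object of class `irs_spectrum`.
#' @export
spectrum <- function(energy_edges, weights, kvp) {
  stopifnot(length(weights) == length(energy_edges) - 1L)
  dw <- diff(energy_edges)
  if (any(dw <= 0) || diff(range(dw)) > 1e-9 * dw[1]) {
    stop("energy_edges must be ascending with uniform bin width")
  }
  if (any(weights < 0)) stop("spectrum weights must be non-negative")
  if (any(weights[energy_edges[-length(energy_edges)] >= kvp] > 0)) {
    stop("bins at or above kvp must have zero weight")
  }
  if (!any(weights > 0)) stop("spectrum must have at least one positive bin")
  structure(list(energy_edges = energy_edges, weights = weights, kvp = kvp),
            class = "irs_spectrum")
}

#' @export
print.irs_spectrum <- function(x, ...) {
  cat(sprintf("<irs_spectrum> %g kVp, %d bins of %g keV, mean energy %.1f keV\n",
              x$kvp, length(x$weights), diff(x$energy_edges[1:2]),
              spectrum_mean_energy(x)))
  invisible(x)
}

bin_mids <- function(s) {
  e <- s$energy_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Generate a tungsten-anode tube spectrum
#'
#' Semi-empirical bremsstrahlung continuum (Kramers-type photon fluence
#' `(kVp - E)/E`) with tungsten K-characteristic lines above the 69.5 keV
#' K edge, hardened by target self-absorption (anode-angle dependent
#' aluminium-equivalent path), the inherent filtration of the tube
#' assembly and the stated added copper/aluminium filtration.
#'
#' @param kvp tube voltage, kV, in `[40, 150]`.
#' @param filtration_cu added copper filtration, mm.
#' @param filtration_al added aluminium filtration beyond the inherent
#'   filtration, mm.
#' @param anode_angle anode angle, degrees; default 12.
#' @param bin_width bin width, keV, in `[0.5, 2]`.
#' @param inherent_al,inherent_cu inherent filtration of the tube
#'   assembly, mm Al / mm Cu equivalent (defaults 2.5 / 0.1).
#' @param normalize if `TRUE`, scale weights to unit total fluence.
#' @return an [spectrum()] object.
#' @export
generate_spectrum <- function(kvp, filtration_cu = 0, filtration_al = 0,
                              anode_angle = 12, bin_width = 1,
                              inherent_al = 2.5, inherent_cu = 0.1,
                              normalize = FALSE) {
  if (kvp < 40 || kvp > 150) stop("kvp must be within [40, 150]")
  if (filtration_cu < 0 || filtration_al < 0) stop("filtration must be >= 0")
  if (bin_width < 0.5 || bin_width > 2) stop("bin_width must be within [0.5, 2]")
  edges <- seq(10, ceiling(kvp / bin_width) * bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- pmax(kvp - mids, 0) / mids
  w[edges[-length(edges)] >= kvp] <- 0

  # tungsten K lines (keV): Kalpha2, Kalpha1, Kbeta1, Kbeta2
  if (kvp > 69.5) {
    lines_e <- c(57.98, 59.32, 67.24, 69.07)
    lines_rel <- c(0.58, 1.0, 0.33, 0.09)
    amp <- 0.35 * sum(w) * ((kvp - 69.5) / kvp)^1.67
    for (i in seq_along(lines_e)) {
      if (lines_e[i] < kvp) {
        j <- findInterval(lines_e[i], edges)
        w[j] <- w[j] + amp * lines_rel[i] / sum(lines_rel)
      }
    }
  }

  # target self-absorption: aluminium-equivalent path scaling with anode angle
  t_anode <- 0.6 * tan(12 * pi / 180) / tan(anode_angle * pi / 180)
  al_mm <- inherent_al + filtration_al + t_anode
  w <- w * exp(-mu_total("aluminium", mids) * al_mm / 10)
  cu_mm <- inherent_cu + filtration_cu
  if (cu_mm > 0) w <- w * exp(-mu_total("copper", mids) * cu_mm / 10)

  if (normalize) w <- w / sum(w)
  spectrum(edges, w, kvp)
}

#' Attenuate a spectrum through a material slab
#'
#' Multiplies each bin weight by `exp(-mu_total(E_mid) * thickness)`.
#'
#' @param s an [spectrum()] object.
#' @param material material name, see [xs_table()].
#' @param thickness slab thickness, cm (>= 0).
#' @return attenuated [spectrum()] object.
#' @export
attenuate <- function(s, material, thickness) {
  stopifnot(inherits(s, "irs_spectrum"))
  if (thickness < 0) stop("thickness must be >= 0")
  if (thickness == 0) return(s)
  mids <- bin_mids(s)
  w <- s$weights * exp(-mu_total(material, mids) * thickness)
  structure(list(energy_edges = s$energy_edges, weights = w, kvp = s$kvp),
            class = "irs_spectrum")
}

#' Spectrum summary quantities
#'
#' `spectrum_mean_energy()` returns the fluence-weighted mean energy (keV);
#' `spectrum_air_kerma()` the air kerma per unit source fluence weight
#' (Gy cm2 units of [air_kerma_per_fluence()]); `first_hvl_al()` the first
#' half-value layer in mm Al, found by bisection on the air-kerma
#' transmission through aluminium.
#'
#' @param s an [spectrum()] object.
#' @return numeric scalar.
#' @export
spectrum_mean_energy <- function(s) {
  sum(bin_mids(s) * s$weights) / sum(s$weights)
}

#' @rdname spectrum_mean_energy
#' @export
spectrum_air_kerma <- function(s) {
  sum(s$weights * air_kerma_per_fluence(bin_mids(s)))
}

#' @rdname spectrum_mean_energy
#' @export
first_hvl_al <- function(s) {
  k0 <- spectrum_air_kerma(s)
  f <- function(t_mm) spectrum_air_kerma(attenuate(s, "aluminium", t_mm / 10)) / k0 - 0.5
  stats::uniroot(f, c(1e-4, 40), tol = 1e-8)$root
}

# sample n photon energies (bin midpoints) from a spectrum
sample_spectrum <- function(s, n) {
  mids <- bin_mids(s)
  mids[sample.int(length(mids), n, replace = TRUE, prob = s$weights)]
}
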