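#' @keywords internal
"_PACKAGE"

# Bundled photon-interaction constants ----------------------------------------
#
# Linear attenuation coefficients (1/cm) for the six supported materials,
# the mass energy-absorption coefficient of air and the ICRU-slab Hp(10)
# fluence-to-dose conversion coefficients ship as plain-text tables under
# inst/extdata/ (see the provenance headers in the files). All lookups
# interpolate log-log between nodes and are exact at the nodes.

.irs_env <- new.env(parent = emptyenv())

MATERIALS <- c("air", "water", "soft_tissue", "aluminium", "copper", "lead")

.table_path <- function(...) {
  system.file("extdata", ..., package = "irscatter", mustWork = TRUE)
}

#' Bundled cross-section table for a material
#'
#' Returns the bundled table of partial and total linear attenuation
#' coefficients (1/cm) on the 10-150 keV grid for one of the supported
#' materials.
#'
#' @param material one of `"air"`, `"water"`, `"soft_tissue"`,
#'   `"aluminium"`, `"copper"`, `"lead"`.
#' @return data.frame with columns `E_keV`, `mu_pe`, `mu_compton`,
#'   `mu_rayleigh`, `mu_total`.
#' @export
xs_table <- function(material) {
  material <- match.arg(material, MATERIALS)
  key <- paste0("xs_", material)
  if (is.null(.irs_env[[key]])) {
    tab <- utils::read.table(.table_path("xs", paste0(material, ".txt")),
                             col.names = c("E_keV", "mu_pe", "mu_compton",
                                           "mu_rayleigh", "mu_total"))
    .irs_env[[key]] <- tab
  }
  .irs_env[[key]]
}

# piecewise log-log interpolation, exact at nodes; errors outside support
loglog_interp <- function(x, xs, ys, what = "energy") {
  if (any(x < xs[1] - 1e-9 | x > xs[length(xs)] + 1e-9)) {
    stop(sprintf("%s outside table support [%g, %g]", what, xs[1], xs[length(xs)]))
  }
  x <- pmin(pmax(x, xs[1]), xs[length(xs)])
  exp(stats::approx(log(xs), log(ys), log(x), ties = "ordered")$y)
}

#' Linear attenuation coefficients at given energies
#'
#' Log-log interpolates the bundled table for a material. `mu_total()`
#' returns the total linear attenuation coefficient; `mu_partial()` all
#' three partial coefficients.
#'
#' @param material material name, see [xs_table()].
#' @param energy photon energy, keV (vectorised); must lie in 10-150 keV.
#' @return `mu_total()`: numeric vector (1/cm). `mu_partial()`: list with
#'   components `pe`, `compton`, `rayleigh`, `total`.
#' @export
mu_total <- function(material, energy) {
  tab <- xs_table(material)
  loglog_interp(energy, tab$E_keV, tab$mu_total)
}

#' @rdname mu_total
#' @export
mu_partial <- function(material, energy) {
  tab <- xs_table(material)
  list(pe       = loglog_interp(energy, tab$E_keV, tab$mu_pe),
       compton  = loglog_interp(energy, tab$E_keV, tab$mu_compton),
       rayleigh = loglog_interp(energy, tab$E_keV, tab$mu_rayleigh),
       total    = loglog_interp(energy, tab$E_keV, tab$mu_total))
}

.air_muen_table <- function() {
  if (is.null(.irs_env$air_muen)) {
    .irs_env$air_muen <- utils::read.table(.table_path("air_muen.txt"),
                                           col.names = c("E_keV", "muen"))
  }
  .irs_env$air_muen
}

#' Air kerma per unit photon fluence
#'
#' Free-in-air kerma per unit fluence, `E * (mu_en/rho)_air`, with unit
#' bookkeeping to Gy per (photon/cm2), i.e. Gy cm2 per photon. Used to
#' express the simulated tube output in the normalisation quantities
#' (kerma-area product, reference-point air kerma).
#'
#' @param energy photon energy, keV (vectorised), within 10-150 keV.
#' @return air kerma per fluence, Gy cm2 (numeric vector).
#' @export
air_kerma_per_fluence <- function(energy) {
  tab <- .air_muen_table()
  muen <- loglog_interp(energy, tab$E_keV, tab$muen)
  # keV -> J (1.602177e-16), cm2/g -> cm2/kg (1e3); Gy = J/kg
  energy * 1.602176634e-16 * muen * 1e3
}

.hp10_table <- function() {
  if (is.null(.irs_env$hp10)) {
    .irs_env$hp10 <- utils::read.table(.table_path("hp10_slab.txt"),
                                       col.names = c("E_keV", "hp10"))
  }
  .irs_env$hp10
}

#' Hp(10) per unit photon fluence (ICRU slab, normal incidence)
#'
#' Personal dose equivalent at 10 mm depth in the ICRU slab per unit
#' fluence at normal incidence, log-log interpolated from the bundled
#' conversion-coefficient table.
#'
#' @param energy photon energy, keV (vectorised), within 10-150 keV.
#' @return conversion coefficient, pSv cm2 (numeric vector).
#' @export
hp10_per_fluence <- function(energy) {
  tab <- .hp10_table()
  loglog_interp(energy, tab$E_keV, tab$hp10)
}
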