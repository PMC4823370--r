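## Media metabolite quantification from 1H NMR integrals, signed exchange
## fluxes, per-glucose molar ratios, and 13C-satellite source attribution.

## single-site natural 13C abundance: NMR satellites report one carbon
.C13_NATURAL <- 0.0107

#' Quantify a metabolite concentration from NMR integrals
#'
#' Internal-standard quantification against TSP: the metabolite
#' concentration in the original medium is the total (center + satellite)
#' integral relative to TSP, scaled by the proton-count ratio, the TSP
#' concentration in the tube, and the dilution factor of the sample in the
#' tube (default 600/550 for 550 uL medium + 50 uL TSP/D2O).
#'
#' @param center center-peak (12C) integral
#' @param satellites summed 13C-satellite integral
#' @param tsp TSP reference integral (> 0)
#' @param protons proton count of the metabolite multiplet
#' @param tspConc TSP concentration in the tube (mM); default 11.6 mM stock
#'   diluted 50/600
#' @param tspProtons proton count of the TSP singlet (9)
#' @param dilution medium dilution factor in the tube
#' @return concentration in mM
#' @examples
#' quantifyConcentration(100, 1.1, 50, protons = 3)
#' @export
quantifyConcentration <- function(center, satellites = 0, tsp, protons,
                                  tspConc = 11.6 * 50 / 600, tspProtons = 9L,
                                  dilution = 600 / 550) {
  stopifnot(protons > 0, tspProtons > 0)
  if (!is.finite(tsp) || tsp <= 0) stop("TSP integral must be > 0")
  if (center < 0 || satellites < 0) stop("integrals must be >= 0")
  (center + satellites) / tsp * (tspProtons / protons) * tspConc * dilution
}

#' Net media exchange per mg protein
#'
#' Signed consumption/release: `(end - fresh) * volume / protein`, in
#' umol per mg protein. Negative values are net consumption from the
#' medium, positive values net release. Metabolites absent from fresh
#' medium (lactate, alanine, formate, glutamate) have `fresh = 0` and are
#' pure release.
#'
#' @param fresh fresh-medium concentration (mM)
#' @param end spent-medium concentration (mM)
#' @param volume medium volume (mL)
#' @param protein protein content (mg)
#' @return exchange in umol/mg protein
#' @examples
#' netExchange(25, 20, 2, 0.1)  # -100: consumed
#' @export
netExchange <- function(fresh, end, volume, protein) {
  if (any(protein <= 0)) stop("protein must be > 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  (end - fresh) * volume / protein
}

#' Molar release ratio per unit glucose consumed
#'
#' `release / |glucose_exchange|`, a molar ratio independent of cell
#' number. Undefined when glucose is not net-consumed.
#'
#' @param release release of the metabolite (umol/mg protein, >= 0 typically)
#' @param glucoseExchange net glucose exchange (umol/mg protein; must be < 0)
#' @return dimensionless molar ratio
#' @examples
#' ratioPerGlucose(160, -100)  # 1.6
#' @export
ratioPerGlucose <- function(release, glucoseExchange) {
  if (any(glucoseExchange >= 0))
    stop("glucose is not net-consumed (exchange >= 0); ratio undefined")
  release / abs(glucoseExchange)
}

#' 13C-labeled and tracer-derived fraction from satellite integrals
#'
#' The fraction of molecules 13C-labeled at the observed carbon is
#' `satellites / (center + satellites)`. The tracer-derived fraction
#' subtracts the single-site natural 13C abundance (1.07%):
#' `(f13 - 0.0107) / (1 - 0.0107)`, clipped to `[0, 1]`.
#'
#' @param center center-peak (12C) integral
#' @param satellites summed 13C-satellite integral
#' @return list with `f13` (raw labeled fraction) and `tracerFraction`
#' @examples
#' satelliteFraction(20, 80)
#' @export
satelliteFraction <- function(center, satellites) {
  if (center < 0 || satellites < 0) stop("integrals must be >= 0")
  tot <- center + satellites
  if (tot <= 0) stop("zero total intensity")
  f13 <- satellites / tot
  list(f13 = f13,
       tracerFraction = min(1, max(0, (f13 - .C13_NATURAL) / (1 - .C13_NATURAL))))
}
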