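#' Physical constants for hyaluronan brush calculations
#'
#' Default constants for HA: one disaccharide repeat unit weighs 400 Da
#' and contributes ~1 nm of contour length. The dry-thickness relation
#' \eqn{H = N \tau^{-1} \sigma b^3} uses the solvent-quality virial factor
#' \eqn{\tau} (1 for poor solvent, i.e. the collapsed dry layer). The
#' hydrodynamic radius scales as \eqn{R_H \sim M^{\nu}} with
#' \eqn{0.6 < \nu < 0.8} for high-MW HA; since no absolute prefactor is
#' available, scaling is anchored at a reference point, by default
#' (0.72 MDa, 100 nm). The UV deactivation threshold is the energy density
#' above which 405 nm irradiation destroys HA synthase activity.
#'
#' @param monomerMassDa disaccharide mass (Da)
#' @param monomerLengthNm disaccharide contour length (nm)
#' @param tau solvent-quality virial factor (dimensionless)
#' @param nu Flory-like scaling exponent for \eqn{R_H}; a warning is
#'   issued outside the supported band \[0.6, 0.8\]
#' @param rhAnchorMDa,rhAnchorNm anchor point for the \eqn{R_H} scaling
#' @param uvThresholdJPerUm2 HA synthase UV deactivation threshold (J/um^2)
#' @return named list of constants
#' @export
physicsConstants <- function(monomerMassDa = 400, monomerLengthNm = 1.0,
                             tau = 1.0, nu = 0.7,
                             rhAnchorMDa = 0.72, rhAnchorNm = 100,
                             uvThresholdJPerUm2 = 2.13e-4) {
  vals <- c(monomerMassDa, monomerLengthNm, tau, nu, rhAnchorMDa,
            rhAnchorNm, uvThresholdJPerUm2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physics constants must be finite and positive")
  if (nu < 0.6 || nu > 0.8)
    warning(sprintf("nu = %g lies outside the supported band [0.6, 0.8] for high-MW HA",
                    nu))
  list(monomerMassDa = monomerMassDa, monomerLengthNm = monomerLengthNm,
       tau = tau, nu = nu, rhAnchorMDa = rhAnchorMDa,
       rhAnchorNm = rhAnchorNm, uvThresholdJPerUm2 = uvThresholdJPerUm2)
}

.checkPositive <- function(x, what) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive and finite", what))
  invisible(x)
}

#' Number of monomers in a chain of given molecular weight
#'
#' `N = MW / m0` with `m0` the disaccharide mass (400 Da for HA). The
#' value is returned at full precision; round for display.
#'
#' @param mwDa molecular weight (Da); vectorized
#' @param constants see [physicsConstants()]
#' @return monomer (disaccharide) count, dimensionless
#' @examples
#' mwToMonomerCount(2.42e6)  # 6050
#' @export
mwToMonomerCount <- function(mwDa, constants = physicsConstants()) {
  .checkPositive(mwDa, "mwDa")
  mwDa / constants$monomerMassDa
}

#' Contour length of a chain of given molecular weight
#'
#' `L = (MW / m0) * b`, i.e. monomer count times the monomer length
#' (1 nm per HA disaccharide).
#'
#' @inheritParams mwToMonomerCount
#' @return contour length (nm); vectorized
#' @examples
#' contourLength(5.13e6) / 1e3  # ~12.8 um
#' @export
contourLength <- function(mwDa, constants = physicsConstants()) {
  mwToMonomerCount(mwDa, constants) * constants$monomerLengthNm
}

#' Grafting density from dry brush thickness
#'
#' Inverts the dry-layer relation \eqn{H = N \tau^{-1} \sigma b^3} to
#' \eqn{\sigma = H \tau / (N b^3)}. For a polydisperse brush, using the
#' number-average monomer count gives the upper density bound and the
#' weight-average count the lower bound.
#'
#' @param dryHeightNm dry brush thickness H (nm)
#' @param monomerCount monomer count N per chain (dimensionless)
#' @param tau solvent-quality virial factor
#' @param monomerLengthNm monomer length b (nm)
#' @return list with `sigma` (chains/nm^2), `densityPerUm2` (chains/um^2,
#'   exactly `sigma * 1e6`) and `spacingNm` (mean inter-chain distance,
#'   `density^(-1/2)` in consistent units)
#' @examples
#' graftingDensityFromDryHeight(12.5, 6050)$sigma   # 0.0021 chains/nm^2
#' graftingDensityFromDryHeight(12.5, 16900)$sigma  # 0.00074 chains/nm^2
#' @export
graftingDensityFromDryHeight <- function(dryHeightNm, monomerCount,
                                         tau = 1, monomerLengthNm = 1) {
  .checkPositive(dryHeightNm, "dryHeightNm")
  .checkPositive(monomerCount, "monomerCount")
  .checkPositive(tau, "tau")
  .checkPositive(monomerLengthNm, "monomerLengthNm")
  sigma <- dryHeightNm * tau / (monomerCount * monomerLengthNm^3)
  list(sigma = sigma, densityPerUm2 = sigma * 1e6,
       spacingNm = meanSpacing(sigma * 1e6))
}

#' Dry brush thickness from grafting density
#'
#' The forward relation \eqn{H = N \tau^{-1} \sigma b^3}; the exact
#' inverse of [graftingDensityFromDryHeight()].
#'
#' @param sigma grafting density (chains/nm^2)
#' @inheritParams graftingDensityFromDryHeight
#' @return dry thickness H (nm)
#' @export
dryHeightFromGraftingDensity <- function(sigma, monomerCount, tau = 1,
                                         monomerLengthNm = 1) {
  .checkPositive(sigma, "sigma")
  .checkPositive(monomerCount, "monomerCount")
  monomerCount * sigma * monomerLengthNm^3 / tau
}

#' Mean spacing between grafted chains
#'
#' For a surface density of `d` chains per um^2 the mean inter-chain
#' distance is \eqn{s = 1000/\sqrt{d}} nm.
#'
#' @param densityPerUm2 chains per um^2; vectorized
#' @return spacing (nm)
#' @examples
#' meanSpacing(740)   # ~37 nm
#' meanSpacing(2040)  # ~22 nm
#' @export
meanSpacing <- function(densityPerUm2) {
  .checkPositive(densityPerUm2, "densityPerUm2")
  1000 / sqrt(densityPerUm2)
}

#' Surface density of HA synthase from total membrane-protein density
#'
#' Multiplies the total membrane-protein surface density by the HA
#' synthase mass fraction. This treats the synthase as having the average
#' protein mass (an equal-mass simplification): with 30,000 proteins per
#' um^2 and a 6.8% synthase mass fraction it yields 2040 synthases per
#' um^2.
#'
#' @param proteinDensityPerUm2 total membrane proteins per um^2 (>= 0)
#' @param massFraction synthase mass fraction, in \[0, 1\]
#' @return synthase density (per um^2)
#' @export
synthaseSurfaceDensity <- function(proteinDensityPerUm2, massFraction) {
  if (any(!is.finite(proteinDensityPerUm2)) || any(proteinDensityPerUm2 < 0))
    stop("'proteinDensityPerUm2' must be finite and >= 0")
  if (any(!is.finite(massFraction)) || any(massFraction < 0) ||
      any(massFraction > 1))
    stop("'massFraction' must lie in [0, 1]")
  proteinDensityPerUm2 * massFraction
}

#' Hydrodynamic radius from molecular weight
#'
#' Power-law scaling \eqn{R_H = R_a (M/M_a)^{\nu}} anchored at a reference
#' molecular weight/radius pair; no absolute prefactor for HA is assumed.
#'
#' @param mwDa molecular weight (Da); vectorized
#' @param nu scaling exponent
#' @param anchorMwDa,anchorRhNm the anchor pair \eqn{(M_a, R_a)}; required
#' @return \eqn{R_H} (nm)
#' @examples
#' hydrodynamicRadius(0.72e6)                # 100 nm at the anchor
#' hydrodynamicRadius(2.88e6)                # 100 * 4^0.7
#' @export
hydrodynamicRadius <- function(mwDa, nu = 0.7, anchorMwDa = 0.72e6,
                               anchorRhNm = 100) {
  if (is.null(anchorMwDa) || is.null(anchorRhNm))
    stop("an (anchorMwDa, anchorRhNm) reference point is required: the R_H scaling has no absolute prefactor")
  .checkPositive(mwDa, "mwDa")
  .checkPositive(nu, "nu")
  .checkPositive(anchorMwDa, "anchorMwDa")
  .checkPositive(anchorRhNm, "anchorRhNm")
  anchorRhNm * (mwDa / anchorMwDa)^nu
}

#' Brush-regime ratio
#'
#' Ratio of the chain's solution diameter (2 R_H) to the mean inter-graft
#' spacing. A ratio > 1 means neighbouring chains overlap laterally and
#' the layer is in the brush regime; <= 1 is the mushroom regime
#' (ratio exactly 1 is the boundary).
#'
#' @param chainDiameterNm chain diameter in solution (nm)
#' @param spacingNm mean spacing between grafting points (nm)
#' @return list with `ratio` and `regime` ("brush", "mushroom" or
#'   "boundary")
#' @examples
#' brushRegimeRatio(200, 37)  # ratio ~5.4: well inside the brush regime
#' @export
brushRegimeRatio <- function(chainDiameterNm, spacingNm) {
  .checkPositive(chainDiameterNm, "chainDiameterNm")
  .checkPositive(spacingNm, "spacingNm")
  ratio <- chainDiameterNm / spacingNm
  regime <- ifelse(ratio > 1, "brush",
                   ifelse(ratio < 1, "mushroom", "boundary"))
  list(ratio = ratio, regime = regime)
}

#' Density ratio between the achieved grafting density and the enzyme
#' density, with display rounding
#'
#' Reports the achieved-to-available density ratio as a percentage, after
#' rounding both densities to two significant figures (the headline form
#' in which such densities are reported, e.g. 740 and 2100 chains/um^2 ->
#' 35%). Set `roundedInputs = FALSE` for the full-precision ratio.
#'
#' @param densityPerUm2 achieved grafting density (chains/um^2)
#' @param referencePerUm2 reference (maximum enzyme) density (chains/um^2)
#' @param roundedInputs round both densities to 2 significant figures
#'   before dividing (default)
#' @return percentage (0-100 scale)
#' @export
densityRatioPercent <- function(densityPerUm2, referencePerUm2,
                                roundedInputs = TRUE) {
  .checkPositive(densityPerUm2, "densityPerUm2")
  .checkPositive(referencePerUm2, "referencePerUm2")
  if (roundedInputs) {
    densityPerUm2 <- signif(densityPerUm2, 2)
    referencePerUm2 <- signif(referencePerUm2, 2)
  }
  100 * densityPerUm2 / referencePerUm2
}

#' UV micropatterning dose check
#'
#' Energy density delivered by a focused laser: `dose = power * dwell /
#' area`. HA synthase activity is destroyed at or above the deactivation
#' threshold (2.13e-4 J/um^2 at 405 nm); the threshold is treated as
#' inclusive since it is reported as a sufficiency bound.
#'
#' @param powerW laser power (W), >= 0
#' @param dwellS dwell time (s), >= 0
#' @param areaUm2 illuminated area (um^2), > 0
#' @param thresholdJPerUm2 deactivation threshold (J/um^2)
#' @return list with `doseJPerUm2` and logical `deactivated`
#' @export
uvDoseCheck <- function(powerW, dwellS, areaUm2,
                        thresholdJPerUm2 = physicsConstants()$uvThresholdJPerUm2) {
  if (any(powerW < 0) || any(dwellS < 0))
    stop("power and dwell time must be >= 0")
  .checkPositive(areaUm2, "areaUm2")
  dose <- powerW * dwellS / areaUm2
  list(doseJPerUm2 = dose, deactivated = dose >= thresholdJPerUm2)
}

#' Full closed-form brush physics report
#'
#' Runs the complete chain of closed-form calculations for a polydisperse
#' brush characterized by its number- and weight-average molecular
#' weights and a measured dry thickness: monomer counts, contour lengths,
#' the grafting-density bounds (chains/nm^2 and chains/um^2), mean
#' spacings, hydrodynamic radius of a reference chain, and the
#' brush-regime ratio.
#'
#' @param mnDa number-average molecular weight (Da)
#' @param mwDa weight-average molecular weight (Da)
#' @param dryHeightNm measured dry brush thickness (nm)
#' @param enzymeDensityPerUm2 optional reference enzyme surface density
#'   (per um^2) for the density-ratio entry
#' @param regimeMwDa molecular weight (Da) of the reference chain used for
#'   the regime check (default the R_H anchor)
#' @param constants see [physicsConstants()]
#' @return a [BrushPhysicsReport-class]
#' @examples
#' brushPhysicsReport(2.42e6, 6.76e6, 12.5, enzymeDensityPerUm2 = 2040)
#' @export
brushPhysicsReport <- function(mnDa, mwDa, dryHeightNm,
                               enzymeDensityPerUm2 = NULL,
                               regimeMwDa = NULL,
                               constants = physicsConstants()) {
  if (mwDa < mnDa) stop("Mw must be >= Mn")
  nN <- mwToMonomerCount(mnDa, constants)
  nW <- mwToMonomerCount(mwDa, constants)
  gUpper <- graftingDensityFromDryHeight(dryHeightNm, nN, constants$tau,
                                         constants$monomerLengthNm)
  gLower <- graftingDensityFromDryHeight(dryHeightNm, nW, constants$tau,
                                         constants$monomerLengthNm)
  if (is.null(regimeMwDa)) regimeMwDa <- constants$rhAnchorMDa * 1e6
  rh <- hydrodynamicRadius(regimeMwDa, constants$nu,
                           constants$rhAnchorMDa * 1e6, constants$rhAnchorNm)
  regime <- brushRegimeRatio(2 * rh, gLower$spacingNm)
  q <- function(value, unit) list(value = value, unit = unit)
  values <- list(
    monomerCountMn   = q(nN, "monomers"),
    monomerCountMw   = q(nW, "monomers"),
    contourLengthMn  = q(contourLength(mnDa, constants), "nm"),
    contourLengthMw  = q(contourLength(mwDa, constants), "nm"),
    sigmaUpper       = q(gUpper$sigma, "chains/nm^2"),
    sigmaLower       = q(gLower$sigma, "chains/nm^2"),
    densityUpper     = q(gUpper$densityPerUm2, "chains/um^2"),
    densityLower     = q(gLower$densityPerUm2, "chains/um^2"),
    spacingAtLower   = q(gLower$spacingNm, "nm"),
    spacingAtUpper   = q(gUpper$spacingNm, "nm"),
    referenceRh      = q(rh, "nm"),
    regimeRatio      = q(regime$ratio, ""),
    regime           = q(regime$regime, ""))
  if (!is.null(enzymeDensityPerUm2))
    values$densityRatio <- q(
      densityRatioPercent(gLower$densityPerUm2, gUpper$densityPerUm2),
      "% (lower/upper bound, 2-sig-fig rounded)")
  inputs <- list(
    Mn = q(mnDa, "Da"), Mw = q(mwDa, "Da"),
    dryHeight = q(dryHeightNm, "nm"),
    tau = q(constants$tau, ""), b = q(constants$monomerLengthNm, "nm"),
    m0 = q(constants$monomerMassDa, "Da"), nu = q(constants$nu, ""))
  if (!is.null(enzymeDensityPerUm2)) {
    inputs$enzymeDensity <- q(enzymeDensityPerUm2, "chains/um^2")
    values$enzymeSpacing <- q(meanSpacing(enzymeDensityPerUm2), "nm")
  }
  new("BrushPhysicsReport", values = values, inputs = inputs)
}
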