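#' @include AllClasses.R constructors.R
NULL

## Band selection. `edges` controls whether the lo/hi limits are included;
## the contiguous 13 GHz split uses closed soft [4,13] and left-open hard
## (13,32] so the edge channel is counted exactly once (in the soft band).
.bandChannels <- function(axis, band, edges = c(TRUE, TRUE)) {
  lo <- if (edges[1]) axis >= band[1] else axis > band[1]
  hi <- if (edges[2]) axis <= band[2] else axis < band[2]
  which(lo & hi)
}

#' Band spectral moment (intensity-weighted band centre)
#'
#' The fit-free estimator of a band's centre frequency: the first spectral
#' moment \eqn{\bar\nu = \sum_i I_i \nu_i / \sum_i I_i} over the channels
#' falling inside the band (both edges included by default). Used for the
#' soft and hard Brillouin peak shifts and, on the Raman axis, for the
#' CH2-CH3 and heme-amide band positions.
#'
#' @param x a [Spectrum-class].
#' @param band numeric `(lo, hi)` in the units of the spectrum axis.
#' @param edges length-2 logical: include the lo / hi edge channel.
#' @return The band centre in axis units, guaranteed inside `[lo, hi]`;
#'   `NA_real_` (an empty-band result, distinct from 0) when the band holds
#'   no positive intensity.
#' @examples
#' s <- spectrum(c(5, 6), c(1, 3), "brillouin")
#' spectralMoment(s, c(4, 13))  # (5*1 + 6*3) / 4 = 5.75
#' @seealso [bandIntensity()], [bandFirstMoment()]
#' @export
spectralMoment <- function(x, band, edges = c(TRUE, TRUE)) {
  stopifnot(is(x, "Spectrum"), length(band) == 2L, band[1] < band[2])
  idx <- .bandChannels(x@axis, band, edges)
  tot <- sum(x@intensity[idx])
  if (length(idx) == 0L || !is.finite(tot) || tot <= 0)
    return(NA_real_)
  sum(x@intensity[idx] * x@axis[idx]) / tot
}

#' Integrated band intensity
#'
#' Trapezoidal integral of the intensity over a band. Proportional to the
#' concentration of the elastic species supporting the acoustic mode, so the
#' soft/hard ratio of these areas (after efficiency weighting) yields the
#' phase volume fractions.
#'
#' @inheritParams spectralMoment
#' @return Non-negative integrated counts (axis units x counts); 0 with no
#'   signal in the band. A single in-band channel integrates to 0 by the
#'   trapezoidal rule, so at least two channels are needed for a nonzero
#'   area.
#' @examples
#' s <- spectrum(4:13, rep(1, 10), "brillouin")
#' bandIntensity(s, c(4, 13))  # 9
#' @export
bandIntensity <- function(x, band, edges = c(TRUE, TRUE)) {
  stopifnot(is(x, "Spectrum"), length(band) == 2L, band[1] < band[2])
  idx <- .bandChannels(x@axis, band, edges)
  if (length(idx) < 2L) return(0)
  ax <- x@axis[idx]
  iy <- x@intensity[idx]
  sum(diff(ax) * (iy[-1] + iy[-length(iy)])) / 2
}

#' Relative phase fractions from band intensities
#'
#' Converts the two integrated band intensities into relative volume
#' percentages. The soft band's photometric intensity is divided by
#' `efficiencyRatio` (its scattering efficiency relative to the hard phase)
#' before normalisation; normalising the pair to 100% absorbs the per-pixel
#' filling factor of the rough tissue surface, so the result is independent
#' of how much material the laser actually illuminated.
#'
#' @param softArea,hardArea non-negative integrated band intensities.
#' @param efficiencyRatio positive soft-vs-hard scattering-efficiency weight.
#' @return Named numeric `c(I_soft, I_hard)` in percent, summing to 100;
#'   both `NA` when both areas are zero (missing feature, not 0/100).
#' @examples
#' relativeFractions(4, 3, efficiencyRatio = 2)  # 40 / 60
#' @export
relativeFractions <- function(softArea, hardArea, efficiencyRatio = 1) {
  stopifnot(length(softArea) == 1L, length(hardArea) == 1L,
            is.finite(efficiencyRatio), efficiencyRatio > 0)
  if (is.na(softArea) || is.na(hardArea) ||
      softArea < 0 || hardArea < 0)
    stop("band areas must be non-negative numbers")
  if (softArea == 0 && hardArea == 0)
    return(c(I_soft = NA_real_, I_hard = NA_real_))
  w <- softArea / efficiencyRatio
  isoft <- 100 * w / (w + hardArea)
  c(I_soft = isoft, I_hard = 100 - isoft)
}

#' Longitudinal elastic modulus from a Brillouin shift
#'
#' Backscattering conversion \eqn{M = \nu_B^2 \lambda^2 \kappa / 4} with
#' \eqn{\kappa = \rho / n^2}. Units are tracked explicitly: the shift in GHz
#' becomes s^-1, the wavelength in nm becomes m, kappa in g/cm^3 becomes
#' kg/m^3, and the Pa result is returned in GPa. Exactly quadratic in the
#' shift.
#'
#' @param nu Brillouin frequency shift(s), GHz (vectorised).
#' @param lambdaLaser laser wavelength, nm.
#' @param kappa rho/n^2, g/cm^3.
#' @return Longitudinal modulus in GPa; `NA` inputs propagate to `NA`.
#' @examples
#' longitudinalModulus(10)          # 9.1275 GPa
#' longitudinalModulus(20)          # exactly 4x the above
#' @export
longitudinalModulus <- function(nu, lambdaLaser = 532, kappa = 1.29) {
  if (any(!is.finite(c(lambdaLaser, kappa))) || lambdaLaser <= 0 ||
      kappa <= 0)
    stop("lambdaLaser and kappa must be positive and finite")
  if (any(!is.na(nu) & !is.finite(nu)) || any(nu < 0, na.rm = TRUE))
    stop("nu must be finite and non-negative")
  nu_si  <- nu * 1e9            # GHz -> s^-1
  lam_si <- lambdaLaser * 1e-9  # nm -> m
  kap_si <- kappa * 1000        # g/cm^3 -> kg/m^3
  (nu_si^2 * lam_si^2 * kap_si / 4) / 1e9  # Pa -> GPa
}

#' Voigt-averaged modulus of a two-phase pixel
#'
#' Fraction-weighted arithmetic mean
#' \eqn{M = (I_s M_s + I_h M_h) / (I_s + I_h)}: the Voigt (iso-strain) upper
#' bound for the composite stiffness. Invariant under common rescaling of
#' the two fractions and bounded by the two phase moduli.
#'
#' @param mSoft,mHard phase moduli, GPa.
#' @param iSoft,iHard non-negative phase fractions (any common scale).
#' @return Averaged modulus in GPa; `NA` when both fractions are zero or any
#'   required input is missing. A phase with zero fraction may have an `NA`
#'   modulus (absent phase) without poisoning the average.
#' @examples
#' voigtAverage(4, 30, 50, 50)  # 17
#' @export
voigtAverage <- function(mSoft, mHard, iSoft, iHard) {
  if (is.na(iSoft) || is.na(iHard)) return(NA_real_)
  stopifnot(iSoft >= 0, iHard >= 0)
  if (iSoft == 0 && iHard == 0) return(NA_real_)
  if (iSoft == 0) return(mHard)
  if (iHard == 0) return(mSoft)
  if (is.na(mSoft) || is.na(mHard)) return(NA_real_)
  (iSoft * mSoft + iHard * mHard) / (iSoft + iHard)
}

## Constant-background estimate: median intensity outside both bands.
.brillouinBackground <- function(x, config) {
  out <- x@axis < config@softRange[1] | x@axis > config@hardRange[2]
  if (!any(out)) return(0)
  stats::median(x@intensity[out])
}

#' Per-pixel Brillouin mechanics
#'
#' Full single-spectrum Brillouin analysis: band spectral moments for the
#' soft and hard peaks, trapezoidal band intensities, efficiency-weighted
#' relative fractions, modulus conversion of each shift, and the
#' Voigt-averaged modulus. The soft band is closed `[lo, hi]` and the hard
#' band left-open `(lo, hi]`, so a channel at the shared 13 GHz edge is
#' counted once, in the soft band. An empty band yields `NA` for its shift
#' and modulus (and 0/100 fractions when the other band has signal); the
#' pixel is retained with partial features. All outputs are invariant under
#' rescaling of the spectrum by a positive constant.
#'
#' @param x a Brillouin [Spectrum-class] covering both configured bands.
#' @param config an [AnalysisConfig-class].
#' @return Named numeric vector with elements `nu_soft`, `nu_hard` (GHz),
#'   `I_soft`, `I_hard` (percent), `M_soft`, `M_hard`, `M_avg` (GPa).
#' @examples
#' ax <- seq(2, 35, by = 0.05)
#' tr <- pixelTruth(nuSoft = 6.87, nuHard = 18, fracSoft = 50)
#' s <- simulateBrillouinSpectrum(tr, ax)
#' extractBrillouinFeatures(s, analysisConfig())
#' @export
extractBrillouinFeatures <- function(x, config = analysisConfig()) {
  stopifnot(is(x, "Spectrum"), is(config, "AnalysisConfig"))
  if (x@modality != "brillouin")
    stop("extractBrillouinFeatures requires a Brillouin spectrum")
  if (config@backgroundSubtract) {
    bg <- .brillouinBackground(x, config)
    x@intensity <- pmax(x@intensity - bg, 0)
  }
  soft <- config@softRange
  hard <- config@hardRange
  contiguous <- isTRUE(all.equal(soft[2], hard[1]))
  hardEdges <- if (contiguous) c(FALSE, TRUE) else c(TRUE, TRUE)

  nuS <- spectralMoment(x, soft)
  nuH <- spectralMoment(x, hard, edges = hardEdges)
  aS <- if (is.na(nuS)) 0 else bandIntensity(x, soft)
  aH <- if (is.na(nuH)) 0 else bandIntensity(x, hard, edges = hardEdges)
  fr <- if (aS == 0 && aH == 0) c(I_soft = NA_real_, I_hard = NA_real_)
        else relativeFractions(aS, aH, config@efficiencyRatio)
  mS <- if (is.na(nuS)) NA_real_
        else longitudinalModulus(nuS, config@lambdaLaser, config@kappa)
  mH <- if (is.na(nuH)) NA_real_
        else longitudinalModulus(nuH, config@lambdaLaser, config@kappa)
  mAvg <- voigtAverage(mS, mH, fr[["I_soft"]], fr[["I_hard"]])
  c(nu_soft = nuS, nu_hard = nuH,
    I_soft = fr[["I_soft"]], I_hard = fr[["I_hard"]],
    M_soft = mS, M_hard = mH, M_avg = mAvg)
}
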