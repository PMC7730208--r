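# Modified Beer-Lambert law (MBLL) conversion between dual-wavelength
# absorbance changes and hemoglobin concentration changes, and its algebraic
# inverse (used by the simulator to emit raw absorbance).

#' Default hemoglobin extinction coefficients at 760 and 850 nm
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin from the
#' standard tabulated hemoglobin absorption spectrum (Prahl compilation),
#' converted to \eqn{\mu M^{-1} cm^{-1}}.  Rows are wavelengths (760, 850 nm),
#' columns are chromophores (HbO, HbR).
#'
#' @return A 2x2 numeric matrix.
#' @export
defaultExtinction <- function() {
  matrix(c(1486.5865, 3843.707,
           2526.391,  1798.643) * 1e-6,
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

#' MBLL conversion parameters
#'
#' @param extinction 2x2 matrix of extinction coefficients, rows =
#'   wavelengths, columns = (HbO, HbR), in \eqn{\mu M^{-1} cm^{-1}}.
#' @param dpf differential path-length factor per wavelength
#'   (dimensionless); a scalar is recycled to both wavelengths.
#' @param separation emitter-detector distance in cm.
#' @return A list of validated parameters for [mbllConvert()] /
#'   [inverseMbll()].
#' @details The per-sample model is
#'   \deqn{[\Delta HbO; \Delta HbR] = \epsilon^{-1} \,
#'     [\Delta A(\lambda_1)/(d_1 l);\; \Delta A(\lambda_2)/(d_2 l)]}
#'   with the path-length denominator \eqn{d \times l} applied as a scalar
#'   per wavelength (the DPF may differ between wavelengths).
#' @export
mbllParams <- function(extinction = defaultExtinction(), dpf = c(6, 6),
                       separation = 3) {
  extinction <- as.matrix(extinction)
  if (!identical(dim(extinction), c(2L, 2L)))
    stop("'extinction' must be a 2x2 matrix")
  dpf <- rep_len(as.numeric(dpf), 2L)
  if (any(dpf <= 0)) stop("'dpf' must be positive")
  if (length(separation) != 1L || separation <= 0)
    stop("'separation' must be a single positive number (cm)")
  if (!all(is.finite(extinction)) || abs(det(extinction)) < 1e-12)
    stop("singular extinction matrix: chromophores cannot be separated")
  list(extinction = extinction, dpf = dpf, separation = separation)
}

.absorbanceBlocks <- function(rec) {
  if (chromophore(rec) != "absorbance")
    stop("expected an absorbance recording (two wavelength blocks)")
  if (length(rec@wavelengths) != 2L)
    stop("absorbance recording must carry exactly 2 wavelengths")
  nc <- nChannels(rec)
  d <- signalMatrix(rec)
  list(a1 = d[, seq_len(nc), drop = FALSE],
       a2 = d[, nc + seq_len(nc), drop = FALSE])
}

#' Convert dual-wavelength absorbance changes to hemoglobin concentrations
#'
#' Applies the modified Beer-Lambert law per time sample: each wavelength
#' block is divided by its path length \eqn{d_w \times l} and the 2x2
#' extinction matrix is inverted to separate HbO from HbR.
#'
#' @param absorbance an [NirsRecording-class] with
#'   \code{chromophore = "absorbance"} (column blocks = wavelengths, see
#'   [NirsRecording-class]).
#' @param params parameters from [mbllParams()].
#' @return A list with elements \code{HbO} and \code{HbR}, each an
#'   [NirsRecording-class] in \eqn{\mu}M with the original channel ids.
#' @seealso [inverseMbll()]
#' @export
mbllConvert <- function(absorbance, params = mbllParams()) {
  blocks <- .absorbanceBlocks(absorbance)
  l <- params$separation
  s1 <- blocks$a1 / (params$dpf[1L] * l)
  s2 <- blocks$a2 / (params$dpf[2L] * l)
  inv <- solve(params$extinction)
  hbo <- inv[1L, 1L] * s1 + inv[1L, 2L] * s2
  hbr <- inv[2L, 1L] * s1 + inv[2L, 2L] * s2
  mk <- function(m, chrom) NirsRecording(m, fs = fs(absorbance),
                                         chromophore = chrom,
                                         channelIds = channelIds(absorbance),
                                         montage = montage(absorbance))
  list(HbO = mk(hbo, "HbO"), HbR = mk(hbr, "HbR"))
}

#' Convert hemoglobin concentration changes to absorbance changes
#'
#' Algebraic inverse of [mbllConvert()]:
#' \eqn{\Delta A(\lambda_w) = d_w l\, (\epsilon_{HbO,w}\Delta HbO +
#' \epsilon_{HbR,w}\Delta HbR)}.
#'
#' @param hbo,hbr [NirsRecording-class] objects of equal shape.
#' @param params parameters from [mbllParams()].
#' @param wavelengths the wavelengths (nm) to record on the output.
#' @return An absorbance [NirsRecording-class] with \code{2 * nChannels}
#'   columns (wavelength blocks).
#' @export
inverseMbll <- function(hbo, hbr, params = mbllParams(),
                        wavelengths = c(760, 850)) {
  if (!identical(dim(signalMatrix(hbo)), dim(signalMatrix(hbr))))
    stop("HbO and HbR recordings must have identical shape")
  if (!isTRUE(all.equal(fs(hbo), fs(hbr))))
    stop("HbO and HbR recordings must share the sampling frequency")
  eps <- params$extinction
  l <- params$separation
  o <- signalMatrix(hbo); r <- signalMatrix(hbr)
  a1 <- params$dpf[1L] * l * (eps[1L, 1L] * o + eps[1L, 2L] * r)
  a2 <- params$dpf[2L] * l * (eps[2L, 1L] * o + eps[2L, 2L] * r)
  NirsRecording(cbind(a1, a2), fs = fs(hbo), chromophore = "absorbance",
                wavelengths = wavelengths, channelIds = channelIds(hbo),
                montage = montage(hbo))
}
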