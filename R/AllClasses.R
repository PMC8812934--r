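#' CalibrationModel: robust zero-intercept fluorescence-to-TChla conversion
#'
#' Holds the result of a robust M-regression of bottle TChla (ug/L) on raw
#' fluorescence at one excitation channel, with the intercept fixed at zero
#' so that predicted chlorophyll can never be negative. Samples whose final
#' robustness weight falls below 1e-3 are flagged as outliers; they are the
#' set removed from the reference database downstream.
#'
#' @slot channel excitation wavelength (nm).
#' @slot slope conversion coefficient (ug/L per fluorescence unit).
#' @slot slopeSE asymptotic standard error of the slope.
#' @slot r2 coefficient of determination through the origin, on non-outliers.
#' @slot weights final per-sample robustness weights in [0, 1].
#' @slot outliers logical, \code{weights < 1e-3}.
#' @slot n sample count.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(channel = "integer", slope = "numeric", slopeSE = "numeric",
                 r2 = "numeric", weights = "numeric", outliers = "logical",
                 n = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) != 1 || is.na(object@slope) || object@slope <= 0)
      msg <- c(msg, "slope must be a single positive number")
    if (length(object@r2) != 1 || object@r2 < 0 || object@r2 > 1)
      msg <- c(msg, "r2 must lie in [0, 1]")
    if (length(object@weights) != length(object@outliers))
      msg <- c(msg, "weights and outliers must have equal length")
    if (length(object@weights) &&
        !identical(unname(object@outliers), unname(object@weights < 1e-3)))
      msg <- c(msg, "outlier flags must equal weights < 1e-3")
    if (length(object@weights) &&
        (any(object@weights < 0) || any(object@weights > 1)))
      msg <- c(msg, "weights must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' ReferenceDatabase: paired spectra and pigment-based compositions
#'
#' The empirical conversion core: indexed pairs of a standardized nine-channel
#' excitation spectrum and the pigment-based nine-group composition of the
#' same water sample, with TChla, sampling metadata and a calibration-outlier
#' flag. The \emph{active} view (records not flagged as outliers) is what all
#' conversions use; flagged records are retained for provenance but never
#' enter a decomposition.
#'
#' @slot spectra numeric matrix, records x 9 channels, each row summing to 1.
#' @slot compositions numeric matrix, records x 9 groups, each row summing
#'   to 1.
#' @slot tchla numeric, TChla (ug/L) per record.
#' @slot metadata data.frame with columns cruise, station, depth_m, area,
#'   season.
#' @slot outlier logical calibration-outlier flag per record.
#' @slot provenance list (free-form: calibration channel, build date, ...).
#' @exportClass ReferenceDatabase
setClass("ReferenceDatabase",
  representation(spectra = "matrix", compositions = "matrix",
                 tchla = "numeric", metadata = "data.frame",
                 outlier = "logical", provenance = "list"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@spectra)
    if (!identical(colnames(object@spectra), channelNames()))
      msg <- c(msg, "spectra columns must be the nine MEX channels")
    if (!identical(colnames(object@compositions), taxonGroups()))
      msg <- c(msg, "composition columns must be the nine taxon groups")
    if (nrow(object@compositions) != n || length(object@tchla) != n ||
        nrow(object@metadata) != n || length(object@outlier) != n)
      msg <- c(msg, "all record-wise slots must have equal length")
    need <- c("cruise", "station", "depth_m", "area", "season")
    if (!all(need %in% names(object@metadata)))
      msg <- c(msg, paste("metadata must contain:", paste(need, collapse = ", ")))
    if (n > 0) {
      if (any(object@spectra < 0) || any(object@compositions < 0))
        msg <- c(msg, "spectra and compositions must be non-negative")
      if (max(abs(rowSums(object@spectra) - 1)) > 1e-9)
        msg <- c(msg, "spectra must be standardized (rows sum to 1)")
      if (max(abs(rowSums(object@compositions) - 1)) > 1e-9)
        msg <- c(msg, "compositions must sum to 1 per record")
      if (any(object@tchla < 0)) msg <- c(msg, "tchla must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })
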