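#' Standardize a nine-channel excitation spectrum
#'
#' Divides each channel by the channel sum so the nine values add to 1. All
#' reference spectra and every target spectrum are standardized before
#' decomposition; standardization makes the shape of the excitation response
#' the carrier of taxonomic information and removes the biomass scale (which
#' is recovered separately through the TChla calibration).
#'
#' @param raw named numeric vector over \code{channelNames()}, or a matrix
#'   with one spectrum per row.
#' @return spectrum (or matrix) with rows summing to 1.
#' @export
standardizeSpectrum <- function(raw) {
  one <- is.null(dim(raw))
  m <- if (one) matrix(raw, 1, dimnames = list(NULL, names(raw)))
       else as.matrix(raw)
  if (!all(channelNames() %in% colnames(m)))
    stop("spectrum must be named with: ", paste(channelNames(), collapse = ", "))
  m <- m[, channelNames(), drop = FALSE]
  if (anyNA(m) || any(m < 0)) stop("spectrum channels must be >= 0")
  s <- rowSums(m)
  if (any(s == 0)) stop("cannot standardize an all-zero spectrum")
  out <- m / s
  if (one) out[1, ] else out
}

#' Construct a reference database
#'
#' Low-level constructor; see [buildReferenceDatabase()] for the full build
#' from paired pigment samples and raw spectra.
#'
#' @param spectra records x 9 matrix of raw or standardized spectra
#'   (standardized internally).
#' @param compositions records x 9 matrix of group fractions (rows sum to 1).
#' @param tchla TChla (ug/L) per record.
#' @param metadata data.frame with cruise, station, depth_m, area, season.
#' @param outlier logical flag per record (default all FALSE).
#' @param provenance free-form list.
#' @return a [ReferenceDatabase-class].
#' @export
ReferenceDatabase <- function(spectra, compositions, tchla, metadata,
                              outlier = rep(FALSE, nrow(spectra)),
                              provenance = list()) {
  spectra <- standardizeSpectrum(as.matrix(spectra))
  compositions <- as.matrix(compositions)[, taxonGroups(), drop = FALSE]
  new("ReferenceDatabase", spectra = spectra, compositions = compositions,
      tchla = as.numeric(tchla), metadata = as.data.frame(metadata),
      outlier = as.logical(outlier), provenance = provenance)
}

#' Build the reference database from paired samples
#'
#' Assembles the conversion reference set from water samples for which both
#' an HPLC pigment analysis and a MEX spectrum exist. Compositions come from
#' [estimateComposition()]; spectra are standardized; records flagged as
#' outliers of the TChla calibration (robustness weight < 1e-3) are marked
#' and excluded from the active view. Duplicate (cruise, station, depth_m)
#' keys raise a warning but both records are kept.
#'
#' @param pigments data.frame of pigment samples (columns: the eleven
#'   \code{ratioPigments()}, plus cruise, station, depth_m, area, season).
#' @param spectra matrix of raw spectra, one row per pigment row.
#' @param calibration [CalibrationModel-class] fitted on these pairs; its
#'   per-sample outlier flags (if any) mark records. \code{NULL} for no flags.
#' @param ratios ratio matrix.
#' @return a [ReferenceDatabase-class].
#' @export
buildReferenceDatabase <- function(pigments, spectra, calibration = NULL,
                                   ratios = defaultRatioMatrix()) {
  if (nrow(pigments) < 10) stop("need at least 10 reference pairs")
  if (nrow(pigments) != nrow(spectra))
    stop("pigments and spectra must pair row-wise")
  est <- batchEstimateComposition(pigments, ratios)
  if (!all(est$ok))
    stop("composition failed for rows: ",
         paste(which(!est$ok), collapse = ", "))
  flags <- rep(FALSE, nrow(pigments))
  if (!is.null(calibration) && length(outlierFlags(calibration))) {
    if (length(outlierFlags(calibration)) != nrow(pigments))
      stop("calibration flags do not align with the reference pairs")
    flags <- outlierFlags(calibration)
  }
  if (all(flags)) stop("empty reference database: every pair flagged as outlier")
  key <- with(pigments, paste(cruise, station, depth_m, sep = "/"))
  if (anyDuplicated(key))
    warning("duplicate (cruise, station, depth) keys: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  meta <- pigments[, c("cruise", "station", "depth_m", "area", "season")]
  tch <- pigments$MVChla + pigments$DVChla
  prov <- list(built = format(Sys.time(), "%Y-%m-%d"),
               calibration_channel = if (!is.null(calibration))
                 calibrationChannel(calibration) else NA_integer_)
  ReferenceDatabase(spectra, est$fractions, tch, meta, flags, prov)
}

#' Write / read a reference database as CSV
#'
#' Plain-text round trip: nine spectrum columns (f375...f590), nine
#' composition columns, tchla, cruise, station, depth_m, area, season,
#' outlier.
#'
#' @param db a [ReferenceDatabase-class].
#' @param path CSV file path.
#' @return \code{readReferenceDatabase}: the database;
#'   \code{writeReferenceDatabase}: invisibly \code{path}.
#' @export
writeReferenceDatabase <- function(db, path) {
  df <- data.frame(refSpectra(db), refCompositions(db),
                   tchla = refTChla(db), refMetadata(db),
                   outlier = outlierFlags(db), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceDatabase
#' @export
readReferenceDatabase <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c(channelNames(), taxonGroups(), "tchla", "cruise", "station",
            "depth_m", "area", "season", "outlier")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reference CSV missing columns: ",
                         paste(miss, collapse = ", "))
  ReferenceDatabase(as.matrix(df[, channelNames()]),
                    as.matrix(df[, taxonGroups()]),
                    df$tchla,
                    df[, c("cruise", "station", "depth_m", "area", "season")],
                    as.logical(df$outlier))
}
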