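#' @rdname CalibrationModel-class
#' @param object,x a \code{CalibrationModel} or \code{ReferenceDatabase}.
#' @export
setGeneric("calibrationSlope", function(object) standardGeneric("calibrationSlope"))
#' @rdname CalibrationModel-class
#' @export
setGeneric("calibrationChannel", function(object) standardGeneric("calibrationChannel"))
#' @rdname CalibrationModel-class
#' @export
setGeneric("calibrationWeights", function(object) standardGeneric("calibrationWeights"))
#' @rdname CalibrationModel-class
#' @export
setGeneric("outlierFlags", function(object) standardGeneric("outlierFlags"))

#' @rdname ReferenceDatabase-class
#' @export
setGeneric("refSpectra", function(object) standardGeneric("refSpectra"))
#' @rdname ReferenceDatabase-class
#' @export
setGeneric("refCompositions", function(object) standardGeneric("refCompositions"))
#' @rdname ReferenceDatabase-class
#' @export
setGeneric("refTChla", function(object) standardGeneric("refTChla"))
#' @rdname ReferenceDatabase-class
#' @export
setGeneric("refMetadata", function(object) standardGeneric("refMetadata"))
#' @rdname ReferenceDatabase-class
#' @export
setGeneric("activeRecords", function(object) standardGeneric("activeRecords"))

setMethod("calibrationSlope", "CalibrationModel", function(object) object@slope)
setMethod("calibrationChannel", "CalibrationModel", function(object) object@channel)
setMethod("calibrationWeights", "CalibrationModel", function(object) object@weights)
setMethod("outlierFlags", "CalibrationModel", function(object) object@outliers)
setMethod("outlierFlags", "ReferenceDatabase", function(object) object@outlier)

setMethod("refSpectra", "ReferenceDatabase", function(object) object@spectra)
setMethod("refCompositions", "ReferenceDatabase", function(object) object@compositions)
setMethod("refTChla", "ReferenceDatabase", function(object) object@tchla)
setMethod("refMetadata", "ReferenceDatabase", function(object) object@metadata)

#' @rdname ReferenceDatabase-class
#' @export
setMethod("activeRecords", "ReferenceDatabase",
          function(object) which(!object@outlier))

#' @rdname ReferenceDatabase-class
#' @export
setMethod("length", "ReferenceDatabase", function(x) nrow(x@spectra))

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel:", object@channel, "nm\n")
  cat(sprintf("  TChla = %.5f x F%dnm  (SE %.5f, r2 %.4f, n = %d",
              object@slope, object@channel, object@slopeSE, object@r2,
              object@n))
  if (length(object@outliers))
    cat(sprintf(", %d outliers", sum(object@outliers)))
  cat(")\n")
})

setMethod("show", "ReferenceDatabase", function(object) {
  n <- length(object); act <- length(activeRecords(object))
  cat(sprintf("ReferenceDatabase: %d records (%d active, %d outliers)\n",
              n, act, n - act))
  if (n) {
    ar <- table(object@metadata$area)
    cat("  areas:", paste(sprintf("%s=%d", names(ar), ar), collapse = ", "), "\n")
    cat(sprintf("  TChla: %.3g-%.3g ug/L\n",
                min(object@tchla), max(object@tchla)))
  }
})

#' Subset a reference database by record index
#'
#' @param x a \code{ReferenceDatabase}.
#' @param i integer or logical record index.
#' @param j,...,drop ignored.
#' @return a \code{ReferenceDatabase} with the selected records.
#' @export
setMethod("[", "ReferenceDatabase", function(x, i, j, ..., drop = FALSE) {
  new("ReferenceDatabase",
      spectra = x@spectra[i, , drop = FALSE],
      compositions = x@compositions[i, , drop = FALSE],
      tchla = x@tchla[i],
      metadata = x@metadata[i, , drop = FALSE],
      outlier = x@outlier[i],
      provenance = x@provenance)
})
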