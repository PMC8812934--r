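#' Read an HPLC pigment table
#'
#' Required columns: the eleven \code{ratioPigments()}, the two extra
#' pigments (\code{Neo}, \code{Lut}), and metadata cruise, station, depth_m,
#' area, season. Concentrations are ug/L. Rows with a negative pigment value
#' are flagged (not dropped); missing columns raise a schema error naming
#' them.
#'
#' @param path CSV file path.
#' @return data.frame with an added logical column \code{valid} (FALSE where
#'   a pigment is negative or missing) and attribute \code{rowErrors}
#'   (character per flagged row).
#' @export
readPigmentTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c(ratioPigments(), extraPigments(),
            "cruise", "station", "depth_m", "area", "season")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pigment table missing columns: ",
                         paste(miss, collapse = ", "))
  pig <- as.matrix(df[, c(ratioPigments(), extraPigments())])
  bad <- apply(pig, 1, function(r) anyNA(r) || any(r < 0))
  df$valid <- !bad
  errs <- ifelse(bad, "negative or missing pigment concentration", "")
  attr(df, "rowErrors") <- errs
  if (any(bad))
    warning(sum(bad), " row(s) flagged: negative or missing pigments")
  df
}

#' Read a raw MEX cast
#'
#' Required columns: time_s, depth_m, temp_c and the nine channel columns
#' f375...f590. Rows are time-sorted on load; duplicate timestamps keep the
#' first occurrence (with a message).
#'
#' @param path CSV file path.
#' @return data.frame cast.
#' @export
readCast <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_s", "depth_m", "temp_c", channelNames())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cast missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty cast file: ", path)
  df <- df[order(df$time_s), need]
  dup <- duplicated(df$time_s)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate timestamp(s), keeping first")
    df <- df[!dup, ]
  }
  rownames(df) <- NULL
  df
}

#' Write / read a calibration model as YAML
#'
#' Serialises channel, slope, standard error, r-squared, n and the indices
#' of flagged outliers; weights are not stored (they are reproducible from
#' the data).
#'
#' @param model a [CalibrationModel-class].
#' @param path YAML file path.
#' @return \code{readCalibrationModel}: the model (with empty weights);
#'   \code{writeCalibrationModel}: invisibly \code{path}.
#' @export
writeCalibrationModel <- function(model, path) {
  yaml::write_yaml(list(
    channel = calibrationChannel(model),
    slope = calibrationSlope(model),
    slope_se = model@slopeSE,
    r2 = model@r2,
    n = model@n,
    outliers = which(outlierFlags(model))), path, precision = 15L)
  invisible(path)
}

#' @rdname writeCalibrationModel
#' @export
readCalibrationModel <- function(path) {
  y <- yaml::read_yaml(path)
  new("CalibrationModel", channel = as.integer(y$channel),
      slope = as.numeric(y$slope), slopeSE = as.numeric(y$slope_se),
      r2 = as.numeric(y$r2), weights = numeric(0), outliers = logical(0),
      n = as.integer(y$n))
}

#' Write a binned profile as CSV
#'
#' @param profile binned profile (from [binProfile1m()]).
#' @param path CSV file path.
#' @return invisibly \code{path}.
#' @export
writeProfile <- function(profile, path) {
  write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
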