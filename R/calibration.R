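#' Robust zero-intercept regression of TChla on fluorescence
#'
#' Fits \code{y = slope * x} by iteratively reweighted M-estimation with the
#' Tukey bisquare psi (tuning constant 4.685) and scale taken as the MAD of
#' the residuals. The intercept is fixed at zero so that predicted TChla is
#' never negative. Bisquare weights reach exactly zero for gross outliers,
#' which makes the outlier rule (final weight < 1e-3) well defined. The slope
#' standard error is the asymptotic M-estimator sandwich on the final fit;
#' r-squared is computed through the origin on the non-outlier points as
#' \code{1 - SSres/SSy} with uncentred sums of squares.
#'
#' @param x fluorescence values (raw instrument units).
#' @param y TChla concentrations (ug/L), same length.
#' @param channel excitation wavelength (nm) to record on the model; purely
#'   descriptive.
#' @param maxit maximum IRLS iterations (default 200; bisquare IRLS
#'   converges linearly, and tight tolerances routinely need over 100
#'   iterations on contaminated data).
#' @param tol convergence tolerance on the relative slope change (default
#'   1e-8).
#' @return a [CalibrationModel-class] object.
#' @examples
#' set.seed(1)
#' x <- runif(30, 0, 5)
#' m <- fitRobustZeroIntercept(x, 0.5 * x + rnorm(30, sd = 0.01))
#' calibrationSlope(m)
#' @export
fitRobustZeroIntercept <- function(x, y, channel = NA_integer_,
                                   maxit = 200L, tol = 1e-8) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  if (all(x == 0)) stop("degenerate predictor: all fluorescence values zero")
  cc <- 4.685
  b <- sum(x * y) / sum(x * x)  # OLS start
  w <- rep(1, length(x))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - b * x
    s <- mad(r)
    if (s == 0) {
      # (near-)perfect fit on the majority: weight by exact-zero residuals
      w <- as.numeric(r == 0)
      if (sum(w * x * x) == 0) w <- rep(1, length(x))
      converged <- TRUE
      break
    }
    u <- r / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w * x * x) == 0)
      stop("robust fit degenerate: all weights vanished")
    bNew <- sum(w * x * y) / sum(w * x * x)
    if (abs(bNew - b) <= tol * max(1, abs(b))) {
      b <- bNew; converged <- TRUE; break
    }
    b <- bNew
  }
  if (!converged)
    stop(sprintf("M-estimation did not converge in %d iterations (last slope %.6g)",
                 maxit, b))
  r <- y - b * x
  s <- mad(r)
  # sandwich SE: psi(r) = r w(r); A = sum x^2 psi'(r), B = sum x^2 psi(r)^2
  if (s > 0) {
    u <- r / (cc * s)
    psi <- ifelse(abs(u) < 1, r * (1 - u^2)^2, 0)
    dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    A <- sum(x^2 * dpsi); B <- sum(x^2 * psi^2)
    se <- if (A > 0) sqrt(B) / A else NA_real_
  } else se <- 0
  keep <- w >= 1e-3
  ssres <- sum((y[keep] - b * x[keep])^2)
  ssy <- sum(y[keep]^2)
  r2 <- if (ssy > 0) max(0, min(1, 1 - ssres / ssy)) else NA_real_
  new("CalibrationModel", channel = as.integer(channel), slope = b,
      slopeSE = se, r2 = r2, weights = pmin(pmax(w, 0), 1),
      outliers = w < 1e-3, n = length(x))
}

#' Select the calibration channel by coefficient of determination
#'
#' Fits [fitRobustZeroIntercept()] independently for every excitation channel
#' and returns the channel with the highest r-squared together with the full
#' ranking table. Ties are broken toward the shorter wavelength. Channels on
#' which the fit fails (e.g. all-zero fluorescence) are recorded with
#' \code{NA} r-squared and never selected.
#'
#' @param fluor matrix or data.frame of fluorescence, one column per channel,
#'   columns named as in \code{channelNames()} (or a subset, >= 2 columns).
#' @param tchla TChla (ug/L), one value per row.
#' @return list with \code{model} (the winning [CalibrationModel-class]),
#'   \code{channel} (nm) and \code{table} (data.frame: channel, r2, slope,
#'   ok) sorted by decreasing r2.
#' @export
selectCalibrationChannel <- function(fluor, tchla) {
  fluor <- as.matrix(fluor)
  if (ncol(fluor) < 2) stop("need at least 2 channels to select from")
  chs <- sub("^f", "", colnames(fluor))
  wl <- as.integer(chs)
  if (anyNA(wl)) stop("fluorescence columns must be named f<wavelength>")
  fits <- lapply(seq_along(wl), function(j)
    tryCatch(fitRobustZeroIntercept(fluor[, j], tchla, channel = wl[j]),
             error = identity))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("calibration failed on every channel")
  r2 <- ifelse(ok, vapply(fits, function(f)
    if (inherits(f, "error")) NA_real_ else f@r2, numeric(1)), NA_real_)
  slope <- vapply(fits, function(f)
    if (inherits(f, "error")) NA_real_ else f@slope, numeric(1))
  tab <- data.frame(channel = wl, r2 = r2, slope = slope, ok = ok)
  # argmax r2; ties toward shorter wavelength
  cand <- which(ok)
  best <- cand[order(-r2[cand], wl[cand])][1]
  list(model = fits[[best]], channel = wl[best],
       table = tab[order(-ifelse(is.na(r2), -Inf, r2), wl), ])
}

#' The published MEX calibration
#'
#' The deployed conversion between raw 435 nm excitation fluorescence and
#' TChla: slope 0.54095 ug/L per fluorescence unit (SE 0.02205), fitted on
#' 271 bottle pairs with r-squared 0.8844. Use with [estimateTChla()] when no
#' site-specific calibration is available.
#'
#' @return a [CalibrationModel-class] for the 435 nm channel.
#' @export
publishedCalibration <- function() {
  new("CalibrationModel", channel = 435L, slope = 0.54095, slopeSE = 0.02205,
      r2 = 0.8844, weights = numeric(0), outliers = logical(0), n = 271L)
}

#' Convert 435 nm fluorescence to TChla
#'
#' Applies the zero-intercept conversion \code{TChla_MEX = slope * f435}.
#'
#' @param f435 raw (unstandardized) fluorescence at the calibration channel;
#'   vectorised, must be >= 0.
#' @param model a [CalibrationModel-class], default [publishedCalibration()].
#' @return TChla_MEX in ug/L.
#' @examples
#' estimateTChla(1.0)  # 0.54095
#' @export
estimateTChla <- function(f435, model = publishedCalibration()) {
  if (anyNA(f435) || any(f435 < 0))
    stop("fluorescence must be non-negative and non-missing")
  model@slope * f435
}

#' Match bottle samples to cast fluorescence by depth
#'
#' Pairs each discrete (bottle) sample depth with the 1-m bin of a despiked
#' cast nearest to it, within a tolerance. Used to assemble the (fluorescence,
#' TChla) pairs that feed the calibration.
#'
#' @param bottleDepths depths (m) of the bottle samples.
#' @param binDepths depths (m) of the cast's 1-m bins.
#' @param tol maximum |depth difference| to accept (m), default 1.
#' @return integer vector: for each bottle, the matched bin index or NA.
#' @export
matchBottleDepths <- function(bottleDepths, binDepths, tol = 1) {
  vapply(bottleDepths, function(d) {
    j <- which.min(abs(binDepths - d))
    if (length(j) && abs(binDepths[j] - d) <= tol) j else NA_integer_
  }, integer(1))
}
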