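# Box-constrained linear least squares: minimize ||M a - f||^2, 0 <= a <= 1.
# Convex quadratic; solved by projected quasi-Newton (L-BFGS-B) from a zero
# start with an analytic gradient and tight tolerances, which is
# deterministic for fixed input. With more references than channels the
# minimiser need not be unique; the zero start selects one reproducibly.
boundedLsq <- function(M, f, lower = 0, upper = 1) {
  n <- ncol(M)
  MtM <- crossprod(M)
  Mtf <- crossprod(M, f)
  fn <- function(a) sum((M %*% a - f)^2)
  gr <- function(a) as.numeric(2 * (MtM %*% a - Mtf))
  res <- optim(rep(0, n), fn, gr, method = "L-BFGS-B",
               lower = rep(lower, n), upper = rep(upper, n),
               control = list(maxit = 1000L, factr = 10, pgtol = 1e-14))
  a <- pmin(pmax(res$par, lower), upper)
  # active-set polish: re-solve the free coordinates exactly (minimal-norm
  # least squares via the pseudo-inverse); coordinates the exact solve pushes
  # past a bound are pinned there and the solve repeated. Accept if no worse.
  tol <- 1e-7
  free <- a > lower + tol & a < upper - tol
  cand <- a
  for (it in seq_len(n)) {
    if (!any(free)) break
    rhs <- f - M[, !free, drop = FALSE] %*% cand[!free]
    sv <- svd(M[, free, drop = FALSE])
    pos <- sv$d > max(sv$d) * 1e-10
    xf <- as.numeric(sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos]))
    viol <- xf < lower - 1e-12 | xf > upper + 1e-12
    cand[free] <- pmin(pmax(xf, lower), upper)
    if (!any(viol)) break
    free[free] <- !viol
  }
  if (fn(cand) <= fn(a) + 1e-15) a <- cand
  a
}

#' Decompose a standardized spectrum over the reference database
#'
#' Expresses a target standardized spectrum \code{f} as a combination of the
#' active reference spectra: coefficients \code{alpha} minimise the Euclidean
#' residual \code{|| f - sum(alpha_i * F_i) ||} subject to
#' \code{0 <= alpha_i <= 1}. No sum constraint is imposed on the
#' coefficients: only the bounds and the minimal residual. The fit is
#' deterministic for a fixed database and target.
#'
#' @param f standardized nine-channel spectrum (named vector summing to 1).
#' @param db a [ReferenceDatabase-class]; only active (non-outlier) records
#'   are used.
#' @return list with \code{alphas} (named by active record index),
#'   \code{residualNorm}, \code{nActive} (count of alpha > 1e-6) and
#'   \code{maxSpectralCor} (largest pairwise correlation among reference
#'   spectra carrying alpha > 1e-6 — a collinearity diagnostic; NA when
#'   fewer than two are active).
#' @export
decomposeSpectrum <- function(f, db) {
  idx <- activeRecords(db)
  if (!length(idx)) stop("reference database has no active records")
  f <- .checkNamedNonneg(f, channelNames(), "spectrum")
  if (abs(sum(f) - 1) > 1e-6)
    stop("spectrum must be standardized (sum to 1); see standardizeSpectrum()")
  M <- t(refSpectra(db)[idx, , drop = FALSE])  # 9 x nActive
  a <- boundedLsq(M, as.numeric(f))
  names(a) <- as.character(idx)
  act <- a > 1e-6
  maxCor <- NA_real_
  if (sum(act) >= 2) {
    S <- refSpectra(db)[idx[act], , drop = FALSE]
    cm <- suppressWarnings(cor(t(S)))
    maxCor <- max(cm[upper.tri(cm)], na.rm = TRUE)
  }
  list(alphas = a,
       residualNorm = sqrt(sum((M %*% a - f)^2)),
       nActive = sum(act),
       maxSpectralCor = maxCor)
}

#' Reconstruct a group composition from decomposition coefficients
#'
#' Applies the coefficient-weighted sum of the reference compositions,
#' \code{p_raw = sum(alpha_i * P_i)}, then renormalizes to a proper
#' composition summing to 1. The raw coefficient sum is returned as a
#' diagnostic: values far from 1 indicate a target spectrum poorly covered by
#' the reference span.
#'
#' @param decomposition result of [decomposeSpectrum()].
#' @param db the same [ReferenceDatabase-class] used for the decomposition.
#' @return list with \code{composition} (named fractions, sum 1),
#'   \code{alphaSum} and \code{residualNorm} (carried through).
#' @export
reconstructComposition <- function(decomposition, db) {
  a <- decomposition$alphas
  idx <- as.integer(names(a))
  if (sum(a) <= 0) stop("no reference support: all coefficients are zero")
  praw <- as.numeric(t(refCompositions(db)[idx, , drop = FALSE]) %*% a)
  names(praw) <- taxonGroups()
  list(composition = praw / sum(praw),
       alphaSum = sum(a),
       residualNorm = decomposition$residualNorm)
}

#' Convert a raw MEX spectrum to composition and TChla
#'
#' The full per-spectrum conversion: standardize, decompose over the active
#' reference records, reconstruct the composition, and estimate TChla_MEX
#' from the raw (unstandardized) fluorescence at the calibration channel.
#' TChla uses the raw channel because the calibration was fitted on recorded
#' fluorescence; the composition uses only the standardized shape, so scaling
#' the raw spectrum changes TChla_MEX proportionally but leaves the
#' composition untouched.
#'
#' @param raw named raw nine-channel spectrum (instrument units, >= 0, not
#'   all zero).
#' @param db a [ReferenceDatabase-class].
#' @param calibration a [CalibrationModel-class]; default
#'   [publishedCalibration()].
#' @return list with \code{composition}, \code{tchla} (ug/L) and
#'   \code{diagnostics} (alphaSum, residualNorm, nActive, maxSpectralCor).
#' @export
convertSpectrum <- function(raw, db, calibration = publishedCalibration()) {
  f <- standardizeSpectrum(raw)
  dec <- decomposeSpectrum(f, db)
  rec <- reconstructComposition(dec, db)
  chan <- paste0("f", calibrationChannel(calibration))
  raw <- raw[channelNames()]
  list(composition = rec$composition,
       tchla = estimateTChla(unname(raw[chan]), calibration),
       diagnostics = list(alphaSum = rec$alphaSum,
                          residualNorm = dec$residualNorm,
                          nActive = dec$nActive,
                          maxSpectralCor = dec$maxSpectralCor))
}
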