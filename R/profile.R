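#' Segment a raw cast into observations
#'
#' An \emph{observation} is a maximal contiguous run of records with sensor
#' depth >= \code{minDepth} lasting at least \code{minDuration}. Runs are
#' broken by any record shallower than the threshold (no gap tolerance by
#' default; \code{maxGap} seconds of shallow records can be bridged if set).
#' Shorter runs are discarded. Used to split multi-station files into
#' per-station profiles.
#'
#' @param cast data.frame with columns time_s, depth_m, temp_c and the nine
#'   channel columns (see [readCast()]).
#' @param minDepth depth threshold (m), default 2.
#' @param minDuration minimum run duration (s), default 300.
#' @param maxGap tolerated interruption (s), default 0.
#' @return list of casts (possibly empty), each a data.frame like the input.
#' @export
segmentObservations <- function(cast, minDepth = 2, minDuration = 300,
                                maxGap = 0) {
  if (!nrow(cast)) stop("empty cast")
  deep <- cast$depth_m >= minDepth
  r <- rle(deep)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  if (maxGap > 0 && length(r$values) > 2) {
    # bridge shallow interruptions shorter than maxGap seconds
    for (k in which(!r$values)) {
      if (k == 1 || k == length(r$values)) next
      if (cast$time_s[ends[k]] - cast$time_s[starts[k]] <= maxGap)
        r$values[k] <- TRUE
    }
    deep <- inverse.rle(r)
    r <- rle(deep); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  }
  segs <- lapply(which(r$values), function(k) cast[starts[k]:ends[k], ])
  keep <- vapply(segs, function(s)
    (max(s$time_s) - min(s$time_s)) >= minDuration, logical(1))
  segs[keep]
}

#' Despike a cast by 1-second medians
#'
#' Reduces the 10 Hz record to 1 Hz by taking, within every whole-second
#' window, the median of each channel, depth and temperature. Medians of
#' even-length windows are midpoint averages (the stats::median convention).
#' The output timestamp is the window start.
#'
#' @param cast data.frame as in [segmentObservations()].
#' @return data.frame at 1 Hz with the same columns.
#' @export
medianResample1s <- function(cast) {
  if (!nrow(cast)) stop("empty cast")
  win <- floor(cast$time_s)
  num <- setdiff(names(cast), "time_s")
  agg <- lapply(split(seq_len(nrow(cast)), win), function(i)
    vapply(cast[i, num, drop = FALSE], median, numeric(1)))
  out <- as.data.frame(do.call(rbind, agg))
  out$time_s <- as.numeric(names(agg))
  out[order(out$time_s), c("time_s", num)]
}

#' Bin an observation to 1-m depth resolution and convert
#'
#' Assigns every 1-s record to a half-open depth bin [k, k+1) m (a sample at
#' exactly 3.0 m falls in [3,4)), averages the raw channels per bin, and runs
#' the spectral conversion on each bin-mean spectrum: composition via
#' [convertSpectrum()], TChla_MEX from the bin-mean raw fluorescence at the
#' calibration channel.
#'
#' @param cast 1 Hz observation (from [medianResample1s()]).
#' @param db a [ReferenceDatabase-class].
#' @param calibration a [CalibrationModel-class].
#' @param binSize bin width (m), default 1.
#' @param minDepth shallowest bin edge (m), default 2.
#' @return data.frame (the binned profile): depth (bin lower edge, m),
#'   tchla (ug/L), nine group-fraction columns, n (records in the bin).
#'   Empty bins inside the covered range are absent (interpolated later by
#'   [integrateWaterColumn()]).
#' @export
binProfile1m <- function(cast, db, calibration = publishedCalibration(),
                         binSize = 1, minDepth = 2) {
  cast <- cast[cast$depth_m >= minDepth, , drop = FALSE]
  if (!nrow(cast)) stop("no records at or below the minimum depth")
  bin <- floor((cast$depth_m - minDepth) / binSize) * binSize + minDepth
  rows <- lapply(split(seq_len(nrow(cast)), bin), function(i) {
    spec <- colMeans(cast[i, channelNames(), drop = FALSE])
    conv <- convertSpectrum(spec, db, calibration)
    c(depth = bin[i[1]], tchla = conv$tchla, conv$composition,
      n = length(i))
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$depth), ]
}

#' Quartile coefficient of dispersion
#'
#' \code{(Q3 - Q1) / (Q3 + Q1)} with quartiles by linear interpolation
#' between order statistics (quantile type 7). Used as a vertical
#' heterogeneity index of a group's proportion over depth: 0 for a constant
#' profile, approaching 1 for strongly layered ones.
#'
#' @param values numeric vector (>= 4 values, >= 0).
#' @return scalar QCoD, or \code{NA} (with a warning) when Q1 + Q3 = 0.
#' @export
qcod <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  if (anyNA(values)) stop("values must not contain NA")
  q <- quantile(values, c(0.25, 0.75), names = FALSE)
  if (sum(q) == 0) { warning("QCoD undefined: Q1 + Q3 = 0"); return(NA_real_) }
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Heterogeneity threshold from a QCoD population
#'
#' The screening threshold for \emph{high} vertical heterogeneity is the
#' mean plus twice the standard deviation of all observed QCoD values.
#'
#' @param meanQcod,sdQcod summary statistics of the QCoD population.
#' @return scalar threshold.
#' @examples
#' qcodThreshold(0.134, 0.0912)
#' @export
qcodThreshold <- function(meanQcod, sdQcod) meanQcod + 2 * sdQcod

#' Vertical-heterogeneity report over a set of profiles
#'
#' Computes the QCoD of every group's proportion over depth for each binned
#' profile, sets the threshold at mean + 2 sd of all defined QCoD values,
#' and flags profile x group combinations above it.
#'
#' @param profiles list of binned profiles (from [binProfile1m()]), >= 2.
#' @return list with \code{qcod} (profiles x groups matrix),
#'   \code{threshold}, \code{flags} (logical matrix), \code{nUndefined}.
#' @export
heterogeneityReport <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  qm <- t(vapply(profiles, function(pr)
    vapply(taxonGroups(), function(g)
      suppressWarnings(qcod(pr[[g]])), numeric(1)),
    numeric(9)))
  colnames(qm) <- taxonGroups()
  vals <- qm[!is.na(qm)]
  thr <- qcodThreshold(mean(vals), sd(vals))
  list(qcod = qm, threshold = thr,
       flags = !is.na(qm) & qm > thr,
       nUndefined = sum(is.na(qm)))
}

#' Water-column integrated group biomass
#'
#' Integrates \code{fraction x TChla_MEX} per group over depth by the
#' trapezoidal rule on the profile's bin grid, restricted to
#' [\code{zmin}, \code{zmax}]. Missing bins are linearly interpolated;
#' beyond the outermost bins the edge values are held constant. Because the
#' same piecewise-linear grid is used for every group and fractions sum to 1
#' at each node, group integrals add up exactly to the TChla integral.
#'
#' @param profile binned profile (from [binProfile1m()]).
#' @param zmin,zmax integration limits (m); \code{zmax} defaults to the
#'   deepest bin.
#' @return list with \code{integrated} (named, mg/m^2), \code{total}
#'   (TChla integral, mg/m^2) and \code{shares} (each group's fraction of
#'   the total).
#' @export
integrateWaterColumn <- function(profile, zmin = 2, zmax = max(profile$depth)) {
  if (zmax <= zmin) stop("zmax must exceed zmin")
  d <- profile$depth
  if (sum(d >= zmin & d <= zmax) < 2)
    stop("need at least 2 bins inside [zmin, zmax]")
  if (zmin < min(d) - 1 || zmax > max(d) + 1)
    stop("integration range extends beyond profile coverage")
  grid <- sort(unique(c(zmin, d[d > zmin & d < zmax], zmax)))
  interp <- function(v) approx(d, v, xout = grid, rule = 2)$y
  gInt <- vapply(taxonGroups(), function(g)
    pracma::trapz(grid, interp(profile[[g]] * profile$tchla)), numeric(1))
  tot <- pracma::trapz(grid, interp(profile$tchla))
  list(integrated = gInt, total = tot,
       shares = if (tot > 0) gInt / sum(gInt) else gInt * NA)
}

#' Ordination of observations by community similarity
#'
#' Bray-Curtis dissimilarities among observations (rows of group shares)
#' embedded in two dimensions by non-metric multidimensional scaling
#' (Kruskal stress-1, monotone regression, seeded random restarts,
#' best-of-restarts returned), via \code{vegan::metaMDS}.
#'
#' @param shares matrix of observations x group shares (rows >= 4, summing
#'   to ~1).
#' @param seed integer seed.
#' @param tries random restarts (default 20).
#' @return list with \code{points} (n x 2 coordinates), \code{stress}
#'   (Kruskal stress-1) and \code{dist} (the Bray-Curtis \code{dist}).
#' @export
stationSimilarity <- function(shares, seed = 1L, tries = 20L) {
  shares <- as.matrix(shares)
  if (nrow(shares) < 4) stop("need at least 4 observations")
  dd <- vegan::vegdist(shares, method = "bray")
  set.seed(seed)
  fit <- vegan::metaMDS(dd, k = 2, try = tries, trymax = tries,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress, dist = dd)
}
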