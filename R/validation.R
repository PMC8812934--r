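# convert one standardized spectrum against a database view; NULL if the
# view has no active record
.convertStd <- function(f, db) {
  rec <- reconstructComposition(decomposeSpectrum(f, db), db)
  rec$composition
}

#' Leave-one-out cross-validation of the spectral conversion
#'
#' For every active record j, converts its spectrum against the database from
#' which all records sharing j's (cruise, station, depth_m) key have been
#' removed — so replicate bottles from the same water never inform their own
#' estimate. Returns the estimated compositions (\code{p_test}) aligned with
#' the pigment-based truth (\code{P}).
#'
#' @param db a [ReferenceDatabase-class] with at least two distinct
#'   (cruise, station, depth_m) keys among active records.
#' @return list with matrices \code{estimated} and \code{truth} (records x 9),
#'   \code{index} (active record indices) and \code{excluded} (per record,
#'   how many references were withheld).
#' @export
loocvConversion <- function(db) {
  idx <- activeRecords(db)
  meta <- refMetadata(db)
  key <- paste(meta$cruise, meta$station, meta$depth_m, sep = "/")[idx]
  if (length(unique(key)) < 2)
    stop("need at least 2 distinct (cruise, station, depth) keys")
  act <- db[idx]  # active view; indices now 1..n
  est <- matrix(NA_real_, length(idx), 9,
                dimnames = list(NULL, taxonGroups()))
  excl <- integer(length(idx))
  for (j in seq_along(idx)) {
    keep <- key != key[j]
    excl[j] <- sum(!keep)
    sub <- act[keep]
    est[j, ] <- .convertStd(refSpectra(act)[j, ], sub)
  }
  list(estimated = est, truth = refCompositions(act), index = idx,
       excluded = excl)
}

#' Leave-area-out cross-validation of the spectral conversion
#'
#' Converts every active record against only the references collected in
#' \emph{other} areas, probing whether the conversion transfers across water
#' masses rather than interpolating within one.
#'
#' @param db a [ReferenceDatabase-class] with >= 2 areas among active records.
#' @return as [loocvConversion()], plus \code{area} per record.
#' @export
leaveAreaOutConversion <- function(db) {
  idx <- activeRecords(db)
  area <- as.character(refMetadata(db)$area)[idx]
  if (length(unique(area)) < 2) stop("need at least 2 areas")
  act <- db[idx]
  est <- matrix(NA_real_, length(idx), 9,
                dimnames = list(NULL, taxonGroups()))
  excl <- integer(length(idx))
  for (j in seq_along(idx)) {
    keep <- area != area[j]
    excl[j] <- sum(!keep)
    est[j, ] <- .convertStd(refSpectra(act)[j, ], act[keep])
  }
  list(estimated = est, truth = refCompositions(act), index = idx,
       excluded = excl, area = area)
}

#' Per-group agreement statistics between estimated and true compositions
#'
#' For each group: ordinary least-squares regression of the estimated on the
#' true proportion (slope, t-value, p-value, r-squared), the mean absolute
#' difference, and the 95% interval half-width of the differences. Both an
#' empirical (percentile) and a normal (1.96 sd) half-width are reported;
#' the percentile version is primary because difference distributions are
#' often skewed. Proportions are compared on the percent scale.
#'
#' @param estimated,truth matrices (pairs x 9 groups), fractions in [0, 1].
#' @return data.frame, one row per group: n, slope, t, p, r2, meanAbsDiff
#'   (percent points), ciHalfWidth (percentile, percent points),
#'   ciHalfWidthNormal, skipped (TRUE where the truth had zero variance).
#' @export
comparisonStats <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  if (!all(dim(estimated) == dim(truth)))
    stop("estimated and truth must have identical shape")
  if (nrow(truth) < 3) stop("need at least 3 pairs")
  groups <- colnames(truth)
  out <- lapply(groups, function(g) {
    x <- truth[, g] * 100; y <- estimated[, g] * 100
    d <- y - x
    row <- data.frame(group = g, n = length(x), slope = NA_real_,
                      t = NA_real_, p = NA_real_, r2 = NA_real_,
                      meanAbsDiff = mean(abs(d)),
                      ciHalfWidth = unname(diff(quantile(d, c(0.025, 0.975))) / 2),
                      ciHalfWidthNormal = 1.96 * sd(d),
                      skipped = FALSE)
    if (sd(x) == 0) { row$skipped <- TRUE; return(row) }
    fit <- summary(lm(y ~ x))
    row$slope <- fit$coefficients["x", "Estimate"]
    row$t <- fit$coefficients["x", "t value"]
    row$p <- fit$coefficients["x", "Pr(>|t|)"]
    row$r2 <- fit$r.squared
    row
  })
  do.call(rbind, out)
}

#' Bootstrap sensitivity of the conversion to the reference set
#'
#' For each active record j, the leave-one-out reference set (all records
#' sharing j's sampling key withheld) is resampled with replacement R times;
#' j's spectrum is converted against every replicate, and the coefficient of
#' variation of the estimated proportion is computed per group
#' (\code{CV_jm}, percent). Group-level summaries are the mean and sd of
#' \code{CV_jm} and the upper 95% limit mean + 2 sd. Low values mean the
#' conversion does not hinge on a handful of reference records. Fully
#' reproducible for a fixed seed.
#'
#' @param db a [ReferenceDatabase-class] with >= 10 active records.
#' @param R bootstrap replicates (default 1000).
#' @param seed integer seed (required).
#' @return list with \code{cvJM} (records x groups, percent), \code{summary}
#'   (data.frame: group, meanCV, sdCV, upper95), \code{R}, \code{seed}.
#' @export
bootstrapSensitivity <- function(db, R = 1000L, seed) {
  if (missing(seed)) stop("seed is required")
  if (R < 2) stop("R must be >= 2")
  idx <- activeRecords(db)
  if (length(idx) < 10) stop("need at least 10 active records")
  set.seed(seed)
  act <- db[idx]
  meta <- refMetadata(act)
  key <- paste(meta$cruise, meta$station, meta$depth_m, sep = "/")
  cvJM <- matrix(NA_real_, length(idx), 9,
                 dimnames = list(NULL, taxonGroups()))
  for (j in seq_along(idx)) {
    pool <- which(key != key[j])
    if (!length(pool)) stop("record ", idx[j], " would empty the database")
    f <- refSpectra(act)[j, ]
    ps <- matrix(NA_real_, R, 9)
    for (r in seq_len(R)) {
      take <- sample(pool, length(pool), replace = TRUE)
      ps[r, ] <- .convertStd(f, act[take])
    }
    mu <- colMeans(ps); s <- apply(ps, 2, sd)
    cvJM[j, ] <- ifelse(mu > 0, 100 * s / mu, 0)
  }
  sm <- data.frame(group = taxonGroups(),
                   meanCV = colMeans(cvJM),
                   sdCV = apply(cvJM, 2, sd))
  sm$upper95 <- sm$meanCV + 2 * sm$sdCV
  list(cvJM = cvJM, summary = sm, R = as.integer(R), seed = seed)
}

#' PERMANOVA of compositions against the nine fluorescence channels
#'
#' Tests how much of the variation among pigment-based compositions the
#' standardized fluorescence explains: sequential (type-I) PERMANOVA of the
#' Bray-Curtis distances among active-record compositions on the nine
#' standardized channel values, in wavelength order.
#'
#' @param db a [ReferenceDatabase-class] with >= 10 active records.
#' @param nPerm permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return list with \code{table} (term, df, R2, F, p), \code{sumR2} (over
#'   channel terms), \code{residualR2} and \code{skipped} (constant channels
#'   dropped from the model).
#' @export
permanovaFluorescence <- function(db, nPerm = 1000L, seed = 1L) {
  idx <- activeRecords(db)
  if (length(idx) < 10) stop("need at least 10 active records")
  comp <- refCompositions(db)[idx, , drop = FALSE]
  ch <- as.data.frame(refSpectra(db)[idx, , drop = FALSE])
  keep <- vapply(ch, function(v) sd(v) > 0, logical(1))
  skipped <- names(ch)[!keep]
  ch <- ch[, keep, drop = FALSE]
  if (!ncol(ch)) stop("all channel predictors are constant")
  fm <- stats::as.formula(paste("comp ~", paste(names(ch), collapse = " + ")))
  set.seed(seed)
  av <- vegan::adonis2(fm, data = ch, permutations = nPerm,
                       method = "bray", by = "terms")
  tab <- data.frame(term = rownames(av), df = av$Df, R2 = av$R2,
                    F = av$F, p = av$`Pr(>F)`)
  chTerms <- tab$term %in% names(ch)
  list(table = tab,
       sumR2 = sum(tab$R2[chTerms]),
       residualR2 = tab$R2[tab$term == "Residual"],
       skipped = skipped)
}
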