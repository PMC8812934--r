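#' Estimate a nine-group chemotaxonomic composition from marker pigments
#'
#' Attributes the chlorophyll-a biomass of a water sample to nine algal
#' groups by compositional linear inversion. The non-negative group
#' chlorophyll vector \code{x} minimising
#' \deqn{\| pigments - x^T (ratios/100) \|_2, \quad x \ge 0}
#' is found by non-negative least squares (Lawson-Hanson, via
#' \code{pracma::lsqnonneg}); group fractions are \code{x / sum(x)}. The
#' misfit is computed on raw concentrations (ug/L), unweighted. Neoxanthin
#' and lutein, though routinely measured by HPLC, carry no ratio-matrix
#' column and are ignored by the fit.
#'
#' @param pigments named numeric vector of pigment concentrations (ug/L);
#'   must contain the eleven \code{ratioPigments()} (extra names are
#'   tolerated and ignored).
#' @param ratios ratio matrix, default [defaultRatioMatrix()].
#' @return list with components \code{fractions} (named, sums to 1),
#'   \code{groupChla} (absolute contributions, ug/L), \code{residual}
#'   (Euclidean pigment misfit) and \code{tchla} (MVChla + DVChla of the
#'   input).
#' @examples
#' p <- setNames(numeric(11), ratioPigments())
#' p["Fuc"] <- 0.75; p["MVChla"] <- 1
#' estimateComposition(p)$fractions["diatoms"]
#' @export
estimateComposition <- function(pigments, ratios = defaultRatioMatrix()) {
  b <- .checkNamedNonneg(pigments, ratioPigments(), "pigments")
  if (sum(b) == 0)
    stop("undefined composition: all pigment concentrations are zero")
  A <- t(ratios[, ratioPigments(), drop = FALSE] / 100)  # 11 x 9
  fit <- pracma::lsqnonneg(A, as.numeric(b))
  x <- setNames(pmax(fit$x, 0), rownames(ratios))
  if (sum(x) == 0)
    stop("undefined composition: no group can explain the pigment vector")
  list(fractions = x / sum(x),
       groupChla = x,
       residual = sqrt(sum((A %*% x - b)^2)),
       tchla = unname(b["MVChla"] + b["DVChla"]))
}

#' Estimate compositions for a table of pigment samples
#'
#' Row-wise [estimateComposition()] with per-row error isolation: a row that
#' fails (e.g. all-zero pigments) is flagged and reported, the rest of the
#' batch is computed.
#'
#' @param samples data.frame with the eleven \code{ratioPigments()} columns
#'   (e.g. from [readPigmentTable()]); extra columns are carried through
#'   untouched.
#' @param ratios ratio matrix.
#' @return list with \code{fractions} (n x 9 matrix, NA rows where failed),
#'   \code{groupChla} (n x 9), \code{ok} (logical), \code{errors} (character,
#'   "" where ok).
#' @export
batchEstimateComposition <- function(samples, ratios = defaultRatioMatrix()) {
  if (!is.data.frame(samples) || nrow(samples) == 0)
    stop("samples must be a non-empty data.frame")
  n <- nrow(samples)
  groups <- rownames(ratios)
  fr <- ch <- matrix(NA_real_, n, length(groups),
                     dimnames = list(NULL, groups))
  ok <- logical(n); errs <- character(n)
  for (i in seq_len(n)) {
    p <- unlist(samples[i, ratioPigments(), drop = TRUE])
    res <- tryCatch(estimateComposition(p, ratios), error = identity)
    if (inherits(res, "error")) {
      errs[i] <- conditionMessage(res)
    } else {
      fr[i, ] <- res$fractions; ch[i, ] <- res$groupChla; ok[i] <- TRUE
    }
  }
  list(fractions = fr, groupChla = ch, ok = ok, errors = errs)
}

#' Merge chemotaxonomic groups into coarser assemblages
#'
#' Standard merges used when individual groups are not separable from the
#' fluorescence signal: \code{"eukaryotes_merge"} pools chlorophytes,
#' prasinophytes and both haptophyte types into \code{eukaryotes};
#' \code{"cyanobacteria_merge"} pools cyanophytes and prochlorophytes into
#' \code{cyanobacteria}; \code{"both"} applies both. Totals are preserved.
#'
#' @param p named composition vector over \code{taxonGroups()} (fractions or
#'   absolute chlorophyll), or a matrix with one composition per row.
#' @param scheme one of \code{"eukaryotes_merge"}, \code{"cyanobacteria_merge"},
#'   \code{"both"}.
#' @return merged composition (vector or matrix matching the input shape).
#' @export
aggregateGroups <- function(p, scheme = c("eukaryotes_merge",
                                          "cyanobacteria_merge", "both")) {
  scheme <- match.arg(scheme)
  one <- is.null(dim(p))
  m <- if (one) matrix(p, 1, dimnames = list(NULL, names(p))) else as.matrix(p)
  if (!all(taxonGroups() %in% colnames(m)))
    stop("composition must cover all nine groups")
  m <- m[, taxonGroups(), drop = FALSE]
  euk <- c("chlorophytes", "prasinophytes", "haptophytes3", "haptophytes4")
  cya <- c("cyanophytes", "prochlorophytes")
  merge1 <- function(m, members, name) {
    pooled <- rowSums(m[, members, drop = FALSE])
    keep <- m[, setdiff(colnames(m), members), drop = FALSE]
    cbind(keep, matrix(pooled, ncol = 1, dimnames = list(NULL, name)))
  }
  if (scheme %in% c("eukaryotes_merge", "both")) m <- merge1(m, euk, "eukaryotes")
  if (scheme %in% c("cyanobacteria_merge", "both")) m <- merge1(m, cya, "cyanobacteria")
  if (one) m[1, ] else m
}
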