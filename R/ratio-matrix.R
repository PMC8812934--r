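#' Load the default pigment:chlorophyll ratio matrix
#'
#' Returns the fixed 9 group x 11 pigment matrix of marker-pigment ratios,
#' expressed as pigment units per 100 units of chlorophyll a. Every group
#' carries \code{MVChla = 100} except prochlorophytes, whose chlorophyll is
#' divinyl (\code{DVChla = 100}, \code{MVChla = 0}). The matrix is held fixed
#' throughout: no CHEMTAX-style iterative re-optimisation of the ratios is
#' performed.
#'
#' @return numeric matrix with rownames \code{taxonGroups()} and colnames
#'   \code{ratioPigments()}.
#' @seealso [estimateComposition()] which inverts a pigment vector against
#'   this matrix; [readRatioMatrix()] for user-supplied ratio tables.
#' @examples
#' rm <- defaultRatioMatrix()
#' rm["diatoms", "Fuc"]
#' @export
defaultRatioMatrix <- function() {
  path <- system.file("extdata", "ratio_matrix.csv", package = "fluorotax",
                      mustWork = TRUE)
  readRatioMatrix(path)
}

#' Read a ratio matrix from CSV
#'
#' The expected layout is one header row of pigment names, a leading
#' \code{group} column, and one row per chemotaxonomic group. The matrix is
#' validated: entries non-negative, exactly one of MVChla/DVChla equal to 100
#' per group.
#'
#' @param path CSV file path.
#' @return validated ratio matrix (groups x pigments).
#' @export
readRatioMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) stop("ratio matrix CSV needs a 'group' column")
  m <- as.matrix(df[, setdiff(names(df), "group"), drop = FALSE])
  rownames(m) <- df$group
  validateRatioMatrix(m)
  m
}

#' Validate a ratio matrix
#'
#' @param m numeric matrix, groups x pigments.
#' @return invisibly \code{TRUE}; stops with a message on violation.
#' @export
validateRatioMatrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("ratio matrix must be numeric")
  miss <- setdiff(ratioPigments(), colnames(m))
  if (length(miss)) stop("ratio matrix missing pigments: ",
                         paste(miss, collapse = ", "))
  if (anyNA(m) || any(m < 0)) stop("ratio matrix entries must be >= 0")
  mv <- m[, "MVChla"]; dv <- m[, "DVChla"]
  ok <- (mv == 100 & dv == 0) | (mv == 0 & dv == 100)
  if (!all(ok))
    stop("each group must have exactly one of MVChla/DVChla equal to 100: ",
         paste(rownames(m)[!ok], collapse = ", "))
  invisible(TRUE)
}

#' Forward pigment model
#'
#' Computes the marker-pigment concentrations implied by a group composition
#' and total chlorophyll: \code{pigments = TChla * composition %*% ratios/100}.
#' This is the generative counterpart of [estimateComposition()] and the
#' backbone of the synthetic-data generator and recovery tests.
#'
#' @param composition named fractions over \code{taxonGroups()} (summing to
#'   1), or a matrix with one composition per row.
#' @param tchla total chlorophyll a (ug/L); scalar or one value per row.
#' @param ratios ratio matrix, default [defaultRatioMatrix()].
#' @return named pigment vector (ug/L), or a matrix with one row per input
#'   composition.
#' @export
forwardPigments <- function(composition, tchla = 1, ratios = defaultRatioMatrix()) {
  one <- is.null(dim(composition))
  q <- if (one) matrix(composition, nrow = 1,
                       dimnames = list(NULL, names(composition)))
       else as.matrix(composition)
  q <- q[, rownames(ratios), drop = FALSE]
  out <- (q * tchla) %*% (ratios / 100)
  if (one) out[1, ] else out
}
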