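# Independent brute-force oracles and tiny fixture builders.

# Coarse-to-fine grid search for min ||M a - f||, a in [0,1]^n (n <= 3).
# The objective is convex, so refining around the coarse optimum cannot miss
# the global minimum; the effective step of the final grid is `step`.
gridDecompose <- function(M, f, step = 0.001, coarse = 0.02) {
  n <- ncol(M)
  evalGrid <- function(ranges) {
    vals <- lapply(ranges, function(r) seq(r[1], r[2], by = r[3]))
    A <- as.matrix(expand.grid(vals))
    pred <- A %*% t(M)
    sse <- rowSums((pred - matrix(f, nrow(pred), length(f), byrow = TRUE))^2)
    A[which.min(sse), ]
  }
  a0 <- evalGrid(replicate(n, c(0, 1, coarse), simplify = FALSE))
  ranges <- lapply(seq_len(n), function(j)
    c(max(0, a0[j] - coarse), min(1, a0[j] + coarse), step))
  unname(evalGrid(ranges))
}

# Grid-search oracle for the non-negative pigment inversion with <= 3 active
# groups: minimizes ||A x - b|| over x in [0, xmax]^k (convex, coarse-to-fine).
gridNNLS <- function(A, b, active, xmax, step = 0.001, coarse = 0.02) {
  k <- length(active)
  evalGrid <- function(ranges) {
    vals <- lapply(ranges, function(r) seq(r[1], r[2], by = r[3]))
    X <- as.matrix(expand.grid(vals))
    pred <- X %*% t(A[, active, drop = FALSE])
    sse <- rowSums((pred - matrix(b, nrow(pred), length(b), byrow = TRUE))^2)
    X[which.min(sse), ]
  }
  x0 <- evalGrid(replicate(k, c(0, xmax, coarse * xmax), simplify = FALSE))
  ranges <- lapply(seq_len(k), function(j)
    c(max(0, x0[j] - coarse * xmax), min(xmax, x0[j] + coarse * xmax),
      step * xmax))
  unname(evalGrid(ranges))
}

# Tiny ReferenceDatabase from raw spectra + composition rows.
tinyDb <- function(spectra, comps, tchla = NULL, area = NULL,
                   station = NULL, depth = NULL, outlier = NULL) {
  n <- nrow(spectra)
  colnames(spectra) <- channelNames()
  colnames(comps) <- taxonGroups()
  ReferenceDatabase(
    spectra, comps,
    tchla = if (is.null(tchla)) rep(1, n) else tchla,
    metadata = data.frame(
      cruise = "T1",
      station = if (is.null(station)) sprintf("S%02d", seq_len(n)) else station,
      depth_m = if (is.null(depth)) rep(10, n) else depth,
      area = if (is.null(area)) rep(c("A", "B"), length.out = n) else area,
      season = "spring"),
    outlier = if (is.null(outlier)) rep(FALSE, n) else outlier)
}

# n well-separated standardized spectra (rows) for decomposition fixtures.
randomSpectra <- function(n, peaked = TRUE) {
  m <- matrix(runif(n * 9, 0.2, 1), n)
  if (peaked) for (i in seq_len(n)) m[i, 1 + (i * 3) %% 9] <- 4 + i
  m / rowSums(m)
}

# pure-group composition vector
pureComp <- function(group) {
  setNames(as.numeric(taxonGroups() == group), taxonGroups())
}

# simplex-uniform weights for mixture fixtures
.rdirichletTest <- function(n) { g <- rgamma(n, 1); g / sum(g) }
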