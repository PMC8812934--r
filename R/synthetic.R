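#' Synthetic group-specific excitation endmember spectra
#'
#' Builds nine distinct standardized nine-channel spectra, one per
#' chemotaxonomic group, as sums of Gaussian bumps over wavelength. These are
#' \emph{synthetic} shapes constrained by qualitative bio-optics, not
#' measured excitation spectra: every group excites broadly in the
#' chlorophyll-a blue band (435-470 nm); dinoflagellates carry an elevated
#' 505 nm response relative to diatoms (peridinin-chlorophyll protein);
#' cyanophytes and prochlorophytes carry elevated 570/590 nm responses
#' (phycobilin excitation). A small seeded jitter keeps the endmember matrix
#' well conditioned; pairwise correlations are checked to be < 0.999 at
#' generation time.
#'
#' @param seed integer seed for the jitter.
#' @return 9 x 9 matrix (groups x channels), rows standardized to sum 1.
#' @export
makeEndmemberSpectra <- function(seed = 1L) {
  wl <- mexChannels()
  bump <- function(a, mu, s) a * exp(-((wl - mu)^2) / (2 * s^2))
  shapes <- list(
    diatoms         = bump(1, 435, 20) + bump(0.85, 470, 18) + bump(0.25, 505, 15),
    haptophytes3    = bump(0.80, 400, 16) + bump(1, 435, 18) + bump(0.45, 465, 15),
    haptophytes4    = bump(0.45, 400, 14) + bump(0.80, 435, 16) + bump(1, 487, 13),
    dinoflagellates = bump(0.70, 435, 18) + bump(0.40, 470, 15) +
                      bump(1, 503, 13) + bump(0.25, 525, 14),
    cryptophytes    = bump(0.55, 435, 18) + bump(0.85, 525, 15) + bump(0.65, 565, 14),
    prasinophytes   = bump(0.75, 375, 13) + bump(0.60, 420, 13) + bump(1, 452, 12),
    chlorophytes    = bump(0.15, 375, 12) + bump(0.35, 420, 12) +
                      bump(0.45, 435, 14) + bump(1, 475, 11),
    cyanophytes     = bump(0.30, 435, 20) + bump(0.55, 570, 14) + bump(1, 592, 16),
    prochlorophytes = bump(0.70, 375, 14) + bump(0.80, 400, 14) +
                      bump(1, 447, 16) + bump(0.22, 590, 20)
  )
  E <- do.call(rbind, shapes)
  set.seed(seed)
  E <- E * matrix(exp(rnorm(length(E), 0, 0.02)), nrow(E))
  E <- E / rowSums(E)
  dimnames(E) <- list(taxonGroups(), channelNames())
  cm <- cor(t(E))
  if (max(cm[upper.tri(cm)]) >= 0.999)
    stop("endmember spectra too collinear for identification")
  E
}

#' Community archetypes of the composition simulator
#'
#' Four canonical assemblages spanning the compositional variation the
#' simulator generates: a diatom \code{bloom} community, an oligotrophic
#' \code{pico} community (prochlorophytes/cyanophytes), a green/nano-flagellate
#' \code{nano} community (chlorophytes, prasinophytes, haptophytes) and a
#' dinoflagellate/cryptophyte \code{coastal} community. Simulated compositions
#' are convex mixtures of these rows: phytoplankton succession is treated as
#' movement along gradients between recurring community states, so the
#' assemblages of different samples covary the way field assemblages do
#' instead of filling the nine-group simplex uniformly.
#'
#' @return 4 x 9 matrix (archetypes x groups), rows summing to 1.
#' @export
communityArchetypes <- function() {
  A <- rbind(
    bloom   = c(.62, .04, .07, .08, .06, .04, .04, .03, .02),
    pico    = c(.04, .14, .06, .03, .03, .05, .05, .20, .40),
    nano    = c(.05, .15, .15, .04, .07, .15, .30, .05, .04),
    coastal = c(.13, .05, .08, .27, .25, .06, .09, .05, .02))
  colnames(A) <- taxonGroups()
  A
}

#' Simulation configuration
#'
#' Bundles the parameters of the reference-database simulator. Defaults echo
#' the structure of the field reference set: 271 samples over 4 areas with
#' area-specific assemblage tendencies (diatom-heavy subarctic "Oyashio" and
#' "Okhotsk" areas, a picoplankton/prochlorophyte-heavy subtropical
#' "Kuroshio" area, a small-eukaryote-heavy "JS" area), 5% multiplicative
#' spectral noise, 2% pigment noise (HPLC replicate precision) and TChla
#' log-uniform between 0.05 and 5 ug/L. Compositions are Dirichlet mixtures
#' of the [communityArchetypes()]: per sample, archetype weights are drawn
#' from the area's Dirichlet and multiplied into the archetype matrix.
#'
#' @param nSamples number of reference pairs (default 271).
#' @param areas area labels (default Kuroshio, JS, Okhotsk, Oyashio).
#' @param dirichletAlpha named list of per-area Dirichlet concentration
#'   vectors over the archetype weights; \code{NULL} for the defaults.
#' @param archetypes archetype matrix (default [communityArchetypes()]).
#' @param spectralNoiseSD sd of multiplicative (lognormal) channel noise
#'   (default 0.05).
#' @param pigmentNoiseSD sd of multiplicative pigment noise (default 0.02).
#' @param tchlaRange range of TChla (ug/L), sampled log-uniformly.
#' @param gain instrument gain: raw fluorescence per (mixture x TChla) unit.
#' @param seed integer seed (mandatory).
#' @return list of class \code{simConfig}.
#' @export
simulationConfig <- function(nSamples = 271L,
                             areas = c("Kuroshio", "JS", "Okhotsk", "Oyashio"),
                             dirichletAlpha = NULL,
                             archetypes = communityArchetypes(),
                             spectralNoiseSD = 0.05,
                             pigmentNoiseSD = 0.02,
                             tchlaRange = c(0.05, 5),
                             gain = 2,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (nSamples < 1) stop("nSamples must be >= 1")
  if (spectralNoiseSD < 0 || pigmentNoiseSD < 0) stop("noise sds must be >= 0")
  k <- nrow(archetypes)
  if (is.null(dirichletAlpha)) {
    defaults <- list(                   #  bloom pico nano coastal
      Kuroshio = c(0.8, 6.0, 2.0, 0.8),
      JS       = c(1.0, 1.0, 6.0, 1.5),
      Okhotsk  = c(5.0, 0.5, 1.5, 1.5),
      Oyashio  = c(6.0, 0.5, 1.5, 1.0))
    dirichletAlpha <- lapply(seq_along(areas), function(i)
      if (areas[i] %in% names(defaults)) defaults[[areas[i]]]
      else rep(2, k))
    names(dirichletAlpha) <- areas
  }
  if (any(lengths(dirichletAlpha) != k))
    stop("each dirichletAlpha must have one entry per archetype")
  structure(list(nSamples = as.integer(nSamples), areas = areas,
                 dirichletAlpha = dirichletAlpha, archetypes = archetypes,
                 spectralNoiseSD = spectralNoiseSD,
                 pigmentNoiseSD = pigmentNoiseSD,
                 tchlaRange = tchlaRange, gain = gain, seed = as.integer(seed)),
            class = "simConfig")
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a reference database with known ground truth
#'
#' Generates paired pigment samples and raw spectra under the model the
#' conversion assumes: per sample an area-specific Dirichlet draw of
#' archetype weights mixed into the [communityArchetypes()] to give the
#' composition q, pigments from the ratio-matrix forward model with
#' multiplicative lognormal noise, and a raw spectrum as the q-weighted
#' mixture of the group endmember spectra scaled by TChla and gain, with
#' multiplicative channel noise. A robust TChla calibration is then fitted on the simulated
#' pairs (channel selected by r-squared) and the reference database is built
#' exactly as it would be from field data. Fully deterministic for a fixed
#' seed.
#'
#' @param config a [simulationConfig()].
#' @return list with \code{db} (a [ReferenceDatabase-class]), \code{truth}
#'   (n x 9 matrix of simulated compositions), \code{calibration} (the fitted
#'   [CalibrationModel-class]), \code{endmembers}, \code{pigments} (the
#'   simulated pigment table) and \code{spectraRaw}.
#' @export
simulateReferenceDb <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  E <- makeEndmemberSpectra(config$seed)
  n <- config$nSamples
  area <- rep(config$areas, length.out = n)
  q <- t(vapply(area, function(a)
    as.numeric(.rdirichlet(config$dirichletAlpha[[a]]) %*% config$archetypes),
    numeric(9)))
  colnames(q) <- taxonGroups()
  lo <- log(config$tchlaRange[1]); hi <- log(config$tchlaRange[2])
  tchla <- exp(runif(n, lo, hi))
  pig <- forwardPigments(q, tchla)
  pig <- pig * matrix(rlnorm(length(pig), 0, config$pigmentNoiseSD), n)
  spec <- (q %*% E) * tchla * config$gain
  spec <- spec * matrix(rlnorm(length(spec), 0, config$spectralNoiseSD), n)
  colnames(spec) <- channelNames()
  pigDf <- data.frame(pig, check.names = FALSE)
  for (p in extraPigments()) pigDf[[p]] <- 0
  pigDf$cruise <- paste0("SIM-", area)
  pigDf$station <- sprintf("S%03d", seq_len(n))
  pigDf$depth_m <- round(runif(n, 10, 170))
  pigDf$area <- area
  pigDf$season <- rep(c("winter", "spring", "summer", "autumn"),
                      length.out = n)
  sel <- selectCalibrationChannel(spec, pigDf$MVChla + pigDf$DVChla)
  db <- buildReferenceDatabase(pigDf, spec, sel$model)
  list(db = db, truth = q, calibration = sel$model, endmembers = E,
       pigments = pigDf, spectraRaw = spec)
}

#' Simulate a 10 Hz MEX cast through a layered water column
#'
#' Descends at constant rate through user-defined layers, each with its own
#' composition and background TChla; an optional Gaussian subsurface
#' chlorophyll maximum is superimposed. Channels are the endmember mixture
#' scaled by local TChla and gain with multiplicative noise; a configurable
#' fraction of records is contaminated by multiplicative spikes (for
#' median-filter tests).
#'
#' @param layers list of layers, each \code{list(top =, bottom =,
#'   composition = <named 9 fractions>, tchla = <ug/L>)}; depth ranges
#'   must not overlap.
#' @param maxDepth final depth (m); default the deepest layer bottom.
#' @param descentRate m/s (default 0.25).
#' @param sampleHz sampling rate (default 10).
#' @param noiseSD multiplicative channel noise sd (default 0.02).
#' @param spikeRate fraction of records spiked (default 0).
#' @param spikeFactor spike multiplier (default 100).
#' @param scm optional subsurface chlorophyll maximum:
#'   \code{list(depth =, sd =, amplitude =)} (ug/L added at the peak).
#' @param endmembers endmember matrix (default [makeEndmemberSpectra()]).
#' @param gain instrument gain (default 2).
#' @param seed integer seed (mandatory).
#' @return data.frame cast: time_s, depth_m, temp_c, nine channel columns.
#' @export
simulateCast <- function(layers, maxDepth = NULL, descentRate = 0.25,
                         sampleHz = 10, noiseSD = 0.02, spikeRate = 0,
                         spikeFactor = 100, scm = NULL,
                         endmembers = NULL, gain = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  tops <- vapply(layers, `[[`, numeric(1), "top")
  bots <- vapply(layers, `[[`, numeric(1), "bottom")
  o <- order(tops)
  if (any(bots[o][-length(o)] > tops[o][-1] + 1e-9))
    stop("layers must not overlap")
  set.seed(seed)
  if (is.null(endmembers)) endmembers <- makeEndmemberSpectra(seed)
  if (is.null(maxDepth)) maxDepth <- max(bots)
  dt <- 1 / sampleHz
  t <- seq(0, maxDepth / descentRate, by = dt)
  depth <- t * descentRate
  layerOf <- vapply(depth, function(d) {
    k <- which(tops <= d & d <= bots)
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  # outside any layer: carry the nearest layer downward
  for (i in seq_along(layerOf))
    if (is.na(layerOf[i])) layerOf[i] <- layerOf[max(which(!is.na(layerOf[1:i])), 1)]
  q <- t(vapply(layerOf, function(k)
    layers[[k]]$composition[taxonGroups()], numeric(9)))
  tch <- vapply(layerOf, function(k) layers[[k]]$tchla, numeric(1))
  if (!is.null(scm))
    tch <- tch + scm$amplitude * exp(-((depth - scm$depth)^2) / (2 * scm$sd^2))
  spec <- (q %*% endmembers) * tch * gain
  spec <- spec * matrix(rlnorm(length(spec), 0, noiseSD), nrow(spec))
  if (spikeRate > 0) {
    hit <- runif(nrow(spec)) < spikeRate
    spec[hit, ] <- spec[hit, ] * spikeFactor
  }
  colnames(spec) <- channelNames()
  data.frame(time_s = t, depth_m = depth,
             temp_c = 20 - 0.05 * depth, spec, check.names = FALSE)
}
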