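## 1D lattice simulation of clamp loading, sliding and unloading.

#' Construct a LatticeConfig
#'
#' @param windowLength lattice size (bp).
#' @param parSPos 0-based parS position; default window center.
#' @param D diffusion coefficient (bp^2/s): the per-direction 1-bp hop
#'   rate, so the positional variance of a free clamp grows as 2 D t.
#' @param loadingRate clamp injections at parS (clamps/s).
#' @param kOff per-clamp hydrolysis-driven unloading rate (1/s); set 0 for
#'   hydrolysis-dead (EQ) clamps. The wild-type proxy is the hydrolysis
#'   rate kH.
#' @param pRetain probability that a hydrolysis event is survived through
#'   CTP re-capture; the effective unloading rate is
#'   \code{kOff * (1 - pRetain)}.
#' @param roadblocks data.frame with columns \code{pos} (0-based bp) and
#'   \code{behavior} ("reflect" or "absorb"); default none.
#' @param boundaryLeft,boundaryRight window edge behavior.
#' @param exclusion at most one clamp per site?
#' @return a \linkS4class{LatticeConfig}.
#' @export
latticeConfig <- function(windowLength = 20001L,
                          parSPos = (windowLength - 1L) %/% 2L,
                          D = 100, loadingRate = 1, kOff = 1 / 60,
                          pRetain = 0,
                          roadblocks = data.frame(pos = integer(),
                                                  behavior = character()),
                          boundaryLeft = "reflect",
                          boundaryRight = "reflect",
                          exclusion = FALSE) {
  new("LatticeConfig",
      windowLength = as.integer(windowLength), parSPos = as.integer(parSPos),
      D = as.numeric(D), loadingRate = as.numeric(loadingRate),
      kOff = as.numeric(kOff), pRetain = as.numeric(pRetain),
      roadblocks = as.data.frame(roadblocks),
      boundaryLeft = boundaryLeft, boundaryRight = boundaryRight,
      exclusion = isTRUE(exclusion))
}

#' Effective unloading rate of a lattice configuration
#' @param config a \linkS4class{LatticeConfig}.
#' @return numeric(1), \code{kOff * (1 - pRetain)} (1/s).
#' @export
kOffEffective <- function(config) config@kOff * (1 - config@pRetain)

#' Construct an OccupancyProfile
#' @param binStart 0-based bin starts (bp).
#' @param occupancy per-bin mean occupancy.
#' @param binSize bin width (bp).
#' @param metadata list.
#' @return an \linkS4class{OccupancyProfile}.
#' @export
occupancyProfile <- function(binStart, occupancy, binSize = 1,
                             metadata = list()) {
  new("OccupancyProfile", binStart = as.numeric(binStart),
      binSize = as.numeric(binSize), occupancy = as.numeric(occupancy),
      metadata = metadata)
}

setMethod("occupancy", "OccupancyProfile", function(x) x@occupancy)
setMethod("binStarts", "OccupancyProfile", function(x) x@binStart)
setMethod("binSize", "OccupancyProfile", function(x) x@binSize)

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf("OccupancyProfile: %d bins of %g bp, total occupancy %.4g\n",
              length(object@binStart), object@binSize,
              sum(object@occupancy)))
  if (length(object@metadata))
    cat("metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

.siteCodes <- function(config) {
  code <- integer(config@windowLength)
  rb <- config@roadblocks
  if (nrow(rb))
    code[rb$pos + 1L] <- ifelse(rb$behavior == "absorb", 2L, 1L)
  code
}

#' Simulate a spreading occupancy profile
#'
#' Continuous-time random walkers are injected at parS at the loading
#' rate, hop 1 bp at rate \code{D} per direction, and are removed at the
#' effective unloading rate \code{kOff * (1 - pRetain)}. Roadblocks and
#' boundaries reflect or absorb. The returned profile is either the
#' time-averaged occupancy after \code{burnIn} (\code{mode = "steady"})
#' or the terminal snapshot (\code{mode = "terminal"}, for transient,
#' EQ-mutant-like runs). With \code{exclusion = TRUE} a loading rate that
#' saturates the parS site triggers a warning and injections are capped.
#'
#' @param config a \linkS4class{LatticeConfig}.
#' @param tEnd simulated time (s), > 0.
#' @param seed integer seed (mandatory).
#' @param mode "steady" (time-averaged) or "terminal" (snapshot counts).
#' @param burnIn excluded from the time average; default \code{tEnd / 5}.
#' @param initialClamps clamps placed at parS at time 0 (useful with
#'   \code{loadingRate = 0} to follow a synchronized cohort).
#' @return an \linkS4class{OccupancyProfile}; the terminal clamp positions
#'   and load/unload counts are kept in its metadata.
#' @export
simulateProfile <- function(config, tEnd, seed, mode = c("steady", "terminal"),
                            burnIn = tEnd / 5, initialClamps = 0L) {
  stopifnot(is(config, "LatticeConfig"), tEnd > 0)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  mode <- match.arg(mode)
  res <- .withSeed(seed, .spread_sim(
    config@windowLength, config@parSPos, config@D, config@loadingRate,
    kOffEffective(config), .siteCodes(config),
    as.integer(config@boundaryLeft == "absorb"),
    as.integer(config@boundaryRight == "absorb"),
    config@exclusion, tEnd, burnIn, as.integer(initialClamps)))
  if (res$blocked_loads > 0)
    warning(sprintf(
      "exclusion capped %g injection(s): loading rate saturates the parS site",
      res$blocked_loads))
  occ <- if (mode == "steady") res$occupancy else
    tabulate(res$terminal + 1L, nbins = config@windowLength)
  occupancyProfile(
    binStart = seq_len(config@windowLength) - 1, occupancy = occ,
    binSize = 1,
    metadata = list(configHash = .hashObject(config), seed = as.integer(seed),
                    simulatedTime = tEnd, burnIn = burnIn, mode = mode,
                    parSPos = config@parSPos,
                    kOffEffective = kOffEffective(config), D = config@D,
                    loadingRate = config@loadingRate,
                    terminalPositions = res$terminal,
                    loaded = res$loaded, unloaded = res$unloaded,
                    absorbed = res$absorbed))
}

#' Closed-form steady-state spreading profile
#'
#' In the no-exclusion, no-roadblock, reflecting-window case with
#' \code{kOffEffective > 0}, loading-unloading balance gives a total
#' steady-state clamp number of \code{loadingRate / kOffEffective}
#' distributed as a two-sided exponential around parS with decay length
#' \eqn{\lambda = \sqrt{D / k_{off}^{eff}}} (continuum diffusion-decay
#' balance). Used as the analytic oracle for \code{\link{simulateProfile}}.
#'
#' @param config a \linkS4class{LatticeConfig} inside the validity regime.
#' @return an \linkS4class{OccupancyProfile} (1-bp bins).
#' @export
analyticProfile <- function(config) {
  stopifnot(is(config, "LatticeConfig"))
  keff <- kOffEffective(config)
  if (keff <= 0)
    stop("analyticProfile requires kOffEffective > 0 (no steady state otherwise)")
  if (config@exclusion || nrow(config@roadblocks) > 0 ||
      config@boundaryLeft != "reflect" || config@boundaryRight != "reflect")
    stop("analyticProfile is only valid without exclusion, roadblocks or absorbing boundaries")
  if (config@D <= 0) stop("analyticProfile requires D > 0")
  lambda <- sqrt(config@D / keff)
  x <- seq_len(config@windowLength) - 1
  shape <- exp(-abs(x - config@parSPos) / lambda)
  total <- config@loadingRate / keff
  occupancyProfile(
    binStart = x, occupancy = total * shape / sum(shape), binSize = 1,
    metadata = list(lambda = lambda, total = total, analytic = TRUE,
                    parSPos = config@parSPos))
}

#' Width of an occupancy peak
#'
#' Either the full width at half maximum (linear interpolation between
#' bin centers) or the length of the smallest parS-containing symmetric
#' interval holding a fraction \code{q} of the total occupancy.
#'
#' @param x an \linkS4class{OccupancyProfile} with a positive maximum.
#' @param method "fwhm" or "central-mass".
#' @param q central-mass fraction (default 0.9).
#' @param center peak center (bp) for "central-mass"; default the parS
#'   position from metadata, else the occupancy-weighted argmax.
#' @param ... unused.
#' @return width in bp.
#' @export
setMethod("peakWidth", "OccupancyProfile",
  function(x, method = c("fwhm", "central-mass"), q = 0.9, center = NULL,
           ...) {
  method <- match.arg(method)
  occ <- x@occupancy
  if (max(occ) <= 0) stop("flat profile: peak width undefined")
  if (diff(range(occ)) == 0) stop("flat profile: peak width undefined")
  mid <- x@binStart + x@binSize / 2
  if (method == "fwhm") {
    half <- max(occ) / 2
    above <- which(occ >= half)
    i1 <- above[1]; i2 <- above[length(above)]
    ## interpolate the crossings just outside the above-half run
    left <- if (i1 > 1)
      mid[i1] - x@binSize * (occ[i1] - half) / (occ[i1] - occ[i1 - 1])
    else mid[i1] - x@binSize / 2
    right <- if (i2 < length(occ))
      mid[i2] + x@binSize * (occ[i2] - half) / (occ[i2] - occ[i2 + 1])
    else mid[i2] + x@binSize / 2
    max(right - left, x@binSize)
  } else {
    if (is.null(center))
      center <- if (!is.null(x@metadata$parSPos)) x@metadata$parSPos else
        mid[which.max(occ)]
    tot <- sum(occ)
    d <- abs(mid - center)
    o <- order(d)
    cum <- cumsum(occ[o])
    k <- which(cum >= q * tot)[1]
    max(2 * d[o[k]] + x@binSize, x@binSize)
  }
})

#' Rebin an occupancy profile
#'
#' Sums occupancy into half-open bins of \code{binSize} bp (ChIP-style;
#' 1 kb is the conventional choice for ParB tracks). The last bin may be
#' truncated by the window edge; total occupancy is conserved.
#'
#' @param x an \linkS4class{OccupancyProfile}.
#' @param binSize new bin width (bp), a positive multiple of the current
#'   bin size.
#' @param ... unused.
#' @return an \linkS4class{OccupancyProfile}.
#' @export
setMethod("binProfile", "OccupancyProfile", function(x, binSize = 1000, ...) {
  if (binSize <= 0) stop("'binSize' must be > 0")
  if (abs(binSize / x@binSize - round(binSize / x@binSize)) > 1e-9)
    stop("'binSize' must be a multiple of the current bin size")
  if (binSize == x@binSize) return(x)
  origin <- x@binStart[1]
  idx <- floor((x@binStart - origin) / binSize)
  occ <- as.numeric(tapply(x@occupancy, idx, sum))
  occupancyProfile(binStart = origin + sort(unique(idx)) * binSize,
                   occupancy = occ, binSize = binSize,
                   metadata = x@metadata)
})

#' @describeIn toGRanges Occupancy profile as a GRanges with a score column.
#' @param x an \linkS4class{OccupancyProfile}.
#' @param seqname chromosome name for the track.
#' @param ... unused.
#' @export
setMethod("toGRanges", "OccupancyProfile", function(x, seqname = "chr", ...) {
  GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = x@binStart + 1,  # 1-based closed
                              width = x@binSize),
    score = x@occupancy)
})

#' @describeIn writeBedGraph Write the profile as a bedGraph track
#'   (0-based half-open intervals).
#' @param x an \linkS4class{OccupancyProfile}.
#' @param file output path.
#' @param seqname chromosome name.
#' @param ... unused.
#' @export
setMethod("writeBedGraph", "OccupancyProfile",
  function(x, file, seqname = "chr", ...) {
  rtracklayer::export.bedGraph(toGRanges(x, seqname = seqname), file)
  invisible(file)
})

#' Read a bedGraph track back into an OccupancyProfile
#' @param file bedGraph path.
#' @return an \linkS4class{OccupancyProfile}.
#' @export
readBedGraph <- function(file) {
  gr <- rtracklayer::import.bedGraph(file)
  occupancyProfile(binStart = GenomicRanges::start(gr) - 1,
                   occupancy = gr$score,
                   binSize = GenomicRanges::width(gr)[1])
}
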