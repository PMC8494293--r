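## Synthetic-data generators with embedded ground truth, for recovery
## testing of every fitter in the package.

#' Construct a NoiseSpec
#' @param model "gaussian-additive", "gaussian-relative" or "poisson".
#' @param scale additive SD, relative SD, or ignored for "poisson".
#' @param seed integer seed; mandatory.
#' @return a \linkS4class{NoiseSpec}.
#' @export
noiseSpec <- function(model = c("gaussian-additive", "gaussian-relative",
                                "poisson"),
                      scale = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  new("NoiseSpec", model = match.arg(model), scale = as.numeric(scale),
      seed = as.integer(seed))
}

.applyNoise <- function(x, noise) {
  stopifnot(is(noise, "NoiseSpec"))
  .withSeed(noise@seed, switch(noise@model,
    "gaussian-additive" = x + stats::rnorm(length(x), 0, noise@scale),
    "gaussian-relative" = x * (1 + stats::rnorm(length(x), 0, noise@scale)),
    "poisson" = stats::rpois(length(x), x)))
}

#' Generate a synthetic ITC titration
#'
#' Observed heats are \code{\link{injectionHeats}} of the ground-truth
#' (K, dH) plus noise. Defaults mirror the standard cell setup: a 280-uL
#' class cell loaded with protein at 100 uM (within the usual 80-120 uM
#' monomer range) titrated from a 2 mM nucleotide syringe in 20 x 2 uL
#' injections.
#'
#' @param K true association constant (1/uM).
#' @param dH true molar heat (kcal/mol injectant).
#' @param noise a \linkS4class{NoiseSpec}.
#' @param vo,dvi,m0,xsyringe,nInjections schedule, as in
#'   \code{\link{titrationExperiment}}.
#' @return a \linkS4class{TitrationExperiment}; ground truth and seed are
#'   embedded in its metadata.
#' @export
genITC <- function(K, dH, noise, vo = 280, dvi = 2, m0 = 100,
                   xsyringe = 2000, nInjections = 20) {
  exp0 <- titrationExperiment(vo = vo, dvi = dvi, m0 = m0,
                              xsyringe = xsyringe,
                              nInjections = nInjections)
  clean <- injectionHeats(exp0, K, dH)
  exp0@heats <- .applyNoise(clean, noise)
  exp0@metadata <- c(exp0@metadata, list(
    truth = list(K = K, Kd = 1 / K, dH = dH),
    noise = list(model = noise@model, scale = noise@scale,
                 seed = noise@seed)))
  exp0
}

#' Generate a synthetic BLI trace
#'
#' Baseline, association (saturating exponential toward
#' \code{amplitude}), then exponential dissociation
#' \code{amplitude * exp(-kApp t) + offset}, sampled at \code{dt} and
#' noised. The default dissociation window is 5 min, the standard
#' protocol length.
#'
#' @param kApp true apparent dissociation rate (1/s).
#' @param amplitude association plateau (signal units).
#' @param noise a \linkS4class{NoiseSpec}.
#' @param baselineTime,associationTime,dissociationTime phase lengths (s).
#' @param dt sampling interval (s).
#' @param kOn association-phase observed rate (1/s), cosmetic only.
#' @param offset additive sensor offset.
#' @return a \linkS4class{SensorTrace} with truth in metadata.
#' @export
genBLI <- function(kApp, amplitude = 1, noise,
                   baselineTime = 30, associationTime = 120,
                   dissociationTime = 300, dt = 1, kOn = 0.05,
                   offset = 0) {
  tb <- seq(0, baselineTime, by = dt)
  ta <- seq(dt, associationTime, by = dt)
  td <- seq(dt, dissociationTime, by = dt)
  sig <- c(rep(0, length(tb)),
           amplitude * (1 - exp(-kOn * ta)),
           amplitude * (1 - exp(-kOn * associationTime)) * exp(-kApp * td)) +
    offset
  time <- c(tb, baselineTime + ta, baselineTime + associationTime + td)
  phase <- c(rep("baseline", length(tb)),
             rep("association", length(ta)),
             rep("dissociation", length(td)))
  sensorTrace(time, .applyNoise(sig, noise), phase,
              metadata = list(
                truth = list(kApp = kApp, amplitude = amplitude,
                             offset = offset),
                noise = list(model = noise@model, scale = noise@scale,
                             seed = noise@seed)))
}

#' Generate a synthetic CTPase phosphate time course
#'
#' Linear phosphate accumulation \code{rate * protein * t}, capped at
#' substrate exhaustion, plus noise. Defaults mirror the standard assay:
#' 10 uM protein, 1 mM CTP, 60 min at fixed temperature.
#'
#' @param rate true per-enzyme turnover rate (1/min).
#' @param noise a \linkS4class{NoiseSpec}.
#' @param protein enzyme concentration (uM).
#' @param duration assay length (min).
#' @param dt sampling interval (min).
#' @param substrate CTP pool (uM); accumulation saturates here.
#' @return a \linkS4class{PhosphateTimeCourse} with truth in metadata.
#' @export
genCTPase <- function(rate, noise, protein = 10, duration = 60, dt = 5,
                      substrate = 1000) {
  stopifnot(duration > 0)
  t <- seq(0, duration, by = dt)
  pi <- pmin(rate * protein * t, substrate)
  phosphateTimeCourse(
    time = t, phosphate = pmax(.applyNoise(pi, noise), 0),
    protein = protein,
    metadata = list(truth = list(rate = rate), substrate = substrate,
                    noise = list(model = noise@model, scale = noise@scale,
                                 seed = noise@seed)))
}

#' Generate ChIP-like per-bin read counts from an occupancy profile
#'
#' IP counts are Poisson with mean \code{depth * (background +
#' occupancy)} per bin; the input control is Poisson with mean
#' \code{depth * background}. The background level defaults to 10\% of
#' the peak occupancy (a free parameter: real input tracks set their own
#' scale). Profiles should be binned (1 kb is the ChIP convention) before
#' counting.
#'
#' @param profile an \linkS4class{OccupancyProfile}.
#' @param depth mean reads per bin at unit occupancy.
#' @param noise a \linkS4class{NoiseSpec} with model "poisson" (its seed
#'   drives the counts).
#' @param background flat background occupancy; default
#'   \code{0.1 * max(occupancy)}.
#' @return list of two \linkS4class{OccupancyProfile}s (\code{ip},
#'   \code{control}) carrying counts, plus the generating truth in each
#'   metadata.
#' @export
genChipCounts <- function(profile, depth, noise,
                          background = 0.1 * max(occupancy(profile))) {
  stopifnot(is(profile, "OccupancyProfile"))
  if (noise@model != "poisson")
    stop("ChIP counts use the 'poisson' noise model")
  muIP <- depth * (background + profile@occupancy)
  muBG <- rep(depth * background, length(profile@occupancy))
  counts <- .withSeed(noise@seed, list(
    ip = stats::rpois(length(muIP), muIP),
    control = stats::rpois(length(muBG), muBG)))
  meta <- list(depth = depth, background = background, seed = noise@seed,
               truthProfile = profile@metadata)
  list(
    ip = occupancyProfile(profile@binStart, counts$ip, profile@binSize,
                          metadata = c(meta, list(track = "ip"))),
    control = occupancyProfile(profile@binStart, counts$control,
                               profile@binSize,
                               metadata = c(meta, list(track = "control"))))
}

#' IP/control ratio track from ChIP count tracks
#'
#' Per-bin ratio \code{(ip + pseudo) / (control + pseudo)}, the usual
#' display for ParB enrichment around parS.
#'
#' @param ip,control \linkS4class{OccupancyProfile}s of counts on the same
#'   bins.
#' @param pseudo pseudocount guarding against division by zero.
#' @return an \linkS4class{OccupancyProfile} of ratios.
#' @export
chipRatio <- function(ip, control, pseudo = 1) {
  stopifnot(identical(ip@binStart, control@binStart),
            ip@binSize == control@binSize)
  occupancyProfile(ip@binStart,
                   (ip@occupancy + pseudo) / (control@occupancy + pseudo),
                   ip@binSize, metadata = ip@metadata)
}
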