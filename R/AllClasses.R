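## S4 class definitions for the ParB clamp-cycle machinery.

#' Kinetic constants of the ParB clamp cycle
#'
#' A \code{RateSet} holds the rate constants of the coarse clamp cycle:
#' closure (\code{kOC}) and opening (\code{kCO}) of the free ParB dimer,
#' their DNA-bound counterparts (\code{kOCdna}, \code{kCOdna}; for a parS
#' substrate \code{kOCdna} is the parS-catalyzed closure rate), the CTP
#' hydrolysis rate \code{kH} (assumed identical on and off DNA), and the
#' dissociation constant \code{kdOpen} of the open form for the DNA
#' substrate. \code{kOn} is the association rate of open ParB to DNA; the
#' analytic theory does not need it, but dynamic solvers (ODE relaxation,
#' stochastic simulation) do, with \code{kOffOpen = kOn * kdOpen}.
#'
#' Canonical internal units are 1/s for rates, uM for concentrations and
#' 1/(uM s) for \code{kOn}; see \code{\link{rateSet}} for unit handling.
#'
#' @slot kOC numeric(1), closure rate of free ParB (1/s).
#' @slot kCO numeric(1), opening rate of free ParB (1/s).
#' @slot kOCdna numeric(1), closure rate of DNA-bound ParB (1/s).
#' @slot kCOdna numeric(1), opening rate of DNA-bound ParB (1/s).
#' @slot kH numeric(1), CTP hydrolysis rate (1/s).
#' @slot kdOpen numeric(1), open-form dissociation constant (uM).
#' @slot kOn numeric(1), open-form association rate (1/(uM s)); may be
#'   \code{NA} when only the analytic theory is used.
#' @aliases RateSet-class
#' @exportClass RateSet
setClass("RateSet",
  representation(
    kOC = "numeric", kCO = "numeric",
    kOCdna = "numeric", kCOdna = "numeric",
    kH = "numeric", kdOpen = "numeric", kOn = "numeric"
  ),
  prototype(kOn = NA_real_)
)

setValidity("RateSet", function(object) {
  msgs <- character()
  for (nm in c("kOC", "kCO", "kOCdna", "kCOdna", "kH", "kdOpen")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single finite value >= 0", nm))
  }
  v <- object@kOn
  if (length(v) != 1L || (!is.na(v) && (!is.finite(v) || v <= 0)))
    msgs <- c(msgs, "'kOn' must be NA or a single finite value > 0")
  if (length(msgs)) msgs else TRUE
})

#' Steady-state (or instantaneous) concentrations of the clamp-cycle species
#'
#' Concentrations of the four ParB species (open/closed crossed with
#' free/DNA-bound) plus free DNA, all in the same unit (uM by convention).
#'
#' @slot parbOpenFree,parbClosedFree,parbOpenBound,parbClosedBound numeric(1)
#'   concentrations of the four ParB pools (uM).
#' @slot dnaFree numeric(1), free DNA concentration (uM).
#' @slot dnaClamped logical(1), whether free DNA was held fixed
#'   (excess-substrate approximation) rather than conserved.
#' @aliases SpeciesState-class
#' @exportClass SpeciesState
setClass("SpeciesState",
  representation(
    parbOpenFree = "numeric", parbClosedFree = "numeric",
    parbOpenBound = "numeric", parbClosedBound = "numeric",
    dnaFree = "numeric", dnaClamped = "logical"
  ),
  prototype(dnaClamped = FALSE)
)

setValidity("SpeciesState", function(object) {
  vals <- c(object@parbOpenFree, object@parbClosedFree,
            object@parbOpenBound, object@parbClosedBound, object@dnaFree)
  if (length(vals) != 5L || any(!is.finite(vals)))
    return("all five concentrations must be single finite values")
  ## tiny negative round-off from solvers is rejected: callers clip first
  if (any(vals < 0)) return("concentrations must be >= 0")
  TRUE
})

#' A stochastic mass-action reaction network
#'
#' Integer-copy-number representation of a reaction scheme for exact
#' stochastic simulation. Reactant and product stoichiometries are stored
#' as species-by-reaction matrices; \code{rates} are the stochastic rate
#' constants (already converted from concentration units using
#' \code{volumeFactor}, the number of copies corresponding to 1 uM).
#'
#' @slot species named integer vector of initial copy numbers.
#' @slot reactants,products integer matrices (species x reactions).
#' @slot rates numeric vector of stochastic rate constants (1/s).
#' @slot reactionNames character vector.
#' @slot hydrolysisReactions integer indices of reactions whose firing is a
#'   CTP hydrolysis event.
#' @slot volumeFactor numeric(1), copies per uM.
#' @slot conserved named list of conserved-moiety coefficient vectors
#'   (named integer vectors over species).
#' @aliases ReactionNetwork-class
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(
    species = "integer", reactants = "matrix", products = "matrix",
    rates = "numeric", reactionNames = "character",
    hydrolysisReactions = "integer", volumeFactor = "numeric",
    conserved = "list"
  )
)

setValidity("ReactionNetwork", function(object) {
  ns <- length(object@species); nr <- length(object@rates)
  msgs <- character()
  if (is.null(names(object@species))) msgs <- c(msgs, "species must be named")
  if (any(object@species < 0)) msgs <- c(msgs, "copy numbers must be >= 0")
  if (!all(dim(object@reactants) == c(ns, nr)) ||
      !all(dim(object@products) == c(ns, nr)))
    msgs <- c(msgs, "stoichiometry matrices must be species x reactions")
  if (any(object@reactants < 0) || any(object@products < 0) ||
      any(object@reactants != round(object@reactants)))
    msgs <- c(msgs, "stoichiometries must be nonnegative integers")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    msgs <- c(msgs, "rate constants must be finite and >= 0")
  if (length(object@reactionNames) != nr)
    msgs <- c(msgs, "one name per reaction required")
  if (length(msgs)) msgs else TRUE
})

#' A sampled trajectory of a reaction network
#'
#' Event log and summary statistics from one exact-simulation run. Event
#' times are strictly increasing; \code{reactionIds} give the reaction
#' fired at each event. Time-averaged species means are accumulated after
#' \code{burnIn}, together with batch means for standard-error estimation.
#' The seed and a hash of the network are kept in \code{metadata} so that
#' (seed, network) fully determines the trajectory.
#'
#' @slot times numeric, event times (possibly truncated at the storage cap).
#' @slot reactionIds integer, fired reaction per stored event.
#' @slot initialState,finalState named integer vectors.
#' @slot firedTotal,firedPost integer, per-reaction firing counts overall
#'   and after the burn-in.
#' @slot tavgMean named numeric, time-averaged copy numbers after burn-in.
#' @slot batchMeans matrix (batches x species) of per-batch time averages.
#' @slot hydrolysisCount numeric(1), hydrolysis events after burn-in.
#' @slot tEnd,burnIn numeric(1).
#' @slot metadata list (seed, network hash, event counts).
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    times = "numeric", reactionIds = "integer",
    initialState = "integer", finalState = "integer",
    firedTotal = "numeric", firedPost = "numeric",
    tavgMean = "numeric", batchMeans = "matrix",
    hydrolysisCount = "numeric", tEnd = "numeric", burnIn = "numeric",
    metadata = "list"
  )
)

setValidity("Trajectory", function(object) {
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("event times must be strictly increasing")
  if (any(object@finalState < 0)) return("copy numbers must be >= 0")
  TRUE
})

#' Configuration of the 1D spreading lattice
#'
#' Geometry and rates for the lattice simulator: a window of
#' \code{windowLength} base pairs with a parS loading site, clamps hopping
#' at rate \code{D} per direction (1-bp steps, so \code{D} is in bp^2/s),
#' loaded at \code{loadingRate} clamps/s, and unloaded at the effective
#' rate \code{kOff * (1 - pRetain)} (hydrolysis events are survived with
#' probability \code{pRetain} through CTP re-capture). Roadblocks and
#' window boundaries either reflect or absorb clamps.
#'
#' @slot windowLength integer(1), lattice size (bp).
#' @slot parSPos integer(1), 0-based parS position.
#' @slot D numeric(1), diffusion coefficient (bp^2/s).
#' @slot loadingRate numeric(1), clamp injections per second at parS.
#' @slot kOff numeric(1), per-clamp hydrolysis-driven unloading rate (1/s);
#'   0 models hydrolysis-dead (EQ) mutants.
#' @slot pRetain numeric(1) in [0,1], per-hydrolysis retention probability.
#' @slot roadblocks data.frame with columns \code{pos} (0-based bp) and
#'   \code{behavior} ("reflect" or "absorb").
#' @slot boundaryLeft,boundaryRight character(1), "reflect" or "absorb".
#' @slot exclusion logical(1), at most one clamp per site when TRUE.
#' @aliases LatticeConfig-class
#' @exportClass LatticeConfig
setClass("LatticeConfig",
  representation(
    windowLength = "integer", parSPos = "integer",
    D = "numeric", loadingRate = "numeric", kOff = "numeric",
    pRetain = "numeric", roadblocks = "data.frame",
    boundaryLeft = "character", boundaryRight = "character",
    exclusion = "logical"
  )
)

setValidity("LatticeConfig", function(object) {
  msgs <- character()
  L <- object@windowLength
  if (L < 3L) msgs <- c(msgs, "windowLength must be >= 3")
  if (object@parSPos < 0L || object@parSPos >= L)
    msgs <- c(msgs, "parSPos must lie inside the window")
  if (object@D < 0 || object@loadingRate < 0 || object@kOff < 0)
    msgs <- c(msgs, "D and rates must be >= 0")
  if (object@pRetain < 0 || object@pRetain > 1)
    msgs <- c(msgs, "pRetain must be in [0, 1]")
  rb <- object@roadblocks
  if (nrow(rb)) {
    if (!all(c("pos", "behavior") %in% names(rb)))
      msgs <- c(msgs, "roadblocks need columns 'pos' and 'behavior'")
    else {
      if (any(rb$pos < 0 | rb$pos >= L))
        msgs <- c(msgs, "roadblock positions must lie inside the window")
      if (!all(rb$behavior %in% c("reflect", "absorb")))
        msgs <- c(msgs, "roadblock behavior must be 'reflect' or 'absorb'")
    }
  }
  if (!object@boundaryLeft %in% c("reflect", "absorb") ||
      !object@boundaryRight %in% c("reflect", "absorb"))
    msgs <- c(msgs, "boundaries must be 'reflect' or 'absorb'")
  if (length(msgs)) msgs else TRUE
})

#' Mean clamp occupancy along a genomic window
#'
#' Per-bin mean occupancy around a parS site, with 0-based half-open bins
#' that tile the window without overlap. Produced by the lattice simulator
#' (time-averaged or terminal occupancy), by the analytic diffusion-decay
#' profile, or by rebinning; exported as bedGraph.
#'
#' @slot binStart numeric, 0-based bin start coordinates (bp).
#' @slot binSize numeric(1), bin width (bp).
#' @slot occupancy numeric, mean occupancy per bin (clamps, or normalized).
#' @slot metadata list (config hash, seed, simulated time, ...).
#' @aliases OccupancyProfile-class
#' @exportClass OccupancyProfile
setClass("OccupancyProfile",
  representation(
    binStart = "numeric", binSize = "numeric",
    occupancy = "numeric", metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("OccupancyProfile", function(object) {
  msgs <- character()
  if (length(object@binStart) != length(object@occupancy))
    msgs <- c(msgs, "binStart and occupancy must have equal length")
  if (any(object@occupancy < 0)) msgs <- c(msgs, "occupancy must be >= 0")
  if (length(object@binStart) > 1L) {
    d <- diff(object@binStart)
    if (any(abs(d - object@binSize) > 1e-9))
      msgs <- c(msgs, "bins must tile the window without gaps or overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' An ITC titration: geometry, schedule and integrated heats
#'
#' Cell volume \code{vo}, per-injection volumes \code{dvi}, and the
#' per-injection cell concentrations of macromolecule (\code{mt}, ParB)
#' and cumulative ligand (\code{xt}, nucleotide) after dilution, together
#' with the observed integrated heats in energy per mole of injectant
#' (kcal/mol by convention, as in a Wiseman plot).
#'
#' @slot vo numeric(1), cell volume (uL).
#' @slot dvi numeric, injection volumes (uL), one per injection.
#' @slot mt numeric, cell macromolecule concentration at each injection (uM).
#' @slot xt numeric, cumulative ligand concentration at each injection (uM),
#'   nondecreasing.
#' @slot heats numeric, observed per-injection heats (kcal/mol injectant).
#' @slot xsyringe numeric(1), syringe ligand concentration (uM).
#' @slot metadata list (ground truth for synthetic data, units, ...).
#' @aliases TitrationExperiment-class
#' @exportClass TitrationExperiment
setClass("TitrationExperiment",
  representation(
    vo = "numeric", dvi = "numeric", mt = "numeric", xt = "numeric",
    heats = "numeric", xsyringe = "numeric", metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("TitrationExperiment", function(object) {
  msgs <- character()
  n <- length(object@dvi)
  if (object@vo <= 0) msgs <- c(msgs, "'vo' must be > 0")
  if (any(object@dvi < 0)) msgs <- c(msgs, "injection volumes must be >= 0")
  if (length(object@mt) != n || length(object@xt) != n ||
      length(object@heats) != n)
    msgs <- c(msgs, "mt, xt and heats must have one entry per injection")
  if (n > 1L && any(diff(object@xt) < -1e-12))
    msgs <- c(msgs, "cumulative ligand concentration must be nondecreasing")
  if (length(msgs)) msgs else TRUE
})

#' A BLI-like sensor trace
#'
#' Time-stamped signal (wavelength-shift units) with a phase label per
#' point: \code{baseline}, \code{association} or \code{dissociation}.
#' Times are strictly increasing within each phase.
#'
#' @slot time numeric, seconds.
#' @slot signal numeric, sensor signal (nm shift or arbitrary units).
#' @slot phase character, one of "baseline", "association", "dissociation".
#' @slot metadata list (ground truth for synthetic traces, ...).
#' @aliases SensorTrace-class
#' @exportClass SensorTrace
setClass("SensorTrace",
  representation(
    time = "numeric", signal = "numeric", phase = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("SensorTrace", function(object) {
  msgs <- character()
  if (length(object@time) != length(object@signal) ||
      length(object@time) != length(object@phase))
    msgs <- c(msgs, "time, signal and phase must have equal length")
  if (!all(object@phase %in% c("baseline", "association", "dissociation")))
    msgs <- c(msgs, "unknown phase label")
  for (ph in unique(object@phase)) {
    tt <- object@time[object@phase == ph]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      msgs <- c(msgs, sprintf("times must be strictly increasing within the %s phase", ph))
  }
  if (length(msgs)) msgs else TRUE
})

#' A phosphate-release time course from a CTPase assay
#'
#' Either phosphate concentrations directly (uM) or raw OD620 readings
#' plus the linear standard curve (\code{OD = slope * [Pi] + intercept})
#' used to convert them, together with the protein concentration that
#' normalizes the slope to a per-enzyme turnover rate.
#'
#' @slot time numeric, minutes.
#' @slot phosphate numeric, uM (may be empty when \code{od} is supplied).
#' @slot od numeric, raw OD620 (may be empty).
#' @slot curveSlope,curveIntercept numeric(1), standard curve parameters
#'   (OD per uM Pi, and OD offset).
#' @slot protein numeric(1), enzyme concentration (uM), > 0.
#' @slot metadata list.
#' @aliases PhosphateTimeCourse-class
#' @exportClass PhosphateTimeCourse
setClass("PhosphateTimeCourse",
  representation(
    time = "numeric", phosphate = "numeric", od = "numeric",
    curveSlope = "numeric", curveIntercept = "numeric",
    protein = "numeric", metadata = "list"
  ),
  prototype(phosphate = numeric(), od = numeric(),
            curveSlope = NA_real_, curveIntercept = NA_real_,
            metadata = list())
)

setValidity("PhosphateTimeCourse", function(object) {
  msgs <- character()
  if (length(object@protein) != 1L || !is.finite(object@protein) ||
      object@protein <= 0)
    msgs <- c(msgs, "'protein' must be a single value > 0")
  np <- length(object@phosphate); no <- length(object@od)
  if (np == 0L && no == 0L)
    msgs <- c(msgs, "either phosphate or od values are required")
  if (np > 0L && np != length(object@time))
    msgs <- c(msgs, "phosphate must match time in length")
  if (no > 0L) {
    if (no != length(object@time)) msgs <- c(msgs, "od must match time in length")
    if (!is.finite(object@curveSlope) || object@curveSlope == 0)
      msgs <- c(msgs, "a standard curve (nonzero slope) is required with raw OD")
  }
  if (length(msgs)) msgs else TRUE
})

#' Noise specification for the synthetic-data generators
#'
#' @slot model character(1): "gaussian-additive", "gaussian-relative" or
#'   "poisson".
#' @slot scale numeric(1) >= 0: the additive SD, the relative SD, or ignored
#'   for "poisson" (whose scale is set by the expected counts).
#' @slot seed integer(1); mandatory, no silent entropy.
#' @aliases NoiseSpec-class
#' @exportClass NoiseSpec
setClass("NoiseSpec",
  representation(model = "character", scale = "numeric", seed = "integer")
)

setValidity("NoiseSpec", function(object) {
  msgs <- character()
  if (!object@model %in% c("gaussian-additive", "gaussian-relative", "poisson"))
    msgs <- c(msgs, "unknown noise model")
  if (!is.finite(object@scale) || object@scale < 0)
    msgs <- c(msgs, "'scale' must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "'seed' is mandatory")
  if (length(msgs)) msgs else TRUE
})
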