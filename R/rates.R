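## Constructors, unit handling and accessors for RateSet / SpeciesState.

.RATE_UNITS <- c("per_s" = 1, "per_min" = 1 / 60)

#' Convert a rate to the canonical 1/s unit
#'
#' @param x numeric rate value(s).
#' @param unit "per_s" or "per_min".
#' @return rate in 1/s.
#' @export
rateToPerSecond <- function(x, unit = c("per_s", "per_min")) {
  unit <- match.arg(unit)
  x * .RATE_UNITS[[unit]]
}

#' Construct a RateSet
#'
#' Builds the kinetic parameter set of the coarse clamp cycle. Rates may be
#' given in 1/min via the \code{units} tag (the canonical internal unit is
#' 1/s; concentrations are uM). When \code{kOn} is omitted it stays
#' \code{NA}; dynamic solvers that need it will either error or pick the
#' documented default via \code{\link{defaultKon}}.
#'
#' @param kOC closure rate of free ParB.
#' @param kCO opening rate of free ParB.
#' @param kOCdna closure rate of DNA-bound ParB (the parS-catalyzed rate
#'   when the substrate is parS).
#' @param kCOdna opening rate of DNA-bound ParB.
#' @param kH CTP hydrolysis rate (same on and off DNA).
#' @param kdOpen dissociation constant of the open form (uM).
#' @param kOn association rate of open ParB to DNA (1/(uM s)); optional.
#' @param units unit of the supplied rates: "per_s" (default) or "per_min".
#'   \code{kdOpen} is always uM; \code{kOn} is always 1/(uM s).
#' @return a \linkS4class{RateSet}.
#' @examples
#' rateSet(kOC = 0.001, kCO = 0.001, kOCdna = 1, kCOdna = 0.001,
#'         kH = 1, kdOpen = 1, units = "per_s")
#' @export
rateSet <- function(kOC, kCO, kOCdna, kCOdna, kH, kdOpen,
                    kOn = NA_real_, units = c("per_s", "per_min")) {
  units <- match.arg(units)
  f <- .RATE_UNITS[[units]]
  new("RateSet",
      kOC = as.numeric(kOC) * f, kCO = as.numeric(kCO) * f,
      kOCdna = as.numeric(kOCdna) * f, kCOdna = as.numeric(kCOdna) * f,
      kH = as.numeric(kH) * f, kdOpen = as.numeric(kdOpen),
      kOn = as.numeric(kOn))
}

#' Default association rate for dynamic solvers
#'
#' The analytic theory needs only \code{kdOpen}; ODE and stochastic solvers
#' need \code{kOn} and \code{kOffOpen = kOn * kdOpen} separately. When the
#' user does not supply \code{kOn}, the default makes binding equilibrate
#' much faster (factor \code{speedup}, default 100) than the slowest
#' conformational rate, so that the steady state is insensitive to the
#' choice. The choice is flagged in solver metadata.
#'
#' @param rates a \linkS4class{RateSet}.
#' @param speedup how much faster than the slowest conformational rate the
#'   open-form unbinding rate is made.
#' @return kOn in 1/(uM s).
#' @export
defaultKon <- function(rates, speedup = 100) {
  conf <- c(rates@kOC, rates@kCO, rates@kOCdna, rates@kCOdna, rates@kH)
  conf <- conf[conf > 0]
  if (!length(conf))
    stop("degenerate parameterization: all conformational rates are zero")
  if (rates@kdOpen <= 0) stop("'kdOpen' must be > 0 to derive a default kOn")
  ## choose kOffOpen = speedup * min(conf); kOn = kOffOpen / kdOpen
  speedup * min(conf) / rates@kdOpen
}

.konOrDefault <- function(rates) {
  if (is.na(rates@kOn)) {
    list(kOn = defaultKon(rates), defaulted = TRUE)
  } else {
    list(kOn = rates@kOn, defaulted = FALSE)
  }
}

#' Construct a SpeciesState
#'
#' @param parbOpenFree,parbClosedFree,parbOpenBound,parbClosedBound,dnaFree
#'   concentrations (uM), all >= 0.
#' @param dnaClamped whether free DNA is held fixed rather than conserved.
#' @return a \linkS4class{SpeciesState}.
#' @export
speciesState <- function(parbOpenFree, parbClosedFree, parbOpenBound,
                         parbClosedBound, dnaFree, dnaClamped = FALSE) {
  new("SpeciesState",
      parbOpenFree = as.numeric(parbOpenFree),
      parbClosedFree = as.numeric(parbClosedFree),
      parbOpenBound = as.numeric(parbOpenBound),
      parbClosedBound = as.numeric(parbClosedBound),
      dnaFree = as.numeric(dnaFree),
      dnaClamped = isTRUE(dnaClamped))
}

#' Total ParB concentration of a state
#' @param state a \linkS4class{SpeciesState}.
#' @return numeric(1), uM.
#' @export
parbTotal <- function(state) {
  state@parbOpenFree + state@parbClosedFree +
    state@parbOpenBound + state@parbClosedBound
}

#' Total DNA concentration of a state (free + bound)
#' @param state a \linkS4class{SpeciesState}.
#' @return numeric(1), uM.
#' @export
dnaTotal <- function(state) {
  state@dnaFree + state@parbOpenBound + state@parbClosedBound
}

#' Fraction of ParB bound to DNA
#' @param state a \linkS4class{SpeciesState}.
#' @return numeric(1) in [0, 1].
#' @export
boundFraction <- function(state) {
  (state@parbOpenBound + state@parbClosedBound) / parbTotal(state)
}

#' @describeIn rateSet Coerce a SpeciesState to a named numeric vector.
#' @param state a \linkS4class{SpeciesState}.
#' @export
stateAsVector <- function(state) {
  c(parb_open_free = state@parbOpenFree,
    parb_closed_free = state@parbClosedFree,
    parb_open_bound = state@parbOpenBound,
    parb_closed_bound = state@parbClosedBound,
    dna_free = state@dnaFree)
}

setMethod("show", "RateSet", function(object) {
  cat("RateSet (1/s; kdOpen in uM, kOn in 1/(uM s))\n")
  v <- c(kOC = object@kOC, kCO = object@kCO, kOCdna = object@kOCdna,
         kCOdna = object@kCOdna, kH = object@kH, kdOpen = object@kdOpen,
         kOn = object@kOn)
  print(signif(v, 5))
})

setMethod("show", "SpeciesState", function(object) {
  cat("SpeciesState (uM",
      if (object@dnaClamped) ", free DNA clamped" else "", ")\n", sep = "")
  print(signif(stateAsVector(object), 5))
  cat(sprintf("  ParB total %.5g, DNA total %.5g, bound fraction %.4f\n",
              parbTotal(object), dnaTotal(object), boundFraction(object)))
})
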