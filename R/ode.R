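## Mass-action ODE relaxation of the coarse network -- the dynamic
## counterpart (and numerical oracle) of the analytic steadyState().

#' Relax the coarse clamp network by mass-action ODE integration
#'
#' Integrates the deterministic mass-action kinetics of the coarse
#' network from an initial \linkS4class{SpeciesState}. Binding uses
#' \code{kOn} and \code{kOffOpen = kOn * kdOpen}; if the
#' \linkS4class{RateSet} carries no \code{kOn} the documented default
#' (\code{\link{defaultKon}}) is used and flagged in the result
#' attributes. For \eqn{t_{end}} much longer than the slowest timescale
#' the terminal state matches \code{\link{steadyState}}.
#'
#' @param rates a \linkS4class{RateSet}.
#' @param initial a \linkS4class{SpeciesState}.
#' @param tEnd end time (s).
#' @param nOut number of output time points (including 0 and tEnd).
#' @param dnaClamped hold free DNA constant at its initial value?
#' @param rtol,atol integrator tolerances (lsoda).
#' @return a data.frame with columns \code{time} and the five species;
#'   attributes \code{finalState} (a \linkS4class{SpeciesState}) and
#'   \code{konDefaulted}.
#' @export
relaxODE <- function(rates, initial, tEnd, nOut = 200,
                     dnaClamped = initial@dnaClamped,
                     rtol = 1e-10, atol = 1e-12) {
  stopifnot(is(rates, "RateSet"), is(initial, "SpeciesState"), tEnd > 0)
  kon <- .konOrDefault(rates)
  koff <- kon$kOn * rates@kdOpen
  y0 <- stateAsVector(initial)
  p <- c(koc = rates@kOC, kco = rates@kCO, kocD = rates@kOCdna,
         kcoD = rates@kCOdna, kh = rates@kH, kon = kon$kOn, koff = koff)

  deriv <- function(t, y, p) {
    po <- y[1]; pc <- y[2]; bo <- y[3]; bc <- y[4]; d <- y[5]
    bind <- p["kon"] * po * d
    unbind <- p["koff"] * bo
    dpo <- -p["koc"] * po + (p["kco"] + p["kh"]) * pc - bind + unbind
    dpc <- p["koc"] * po - (p["kco"] + p["kh"]) * pc
    dbo <- -p["kocD"] * bo + (p["kcoD"] + p["kh"]) * bc + bind - unbind
    dbc <- p["kocD"] * bo - (p["kcoD"] + p["kh"]) * bc
    dd <- if (dnaClamped) 0 else unbind - bind
    list(c(dpo, dpc, dbo, dbc, dd))
  }

  times <- seq(0, tEnd, length.out = max(2L, as.integer(nOut)))
  sol <- deSolve::lsoda(y0, times, deriv, p, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failure: reduce tEnd or tighten tolerances ",
         "(lsoda istate ", attr(sol, "istate")[1], ")")
  out <- as.data.frame(sol)
  names(out) <- c("time", names(y0))
  fin <- pmax(as.numeric(out[nrow(out), -1]), 0)
  attr(out, "finalState") <- speciesState(fin[1], fin[2], fin[3], fin[4],
                                          fin[5], dnaClamped = dnaClamped)
  attr(out, "konDefaulted") <- kon$defaulted
  attr(out, "kOn") <- kon$kOn
  out
}
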