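## Analytic steady-state theory of the coarse clamp cycle.
##
## The coarse network has four ParB pools -- open/closed crossed with
## free/DNA-bound -- plus free DNA. Closure converts open -> closed
## (kOC off DNA, kOCdna on DNA); opening and CTP hydrolysis both convert
## closed -> open (kCO + kH off DNA, kCOdna + kH on DNA); only the open
## form exchanges with DNA, at dissociation constant kdOpen. Because the
## reaction graph over these pools is a tree, each edge carries zero net
## flux at steady state, which yields the closed-form solution below.

#' Open/closed partition of a ParB pool at steady state
#'
#' At steady state the open fraction of a pool is
#' \eqn{(k_{co}^* + k_h) / (k_{oc}^* + k_{co}^* + k_h)}, where the starred
#' rates are the on- or off-DNA values. Hydrolysis adds to the
#' closed-to-open flux, so it shifts the partition toward the open state
#' even when closure is fast.
#'
#' @param rates a \linkS4class{RateSet}.
#' @param onDNA use the DNA-bound rates (\code{kOCdna}, \code{kCOdna})?
#' @return named numeric: \code{open} and \code{closed} fractions (sum 1).
#' @examples
#' r <- rateSet(kOC = 1, kCO = 1, kOCdna = 1, kCOdna = 1, kH = 0, kdOpen = 1)
#' openClosedPartition(r)          # c(open = 0.5, closed = 0.5)
#' @export
openClosedPartition <- function(rates, onDNA = FALSE) {
  stopifnot(is(rates, "RateSet"))
  koc <- if (onDNA) rates@kOCdna else rates@kOC
  kco <- if (onDNA) rates@kCOdna else rates@kCO
  den <- koc + kco + rates@kH
  if (den == 0)
    stop("degenerate parameterization: kOC", if (onDNA) "dna" else "",
         ", kCO", if (onDNA) "dna" else "", " and kH are all zero")
  open <- (kco + rates@kH) / den
  c(open = open, closed = 1 - open)
}

#' Observed (apparent) dissociation constant of the clamp cycle
#'
#' The full steady-state expression
#' \deqn{K_d^{obs} = K_d^{open}
#'   \frac{k_{co}^{DNA}+k_h}{k_{co}+k_h}\,
#'   \frac{k_{oc}+k_{co}+k_h}{k_{oc}^{DNA}+k_{co}^{DNA}+k_h}}
#' relating total ParB, free DNA and total bound ParB at steady state.
#' With hydrolysis off (\eqn{k_h = 0}) and equal open/closed equilibria on
#' and off DNA it reduces to \eqn{K_d^{open}} (the equilibrium value);
#' parS-accelerated closure (\eqn{k_{oc}^{DNA} \gg k_h}) drives it far
#' below \eqn{K_d^{open}} -- the ultra-affinity regime.
#'
#' @param rates a \linkS4class{RateSet} with \code{kdOpen > 0}.
#' @return numeric(1), uM.
#' @seealso \code{\link{kdObservedApprox}} for the fast-recycling
#'   approximation, \code{\link{steadyState}} for the full species solution.
#' @export
kdObserved <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  if (rates@kdOpen <= 0) stop("'kdOpen' must be > 0")
  d1 <- rates@kCO + rates@kH
  d2 <- rates@kOCdna + rates@kCOdna + rates@kH
  if (d1 == 0)
    stop("degenerate parameterization: kCO + kH is zero (free closed pool cannot reopen)")
  if (d2 == 0)
    stop("degenerate parameterization: kOCdna + kCOdna + kH is zero")
  rates@kdOpen * (rates@kCOdna + rates@kH) / d1 *
    (rates@kOC + rates@kCO + rates@kH) / d2
}

#' Fast-recycling approximation to the observed dissociation constant
#'
#' \eqn{K_d^{obs} \approx K_d^{open} k_h / (k_{oc}^{DNA} + k_h)}, valid
#' when hydrolysis dominates the free-pool conformational rates
#' (\eqn{k_h \gg k_{co}, k_{oc}}, ensuring recycling of closed clamps) and
#' closure on DNA dominates reopening
#' (\eqn{k_{oc}^{DNA} \gg k_{co}^{DNA}}). For nonspecific DNA
#' (\eqn{k_{oc}^{DNA} \to 0}) it returns \code{kdOpen}.
#'
#' @param rates a \linkS4class{RateSet}.
#' @return numeric(1), uM.
#' @export
kdObservedApprox <- function(rates) {
  stopifnot(is(rates, "RateSet"))
  if (rates@kH + rates@kOCdna <= 0)
    stop("kH + kOCdna must be > 0")
  rates@kdOpen * rates@kH / (rates@kOCdna + rates@kH)
}

#' Ultra-affinity fold reduction of the dissociation constant
#'
#' The ratio \eqn{K_d^{open} / K_d^{obs}} in the fast-recycling
#' approximation, \eqn{(k_{oc}^{parS} + k_h) / k_h}. With the literature
#' estimates \eqn{k_h \sim 1/\mathrm{min}} and
#' \eqn{k_{oc}^{parS} \sim 1/\mathrm{s}} this is 61: hydrolysis-driven
#' recycling buys parS roughly a 50-fold affinity gain over the
#' equilibrium (hydrolysis-dead) value.
#'
#' @param kH hydrolysis rate (1/s); must be > 0 unless
#'   \code{infiniteOK = TRUE}, in which case 0 returns \code{Inf}.
#' @param kOCparS parS-catalyzed closure rate (1/s).
#' @param infiniteOK return \code{Inf} for \code{kH = 0} instead of erroring.
#' @return dimensionless fold.
#' @examples
#' foldReduction(kH = 1 / 60, kOCparS = 1)   # 61
#' @export
foldReduction <- function(kH, kOCparS, infiniteOK = FALSE) {
  stopifnot(kH >= 0, kOCparS >= 0)
  if (kH == 0) {
    if (infiniteOK) return(Inf)
    stop("kH = 0: the fold reduction diverges (set infiniteOK = TRUE for Inf)")
  }
  (kOCparS + kH) / kH
}

#' Catalytic capacity of a parS site
#'
#' \eqn{k_{oc}^{parS} / k_h}: the number of closure events one parS site
#' can catalyze per hydrolysis turnover time. A capacity well above 1
#' explains why strongly substoichiometric parS fully stimulates closure
#' and hydrolysis -- a step other than closure is rate-limiting.
#'
#' @inheritParams foldReduction
#' @return dimensionless fold.
#' @export
catalyticCapacity <- function(kOCparS, kH, infiniteOK = FALSE) {
  stopifnot(kH >= 0, kOCparS >= 0)
  if (kH == 0) {
    if (infiniteOK) return(Inf)
    stop("kH = 0: capacity diverges (set infiniteOK = TRUE for Inf)")
  }
  kOCparS / kH
}

#' Analytic steady state of the coarse clamp network
#'
#' Solves the zero-net-flux conditions of the coarse network for given
#' ParB and DNA totals. Writing \eqn{a = k_{oc}/(k_{co}+k_h)} and
#' \eqn{b = k_{oc}^{DNA}/(k_{co}^{DNA}+k_h)} for the closed/open ratios of
#' the free and bound pools, the bound and free ParB pools behave like a
#' single 1:1 binding equilibrium with constant \code{kdObserved(rates)},
#' which is solved in closed form (quadratic); the open/closed split within
#' each pool follows from \code{a} and \code{b}. With
#' \code{dnaClamped = TRUE} free DNA is held at \code{dnaTotal}
#' (excess-substrate approximation) and no quadratic is needed.
#'
#' @param rates a \linkS4class{RateSet}.
#' @param parbTotal total ParB concentration (uM), > 0.
#' @param dnaTotal total (or clamped free) DNA concentration (uM), >= 0.
#' @param dnaClamped hold free DNA fixed at \code{dnaTotal}?
#' @return a \linkS4class{SpeciesState} satisfying the conservation laws.
#' @examples
#' r <- rateSet(kOC = 0, kCO = 0, kOCdna = 1, kCOdna = 0, kH = 1 / 60,
#'              kdOpen = 1)
#' st <- steadyState(r, parbTotal = 1, dnaTotal = 1, dnaClamped = TRUE)
#' boundFraction(st)    # 61/62: ultra-affinity at [DNA] = kdOpen
#' @export
steadyState <- function(rates, parbTotal, dnaTotal, dnaClamped = FALSE) {
  stopifnot(is(rates, "RateSet"), parbTotal > 0, dnaTotal >= 0)
  dFree <- rates@kCO + rates@kH
  dBound <- rates@kCOdna + rates@kH
  if (dFree == 0)
    stop("degenerate parameterization: kCO + kH is zero (free closed pool cannot reopen)")
  if (dBound == 0)
    stop("degenerate parameterization: kCOdna + kH is zero (bound closed pool cannot reopen)")
  if (rates@kdOpen <= 0) stop("'kdOpen' must be > 0")
  a <- rates@kOC / dFree        # closed/open ratio, free pool
  b <- rates@kOCdna / dBound    # closed/open ratio, bound pool
  kdObs <- kdObserved(rates)

  if (dnaClamped || dnaTotal == 0) {
    D <- dnaTotal
    ## free pool F = Po (1 + a); bound pool C = F * D / kdObs
    po <- parbTotal / ((1 + a) * (1 + D / kdObs))
    bo <- po * D / rates@kdOpen
    st <- speciesState(po, a * po, bo, b * bo, D, dnaClamped = dnaClamped)
  } else {
    ## 1:1 binding with effective constant kdObs:
    ## C^2 - (P + D + K) C + P D = 0, take the physical root
    s <- parbTotal + dnaTotal + kdObs
    C <- (s - sqrt(s * s - 4 * parbTotal * dnaTotal)) / 2
    C <- min(max(C, 0), parbTotal, dnaTotal)
    D <- dnaTotal - C
    po <- (parbTotal - C) / (1 + a)
    bo <- C / (1 + b)
    st <- speciesState(po, a * po, bo, b * bo, D)
  }
  st
}
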