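## Shared fixtures: reference rate sets and independent oracles.

## literature-estimate parameterization: hydrolysis ~1/min, parS-catalyzed
## closure ~1/s, spontaneous rates negligible
discussionRates <- function(kdOpen = 1) {
  rateSet(kOC = 0, kCO = 0, kOCdna = 1, kCOdna = 0, kH = 1 / 60,
          kdOpen = kdOpen)
}

## random valid RateSet with strictly positive denominators
randomRateSet <- function() {
  rateSet(kOC = runif(1, 0.001, 2), kCO = runif(1, 0.001, 2),
          kOCdna = runif(1, 0.001, 5), kCOdna = runif(1, 0.001, 2),
          kH = runif(1, 0, 2), kdOpen = runif(1, 0.05, 10),
          kOn = runif(1, 0.1, 10))
}

## steady-state concentration ratio [ParB][DNA]/[ParB.DNA] -- the
## operational definition of the observed dissociation constant
kdFromState <- function(st) {
  free <- st@parbOpenFree + st@parbClosedFree
  bound <- st@parbOpenBound + st@parbClosedBound
  free * st@dnaFree / bound
}

## independent 1:1 equilibrium oracle: complex concentration from
## K (Mt - c)(Xt - c) = c solved numerically
complexConcOracle <- function(K, Mt, Xt) {
  if (Xt == 0) return(0)
  f <- function(cc) K * (Mt - cc) * (Xt - cc) - cc
  stats::uniroot(f, lower = 0, upper = min(Mt, Xt) * (1 - 1e-12),
                 tol = 1e-14)$root
}

## detailed-network parameterization in the fast-exchange limit, matched
## to a coarse RateSet (see test-networks.R)
fastExchangeParams <- function(closureParS = 0.5, closureFree = 0.05,
                               kH = 0.2, kdOpen = 1, koff = 5) {
  list(ctp = 100, ctpOn = 10, ctpOff = 0, untether = 200, retether = 0,
       closureFree = closureFree, closureParS = closureParS, kH = kH,
       kdCTP = 5, kOn = koff / kdOpen, kdOpen = kdOpen,
       pRetain = closureParS / (closureParS + koff))
}
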