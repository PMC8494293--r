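test_that("single-reaction waiting times are exponential with rate k*nA", {
  ## A -> B, first-event time ~ Exp(k * nA); mean within 3 SE over
  ## many replicates
  k <- 0.5; nA <- 10L
  net <- new("ReactionNetwork",
             species = c(A = nA, B = 0L),
             reactants = matrix(c(1L, 0L), 2, 1,
                                dimnames = list(c("A", "B"), NULL)),
             products = matrix(c(0L, 1L), 2, 1,
                               dimnames = list(c("A", "B"), NULL)),
             rates = k, reactionNames = "decay",
             hydrolysisReactions = integer(0), volumeFactor = 1,
             conserved = list(total = c(A = 1L, B = 1L)))
  nrep <- 10000
  first <- vapply(seq_len(nrep), function(s) {
    simulateNetwork(net, tEnd = 50, seed = s, maxStore = 1,
                    burnIn = 0, nBatch = 1L)@times[1]
  }, numeric(1))
  mu <- 1 / (k * nA)
  se <- mu / sqrt(nrep)   # SD of Exp(rate) equals its mean
  expect_lt(abs(mean(first) - mu), 3 * se)
})

test_that("two-state stationary occupancancy matches the binomial law", {
  ## n independent clamps flipping open<->closed; the stationary closed
  ## count is Binomial(n, p) with p from the flux-balance partition
  r <- rateSet(kOC = 1, kCO = 0.5, kOCdna = 1, kCOdna = 1, kH = 0.25,
               kdOpen = 1)
  p <- openClosedPartition(r)[["closed"]]
  n <- 10L
  net <- buildCoarseNetwork(r, parbCopies = n, dnaCopies = 0L)
  nrep <- 400
  closed <- vapply(seq_len(nrep), function(s) {
    simulateNetwork(net, tEnd = 20, seed = 1000 + s, maxStore = 0,
                    burnIn = 10, nBatch = 1L)@finalState[["parb_closed_free"]]
  }, numeric(1))
  counts <- tabulate(closed + 1L, nbins = n + 1L)
  probs <- stats::dbinom(0:n, n, p)
  ## pool low-expectation bins for a valid chi-square
  keep <- probs * nrep >= 5
  obs <- c(counts[keep], sum(counts[!keep]))
  expe <- c(probs[keep], sum(probs[!keep]))
  pval <- suppressWarnings(stats::chisq.test(obs, p = expe)$p.value)
  expect_gt(pval, 0.01)
})

test_that("the same seed and network reproduce the trajectory exactly", {
  r <- rateSet(kOC = 0.2, kCO = 0.1, kOCdna = 1, kCOdna = 0.1, kH = 0.2,
               kdOpen = 1, kOn = 1)
  net <- buildCoarseNetwork(r, parbCopies = 100L, dnaCopies = 20L)
  t1 <- simulateNetwork(net, tEnd = 50, seed = 7)
  t2 <- simulateNetwork(net, tEnd = 50, seed = 7)
  expect_identical(t1@times, t2@times)
  expect_identical(t1@reactionIds, t2@reactionIds)
  expect_identical(t1@metadata$networkHash, t2@metadata$networkHash)
  t3 <- simulateNetwork(net, tEnd = 50, seed = 8)
  expect_false(identical(t1@times, t3@times))
})

test_that("conserved moieties hold at every event of a trajectory", {
  r <- rateSet(kOC = 0.5, kCO = 0.2, kOCdna = 2, kCOdna = 0.2, kH = 0.5,
               kdOpen = 1, kOn = 2)
  net <- buildCoarseNetwork(r, parbCopies = 50L, dnaCopies = 10L)
  traj <- simulateNetwork(net, tEnd = 30, seed = 3)
  states <- trajectoryStates(traj, net)
  parb <- rowSums(states[, c("parb_open_free", "parb_closed_free",
                             "parb_open_bound", "parb_closed_bound")])
  dna <- rowSums(states[, c("dna_free", "parb_open_bound",
                            "parb_closed_bound")])
  expect_true(all(parb == 50))
  expect_true(all(dna == 10))
  expect_true(all(states[, -(1:2)] >= 0))
  expect_true(all(diff(traj@times) > 0))
})

test_that("time-averaged occupancies reproduce the analytic steady state", {
  r <- rateSet(kOC = 0.2, kCO = 0.1, kOCdna = 1, kCOdna = 0.1, kH = 0.2,
               kdOpen = 1, kOn = 1)
  vf <- 100
  net <- buildCoarseNetwork(r, parbCopies = 500L, dnaCopies = 100L,
                            volumeFactor = vf)
  traj <- simulateNetwork(net, tEnd = 1500, seed = 42, maxStore = 0,
                          burnIn = 150)
  ref <- stateAsVector(steadyState(r, 500 / vf, 100 / vf)) * vf
  se <- tavgSE(traj)
  for (sp in names(ref)) {
    expect_lt(abs(traj@tavgMean[[sp]] - ref[[sp]]),
              3 * se[[sp]] + 1e-9)
  }
})

test_that("with kH = 0 the free pool obeys detailed balance", {
  r <- rateSet(kOC = 0.8, kCO = 0.4, kOCdna = 1, kCOdna = 1, kH = 0,
               kdOpen = 1)
  net <- buildCoarseNetwork(r, parbCopies = 500L, dnaCopies = 0L)
  traj <- simulateNetwork(net, tEnd = 500, seed = 5, maxStore = 0,
                          burnIn = 50)
  ratio <- traj@tavgMean[["parb_closed_free"]] /
    traj@tavgMean[["parb_open_free"]]
  se <- tavgSE(traj)
  relSE <- sqrt((se[["parb_closed_free"]] /
                   traj@tavgMean[["parb_closed_free"]])^2 +
                (se[["parb_open_free"]] /
                   traj@tavgMean[["parb_open_free"]])^2)
  expect_lt(abs(ratio - 0.8 / 0.4), 3 * ratio * relSE)
})

test_that("hydrolysis flux estimates the per-ParB turnover rate", {
  ## no hydrolysis -> zero flux
  r0 <- rateSet(kOC = 0.5, kCO = 0.5, kOCdna = 1, kCOdna = 1, kH = 0,
                kdOpen = 1)
  net0 <- buildCoarseNetwork(r0, parbCopies = 100L, dnaCopies = 0L)
  expect_equal(hydrolysisFlux(simulateNetwork(net0, 50, seed = 1,
                                              maxStore = 0)), 0)

  ## flux is invariant to the volume factor at fixed concentrations
  r <- rateSet(kOC = 0.2, kCO = 0.1, kOCdna = 1, kCOdna = 0.1, kH = 0.2,
               kdOpen = 1, kOn = 1)
  fluxes <- ses <- numeric(2)
  for (i in 1:2) {
    vf <- c(50, 200)[i]
    net <- buildCoarseNetwork(r, parbCopies = as.integer(5 * vf),
                              dnaCopies = as.integer(1 * vf),
                              volumeFactor = vf)
    reps <- vapply(1:4, function(s)
      hydrolysisFlux(simulateNetwork(net, 400, seed = 100 * i + s,
                                     maxStore = 0, burnIn = 50)),
      numeric(1))
    fluxes[i] <- mean(reps); ses[i] <- stats::sd(reps) / sqrt(length(reps))
  }
  expect_lt(abs(fluxes[1] - fluxes[2]), 3 * sqrt(sum(ses^2)))
})

test_that("propensities respect mass-action combinatorics for order two", {
  ## A + A -> B at rate c: propensity c * nA (nA - 1); with nA = 2 the
  ## first-event time is Exp(2c)
  cc <- 0.25
  net <- new("ReactionNetwork",
             species = c(A = 2L, B = 0L),
             reactants = matrix(c(2L, 0L), 2, 1,
                                dimnames = list(c("A", "B"), NULL)),
             products = matrix(c(0L, 1L), 2, 1,
                               dimnames = list(c("A", "B"), NULL)),
             rates = cc, reactionNames = "dimerize",
             hydrolysisReactions = integer(0), volumeFactor = 1,
             conserved = list())
  nrep <- 4000
  first <- vapply(seq_len(nrep), function(s)
    simulateNetwork(net, tEnd = 100, seed = s, maxStore = 1,
                    burnIn = 0, nBatch = 1L)@times[1], numeric(1))
  mu <- 1 / (cc * 2 * 1)
  expect_lt(abs(mean(first) - mu), 3 * mu / sqrt(nrep))
})
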