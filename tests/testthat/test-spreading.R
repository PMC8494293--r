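test_that("the analytic profile encodes diffusion-decay balance", {
  cfg <- latticeConfig(windowLength = 4001, D = 100, loadingRate = 2,
                       kOff = 0.04)
  an <- analyticProfile(cfg)
  ## birth-death balance: total clamps = loading / unloading
  expect_equal(sum(occupancy(an)), 2 / 0.04, tolerance = 1e-9)
  expect_equal(an@metadata$lambda, sqrt(100 / 0.04))
  ## lambda doubles when D quadruples
  cfg4 <- latticeConfig(windowLength = 4001, D = 400, loadingRate = 2,
                        kOff = 0.04)
  expect_equal(analyticProfile(cfg4)@metadata$lambda,
               2 * an@metadata$lambda)
  ## FWHM of the two-sided exponential is 2 lambda ln 2
  expect_equal(peakWidth(an, "fwhm"), 2 * an@metadata$lambda * log(2),
               tolerance = 0.01)
  ## outside the validity regime the oracle refuses
  expect_error(analyticProfile(latticeConfig(kOff = 0)), "kOffEffective")
  expect_error(
    analyticProfile(latticeConfig(
      roadblocks = data.frame(pos = 10, behavior = "absorb"))),
    "valid")
})

test_that("simulated steady-state profiles match the analytic oracle", {
  cfg <- latticeConfig(windowLength = 2001, D = 100, loadingRate = 2,
                       kOff = 0.04)
  an <- binProfile(analyticProfile(cfg), 50)
  reps <- lapply(1:6, function(s)
    occupancy(binProfile(simulateProfile(cfg, tEnd = 1500, seed = s,
                                         burnIn = 300), 50)))
  m <- Reduce(`+`, reps) / 6
  se <- sqrt(Reduce(`+`, lapply(reps, function(x) (x - m)^2)) / 5) /
    sqrt(6)
  ## keep bins with enough signal for a meaningful SE
  keep <- occupancy(an) > 0.05
  viol <- abs(m - occupancy(an))[keep] > (3 * se + 1e-6)[keep]
  expect_lt(mean(viol), 0.05)

  ## terminal clamp positions are iid two-sided exponential at steady
  ## state: KS test on the folded distances, not rejected at alpha 0.01
  prof <- simulateProfile(cfg, tEnd = 4000, seed = 99, burnIn = 500)
  term <- prof@metadata$terminalPositions
  expect_gt(length(term), 25)
  lam <- sqrt(cfg@D / kOffEffective(cfg))
  d <- abs(term - cfg@parSPos) + stats::runif(length(term)) - 0.5
  pv <- suppressWarnings(
    stats::ks.test(d[d > 0], function(q) 1 - exp(-q / lam))$p.value)
  expect_gt(pv, 0.01)
})

test_that("without unloading the cohort broadens as sqrt(2 D t)", {
  D <- 50
  sds <- vapply(c(100, 1000), function(tEnd) {
    cfg <- latticeConfig(windowLength = 8001, D = D, loadingRate = 0,
                         kOff = 0)
    prof <- simulateProfile(cfg, tEnd = tEnd, seed = 13,
                            mode = "terminal", burnIn = tEnd / 100,
                            initialClamps = 4000L)
    stats::sd(prof@metadata$terminalPositions)
  }, numeric(1))
  expect_lt(abs(sds[1] / sqrt(2 * D * 100) - 1), 0.05)
  expect_lt(abs(sds[2] / sqrt(2 * D * 1000) - 1), 0.05)
})

test_that("an absorbing roadblock on one side skews the profile", {
  cfg <- latticeConfig(windowLength = 2001, parSPos = 1000L, D = 100,
                       loadingRate = 2, kOff = 0.02,
                       roadblocks = data.frame(pos = 990,
                                               behavior = "absorb"))
  prof <- simulateProfile(cfg, tEnd = 2000, seed = 17, burnIn = 400)
  occ <- occupancy(prof)
  left <- sum(occ[1:1000]); right <- sum(occ[1002:2001])
  expect_gt(right, 2 * left)   # heavier tail on the open side
})

test_that("peak widths behave on spikes, flats and binned tracks", {
  spike <- occupancyProfile(0:10, c(rep(0, 5), 3, rep(0, 5)), 1)
  expect_equal(peakWidth(spike, "fwhm"), 1)
  expect_equal(peakWidth(spike, "central-mass", q = 0.9, center = 5.5), 1)
  flat <- occupancyProfile(0:10, rep(1, 11), 1)
  expect_error(peakWidth(flat), "flat profile")
  ## central-mass on the exact exponential: interval holding q of the
  ## mass has half-length lambda ln(1/(1-q))
  cfg <- latticeConfig(windowLength = 8001, D = 100, loadingRate = 1,
                       kOff = 0.04)
  an <- analyticProfile(cfg)
  lam <- an@metadata$lambda
  expect_equal(peakWidth(an, "central-mass", q = 0.9),
               2 * lam * log(10), tolerance = 0.02)
})

test_that("width ordering: EQ-mutant transient exceeds wild-type steady state", {
  ## same D, loading rate and observation time; the wild type turns over
  ## (width pinned at ~sqrt(D/kOff)) while the hydrolysis-dead clamps
  ## keep broadening as sqrt(2 D t)
  D <- 100; load <- 1; tEnd <- 1200
  wt <- latticeConfig(windowLength = 20001, D = D, loadingRate = load,
                      kOff = 1 / 60)
  wtProf <- simulateProfile(wt, tEnd = tEnd, seed = 23, burnIn = 300)
  eq <- latticeConfig(windowLength = 20001, D = D, loadingRate = load,
                      kOff = 0)
  eqProf <- simulateProfile(eq, tEnd = tEnd, seed = 24,
                            mode = "terminal", burnIn = tEnd / 100)
  wWT <- peakWidth(binProfile(wtProf, 250), "central-mass", q = 0.9)
  wEQ <- peakWidth(binProfile(eqProf, 250), "central-mass", q = 0.9)
  expect_gt(wEQ, 1.2 * wWT)
})

test_that("width responds monotonically to D, unloading and retention", {
  base <- function(D, kOff, pRetain = 0)
    peakWidth(analyticProfile(
      latticeConfig(windowLength = 40001, D = D, loadingRate = 1,
                    kOff = kOff, pRetain = pRetain)), "fwhm")
  Ds <- c(25, 100, 400)
  expect_true(all(diff(vapply(Ds, base, numeric(1), kOff = 0.02)) > 0))
  ks <- c(0.08, 0.02, 0.005)
  expect_true(all(diff(vapply(ks, function(k) base(100, k),
                              numeric(1))) > 0))
  ## raising pRetain at fixed hydrolysis rate widens the profile
  ps <- c(0, 0.5, 0.9)
  expect_true(all(diff(vapply(ps, function(p) base(100, 0.02, p),
                              numeric(1))) > 0))
})

test_that("binning conserves occupancy and is associative", {
  cfg <- latticeConfig(windowLength = 4000, D = 100, loadingRate = 1,
                       kOff = 0.02)
  an <- analyticProfile(cfg)
  expect_identical(binProfile(an, 1), an)
  b1 <- binProfile(an, 1000)
  expect_equal(sum(occupancy(b1)), sum(occupancy(an)), tolerance = 1e-12)
  expect_equal(occupancy(binProfile(b1, 2000)),
               occupancy(binProfile(an, 2000)), tolerance = 1e-12)
  expect_error(binProfile(an, 0), "binSize")
  expect_error(binProfile(b1, 1500), "multiple")
})

test_that("profiles round-trip through bedGraph", {
  cfg <- latticeConfig(windowLength = 5000, D = 100, loadingRate = 1,
                       kOff = 0.02)
  prof <- binProfile(analyticProfile(cfg), 1000)
  f <- tempfile(fileext = ".bedGraph")
  writeBedGraph(prof, f)
  back <- readBedGraph(f)
  expect_equal(binStarts(back), binStarts(prof))
  expect_equal(occupancy(back), occupancy(prof), tolerance = 1e-6)
  ## 0-based half-open, non-overlapping, monotone
  gr <- toGRanges(prof)
  expect_true(all(diff(GenomicRanges::start(gr)) == 1000))
})

test_that("exclusion caps injections at a saturated parS site", {
  cfg <- latticeConfig(windowLength = 101, parSPos = 50L, D = 0.5,
                       loadingRate = 50, kOff = 0.01, exclusion = TRUE)
  expect_warning(simulateProfile(cfg, tEnd = 20, seed = 5),
                 "saturates")
})
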