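test_that("open/closed partition follows the flux-balance ratio", {
  r <- rateSet(kOC = 0.3, kCO = 0.3, kOCdna = 1, kCOdna = 0, kH = 0,
               kdOpen = 1)
  expect_equal(unname(openClosedPartition(r)), c(0.5, 0.5))

  ## hydrolysis shifts the bound pool toward open: kH/(kOCdna + kH)
  r2 <- rateSet(kOC = 1, kCO = 1, kOCdna = 1, kCOdna = 0, kH = 1 / 60,
                kdOpen = 1)
  expect_equal(unname(openClosedPartition(r2, onDNA = TRUE)[1]),
               (1 / 60) / (1 + 1 / 60), tolerance = 1e-12)

  ## kH = 0 recovers detailed balance: closed/open = kOC/kCO
  r3 <- rateSet(kOC = 0.7, kCO = 0.2, kOCdna = 1, kCOdna = 1, kH = 0,
                kdOpen = 1)
  p <- openClosedPartition(r3)
  expect_equal(p[["closed"]] / p[["open"]], 0.7 / 0.2, tolerance = 1e-12)

  r0 <- rateSet(kOC = 0, kCO = 0, kOCdna = 1, kCOdna = 1, kH = 0,
                kdOpen = 1)
  expect_error(openClosedPartition(r0), "degenerate")
})

test_that("kdObserved evaluates the full steady-state expression", {
  ## frozen by direct arithmetic on the printed expression:
  ## 1 * (0.001 + 1/60)/(0.001 + 1/60) * (0.002 + 1/60)/(1.001 + 1/60)
  r <- rateSet(kOC = 0.001, kCO = 0.001, kOCdna = 1, kCOdna = 0.001,
               kH = 1 / 60, kdOpen = 1)
  expect_equal(kdObserved(r), 0.0183426138, tolerance = 1e-8)

  expect_error(kdObserved(rateSet(kOC = 1, kCO = 0, kOCdna = 1,
                                  kCOdna = 1, kH = 0, kdOpen = 1)),
               "degenerate")
})

test_that("limiting cases of the observed dissociation constant hold exactly", {
  ## case 1: hydrolysis-dead with unchanged open/closed equilibrium
  r1 <- rateSet(kOC = 0.4, kCO = 0.1, kOCdna = 2, kCOdna = 0.5, kH = 0,
                kdOpen = 3)   # kOCdna/kCOdna = kOC/kCO = 4
  expect_equal(kdObserved(r1), 3, tolerance = 1e-12)

  ## case 2: DNA leaves the transitions unchanged (any kH)
  for (kH in c(0.01, 0.5, 3)) {
    r2 <- rateSet(kOC = 0.3, kCO = 0.2, kOCdna = 0.3, kCOdna = 0.2,
                  kH = kH, kdOpen = 2.5)
    expect_equal(kdObserved(r2), 2.5, tolerance = 1e-12)
  }

  ## case 3 (parS): fast closure on DNA drives kd far below kdOpen,
  ## approaching the fast-recycling approximation
  r3 <- rateSet(kOC = 1e-4, kCO = 0, kOCdna = 1, kCOdna = 0, kH = 1 / 60,
                kdOpen = 1)
  expect_lt(kdObserved(r3), 0.02)
  expect_equal(kdObserved(r3), kdObservedApprox(r3), tolerance = 0.01)
})

test_that("the fast-recycling approximation behaves as documented", {
  r <- discussionRates()
  expect_equal(kdObservedApprox(r), 1 / 61, tolerance = 1e-12)

  ## nonspecific-DNA limit
  rns <- rateSet(kOC = 0.1, kCO = 0.1, kOCdna = 0, kCOdna = 0.1,
                 kH = 0.5, kdOpen = 2)
  expect_equal(kdObservedApprox(rns), 2, tolerance = 1e-12)

  ## within the validity regime approx and full expression agree to <= 5%
  for (kocD in c(0.5, 1, 2, 5)) {
    for (kh in c(0.05, 0.1, 0.2)) {
      r <- rateSet(kOC = kh / 100, kCO = 0, kOCdna = kocD, kCOdna = 0,
                   kH = kh, kdOpen = 1)
      expect_lt(abs(kdObservedApprox(r) / kdObserved(r) - 1), 0.05)
    }
  }

  ## monotonicity: increasing in kH, decreasing in kOCdna
  kh <- seq(0.01, 2, length.out = 20)
  v <- vapply(kh, function(h) kdObservedApprox(
    rateSet(kOC = 0, kCO = 0, kOCdna = 1, kCOdna = 0, kH = h,
            kdOpen = 1)), numeric(1))
  expect_true(all(diff(v) > 0))
  kocD <- seq(0.1, 5, length.out = 20)
  v <- vapply(kocD, function(k) kdObservedApprox(
    rateSet(kOC = 0, kCO = 0, kOCdna = k, kCOdna = 0, kH = 0.3,
            kdOpen = 1)), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("fold reduction and catalytic capacity quantify parS catalysis", {
  expect_equal(foldReduction(kH = 1 / 60, kOCparS = 1), 61)
  expect_equal(foldReduction(kH = 1, kOCparS = 0), 1)
  expect_equal(foldReduction(kH = 0.5, kOCparS = 0.5), 2)
  expect_error(foldReduction(kH = 0, kOCparS = 1), "diverges")
  expect_identical(foldReduction(kH = 0, kOCparS = 1, infiniteOK = TRUE),
                   Inf)
  ## fold reduction is exactly kdOpen / kdObservedApprox
  r <- discussionRates(kdOpen = 2.5)
  expect_equal(foldReduction(r@kH, r@kOCdna),
               r@kdOpen / kdObservedApprox(r), tolerance = 1e-12)

  expect_equal(catalyticCapacity(kOCparS = 1, kH = 1 / 60), 60)
  expect_equal(catalyticCapacity(kOCparS = 0.3, kH = 0.3), 1)
  expect_equal(catalyticCapacity(kOCparS = 2, kH = 0.1),
               2 * catalyticCapacity(kOCparS = 1, kH = 0.1))
})

test_that("steadyState solves the network and satisfies conservation", {
  ## two-state equilibrium without DNA or hydrolysis
  r <- rateSet(kOC = 0.6, kCO = 0.2, kOCdna = 1, kCOdna = 1, kH = 0,
               kdOpen = 1)
  st <- steadyState(r, parbTotal = 3, dnaTotal = 0)
  expect_equal(st@parbClosedFree / st@parbOpenFree, 0.6 / 0.2,
               tolerance = 1e-12)
  expect_equal(st@parbOpenBound + st@parbClosedBound, 0)

  ## ultra-affinity at [DNA] clamped at kdOpen: bound fraction 61/62,
  ## vs 1/2 for the hydrolysis-free nonspecific case
  rUltra <- discussionRates()
  stU <- steadyState(rUltra, 1, 1, dnaClamped = TRUE)
  expect_equal(boundFraction(stU), 61 / 62, tolerance = 1e-9)
  rEq <- rateSet(kOC = 0.1, kCO = 0.1, kOCdna = 0.1, kCOdna = 0.1,
                 kH = 0, kdOpen = 1)
  expect_equal(boundFraction(steadyState(rEq, 1, 1, dnaClamped = TRUE)),
               0.5, tolerance = 1e-9)

  expect_error(steadyState(rateSet(kOC = 1, kCO = 0, kOCdna = 1,
                                   kCOdna = 1, kH = 0, kdOpen = 1),
                           1, 1), "degenerate")
})

test_that("kdObserved equals the concentration ratio from steadyState", {
  set.seed(421)
  for (i in 1:50) {
    r <- randomRateSet()
    pt <- runif(1, 0.1, 20); dt <- runif(1, 0.1, 20)
    st <- steadyState(r, pt, dt)
    expect_equal(kdFromState(st), kdObserved(r), tolerance = 1e-9)
    expect_equal(parbTotal(st), pt, tolerance = 1e-9)
    expect_equal(dnaTotal(st), dt, tolerance = 1e-9)
  }
})

test_that("ultra-affinity direction: faster closure on DNA lowers kd", {
  set.seed(77)
  for (i in 1:40) {
    kco <- runif(1, 0.01, 1)
    r <- rateSet(kOC = runif(1, 0.01, 2), kCO = kco,
                 kOCdna = runif(1, 0.01, 2), kCOdna = kco,
                 kH = runif(1, 0.01, 1), kdOpen = 1)
    if (r@kOCdna >= r@kOC) expect_lte(kdObserved(r), r@kdOpen)
    else expect_gt(kdObserved(r), r@kdOpen)
  }
})

test_that("rate units convert and defaults derive as documented", {
  rMin <- rateSet(kOC = 60, kCO = 60, kOCdna = 60, kCOdna = 60, kH = 60,
                  kdOpen = 1, units = "per_min")
  expect_equal(rMin@kOC, 1)
  expect_equal(rMin@kH, 1)
  expect_equal(rMin@kdOpen, 1)   # concentrations are never rescaled
  expect_equal(rateToPerSecond(1, "per_min"), 1 / 60)

  ## default kOn: unbinding 100x faster than the slowest conformational rate
  r <- rateSet(kOC = 0.1, kCO = 0.02, kOCdna = 1, kCOdna = 0.5, kH = 0.3,
               kdOpen = 2)
  expect_equal(defaultKon(r) * r@kdOpen, 100 * 0.02)
})
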