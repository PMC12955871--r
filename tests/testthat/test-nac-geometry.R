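test_that("angleDeg handles collinear, orthogonal and equilateral cases", {
  expect_equal(angleDeg(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(angleDeg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  # equilateral triangle: all internal angles 60 degrees
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(angleDeg(tri[2, ], tri[1, ], tri[3, ]), 60)
  expect_error(angleDeg(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
  # clamped against rounding: never NaN for near-collinear arms
  expect_true(is.finite(angleDeg(c(1, 1e-9, 0), c(0, 0, 0), c(2, 0, 0))))
})

test_that("measureSite uses the minimum acceptor-N distance and the C1 angle", {
  # collinear construction: O-(0,0,0), N at 3.3, C1 at (-2,0,0), S at (-3.8,0,0)
  xyz <- rbind(c(0, 0, 0), c(3.3, 0, 0), c(-2, 0, 0), c(-3.8, 0, 0),
               c(5, 0, 0))
  atoms <- data.frame(serial = 1:5,
                      name = c("O", "NE2", "C1", "S", "ND1"),
                      resname = c("LIG", "HIS", "SAM", "SAM", "HIS"),
                      chain = "A", resseq = c(2L, 3L, 1L, 1L, 3L),
                      element = c("O", "N", "C", "S", "N"))
  ens <- Ensemble(atoms, array(xyz, dim = c(5, 3, 1)))
  site1 <- siteSpec("x",
    oSel = selector(resname = "LIG", atomNames = "O"),
    nSels = selector(atomNames = "NE2"),
    c1Sel = selector(atomNames = "C1"),
    sSel = selector(atomNames = "S"))
  rec <- measureSite(ens, site1)
  expect_equal(rec$d_angstrom, 3.3)
  expect_equal(rec$theta_deg, 180)
  # two candidate nitrogens at 3.3 and 5.0: the minimum wins
  site2 <- siteSpec("x2",
    oSel = selector(resname = "LIG", atomNames = "O"),
    nSels = list(selector(atomNames = "NE2"), selector(atomNames = "ND1")),
    c1Sel = selector(atomNames = "C1"),
    sSel = selector(atomNames = "S"))
  expect_equal(measureSite(ens, site2)$d_angstrom, 3.3)
  # selector resolving to 0 or >= 2 atoms names the site in the error
  site3 <- siteSpec("bad",
    oSel = selector(resname = "LIG", atomNames = "O"),
    nSels = selector(atomNames = c("NE2", "ND1")),
    c1Sel = selector(atomNames = "C1"),
    sSel = selector(atomNames = "S"))
  expect_error(measureSite(ens, site3), "bad")
  expect_error(measureSite(ens, siteSpec("gone",
    oSel = selector(atomNames = "OX"),
    nSels = selector(atomNames = "NE2"),
    c1Sel = selector(atomNames = "C1"),
    sSel = selector(atomNames = "S"))), "gone")
})

test_that("measureSite recovers embedded internal coordinates to 1e-6", {
  set.seed(101)
  n <- 500
  d <- runif(n, 0.8, 7.5)
  th <- runif(n, 5, 175)
  xyz <- embedGeometry(d, th)
  atoms <- data.frame(serial = 1:4, name = c("S", "C1", "O", "NE2"),
                      resname = c("SAM", "SAM", "LIG", "HIS"),
                      chain = "A", resseq = c(1L, 1L, 2L, 3L),
                      element = c("S", "C", "O", "N"))
  ens <- Ensemble(atoms, xyz)
  rec <- measureSite(ens, scaffold_site("A"))
  expect_lt(max(abs(rec$d_angstrom - d)), 1e-6)
  expect_lt(max(abs(rec$theta_deg - th)), 1e-6)
})

test_that("classifyReactive applies strict distance and inclusive angle bounds", {
  # printed worked-example geometries: 2'/3'/4'-OH of the gallacetophenone
  expect_false(classifyReactive(5.8, 110))  # both criteria fail
  expect_true(classifyReactive(3.3, 155))   # inside the region
  expect_false(classifyReactive(4.0, 160))  # distance fails
  # boundary semantics
  expect_false(classifyReactive(3.5, 150))  # strict <
  expect_true(classifyReactive(3.499999, 125))   # inclusive lower angle
  expect_true(classifyReactive(3.499999, 170))   # inclusive upper angle
  expect_false(classifyReactive(3.0, 170.0001))
})

test_that("classification is monotone under region shrinkage", {
  set.seed(21)
  d <- runif(200, 0, 8); th <- runif(200, 0, 180)
  wide <- classifyReactive(d, th, reactiveRegion(3.5, 125, 170))
  narrow <- classifyReactive(d, th, reactiveRegion(3.0, 135, 160))
  expect_true(all(narrow <= wide))  # shrinking never adds reactive frames
})

test_that("rankSites orders by fraction, breaks ties alphabetically, flags ties", {
  mk <- function(lab, nr, n) {
    gen <- generateEnsemble(siteDistribution(lab, 3.3, 0.3, 155, 10), 2, 1)
    new("SiteStats", siteLabel = lab, nFrames = as.integer(n),
        nReactive = as.integer(nr), fraction = nr / n,
        records = data.frame(), kde = list(), region = reactiveRegion())
  }
  r <- rankSites(list(mk("4'-OH", 3, 1000), mk("3'-OH", 319, 1000),
                      mk("2'-OH", 1, 10000)))
  expect_equal(r$site, c("3'-OH", "4'-OH", "2'-OH"))
  expect_false(any(r$tie))
  r2 <- rankSites(list(mk("B", 2, 10), mk("A", 2, 10)))
  expect_equal(r2$site, c("A", "B"))
  expect_true(all(r2$tie))
  r3 <- rankSites(mk("solo", 1, 2))
  expect_equal(nrow(r3), 1L)
})
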