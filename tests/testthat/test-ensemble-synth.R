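test_that("sampleInternal is deterministic, truncated, and hits the degenerate limit", {
  dist <- siteDistribution("s", 3.3, 0.3, 155, 10)
  a <- sampleInternal(dist, 100, seed = 9)
  b <- sampleInternal(dist, 100, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$d > 0.5))
  expect_true(all(a$theta >= 0 & a$theta <= 180))
  # sd -> 0 limit: all draws collapse onto the means
  tight <- sampleInternal(siteDistribution("t", 3.3, 1e-9, 155, 1e-9), 50, 1)
  expect_lt(max(abs(tight$d - 3.3)), 1e-6)
  expect_lt(max(abs(tight$theta - 155)), 1e-6)
})

test_that("sample moments recover the distribution parameters within CLT bounds", {
  n <- 20000
  dr <- sampleInternal(siteDistribution("s", 3.3, 0.3, 155, 10), n, seed = 123)
  # analytic truncated-normal moments (theta is truncated above at 180,
  # i.e. at beta = 2.5 sd; the d truncation at 0.5 A is ~9 sd away)
  tmean <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    Z <- pnorm(be) - pnorm(al)
    mu + s * (dnorm(al) - dnorm(be)) / Z
  }
  tsd <- function(mu, s, a, b) {
    al <- (a - mu) / s; be <- (b - mu) / s
    Z <- pnorm(be) - pnorm(al)
    f <- function(x) ifelse(is.finite(x), x * dnorm(x), 0)
    s * sqrt(1 + (f(al) - f(be)) / Z - ((dnorm(al) - dnorm(be)) / Z)^2)
  }
  expect_lt(abs(mean(dr$d) - tmean(3.3, 0.3, 0.5, Inf)), 3 * 0.3 / sqrt(n))
  expect_lt(abs(mean(dr$theta) - tmean(155, 10, 0, 180)), 3 * 10 / sqrt(n))
  expect_lt(abs(sd(dr$d) - tsd(3.3, 0.3, 0.5, Inf)), 0.01)
  expect_lt(abs(sd(dr$theta) - tsd(155, 10, 0, 180)), 0.3)
  # copula correlation materialises in the draws
  cor_dr <- sampleInternal(siteDistribution("c", 3.3, 0.3, 155, 10, rho = 0.8),
                           5000, seed = 7)
  expect_gt(cor(cor_dr$d, cor_dr$theta), 0.7)
})

test_that("embedGeometry places the right-angle construction and rejects degenerate angles", {
  xyz <- embedGeometry(1.0, 90)[, , 1]
  expect_equal(xyz[3, ], c(1.80, 3.0, 0))        # O
  expect_equal(sqrt(sum((xyz[3, ] - xyz[2, ])^2)), 3.0)  # |O - C1|
  expect_equal(xyz[1, ], c(0, 0, 0))             # S at origin
  expect_equal(xyz[2, ], c(1.80, 0, 0))          # C1 on x-axis
  expect_error(embedGeometry(1.0, 180), "degenerate")
  expect_error(embedGeometry(1.0, 0), "degenerate")
  expect_error(embedGeometry(-1, 90), "positive")
})

test_that("measureSite after a random rigid motion still recovers (d, theta)", {
  set.seed(12)
  gen <- generateEnsemble(siteDistribution("s", 3.3, 0.3, 155, 10), 50, 3)
  moved <- transformEnsemble(gen$ensemble, random_rotation(), rnorm(3, sd = 30))
  rec <- measureSite(moved, gen$sites$s)
  expect_lt(max(abs(rec$d_angstrom - gen$truth$d)), 1e-6)
  expect_lt(max(abs(rec$theta_deg - gen$truth$theta)), 1e-6)
})

test_that("generateEnsemble truth table matches siteStats and survives PDB round-trip", {
  gen <- generateEnsemble(
    list(siteDistribution("3'-OH", 3.3, 0.3, 155, 10),
         siteDistribution("4'-OH", 5.0, 0.5, 150, 15)),
    n = 200, seed = 17)
  for (lab in names(gen$sites)) {
    st <- siteStats(gen$ensemble, gen$sites[[lab]])
    tr <- gen$truth[gen$truth$site == lab, ]
    expect_identical(st@fraction, mean(tr$reactive))
    expect_equal(st@records$d_angstrom, tr$d, tolerance = 1e-6)
  }
  # flags are consistent with classify applied to the sampled pairs
  expect_identical(gen$truth$reactive,
                   classifyReactive(gen$truth$d, gen$truth$theta))
  # PDB round-trip: stats agree within column precision of the coordinates
  reparsed <- parsePDB(writePDB(gen$ensemble))
  st1 <- siteStats(gen$ensemble, gen$sites[["3'-OH"]])
  st2 <- siteStats(reparsed, gen$sites[["3'-OH"]])
  expect_equal(st2@records$d_angstrom, st1@records$d_angstrom, tolerance = 5e-3)
  expect_equal(st2@fraction, st1@fraction, tolerance = 0.05)
})

test_that("per-site streams are independent: adding a site never perturbs another", {
  one <- generateEnsemble(siteDistribution("A-site", 3.3, 0.3, 155, 10),
                          n = 100, seed = 11)
  two <- generateEnsemble(
    list(siteDistribution("A-site", 3.3, 0.3, 155, 10),
         siteDistribution("B-site", 4.5, 0.4, 140, 12)),
    n = 100, seed = 11)
  expect_identical(one$truth[one$truth$site == "A-site", c("d", "theta")],
                   two$truth[two$truth$site == "A-site", c("d", "theta")])
  expect_error(generateEnsemble(
    list(siteDistribution("X", 3, 0.3, 150, 9),
         siteDistribution("X", 3, 0.3, 150, 9)), 10, 1), "unique")
})

test_that("a region placed at an empirical quantile yields the expected fraction", {
  # choose the region after sampling so that exactly the 4 smallest of 10
  # distances are inside it: the reported fraction must be 0.4 exactly
  dist <- siteDistribution("q", 3.3, 0.3, 170, 1)
  probe <- generateEnsemble(dist, n = 10, seed = 23)
  cut <- sort(probe$truth$d)[4] + 1e-9
  region <- reactiveRegion(cut, 0.1, 179.9)
  # same seed regenerates identical draws, now flagged under the new region
  gen <- generateEnsemble(dist, n = 10, seed = 23, region = region)
  expect_identical(gen$truth$d, probe$truth$d)
  expect_equal(mean(gen$truth$reactive), 0.4)
  st <- siteStats(gen$ensemble, gen$sites$q, region)
  expect_equal(st@fraction, 0.4)
})
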