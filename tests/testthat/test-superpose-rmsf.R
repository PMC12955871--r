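test_that("superposition of identical and rigidly moved frames gives zero RMSD", {
  set.seed(55)
  f <- make_ensemble(list(matrix(rnorm(30, sd = 5), 10, 3)))
  expect_equal(superpose(f, f)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation()
  moved <- transformEnsemble(f, R, c(4, -2, 7))
  fit <- superpose(moved, f)
  expect_lt(fit$rmsd, 1e-10)
  # recovered rotation inverts the applied one
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # proper rotation enforced
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("superposition RMSD matches a brute-force rigid-motion minimisation", {
  # 3 reference points, one displaced out of plane
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  for (dz in c(0.1, 0.5, 1.0)) {
    mob <- ref
    mob[3, ] <- c(0, 1, dz)
    e_ref <- make_ensemble(list(ref))
    e_mob <- make_ensemble(list(mob))
    kab <- superpose(e_mob, e_ref)$rmsd
    # independent oracle: numeric minimisation over Euler angles + translation
    obj <- function(par) {
      ca <- cos(par[1:3]); sa <- sin(par[1:3])
      Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
      Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
      Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
      moved <- sweep(mob %*% t(Rz %*% Ry %*% Rx), 2, par[4:6], "+")
      sqrt(mean(rowSums((moved - ref)^2)))
    }
    best <- Inf
    set.seed(7)
    for (k in 1:20) {
      st <- c(runif(3, -pi, pi), rnorm(3, sd = 0.5))
      o <- optim(st, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_equal(kab, best, tolerance = 1e-5)
    expect_lte(kab, best + 1e-8)  # Kabsch is the global least-squares optimum
  }
})

test_that("superposition RMSD is invariant under proper rigid motions of both frames", {
  set.seed(66)
  a <- make_ensemble(list(matrix(rnorm(24, sd = 4), 8, 3)))
  b <- make_ensemble(list(matrix(rnorm(24, sd = 4), 8, 3)))
  base <- superpose(a, b)$rmsd
  for (k in 1:5) {
    R <- random_rotation(); tv <- rnorm(3, sd = 10)
    expect_equal(superpose(transformEnsemble(a, R, tv),
                           transformEnsemble(b, R, tv))$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("superposition cross-checks against bio3d and rejects bad input", {
  skip_if_not_installed("bio3d")
  set.seed(77)
  a <- matrix(rnorm(30, sd = 5), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
  mine <- superpose(make_ensemble(list(a)), make_ensemble(list(b)))$rmsd
  ref <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
  expect_error(superpose(make_ensemble(list(a[1:2, ])),
                         make_ensemble(list(b[1:2, ]))), "underdetermined")
  expect_error(superpose(make_ensemble(list(a)),
                         make_ensemble(list(b[1:5, ]))), "pairing")
})

test_that("RMSF is zero for identical frames and recovers a known displacement", {
  base <- matrix(rnorm(15, sd = 3), 5, 3)
  ens0 <- make_ensemble(list(base, base, base),
                        names = c("N", "CA", "C", "O", "CB"))
  expect_true(all(rmsf(ens0)$rmsf < 1e-12))
  # one atom oscillating +/- delta along x about its mean, others fixed:
  # without refit (no net rigid motion), that atom's RMSF is exactly delta
  delta <- 0.4
  names5 <- c("N", "CA", "C", "O", "CB")
  f1 <- base; f1[5, 1] <- base[5, 1] + delta
  f2 <- base; f2[5, 1] <- base[5, 1] - delta
  ens <- make_ensemble(list(f1, f2), names = names5,
                       resseq = c(1, 1, 1, 1, 2))
  prof <- rmsf(ens, sel = selector(atomNames = names5), refit = FALSE)
  expect_equal(prof$rmsf[prof$resseq == 2], delta, tolerance = 1e-12)
  expect_equal(prof$rmsf[prof$resseq == 1], 0, tolerance = 1e-12)
})

test_that("RMSF with and without refit agree on a pre-aligned ensemble", {
  # symmetric displacements orthogonal to all six rigid modes leave the
  # ensemble mean and every optimal fit at the identity
  set.seed(88)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  cen <- sweep(base, 2, colMeans(base))
  modes <- cbind(
    as.numeric(matrix(rep(c(1, 0, 0), each = 10), 10)),  # translations
    as.numeric(matrix(rep(c(0, 1, 0), each = 10), 10)),
    as.numeric(matrix(rep(c(0, 0, 1), each = 10), 10)),
    as.numeric(cbind(0, -cen[, 3], cen[, 2])),  # infinitesimal rotations
    as.numeric(cbind(cen[, 3], 0, -cen[, 1])),
    as.numeric(cbind(-cen[, 2], cen[, 1], 0))
  )
  disp <- matrix(rnorm(30, sd = 1e-5), 10, 3)
  dv <- as.numeric(disp)
  dv <- dv - modes %*% qr.solve(crossprod(modes), crossprod(modes, dv))
  disp <- matrix(dv, 10, 3)
  ens <- make_ensemble(list(base + disp, base - disp),
                       names = rep(c("N", "CA"), 5),
                       resseq = rep(1:5, each = 2))
  sel <- selector(atomNames = c("N", "CA"))
  with_refit <- rmsf(ens, sel, refit = TRUE)
  without <- rmsf(ens, sel, refit = FALSE)
  expect_equal(with_refit$rmsf, without$rmsf, tolerance = 1e-8)
  expect_error(rmsf(make_ensemble(list(base)), sel), "2 frames")
})
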