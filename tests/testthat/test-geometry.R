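test_that("kabsch recovers known rigid motions and is self-consistent", {
  set.seed(21)
  P <- matrix(rnorm(60, sd = 8), ncol = 3)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "3 point")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch(line, line), "collinear")

  idfit <- kabsch(P, P)
  expect_equal(idfit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idfit$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-9)

  for (rep in 1:25) {
    R <- oracle_rotation(rnorm(3), runif(1, 0, pi))
    tr <- rnorm(3, sd = 20)
    Q <- sweep(P %*% t(R), 2, tr, "+")
    fit <- kabsch(P, Q)
    expect_lt(max(abs(fit$rotation - R)), 1e-6)
    expect_lt(max(abs(fit$translation - tr)), 1e-6)
    expect_lt(fit$rmsd, 1e-9)
    # self-consistency: reported RMSD equals RMSD of transformed coords
    moved <- apply_transform(fit, P)
    expect_equal(sqrt(mean(rowSums((moved - Q)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("kabsch returns proper rotations on mirrored input and inverts cleanly", {
  set.seed(22)
  P <- matrix(rnorm(90, sd = 6), ncol = 3)
  mirror <- P %*% diag(c(-1, 1, 1))
  fit <- kabsch(P, mirror)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.5)

  Q <- sweep(P %*% t(oracle_rotation(c(1, 2, 3), 1.1)), 2, c(5, -3, 2), "+")
  Q <- Q + matrix(rnorm(90, sd = 0.3), ncol = 3)
  fwd <- kabsch(P, Q); bwd <- kabsch(Q, P)
  expect_equal(fwd$rmsd, bwd$rmsd, tolerance = 1e-9)
  expect_equal(fwd$rotation %*% bwd$rotation, diag(3), tolerance = 1e-9)
})

test_that("kabsch RMSD matches the bio3d reference superposition", {
  set.seed(23)
  P <- matrix(rnorm(120, sd = 7), ncol = 3)
  Q <- P + matrix(rnorm(120, sd = 1.5), ncol = 3)
  ours <- kabsch(P, Q)$rmsd
  xyz_fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P))))
  ref <- bio3d::rmsd(as.vector(t(Q)), xyz_fit)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("centre of mass is the coordinate mean and translation-equivariant", {
  expect_equal(center_of_mass(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_error(center_of_mass(matrix(0, 0, 3)), "empty")
  set.seed(24)
  X <- matrix(rnorm(45), ncol = 3)
  t0 <- c(4, -2, 7)
  expect_equal(center_of_mass(sweep(X, 2, t0, "+")),
               center_of_mass(X) + t0)
})

test_that("globularity separates compact from extended chains and is rigid-invariant", {
  fx <- make_chain(c(100), seed = 31)
  g_compact <- globularity(fx$chain, 1:100)
  expect_lt(g_compact, 1.5)

  extended <- cbind(3.8 * (1:100), 0, 0) + matrix(rnorm(300, sd = 0.01), ncol = 3)
  g_ext <- globularity(extended)
  expect_gt(g_ext, 1.5)
  # Rg of N collinear points at spacing d is d * sqrt((N^2 - 1) / 12)
  expect_equal(g_ext, (3.8 * sqrt((100^2 - 1) / 12)) / (2.2 * 100^0.38),
               tolerance = 0.01)

  R <- oracle_rotation(c(0, 1, 1), 0.9)
  moved <- sweep(fx$chain$ca_coords %*% t(R), 2, c(10, 20, 30), "+")
  expect_equal(globularity(moved), globularity(fx$chain$ca_coords),
               tolerance = 1e-9)
})

test_that("symmetry scan finds the repeat period of cyclic and tandem chains", {
  s6 <- symmetry_scan(make_cn_symmetric(6, 15, seed = 2))
  expect_true(s6$best_shift %in% c(15L, 30L, 45L))
  expect_gt(s6$zscore, 9)

  s2 <- symmetry_scan(make_cn_symmetric(2, 40, seed = 5))
  expect_equal(s2$best_shift, 40L)

  # two tandem copies of an asymmetric fold related by a rigid motion
  set.seed(33)
  fx <- make_chain(c(40), seed = 33)
  unit <- fx$chain$ca_coords
  R <- oracle_rotation(c(1, 1, 0), 0.8)
  tandem <- rbind(unit, sweep(unit %*% t(R), 2, c(12, 3, 18), "+"))
  expect_equal(symmetry_scan(tandem)$best_shift, 40L)

  expect_error(symmetry_scan(unit, min_shift = 25), "too short")
})

test_that("repeat score grows with copy number while Z stays above the gate", {
  zs <- numeric(0); best <- numeric(0)
  for (k in c(4, 6, 8)) {
    sr <- symmetry_scan(make_cn_symmetric(k, 15, seed = 5))
    zs <- c(zs, sr$zscore); best <- c(best, sr$best_score)
  }
  expect_true(all(diff(best) > 0))
  expect_true(all(zs > 9))
})
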