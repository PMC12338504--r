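test_that("central radial dipole reproduces the closed-form pole potential", {
  mod <- sphere_model(0.09, 0.33)
  v <- sphere_dipole_potential(mod, c(0, 0, 0), c(0, 0, 1e-8),
                               matrix(c(0, 0, 0.09), 1))
  expect_equal(v, 3e-8 / (4 * pi * 0.33 * 0.09^2), tolerance = 1e-10)
})

test_that("degenerate shells reduce to the homogeneous sphere", {
  set.seed(2)
  pts <- matrix(rnorm(45), 15)
  pts <- 0.09 * pts / sqrt(rowSums(pts^2))
  v1 <- sphere_dipole_potential(sphere_model(0.09, 0.33),
                                c(0, 0, 0.05), c(1e-8, 0, 2e-8), pts)
  v3 <- sphere_dipole_potential(sphere_model(c(0.09, 0.085, 0.08),
                                             c(0.33, 0.33, 0.33)),
                                c(0, 0, 0.05), c(1e-8, 0, 2e-8), pts)
  expect_lt(max(abs(v1 - v3)) / max(abs(v1)), 1e-10)
})

test_that("dipole series matches an independent two-monopole construction", {
  # a current dipole is the limit of two opposite current monopoles; for
  # the homogeneous sphere each monopole's surface response has the simple
  # per-order form (2n+1)/n (b/R)^n, an independent derivation that pins
  # both the radial and tangential orientation conventions of the series
  R <- 0.09; sig <- 0.33
  mod <- sphere_model(R, sig)
  mono_surf <- function(pos, I, pts, nmax = 500) {
    b <- sqrt(sum(pos^2))
    zh <- pos / b
    u <- pmin(1, pmax(-1, as.numeric(pts %*% zh) / sqrt(rowSums(pts^2))))
    leg <- reciprocalEEG:::legendre_table(u, nmax)
    acc <- 0
    for (n in 1:nmax) acc <- acc + (2 * n + 1) / n * (b / R)^n * leg$P[, n]
    I / (4 * pi * sig * R) * acc
  }
  set.seed(2)
  pts <- matrix(rnorm(30), 10)
  pts <- R * pts / sqrt(rowSums(pts^2))
  for (dir in list(c(0, 0, 1), c(1, 0, 0), c(0.6, 0, 0.8))) {
    p0 <- c(0, 0, 0.05); del <- 1e-5; I <- 1e-8 / del
    vd <- sphere_dipole_potential(mod, p0, 1e-8 * dir, pts)
    vm <- mono_surf(p0 + del / 2 * dir, I, pts) +
      mono_surf(p0 - del / 2 * dir, -I, pts)
    expect_lt(max(abs(vd - vm)) / max(abs(vd)), 1e-6)
  }
})

test_that("series is stable under doubling n_terms", {
  set.seed(3)
  pts <- matrix(rnorm(30), 10)
  pts <- 0.09 * pts / sqrt(rowSums(pts^2))
  m1 <- sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.0042, 0.33), 200)
  m2 <- sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.0042, 0.33), 400)
  v1 <- sphere_dipole_potential(m1, c(0, 0, 0.06), c(1e-8, 0, 1e-8), pts)
  v2 <- sphere_dipole_potential(m2, c(0, 0, 0.06), c(1e-8, 0, 1e-8), pts)
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-8)
})

test_that("dipole eccentricity limit is enforced", {
  mod <- sphere_model(c(0.09, 0.08), c(0.33, 0.33))
  expect_error(sphere_dipole_potential(mod, c(0, 0, 0.079), c(0, 0, 1e-8),
                                       matrix(c(0, 0, 0.09), 1)),
               "eccentricity")
})

test_that("two-contact injection has the expected symmetries", {
  mod <- sphere_model(0.09, 0.33)
  a <- c(0, 0, 0.09); b <- c(0, 0, -0.09)
  eq <- matrix(c(0.09, 0, 0), 1)
  expect_lt(abs(sphere_injection_potential(mod, a, b, 1e-3, eq)), 1e-12)
  g <- seq(0.4, pi - 0.4, length.out = 7)
  pts <- 0.09 * cbind(sin(g), 0, cos(g))
  v <- sphere_injection_potential(mod, a, b, 1e-3, pts)
  expect_lt(max(abs(v + rev(v))) / max(abs(v)), 1e-10)  # antipodal antisymmetry
  v2 <- sphere_injection_potential(mod, a, b, -1e-3, pts)
  expect_equal(v2, -v, tolerance = 1e-12)
})

test_that("injection and dipole series close under Helmholtz reciprocity", {
  mod <- sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.0042, 0.33))
  a <- c(0, 0, 0.09); b <- c(0, 0.09 * sin(2.2), 0.09 * cos(2.2))
  p <- c(0.02, 0.01, 0.05); d <- c(0, 0.6, 0.8)
  E <- sphere_injection_field(mod, a, b, 1, matrix(p, 1))
  lhs <- -sum(E[1, ] * d)
  vd <- sphere_dipole_potential(mod, p, d, rbind(a, b))
  rhs <- vd[1L] - vd[2L]
  expect_lt(abs(lhs - rhs) / abs(rhs), 0.01)
})

test_that("buried-monopole solution matches the surface-injection limit", {
  mod <- sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.0042, 0.33))
  a <- c(0, 0, 0.0899)
  b <- c(0, 0.0899 * sin(2.2), 0.0899 * cos(2.2))
  pts <- cbind(0.01, 0.005, seq(-0.07, 0.07, length.out = 6))
  v1 <- sphere_buried_monopole_potential(mod, rbind(a, b), c(1e-3, -1e-3), pts)
  v2 <- sphere_injection_potential(mod, c(0, 0, 0.09),
                                   c(0, 0.09 * sin(2.2), 0.09 * cos(2.2)),
                                   1e-3, pts)
  expect_lt(max(abs(v1 - v2)) / max(abs(v2)), 1e-3)
  expect_error(sphere_buried_monopole_potential(mod, matrix(c(0, 0, 0.05), 1),
                                                1, pts), "sum to zero")
})

test_that("RDM and MAG behave as forward-accuracy metrics", {
  set.seed(4)
  a <- rnorm(20)
  expect_equal(rdm(a, a), 0)
  expect_equal(rdm(a, 3 * a), 0)        # shape metric ignores scale
  expect_equal(mag(2 * a, a), 2)
  expect_equal(rdm(a, -a), 2)           # maximal shape disagreement
})
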