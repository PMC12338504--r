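test_that("identity lead field gives the identity kernel in the small-lambda limit", {
  lf <- make_leadfield_object(diag(2))
  op <- make_inverse_operator(lf, identity_ncov(lf$channel_labels),
                              gamma = 0, lambda = 1e-10,
                              normalize_R = FALSE)
  expect_equal(op$kernel, diag(2), tolerance = 1e-6)
})

test_that("depth prior follows the configured exponent rule", {
  M <- cbind(c(1, 0), c(0, 2))    # column norms 1 and 2
  lf <- make_leadfield_object(M)
  nc <- identity_ncov(lf$channel_labels)
  op <- make_inverse_operator(lf, nc, gamma = 1, lambda = 0.5,
                              normalize_R = FALSE)
  expect_equal(op$R, c(1, 1 / 4), tolerance = 1e-12)
  opp <- make_inverse_operator(lf, nc, gamma = 1, lambda = 0.5,
                               normalize_R = FALSE, exponent = "plusgamma")
  expect_equal(opp$R, c(1, 2), tolerance = 1e-12)
  # deeper (weaker) columns always get the larger prior variance
  set.seed(16)
  L <- matrix(rnorm(6 * 30), 6)
  o2 <- make_inverse_operator(make_leadfield_object(L),
                              identity_ncov(sprintf("E%02d", 1:6)),
                              gamma = 1.4, lambda = 0.8)
  cn <- sqrt(colSums(L^2))
  expect_true(all(diff(o2$R[order(cn)]) <= 1e-12))
})

test_that("pipeline default regularization parameters are accepted", {
  set.seed(17)
  lf <- make_leadfield_object(matrix(rnorm(8 * 50), 8))
  op <- make_inverse_operator(lf, identity_ncov(lf$channel_labels),
                              gamma = 1.4, lambda = 0.8)
  expect_s3_class(op, "inverse_operator")
  expect_equal(op$gamma, 1.4)
  expect_equal(op$lambda, 0.8)
  expect_true(all(op$dspm_normalizers > 0))
})

test_that("auto_regularize meets the condition-number contract", {
  set.seed(18)
  Lh <- matrix(rnorm(6 * 40), 6)
  R <- rep(1, 40)
  well <- auto_regularize(Lh, R, lambda_init = 0.8, cond_max = 1e8)
  expect_equal(well$lambda, 0.8)      # already well conditioned
  expect_lte(well$cond, 1e8)

  # rank-deficient lead field forces lambda growth for any finite target
  Ld <- Lh; Ld[6, ] <- Ld[5, ]
  out <- auto_regularize(Ld, R, lambda_init = 1e-12, cond_max = 1e6)
  expect_gt(out$lambda, 1e-12)
  expect_lte(out$cond, 1e6)
  expect_error(auto_regularize(Lh, R, lambda_init = -1, cond_max = 10),
               "positive")
})

test_that("apply_inverse is linear and shape-checked", {
  set.seed(19)
  lf <- make_leadfield_object(matrix(rnorm(8 * 50), 8))
  op <- make_inverse_operator(lf, identity_ncov(lf$channel_labels))
  v1 <- matrix(rnorm(8 * 5), 8)
  v2 <- matrix(rnorm(8 * 5), 8)
  e0 <- apply_inverse(op, matrix(0, 8, 3))
  expect_true(all(e0$data == 0))
  ea <- apply_inverse(op, 2 * v1 + v2)
  expect_equal(ea$data,
               2 * apply_inverse(op, v1)$data + apply_inverse(op, v2)$data,
               tolerance = 1e-12)
  expect_equal(ea$kind, "raw")
  expect_error(apply_inverse(op, matrix(0, 5, 3)), "channel count")
})

test_that("minimum-norm kernel approaches the pseudo-inverse as lambda vanishes", {
  set.seed(20)
  Lh <- matrix(rnorm(5 * 30), 5)    # full row rank
  lf <- make_leadfield_object(Lh)
  op <- make_inverse_operator(lf, identity_ncov(lf$channel_labels),
                              gamma = 0, lambda = 1e-10,
                              normalize_R = FALSE)
  expect_lt(norm(Lh %*% op$kernel %*% Lh - Lh, "F") / norm(Lh, "F"), 1e-6)
})

test_that("dSPM is noise-normalized by construction", {
  set.seed(21)
  lf <- make_leadfield_object(matrix(rnorm(10 * 60), 10))
  nc <- identity_ncov(lf$channel_labels)
  op <- make_inverse_operator(lf, nc, gamma = 1.4, lambda = 0.8)
  noise <- matrix(rnorm(10 * 10000), 10)   # unit white = whitened noise
  est <- dspm_normalize(op, apply_inverse(op, noise))
  v <- apply(est$data, 1L, var)
  expect_true(all(abs(v - 1) < 0.15))
  expect_equal(est$kind, "dSPM")
  expect_error(dspm_normalize(op, est), "already")
})

test_that("dSPM values are invariant to a change of measurement units", {
  # expressing the data in rescaled units (v -> c v, Sigma -> c^2 Sigma)
  # must not change the noise-normalized source map; the raw estimate
  # scales with the units while the dSPM normalizers absorb the factor
  set.seed(22)
  lf <- make_leadfield_object(matrix(rnorm(6 * 40), 6))
  labs <- lf$channel_labels
  c0 <- identity_ncov(labs)
  c1 <- c0
  c1$sigma <- 9 * c0$sigma
  c1$whitener <- c0$whitener / 3
  v <- matrix(rnorm(6 * 7), 6)
  e0 <- dspm_normalize(make_inverse_operator(lf, c0),
                       apply_inverse(make_inverse_operator(lf, c0), v))
  e1 <- dspm_normalize(make_inverse_operator(lf, c1),
                       apply_inverse(make_inverse_operator(lf, c1), 3 * v))
  expect_equal(e0$data, e1$data, tolerance = 1e-8)
})

test_that("peak_summary normalizes to [0,1] and ranks robustly", {
  est <- structure(list(
    data = rbind(c(0, 0.2, 0), c(0, -3, 0.5), c(0.1, 0, 0)),
    kind = "dSPM",
    source_space = structure(list(positions = diag(3) * 0.01),
                             class = "source_space"),
    source_index = 1:3), class = "source_estimate")
  ps <- peak_summary(est, top_k = 3L)
  expect_equal(ps$source[1L], 2L)
  expect_equal(ps$value[1L], 1)
  expect_true(all(ps$value >= 0 & ps$value <= 1))
  est2 <- est; est2$data <- -est2$data
  expect_equal(peak_summary(est2, 3L)$source, ps$source)  # sign invariant
})
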