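test_that("reciprocal build yields one row per channel electrode", {
  lf <- small_leadfield()
  expect_equal(nrow(lf$matrix), 9L)     # 10 electrodes, one reference
  expect_equal(lf$ref_label, "REF")
  expect_false(lf$pca_corrected)
})

test_that("lead-field entries are independent of the injection current", {
  st <- small_stack()
  ss <- st$ss
  l1 <- build_reciprocal_leadfield(st$head, ss, current = 1e-3, op = st$op)
  l2 <- build_reciprocal_leadfield(st$head, ss, current = 2e-3, op = st$op)
  expect_equal(l1$matrix, l2$matrix, tolerance = 1e-10)
})

test_that("a single-source direct build is the potential difference by definition", {
  st <- small_stack()
  ld <- build_direct_leadfield(st$head, st$ss, sources = 5L, op = st$op)
  sol <- solve_dipole(st$head, st$ss$positions[5L, ], st$ss$normals[5L, ],
                      op = st$op)
  contacts <- attr(st$head, "contacts")
  skin <- st$head$surfaces[[1L]]
  avg <- function(lab) {
    f <- contacts[[lab]]
    sum(evaluate_potential(sol, skin$centroids[f, , drop = FALSE]) *
          skin$areas[f]) / sum(skin$areas[f])
  }
  manual <- vapply(ld$channel_labels, avg, numeric(1)) - avg("REF")
  expect_equal(as.numeric(ld$matrix), as.numeric(manual), tolerance = 1e-10)
})

test_that("reciprocal and direct builds agree on the small model", {
  st <- small_stack()
  lr <- small_leadfield()
  set.seed(9)
  sub <- sample(nrow(st$ss$positions), 12)
  ld <- build_direct_leadfield(st$head, st$ss, sources = sub, op = st$op)
  A <- lr$matrix[, sub]
  B <- ld$matrix
  # this deliberately coarse smoke configuration only brackets the
  # agreement; the study-scale equivalence check lives in the acceptance
  # suite
  expect_gt(cor(as.vector(A), as.vector(B)), 0.97)
  expect_lt(norm(A - B, "F") / norm(B, "F"), 0.35)
})

test_that("PCA correction removes the leading component exactly", {
  lf <- make_leadfield_object(rbind(c(2, 0), c(0, 1)))
  out <- pca_correct(lf)
  expect_equal(out$matrix, rbind(c(0, 0), c(0, 1)), tolerance = 1e-12)
  expect_equal(out$u, c(1, 0), tolerance = 1e-12)
  expect_true(out$pca_corrected)
  expect_error(pca_correct(out), "already")
})

test_that("a rank-one lead field is annihilated by PCA correction", {
  r <- c(1, -2, 0.5, 3)
  M <- outer(c(1, 2, 3), r)
  out <- pca_correct(make_leadfield_object(M))
  expect_lt(max(abs(out$matrix)), 1e-12 * max(abs(M)))
})

test_that("PCA correction refuses a degenerate leading eigenvalue", {
  expect_error(pca_correct(make_leadfield_object(diag(2))), "degenerate")
})

test_that("PCA correction satisfies its algebraic invariants", {
  set.seed(10)
  M <- matrix(rnorm(9 * 40), 9)
  out <- pca_correct(make_leadfield_object(M))
  expect_lt(max(abs(crossprod(out$u, out$matrix))),
            1e-12 * max(abs(M)))                      # u' L' = 0
  expect_lte(norm(out$matrix, "F"), norm(M, "F"))      # projection shrinks
  expect_equal(qr(out$matrix)$rank, qr(M)$rank - 1L)   # u in the row space
})

test_that("planted common component: PCA beats mean subtraction by >= 10x", {
  # rows share one cortical pattern with row-dependent scales - removing
  # the mean row leaves a residual proportional to the scale spread,
  # while the leading-PC projection removes the shared direction itself
  set.seed(11)
  nsrc <- 300L; nch <- 20L
  B <- matrix(rnorm(nch * nsrc), nch)
  cvec <- rnorm(nsrc)
  cvec <- cvec / sqrt(sum(cvec^2))
  scales <- seq(4, 12, length.out = nch)
  L <- B + scales %o% cvec * sqrt(nsrc) / 2
  common_energy <- function(M) sqrt(sum((M %*% cvec)^2))
  after_pca <- common_energy(pca_correct(make_leadfield_object(L))$matrix)
  after_mean <- common_energy(sweep(L, 2L, colMeans(L)))
  expect_lt(after_pca * 10, after_mean)
})

test_that("CAR re-referencing zeroes augmented column sums and is idempotent", {
  set.seed(12)
  M <- matrix(rnorm(9 * 25), 9)
  lf <- make_leadfield_object(M)
  car1 <- rereference_leadfield(lf, "CAR")
  # every column of the augmented (channels + reference) matrix sums to 0
  expect_lt(max(abs(colSums(rbind(car1$matrix, car1$ref_row)))),
            1e-12 * max(abs(M)))
  expect_equal(car1$reference_scheme, "CAR")
  car2 <- rereference_leadfield(car1, "CAR")
  expect_equal(car2$matrix, car1$matrix, tolerance = 1e-12)
  # common-mode rejection: a source pattern that reaches every channel
  # identically contributes nothing after CAR beyond what the implicit
  # zero reference row re-introduces; shifting all rows by a constant
  # pattern changes the CAR result by exactly 1/(rows+1) of that pattern
  cm <- rnorm(25)
  shifted <- rereference_leadfield(make_leadfield_object(M +
    rep(1, 9) %o% cm), "CAR")
  base <- rereference_leadfield(lf, "CAR")
  expect_equal(shifted$matrix - base$matrix, rep(1, 9) %o% (cm / 10),
               tolerance = 1e-10)
  # a pattern common to ALL augmented rows (channels and reference alike)
  # is rejected entirely
  lf_cm <- make_leadfield_object(M + rep(1, 9) %o% cm)
  lf_cm$ref_row <- cm
  expect_equal(rereference_leadfield(lf_cm, "CAR")$matrix, base$matrix,
               tolerance = 1e-10)
  expect_error(rereference_leadfield(car1, "original"), "cannot")
})

test_that("the leading second-moment eigenvector of a single-reference build is single-signed", {
  # the shared reference-electrode charge gives all basis functions a
  # common component, so the leading eigenvector of L L' has one sign -
  # exactly the component the PCA correction removes (the stronger claim,
  # that every pairwise row correlation is positive, is asserted on the
  # study-scale build in the acceptance suite)
  lf <- small_leadfield()
  u <- eigen(tcrossprod(lf$matrix), symmetric = TRUE)$vectors[, 1L]
  expect_true(all(u > 0) || all(u < 0))
})
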