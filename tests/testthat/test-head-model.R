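test_that("icosphere construction gives the expected counts and geometry", {
  ico <- make_icosphere(1.0, 0)
  expect_equal(nrow(ico$vertices), 12L)
  expect_equal(nrow(ico$faces), 20L)
  expect_equal(euler_characteristic(ico), 2L)

  m2 <- make_icosphere(1.0, 2)
  expect_equal(nrow(m2$faces), 320L)
  expect_equal(euler_characteristic(m2), 2L)

  m3 <- make_icosphere(0.09, 3)
  expect_lt(abs(sum(m3$areas) / (4 * pi * 0.09^2) - 1), 0.01)
  expect_true(all(abs(sqrt(rowSums(m3$vertices^2)) - 0.09) < 1e-12 * 0.09))
  expect_gt(signed_volume(m3), 0)
})

test_that("icosphere rejects invalid arguments", {
  expect_error(make_icosphere(-1, 2), "radius")
  expect_error(make_icosphere(1, -1), "n_subdiv")
  expect_error(make_icosphere(1, 1.5), "n_subdiv")
})

test_that("subdivision refines without changing topology and converges in area", {
  areas <- vapply(0:3, function(n) sum(make_icosphere(0.09, n)$areas),
                  numeric(1))
  expect_true(all(diff(areas) > 0))            # monotone toward 4 pi r^2
  expect_true(all(areas < 4 * pi * 0.09^2))
  eulers <- vapply(0:3, function(n) euler_characteristic(make_icosphere(1, n)),
                   integer(1))
  expect_true(all(eulers == 2L))
})

test_that("nested sphere head computes conductivity contrasts", {
  h1 <- make_nested_sphere_head(0.09, 0.33, n_subdiv = 1)
  expect_equal(h1$contrast, 1)

  h3 <- make_nested_sphere_head(n_subdiv = 1)
  expect_equal(h3$contrast[2L], (0.0042 - 0.33) / (0.0042 + 0.33))
  expect_lt(abs(abs(h3$contrast[2L]) - 0.97487), 1e-4)
  expect_equal(h3$contrast[1L], 1)

  expect_error(make_nested_sphere_head(c(0.08, 0.09), c(0.33, 0.33), 1),
               "decreasing")
})

test_that("head_model validates nesting and conductivities", {
  s_out <- make_icosphere(0.09, 1)
  s_in <- make_icosphere(0.08, 1)
  expect_error(head_model(list(s_in, s_out), c(0.33, 0.33), c(0, 0.33)),
               "inside")
  expect_error(head_model(list(s_out), 0.33, 0.1), "air")
  expect_error(head_model(list(s_out, s_in), c(0.33, -1), c(0, 0.33)),
               "positive")
  expect_silent(head_model(list(s_out, s_in), c(0.33, 0.5), c(0, 0.33)))
})

test_that("winding number separates inside from outside", {
  ico <- make_icosphere(0.05, 2)
  w <- winding_number(ico, rbind(c(0, 0, 0), c(0, 0, 0.2), c(0.01, 0, 0)))
  expect_gt(w[1L], 0.99)
  expect_lt(abs(w[2L]), 0.01)
  expect_gt(w[3L], 0.99)
})

test_that("validate_mesh reports watertightness, orientation and topology", {
  ico <- make_icosphere(0.09, 2)
  rep <- validate_mesh(ico)
  expect_true(rep$watertight)
  expect_equal(rep$euler_characteristic, 2L)
  expect_true(rep$outward_normals)

  holed <- triangle_mesh(ico$vertices, ico$faces[-1L, ])
  expect_false(validate_mesh(holed)$watertight)

  flipped <- triangle_mesh(ico$vertices, ico$faces[, c(1L, 3L, 2L)])
  expect_lt(validate_mesh(flipped)$signed_volume, 0)
})

test_that("montage construction enforces its invariants", {
  pos <- rbind(c(0, 0, 0.09), c(0.09, 0, 0))
  expect_error(electrode_montage(c("A", "A"), pos, c("reference", "channel")),
               "unique")
  expect_error(electrode_montage(c("A", "B"), pos, c("channel", "channel")),
               "reference")
  expect_error(electrode_montage("A", pos[1, , drop = FALSE], "reference"),
               "at least 2")
  m <- fibonacci_montage(n = 16, radius = 0.09)
  expect_equal(sum(m$role == "reference"), 1L)
  expect_equal(nrow(m), 16L)
  expect_true(all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 0.09) < 1e-12))
})

test_that("electrode imprinting refines contacts and preserves the mesh contract", {
  st <- small_stack()
  head <- st$head
  skin <- head$surfaces[[1L]]
  rep <- validate_mesh(skin)
  expect_true(rep$watertight)
  expect_equal(rep$euler_characteristic, 2L)
  expect_gt(rep$signed_volume, 0)

  contacts <- attr(head, "contacts")
  expect_equal(length(contacts), 10L)
  expect_true(all(vapply(contacts, length, integer(1)) > 0L))
  all_faces <- unlist(contacts)
  expect_equal(anyDuplicated(all_faces), 0L)   # disjoint face sets
  # contact faces meet the edge-length target
  expect_true(all(skin$diameters[all_faces] <= 0.004 + 1e-12))
})

test_that("imprinting is idempotent for a fixed max_edge", {
  mon <- small_montage()
  h <- make_nested_sphere_head(n_subdiv = 2)
  h1 <- imprint_electrodes(h, mon, max_edge = 0.004)
  h2 <- imprint_electrodes(h1, mon, max_edge = 0.004)
  expect_equal(nrow(h2$surfaces[[1L]]$faces), nrow(h1$surfaces[[1L]]$faces))
  expect_equal(attr(h2, "contacts"), attr(h1, "contacts"))
})

test_that("imprinting rejects off-surface electrodes and overlapping discs", {
  h <- make_nested_sphere_head(n_subdiv = 2)
  far <- electrode_montage(c("R", "X"), rbind(c(0, 0, 0.09), c(0, 0, 0.15)),
                           c("reference", "channel"))
  expect_error(imprint_electrodes(h, far), "farther")
  close_pair <- electrode_montage(
    c("R", "X"), rbind(c(0, 0, 0.09), c(0.002, 0, 0.0899778)),
    c("reference", "channel"), contact_radius = 0.005)
  expect_error(imprint_electrodes(h, close_pair), "overlap")
})

test_that("a contact smaller than any face still gets its nearest face", {
  h <- make_nested_sphere_head(n_subdiv = 1)  # 320-face skin, ~24 mm edges
  mon <- electrode_montage(c("R", "X"),
                           rbind(c(0, 0, 0.09), c(0, 0, -0.09)),
                           c("reference", "channel"),
                           contact_radius = 0.0002)
  hi <- imprint_electrodes(h, mon, max_edge = 0.02, position_tol = 0.01)
  contacts <- attr(hi, "contacts")
  expect_true(all(vapply(contacts, length, integer(1)) >= 1L))
})
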