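# Shared fixtures, built lazily and cached for the whole test run. The
# small stack keeps unit tests fast; the full-scale stack (61 electrodes,
# n_subdiv 3) is only materialized by the acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_montage <- function(n = 10) {
  fibonacci_montage(n = n, radius = 0.09, contact_radius = 0.007)
}

# imprinted 3-shell head at low resolution with a 10-electrode cap
small_stack <- function() fix("small_stack", function() {
  head <- make_nested_sphere_head(n_subdiv = c(2, 2, 3))
  hi <- imprint_electrodes(head, small_montage(), max_edge = 0.004)
  op <- bem_operator(hi)
  list(head = hi, op = op, montage = small_montage(),
       ss = make_sphere_source_space(0.06, 1))
})

# plain homogeneous sphere (oracle comparisons)
homog_stack <- function() fix("homog_stack", function() {
  head <- make_nested_sphere_head(0.09, 0.33, n_subdiv = 3)
  list(head = head, op = bem_operator(head),
       model = sphere_model(0.09, 0.33))
})

three_shell_model <- function() {
  sphere_model(c(0.09, 0.085, 0.08), c(0.33, 0.0042, 0.33))
}

# a 9-channel lead field on the small stack (reciprocal route)
small_leadfield <- function() fix("small_leadfield", function() {
  st <- small_stack()
  build_reciprocal_leadfield(st$head, st$ss, op = st$op)
})

# synthetic noise covariance with known structure
identity_ncov <- function(labels) {
  M <- length(labels)
  structure(list(sigma = diag(M), whitener = diag(M), rank = M,
                 labels = labels, shrinkage = 0),
            class = "noise_covariance")
}

make_leadfield_object <- function(M, labels = sprintf("E%02d", seq_len(nrow(M)))) {
  ss <- structure(list(positions = matrix(0, ncol(M), 3L),
                       normals = matrix(rep(c(0, 0, 1), each = ncol(M)), ncol = 3L),
                       areas = rep(1, ncol(M)), id = "synthetic"),
                  class = "source_space")
  reciprocalEEG:::new_leadfield(M, labels, "REF", ss, seq_len(ncol(M)),
                                NULL)
}
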