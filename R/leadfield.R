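#' Cortical source space
#'
#' Source locations at the face centroids of a designated cortical surface
#' with dipole orientations along the outward face normals (normally
#' oriented sources).
#'
#' @param mesh a `triangle_mesh` representing the cortical surface
#' @param id identifier string for the parent surface
#' @return object of class `source_space` with `positions`, `normals`,
#'   `areas`, `id`, `mesh`
#' @export
make_source_space <- function(mesh, id = "cortex") {
  structure(list(positions = mesh$centroids, normals = mesh$normals,
                 areas = mesh$areas, id = id, mesh = mesh),
            class = "source_space")
}

#' Spherical source space for nested-sphere heads
#'
#' Icosphere "cortex" inside the innermost compartment. The default radius
#' of 0.06 m sits 20 mm below the innermost (brain) surface of the default
#' three-shell head - at least two brain-mesh face diameters, so the
#' boundary-element field evaluation at the sources stays in its smooth
#' regime.
#'
#' @param radius cortex sphere radius (m)
#' @param n_subdiv icosphere subdivision (3 gives 1280 sources)
#' @return a `source_space`
#' @export
make_sphere_source_space <- function(radius = 0.06, n_subdiv = 3) {
  make_source_space(make_icosphere(radius, n_subdiv),
                    id = sprintf("sphere-cortex-%g", radius))
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space '%s': %d normally-oriented sources\n",
              x$id, nrow(x$positions)))
  invisible(x)
}

new_leadfield <- function(matrix, channel_labels, ref_label, source_space,
                          source_index, montage, pca_corrected = FALSE,
                          reference_scheme = "original", u = NULL,
                          ref_row = NULL) {
  if (is.null(ref_row)) ref_row <- rep(0, ncol(matrix))
  structure(list(matrix = matrix, channel_labels = channel_labels,
                 ref_label = ref_label, source_space = source_space,
                 source_index = source_index, montage = montage,
                 pca_corrected = pca_corrected,
                 reference_scheme = reference_scheme, u = u,
                 ref_row = ref_row),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("leadfield: %d channels (ref '%s') x %d sources | pca %s | ref scheme %s\n",
              nrow(x$matrix), x$ref_label, ncol(x$matrix),
              if (x$pca_corrected) "corrected" else "raw",
              x$reference_scheme))
  invisible(x)
}

#' Reciprocal lead-field build (rows via injection solves)
#'
#' For every channel electrode, solves one current-injection problem with
#' the channel as anode and the reference as cathode, then fills the
#' corresponding lead-field row with \eqn{-E(p_j) \cdot d_j / I} over the
#' source space: by Helmholtz reciprocity this equals the referenced
#' potential a unit dipole at p_j (oriented along d_j) produces at that
#' channel. Entries are normalized per unit reciprocal current, so the
#' matrix is independent of `current`. With `amr_passes > 1` each
#' injection solve runs the adaptive-refinement loop around its electrode
#' pair.
#'
#' @param head imprinted `head_model`
#' @param source_space a `source_space`
#' @param current implementation injection current (A); default 1 mA
#' @param op optional prebuilt [bem_operator()]
#' @param amr_passes maximum adaptive-refinement passes per solve (1 = one
#'   plain solve on the imprinted mesh)
#' @param lead_tol adaptive-refinement stopping tolerance
#' @param tol solver tolerance
#' @param solver "lu" or "gmres"
#' @param allow_flagged keep rows whose solve did not converge (flagged in
#'   attribute `flagged_rows`) instead of failing
#' @return a `leadfield` with one row per non-reference electrode
#' @export
build_reciprocal_leadfield <- function(head, source_space, current = 1e-3,
                                       op = NULL, amr_passes = 1L,
                                       lead_tol = 0.02, tol = 1e-8,
                                       solver = "lu",
                                       allow_flagged = FALSE) {
  montage <- attr(head, "montage")
  if (is.null(montage)) stop("head has no imprinted montage")
  ref <- montage$label[montage$role == "reference"]
  chans <- montage$label[montage$role == "channel"]
  pts <- source_space$positions
  nrm <- source_space$normals
  if (amr_passes == 1L) {
    if (is.null(op)) op <- bem_operator(head)
    B <- matrix(0, op$n, length(chans))
    for (i in seq_along(chans))
      B[, i] <- tes_rhs(op, chans[i], ref, current)
    sol <- bem_solve(op, B, solver = solver, tol = tol)
    bad <- which(sol$residual > 10 * tol)
    if (length(bad) && !allow_flagged)
      stop(sprintf("injection solve for %d channel(s) above tolerance",
                   length(bad)))
    Eind <- cpp_eval_field(op$triV, op$cen, op$area, op$diam, sol$G, pts,
                           op$near_mult)
    L <- matrix(0, length(chans), nrow(pts))
    sigma_skin <- head$sigma_in[1L]
    for (i in seq_along(chans)) {
      an <- contact_monopoles(head, chans[i], current)
      ca <- contact_monopoles(head, ref, -current)
      Ep <- monopole_primary_field(pts, rbind(an$positions, ca$positions),
                                   c(an$currents, ca$currents), sigma_skin)
      E <- Ep + matrix(Eind[, , i], nrow(pts), 3L)
      L[i, ] <- -rowSums(E * nrm) / current
    }
  } else {
    L <- matrix(0, length(chans), nrow(pts))
    bad <- integer(0)
    for (i in seq_along(chans)) {
      s <- adaptive_refine_solve(head, chans[i], ref, current,
                                 lead_tol = lead_tol,
                                 max_passes = amr_passes, tol = tol,
                                 solver = solver, op = op)
      if (!attr(s, "converged")) bad <- c(bad, i)
      E <- evaluate_field(s, pts)
      L[i, ] <- -rowSums(E * nrm) / current
    }
    if (length(bad) && !allow_flagged)
      stop(sprintf("adaptive refinement not converged for %d channel(s)",
                   length(bad)))
  }
  lf <- new_leadfield(L, chans, ref, source_space,
                      seq_len(nrow(pts)), montage)
  if (length(bad)) attr(lf, "flagged_rows") <- bad
  lf
}

#' Direct lead-field build (columns via dipole solves)
#'
#' One forward dipole solve per requested source; column j holds the
#' contact-averaged potential difference \eqn{\phi(r_i) - \phi(r_0)} for a
#' unit dipole (1 A m) at source j oriented along its normal. Intended for
#' modest source subsets (each column is a full forward solve); serves as
#' the independent oracle for the reciprocal build.
#'
#' @param head imprinted `head_model`
#' @param source_space a `source_space`
#' @param sources integer indices of the sources to compute (default all)
#' @param op optional prebuilt operator
#' @param tol solver tolerance
#' @param solver "lu" or "gmres"
#' @return a `leadfield` whose `source_index` records the column subset
#' @export
build_direct_leadfield <- function(head, source_space, sources = NULL,
                                   op = NULL, tol = 1e-8, solver = "lu") {
  montage <- attr(head, "montage")
  if (is.null(montage)) stop("head has no imprinted montage")
  if (is.null(op)) op <- bem_operator(head)
  if (is.null(sources)) sources <- seq_len(nrow(source_space$positions))
  ref <- montage$label[montage$role == "reference"]
  chans <- montage$label[montage$role == "channel"]
  contacts <- attr(head, "contacts")
  skin <- head$surfaces[[1L]]
  # conductivity at the sources (all inside the innermost compartment for
  # the default models; computed generally)
  pts <- source_space$positions[sources, , drop = FALSE]
  nrm <- source_space$normals[sources, , drop = FALSE]
  sigs <- compartment_sigma(head, pts)
  if (any(sigs <= 0)) stop("some sources lie outside the conductor")
  B <- matrix(0, op$n, length(sources))
  for (j in seq_along(sources))
    B[, j] <- cpp_rhs_dipole(op$triV, op$nor, op$kvec, pts[j, ], nrm[j, ],
                             sigs[j], 4L)
  sol <- bem_solve(op, B, solver = solver, tol = tol)
  # potentials at all contact faces, induced part for all columns at
  # once: the evaluation weights are assembled in blocks and applied to
  # the charge matrix with BLAS
  all_faces <- unlist(contacts)
  cpts <- skin$centroids[all_faces, , drop = FALSE]
  phi_ind <- matrix(0, nrow(cpts), ncol(sol$G))
  for (s0 in seq(1L, nrow(cpts), by = 2000L)) {
    blk <- s0:min(s0 + 1999L, nrow(cpts))
    W <- cpp_potential_weights(op$triV, op$cen, op$area, op$diam,
                               cpts[blk, , drop = FALSE],
                               min(op$near_mult, 2))
    phi_ind[blk, ] <- W %*% sol$G
  }
  L <- matrix(0, length(chans), length(sources))
  w <- skin$areas[all_faces]
  grp <- rep(names(contacts), vapply(contacts, length, integer(1)))
  for (j in seq_along(sources)) {
    phi <- phi_ind[, j] + dipole_primary_potential(cpts, pts[j, ], nrm[j, ],
                                                   sigs[j])
    el <- vapply(split(seq_along(phi), grp)[unique(grp)], function(ii)
      sum(phi[ii] * w[ii]) / sum(w[ii]), numeric(1))
    names(el) <- unique(grp)
    L[, j] <- el[chans] - el[ref]
  }
  new_leadfield(L, chans, ref, source_space, sources, montage)
}

#' PCA correction of the reference-electrode bias
#'
#' Reciprocal basis functions built against a single reference electrode
#' all share a charge concentration near the reference, which biases
#' source estimates toward it. Subtracting the mean basis function is not
#' enough because the shared component enters each row with a different
#' scale. This correction projects all rows onto the orthogonal complement
#' of the leading eigenvector u of the uncentered second-moment matrix
#' L L^T, which removes the common component exactly: u' L' = 0.
#'
#' @param L a `leadfield`, not yet corrected, with at least 2 rows
#' @param tie_tol relative eigenvalue gap below which the leading component
#'   is considered ambiguous (refused rather than tie-broken)
#' @return the corrected `leadfield` (component stored in `$u`)
#' @export
pca_correct <- function(L, tie_tol = 1e-10) {
  if (L$pca_corrected) stop("lead field is already PCA-corrected")
  M <- L$matrix
  if (nrow(M) < 2L) stop("need at least 2 rows")
  e <- eigen(tcrossprod(M), symmetric = TRUE)
  if ((e$values[1L] - e$values[2L]) <= tie_tol * abs(e$values[1L]))
    stop("leading eigenvalue is (near-)degenerate; refusing ambiguous correction")
  u <- e$vectors[, 1L]
  if (sum(u) < 0) u <- -u
  L$matrix <- M - u %*% crossprod(u, M)
  L$pca_corrected <- TRUE
  L$u <- u
  L
}

#' Re-reference a lead field
#'
#' `CAR`: augments the matrix with the implicit all-zero reference row,
#' subtracts the per-column mean over the augmented channel set and drops
#' the reference row again, making the lead field compatible with
#' common-average-referenced data. Idempotent. The original single-
#' reference scheme cannot be recovered (one-way).
#'
#' @param L a `leadfield`
#' @param scheme "CAR" or "original"
#' @return a `leadfield`
#' @export
rereference_leadfield <- function(L, scheme = c("CAR", "original")) {
  scheme <- match.arg(scheme)
  if (scheme == "original") {
    if (L$reference_scheme != "original")
      stop("cannot restore the original reference from a CAR lead field")
    return(L)
  }
  aug <- rbind(L$matrix, L$ref_row)
  aug <- sweep(aug, 2L, colMeans(aug))
  L$matrix <- aug[-nrow(aug), , drop = FALSE]
  L$ref_row <- aug[nrow(aug), ]
  L$reference_scheme <- "CAR"
  L
}

#' Extract a column subset of a lead field
#'
#' Returns a lead field restricted to the requested sources (which must be
#' covered by the input's `source_index`).
#'
#' @param L a `leadfield`
#' @param sources source indices (into the source space)
#' @return a `leadfield` whose columns are the requested sources
#' @export
leadfield_columns <- function(L, sources) {
  cols <- match(sources, L$source_index)
  if (anyNA(cols)) stop("requested sources not covered by this lead field")
  out <- L
  out$matrix <- L$matrix[, cols, drop = FALSE]
  out$source_index <- L$source_index[cols]
  out$ref_row <- L$ref_row[cols]
  out
}
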