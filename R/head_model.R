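#' Nested-compartment conductor model
#'
#' A head model is an ordered list of closed triangulated surfaces
#' (outermost first) with, for each surface, the conductivity just inside
#' (`sigma_in`) and just outside (`sigma_out`) in S/m. The outermost surface
#' has `sigma_out = 0` (air). The per-surface conductivity contrast
#' k = (sigma_in - sigma_out) / (sigma_in + sigma_out) drives the
#' boundary-element solver.
#'
#' @param surfaces list of `triangle_mesh`, outermost first
#' @param sigma_in,sigma_out numeric vectors, S/m, one entry per surface
#' @param check_nesting verify strict nesting by winding numbers (subsampled)
#' @return an object of class `head_model`
#' @export
head_model <- function(surfaces, sigma_in, sigma_out, check_nesting = TRUE) {
  ns <- length(surfaces)
  if (length(sigma_in) != ns || length(sigma_out) != ns)
    stop("sigma_in/sigma_out must match the number of surfaces")
  if (sigma_out[1L] != 0)
    stop("outermost surface must have sigma_out = 0 (air)")
  if (any(sigma_in <= 0))
    stop("conductivities inside the head must be positive")
  if (check_nesting && ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      vi <- surfaces[[i + 1L]]$vertices
      take <- seq_len(nrow(vi))
      if (length(take) > 200L) take <- round(seq(1L, nrow(vi), length.out = 200L))
      w <- winding_number(surfaces[[i]], vi[take, , drop = FALSE])
      if (any(w < 0.5))
        stop(sprintf("surface %d is not strictly inside surface %d", i + 1L, i))
    }
  }
  k <- (sigma_in - sigma_out) / (sigma_in + sigma_out)
  structure(list(surfaces = surfaces, sigma_in = sigma_in,
                 sigma_out = sigma_out, contrast = k),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("head_model: %d nested surface(s)\n", length(x$surfaces)))
  for (i in seq_along(x$surfaces)) {
    cat(sprintf("  [%d] %6d faces | sigma in/out %.4g/%.4g S/m | k = %.5f\n",
                i, nrow(x$surfaces[[i]]$faces), x$sigma_in[i], x$sigma_out[i],
                x$contrast[i]))
  }
  if (!is.null(attr(x, "montage")))
    cat(sprintf("  imprinted montage: %d electrodes\n",
                nrow(attr(x, "montage"))))
  invisible(x)
}

#' Nested-sphere head model
#'
#' Concentric icosphere shells, a desk-scale stand-in for segmented
#' skin/skull/brain meshes. The default three-shell configuration uses the
#' classic radii 0.09/0.085/0.080 m and conductivities 0.33/0.0042/0.33 S/m.
#'
#' @param radii numeric, strictly decreasing, outermost first (m)
#' @param conductivities numeric, one per compartment (S/m); compartment i
#'   lies directly inside surface i
#' @param n_subdiv icosphere subdivision level, recycled over shells (the
#'   innermost surface benefits from one extra level when the source space
#'   sits close beneath it)
#' @return a `head_model`
#' @export
make_nested_sphere_head <- function(radii = c(0.09, 0.085, 0.080),
                                    conductivities = c(0.33, 0.0042, 0.33),
                                    n_subdiv = 3) {
  if (length(radii) != length(conductivities))
    stop("radii and conductivities must have the same length")
  if (any(diff(radii) >= 0))
    stop("radii must be strictly decreasing (outermost first)")
  if (any(radii <= 0)) stop("radii must be positive")
  n_subdiv <- rep_len(n_subdiv, length(radii))
  surfaces <- mapply(make_icosphere, radii, n_subdiv, SIMPLIFY = FALSE)
  sigma_in <- conductivities
  sigma_out <- c(0, conductivities[-length(conductivities)])
  head_model(surfaces, sigma_in, sigma_out, check_nesting = FALSE)
}

#' Electrode montage
#'
#' A set of labelled scalp electrodes with circular contacts. Exactly one
#' electrode has role "reference".
#'
#' @param label character, unique labels
#' @param positions k x 3 matrix, contact centers on the skin (m)
#' @param role character, "channel" or "reference" (exactly one reference)
#' @param contact_radius contact disc radius in meters (recycled)
#' @return a data.frame of class `electrode_montage` with columns
#'   label, x, y, z, role, contact_radius
#' @export
electrode_montage <- function(label, positions, role,
                              contact_radius = 0.005) {
  positions <- matrix(as.double(positions), ncol = 3L)
  n <- length(label)
  if (n < 2L) stop("a montage needs at least 2 electrodes")
  if (anyDuplicated(label)) stop("electrode labels must be unique")
  if (nrow(positions) != n || length(role) != n)
    stop("label, positions and role lengths differ")
  if (sum(role == "reference") != 1L)
    stop("exactly one electrode must have role 'reference'")
  out <- data.frame(label = as.character(label),
                    x = positions[, 1L], y = positions[, 2L],
                    z = positions[, 3L],
                    role = as.character(role),
                    contact_radius = rep_len(contact_radius, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("electrode_montage", "data.frame")
  out
}

#' Fibonacci-lattice EEG cap montage
#'
#' Places `n - 1` channel electrodes area-uniformly (golden-angle lattice)
#' on the upper spherical cap of the skin sphere down to `max_polar` degrees,
#' plus the reference electrode at the cap apex - a synthetic analogue of a
#' 10-20-style cap with a single central reference.
#'
#' @param n total electrode count including the reference (default 61)
#' @param radius skin sphere radius (m)
#' @param max_polar largest polar angle of the cap, degrees
#' @param contact_radius contact disc radius (m)
#' @return an `electrode_montage`
#' @export
fibonacci_montage <- function(n = 61, radius = 0.09, max_polar = 100,
                              contact_radius = 0.005) {
  if (n < 2L) stop("need at least 2 electrodes")
  zmin <- cos(max_polar * pi / 180)
  k <- seq_len(n - 1L)
  z <- 1 - (1 - zmin) * (k - 0.5) / (n - 1L)
  golden <- pi * (3 - sqrt(5))
  az <- golden * k
  pos <- radius * cbind(sqrt(1 - z^2) * cos(az), sqrt(1 - z^2) * sin(az), z)
  pos <- rbind(c(0, 0, radius), pos)
  labels <- c("REF", sprintf("E%02d", k))
  roles <- c("reference", rep("channel", n - 1L))
  m <- electrode_montage(labels, pos, roles, contact_radius)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  if (min(d) < 2 * max(m$contact_radius))
    stop("montage electrodes closer than one contact diameter")
  m
}

montage_positions <- function(montage) {
  cbind(montage$x, montage$y, montage$z)
}

# squared geodesic (arc) distance on a star-shaped surface between face
# centroids and an on-surface electrode center: |e| * angle. Plain 3D
# distance under-counts membership for coarse faceted meshes (centroids
# sit below the smooth surface), which can leave an electrode with no
# refined contact at all.
arc_dist2 <- function(cen, e) {
  re <- sqrt(sum(e^2))
  rc <- sqrt(cen[, 1L]^2 + cen[, 2L]^2 + cen[, 3L]^2)
  cosang <- (cen[, 1L] * e[1L] + cen[, 2L] * e[2L] + cen[, 3L] * e[3L]) /
    (rc * re)
  (re * acos(pmin(1, pmax(-1, cosang))))^2
}

# distance from a point to a triangulated surface (point-triangle
# distance over the faces nearest by centroid)
dist_to_surface <- function(p, mesh, n_cand = 12L) {
  d2 <- (mesh$centroids[, 1L] - p[1L])^2 + (mesh$centroids[, 2L] - p[2L])^2 +
    (mesh$centroids[, 3L] - p[3L])^2
  cand <- order(d2)[seq_len(min(n_cand, length(d2)))]
  min(vapply(cand, function(f) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    point_triangle_distance(p, tri[1, ], tri[2, ], tri[3, ])
  }, numeric(1)))
}

# Euclidean distance from point p to triangle (a, b, c); standard
# barycentric clamping
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3)
    return(sqrt(sum((p - (a + v * ab))^2)))
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - c)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6)
    return(sqrt(sum((p - (a + w * ac))^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(sqrt(sum((p - (b + w * (c - b)))^2)))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  sqrt(sum((p - (a + ab * v + ac * w))^2))
}

#' Imprint electrode contacts onto the skin mesh
#'
#' Refines skin faces whose centroid lies within the contact radius of an
#' electrode center, by conforming longest-edge bisection, until their
#' longest edge is at most `max_edge`; then assigns each electrode the set
#' of faces whose centroid lies inside its contact disc (or, if the disc is
#' smaller than every face, the single nearest face). Watertightness and
#' topology are preserved; contact face sets are disjoint. The montage and
#' the per-electrode face sets are stored as attributes of the returned
#' model.
#'
#' @param head a `head_model`
#' @param montage an `electrode_montage`
#' @param max_edge target longest edge inside contact discs (m); default
#'   one third of the smallest contact radius
#' @param position_tol how far (m) an electrode center may lie from the skin
#'   surface; default 5 mm
#' @return the imprinted `head_model` (attributes `montage`, `contacts`)
#' @export
imprint_electrodes <- function(head, montage,
                               max_edge = min(montage$contact_radius) / 3,
                               position_tol = 0.005, refine_inner = FALSE) {
  skin <- head$surfaces[[1L]]
  pos <- montage_positions(montage)
  rad <- montage$contact_radius
  # placement check: point-to-triangle distance over the nearest faces
  for (i in seq_len(nrow(pos))) {
    d2 <- (skin$centroids[, 1L] - pos[i, 1L])^2 +
      (skin$centroids[, 2L] - pos[i, 2L])^2 +
      (skin$centroids[, 3L] - pos[i, 3L])^2
    cand <- order(d2)[seq_len(min(12L, length(d2)))]
    dmin <- min(vapply(cand, function(f) {
      tri <- skin$vertices[skin$faces[f, ], , drop = FALSE]
      point_triangle_distance(pos[i, ], tri[1, ], tri[2, ], tri[3, ])
    }, numeric(1)))
    if (dmin > position_tol)
      stop(sprintf("electrode '%s' is farther than %g m from the skin surface",
                   montage$label[i], position_tol))
  }
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  overlap <- which(d < outer(rad, rad, "+"), arr.ind = TRUE)
  if (nrow(overlap))
    stop("overlapping electrode contact discs")

  # a face is refined when its centroid lies inside the contact disc, or
  # when the face itself is large enough that its footprint can overlap
  # the disc even though its centroid falls outside (coarse base meshes)
  needs_fun <- function(cen, diam) {
    inside <- rep(FALSE, nrow(cen))
    for (i in seq_len(nrow(pos))) {
      reach <- pmax(rad[i], 0.6 * diam)
      inside <- inside | (arc_dist2(cen, pos[i, ]) < reach^2)
    }
    inside & (diam > max_edge)
  }
  skin2 <- rivara_refine(skin, needs_fun)

  out <- head
  out$surfaces[[1L]] <- skin2
  # The injected current also imprints on the surfaces underneath: the
  # induced charge on an interface a gap g below a contact varies on the
  # scale of g, which the base mesh need not resolve. Refine each inner
  # surface in a zone around the contact axis until its edges resolve
  # that scale.
  if (refine_inner && length(head$surfaces) > 1L) {
    for (s in 2L:length(head$surfaces)) {
      surf <- out$surfaces[[s]]
      gaps <- numeric(nrow(pos))
      axes <- matrix(0, nrow(pos), 3L)
      for (i in seq_len(nrow(pos))) {
        d2 <- (surf$centroids[, 1L] - pos[i, 1L])^2 +
          (surf$centroids[, 2L] - pos[i, 2L])^2 +
          (surf$centroids[, 3L] - pos[i, 3L])^2
        j <- which.min(d2)
        gaps[i] <- sqrt(d2[j])
        axes[i, ] <- surf$centroids[j, ]
      }
      target <- pmax(max_edge, gaps / 1.5)
      zone <- rad + 0.5 * gaps
      nf2 <- function(cen, diam) {
        need <- rep(FALSE, nrow(cen))
        for (i in seq_len(nrow(pos))) {
          d2 <- (cen[, 1L] - axes[i, 1L])^2 + (cen[, 2L] - axes[i, 2L])^2 +
            (cen[, 3L] - axes[i, 3L])^2
          need <- need | (d2 < zone[i]^2 & diam > target[i])
        }
        need
      }
      out$surfaces[[s]] <- rivara_refine(surf, nf2)
    }
  }

  contacts <- vector("list", nrow(pos))
  names(contacts) <- montage$label
  owner <- integer(nrow(skin2$faces))
  for (i in seq_len(nrow(pos))) {
    d2 <- arc_dist2(skin2$centroids, pos[i, ])
    sel <- which(d2 < rad[i]^2)
    if (!length(sel)) sel <- which.min(d2)
    clash <- sel[owner[sel] != 0L]
    if (length(clash))
      stop("electrode contact face sets overlap")
    owner[sel] <- i
    contacts[[i]] <- sel
  }
  attr(out, "montage") <- montage
  attr(out, "contacts") <- contacts
  out
}

#' Face centroids of the skin contact patch of one electrode
#' @param head imprinted `head_model`
#' @param label electrode label
#' @return list with `faces` (indices into skin mesh), `areas`, `centroids`
#' @export
contact_patch <- function(head, label) {
  contacts <- attr(head, "contacts")
  if (is.null(contacts)) stop("head has no imprinted montage")
  if (!label %in% names(contacts))
    stop(sprintf("unknown electrode label '%s'", label))
  skin <- head$surfaces[[1L]]
  idx <- contacts[[label]]
  list(faces = idx, areas = skin$areas[idx],
       centroids = skin$centroids[idx, , drop = FALSE],
       normals = skin$normals[idx, , drop = FALSE])
}
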