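#' Triangulated surface mesh
#'
#' Constructs a closed triangulated surface. Faces are triples of vertex
#' indices, counter-clockwise when seen from outside, so that face normals
#' point outward. Per-face areas (m^2), centroids (m) and outward unit
#' normals are derived on construction. All coordinates are in meters.
#'
#' @param vertices numeric matrix, n x 3, vertex positions in meters.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `areas`, `centroids`, `normals`, `diameters` (longest edge
#'   per face).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  mesh_update_derived(m)
}

mesh_update_derived <- function(m) {
  V <- m$vertices; F <- m$faces
  v1 <- V[F[, 1L], , drop = FALSE]
  v2 <- V[F[, 2L], , drop = FALSE]
  v3 <- V[F[, 3L], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nn <- sqrt(rowSums(cr^2))
  m$areas <- nn / 2
  m$centroids <- (v1 + v2 + v3) / 3
  m$normals <- cr / nn
  l12 <- sqrt(rowSums((v2 - v1)^2))
  l23 <- sqrt(rowSums((v3 - v2)^2))
  l31 <- sqrt(rowSums((v1 - v3)^2))
  m$diameters <- pmax(l12, l23, l31)
  m
}

# face vertex coordinates as an m x 9 matrix (v1 | v2 | v3), the layout the
# C++ kernels expect
mesh_tri_coords <- function(m) {
  V <- m$vertices; F <- m$faces
  cbind(V[F[, 1L], , drop = FALSE], V[F[, 2L], , drop = FALSE],
        V[F[, 3L], , drop = FALSE])
}

mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Euler characteristic of a mesh (V - E + F)
#' @param mesh a `triangle_mesh`
#' @return integer
#' @export
euler_characteristic <- function(mesh) {
  nE <- length(unique(mesh_edge_keys(mesh$faces)))
  nrow(mesh$vertices) - nE + nrow(mesh$faces)
}

#' Signed enclosed volume of a closed mesh
#'
#' Positive when face normals point outward.
#' @param mesh a `triangle_mesh`
#' @return volume in m^3 (signed)
#' @export
signed_volume <- function(mesh) {
  sum(mesh$areas * rowSums(mesh$centroids * mesh$normals)) / 3
}

#' Geodesic icosphere
#'
#' Subdivided icosahedron with all vertices projected onto the sphere of the
#' given radius; `n_subdiv` quadruples the face count at each level, giving
#' 20 * 4^n faces.
#'
#' @param radius sphere radius in meters (> 0)
#' @param n_subdiv number of 4:1 subdivision passes (>= 0)
#' @return a `triangle_mesh`
#' @export
make_icosphere <- function(radius, n_subdiv) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive number")
  if (!is.numeric(n_subdiv) || length(n_subdiv) != 1L || n_subdiv < 0 ||
      n_subdiv != round(n_subdiv))
    stop("n_subdiv must be a non-negative integer")
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(F) <- "integer"
  # enforce outward orientation
  for (i in seq_len(nrow(F))) {
    tri <- V[F[i, ], ]
    n <- crossprod3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * colMeans(tri)) < 0) F[i, ] <- F[i, c(1L, 3L, 2L)]
  }
  for (s in seq_len(n_subdiv)) {
    nv <- nrow(V)
    ekey_all <- mesh_edge_keys(F)
    ekey <- unique(ekey_all)
    idx <- match(ekey_all, ekey)
    pair <- do.call(rbind, strsplit(ekey, " ", fixed = TRUE))
    a <- as.integer(pair[, 1L]); b <- as.integer(pair[, 2L])
    mid <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    V <- rbind(V, mid)
    nf <- nrow(F)
    m12 <- nv + idx[seq_len(nf)]
    m23 <- nv + idx[nf + seq_len(nf)]
    m31 <- nv + idx[2L * nf + seq_len(nf)]
    F <- rbind(cbind(F[, 1L], m12, m31),
               cbind(m12, F[, 2L], m23),
               cbind(m31, m23, F[, 3L]),
               cbind(m12, m23, m31))
    storage.mode(F) <- "integer"
  }
  triangle_mesh(V * radius, F)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mesh validation report
#'
#' Reports watertightness (every edge shared by exactly two faces), Euler
#' characteristic, normal orientation (signed volume), minimum face area and
#' the edge-length range. Purely diagnostic; never throws.
#'
#' @param mesh a `triangle_mesh`
#' @return a list of class `mesh_validation`
#' @export
validate_mesh <- function(mesh) {
  keys <- mesh_edge_keys(mesh$faces)
  tab <- table(keys)
  watertight <- all(tab == 2L)
  sv <- signed_volume(mesh)
  F <- mesh$faces; V <- mesh$vertices
  el <- c(sqrt(rowSums((V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE])^2)),
          sqrt(rowSums((V[F[, 3L], , drop = FALSE] - V[F[, 2L], , drop = FALSE])^2)),
          sqrt(rowSums((V[F[, 1L], , drop = FALSE] - V[F[, 3L], , drop = FALSE])^2)))
  structure(list(
    watertight = watertight,
    euler_characteristic = nrow(V) - length(tab) + nrow(F),
    outward_normals = sv > 0,
    signed_volume = sv,
    min_face_area = min(mesh$areas),
    min_edge_length = min(el),
    max_edge_length = max(el),
    n_vertices = nrow(V),
    n_faces = nrow(F)), class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("Mesh validation report\n")
  cat(sprintf("  vertices/faces : %d / %d\n", x$n_vertices, x$n_faces))
  cat(sprintf("  watertight     : %s\n", x$watertight))
  cat(sprintf("  Euler char.    : %d\n", x$euler_characteristic))
  cat(sprintf("  outward normals: %s (signed volume %.4g m^3)\n",
              x$outward_normals, x$signed_volume))
  cat(sprintf("  face area  min : %.4g m^2\n", x$min_face_area))
  cat(sprintf("  edge length    : %.4g - %.4g m\n", x$min_edge_length,
              x$max_edge_length))
  invisible(x)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, area %.4g m^2\n",
              nrow(x$vertices), nrow(x$faces), sum(x$areas)))
  invisible(x)
}

#' Fraction of points inside a closed mesh
#'
#' Generalized winding number (~1 inside, ~0 outside).
#' @param mesh a `triangle_mesh`
#' @param points k x 3 matrix
#' @return numeric vector of winding numbers
#' @export
winding_number <- function(mesh, points) {
  points <- matrix(as.double(points), ncol = 3L)
  cpp_winding_number(mesh_tri_coords(mesh), points)
}

# ---- conforming longest-edge (Rivara) bisection refinement ----------------
#
# Refines every face for which `needs_fun(centroid_matrix, diam_vector)`
# returns TRUE until it no longer does, by recursive longest-edge bisection.
# Bisection propagates through neighbours (LEPP), which keeps the mesh
# watertight and conforming. Topology (Euler characteristic) is preserved.
rivara_refine <- function(mesh, needs_fun, max_faces = 400000L) {
  V <- mesh$vertices
  nv <- nrow(V)
  capV <- max(2L * nv, 1024L)
  Vbuf <- matrix(0, capV, 3L)
  Vbuf[seq_len(nv), ] <- V
  F <- mesh$faces
  nf <- nrow(F)
  capF <- max(4L * nf, 2048L)
  Fbuf <- matrix(0L, capF, 3L)
  Fbuf[seq_len(nf), ] <- F
  alive <- rep(FALSE, capF)
  alive[seq_len(nf)] <- TRUE

  edges <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) if (a < b) paste(a, b) else paste(b, a)
  eadd <- function(a, b, f) {
    k <- ekey(a, b)
    cur <- edges[[k]]
    edges[[k]] <- c(cur, f)
  }
  erem <- function(a, b, f) {
    k <- ekey(a, b)
    cur <- edges[[k]]
    cur <- cur[cur != f]
    if (length(cur)) edges[[k]] <- cur else rm(list = k, envir = edges)
  }
  for (f in seq_len(nf)) {
    eadd(Fbuf[f, 1L], Fbuf[f, 2L], f)
    eadd(Fbuf[f, 2L], Fbuf[f, 3L], f)
    eadd(Fbuf[f, 3L], Fbuf[f, 1L], f)
  }

  longest_edge <- function(f) {
    tri <- Fbuf[f, ]
    p <- Vbuf[tri, , drop = FALSE]
    l <- c(sum((p[2, ] - p[1, ])^2), sum((p[3, ] - p[2, ])^2),
           sum((p[1, ] - p[3, ])^2))
    i <- which.max(l)
    if (i == 1L) c(tri[1L], tri[2L]) else if (i == 2L) c(tri[2L], tri[3L])
    else c(tri[3L], tri[1L])
  }
  face_diam <- function(f) {
    tri <- Fbuf[f, ]
    p <- Vbuf[tri, , drop = FALSE]
    sqrt(max(sum((p[2, ] - p[1, ])^2), sum((p[3, ] - p[2, ])^2),
             sum((p[1, ] - p[3, ])^2)))
  }
  centroid_of <- function(f) colMeans(Vbuf[Fbuf[f, ], , drop = FALSE])

  grow_if_needed <- function() {
    if (nf + 4L > capF) {
      capF <<- capF * 2L
      tmp <- matrix(0L, capF, 3L)
      tmp[seq_len(nf), ] <- Fbuf[seq_len(nf), ]
      Fbuf <<- tmp
      tmp2 <- rep(FALSE, capF)
      tmp2[seq_len(nf)] <- alive[seq_len(nf)]
      alive <<- tmp2
    }
    if (nv + 2L > capV) {
      capV <<- capV * 2L
      tmp <- matrix(0, capV, 3L)
      tmp[seq_len(nv), ] <- Vbuf[seq_len(nv), ]
      Vbuf <<- tmp
    }
  }

  # bisect face f across edge (a, b) with midpoint vertex m
  bisect_one <- function(f, a, b, mvert) {
    tri <- Fbuf[f, ]
    # locate (a, b) in cyclic order; opposite vertex keeps orientation
    ord <- c(tri, tri[1L])
    pos <- which((ord[1:3] == a & ord[2:4] == b) |
                 (ord[1:3] == b & ord[2:4] == a))[1L]
    va <- ord[pos]; vb <- ord[pos + 1L]
    vc <- setdiff(tri, c(a, b))[1L]
    erem(tri[1L], tri[2L], f); erem(tri[2L], tri[3L], f)
    erem(tri[3L], tri[1L], f)
    alive[f] <<- FALSE
    grow_if_needed()
    f1 <- nf + 1L; f2 <- nf + 2L
    Fbuf[f1, ] <<- c(va, mvert, vc)
    Fbuf[f2, ] <<- c(mvert, vb, vc)
    alive[f1] <<- TRUE; alive[f2] <<- TRUE
    nf <<- nf + 2L
    eadd(va, mvert, f1); eadd(mvert, vc, f1); eadd(vc, va, f1)
    eadd(mvert, vb, f2); eadd(vb, vc, f2); eadd(vc, mvert, f2)
    c(f1, f2)
  }

  bisect_pair <- function(f, g, a, b) {
    grow_if_needed()
    nv <<- nv + 1L
    Vbuf[nv, ] <<- (Vbuf[a, ] + Vbuf[b, ]) / 2
    out <- bisect_one(f, a, b, nv)
    if (!is.na(g)) out <- c(out, bisect_one(g, a, b, nv))
    out
  }

  # LEPP: follow longest edges until a terminal pair, bisect it; repeat
  # until the starting face itself is bisected
  lepp_bisect <- function(f0) {
    new_faces <- integer(0)
    guard <- 0L
    while (alive[f0]) {
      guard <- guard + 1L
      if (guard > 10000L) stop("refinement did not terminate")
      f <- f0
      repeat {
        e <- longest_edge(f)
        nb <- edges[[ekey(e[1L], e[2L])]]
        g <- nb[nb != f]
        g <- if (length(g)) g[1L] else NA_integer_
        if (is.na(g)) {
          new_faces <- c(new_faces, bisect_pair(f, NA_integer_, e[1L], e[2L]))
          break
        }
        eg <- longest_edge(g)
        if (all(sort(eg) == sort(e))) {
          new_faces <- c(new_faces, bisect_pair(f, g, e[1L], e[2L]))
          break
        }
        f <- g
      }
    }
    new_faces
  }

  work <- which(alive[seq_len(nf)])
  # seed: only faces currently needing refinement
  cen0 <- t(vapply(work, centroid_of, numeric(3)))
  dia0 <- vapply(work, face_diam, numeric(1))
  work <- work[needs_fun(cen0, dia0)]
  while (length(work)) {
    f <- work[[1L]]
    work <- work[-1L]
    if (!alive[f]) next
    cen <- matrix(centroid_of(f), 1L)
    if (!needs_fun(cen, face_diam(f))) next
    if (nf > max_faces) stop("refinement exceeded max_faces")
    nw <- lepp_bisect(f)
    if (length(nw)) {
      cenN <- t(vapply(nw, centroid_of, numeric(3)))
      diaN <- vapply(nw, face_diam, numeric(1))
      work <- c(work, nw[needs_fun(cenN, diaN)])
    }
  }

  keep <- which(alive[seq_len(nf)])
  Fout <- Fbuf[keep, , drop = FALSE]
  used <- sort(unique(as.vector(Fout)))
  remap <- integer(nv)
  remap[used] <- seq_along(used)
  Fout <- matrix(remap[Fout], ncol = 3L)
  storage.mode(Fout) <- "integer"
  triangle_mesh(Vbuf[used, , drop = FALSE], Fout)
}
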