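EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Boundary-element operator for a head model
#'
#' Collects the collocation geometry (face centroids, outward normals,
#' areas, conductivity contrasts) of all surfaces of a head model and
#' prepares the second-kind integral operator
#' \deqn{g/2 - k\, n \cdot E_{ind}(g) = k\, n \cdot E_{primary}}
#' whose unknown g is the induced surface charge density over the vacuum
#' permittivity. Near-field interactions (within `near_mult` face diameters)
#' use closed-form flat-triangle integrals; far pairs use centroid point
#' charges. The dense system matrix and its LU factorization are built
#' lazily on first use and cached, so repeated solves on the same geometry
#' (for example the 60 injection solves of a reciprocal lead-field build)
#' amortize one factorization.
#'
#' @param head a `head_model`
#' @param near_mult near-field radius in units of the source-face diameter
#' @return an environment of class `bem_operator`
#' @export
bem_operator <- function(head, near_mult = 6, use_rowsum = TRUE,
                         use_obsavg = FALSE) {
  ns <- length(head$surfaces)
  cen <- do.call(rbind, lapply(head$surfaces, `[[`, "centroids"))
  nor <- do.call(rbind, lapply(head$surfaces, `[[`, "normals"))
  area <- unlist(lapply(head$surfaces, `[[`, "areas"))
  diam <- unlist(lapply(head$surfaces, `[[`, "diameters"))
  triV <- do.call(rbind, lapply(head$surfaces, mesh_tri_coords))
  nf <- vapply(head$surfaces, function(s) nrow(s$faces), integer(1))
  kvec <- rep(head$contrast, nf)
  surface_of <- rep(seq_len(ns), nf)
  op <- new.env(parent = emptyenv())
  op$head <- head
  op$cen <- cen; op$nor <- nor; op$area <- area; op$diam <- diam
  op$triV <- triV; op$kvec <- kvec; op$surface_of <- surface_of
  op$near_mult <- near_mult
  op$use_rowsum <- use_rowsum
  op$use_obsavg <- use_obsavg
  op$n <- length(area)
  op$A <- NULL; op$lu <- NULL
  class(op) <- "bem_operator"
  op
}

#' @export
print.bem_operator <- function(x, ...) {
  cat(sprintf("bem_operator: %d charge unknowns on %d surface(s)%s\n",
              x$n, length(x$head$surfaces),
              if (!is.null(x$lu)) " [factorized]" else ""))
  invisible(x)
}

bem_dense <- function(op) {
  if (is.null(op$A)) {
    # The assembly includes a per-surface deflation term: the net-charge
    # (uniform) mode of a closed surface with contrast k has operator
    # eigenvalue (1 - k)/2, which is 0 for the outer surface (k = 1, air)
    # and tiny for a resistive skull boundary (k ~ 0.975); discretization
    # error in those modes is hugely amplified. The physical solution
    # carries zero net charge on every closed interface, so a rank-1 term
    # per surface proportional to its charge total leaves the solution
    # unchanged while moving those eigenvalues to O(1/2).
    defl <- op$area
    for (s in seq_along(op$head$surfaces)) {
      rows <- op$surface_of == s
      defl[rows] <- 0.5 * op$area[rows] / sum(op$area[rows])
    }
    op$A <- cpp_bem_matrix(op$cen, op$nor, op$area, op$kvec, op$triV,
                           op$diam, op$surface_of, op$near_mult, defl,
                           op$use_rowsum, op$use_obsavg)
  }
  op$A
}

# Factor the dense matrix in place (dgetrf); afterwards op$A holds the
# L\U factors and op$ipiv the pivots. Peak memory stays at one matrix.
bem_factor <- function(op) {
  if (is.null(op$ipiv)) {
    A <- bem_dense(op)
    op$ipiv <- cpp_lu_factor(A)
    op$factored <- TRUE
  }
  invisible(op)
}

# y = A x; uses the factors (P L U x) when A has been factored in place,
# the stored dense matrix when not, or the matrix-free kernel pass.
bem_matvec <- function(op, x) {
  x <- as.matrix(x)
  if (!is.null(op$ipiv))
    return(cpp_lu_apply(op$A, op$ipiv, x))
  if (!is.null(op$A)) return(op$A %*% x)
  y <- apply(x, 2L, function(v)
    cpp_bem_matvec(op$cen, op$nor, op$area, op$kvec, op$triV, op$diam,
                   op$surface_of, op$near_mult, op$use_rowsum,
                   op$use_obsavg, v))
  y <- matrix(y, nrow(x), ncol(x))
  for (s in seq_along(op$head$surfaces)) {
    rows <- op$surface_of == s
    alpha <- 0.5 / sum(op$area[rows])
    y[rows, ] <- y[rows, , drop = FALSE] +
      alpha * rep(colSums(x[rows, , drop = FALSE] * op$area[rows]),
                  each = sum(rows))
  }
  y
}

# Solve the BEM system for one or several right-hand sides.
# solver "lu": dense factorization, reused across calls.
# solver "gmres": restarted matrix-free GMRES per column.
bem_solve <- function(op, B, solver = c("lu", "gmres"), tol = 1e-8,
                      restart = 200L, maxit = 500L) {
  solver <- match.arg(solver)
  B <- as.matrix(B)
  if (solver == "lu") {
    bem_factor(op)
    G <- cpp_lu_solve(op$A, op$ipiv, B)
    iters <- rep(NA_integer_, ncol(B))
  } else {
    G <- matrix(0, nrow(B), ncol(B))
    iters <- integer(ncol(B))
    for (j in seq_len(ncol(B))) {
      res <- gmres(function(v) as.numeric(bem_matvec(op, v)), B[, j],
                   tol = tol, restart = restart, maxit = maxit)
      if (!res$converged)
        stop(sprintf("GMRES did not converge (residual %.3g after %d iterations)",
                     res$residual, res$iterations))
      G[, j] <- res$x
      iters[j] <- res$iterations
    }
  }
  R <- bem_matvec(op, G) - B
  resid <- sqrt(colSums(R^2) / colSums(B^2))
  list(G = G, residual = resid, iterations = iters)
}

#' Restarted GMRES
#'
#' Matrix-free restarted GMRES with modified Gram-Schmidt Arnoldi; `matvec`
#' is any function computing A x.
#'
#' @param matvec function of one vector argument
#' @param b right-hand side
#' @param tol relative residual target
#' @param restart Krylov dimension per cycle
#' @param maxit maximum total iterations
#' @param x0 initial guess (default zero)
#' @return list with `x`, `residual`, `iterations`, `converged`
#' @export
gmres <- function(matvec, b, tol = 1e-8, restart = 200L, maxit = 500L,
                  x0 = NULL) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, residual = 0, iterations = 0L,
                              converged = TRUE))
  total <- 0L
  repeat {
    r <- b - matvec(x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol || total >= maxit)
      return(list(x = x, residual = beta / bnorm, iterations = total,
                  converged = beta / bnorm <= tol))
    m <- min(restart, maxit - total)
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    cs <- sn <- numeric(m)
    g <- numeric(m + 1L)
    V[, 1L] <- r / beta
    g[1L] <- beta
    k_used <- 0L
    for (k in seq_len(m)) {
      w <- matvec(V[, k])
      for (i in seq_len(k)) {
        H[i, k] <- sum(w * V[, i])
        w <- w - H[i, k] * V[, i]
      }
      H[k + 1L, k] <- sqrt(sum(w^2))
      if (H[k + 1L, k] > 0) V[, k + 1L] <- w / H[k + 1L, k]
      # apply previous Givens rotations
      if (k > 1L) for (i in seq_len(k - 1L)) {
        t <- cs[i] * H[i, k] + sn[i] * H[i + 1L, k]
        H[i + 1L, k] <- -sn[i] * H[i, k] + cs[i] * H[i + 1L, k]
        H[i, k] <- t
      }
      d <- sqrt(H[k, k]^2 + H[k + 1L, k]^2)
      cs[k] <- H[k, k] / d; sn[k] <- H[k + 1L, k] / d
      H[k, k] <- d; H[k + 1L, k] <- 0
      g[k + 1L] <- -sn[k] * g[k]
      g[k] <- cs[k] * g[k]
      total <- total + 1L
      k_used <- k
      if (abs(g[k + 1L]) / bnorm <= tol) break
    }
    y <- backsolve(H[seq_len(k_used), seq_len(k_used), drop = FALSE],
                   g[seq_len(k_used)])
    x <- x + V[, seq_len(k_used), drop = FALSE] %*% y
    x <- as.numeric(x)
  }
}

# ---- primary (impressed-source) fields in an unbounded medium -------------

dipole_primary_potential <- function(points, p, m, sigma) {
  d <- sweep(points, 2L, p)
  r2 <- rowSums(d^2)
  as.numeric((d %*% m) / (4 * pi * sigma * r2^1.5))
}

dipole_primary_field <- function(points, p, m, sigma) {
  d <- sweep(points, 2L, p)
  r2 <- rowSums(d^2)
  r <- sqrt(r2)
  mdotu <- as.numeric(d %*% m) / r
  (3 * mdotu * d / r - matrix(m, nrow(points), 3L, byrow = TRUE)) /
    (4 * pi * sigma * r2 * r)
}

monopole_primary_potential <- function(points, S, I, sigma) {
  out <- numeric(nrow(points))
  for (s in seq_len(nrow(S))) {
    d <- sweep(points, 2L, S[s, ])
    out <- out + I[s] / (4 * pi * sigma * sqrt(rowSums(d^2)))
  }
  out
}

monopole_primary_field <- function(points, S, I, sigma) {
  out <- matrix(0, nrow(points), 3L)
  for (s in seq_len(nrow(S))) {
    d <- sweep(points, 2L, S[s, ])
    r3 <- rowSums(d^2)^1.5
    out <- out + (I[s] / (4 * pi * sigma)) * d / r3
  }
  out
}

# conductivity of the compartment containing each point (0 outside the head)
compartment_sigma <- function(head, points) {
  points <- matrix(as.double(points), ncol = 3L)
  sig <- rep(0, nrow(points))
  for (i in seq_along(head$surfaces)) {
    inside <- cpp_winding_number(mesh_tri_coords(head$surfaces[[i]]),
                                 points) > 0.5
    sig[inside] <- head$sigma_in[i]
  }
  sig
}

charge_solution <- function(op, source, G, residual, iterations) {
  structure(list(head = op$head, op = op, source = source,
                 charge = as.numeric(G),
                 rho = EPS0 * as.numeric(G),
                 residual = residual, iterations = iterations),
            class = "charge_solution")
}

#' @export
print.charge_solution <- function(x, ...) {
  cat(sprintf("charge_solution: %s source, %d faces, residual %.2e\n",
              x$source$type, length(x$charge), x$residual))
  tot <- sum(x$charge * x$op$area)
  cat(sprintf("  net induced charge / total |charge|: %.2e\n",
              abs(tot) / sum(abs(x$charge) * x$op$area)))
  invisible(x)
}

#' Forward solve for an interior current dipole
#'
#' Solves the charge-based boundary integral equation for a point current
#' dipole inside the head and returns the induced surface charge density,
#' from which potentials and fields anywhere follow via
#' [evaluate_potential()] and [evaluate_field()].
#'
#' @param head a `head_model` (or pass a prebuilt `op`)
#' @param position dipole position (m), strictly inside a conducting
#'   compartment
#' @param moment dipole moment q*d in A*m
#' @param tol relative residual tolerance
#' @param op optional prebuilt [bem_operator()] for `head`
#' @param solver "lu" (dense factorization, cached) or "gmres" (matrix-free)
#' @return a `charge_solution`
#' @export
solve_dipole <- function(head, position, moment, tol = 1e-8, op = NULL,
                         solver = "lu") {
  if (is.null(op)) op <- bem_operator(head)
  sigma <- compartment_sigma(op$head, matrix(position, 1L))
  if (sigma <= 0)
    stop("dipole position is outside all conducting compartments")
  b <- cpp_rhs_dipole(op$triV, op$nor, op$kvec, position, moment, sigma, 4L)
  sol <- bem_solve(op, b, solver = solver, tol = tol)
  charge_solution(op,
                  list(type = "dipole", position = position, moment = moment,
                       sigma = sigma),
                  sol$G, sol$residual, sol$iterations)
}

# impressed current monopoles for one electrode contact patch: one monopole
# per contact face, displaced inward by half the local edge length, with
# face-area current shares
# The monopoles sit mid-way through the outermost compartment (half the
# local skin thickness, never shallower than half the local edge): the
# skin's shielding response above an impressed monopole has spatial scale
# equal to its depth, so monopoles placed a fraction of a (refined) edge
# below the surface create structure the mesh cannot represent, and the
# representation error acts like current leaking out of the head.
contact_monopoles <- function(head, label, current) {
  patch <- contact_patch(head, label)
  local_half_edge <- head$surfaces[[1L]]$diameters[patch$faces] / 2
  if (length(head$surfaces) > 1L) {
    ctr <- colMeans(patch$centroids)
    gap <- dist_to_surface(ctr, head$surfaces[[2L]])
    delta <- pmin(pmax(local_half_edge, 0.5 * gap), 0.9 * gap)
  } else {
    delta <- pmax(local_half_edge,
                  0.5 * mean(attr(head, "montage")$contact_radius))
  }
  pos <- patch$centroids - patch$normals * delta
  share <- current * patch$areas / sum(patch$areas)
  list(positions = pos, currents = share)
}

#' Forward solve for transcranial current injection
#'
#' Injects `current` at the anode contact and withdraws it at the cathode
#' contact of an imprinted montage. The impressed source is a set of current
#' monopoles under the contact faces (area-weighted shares, displaced
#' inward by half the local edge length).
#'
#' @param head an imprinted `head_model`
#' @param anode_label,cathode_label electrode labels
#' @param current total injected current (A), nonzero
#' @param tol relative residual tolerance
#' @param op optional prebuilt operator
#' @param solver "lu" or "gmres"
#' @return a `charge_solution`
#' @export
solve_tes <- function(head, anode_label, cathode_label, current,
                      tol = 1e-8, op = NULL, solver = "lu") {
  if (current == 0) stop("current must be nonzero")
  if (identical(anode_label, cathode_label))
    stop("anode and cathode must differ")
  if (is.null(op)) op <- bem_operator(head)
  b <- tes_rhs(op, anode_label, cathode_label, current)
  sol <- bem_solve(op, b, solver = solver, tol = tol)
  mono <- attr(b, "monopoles")
  charge_solution(op,
                  list(type = "electrode_pair", anode = anode_label,
                       cathode = cathode_label, current = current,
                       monopoles = mono$positions,
                       monopole_currents = mono$currents,
                       sigma = op$head$sigma_in[1L]),
                  sol$G, sol$residual, sol$iterations)
}

tes_rhs <- function(op, anode_label, cathode_label, current) {
  head <- op$head
  an <- contact_monopoles(head, anode_label, current)
  ca <- contact_monopoles(head, cathode_label, -current)
  S <- rbind(an$positions, ca$positions)
  I <- c(an$currents, ca$currents)
  sigma <- head$sigma_in[1L]
  b <- cpp_rhs_monopoles(op$triV, op$nor, op$kvec, S, I, sigma, op$area)
  attr(b, "monopoles") <- list(positions = S, currents = I)
  b
}

primary_potential_of <- function(sol, points) {
  src <- sol$source
  if (src$type == "dipole") {
    dipole_primary_potential(points, src$position, src$moment, src$sigma)
  } else {
    monopole_primary_potential(points, src$monopoles, src$monopole_currents,
                               src$sigma)
  }
}

primary_field_of <- function(sol, points) {
  src <- sol$source
  if (src$type == "dipole") {
    dipole_primary_field(points, src$position, src$moment, src$sigma)
  } else {
    monopole_primary_field(points, src$monopoles, src$monopole_currents,
                           src$sigma)
  }
}

#' Electric potential of a forward solution
#'
#' Sum of the impressed-source potential and the induced-charge potential,
#' in volts. Near-field faces are integrated in closed form, so points on
#' or next to the surfaces are handled accurately.
#'
#' @param sol a `charge_solution`
#' @param points k x 3 evaluation positions (m)
#' @return potentials (V)
#' @export
evaluate_potential <- function(sol, points) {
  points <- matrix(as.double(points), ncol = 3L)
  op <- sol$op
  # the 1/r kernel is smooth: closed-form integration within two face
  # diameters suffices (the wider analytic radius matters only for the
  # field kernel of the system matrix)
  ind <- cpp_eval_potential(op$triV, op$cen, op$area, op$diam,
                            matrix(sol$charge, ncol = 1L), points,
                            min(op$near_mult, 2))
  primary_potential_of(sol, points) + as.numeric(ind)
}

#' Electric field of a forward solution
#'
#' @param sol a `charge_solution`
#' @param points k x 3 evaluation positions (m)
#' @return k x 3 matrix of E vectors (V/m)
#' @export
evaluate_field <- function(sol, points) {
  points <- matrix(as.double(points), ncol = 3L)
  op <- sol$op
  ind <- cpp_eval_field(op$triV, op$cen, op$area, op$diam,
                        matrix(sol$charge, ncol = 1L), points, op$near_mult)
  primary_field_of(sol, points) + matrix(ind, nrow(points), 3L)
}

#' Induced charge density sampled on one model surface
#'
#' @param sol a `charge_solution`
#' @param surface index of the surface in the head model
#' @return per-face charge density rho (C/m^2, free-space convention)
#' @export
sample_charge_density <- function(sol, surface) {
  sel <- sol$op$surface_of == surface
  sol$rho[sel]
}

#' Adaptive mesh refinement around an electrode pair
#'
#' Repeatedly solves the injection problem, then bisects the top decile of
#' skin faces ranked by |rho| * area within three contact radii of either
#' electrode, until the sampled interior field changes by less than
#' `lead_tol` between passes (relative L2) or `max_passes` is reached. With
#' `max_passes = 1` this is exactly one solve on the imprinted mesh.
#'
#' @param head imprinted `head_model`
#' @param anode_label,cathode_label electrode pair
#' @param current injected current (A)
#' @param lead_tol relative change threshold between passes
#' @param max_passes maximum number of solves (>= 1)
#' @param probe_points interior points at which convergence is measured;
#'   default: a small icosphere at 80% of the innermost radius
#' @param tol,solver forwarded to the solver
#' @param op optional prebuilt operator for the *initial* head
#' @return a `charge_solution` with attributes `passes` (per-pass relative
#'   change) and `converged`
#' @export
adaptive_refine_solve <- function(head, anode_label, cathode_label, current,
                                  lead_tol = 0.02, max_passes = 1L,
                                  probe_points = NULL, tol = 1e-8,
                                  solver = "lu", op = NULL) {
  if (max_passes < 1L) stop("max_passes must be at least 1")
  montage <- attr(head, "montage")
  if (is.null(montage)) stop("head has no imprinted montage")
  if (is.null(probe_points)) {
    rin <- max(sqrt(rowSums(
      head$surfaces[[length(head$surfaces)]]$vertices^2)))
    probe <- make_icosphere(0.8 * rin, 1)
    probe_points <- probe$centroids
  }
  sel_rows <- match(c(anode_label, cathode_label), montage$label)
  if (anyNA(sel_rows)) stop("unknown electrode label")
  epos <- montage_positions(montage)[sel_rows, , drop = FALSE]
  erad <- montage$contact_radius[sel_rows]

  cur_head <- head
  cur_op <- op
  prev_field <- NULL
  changes <- numeric(0)
  converged <- FALSE
  sol <- NULL
  for (pass in seq_len(max_passes)) {
    if (is.null(cur_op)) cur_op <- bem_operator(cur_head)
    sol <- solve_tes(cur_head, anode_label, cathode_label, current,
                     tol = tol, op = cur_op, solver = solver)
    fld <- evaluate_field(sol, probe_points)
    if (!is.null(prev_field)) {
      ch <- sqrt(sum((fld - prev_field)^2) / sum(prev_field^2))
      changes <- c(changes, ch)
      if (ch < lead_tol) { converged <- TRUE; break }
    }
    prev_field <- fld
    if (pass == max_passes) {
      converged <- max_passes == 1L || (length(changes) &&
                                          tail(changes, 1L) < lead_tol)
      break
    }
    # mark top decile of |rho|*area near the two electrodes on the skin
    skin_sel <- cur_op$surface_of == 1L
    w <- abs(sol$charge[skin_sel]) * cur_op$area[skin_sel]
    cen <- cur_op$cen[skin_sel, , drop = FALSE]
    near <- rep(FALSE, nrow(cen))
    for (e in 1:2) {
      d2 <- (cen[, 1L] - epos[e, 1L])^2 + (cen[, 2L] - epos[e, 2L])^2 +
        (cen[, 3L] - epos[e, 3L])^2
      near <- near | (d2 < (3 * erad[e])^2)
    }
    cand <- which(near)
    if (!length(cand)) { converged <- TRUE; break }
    thr <- stats::quantile(w[cand], 0.9)
    mark <- cand[w[cand] >= thr]
    skin <- cur_head$surfaces[[1L]]
    mark_cen <- skin$centroids[mark, , drop = FALSE]
    # marked faces are identified by their (current) centroid; children of
    # a bisected face have new centroids, so each marked face is split
    # exactly once per pass
    needs_fun <- local({
      mc <- mark_cen
      function(cen2, diam2) {
        out <- rep(FALSE, nrow(cen2))
        for (i in seq_len(nrow(mc))) {
          d2 <- (cen2[, 1L] - mc[i, 1L])^2 + (cen2[, 2L] - mc[i, 2L])^2 +
            (cen2[, 3L] - mc[i, 3L])^2
          out <- out | (d2 < 1e-18)
        }
        out
      }
    })
    skin2 <- rivara_refine(skin, needs_fun)
    cur_head$surfaces[[1L]] <- skin2
    # re-imprint contact assignment on the refined skin
    cur_head <- reassign_contacts(cur_head, montage)
    cur_op <- NULL
  }
  attr(sol, "passes") <- changes
  attr(sol, "converged") <- converged
  sol
}

# refresh contact face sets after the skin mesh changed
reassign_contacts <- function(head, montage) {
  skin <- head$surfaces[[1L]]
  pos <- montage_positions(montage)
  contacts <- vector("list", nrow(pos))
  names(contacts) <- montage$label
  owner <- integer(nrow(skin$faces))
  for (i in seq_len(nrow(pos))) {
    d2 <- arc_dist2(skin$centroids, pos[i, ])
    sel <- which(d2 < montage$contact_radius[i]^2)
    if (!length(sel)) sel <- which.min(d2)
    owner[sel] <- i
    contacts[[i]] <- sel
  }
  attr(head, "montage") <- montage
  attr(head, "contacts") <- contacts
  head
}
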