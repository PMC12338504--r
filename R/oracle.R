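#' Concentric-sphere analytic model
#'
#' Closed-form/series reference solutions on nested concentric spheres,
#' used to validate the boundary-element solver. Potentials are expanded in
#' Legendre series with per-shell radial recursion; all coordinates are
#' normalized to the outer radius internally so the series is stable.
#'
#' @param radii strictly decreasing radii, outermost first (m)
#' @param conductivities one per compartment (S/m)
#' @param n_terms maximum series order (>= 10)
#' @return object of class `sphere_model`
#' @export
sphere_model <- function(radii, conductivities, n_terms = 200L) {
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (length(radii) != length(conductivities))
    stop("radii and conductivities must have the same length")
  if (n_terms < 10L) stop("n_terms must be at least 10")
  structure(list(radii = as.double(radii),
                 conductivities = as.double(conductivities),
                 n_terms = as.integer(n_terms)),
            class = "sphere_model")
}

# Legendre P_n(u) and associated P_n^1(u) = sqrt(1-u^2) P_n'(u) (positive
# convention), computed by upward recurrence; returns list of matrices
# [length(u) x n_max] for n = 1..n_max
legendre_table <- function(u, n_max) {
  s <- sqrt(pmax(0, 1 - u^2))
  P <- matrix(0, length(u), n_max)
  P1 <- matrix(0, length(u), n_max)
  Pm1 <- rep(1, length(u))   # P_0
  P[, 1L] <- u               # P_1
  P1[, 1L] <- s              # P_1^1
  if (n_max >= 2L) {
    P[, 2L] <- (3 * u^2 - 1) / 2
    P1[, 2L] <- 3 * u * s
    for (n in 2L:(n_max - 1L)) {
      P[, n + 1L] <- ((2 * n + 1) * u * P[, n] - n * P[, n - 1L]) / (n + 1)
      P1[, n + 1L] <- ((2 * n + 1) * u * P1[, n] - (n + 1) * P1[, n - 1L]) / n
    }
  }
  list(P = P, P1 = P1)
}

# Per-order radial solve on normalized radii x_l = R_l/R_1.
# Shell l occupies x_{l+1} < x < x_l (shell L: 0 < x < x_L), potential
# A_l x^n + B_l x^-(n+1); B_L = 0. `src` adds a fixed x^-(n+1) coefficient
# in the innermost shell (interior dipole source); `rhs_outer` is the outer
# Neumann datum sigma_hat * d(phi)/dx at x = 1 (surface current injection).
# Returns c(A_1..A_L, B_1..B_{L-1}).
radial_solve <- function(n, x, sig, src = 0, rhs_outer = 0) {
  L <- length(x)
  sh <- sig / sig[1L]
  if (L == 1L) {
    A1 <- (rhs_outer + (n + 1) * src) / n
    return(c(A1))
  }
  m <- 2L * L - 1L
  M <- matrix(0, m, m)
  rhs <- numeric(m)
  iA <- function(l) l
  iB <- function(l) L + l   # l = 1..L-1
  # column scaling for B unknowns keeps entries O(1) at high n
  bscale <- x[2:L]^(n + 1)
  # outer Neumann at x = 1
  M[1L, iA(1L)] <- n
  if (L > 1L) M[1L, iB(1L)] <- -(n + 1) * bscale[1L]
  rhs[1L] <- rhs_outer
  r <- 1L
  for (l in seq_len(L - 1L)) {
    xi <- x[l + 1L]
    xn <- xi^n; xm <- xi^(-(n + 1))
    # continuity of potential
    r <- r + 1L
    M[r, iA(l)] <- xn
    if (l < L) M[r, iA(l + 1L)] <- -xn
    M[r, iB(l)] <- xm * bscale[l]
    if (l + 1L < L) M[r, iB(l + 1L)] <- -xm * bscale[l + 1L]
    if (l + 1L == L) rhs[r] <- src * xm
    # continuity of sigma * d(phi)/dx  (common 1/x factor dropped)
    r <- r + 1L
    M[r, iA(l)] <- sh[l] * n * xn
    M[r, iA(l + 1L)] <- -sh[l + 1L] * n * xn
    M[r, iB(l)] <- -sh[l] * (n + 1) * xm * bscale[l]
    if (l + 1L < L) M[r, iB(l + 1L)] <- sh[l + 1L] * (n + 1) * xm * bscale[l + 1L]
    if (l + 1L == L) rhs[r] <- -sh[L] * (n + 1) * src * xm
  }
  z <- solve(M, rhs)
  z[(L + 1L):m] <- z[(L + 1L):m] * bscale
  z
}

#' Surface potential of an interior current dipole (Legendre series)
#'
#' Potential on the outer surface of a concentric multilayer sphere
#' produced by a current dipole inside the innermost compartment. The
#' returned potentials have zero mean over the full sphere by construction
#' (no monopole term).
#'
#' @param model a `sphere_model`
#' @param position dipole position (m), strictly inside the innermost
#'   compartment, eccentricity at most 0.95
#' @param moment dipole moment q*d (A*m)
#' @param surface_points k x 3 matrix of evaluation points on the outer
#'   surface (radius is taken from the model)
#' @param tol series convergence tolerance (relative)
#' @return potentials in volts at the surface points
#' @export
sphere_dipole_potential <- function(model, position, moment, surface_points,
                                    tol = 1e-8) {
  R1 <- model$radii[1L]
  RL <- model$radii[length(model$radii)]
  x <- model$radii / R1
  sig <- model$conductivities
  b <- sqrt(sum(position^2))
  if (b > 0.95 * RL)
    stop("dipole eccentricity exceeds 0.95 of the innermost compartment")
  bp <- b / R1
  if (b > 1e-12 * R1) {
    zhat <- position / b
  } else {
    zhat <- c(0, 0, 1)
    bp <- 0
  }
  mr <- sum(moment * zhat)
  mt_vec <- moment - mr * zhat
  mt <- sqrt(sum(mt_vec^2))
  if (mt > 1e-15 * (sqrt(sum(moment^2)) + 1e-300)) {
    xhat <- mt_vec / mt
  } else {
    xhat <- if (abs(zhat[3L]) < 0.9) {
      v <- crossprod3(zhat, c(0, 0, 1)); v / sqrt(sum(v^2))
    } else {
      v <- crossprod3(zhat, c(1, 0, 0)); v / sqrt(sum(v^2))
    }
    mt <- 0
  }
  yhat <- crossprod3(zhat, xhat)
  pts <- matrix(as.double(surface_points), ncol = 3L)
  rp <- sqrt(rowSums(pts^2))
  u <- pmin(1, pmax(-1, as.numeric(pts %*% zhat) / rp))
  cosaz <- {
    px <- as.numeric(pts %*% xhat); py <- as.numeric(pts %*% yhat)
    az <- atan2(py, px)
    cos(az)
  }
  nmax <- model$n_terms
  leg <- legendre_table(u, nmax)
  sigs <- sig[length(sig)]
  phi <- numeric(nrow(pts))
  scale_max <- 0
  converged <- FALSE
  for (n in seq_len(nmax)) {
    bpow <- if (bp == 0) { if (n == 1L) 1 else 0 } else bp^(n - 1L)
    if (bpow == 0 && n > 1L) { converged <- TRUE; break }
    co <- radial_solve(n, x, sig, src = 1, rhs_outer = 0)
    shat <- co[1L] + (if (length(x) == 1L) 1 else co[length(x) + 1L])
    Grad <- n * mr * bpow / (4 * pi * sigs * R1^2)
    Gtan <- mt * bpow / (4 * pi * sigs * R1^2)
    term <- shat * (Grad * leg$P[, n] + Gtan * leg$P1[, n] * cosaz)
    phi <- phi + term
    tm <- max(abs(term))
    scale_max <- max(scale_max, max(abs(phi)))
    if (n > 10L && tm < tol * max(scale_max, 1e-300)) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("dipole series not converged at n_terms = %d", nmax))
  as.numeric(phi)
}

#' Potential for two point-current surface contacts (Legendre series)
#'
#' Potential produced by current `current` injected at surface point
#' `contact_in` and withdrawn at `contact_out` on a concentric multilayer
#' sphere. Surface evaluation splits off the homogeneous-sphere closed form
#' so the series converges quickly away from the contacts; interior points
#' use the plain shell series.
#'
#' @param model a `sphere_model`
#' @param contact_in,contact_out 3-vectors on the outer surface (m)
#' @param current injected current (A)
#' @param points k x 3 evaluation points (surface or interior)
#' @param tol series tolerance
#' @return potentials in volts
#' @export
sphere_injection_potential <- function(model, contact_in, contact_out,
                                       current, points, tol = 1e-8) {
  R1 <- model$radii[1L]
  x <- model$radii / R1
  sig <- model$conductivities
  L <- length(x)
  ahat <- contact_in / sqrt(sum(contact_in^2))
  bhat <- contact_out / sqrt(sum(contact_out^2))
  pts <- matrix(as.double(points), ncol = 3L)
  r <- sqrt(rowSums(pts^2))
  on_surf <- abs(r - R1) < 1e-6 * R1
  Phi0 <- current / (4 * pi * sig[1L] * R1)
  out <- numeric(nrow(pts))
  nmax <- model$n_terms

  # coefficients per order
  coefs <- vector("list", nmax)
  for (n in seq_len(nmax)) {
    coefs[[n]] <- radial_solve(n, x, sig, src = 0, rhs_outer = 2 * n + 1)
  }

  closed_form <- function(cosg) {
    s <- sqrt(pmax(1e-300, (1 - cosg) / 2))
    1 / s - 2 - log(s * (1 + s))
  }

  if (any(on_surf)) {
    p <- pts[on_surf, , drop = FALSE] / r[on_surf]
    ca <- pmin(1, pmax(-1, as.numeric(p %*% ahat)))
    cb <- pmin(1, pmax(-1, as.numeric(p %*% bhat)))
    base <- closed_form(ca) - closed_form(cb)
    la <- legendre_table(ca, nmax)
    lb <- legendre_table(cb, nmax)
    corr <- numeric(length(ca))
    for (n in seq_len(nmax)) {
      co <- coefs[[n]]
      vsurf <- co[1L] + (if (L == 1L) 0 else co[L + 1L])
      dn <- vsurf - (2 * n + 1) / n
      if (abs(dn) < tol / n && n > 10L) break
      corr <- corr + dn * (la$P[, n] - lb$P[, n])
    }
    out[on_surf] <- Phi0 * (base + corr)
  }
  if (any(!on_surf)) {
    idx <- which(!on_surf)
    p <- pts[idx, , drop = FALSE]
    rr <- r[idx]
    xr <- rr / R1
    shell <- vapply(xr, function(z) {
      w <- which(z >= c(x[-1L], 0))[1L]
      min(w, L)
    }, integer(1))
    ca <- pmin(1, pmax(-1, as.numeric(p %*% ahat) / rr))
    cb <- pmin(1, pmax(-1, as.numeric(p %*% bhat) / rr))
    la <- legendre_table(ca, nmax)
    lb <- legendre_table(cb, nmax)
    acc <- numeric(length(idx))
    mx <- 0
    for (n in seq_len(nmax)) {
      co <- coefs[[n]]
      radf <- numeric(length(idx))
      for (l in unique(shell)) {
        sel <- shell == l
        Bl <- if (l < L) co[L + l] else 0
        radf[sel] <- co[l] * xr[sel]^n + Bl * xr[sel]^(-(n + 1))
      }
      term <- radf * (la$P[, n] - lb$P[, n])
      acc <- acc + term
      mx <- max(mx, max(abs(acc)))
      if (n > 10L && max(abs(term)) < tol * max(mx, 1e-300)) break
    }
    out[idx] <- Phi0 * acc
  }
  as.numeric(out)
}

# Radial solve for a current monopole buried in the OUTERMOST shell at
# normalized radius xb (x2 < xb < 1). Returns c(A_1..A_L, B_1..B_{L-1})
# for the induced part; the primary (xb^n / x^(n+1) outside the source
# radius, x^n / xb^(n+1) inside) is added separately by the caller.
radial_solve_shell1 <- function(n, x, sig, xb) {
  L <- length(x)
  sh <- sig / sig[1L]
  c_out <- xb^n
  c_in <- xb^(-(n + 1))
  if (L == 1L) {
    # outer Neumann: n A1 - (n+1)(B1 + c_out) = 0 with B1 = 0 (regular)
    return(c((n + 1) * c_out / n))
  }
  m <- 2L * L - 1L
  M <- matrix(0, m, m)
  rhs <- numeric(m)
  iA <- function(l) l
  iB <- function(l) L + l
  bscale <- x[2:L]^(n + 1)
  M[1L, iA(1L)] <- n
  M[1L, iB(1L)] <- -(n + 1) * bscale[1L]
  rhs[1L] <- (n + 1) * c_out
  r <- 1L
  for (l in seq_len(L - 1L)) {
    xi <- x[l + 1L]
    xn <- xi^n; xm <- xi^(-(n + 1))
    # continuity (the primary is continuous, so no source term)
    r <- r + 1L
    M[r, iA(l)] <- xn
    M[r, iA(l + 1L)] <- -xn
    M[r, iB(l)] <- xm * bscale[l]
    if (l + 1L < L) M[r, iB(l + 1L)] <- -xm * bscale[l + 1L]
    # flux: the primary's radial derivative enters at every interface
    # with a conductivity jump (interfaces all lie below the source)
    r <- r + 1L
    M[r, iA(l)] <- sh[l] * n * xn
    M[r, iA(l + 1L)] <- -sh[l + 1L] * n * xn
    M[r, iB(l)] <- -sh[l] * (n + 1) * xm * bscale[l]
    if (l + 1L < L) M[r, iB(l + 1L)] <- sh[l + 1L] * (n + 1) * xm * bscale[l + 1L]
    rhs[r] <- -(sh[l] - sh[l + 1L]) * n * c_in * xn
  }
  z <- solve(M, rhs)
  z[(L + 1L):m] <- z[(L + 1L):m] * bscale
  z
}

#' Potential of current monopoles buried in the outermost shell
#'
#' Series solution for point current sources strictly inside the
#' outermost compartment of a concentric multilayer sphere (the continuum
#' counterpart of the contact-current injection model, whose impressed
#' monopoles sit inside the skin). Currents must sum to zero. The overall
#' additive constant is fixed to zero mean over the outer sphere for the
#' n >= 1 part; monopole (n = 0) terms cancel between the balanced
#' sources outside the radii that bracket them, so potential differences
#' and fields are exact everywhere below the innermost source radius and
#' on the outer surface.
#'
#' @param model a `sphere_model`
#' @param positions k x 3 matrix of source positions (outermost shell)
#' @param currents source currents (A), summing to zero
#' @param points evaluation points (interior or surface)
#' @param tol series tolerance
#' @return potentials in volts
#' @export
sphere_buried_monopole_potential <- function(model, positions, currents,
                                             points, tol = 1e-10) {
  R1 <- model$radii[1L]
  x <- model$radii / R1
  sig <- model$conductivities
  L <- length(x)
  positions <- matrix(as.double(positions), ncol = 3L)
  if (abs(sum(currents)) > 1e-12 * sum(abs(currents)))
    stop("currents must sum to zero")
  pts <- matrix(as.double(points), ncol = 3L)
  rr <- sqrt(rowSums(pts^2))
  xr <- rr / R1
  shell <- vapply(xr, function(z) {
    w <- which(z >= c(x[-1L], 0))[1L]
    min(w, L)
  }, integer(1))
  nmax <- model$n_terms
  out <- numeric(nrow(pts))
  for (k in seq_len(nrow(positions))) {
    b <- sqrt(sum(positions[k, ]^2))
    if (b >= R1 || (L > 1L && b <= model$radii[2L]))
      stop("monopole must lie strictly inside the outermost shell")
    xb <- b / R1
    u <- positions[k, ] / b
    cosg <- pmin(1, pmax(-1, as.numeric(pts %*% u) / rr))
    leg <- legendre_table(cosg, nmax)
    Phi0 <- currents[k] / (4 * pi * sig[1L] * R1)
    acc <- numeric(nrow(pts))
    mx <- 0
    for (n in seq_len(nmax)) {
      co <- radial_solve_shell1(n, x, sig, xb)
      radf <- numeric(nrow(pts))
      for (l in unique(shell)) {
        sel <- shell == l
        Bl <- if (l < L && L > 1L) co[L + l] else 0
        radf[sel] <- co[l] * xr[sel]^n + Bl * xr[sel]^(-(n + 1))
      }
      above <- shell == 1L & xr > xb
      below <- shell != 1L | xr <= xb
      radf[above] <- radf[above] + xb^n * xr[above]^(-(n + 1))
      radf[below] <- radf[below] + xr[below]^n * xb^(-(n + 1))
      term <- radf * leg$P[, n]
      acc <- acc + term
      mx <- max(mx, max(abs(acc)))
      if (n > 10L && max(abs(term)) < tol * max(mx, 1e-300)) break
    }
    out <- out + Phi0 * acc
  }
  as.numeric(out)
}

#' Electric field of the buried-monopole solution (finite differences)
#' @inheritParams sphere_buried_monopole_potential
#' @param h finite-difference step (m)
#' @return k x 3 matrix of E vectors (V/m)
#' @export
sphere_buried_monopole_field <- function(model, positions, currents,
                                         points, h = 1e-6) {
  pts <- matrix(as.double(points), ncol = 3L)
  E <- matrix(0, nrow(pts), 3L)
  for (d in 1:3) {
    dp <- pts; dp[, d] <- dp[, d] + h
    dm <- pts; dm[, d] <- dm[, d] - h
    fp <- sphere_buried_monopole_potential(model, positions, currents, dp)
    fm <- sphere_buried_monopole_potential(model, positions, currents, dm)
    E[, d] <- -(fp - fm) / (2 * h)
  }
  E
}

#' Electric field of the two-contact injection solution
#'
#' Central finite differences of [sphere_injection_potential()] at interior
#' points; used for reciprocity closure checks.
#'
#' @inheritParams sphere_injection_potential
#' @param h finite-difference step (m)
#' @return k x 3 matrix of E vectors (V/m)
#' @export
sphere_injection_field <- function(model, contact_in, contact_out, current,
                                   points, h = 1e-6) {
  pts <- matrix(as.double(points), ncol = 3L)
  E <- matrix(0, nrow(pts), 3L)
  for (d in 1:3) {
    dp <- pts; dp[, d] <- dp[, d] + h
    dm <- pts; dm[, d] <- dm[, d] - h
    fp <- sphere_injection_potential(model, contact_in, contact_out, current, dp)
    fm <- sphere_injection_potential(model, contact_in, contact_out, current, dm)
    E[, d] <- -(fp - fm) / (2 * h)
  }
  E
}

#' Relative difference measure between two potential vectors
#'
#' RDM = || a/||a|| - b/||b|| ||, the standard shape metric for forward
#' solutions (0 = identical topographies).
#' @param a,b numeric vectors over the same sampling points
#' @return non-negative scalar
#' @export
rdm <- function(a, b) {
  sqrt(sum((a / sqrt(sum(a^2)) - b / sqrt(sum(b^2)))^2))
}

#' Magnitude ratio between two potential vectors
#'
#' MAG = ||a|| / ||b|| (1 = equal strength).
#' @param a,b numeric vectors over the same sampling points
#' @return positive scalar
#' @export
mag <- function(a, b) sqrt(sum(a^2) / sum(b^2))
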