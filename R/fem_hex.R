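# 8-node hexahedral element machinery, vectorized over elements.
# 3x3 tensor fields are stored as E x 9 matrices in column-major entry
# order: column idx(i, j) = i + 3 * (j - 1).

hex_gauss_points <- function() {
  g <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  list(points = pts, weights = rep(1, 8))
}

# corner natural coordinates in standard hex8 ordering:
# bottom face (zeta = -1) counterclockwise, then top face
hex_corners <- function() {
  rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
        c(-1, -1,  1), c(1, -1,  1), c(1, 1,  1), c(-1, 1,  1))
}

hex_shape <- function(xi) {
  cr <- hex_corners()
  0.125 * (1 + xi[1] * cr[, 1]) * (1 + xi[2] * cr[, 2]) * (1 + xi[3] * cr[, 3])
}

# 8 x 3 matrix of dN_a / dxi_j at natural point xi
hex_dshape <- function(xi) {
  cr <- hex_corners()
  cbind(
    0.125 * cr[, 1] * (1 + xi[2] * cr[, 2]) * (1 + xi[3] * cr[, 3]),
    0.125 * cr[, 2] * (1 + xi[1] * cr[, 1]) * (1 + xi[3] * cr[, 3]),
    0.125 * cr[, 3] * (1 + xi[1] * cr[, 1]) * (1 + xi[2] * cr[, 2]))
}

# ---- vectorized 3x3 helpers on E x 9 matrices -------------------------------

m33_idx <- function(i, j) i + 3L * (j - 1L)

m33_identity <- function(n) {
  M <- matrix(0, n, 9)
  M[, c(1, 5, 9)] <- 1
  M
}

m33_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 4] * (A[, 2] * A[, 9] - A[, 3] * A[, 8]) +
  A[, 7] * (A[, 2] * A[, 6] - A[, 3] * A[, 5])
}

m33_inv <- function(A, det = NULL) {
  if (is.null(det)) det <- m33_det(A)
  B <- matrix(0, nrow(A), 9)
  B[, 1] <-  (A[, 5] * A[, 9] - A[, 6] * A[, 8])
  B[, 2] <- -(A[, 2] * A[, 9] - A[, 3] * A[, 8])
  B[, 3] <-  (A[, 2] * A[, 6] - A[, 3] * A[, 5])
  B[, 4] <- -(A[, 4] * A[, 9] - A[, 6] * A[, 7])
  B[, 5] <-  (A[, 1] * A[, 9] - A[, 3] * A[, 7])
  B[, 6] <- -(A[, 1] * A[, 6] - A[, 3] * A[, 4])
  B[, 7] <-  (A[, 4] * A[, 8] - A[, 5] * A[, 7])
  B[, 8] <- -(A[, 1] * A[, 8] - A[, 2] * A[, 7])
  B[, 9] <-  (A[, 1] * A[, 5] - A[, 2] * A[, 4])
  B / det
}

m33_mult <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + A[, m33_idx(i, k)] * B[, m33_idx(k, j)]
    C[, m33_idx(i, j)] <- acc
  }
  C
}

# A %*% t(A)
m33_aat <- function(A) {
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in i:3) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + A[, m33_idx(i, k)] * A[, m33_idx(j, k)]
    C[, m33_idx(i, j)] <- acc
    if (i != j) C[, m33_idx(j, i)] <- acc
  }
  C
}

m33_trace <- function(A) A[, 1] + A[, 5] + A[, 9]

# matrix-vector: (E x 9) x (E x 3) -> E x 3
m33_vec <- function(A, v) {
  cbind(A[, 1] * v[, 1] + A[, 4] * v[, 2] + A[, 7] * v[, 3],
        A[, 2] * v[, 1] + A[, 5] * v[, 2] + A[, 8] * v[, 3],
        A[, 3] * v[, 1] + A[, 6] * v[, 2] + A[, 9] * v[, 3])
}

# outer product v v^T as E x 9
m33_outer <- function(v) {
  C <- matrix(0, nrow(v), 9)
  for (i in 1:3) for (j in 1:3)
    C[, m33_idx(i, j)] <- v[, i] * v[, j]
  C
}

m33_dev <- function(A) {
  tr3 <- m33_trace(A) / 3
  A[, c(1, 5, 9)] <- A[, c(1, 5, 9)] - tr3
  A
}

# ---- reference-element precomputation ---------------------------------------

# For element coordinate array Xe (E x 8 x 3) and a natural point xi,
# returns dNdX (E x 8 x 3) and detJ (length E) of the reference mapping.
hex_ref_derivatives <- function(Xe, xi) {
  E <- dim(Xe)[1]
  dN <- hex_dshape(xi)                       # 8 x 3
  Jm <- matrix(0, E, 9)                      # dX_i/dxi_j
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (a in 1:8) acc <- acc + Xe[, a, i] * dN[a, j]
    Jm[, m33_idx(i, j)] <- acc
  }
  detJ <- m33_det(Jm)
  Jinv <- m33_inv(Jm, detJ)                  # dxi_j/dX_i = Jinv[j, i]
  dNdX <- array(0, c(E, 8, 3))
  for (a in 1:8) for (i in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + dN[a, j] * Jinv[, m33_idx(j, i)]
    dNdX[, a, i] <- acc
  }
  list(dNdX = dNdX, detJ = detJ)
}

# gather element-wise node data: (N x 3, E x 8) -> E x 8 x 3
gather_elem <- function(nodal, conn) {
  E <- nrow(conn)
  out <- array(0, c(E, 8, 3))
  for (a in 1:8) out[, a, ] <- nodal[conn[, a], , drop = FALSE]
  out
}

# Precompute reference derivative data for a connectivity block.
# Returns per-quadrature-point dNdX / detJ plus the element-centroid data
# used by the mean-dilatation (centroid J) treatment of the volumetric term.
hex_precompute <- function(nodes, conn) {
  Xe <- gather_elem(nodes, conn)
  gq <- hex_gauss_points()
  qp <- vector("list", 8)
  for (q in 1:8) qp[[q]] <- hex_ref_derivatives(Xe, gq$points[q, ])
  ctr <- hex_ref_derivatives(Xe, c(0, 0, 0))
  if (any(ctr$detJ <= 0) || any(vapply(qp, function(z) any(z$detJ <= 0), TRUE)))
    stop("non-positive reference Jacobian in hexahedral block", call. = FALSE)
  list(Xe = Xe, qp = qp, ctr = ctr, weights = gq$weights, nelem = nrow(conn))
}

# Deformation gradient field F = I + grad u at one precomputed point.
hex_def_gradient <- function(pre_pt, Ue) {
  E <- dim(Ue)[1]
  F <- m33_identity(E)
  dNdX <- pre_pt$dNdX
  for (i in 1:3) for (j in 1:3) {
    acc <- 0
    for (a in 1:8) acc <- acc + Ue[, a, i] * dNdX[, a, j]
    F[, m33_idx(i, j)] <- F[, m33_idx(i, j)] + acc
  }
  F
}

# ---- vectorized constitutive evaluation -------------------------------------

# Component Cauchy stresses (per unit K, mu, k1) for all elements at one
# quadrature point. J0 is the element-centroid Jacobian determinant used in
# the volumetric pressure (mean-dilatation treatment); the deviatoric terms
# use the actual local kinematics. fiber: list(a1, a2: E x 3; kappa: E).
# Returns list(sK, smu, sk1, J) of E x 9 stress components and local J.
hex_stress_components <- function(F, J0, fiber, k2, tension_only = TRUE,
                                  want_k1 = TRUE) {
  E <- nrow(F)
  J <- m33_det(F)
  if (any(J <= 0)) {
    bad <- which(J <= 0)
    stop(sprintf("inverted element kinematics at %d element(s): %s",
                 length(bad), paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  Jm23 <- J^(-2 / 3)
  btilde <- m33_aat(F) * Jm23
  I1t <- m33_trace(btilde)

  sK <- matrix(0, E, 9)
  sK[, c(1, 5, 9)] <- 0.5 * (J0 - 1 / J0)

  smu <- m33_dev(btilde) / J

  sk1 <- NULL
  if (want_k1 && !is.null(fiber)) {
    sk1 <- matrix(0, E, 9)
    Jm13 <- J^(-1 / 3)
    Fb <- F * Jm13
    kap <- fiber$kappa
    for (a in list(fiber$a1, fiber$a2)) {
      at <- m33_vec(Fb, a)
      I4t <- rowSums(at^2)
      d <- kap * I1t + (1 - 3 * kap) * I4t - 1
      act <- if (tension_only) as.numeric(d > 0) else 1
      x <- k2 * d^2
      w <- if (k2 < .k2_branch_tol) d * (1 + x + x^2 / 2) else d * exp(x)
      struc <- btilde * kap + m33_outer(at) * (1 - 3 * kap)
      sk1 <- sk1 + m33_dev(struc) * (2 * w * act / J)
    }
  }
  list(sK = sK, smu = smu, sk1 = sk1, J = J)
}

# Internal nodal force array(s) for one element block.
# If params is NULL, returns list(fK, fmu, fk1) of E x 8 x 3 component
# forces (per unit parameter); otherwise a single combined E x 8 x 3 array.
hex_block_forces <- function(pre, Ue, fiber, k2, params = NULL,
                             tension_only = TRUE) {
  E <- pre$nelem
  combined <- !is.null(params)
  want_k1 <- if (combined) params$k1 != 0 else TRUE
  Fc <- hex_def_gradient(pre$ctr, Ue)
  J0 <- m33_det(Fc)
  if (any(J0 <= 0))
    stop(sprintf("inverted element(s): %s",
                 paste(utils::head(which(J0 <= 0), 5), collapse = ", ")),
         call. = FALSE)
  if (combined) {
    fout <- array(0, c(E, 8, 3))
  } else {
    fK <- array(0, c(E, 8, 3)); fmu <- array(0, c(E, 8, 3))
    fk1 <- array(0, c(E, 8, 3))
  }
  for (q in 1:8) {
    pt <- pre$qp[[q]]
    F <- hex_def_gradient(pt, Ue)
    fib_q <- if (is.null(fiber)) NULL else fiber[[q]]
    sc <- hex_stress_components(F, J0, fib_q, k2, tension_only, want_k1)
    Finv <- m33_inv(F, sc$J)
    # spatial shape derivatives dN/dx = dN/dX F^{-1}
    dNdx <- array(0, c(E, 8, 3))
    for (a in 1:8) for (i in 1:3) {
      acc <- 0
      for (j in 1:3) acc <- acc + pt$dNdX[, a, j] * Finv[, m33_idx(j, i)]
      dNdx[, a, i] <- acc
    }
    dv <- pre$weights[q] * pt$detJ * sc$J
    if (combined) {
      sig <- sc$sK * params$K + sc$smu * params$mu
      if (want_k1) sig <- sig + sc$sk1 * params$k1
      sig <- sig * dv
      for (a in 1:8) for (i in 1:3) {
        acc <- 0
        for (j in 1:3) acc <- acc + sig[, m33_idx(i, j)] * dNdx[, a, j]
        fout[, a, i] <- fout[, a, i] + acc
      }
    } else {
      sK <- sc$sK * dv; smu <- sc$smu * dv; sk1 <- sc$sk1 * dv
      for (a in 1:8) for (i in 1:3) {
        aK <- 0; amu <- 0; ak1 <- 0
        for (j in 1:3) {
          dn <- dNdx[, a, j]
          aK  <- aK  + sK[, m33_idx(i, j)] * dn
          amu <- amu + smu[, m33_idx(i, j)] * dn
          ak1 <- ak1 + sk1[, m33_idx(i, j)] * dn
        }
        fK[, a, i]  <- fK[, a, i] + aK
        fmu[, a, i] <- fmu[, a, i] + amu
        fk1[, a, i] <- fk1[, a, i] + ak1
      }
    }
  }
  if (combined) fout else list(fK = fK, fmu = fmu, fk1 = fk1)
}
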