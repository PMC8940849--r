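# Quad surface facets: follower pressure loads and cavity volume.
# Facets are stored as F x 4 node-id matrices ordered so that the bilinear
# surface normal t_xi x t_eta points OUT of the solid.

quad_gauss <- function() {
  g <- 1 / sqrt(3)
  list(points = as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g))),
       weights = rep(1, 4))
}

quad_shape <- function(xi) {
  0.25 * c((1 - xi[1]) * (1 - xi[2]), (1 + xi[1]) * (1 - xi[2]),
           (1 + xi[1]) * (1 + xi[2]), (1 - xi[1]) * (1 + xi[2]))
}

quad_dshape <- function(xi) {
  cbind(0.25 * c(-(1 - xi[2]), (1 - xi[2]), (1 + xi[2]), -(1 + xi[2])),
        0.25 * c(-(1 - xi[1]), -(1 + xi[1]), (1 + xi[1]), (1 - xi[1])))
}

# gather facet coordinates: F x 4 x 3
gather_facet <- function(nodal, facets) {
  out <- array(0, c(nrow(facets), 4, 3))
  for (a in 1:4) out[, a, ] <- nodal[facets[, a], , drop = FALSE]
  out
}

vec_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Nodal forces from a pressure acting on the deformed facets:
# t = -p n_out (pressure pushes onto the solid). `pressure` is either a
# scalar or a function of the F x 3 quadrature-point positions returning a
# vector of length F. Returns an F x 4 x 3 local force array.
facet_pressure_local <- function(xf, pressure) {
  F <- dim(xf)[1]
  gq <- quad_gauss()
  fl <- array(0, c(F, 4, 3))
  for (q in 1:4) {
    xi <- gq$points[q, ]
    N <- quad_shape(xi); dN <- quad_dshape(xi)
    xq <- matrix(0, F, 3); t1 <- matrix(0, F, 3); t2 <- matrix(0, F, 3)
    for (a in 1:4) {
      xa <- xf[, a, , drop = FALSE]; dim(xa) <- c(F, 3)
      xq <- xq + N[a] * xa
      t1 <- t1 + dN[a, 1] * xa
      t2 <- t2 + dN[a, 2] * xa
    }
    n_dA <- vec_cross(t1, t2)                 # n_out * dA/dxi deta
    zero <- rowSums(n_dA^2) == 0
    if (any(zero))
      stop("degenerate (zero-area) facet encountered", call. = FALSE)
    p <- if (is.function(pressure)) pressure(xq) else rep(pressure, F)
    w <- gq$weights[q]
    for (a in 1:4) for (i in 1:3)
      fl[, a, i] <- fl[, a, i] - w * N[a] * p * n_dA[, i]
  }
  fl
}

# scatter an F x 4 x 3 facet force array into a global DOF vector
# (repeated node ids across facets must accumulate, hence rowsum)
scatter_facet_safe <- function(fl, facets, ndof) {
  idx <- integer(0); val <- numeric(0)
  for (a in 1:4) for (i in 1:3) {
    idx <- c(idx, 3L * (facets[, a] - 1L) + i)
    val <- c(val, fl[, a, i])
  }
  as.numeric(unname(tapply2_sum(idx, val, ndof)))
}

tapply2_sum <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, group = idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Nodal follower-pressure forces on a facet set
#'
#' Integrates `t = -p n` over the deformed facets (2x2 Gauss), where `n` is
#' the outward surface normal of the solid and `p` the pressure magnitude,
#' and scatters into a global force vector of length `3 * n_nodes`.
#'
#' @param nodes Reference node coordinates (N x 3, mm).
#' @param facets F x 4 facet connectivity, outward oriented.
#' @param U Nodal displacement matrix (N x 3, mm).
#' @param pressure Scalar (MPa) or function of quadrature-point positions
#'   (F x 3 matrix) returning pressures.
#' @return Global force vector (length 3N, in N).
#' @export
facet_pressure_forces <- function(nodes, facets, U, pressure) {
  xf <- gather_facet(nodes + U, facets)
  fl <- facet_pressure_local(xf, pressure)
  scatter_facet_safe(fl, facets, 3L * nrow(nodes))
}

# Signed volume contribution of a facet set, via the divergence theorem:
# -(1/3) sum x . n_out dA  (n_out = out of solid = into the cavity, so the
# result is the cavity-side volume contribution of this boundary patch).
facet_cavity_volume <- function(nodes, facets, U) {
  xf <- gather_facet(nodes + U, facets)
  F <- dim(xf)[1]
  gq <- quad_gauss()
  V <- 0
  for (q in 1:4) {
    xi <- gq$points[q, ]
    N <- quad_shape(xi); dN <- quad_dshape(xi)
    xq <- matrix(0, F, 3); t1 <- matrix(0, F, 3); t2 <- matrix(0, F, 3)
    for (a in 1:4) {
      xa <- xf[, a, , drop = FALSE]; dim(xa) <- c(F, 3)
      xq <- xq + N[a] * xa
      t1 <- t1 + dN[a, 1] * xa
      t2 <- t2 + dN[a, 2] * xa
    }
    n_dA <- vec_cross(t1, t2)
    V <- V - gq$weights[q] / 3 * sum(rowSums(xq * n_dA))
  }
  V
}

# Exact gradient of the discrete cavity-volume integral with respect to
# the nodal coordinates of the wetted facets. For interior surface nodes
# this coincides with the unit-pressure force; at open-surface boundary
# nodes (symmetry edges) it additionally carries the line-term part of the
# variation, which matters for the pressure-volume coupling tangent.
facet_volume_gradient <- function(nodes, facets, U) {
  xf <- gather_facet(nodes + U, facets)
  F <- dim(xf)[1]
  gq <- quad_gauss()
  gl <- array(0, c(F, 4, 3))
  for (q in 1:4) {
    xi <- gq$points[q, ]
    N <- quad_shape(xi); dN <- quad_dshape(xi)
    xq <- matrix(0, F, 3); t1 <- matrix(0, F, 3); t2 <- matrix(0, F, 3)
    for (a in 1:4) {
      xa <- xf[, a, , drop = FALSE]; dim(xa) <- c(F, 3)
      xq <- xq + N[a] * xa
      t1 <- t1 + dN[a, 1] * xa
      t2 <- t2 + dN[a, 2] * xa
    }
    n_dA <- vec_cross(t1, t2)
    t2xx <- vec_cross(t2, xq)
    xxt1 <- vec_cross(xq, t1)
    w <- gq$weights[q] / 3
    for (a in 1:4) for (i in 1:3)
      gl[, a, i] <- gl[, a, i] -
        w * (N[a] * n_dA[, i] + dN[a, 1] * t2xx[, i] + dN[a, 2] * xxt1[, i])
  }
  scatter_facet_safe(gl, facets, 3L * nrow(nodes))
}
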