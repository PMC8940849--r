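# Model container and global assembly. A model bundles node coordinates,
# element groups (each with connectivity, material, optional fiber field and
# precomputed reference derivatives), boundary conditions, facet sets and
# the fluid cavity. Displacements are N x 3 matrices; the flat DOF order is
# dof = 3 * (node - 1) + i.

flatten_disp <- function(U) as.vector(t(U))
unflatten_disp <- function(u) matrix(u, ncol = 3, byrow = TRUE)

model_ndof <- function(model) 3L * nrow(model$nodes)

# scatter an E x 8 x 3 element force array into a global vector
scatter_elem <- function(fe, conn, ndof) {
  E <- nrow(conn)
  idx <- integer(0); val <- numeric(0)
  for (a in 1:8) for (i in 1:3) {
    idx <- c(idx, 3L * (conn[, a] - 1L) + i)
    val <- c(val, fe[, a, i])
  }
  tapply2_sum(idx, val, ndof)
}

# refresh reference-derivative precomputation (after coordinate updates)
model_precompute <- function(model) {
  for (g in names(model$groups)) {
    model$groups[[g]]$pre <- hex_precompute(model$nodes, model$groups[[g]]$conn)
  }
  model
}

# replace reference coordinates (stress-free iteration) and refresh all
# geometry-derived data (reference derivatives, fiber field)
model_set_coords <- function(model, nodes) {
  model$nodes <- nodes
  model <- model_precompute(model)
  if (!is.null(model$kappa_profile))
    model <- build_fiber_field(model, model$kappa_profile)
  model
}

#' Assemble the global internal force vector
#'
#' Standard scatter-add of the element-wise internal force columns
#' `f_e = int B^T sigma dv` over all element groups, evaluated in the
#' current configuration (spatial shape derivatives, Cauchy stress, current
#' element volume). For the corneal group the result is exactly linear in
#' `(K, mu, k1)` at fixed displacements and `k2`.
#'
#' @param model An eye model, see [build_eye_mesh()].
#' @param U Nodal displacement matrix (N x 3, mm).
#' @return Global internal force vector (length 3N, in N).
#' @export
assemble_internal_forces <- function(model, U) {
  ndof <- model_ndof(model)
  f <- numeric(ndof)
  for (g in model$groups) {
    Ue <- gather_elem(U, g$conn)
    mat <- g$material
    fe <- hex_block_forces(g$pre, Ue, g$fiber, mat$k2, params = mat,
                           tension_only = isTRUE(mat$tension_only))
    f <- f + scatter_elem(fe, g$conn, ndof)
  }
  f
}

# Internal force of a single group with its own material (used to fold the
# known non-corneal components into the effective external force).
assemble_group_forces <- function(model, U, group) {
  g <- model$groups[[group]]
  Ue <- gather_elem(U, g$conn)
  mat <- g$material
  fe <- hex_block_forces(g$pre, Ue, g$fiber, mat$k2, params = mat,
                         tension_only = isTRUE(mat$tension_only))
  scatter_elem(fe, g$conn, model_ndof(model))
}

# Parameter-sensitivity force components of one group: global vectors
# (c_K, c_mu, c_k1) with the corresponding parameter set to one and the
# others to zero, i.e. f_int(U) = K c_K + mu c_mu + k1 c_k1 for the group.
assemble_force_components <- function(model, U, group = "cornea", k2 = NULL,
                                      tension_only = NULL) {
  g <- model$groups[[group]]
  mat <- g$material
  if (is.null(k2)) k2 <- mat$k2
  if (is.null(tension_only)) tension_only <- isTRUE(mat$tension_only)
  Ue <- gather_elem(U, g$conn)
  comp <- hex_block_forces(g$pre, Ue, g$fiber, k2, params = NULL,
                           tension_only = tension_only)
  ndof <- model_ndof(model)
  list(c_K = scatter_elem(comp$fK, g$conn, ndof),
       c_mu = scatter_elem(comp$fmu, g$conn, ndof),
       c_k1 = scatter_elem(comp$fk1, g$conn, ndof))
}

#' Internal force vector of a single hexahedral element
#'
#' Convenience wrapper around the vectorized element kernel for one
#' element; mainly useful for verification against closed-form solutions.
#'
#' @param X 8 x 3 reference node coordinates (mm).
#' @param Ue 8 x 3 nodal displacements (mm).
#' @param params [material_parameters()].
#' @param fiber A [fiber_point()] applied at all quadrature points, or NULL
#'   for fiber-free material.
#' @return 8 x 3 nodal force array (N), rows in element node order.
#' @export
element_internal_force <- function(X, Ue, params, fiber = NULL) {
  conn <- matrix(1:8, 1, 8)
  pre <- hex_precompute(as.matrix(X), conn)
  fib <- NULL
  if (!is.null(fiber)) {
    one <- list(a1 = matrix(fiber$a1, 1, 3), a2 = matrix(fiber$a2, 1, 3),
                kappa = fiber$kappa)
    fib <- rep(list(one), 8)
  }
  Uarr <- array(0, c(1, 8, 3)); Uarr[1, , ] <- as.matrix(Ue)
  fe <- hex_block_forces(pre, Uarr, fib, params$k2, params = params,
                         tension_only = isTRUE(params$tension_only))
  matrix(fe[1, , ], 8, 3)
}

# ---- finite-difference tangents --------------------------------------------

# element-level forward-difference stiffness of all groups, assembled sparse
assemble_tangent <- function(model, U, h = 1e-6) {
  ndof <- model_ndof(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (g in model$groups) {
    conn <- g$conn; E <- nrow(conn)
    mat <- g$material
    Ue <- gather_elem(U, conn)
    f0 <- hex_block_forces(g$pre, Ue, g$fiber, mat$k2, params = mat,
                           tension_only = isTRUE(mat$tension_only))
    f0m <- elem_force_as_matrix(f0)
    Ke <- array(0, c(E, 24, 24))
    for (a in 1:8) for (i in 1:3) {
      ld <- (a - 1L) * 3L + i
      Up <- Ue; Up[, a, i] <- Up[, a, i] + h
      fp <- hex_block_forces(g$pre, Up, g$fiber, mat$k2, params = mat,
                             tension_only = isTRUE(mat$tension_only))
      Ke[, , ld] <- (elem_force_as_matrix(fp) - f0m) / h
    }
    G <- matrix(0L, E, 24)
    for (a in 1:8) for (i in 1:3)
      G[, (a - 1L) * 3L + i] <- 3L * (conn[, a] - 1L) + i
    ii <- c(ii, as.vector(G[, rep(1:24, times = 24)]))
    jj <- c(jj, as.vector(G[, rep(1:24, each = 24)]))
    xx <- c(xx, as.vector(Ke))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

# Caution on index order: array E x 24 x 24 flattens with element fastest,
# then row ld, then column ld, matching rep(times)/rep(each) above; this is
# checked against a dense reference in the test suite.

# forward-difference tangent of a facet pressure load (follower stiffness)
facet_tangent_fd <- function(nodes, facets, U, pressure, h = 1e-6) {
  Fn <- nrow(facets)
  ndof <- 3L * nrow(nodes)
  xf <- gather_facet(nodes + U, facets)
  f0 <- facet_force_as_matrix(facet_pressure_local(xf, pressure))
  Kf <- array(0, c(Fn, 12, 12))
  for (a in 1:4) for (i in 1:3) {
    ld <- (a - 1L) * 3L + i
    xp <- xf; xp[, a, i] <- xp[, a, i] + h
    fp <- facet_force_as_matrix(facet_pressure_local(xp, pressure))
    Kf[, , ld] <- (fp - f0) / h
  }
  G <- matrix(0L, Fn, 12)
  for (a in 1:4) for (i in 1:3)
    G[, (a - 1L) * 3L + i] <- 3L * (facets[, a] - 1L) + i
  Matrix::sparseMatrix(i = as.vector(G[, rep(1:12, times = 12)]),
                       j = as.vector(G[, rep(1:12, each = 12)]),
                       x = as.vector(Kf), dims = c(ndof, ndof))
}

# explicit (E x 8 x 3) -> (E x 24) conversion in local-DOF order
# ld = (a - 1) * 3 + i (array flattening would interleave differently)
elem_force_as_matrix <- function(fe) {
  E <- dim(fe)[1]
  out <- matrix(0, E, 24)
  for (a in 1:8) for (i in 1:3)
    out[, (a - 1L) * 3L + i] <- fe[, a, i]
  out
}

facet_force_as_matrix <- function(fl) {
  Fn <- dim(fl)[1]
  out <- matrix(0, Fn, 12)
  for (a in 1:4) for (i in 1:3)
    out[, (a - 1L) * 3L + i] <- fl[, a, i]
  out
}
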