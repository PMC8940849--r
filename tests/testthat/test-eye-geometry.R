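# Mesh generation, fiber field and the stress-free geometry iteration.

test_that("generated meshes have positive Jacobians and exact apex thickness", {
  for (p in list(tiny_params(), small_params(),
                 small_params(cct = 0.5, peripheral_thickness = 0.8))) {
    m <- build_eye_mesh(p)
    # hex_precompute rejects non-positive Jacobians, so construction
    # succeeding is the check; verify the determinants explicitly too
    for (g in m$groups)
      for (q in 1:8) expect_true(all(g$pre$qp[[q]]$detJ > 0))
    # apex anterior-posterior distance equals the central corneal thickness
    apex_ant <- m$nodes[m$node_sets$apex_anterior, ]
    apex_post <- m$nodes[1, ]   # plan node 1, layer 0
    expect_equal(sqrt(sum((apex_ant - apex_post)^2)), p$cct,
                 tolerance = 1e-6 / p$cct)
  }
  expect_error(eye_geometry_params(limbus_start = 6, limbus_width = 2,
                                   Rr = 7.2), "rim")
  expect_error(eye_geometry_params(include_sclera = TRUE), "not implemented")
})

test_that("boundary conditions implement symmetry planes and the rim clamp", {
  m <- tiny_model()
  nodes <- m$nodes
  # all rim nodes fully fixed
  for (nn in m$node_sets$rim)
    expect_true(all(3L * (nn - 1L) + 1:3 %in% m$bc$fixed_dofs))
  # x = 0 plane: u_x fixed; y = 0 plane: u_y fixed
  expect_true(all(abs(nodes[m$node_sets$sym_x, 1]) < 1e-9))
  expect_true(all(abs(nodes[m$node_sets$sym_y, 2]) < 1e-9))
  expect_true(all(3L * (m$node_sets$sym_x - 1L) + 1L %in% m$bc$fixed_dofs))
  expect_true(all(3L * (m$node_sets$sym_y - 1L) + 2L %in% m$bc$fixed_dofs))
})

test_that("fiber field is tangent, orthogonal near the apex, with the configured dispersion", {
  m <- build_eye_mesh(small_params(),
                      kappa_profile = function(r) rep(0.27, length(r)))
  fib <- m$groups$cornea$fiber
  pre <- m$groups$cornea$pre
  gq <- egmeye:::hex_gauss_points()
  for (q in c(1, 8)) {
    f <- fib[[q]]
    expect_true(all(abs(f$kappa - 0.27) < 1e-14))
    # unit length
    expect_true(all(abs(rowSums(f$a1^2) - 1) < 1e-12))
    expect_true(all(abs(rowSums(f$a2^2) - 1) < 1e-12))
    # zero surface-normal (thickness-direction) component by construction
    N <- egmeye:::hex_shape(gq$points[q, ])
    Xq <- matrix(0, pre$nelem, 3)
    for (a in 1:8) Xq <- Xq + N[a] * pre$Xe[, a, ]
    nrm <- egmeye:::anterior_normal(Xq[, 1], Xq[, 2], m$params)
    expect_lt(max(abs(rowSums(f$a1 * nrm))), 1e-8)
    expect_lt(max(abs(rowSums(f$a2 * nrm))), 1e-8)
    # near the apex the families are orthogonal (x/y axes projected);
    # take the innermost quadrature points of the mesh
    r <- sqrt(Xq[, 1]^2 + Xq[, 2]^2)
    near <- rank(r, ties.method = "first") <= 4
    expect_lt(max(abs(rowSums(f$a1[near, , drop = FALSE] *
                                f$a2[near, , drop = FALSE]))), 0.05)
  }
  expect_error(build_fiber_field(m, function(r) rep(0.5, length(r))),
               "kappa")
})

test_that("stress-free iteration converges and reloading reproduces the target", {
  m <- build_eye_mesh(small_params())
  sf <- stress_free_geometry(m)
  expect_lte(utils::tail(sf$max_dist, 1), 2e-3)
  # reload the converged stress-free mesh: the pressurized configuration
  # must match the in-vivo target within the same 2 um bound
  reload <- solve_forward(sf$model, lapply(c(0.5, 1), function(s)
    list(pulse = NULL, cavity = "fixed",
         p_fix = s * mmHg_to_MPa(m$params$iop_mmHg))))
  d <- sf$model$nodes + reload$U - sf$target
  expect_lte(max(sqrt(rowSums(d^2))), 2e-3)
  # prestressed cavity pressure equals the prescribed IOP
  expect_equal(cavity_state(sf$model, sf$U_pre)$pressure,
               mmHg_to_MPa(m$params$iop_mmHg), tolerance = 1e-9)
})

test_that("zero IOP leaves the geometry untouched", {
  m <- build_eye_mesh(tiny_params(iop_mmHg = 0))
  sf <- stress_free_geometry(m, iop_mmHg = 0)
  expect_identical(sf$model$nodes, m$nodes)
  expect_equal(max(abs(sf$U_pre)), 0)
  expect_equal(sf$iterations, 0L)
})

test_that("mesh refinement changes the inflated apex within the discretization bracket", {
  apex_u <- function(n, nl) {
    m <- build_eye_mesh(eye_geometry_params(n_planform = n, n_layers = nl,
                                            n_limbus = max(1L, n %/% 4L)))
    sol <- solve_forward(m, lapply(c(0.5, 1), function(s)
      list(pulse = NULL, cavity = "fixed",
           p_fix = s * mmHg_to_MPa(17.5))))
    sol$U[m$node_sets$apex_anterior, 3]
  }
  u_coarse <- apex_u(4, 1)
  u_fine <- apex_u(8, 2)
  expect_lt(abs(u_fine - u_coarse) / abs(u_fine), 0.10)
})
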