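# Constitutive model: energy, stress, linear-parameter decomposition.

test_that("modified invariant blends matrix and fiber invariants", {
  expect_equal(modified_invariant(3.6, 1.2, 1 / 3), 1.2)
  expect_equal(modified_invariant(3.6, 1.2, 0), 1.2)
  expect_equal(modified_invariant(3.3, 1.2, 0.1), 1.17)
  expect_error(modified_invariant(3, 1, -0.01), "kappa")
  expect_error(modified_invariant(3, 1, 0.34), "kappa")
})

test_that("strain energy vanishes at the reference and matches closed forms", {
  fib <- fiber_point(kappa = 0.1)
  healthy <- material_parameters(10, 0.275, 0.04, 200)
  expect_equal(strain_energy(diag(3), healthy, fib), 0)

  # pure volumetric response at J = 1.1
  vol_only <- material_parameters(10, 0, 0, 200)
  Fv <- diag(3) * 1.1^(1 / 3)
  expect_equal(strain_energy(Fv, vol_only, fib),
               2.5 * (0.21 - 2 * log(1.1)), tolerance = 1e-12)

  # single-family fiber response at I4star = 1.05 (uniaxial isochoric
  # stretch along family 1 with kappa = 0; the transverse family is then
  # in compression and carries the same quadratic-exponential law)
  lam <- sqrt(1.05)
  Ff <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  fib0 <- fiber_point(kappa = 0)
  fib_only <- material_parameters(0, 0, 0.04, 200, tension_only = TRUE)
  expect_equal(strain_energy(Ff, fib_only, fib0),
               0.04 / 400 * (exp(0.5) - 1), tolerance = 1e-10)
})

test_that("small-k2 branch is the quadratic limit and continuous", {
  lam <- sqrt(1.04)
  Ff <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  fib0 <- fiber_point(kappa = 0)
  d <- 0.04
  psi0 <- strain_energy(Ff, material_parameters(0, 0, 1, 0,
                                                tension_only = TRUE), fib0)
  expect_equal(psi0, d^2 / 2 * (1 + 0 + 0), tolerance = 1e-10)
  # continuity across the branch switch at k2 = 1e-6
  below <- strain_energy(Ff, material_parameters(0, 0, 1, 0.99e-6,
                                                 tension_only = TRUE), fib0)
  above <- strain_energy(Ff, material_parameters(0, 0, 1, 1.01e-6,
                                                 tension_only = TRUE), fib0)
  expect_equal(below, above, tolerance = 1e-9)
  expect_error(material_parameters(0, 0, 1, -1), "k2")
})

test_that("Cauchy stress matches closed forms", {
  fib <- fiber_point(kappa = 0.1)
  healthy <- material_parameters(10, 0.275, 0.04, 200)
  expect_equal(cauchy_stress(diag(3), healthy, fib), matrix(0, 3, 3))

  # neo-Hookean deviator under isochoric uniaxial stretch
  lam <- 1.08
  Fu <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  nh <- material_parameters(0, 0.275, 0, 200)
  sig <- cauchy_stress(Fu, nh, fib)
  expect_equal(sig[1, 1] - sig[2, 2], 0.275 * (lam^2 - 1 / lam),
               tolerance = 1e-12)
  expect_error(cauchy_stress(matrix(0, 3, 3), healthy, fib), "determinant")
})

test_that("analytic stress agrees with finite differences of the energy", {
  # sigma = (1/J) P F^T with P = dpsi/dF by central differences
  fib <- fiber_point(a1 = c(1, 0, 0), a2 = c(0, 0.6, 0.8), kappa = 0.12)
  params <- material_parameters(2, 0.3, 0.05, 150)
  set.seed(42)
  h <- 1e-6
  worst <- 0
  for (trial in 1:400) {
    F <- random_defgrad()
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (strain_energy(Fp, params, fib) -
                    strain_energy(Fm, params, fib)) / (2 * h)
    }
    sig_fd <- P %*% t(F) / det(F)
    sig <- cauchy_stress(F, params, fib)
    scale <- max(abs(sig), 1e-8)
    worst <- max(worst, max(abs(sig - sig_fd)) / scale)
  }
  expect_lt(worst, 1e-5)
})

test_that("stress decomposition is exact and linear in (K, mu, k1)", {
  fib <- fiber_point(a1 = c(0.8, 0.6, 0), a2 = c(0, 1, 0), kappa = 0.15)
  set.seed(7)
  for (trial in 1:20) {
    F <- random_defgrad()
    dec <- stress_decomposition(F, fib, k2 = 200, tension_only = FALSE)
    for (rep in 1:5) {
      K <- stats::runif(1, 0, 20); mu <- stats::runif(1, 0, 1)
      k1 <- stats::runif(1, 0, 0.1)
      params <- material_parameters(K, mu, k1, 200)
      direct <- cauchy_stress(F, params, fib)
      rebuilt <- K * dec$sigma_K + mu * dec$sigma_mu + k1 * dec$sigma_k1
      expect_rel_equal(rebuilt, direct, 1e-12)
    }
    # each unit tensor equals the stress at a unit parameter
    expect_rel_equal(dec$sigma_K,
                     cauchy_stress(F, material_parameters(1, 0, 0, 200), fib),
                     1e-12)
    # doubling k1 adds exactly one more k1-unit of fiber stress
    s1 <- cauchy_stress(F, material_parameters(2, 0.3, 0.05, 200), fib)
    s2 <- cauchy_stress(F, material_parameters(2, 0.3, 0.10, 200), fib)
    expect_rel_equal(s2 - s1, 0.05 * dec$sigma_k1, 1e-10)
  }
  # volumetric unit stress vanishes at J = 1
  lam <- 1.1
  Fiso <- diag(c(lam, 1 / lam, 1))
  dec <- stress_decomposition(Fiso, fib, 200)
  expect_equal(dec$sigma_K, matrix(0, 3, 3))
})

test_that("isotropy and dispersion limits hold", {
  set.seed(11)
  F <- random_defgrad()
  rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  # k1 = 0: fiber directions are irrelevant
  iso <- material_parameters(5, 0.4, 0, 200)
  s1 <- cauchy_stress(F, iso, fiber_point(c(1, 0, 0), c(0, 1, 0), 0.1))
  s2 <- cauchy_stress(F, iso, fiber_point(rot[, 1], rot[, 2], 0.1))
  expect_equal(s1, s2, tolerance = 1e-14)
  # kappa = 1/3: only the isotropic invariant survives
  ani <- material_parameters(5, 0.4, 0.05, 200)
  s3 <- cauchy_stress(F, ani, fiber_point(c(1, 0, 0), c(0, 1, 0), 1 / 3))
  s4 <- cauchy_stress(F, ani, fiber_point(rot[, 1], rot[, 3], 1 / 3))
  expect_equal(s3, s4, tolerance = 1e-12)
})

test_that("plate rigidity follows the thin-plate formula", {
  expect_equal(plate_rigidity(12, 1, 0), 1)
  expect_equal(plate_rigidity(17e3, 10e-6, 0.49),
               17e3 * 1e-15 / (12 * (1 - 0.49^2)), tolerance = 1e-12)
  expect_lt(abs(plate_rigidity(17e3, 10e-6, 0.49) - 1.864e-12) / 1.864e-12,
            0.01)
  expect_equal(plate_rigidity(3, 2, 0.3) / plate_rigidity(3, 2, 0),
               1 / (1 - 0.09))
  expect_error(plate_rigidity(1, 1, 0.5), "nu")
  expect_error(plate_rigidity(1, 1, -0.2), "nu")
})

test_that("reference material sets carry the degradation sequence", {
  tab <- reference_material_sets()
  expect_equal(tab$k1, c(0.04, 0.02, 0.01, 0))
  expect_true(all(tab$K == 10), all(tab$mu == 0.275), all(tab$k2 == 200))
  h <- reference_material("H")
  expect_s3_class(h, "material_parameters")
  expect_equal(h$k1, 0.04)
})
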