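# Anisotropic hyperelastic constitutive model of the corneal stroma:
# volumetric penalty + neo-Hookean matrix + two dispersed collagen fiber
# families. All quantities in the mm / N / MPa unit system unless noted.

#' Corneal material parameter set
#'
#' Bundles the four constitutive parameters of the fiber-reinforced cornea
#' model: the volumetric penalty (bulk-like) modulus `K`, the neo-Hookean
#' shear modulus `mu` of the isotropic matrix, the collagen fiber stiffness
#' `k1` and the dimensionless fiber nonlinearity exponent `k2`. `K`, `mu`
#' and `k1` enter the Cauchy stress -- and therefore the assembled internal
#' force vector -- linearly; `k2` enters through the exponential fiber law.
#'
#' The optional variance-correction factor `a = 1 + Kstar * sigma2_I4`
#' scaling the fiber energy is disabled by default (`a = 1`); reference
#' parameter sets carry no values for `Kstar`/`sigma2_I4`.
#'
#' @param K Penalty bulk modulus (MPa), `>= 0`.
#' @param mu Shear modulus of the isotropic matrix (MPa), `>= 0`.
#' @param k1 Fiber stiffness (MPa), `>= 0`.
#' @param k2 Dimensionless fiber nonlinearity, `>= 0`. Values below
#'   `1e-6` are evaluated through a quadratic series branch so that the
#'   fiber energy tends continuously to `(k1/2) * (I4star - 1)^2`.
#' @param variance_correction Logical; enable the `a` factor.
#' @param Kstar,sigma2_I4 Variance-correction coefficient and invariant
#'   variance (dimensionless); only used when `variance_correction = TRUE`.
#' @param tension_only Logical; if `TRUE` fibers contribute energy and
#'   stress only when `I4star > 1` (collagen bears no compression). The
#'   default is `FALSE`: with the dispersed invariant the fiber term is
#'   already quadratically small around `I4star = 1`, and the smooth law
#'   reproduces the characteristic shape of the relative-scatter
#'   objective (secondary minimum toward `k2 -> 0`).
#' @return An object of class `"material_parameters"`.
#' @examples
#' material_parameters(K = 10, mu = 0.275, k1 = 0.04, k2 = 200)
#' @export
material_parameters <- function(K, mu, k1, k2,
                                variance_correction = FALSE,
                                Kstar = NULL, sigma2_I4 = NULL,
                                tension_only = FALSE) {
  stopifnot(is.numeric(K), is.numeric(mu), is.numeric(k1), is.numeric(k2))
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (k1 < 0) stop("k1 must be >= 0", call. = FALSE)
  if (k2 < 0) stop("k2 must be >= 0 (small-k2 series branch handles k2 -> 0)",
                   call. = FALSE)
  if (variance_correction && (is.null(Kstar) || is.null(sigma2_I4)))
    stop("variance_correction = TRUE requires Kstar and sigma2_I4",
         call. = FALSE)
  structure(
    list(K = K, mu = mu, k1 = k1, k2 = k2,
         variance_correction = variance_correction,
         Kstar = Kstar, sigma2_I4 = sigma2_I4,
         tension_only = tension_only),
    class = "material_parameters")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("<material_parameters>  K =", x$K, "MPa, mu =", x$mu,
      "MPa, k1 =", x$k1, "MPa, k2 =", x$k2, "[-]\n")
  if (x$variance_correction)
    cat("  variance correction a = 1 + ", x$Kstar, " * ", x$sigma2_I4, "\n",
        sep = "")
  invisible(x)
}

#' Reference material sets (healthy and keratoconus-degraded)
#'
#' The healthy reference set and three degraded sets that emulate
#' keratoconus in an early stage by reducing the collagen fiber stiffness
#' `k1` (all other parameters unchanged): KK-I halves it, KK-II quarters
#' it, KK-III removes the fibers entirely.
#'
#' @return A tibble with columns `set`, `K`, `mu`, `k1`, `k2`.
#' @examples
#' reference_material_sets()
#' @export
reference_material_sets <- function() {
  tibble::tibble(
    set = c("H", "KK-I", "KK-II", "KK-III"),
    K   = 10,
    mu  = 0.275,
    k1  = c(0.04, 0.02, 0.01, 0.00),
    k2  = 200)
}

#' Look up one reference material set by name
#'
#' @param set One of `"H"`, `"KK-I"`, `"KK-II"`, `"KK-III"`.
#' @inheritParams material_parameters
#' @return A `material_parameters` object.
#' @export
reference_material <- function(set = c("H", "KK-I", "KK-II", "KK-III"),
                               tension_only = FALSE) {
  set <- match.arg(set)
  tab <- reference_material_sets()
  row <- tab[tab$set == set, ]
  material_parameters(K = row$K, mu = row$mu, k1 = row$k1, k2 = row$k2,
                      tension_only = tension_only)
}

#' Auxiliary (non-corneal) component moduli
#'
#' Linear-elastic, quasi-incompressible surrogate properties for the
#' limbus, sclera and lens. Internally these components are modeled with
#' the same hyperelastic machinery (neo-Hookean + volumetric penalty) using
#' the small-strain-equivalent moduli `mu = E / (2 (1 + nu))` and
#' `K = E / (3 (1 - 2 nu))`, which reproduces the stated linear-elastic
#' behavior in the small-strain regime these components experience.
#'
#' @param E_Li,E_Sc,E_Le Elastic moduli of limbus, sclera, lens (MPa).
#' @param nu Poisson ratio shared by the auxiliary components.
#' @return An object of class `"auxiliary_materials"`.
#' @export
auxiliary_materials <- function(E_Li = 1.4, E_Sc = 2.3, E_Le = 2.4,
                                nu = 0.49) {
  stopifnot(E_Li > 0, E_Sc > 0, E_Le > 0, nu >= 0, nu < 0.5)
  structure(list(E_Li = E_Li, E_Sc = E_Sc, E_Le = E_Le, nu = nu),
            class = "auxiliary_materials")
}

# linear-elastic (E, nu) -> equivalent (K, mu) hyperelastic surrogate
linear_equivalent_params <- function(E, nu) {
  material_parameters(K = E / (3 * (1 - 2 * nu)),
                      mu = E / (2 * (1 + nu)),
                      k1 = 0, k2 = 1)
}

#' Fiber point: local directions and dispersion
#'
#' Two collagen fiber family directions (unit 3-vectors) and the dispersion
#' parameter `kappa in [0, 1/3]` at one material/integration point.
#' `kappa = 0` means perfectly aligned fibers, `kappa = 1/3` an isotropic
#' orientation distribution (the structural contribution degenerates to the
#' isotropic invariant).
#'
#' @param a1,a2 Fiber direction 3-vectors (normalized internally).
#' @param kappa Dispersion parameter in `[0, 1/3]`.
#' @return An object of class `"fiber_point"`.
#' @export
fiber_point <- function(a1 = c(1, 0, 0), a2 = c(0, 1, 0), kappa = 0.1) {
  a1 <- as.numeric(a1); a2 <- as.numeric(a2)
  stopifnot(length(a1) == 3, length(a2) == 3)
  n1 <- sqrt(sum(a1^2)); n2 <- sqrt(sum(a2^2))
  if (n1 == 0 || n2 == 0) stop("fiber directions must be non-zero", call. = FALSE)
  check_kappa(kappa)
  structure(list(a1 = a1 / n1, a2 = a2 / n2, kappa = kappa),
            class = "fiber_point")
}

check_kappa <- function(kappa) {
  if (any(kappa < 0) || any(kappa > 1 / 3))
    stop("kappa must lie in [0, 1/3]", call. = FALSE)
  invisible(kappa)
}

#' Modified (dispersed) fourth invariant
#'
#' Blends the isochoric isotropic invariant and the isochoric fiber
#' invariant through the dispersion parameter:
#' `I4star = kappa * I1tilde + (1 - 3 kappa) * I4tilde`.
#'
#' @param I1tilde First isochoric invariant.
#' @param I4tilde Isochoric fourth (fiber-stretch squared) invariant.
#' @param kappa Dispersion in `[0, 1/3]`.
#' @return The modified invariant (same length as the inputs, recycled).
#' @examples
#' modified_invariant(3.3, 1.2, 0.1)  # 1.17
#' @export
modified_invariant <- function(I1tilde, I4tilde, kappa) {
  check_kappa(kappa)
  kappa * I1tilde + (1 - 3 * kappa) * I4tilde
}

#' Kinematic state from a deformation gradient
#'
#' @param F 3x3 deformation gradient with `det(F) > 0`.
#' @return A list with `F`, `J`, the isochoric right Cauchy-Green tensor
#'   `Ctilde`, and `I1tilde`.
#' @export
kinematic_state <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("deformation gradient must have positive determinant", call. = FALSE)
  C <- crossprod(F)           # F^T F
  Ctilde <- J^(-2 / 3) * C
  list(F = F, J = J, Ctilde = Ctilde, I1tilde = sum(diag(Ctilde)))
}

# fiber energy density per family and its derivative w.r.t. I4star,
# divided by k1 (so the caller can scale; keeps the k1-linearity explicit).
# Series branch below k2 = 1e-6 keeps the k2 -> 0 limit finite and smooth:
# psi/k1 = d^2/2 * (exp(x) - 1)/x with x = k2 d^2.
.k2_branch_tol <- 1e-6

psi_ti_unit <- function(d, k2) {
  x <- k2 * d^2
  if (k2 < .k2_branch_tol) {
    0.5 * d^2 * (1 + x / 2 + x^2 / 6)
  } else {
    (exp(x) - 1) / (2 * k2)
  }
}

dpsi_ti_unit <- function(d, k2) {
  x <- k2 * d^2
  if (k2 < .k2_branch_tol) {
    d * (1 + x + x^2 / 2)
  } else {
    d * exp(x)
  }
}

variance_factor <- function(params) {
  if (isTRUE(params$variance_correction))
    1 + params$Kstar * params$sigma2_I4
  else 1
}

#' Strain-energy density of the cornea model
#'
#' `psi = psi_vol(J) + psi_iso(I1tilde) + sum_i psi_ti(I4star_i)` with
#' \itemize{
#'  \item `psi_vol = (K/4) (J^2 - 1 - 2 ln J)` (quasi-incompressibility
#'    penalty),
#'  \item `psi_iso = (mu/2) (I1tilde - 3)` (neo-Hookean matrix),
#'  \item `psi_ti = (k1 / (2 k2)) (exp(k2 (I4star - 1)^2) - 1) * a` per
#'    fiber family (exponentially stiffening collagen), `a` the optional
#'    variance-correction factor.
#' }
#'
#' @param F 3x3 deformation gradient.
#' @param params A [material_parameters()] object.
#' @param fiber A [fiber_point()] object.
#' @return Energy density (MPa).
#' @export
strain_energy <- function(F, params, fiber) {
  st <- kinematic_state(F)
  a_fac <- variance_factor(params)
  psi_vol <- params$K / 4 * (st$J^2 - 1 - 2 * log(st$J))
  psi_iso <- params$mu / 2 * (st$I1tilde - 3)
  psi_ti <- 0
  for (a in list(fiber$a1, fiber$a2)) {
    I4t <- drop(crossprod(a, st$Ctilde %*% a))
    d <- modified_invariant(st$I1tilde, I4t, fiber$kappa) - 1
    if (d > 0 || !isTRUE(params$tension_only))
      psi_ti <- psi_ti + params$k1 * a_fac * psi_ti_unit(d, params$k2)
  }
  psi_vol + psi_iso + psi_ti
}

#' Cauchy stress of the cornea model
#'
#' Computed as the push-forward of the energy derivative,
#' `sigma = (2/J) F (dpsi/dC) F^T`; the volumetric part contributes the
#' pure pressure `(K/2)(J - 1/J) I`, the isochoric parts enter through
#' deviatoric projections.
#'
#' @inheritParams strain_energy
#' @return Symmetric 3x3 Cauchy stress (MPa).
#' @export
cauchy_stress <- function(F, params, fiber) {
  dec <- stress_decomposition(F, fiber, params$k2,
                              tension_only = params$tension_only)
  a_fac <- variance_factor(params)
  params$K * dec$sigma_K + params$mu * dec$sigma_mu +
    params$k1 * a_fac * dec$sigma_k1
}

#' Exact linear-parameter decomposition of the Cauchy stress
#'
#' For fixed kinematics and fixed `k2` the Cauchy stress is exactly linear
#' in `(K, mu, k1)`:
#' `sigma = K * sigma_K + mu * sigma_mu + k1 * sigma_k1`.
#' Each unit tensor equals the stress evaluated with the corresponding
#' parameter set to one and the others to zero. This decomposition is what
#' makes the equilibrium-gap identification a convex 3-parameter
#' least-squares problem.
#'
#' @param F 3x3 deformation gradient.
#' @param fiber A [fiber_point()].
#' @param k2 Fiber nonlinearity (fixed during decomposition).
#' @param tension_only Fiber tension-compression switch, see
#'   [material_parameters()].
#' @return List with 3x3 matrices `sigma_K`, `sigma_mu`, `sigma_k1`.
#' @export
stress_decomposition <- function(F, fiber, k2, tension_only = TRUE) {
  st <- kinematic_state(F)
  J <- st$J
  Fb <- J^(-1 / 3) * st$F
  btilde <- tcrossprod(Fb)        # Fb Fb^T
  I1t <- sum(diag(btilde))
  I3 <- diag(3)
  dev3 <- function(A) A - sum(diag(A)) / 3 * I3

  sigma_K <- 0.5 * (J - 1 / J) * I3
  sigma_mu <- dev3(btilde) / J
  sigma_k1 <- matrix(0, 3, 3)
  for (a in list(fiber$a1, fiber$a2)) {
    at <- drop(Fb %*% a)
    I4t <- sum(at^2)
    d <- modified_invariant(I1t, I4t, fiber$kappa) - 1
    if (d > 0 || !isTRUE(tension_only)) {
      w <- dpsi_ti_unit(d, k2)
      struc <- fiber$kappa * btilde + (1 - 3 * fiber$kappa) * tcrossprod(at)
      sigma_k1 <- sigma_k1 + (2 / J) * w * dev3(struc)
    }
  }
  list(sigma_K = sigma_K, sigma_mu = sigma_mu, sigma_k1 = sigma_k1)
}

#' Bending rigidity of a thin plate
#'
#' `K_Pl = E t^3 / (12 (1 - nu^2))`. Utility used to rank the mechanical
#' relevance of the individual corneal layers; unlike the rest of the
#' package this helper works in SI units (Pa, m -> N m).
#'
#' @param E Elastic modulus (Pa).
#' @param t Thickness (m).
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return Plate rigidity (N m).
#' @examples
#' plate_rigidity(17e3, 10e-6, 0.49)  # Bowman layer, ~1.9e-12 N m
#' @export
plate_rigidity <- function(E, t, nu) {
  stopifnot(E > 0, t > 0)
  if (any(abs(nu) >= 1)) stop("|nu| must be < 1", call. = FALSE)
  if (any(nu < 0) || any(nu >= 0.5))
    stop("nu must lie in [0, 0.5)", call. = FALSE)
  E * t^3 / (12 * (1 - nu^2))
}
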