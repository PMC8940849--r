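# Parametric anterior-eye fixture: ellipsoidal cornea cap + limbus ring,
# clamped at the outer rim, with a single anterior fluid cavity. The
# planform uses an elliptical square-to-quarter-disc mapping so the hex
# grid has no polar singularity at the apex.

#' Eye geometry parameters
#'
#' Describes the reduced anterior-eye fixture: the cornea is an ellipsoid
#' of revolution (semi-axes `Rr` in-plane, `Rz` along the symmetry axis,
#' apex at the origin, anterior side up), its thickness blends smoothly
#' (cosine) from `cct` at the apex to `peripheral_thickness` at the limbus
#' start radius; the limbus forms a ring of width `limbus_width` whose
#' outer rim is clamped. A quarter model with symmetry planes x = 0 and
#' y = 0 is generated by default.
#'
#' @param Rr,Rz Corneal ellipsoid semi-axes (mm); the apex radius of
#'   curvature is `Rr^2 / Rz`.
#' @param cct Central corneal thickness (mm).
#' @param peripheral_thickness Thickness at and beyond the limbus start (mm).
#' @param limbus_start Planform radius where the limbus begins (mm).
#' @param limbus_width Width of the limbus ring (mm).
#' @param n_planform Planform grid divisions of the corneal quarter disc.
#' @param n_layers Element layers through the thickness.
#' @param n_limbus Element rings across the limbus width.
#' @param symmetry `"quarter"` (only mode implemented; generator, loads
#'   and fiber field are symmetric with respect to both planes, so the
#'   quarter model represents the full problem).
#' @param include_sclera,include_lens Inclusion flags for the posterior
#'   components; the reduced fixture does not implement them and raises an
#'   error if requested.
#' @param apex_disc Radius (mm) of the apex disc inside which fiber
#'   directions fall back to the projected global x/y axes (they do
#'   everywhere in the default field; kept as an explicit parameter).
#' @param cavity_KW Effective cavity volume-response modulus (MPa): the
#'   pressure-volume stiffness of the anterior chamber including the
#'   compliance of the surrounding tissue that the reduced fixture does not
#'   mesh. The default gives an IOP rise of a few mmHg at ~1 mm apex
#'   indentation; set to 2000 (water) for a rigid-boundary chamber.
#' @param iop_mmHg Baseline intraocular pressure (mmHg).
#' @return A list of class `"eye_geometry_params"`.
#' @export
eye_geometry_params <- function(Rr = 7.2, Rz = 6.6,
                                cct = 0.545, peripheral_thickness = 0.70,
                                limbus_start = 4.6, limbus_width = 2.0,
                                n_planform = 8, n_layers = 2, n_limbus = 2,
                                symmetry = "quarter",
                                include_sclera = FALSE, include_lens = FALSE,
                                apex_disc = 0.2,
                                cavity_KW = 0.02, iop_mmHg = 17.5) {
  stopifnot(Rr > 0, Rz > 0, cct > 0, peripheral_thickness > 0,
            limbus_width > 0, n_planform >= 2, n_layers >= 1, n_limbus >= 1)
  if (limbus_start + limbus_width >= Rr)
    stop("corneal ellipsoid semi-axis Rr must exceed the outer rim radius",
         call. = FALSE)
  if (!identical(symmetry, "quarter"))
    stop("only the quarter symmetry mode is implemented", call. = FALSE)
  if (include_sclera || include_lens)
    stop("sclera/lens components are not implemented in the reduced fixture",
         call. = FALSE)
  structure(as.list(environment()), class = "eye_geometry_params")
}

# anterior surface height and unit outward normal of the ellipsoid
anterior_z <- function(r, p) p$Rz * (sqrt(pmax(1 - (r / p$Rr)^2, 0)) - 1)

anterior_normal <- function(x, y, p) {
  # gradient of (x^2+y^2)/Rr^2 + (z/Rz+1)^2 = 1, outward (positive z at apex)
  r2 <- x^2 + y^2
  z <- anterior_z(sqrt(r2), p)
  n <- cbind(2 * x / p$Rr^2, 2 * y / p$Rr^2, 2 * (z / p$Rz + 1) / p$Rz)
  n / sqrt(rowSums(n^2))
}

thickness_profile <- function(r, p) {
  t <- ifelse(r >= p$limbus_start, p$peripheral_thickness,
              p$cct + (p$peripheral_thickness - p$cct) *
                0.5 * (1 - cos(pi * r / p$limbus_start)))
  t
}

#' Build the reduced eye model
#'
#' Generates the watertight quarter hex mesh (cornea + limbus), installs
#' symmetry and rim-clamp boundary conditions, the anterior/wetted facet
#' sets, the fluid cavity, the auxiliary limbus material and the corneal
#' fiber field, and precomputes reference element data.
#'
#' @param params [eye_geometry_params()].
#' @param cornea_material [material_parameters()] for the cornea.
#' @param aux [auxiliary_materials()] for the non-corneal components.
#' @param kappa_profile Function of planform radius (mm) returning the
#'   fiber dispersion `kappa`; default constant 0.1.
#' @return An eye model list with `nodes`, `groups`, `bc`, `facet_sets`,
#'   `cavity`, `params`.
#' @export
build_eye_mesh <- function(params = eye_geometry_params(),
                           cornea_material = reference_material("H"),
                           aux = auxiliary_materials(),
                           kappa_profile = function(r) rep(0.1, length(r))) {
  p <- params
  n <- p$n_planform; nl <- p$n_layers; nr <- p$n_limbus
  L <- p$limbus_start

  # planform grid: elliptical square-to-quarter-disc map
  s <- seq(0, 1, length.out = n + 1)
  grid_xy <- function(xi, eta)
    cbind(L * xi * sqrt(1 - eta^2 / 2), L * eta * sqrt(1 - xi^2 / 2))
  plan <- matrix(0, (n + 1)^2, 2)
  pid <- function(i, j) as.integer(i + 1L + (n + 1L) * j)  # i, j in 0..n
  for (j in 0:n) for (i in 0:n)
    plan[pid(i, j), ] <- grid_xy(s[i + 1], s[j + 1])

  # boundary arc (from (L,0) to (0,L)): edge eta-varying at xi=1, then
  # xi-varying at eta=1; angles strictly increasing
  bidx <- c(vapply(0:n, function(j) pid(n, j), 1L),
            vapply((n - 1):0, function(i) pid(i, n), 1L))
  nb <- length(bidx)                                # 2n + 1 boundary nodes
  btheta <- atan2(plan[bidx, 2], plan[bidx, 1])

  # limbus planform rings k = 1..nr at radius L + k * w / nr
  ring_xy <- function(k) {
    r <- L + k * p$limbus_width / nr
    cbind(r * cos(btheta), r * sin(btheta))
  }
  plan_all <- rbind(plan, do.call(rbind, lapply(1:nr, ring_xy)))
  ring_id <- function(k, b)                                 # k>=1, b in 1..nb
    as.integer((n + 1L)^2 + (k - 1L) * nb + b)
  n_plan <- nrow(plan_all)

  # 3D nodes: node layers l = 0 (posterior) .. nl (anterior)
  r_all <- sqrt(rowSums(plan_all^2))
  z_ant <- anterior_z(r_all, p)
  nrm <- anterior_normal(plan_all[, 1], plan_all[, 2], p)
  thick <- thickness_profile(r_all, p)
  nodes <- matrix(0, n_plan * (nl + 1), 3)
  nid <- function(plan_node, l) plan_node + n_plan * l   # l in 0..nl
  for (l in 0:nl) {
    depth <- (1 - l / nl) * thick                        # 0 at anterior
    idx <- nid(seq_len(n_plan), l)
    nodes[idx, 1] <- plan_all[, 1] - depth * nrm[, 1]
    nodes[idx, 2] <- plan_all[, 2] - depth * nrm[, 2]
    nodes[idx, 3] <- z_ant - depth * nrm[, 3]
  }

  # hex connectivity: bottom face (layer l) counterclockwise in plan view
  cells_cornea <- do.call(rbind, lapply(0:(n - 1), function(j)
    t(vapply(0:(n - 1), function(i)
      c(pid(i, j), pid(i + 1, j), pid(i + 1, j + 1), pid(i, j + 1)),
      integer(4)))))
  ring_node <- function(k, b) if (k == 0) bidx[b] else ring_id(k, b)
  cells_limbus <- do.call(rbind, lapply(0:(nr - 1), function(k)
    t(vapply(1:(nb - 1), function(b)
      c(ring_node(k, b), ring_node(k + 1, b),
        ring_node(k + 1, b + 1), ring_node(k, b + 1)),
      integer(4)))))

  hex_from_cells <- function(cells) {
    do.call(rbind, lapply(0:(nl - 1), function(l)
      cbind(nid(cells[, 1], l), nid(cells[, 2], l),
            nid(cells[, 3], l), nid(cells[, 4], l),
            nid(cells[, 1], l + 1), nid(cells[, 2], l + 1),
            nid(cells[, 3], l + 1), nid(cells[, 4], l + 1))))
  }
  conn_cornea <- hex_from_cells(cells_cornea)
  conn_limbus <- hex_from_cells(cells_limbus)

  # facet sets (outward from solid): anterior = top faces (normal up,
  # counterclockwise in plan view), wetted posterior = bottom faces reversed
  all_cells <- rbind(cells_cornea, cells_limbus)
  anterior <- cbind(nid(all_cells[, 1], nl), nid(all_cells[, 2], nl),
                    nid(all_cells[, 3], nl), nid(all_cells[, 4], nl))
  anterior_cornea <- anterior[seq_len(nrow(cells_cornea)), , drop = FALSE]
  wetted <- cbind(nid(all_cells[, 1], 0), nid(all_cells[, 4], 0),
                  nid(all_cells[, 3], 0), nid(all_cells[, 2], 0))

  # node sets
  tol <- 1e-9
  rim_plan <- ring_id(nr, seq_len(nb))
  rim_nodes <- as.vector(vapply(0:nl, function(l) nid(rim_plan, l),
                                integer(nb)))
  sym_x <- which(abs(nodes[, 1]) < tol)   # plane x = 0: fix u_x
  sym_y <- which(abs(nodes[, 2]) < tol)   # plane y = 0: fix u_y
  apex_anterior <- nid(pid(0, 0), nl)
  fixed_dofs <- sort(unique(c(
    as.vector(vapply(rim_nodes, function(nn) 3L * (nn - 1L) + 1:3,
                     integer(3))),
    3L * (sym_x - 1L) + 1L,
    3L * (sym_y - 1L) + 2L)))

  # cavity closure: flat quarter disc at the posterior rim plane, fixed
  # (rim clamped), with the two symmetry planes contributing zero
  post_rim <- nid(rim_plan, 0)
  z_floor <- mean(nodes[post_rim, 3])
  r_floor <- sqrt(nodes[post_rim, 1]^2 + nodes[post_rim, 2]^2)
  area_floor <- 0
  for (b in 1:(nb - 1)) {                # planform fan from the axis
    v1 <- nodes[post_rim[b], 1:2]; v2 <- nodes[post_rim[b + 1], 1:2]
    area_floor <- area_floor + 0.5 * abs(v1[1] * v2[2] - v1[2] * v2[1])
  }
  closure <- (1 / 3) * (-z_floor) * area_floor   # x . n dA with n = -e_z

  groups <- list(
    cornea = list(conn = conn_cornea, material = cornea_material,
                  fiber = NULL),
    limbus = list(conn = conn_limbus,
                  material = linear_equivalent_params(aux$E_Li, aux$nu),
                  fiber = NULL))

  model <- list(
    nodes = nodes,
    groups = groups,
    bc = list(fixed_dofs = fixed_dofs, sym_x = sym_x, sym_y = sym_y,
              rim_nodes = rim_nodes),
    facet_sets = list(anterior = anterior,
                      anterior_cornea = anterior_cornea,
                      wetted = wetted),
    node_sets = list(rim = rim_nodes, sym_x = sym_x, sym_y = sym_y,
                     apex_anterior = apex_anterior),
    cavity = list(facets = wetted, KW = p$cavity_KW,
                  p0 = mmHg_to_MPa(p$iop_mmHg), V0 = NA_real_,
                  closure = closure),
    params = p,
    aux = aux,
    kappa_profile = kappa_profile,
    plan = list(n_plan = n_plan, nl = nl, nid = NULL))
  model <- model_precompute(model)
  model <- build_fiber_field(model, kappa_profile)
  # set the reference cavity volume from the undeformed geometry; the
  # prestressing pipeline overwrites it with the in-vivo volume
  model$cavity$V0 <- model$cavity$closure +
    facet_cavity_volume(model$nodes, model$cavity$facets,
                        matrix(0, nrow(nodes), 3))
  class(model) <- "eye_model"
  model
}

#' @export
print.eye_model <- function(x, ...) {
  ne <- vapply(x$groups, function(g) nrow(g$conn), 1L)
  cat("<eye_model> ", nrow(x$nodes), " nodes; elements:",
      paste(sprintf("%s=%d", names(ne), ne), collapse = ", "),
      "\n  cavity V0 =", signif(x$cavity$V0, 5), "mm^3, p0 =",
      signif(MPa_to_mmHg(x$cavity$p0), 4), "mmHg\n")
  invisible(x)
}

#' Build the corneal fiber field
#'
#' At every corneal quadrature point, family 1 runs nasal-temporal (global
#' x) and family 2 superior-inferior (global y), both projected onto the
#' local surface tangent plane and normalized; the dispersion `kappa` comes
#' from the radial profile. The projection formula is regular at the apex
#' (the surface normal is the z axis there, so the families reduce to the
#' global x/y axes exactly).
#'
#' @param model An eye model.
#' @param kappa_profile Function of planform radius (mm) -> kappa.
#' @return The model with the corneal fiber field attached.
#' @export
build_fiber_field <- function(model, kappa_profile = model$kappa_profile) {
  g <- model$groups$cornea
  pre <- g$pre
  E <- pre$nelem
  gq <- hex_gauss_points()
  fiber <- vector("list", 8)
  for (q in 1:8) {
    N <- hex_shape(gq$points[q, ])
    Xq <- matrix(0, E, 3)
    for (a in 1:8) Xq <- Xq + N[a] * pre$Xe[, a, ]
    nrm <- anterior_normal(Xq[, 1], Xq[, 2], model$params)
    proj <- function(e) {
      v <- matrix(rep(e, each = E), E, 3) - rowSums(sweep(nrm, 2, e, "*")) * nrm
      v / sqrt(rowSums(v^2))
    }
    kap <- kappa_profile(sqrt(Xq[, 1]^2 + Xq[, 2]^2))
    check_kappa(kap)
    fiber[[q]] <- list(a1 = proj(c(1, 0, 0)), a2 = proj(c(0, 1, 0)),
                       kappa = rep(kap, length.out = E))
  }
  model$groups$cornea$fiber <- fiber
  model$kappa_profile <- kappa_profile
  model
}

#' Recover the stress-free reference geometry
#'
#' The in-vivo (target) geometry is measured under intraocular pressure;
#' the mechanical reference configuration is unknown. The fixed-point
#' iteration `X0 <- X0 - relax * (x(X0) - X_target)` updates the reference
#' coordinates until the pressurized configuration `x(X0)` matches the
#' target within `tol` (maximum nodal distance; default 2e-3 mm = 2 um).
#' The IOP is held fixed on the wetted surface during the iteration.
#'
#' @param model Eye model whose `nodes` hold the target (in-vivo) geometry.
#' @param iop_mmHg Intraocular pressure during the iteration (mmHg).
#' @param tol Convergence bound on the maximum nodal distance (mm).
#' @param relax Fixed-point relaxation factor (1 = full update).
#' @param max_iter Maximum fixed-point iterations.
#' @param n_load_steps Pressure ramp steps inside each forward solve.
#' @return A list with `model` (reference coordinates replaced by the
#'   stress-free geometry, cavity `V0`/`p0` set to the in-vivo state),
#'   `U_pre` (prestress displacement from the stress-free reference),
#'   `max_dist` (per-iteration maximum nodal distance, mm), `target`.
#' @export
stress_free_geometry <- function(model, iop_mmHg = model$params$iop_mmHg,
                                 tol = 2e-3, relax = 1, max_iter = 20,
                                 n_load_steps = 4) {
  X_target <- model$nodes
  p_iop <- mmHg_to_MPa(iop_mmHg)
  X0 <- X_target
  dist_log <- numeric(0)
  m <- model
  U <- matrix(0, nrow(X_target), 3)
  if (p_iop == 0) {
    m$cavity$V0 <- m$cavity$closure +
      facet_cavity_volume(m$nodes, m$cavity$facets, U)
    m$cavity$p0 <- 0
    return(list(model = m, U_pre = U, max_dist = 0, target = X_target,
                iterations = 0L))
  }
  schedule <- lapply(seq_len(n_load_steps) / n_load_steps, function(s)
    list(pulse = NULL, cavity = "fixed", p_fix = s * p_iop))
  for (it in seq_len(max_iter)) {
    m <- model_set_coords(m, X0)
    sol <- solve_forward(m, schedule, U0 = U)
    U <- sol$U
    d <- X0 + U - X_target
    maxd <- max(sqrt(rowSums(d^2)))
    dist_log <- c(dist_log, maxd)
    if (maxd <= tol) {
      m$cavity$V0 <- m$cavity$closure +
        facet_cavity_volume(m$nodes, m$cavity$facets, U)
      m$cavity$p0 <- p_iop
      return(list(model = m, U_pre = U, max_dist = dist_log,
                  target = X_target, iterations = it))
    }
    X0 <- X0 - relax * d
  }
  stop(sprintf(
    "stress-free iteration did not reach %.3g mm in %d iterations (distances: %s)",
    tol, max_iter, paste(signif(dist_log, 3), collapse = ", ")), call. = FALSE)
}
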