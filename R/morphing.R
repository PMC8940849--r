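# Mechanical morphing: reconstruct a representative 3D full-field
# displacement from 2D anterior/posterior deformation contours. The
# contours are rotationally extruded to axisymmetric stamps; the stamps
# imprint the corneal surfaces through iterated vertical constraints while
# the cornea slides horizontally; incompressibility is enforced by the
# volumetric penalty of the morph material.

#' Default morph-model material (linear-elastic incompressible surrogate)
#'
#' The morphing step assumes no knowledge of the corneal properties; the
#' cornea is replaced by a quasi-incompressible isotropic surrogate with
#' modulus `E` and effective Poisson ratio `nu` (via the volumetric
#' penalty). The reconstructed displacement field is imposed by the
#' stamps, so identified parameters must be insensitive to `E`.
#'
#' @param E Surrogate elastic modulus (MPa).
#' @param nu Effective Poisson ratio (close to 0.5).
#' @return A [material_parameters()] object with `k1 = 0`.
#' @export
morph_material <- function(E = 1, nu = 0.495) {
  linear_equivalent_params(E, nu)
}

#' Extrude deformation contours to axisymmetric stamps
#'
#' Each 2D polyline (r, z) becomes a surface of revolution about the
#' symmetry axis, evaluable as a height function `z(r)` by spline
#' interpolation of the ordered polyline (clamped to the boundary values
#' outside the sampled range). The anterior stamp is positioned by the
#' deflection amplitude and the posterior stamp aligned through the
#' central corneal thickness; contours extracted by this package carry
#' absolute coordinates, so the positioning is checked rather than
#' re-imposed.
#'
#' @param contours A `"contour_pair"` from [extract_contours()] (or a
#'   compatible list with a `contour` tibble and `DefA`, `CCT` metadata).
#' @return A `"stamp_pair"`: functions `anterior(r)`, `posterior(r)`,
#'   the radial validity range, and the metadata.
#' @export
extrude_stamps <- function(contours) {
  tab <- contours$contour
  mk <- function(tag) {
    d <- tab[tab$surface == tag, ]
    if (nrow(d) < 2) stop("contour needs at least 2 points", call. = FALSE)
    if (any(diff(d$r) <= 0))
      stop("contour polyline must be strictly ordered in r", call. = FALSE)
    # even extension about the symmetry axis: the apex is then an interior
    # point, so the spline captures its curvature instead of imposing an
    # artificial end condition there
    rs <- d$r; zs <- d$z
    if (rs[1] < 1e-9) {
      rs <- c(-rev(rs[-1]), rs); zs <- c(rev(zs[-1]), zs)
    }
    f <- stats::splinefun(rs, zs, method = "fmm")
    rng <- range(d$r)
    function(r) f(pmin(pmax(r, rng[1]), rng[2]))
  }
  ant <- mk("anterior"); post <- mk("posterior")
  rr <- range(tab$r[tab$surface == "anterior"])
  probe <- seq(rr[1], rr[2], length.out = 50)
  if (any(ant(probe) <= post(probe)))
    stop("anterior contour must lie above the posterior contour",
         call. = FALSE)
  structure(list(anterior = ant, posterior = post, r_range = rr,
                 DefA = contours$DefA, CCT = contours$CCT,
                 iop_MPa = contours$iop_MPa, factor = contours$factor),
            class = "stamp_pair")
}

# surface node sets the stamps act on (corneal part, by reference radius)
morph_surface_nodes <- function(model, r_max) {
  pick <- function(facets) {
    nn <- sort(unique(as.vector(facets)))
    r <- sqrt(model$nodes[nn, 1]^2 + model$nodes[nn, 2]^2)
    nn[r <= r_max + 1e-9]
  }
  list(anterior = pick(model$facet_sets$anterior),
       posterior = pick(model$cavity$facets))
}

# Max |J - 1| of a group, evaluated at the element-centroid (volumetric)
# quadrature point. The mean-dilatation element enforces incompressibility
# on the centroid J; the full Gauss points additionally carry the
# bending-parasitic volume change that the scheme deliberately filters, so
# the centroid is the scheme-consistent incompressibility diagnostic.
max_volume_deviation <- function(model, U, group = "cornea") {
  g <- model$groups[[group]]
  Ue <- gather_elem(U, g$conn)
  F <- hex_def_gradient(g$pre$ctr, Ue)
  max(abs(m33_det(F) - 1))
}

#' Morph the full displacement field onto measured contours
#'
#' Iteratively imposes, on each anterior/posterior corneal surface node,
#' the vertical coordinate of the respective stamp evaluated at the node's
#' current horizontal position, leaving the horizontal motion free
#' (vertical force transmission with horizontal sliding). The equilibrium
#' of the quasi-incompressible morph model under these constraints and the
#' coupled cavity pressure yields the representative full field; the
#' sliding loop repeats until the prescribed vertical values stabilize.
#'
#' @param pre A [prestress_eye()] bundle of the morph model (built with
#'   [morph_material()] for the cornea).
#' @param stamps A [extrude_stamps()] result.
#' @param tol_vertical Convergence bound on the vertical imprint residual
#'   (mm; default 1e-3 mm = 1 um).
#' @param tol_horizontal Bound on the horizontal position change between
#'   sliding iterations (mm; default 1e-4 mm = 0.1 um).
#' @param max_sliding Maximum sliding iterations.
#' @return A `"morph_result"`: `U_morph` (total displacement from the
#'   stress-free reference), `U_rel` (relative to the prestressed state),
#'   `iop_MPa` (updated cavity pressure), `vertical_residual` (mm),
#'   `max_J_dev` (max |J-1| over corneal quadrature points),
#'   `iterations`.
#' @export
morph_full_field <- function(pre, stamps, tol_vertical = 1e-3,
                             tol_horizontal = 1e-4, max_sliding = 30) {
  model <- pre$model
  X0 <- model$nodes
  surf <- morph_surface_nodes(model, min(stamps$r_range[2],
                                         model$params$limbus_start))
  zdof <- function(nodes) 3L * (nodes - 1L) + 3L
  dofs <- c(zdof(surf$anterior), zdof(surf$posterior))

  U <- pre$U_pre
  prev_vals <- NULL
  target_vals <- function(U) {
    xy <- X0 + U
    r_ant <- sqrt(xy[surf$anterior, 1]^2 + xy[surf$anterior, 2]^2)
    r_post <- sqrt(xy[surf$posterior, 1]^2 + xy[surf$posterior, 2]^2)
    c(stamps$anterior(r_ant) - X0[surf$anterior, 3],
      stamps$posterior(r_post) - X0[surf$posterior, 3])
  }
  # Warm start that drags the interior node layers along with the surface
  # prescription (linear blend through the thickness); without it the thin
  # corneal elements invert when the surface DOFs jump.
  n_plan <- model$plan$n_plan; nl <- model$plan$nl
  warm_start <- function(U, vals) {
    na <- length(surf$anterior)
    dz_ant <- vals[seq_len(na)] - U[surf$anterior, 3]
    dz_post <- vals[na + seq_along(surf$posterior)] - U[surf$posterior, 3]
    p_ant <- surf$anterior - n_plan * nl    # plan-node ids of the columns
    if (nl > 1) {
      for (l in 1:(nl - 1)) {
        mid <- p_ant + n_plan * l
        U[mid, 3] <- U[mid, 3] + dz_post * (1 - l / nl) + dz_ant * (l / nl)
      }
    }
    U
  }
  # first imprint is ramped from the current surface position to the stamp
  # (a one-shot deep imprint strains the elements too severely)
  vals <- target_vals(U)
  cur <- flatten_disp(U)[dofs]
  n_ramp <- max(1L, ceiling(max(abs(vals - cur)) / 0.25))
  for (k in seq_len(n_ramp)) {
    lam <- k / n_ramp
    v_k <- cur + lam * (vals - cur)
    sol <- newton_solve(model, warm_start(U, v_k),
                        list(pulse = NULL, cavity = "coupled"),
                        prescribed = list(dofs = dofs, values = v_k))
    U <- sol$U
  }
  prev_vals <- vals
  for (it in seq_len(max_sliding)) {
    vals <- target_vals(U)
    dmax <- max(abs(vals - prev_vals))
    if (dmax <= tol_horizontal)
      break   # horizontal positions stabilized; U solves the last imprint
    # sliding corrections concentrate at the steep dimple flank; small
    # prescription sub-steps keep the solves robust there
    nsub <- max(1L, ceiling(dmax / 0.02))
    for (ks in seq_len(nsub)) {
      v_k <- prev_vals + ks / nsub * (vals - prev_vals)
      sol <- newton_solve(model, warm_start(U, v_k),
                          list(pulse = NULL, cavity = "coupled"),
                          prescribed = list(dofs = dofs, values = v_k))
      U <- sol$U
    }
    prev_vals <- vals
    if (it == max_sliding)
      stop("morph sliding iteration did not stabilize", call. = FALSE)
  }
  # verify the imprint: vertical distance of surface nodes to the stamps
  xy <- X0 + U
  vres <- max(abs(c(
    stamps$anterior(sqrt(xy[surf$anterior, 1]^2 + xy[surf$anterior, 2]^2)) -
      xy[surf$anterior, 3],
    stamps$posterior(sqrt(xy[surf$posterior, 1]^2 + xy[surf$posterior, 2]^2)) -
      xy[surf$posterior, 3])))
  if (vres > tol_vertical)
    warning(sprintf("vertical imprint residual %.3g mm exceeds %.3g mm",
                    vres, tol_vertical))
  ce <- cavity_eval(model, U, "coupled")
  structure(list(U_morph = U, U_rel = U - pre$U_pre,
                 iop_MPa = ce$p, volume = ce$V,
                 vertical_residual = vres,
                 max_J_dev = max_volume_deviation(model, U),
                 iterations = it, surface_nodes = surf),
            class = "morph_result")
}

#' @export
print.morph_result <- function(x, ...) {
  cat(sprintf(
    "<morph_result>  max|u| = %.4g mm, IOP = %.3f mmHg\n  vertical residual = %.3g mm, max |J-1| = %.3g, %d sliding iteration(s)\n",
    max(abs(x$U_morph)), MPa_to_mmHg(x$iop_MPa), x$vertical_residual,
    x$max_J_dev, x$iterations))
  invisible(x)
}

#' Contour-only identification through the morphing pipeline
#'
#' Full data-enrichment pipeline: from per-state 2D deformation contours
#' (plus eye geometry, IOP and the known pulse schedule), reconstruct
#' representative 3D displacement fields by mechanical morphing, pair them
#' with the external forces (pulse at the state's load factor, evaluated
#' on the morphed configuration, plus the updated cavity pressure), and
#' run the equilibrium-gap identification with the nested k2 grid search.
#'
#' @param contours List of `"contour_pair"` objects (>= 3 states).
#' @param params [eye_geometry_params()] of the morph model.
#' @param pulse The [pulse_load()] used during acquisition (the device
#'   pressure schedule is known).
#' @param k2_grid Grid for the nested search.
#' @param aux [auxiliary_materials()].
#' @param morph_mat Morph surrogate material.
#' @param morph_pre Optional prestressed morph model (a [prestress_eye()]
#'   bundle built with the morph material); the morph model is
#'   material-independent, so it can be shared across material sets.
#' @param ... Passed to [morph_full_field()].
#' @return A list: `search` (`k2_search`), `morphs` (list of
#'   `morph_result`), `model` (morph model, stress-free reference).
#' @export
enriched_identification <- function(contours, params = eye_geometry_params(),
                                    pulse = pulse_load(),
                                    k2_grid = seq(10, 400, by = 10),
                                    aux = auxiliary_materials(),
                                    morph_mat = morph_material(),
                                    morph_pre = NULL, ...) {
  if (length(contours) < 3)
    stop("enriched identification requires >= 3 contour states",
         call. = FALSE)
  # contours carry the IOP at acquisition (baseline + rise); the morph
  # model is prestressed at the configured baseline IOP
  pre <- if (is.null(morph_pre)) {
    prestress_eye(build_eye_mesh(params, cornea_material = morph_mat,
                                 aux = aux))
  } else morph_pre
  states <- vector("list", length(contours))
  morphs <- vector("list", length(contours))
  for (s in seq_along(contours)) {
    stamps <- extrude_stamps(contours[[s]])
    if (abs(stamps$DefA) < 1e-6)
      stop("zero-deformation contours: nothing to identify", call. = FALSE)
    mr <- morph_full_field(pre, stamps, ...)
    morphs[[s]] <- mr
    f_ext <- facet_pressure_forces(pre$model$nodes,
                                   pre$model$facet_sets$anterior,
                                   mr$U_morph,
                                   function(x) stamps$factor * pulse$fun(x)) +
      mr$iop_MPa * facet_pressure_forces(pre$model$nodes,
                                         pre$model$cavity$facets,
                                         mr$U_morph, 1)
    states[[s]] <- list(U = mr$U_morph, f_ext = f_ext)
  }
  search <- grid_search_k2(pre$model, states, k2_grid)
  list(search = search, morphs = morphs, model = pre$model)
}
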