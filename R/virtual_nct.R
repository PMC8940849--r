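# Virtual non-contact tonometry: prestressing, air-pulse forward runs,
# deformation-state extraction, contours, noise injection and the DefA/PD
# reporting metrics.

#' Surrogate air-pulse load
#'
#' Rotationally symmetric Gaussian pressure profile
#' `p(r) = peak * exp(-r^2 / (2 width^2))` applied as a follower load on
#' the anterior surface, ramped by a monotone schedule of load factors.
#' The default peak is calibrated once so that the healthy default fixture
#' reaches an apex deflection amplitude of about 1 mm at full load.
#'
#' @param peak Peak pressure (MPa).
#' @param width Gaussian spatial width (mm).
#' @param n_steps Number of ramp steps to full load.
#' @return An object of class `"pulse_load"` with the pressure function
#'   and the ramp factors.
#' @export
pulse_load <- function(peak = 0.020, width = 1.2, n_steps = 8) {
  stopifnot(peak >= 0, width > 0, n_steps >= 1)
  fun <- function(x) peak * exp(-(x[, 1]^2 + x[, 2]^2) / (2 * width^2))
  ramp <- seq_len(n_steps) / n_steps
  structure(list(peak = peak, width = width, fun = fun, ramp = ramp),
            class = "pulse_load")
}

#' Prestress the eye model (stress-free reference + in-vivo state)
#'
#' Convenience wrapper: runs [stress_free_geometry()] and returns a bundle
#' holding the stress-free model (with the cavity reference volume and
#' baseline pressure set from the in-vivo state) and the prestress
#' displacement field.
#'
#' @inheritParams stress_free_geometry
#' @return A `"prestressed_eye"` list: `model`, `U_pre`, `max_dist`,
#'   `target`.
#' @export
prestress_eye <- function(model, iop_mmHg = model$params$iop_mmHg, ...) {
  sf <- stress_free_geometry(model, iop_mmHg = iop_mmHg, ...)
  structure(sf, class = "prestressed_eye")
}

apex_sagitta <- function(model, X_cur, disc_radius = 1.0, min_nodes = 8L) {
  # signed deviation of the central anterior surface from its best-fit
  # plane; positive while the cap is convex (apex above the plane).
  # On coarse meshes the disc is widened to the nearest min_nodes nodes so
  # the plane fit is overdetermined.
  ant_nodes <- sort(unique(as.vector(model$facet_sets$anterior)))
  r_ref <- sqrt(model$nodes[ant_nodes, 1]^2 + model$nodes[ant_nodes, 2]^2)
  r_eff <- max(disc_radius, sort(r_ref)[min(min_nodes, length(r_ref))])
  disc <- ant_nodes[r_ref <= r_eff + 1e-9]
  x <- X_cur[disc, , drop = FALSE]
  # mirror the quarter-model nodes across both symmetry planes so the
  # best-fit plane respects the symmetry of the full problem
  xm <- rbind(x,
              cbind(-x[, 1], x[, 2], x[, 3]),
              cbind(x[, 1], -x[, 2], x[, 3]),
              cbind(-x[, 1], -x[, 2], x[, 3]))
  fit <- stats::lm.fit(cbind(1, xm[, 1], xm[, 2]), xm[, 3])
  res <- fit$residuals
  apex <- which.min(sqrt(model$nodes[disc, 1]^2 + model$nodes[disc, 2]^2))
  list(signed = res[apex], max_abs = max(abs(res)), n_nodes = length(disc))
}

#' Run the virtual tonometry forward simulation
#'
#' Ramps the surrogate air pulse on the prestressed model with the fluid
#' cavity pressure coupled to the displaced volume, then extracts the
#' three reference deformation states: state 1 is the applanation state,
#' state 2 lies halfway (on the load schedule) between applanation and
#' maximum deformation, and state 3 is the maximum deformation. Each state
#' is a converged equilibrium solve, so every stored displacement field is
#' paired with external forces that satisfy the forward solver's residual
#' tolerance -- the precondition for exact equilibrium-gap recovery.
#'
#' @param pre A [prestress_eye()] bundle.
#' @param pulse A [pulse_load()].
#' @param material_tag Label stored in the record (e.g. `"H"`).
#' @param applanation_disc,applanation_tol Central-disc radius (mm) and
#'   sagitta tolerance (mm) of the applanation criterion.
#' @param seed Seed recorded for provenance (generation is deterministic).
#' @return An `"nct_record"`: stress-free `model`, `U_pre`, `states` (list
#'   of 3 with `factor`, `U`, `f_ext`, `p_c`, `V`, `DefA`), `trace`
#'   tibble, per-state `contours`, `pulse`, `material_tag`.
#' @export
run_virtual_nct <- function(pre, pulse = pulse_load(),
                            material_tag = NA_character_,
                            applanation_disc = 1.0, applanation_tol = 5e-3,
                            seed = NA_integer_) {
  model <- pre$model
  X0 <- model$nodes
  apex <- model$node_sets$apex_anterior
  z_apex_invivo <- (X0 + pre$U_pre)[apex, 3]

  mk_step <- function(s) list(pulse = list(fun = pulse$fun, factor = s),
                              cavity = "coupled")
  solve_at <- function(factor, U0) {
    newton_solve(model, U0, mk_step(factor))
  }

  if (pulse$peak == 0) {
    # degenerate pulse: every state equals the prestressed state
    sol <- solve_at(0, pre$U_pre)
    st <- list(factor = 0, U = sol$U, f_ext = sol$f_ext, p_c = sol$p_c,
               V = sol$V, DefA = 0)
    rec <- structure(
      list(model = model, U_pre = pre$U_pre, states = list(st, st, st),
           trace = tibble::tibble(factor = 0, DefA = 0,
                                  iop_mmHg = MPa_to_mmHg(sol$p_c),
                                  volume = sol$V, sagitta = NA_real_),
           pulse = pulse[c("peak", "width")], material_tag = material_tag,
           seed = seed, applanation = NULL,
           z_apex_invivo = z_apex_invivo),
      class = "nct_record")
    rec$contours <- lapply(1:3, function(s) extract_contours(rec, s))
    return(rec)
  }

  U <- pre$U_pre
  hist <- vector("list", length(pulse$ramp))
  for (i in seq_along(pulse$ramp)) {
    sol <- solve_at(pulse$ramp[i], U)
    U <- sol$U
    sg <- apex_sagitta(model, X0 + U, applanation_disc)
    hist[[i]] <- list(factor = pulse$ramp[i], U = U, p_c = sol$p_c,
                      V = sol$V, f_ext = sol$f_ext,
                      DefA = z_apex_invivo - (X0 + U)[apex, 3],
                      sagitta = sg$signed)
  }
  trace <- tibble::tibble(
    factor = vapply(hist, `[[`, 1, "factor"),
    DefA = vapply(hist, `[[`, 1, "DefA"),
    iop_mmHg = MPa_to_mmHg(vapply(hist, `[[`, 1, "p_c")),
    volume = vapply(hist, `[[`, 1, "V"),
    sagitta = vapply(hist, `[[`, 1, "sagitta"))

  det <- detect_applanation(trace, tol = applanation_tol)
  f_app <- det$factor
  f_max <- max(pulse$ramp)
  if (f_app >= f_max)
    stop("cornea does not applanate within the pulse ramp", call. = FALSE)
  f_mid <- (f_app + f_max) / 2

  state_at <- function(factor, U0) {
    sol <- solve_at(factor, U0)
    list(factor = factor, U = sol$U, f_ext = sol$f_ext, p_c = sol$p_c,
         V = sol$V, DefA = z_apex_invivo - (X0 + sol$U)[apex, 3])
  }
  # warm starts from the nearest ramp solution below each target factor
  warm <- function(factor) {
    i <- findInterval(factor, trace$factor)
    if (i < 1) pre$U_pre else hist[[i]]$U
  }
  s1 <- state_at(f_app, warm(f_app))
  s2 <- state_at(f_mid, warm(f_mid))
  s3 <- hist[[length(hist)]]
  s3 <- list(factor = s3$factor, U = s3$U, f_ext = s3$f_ext, p_c = s3$p_c,
             V = s3$V, DefA = s3$DefA)
  states <- list(s1, s2, s3)
  ord <- order(vapply(states, `[[`, 1, "DefA"))
  states <- states[ord]

  rec <- structure(
    list(model = model, U_pre = pre$U_pre, states = states, trace = trace,
         pulse = pulse[c("peak", "width")], material_tag = material_tag,
         seed = seed, applanation = det,
         z_apex_invivo = z_apex_invivo),
    class = "nct_record")
  rec$contours <- lapply(seq_along(states), function(s)
    extract_contours(rec, s))
  rec
}

#' @export
print.nct_record <- function(x, ...) {
  cat("<nct_record> material set:", x$material_tag, "\n")
  cat("  states (factor / DefA mm / IOP mmHg):\n")
  for (s in x$states)
    cat(sprintf("   %5.3f / %6.4f / %6.3f\n", s$factor, s$DefA,
                MPa_to_mmHg(s$p_c)))
  invisible(x)
}

#' Detect the applanation state on a loading trace
#'
#' The cornea is applanated when the central anterior surface deviates
#' from its best-fit plane by less than the sagitta tolerance. The signed
#' central sagitta decreases through zero as the cap flattens and
#' inverts; the crossing load factor is found by linear interpolation
#' between ramp steps.
#'
#' @param trace A tibble with columns `factor` and `sagitta` (signed, mm)
#'   as produced by [run_virtual_nct()].
#' @param tol Sagitta tolerance (mm); `Inf` returns the first step.
#' @return A list with `index` (last step before/at applanation),
#'   `factor` (interpolated load factor) and `sagitta_at_index`.
#' @export
detect_applanation <- function(trace, tol = 5e-3) {
  sg <- trace$sagitta
  if (is.infinite(tol)) return(list(index = 0L, factor = 0,
                                    sagitta_at_index = NA_real_))
  hit <- which(abs(sg) <= tol)
  cross <- which(sg[-1] * sg[-length(sg)] <= 0)
  if (length(hit) == 0 && length(cross) == 0)
    stop("no applanation detected under the given load", call. = FALSE)
  if (length(cross) > 0) {
    i <- cross[1]
    # interpolate the sign change of the central sagitta
    f <- trace$factor[i] + (0 - sg[i]) / (sg[i + 1] - sg[i]) *
      (trace$factor[i + 1] - trace$factor[i])
    return(list(index = i, factor = f, sagitta_at_index = sg[i]))
  }
  i <- hit[1]
  list(index = i, factor = trace$factor[i], sagitta_at_index = sg[i])
}

#' Extract 2D deformation contours in the symmetry plane
#'
#' Returns the ordered (r, z) polylines of the anterior and posterior
#' corneal surfaces sampled at the surface nodes lying in the y = 0
#' symmetry plane, in the deformed configuration of the requested state
#' (state 0 = the undeformed in-vivo configuration).
#'
#' @param record An `nct_record`.
#' @param state State number 1..3, or 0 for the in-vivo configuration.
#' @return A `"contour_pair"`: tibble `contour` (columns `surface`, `r`,
#'   `z`) plus metadata `DefA`, `CCT`, `iop_MPa`, `factor`.
#' @export
extract_contours <- function(record, state) {
  model <- record$model
  if (state == 0) {
    U <- record$U_pre
    DefA <- 0; p_c <- model$cavity$p0; factor <- 0
  } else {
    st <- record$states[[state]]
    U <- st$U; DefA <- st$DefA; p_c <- st$p_c; factor <- st$factor
  }
  x_cur <- model$nodes + U
  surf_nodes <- function(facets) {
    nn <- sort(unique(as.vector(facets)))
    r_ref <- sqrt(model$nodes[nn, 1]^2 + model$nodes[nn, 2]^2)
    keep <- abs(model$nodes[nn, 2]) < 1e-9 &
      r_ref <= model$params$limbus_start + 1e-9
    nn[keep]
  }
  mk <- function(facets, tag) {
    nn <- surf_nodes(facets)
    if (length(nn) == 0) stop("no surface nodes in the symmetry plane",
                              call. = FALSE)
    ord <- order(x_cur[nn, 1])
    tibble::tibble(surface = tag, r = x_cur[nn[ord], 1],
                   z = x_cur[nn[ord], 3])
  }
  contour <- dplyr::bind_rows(mk(model$facet_sets$anterior, "anterior"),
                              mk(model$cavity$facets, "posterior"))
  apex_ant <- contour$z[contour$surface == "anterior"][1]
  apex_post <- contour$z[contour$surface == "posterior"][1]
  structure(list(contour = contour, DefA = DefA,
                 CCT = apex_ant - apex_post,
                 iop_MPa = p_c, factor = factor),
            class = "contour_pair")
}

#' Add uniform absolute noise to a displacement field
#'
#' Each displacement component is perturbed independently by a uniform
#' random offset in `[-amplitude, amplitude]`; no smoothing or
#' regularization is applied. Deterministic for a fixed seed.
#'
#' @param U Nodal displacement matrix (N x 3, mm).
#' @param amplitude Noise amplitude (mm); `1e-5` mm corresponds to the
#'   0.01 um study level, `1e-4` mm to 0.1 um.
#' @param seed Integer seed.
#' @return The perturbed displacement matrix.
#' @export
add_noise <- function(U, amplitude, seed) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(U)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  U + matrix(stats::runif(length(U), -amplitude, amplitude), nrow(U), 3)
}

#' Deflection amplitude and peak distance of a deformation state
#'
#' `DefA` is the apex deflection along the symmetry axis relative to the
#' in-vivo configuration. `PD` is the in-plane distance between the two
#' bending maxima of the anterior contour flanking the indented apex; by
#' symmetry of the quarter model the maxima are mirror images, so `PD`
#' equals twice the radius of the local maximum of the deformed contour
#' height. Its resolution is limited by the surface node spacing, which is
#' reported alongside.
#'
#' @param record An `nct_record`.
#' @param state State number (1..3).
#' @return A tibble with `DefA`, `PD`, `PD_resolution` (node spacing, mm)
#'   and `PD_defined`.
#' @export
compute_defa_pd <- function(record, state) {
  cp <- record$contours[[state]]
  ant <- cp$contour[cp$contour$surface == "anterior", ]
  z <- ant$z; r <- ant$r
  n <- length(z)
  pd <- NA_real_; defined <- FALSE
  if (n >= 3) {
    interior <- 2:(n - 1)
    locmax <- interior[z[interior] > z[interior - 1] &
                       z[interior] >= z[interior + 1]]
    if (length(locmax) > 0) {
      pd <- 2 * r[locmax[1]]
      defined <- TRUE
    }
  }
  tibble::tibble(DefA = cp$DefA, PD = pd,
                 PD_resolution = if (n > 1) stats::median(diff(r)) else NA_real_,
                 PD_defined = defined)
}
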