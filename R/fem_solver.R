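# Forward Newton solver. Used only for synthetic data generation, the
# stress-free geometry iteration and the morphing module; the inverse
# identification itself never solves a forward problem.

#' mmHg to MPa conversion constant
#'
#' Defined once for the whole package: 1 mmHg = 133.322e-6 MPa.
#' @param p Pressure in mmHg.
#' @return Pressure in MPa.
#' @export
mmHg_to_MPa <- function(p) p * 133.322e-6

#' @rdname mmHg_to_MPa
#' @export
MPa_to_mmHg <- function(p) p / 133.322e-6

# Current cavity volume and pressure.
# mode "fixed": pressure prescribed (stress-free phase);
# mode "coupled": p = p0 + K_W (V0 - V) / V0 (linearized compressible fluid).
cavity_eval <- function(model, U, mode = c("coupled", "fixed"), p_fix = NULL) {
  mode <- match.arg(mode)
  cav <- model$cavity
  V <- cav$closure + facet_cavity_volume(model$nodes, cav$facets, U)
  p <- if (mode == "fixed") p_fix else cav$p0 + cav$KW * (cav$V0 - V) / cav$V0
  list(V = V, p = p)
}

#' Cavity state (volume and pressure) for a displacement field
#'
#' Volume by a divergence-theorem surface integral over the deformed wetted
#' surface (symmetry planes contribute zero, the fixed closure surface a
#' constant); pressure from the linear pressure-volume law
#' `p = p0 + K_W (V0 - V) / V0`.
#'
#' @param model An eye model with a fluid cavity.
#' @param U Nodal displacement matrix (N x 3, mm).
#' @return A list with `volume` (mm^3) and `pressure` (MPa).
#' @export
cavity_state <- function(model, U) {
  ce <- cavity_eval(model, U, "coupled")
  list(volume = ce$V, pressure = ce$p)
}

# External forces for a loading description:
# ext = list(pulse = list(fun = function(x) p(x), factor = s) or NULL,
#            cavity = "coupled" | "fixed" | "off", p_fix = <MPa>)
external_forces <- function(model, U, ext) {
  ndof <- model_ndof(model)
  f <- numeric(ndof)
  p_c <- NA_real_; V <- NA_real_; g <- NULL
  if (!is.null(ext$pulse) && ext$pulse$factor != 0) {
    s <- ext$pulse$factor; pf <- ext$pulse$fun
    f <- f + facet_pressure_forces(model$nodes, model$facet_sets$anterior, U,
                                   function(x) s * pf(x))
  }
  cmode <- if (is.null(ext$cavity)) "off" else ext$cavity
  f_up <- NULL; g_vol <- NULL
  if (cmode != "off") {
    ce <- cavity_eval(model, U, cmode, ext$p_fix)
    p_c <- ce$p; V <- ce$V
    f_up <- facet_pressure_forces(model$nodes, model$cavity$facets, U, 1)
    f <- f + p_c * f_up
    if (cmode == "coupled")
      g_vol <- facet_volume_gradient(model$nodes, model$cavity$facets, U)
  }
  list(f_ext = f, p_c = p_c, V = V, f_up = f_up, g_vol = g_vol)
}

residual_tangent <- function(model, U, ext, p_c) {
  K <- assemble_tangent(model, U)
  if (!is.null(ext$pulse) && ext$pulse$factor != 0) {
    s <- ext$pulse$factor; pf <- ext$pulse$fun
    K <- K - facet_tangent_fd(model$nodes, model$facet_sets$anterior, U,
                              function(x) s * pf(x))
  }
  cmode <- if (is.null(ext$cavity)) "off" else ext$cavity
  if (cmode != "off" && is.finite(p_c) && p_c != 0) {
    K <- K - p_c * facet_tangent_fd(model$nodes, model$cavity$facets, U, 1)
  }
  K
}

free_dof_set <- function(model, prescribed = NULL) {
  fixed <- model$bc$fixed_dofs
  if (!is.null(prescribed)) fixed <- union(fixed, prescribed$dofs)
  setdiff(seq_len(model_ndof(model)), fixed)
}

# One equilibrium solve at a fixed loading. U0 is the warm start (N x 3).
# prescribed = list(dofs, values) for inhomogeneous Dirichlet data.
newton_solve <- function(model, U0, ext, prescribed = NULL,
                         rtol = 1e-8, atol = 1e-10, max_iter = 30,
                         step_cap = 0.2, quiet = TRUE) {
  u <- flatten_disp(U0)
  if (!is.null(prescribed)) u[prescribed$dofs] <- prescribed$values
  free <- free_dof_set(model, prescribed)
  cmode <- if (is.null(ext$cavity)) "off" else ext$cavity
  rank1 <- cmode == "coupled"
  c_rank1 <- if (rank1) model$cavity$KW / model$cavity$V0 else 0

  res_eval <- function(u) {
    U <- unflatten_disp(u)
    fi <- assemble_internal_forces(model, U)
    exf <- external_forces(model, U, ext)
    list(R = fi - exf$f_ext, ex = exf, U = U)
  }

  st <- res_eval(u)
  lu_fac <- NULL      # cached factorization (modified Newton)
  fresh <- FALSE
  for (it in seq_len(max_iter)) {
    rn <- sqrt(sum(st$R[free]^2))
    fn <- sqrt(sum(st$ex$f_ext[free]^2))
    if (rn <= rtol * fn + atol) {
      return(list(U = st$U, converged = TRUE, iterations = it - 1L,
                  residual_norm = rn, fext_norm = fn,
                  p_c = st$ex$p_c, V = st$ex$V, f_ext = st$ex$f_ext))
    }
    if (is.null(lu_fac)) {
      K <- residual_tangent(model, st$U, ext, st$ex$p_c)
      lu_fac <- Matrix::lu(K[free, free, drop = FALSE])
      fresh <- TRUE
    } else fresh <- FALSE
    rhs <- st$R[free]
    if (rank1 && !is.null(st$ex$g_vol)) {
      # pressure-volume coupling: d f_ext/du has the rank-one part
      # f_up * dp/du^T with dp/du = -(K_W/V0) dV/du; Sherman-Morrison
      uf <- st$ex$f_up[free]
      wf <- c_rank1 * st$ex$g_vol[free]
      a1 <- as.numeric(Matrix::solve(lu_fac, rhs))
      a2 <- as.numeric(Matrix::solve(lu_fac, uf))
      denom <- 1 + sum(wf * a2)
      du <- -(a1 - sum(wf * a1) / denom * a2)
    } else {
      du <- -as.numeric(Matrix::solve(lu_fac, rhs))
    }
    # cap the step length (mm) to keep the iterates in the region where
    # the finite-rotation kinematics stay sane
    du_max <- max(abs(du))
    if (is.finite(step_cap) && du_max > step_cap)
      du <- du * (step_cap / du_max)
    # non-monotone safeguarded step: accept the full Newton step unless it
    # inverts elements or blows the residual up badly (strict monotone
    # backtracking stalls on the strongly nonlinear dimple formation)
    step <- 1; best <- NULL
    for (ls in 1:10) {
      u_try <- u
      u_try[free] <- u[free] + step * du
      st_try <- tryCatch(res_eval(u_try), error = function(e) NULL)
      if (!is.null(st_try)) {
        rn_try <- sqrt(sum(st_try$R[free]^2))
        if (rn_try < 10 * rn || step < 1 / 512) {
          best <- list(u = u_try, st = st_try); break
        }
        if (is.null(best)) best <- list(u = u_try, st = st_try)
      }
      step <- step / 2
    }
    if (is.null(best)) {
      if (!fresh) { lu_fac <- NULL; next }  # retry with a fresh tangent
      stop("Newton step failed (element inversion at all step sizes)",
           call. = FALSE)
    }
    rn_new <- sqrt(sum(best$st$R[free]^2))
    if (!fresh && rn_new > 0.9 * rn) {
      # a reused tangent may not produce descent: reject and retry fresh
      lu_fac <- NULL
      next
    }
    u <- best$u; st <- best$st
    # keep the factorization only while the contraction stays strong
    if (rn_new > 0.3 * rn) lu_fac <- NULL
    if (!quiet) message(sprintf("  newton it %d: |R| = %.3e%s", it, rn_new,
                                if (fresh) "" else " (reused tangent)"))
  }
  rn <- sqrt(sum(st$R[free]^2))
  stop(sprintf("Newton did not converge in %d iterations (|R| = %.3e, tol = %.3e)",
               max_iter, rn, rtol * sqrt(sum(st$ex$f_ext[free]^2)) + atol),
       call. = FALSE)
}

#' Forward solve over a load schedule
#'
#' Runs a sequence of equilibrium solves (Newton with finite-difference
#' consistent tangent, backtracking line search, warm starts) at increasing
#' load factors. Each converged step satisfies
#' `||R||_free <= rtol * ||f_ext||_free + atol`.
#'
#' @param model An eye model.
#' @param schedule A list of load-step descriptions, each a list with
#'   entries `pulse` (list `fun`, `factor` or NULL), `cavity`
#'   (`"coupled"`, `"fixed"` or `"off"`), `p_fix` (MPa, for fixed mode).
#' @param U0 Warm-start displacements (defaults to zero).
#' @param rtol,atol Residual tolerances (relative to the external force
#'   norm; absolute in N).
#' @return A list with `history` (list of per-step solutions with `U`,
#'   `p_c`, `V`, `f_ext`, convergence diagnostics) and `U` (final).
#' @export
solve_forward <- function(model, schedule, U0 = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  if (is.null(U0)) U0 <- matrix(0, nrow(model$nodes), 3)
  hist <- vector("list", length(schedule))
  U <- U0
  for (s in seq_along(schedule)) {
    step <- schedule[[s]]
    sol <- newton_solve(model, U, step,
                        prescribed = step$prescribed,
                        rtol = rtol, atol = atol)
    U <- sol$U
    hist[[s]] <- c(sol, list(step = s,
                             factor = if (is.null(step$pulse)) 0
                                      else step$pulse$factor))
  }
  list(history = hist, U = U)
}
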