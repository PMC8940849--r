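# Equilibrium gap method: assemble the parameter-sensitivity force vectors
# c_K, c_mu, c_k1 from a known displacement field and solve the convex
# least-squares problem for the linear parameters (K, mu, k1). No forward
# problem is solved anywhere in this file.

#' Assemble the parameter-sensitivity force vectors
#'
#' Because the Cauchy stress of the cornea model is exactly linear in
#' `(K, mu, k1)` at fixed `k2`, the corneal internal force vector splits
#' additively: `f_int = K c_K + mu c_mu + k1 c_k1`. Each `c_i` equals the
#' assembled internal force (i.e. the discrete residual with zero external
#' forces) evaluated at the given displacement field with the associated
#' parameter set to one and the others to zero. The internal forces of the
#' non-corneal components (known moduli) are returned separately so they
#' can be folded into the effective external force, keeping the unknown
#' vector strictly 3-dimensional.
#'
#' Rows at Dirichlet/symmetry-constrained DOFs carry unknown reactions and
#' are removed through the DOF mask.
#'
#' @param model An eye model (reference = stress-free geometry).
#' @param U Nodal displacement matrix relative to the model reference
#'   (N x 3, mm).
#' @param k2 Fiber nonlinearity held fixed during the linear
#'   identification.
#' @return A `"sensitivity_matrices"` list: `c_K`, `c_mu`, `c_k1`
#'   (full-length vectors, N), `f_known` (internal forces of known
#'   components), `mask` (identification DOF indices).
#' @export
compute_sensitivity_vectors <- function(model, U, k2) {
  comps <- assemble_force_components(model, U, group = "cornea", k2 = k2)
  f_known <- numeric(model_ndof(model))
  for (g in setdiff(names(model$groups), "cornea"))
    f_known <- f_known + assemble_group_forces(model, U, g)
  mask <- setdiff(seq_len(model_ndof(model)), model$bc$fixed_dofs)
  structure(list(c_K = comps$c_K, c_mu = comps$c_mu, c_k1 = comps$c_k1,
                 f_known = f_known, mask = mask, k2 = k2),
            class = "sensitivity_matrices")
}

#' Solve the equilibrium-gap least-squares problem for (K, mu, k1)
#'
#' Minimizes `||K c_K + mu c_mu + k1 c_k1 - f_eff||^2` over the
#' identification DOFs, where `f_eff` is the effective external force
#' (applied loads + cavity pressure - known-component internal forces).
#' The problem is convex with a unique optimum given full column rank;
#' it is solved through the scaled 3x3 normal equations. If any parameter
#' comes out negative, the problem is re-solved under the non-negativity
#' constraints `K, mu, k1 >= 0` by exhaustive active-set enumeration and
#' the active constraints are flagged.
#'
#' @param S A [compute_sensitivity_vectors()] result.
#' @param f_ext Global external force vector paired with the displacement
#'   field (length 3N, in N).
#' @return An `"egm_fit"` with the identified parameters, residual norms
#'   and flags.
#' @export
solve_linear_parameters <- function(S, f_ext) {
  mask <- S$mask
  A <- cbind(K = S$c_K[mask], mu = S$c_mu[mask], k1 = S$c_k1[mask])
  b <- (f_ext - S$f_known)[mask]

  norms <- sqrt(colSums(A^2))
  deficient <- names(norms)[norms <= 1e-12 * max(norms, 1e-300)]
  scale <- ifelse(norms > 0, norms, 1)
  As <- sweep(A, 2, scale, "/")
  G <- crossprod(As)
  rhs <- crossprod(As, b)
  cnum <- tryCatch(kappa(G, exact = TRUE), error = function(e) Inf)

  solve_subset <- function(active_zero) {
    keep <- setdiff(1:3, active_zero)
    x <- numeric(3)
    if (length(keep) > 0) {
      xk <- tryCatch(solve(G[keep, keep, drop = FALSE], rhs[keep]),
                     error = function(e) NULL)
      if (is.null(xk) || any(!is.finite(xk))) return(NULL)
      x[keep] <- xk
    }
    if (any(x < -1e-14)) return(NULL)
    x
  }

  x <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (!is.null(x) && any(!is.finite(x))) x <- NULL
  constrained <- logical(3)
  if (is.null(x) || any(x < 0)) {
    # exhaustive active-set search over the 2^3 sign patterns
    best <- NULL; best_obj <- Inf
    for (k in 0:7) {
      zero <- which(bitwAnd(k, c(1L, 2L, 4L)) > 0)
      cand <- solve_subset(zero)
      if (is.null(cand)) next
      obj <- sum((As %*% cand - b)^2)
      if (!is.finite(obj)) next
      if (obj < best_obj) {
        best <- cand; best_obj <- obj
        constrained <- seq_len(3) %in% zero
      }
    }
    if (is.null(best))
      stop("linear identification failed: singular normal equations",
           call. = FALSE)
    x <- best
    constrained <- constrained & (abs(x) < 1e-14)
  }
  par <- unname(as.numeric(x) / as.numeric(scale))
  res <- A %*% par - b
  rn <- sqrt(sum(res^2))
  bn <- sqrt(sum(b^2))
  warn <- character(0)
  if (length(deficient) > 0)
    warn <- c(warn, paste0("rank-deficient sensitivity direction(s): ",
                           paste(deficient, collapse = ", ")))
  structure(list(K = par[1], mu = par[2], k1 = par[3], k2 = S$k2,
                 residual_norm = rn, f_eff_norm = bn,
                 rel_residual = if (bn > 0) rn / bn else NA_real_,
                 constrained = stats::setNames(constrained,
                                               c("K", "mu", "k1")),
                 column_norms = norms, condition = cnum,
                 n_dofs = length(mask), warnings = warn),
            class = "egm_fit")
}

#' @export
print.egm_fit <- function(x, ...) {
  cat(sprintf(
    "<egm_fit>  K = %.6g  mu = %.6g  k1 = %.6g MPa  (k2 = %g fixed)\n",
    x$K, x$mu, x$k1, x$k2))
  cat(sprintf("  relative residual ||R||/||f_eff|| = %.3e over %d DOFs\n",
              x$rel_residual, x$n_dofs))
  if (any(x$constrained))
    cat("  active non-negativity constraint(s):",
        paste(names(x$constrained)[x$constrained], collapse = ", "), "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy egm_fit
#' @export
tidy.egm_fit <- function(x, ...) {
  tibble::tibble(term = c("K", "mu", "k1"),
                 estimate = c(x$K, x$mu, x$k1),
                 unit = "MPa",
                 constrained = as.logical(x$constrained))
}

#' @method glance egm_fit
#' @export
glance.egm_fit <- function(x, ...) {
  tibble::tibble(k2 = x$k2, residual_norm = x$residual_norm,
                 rel_residual = x$rel_residual, condition = x$condition,
                 n_dofs = x$n_dofs, n_warnings = length(x$warnings))
}

#' Identify linear parameters independently for several deformation states
#'
#' Runs the equilibrium-gap identification separately for each stored
#' `(u, f_ext)` pair at a common fixed `k2`. The spread of the resulting
#' parameter triples across states is the information the nested `k2`
#' search exploits.
#'
#' @param model Eye model (stress-free reference).
#' @param states List of states, each a list with `U` (N x 3 displacement
#'   from the stress-free reference) and `f_ext` (paired external force
#'   vector).
#' @param k2 Fixed fiber nonlinearity.
#' @return A tibble with one row per state: `state`, `K`, `mu`, `k1`,
#'   `rel_residual`, `constrained`, plus the fits in a list column.
#' @export
identify_states <- function(model, states, k2) {
  stopifnot(length(states) >= 1)
  fits <- lapply(seq_along(states), function(s) {
    st <- states[[s]]
    S <- compute_sensitivity_vectors(model, st$U, k2)
    solve_linear_parameters(S, st$f_ext)
  })
  tibble::tibble(
    state = seq_along(states),
    K = vapply(fits, `[[`, 1, "K"),
    mu = vapply(fits, `[[`, 1, "mu"),
    k1 = vapply(fits, `[[`, 1, "k1"),
    rel_residual = vapply(fits, `[[`, 1, "rel_residual"),
    constrained = vapply(fits, function(f) any(f$constrained), TRUE),
    fit = fits)
}

#' Identify linear parameters from a virtual tonometry record
#'
#' Tidy front end to [identify_states()] on the three deformation states
#' of an [run_virtual_nct()] record.
#'
#' @param record An `nct_record`.
#' @param k2 Fixed fiber nonlinearity (defaults to the generating value
#'   stored in the record's model).
#' @param noise_amplitude,noise_seed Optional uniform displacement noise
#'   applied before identification (see [add_noise()]).
#' @return A tibble as returned by [identify_states()].
#' @export
egm_identify <- function(record, k2 = record$model$groups$cornea$material$k2,
                         noise_amplitude = 0, noise_seed = 1L) {
  states <- lapply(seq_along(record$states), function(s) {
    st <- record$states[[s]]
    U <- st$U
    if (noise_amplitude > 0)
      U <- add_noise(U, noise_amplitude, noise_seed + 1000L * s)
    list(U = U, f_ext = st$f_ext)
  })
  identify_states(record$model, states, k2)
}
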