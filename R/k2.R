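# Nested identification of the nonlinear fiber parameter k2: for each
# candidate k2 the linear parameters are identified independently per
# deformation state; the relative scatter of the state-wise parameter sets
# is the outer objective, minimized by a grid search.

pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

.zero_mean_guard <- 1e-12

#' Relative-scatter objective for the nonlinear parameter
#'
#' `f_rel(k2) = sum_i sd(alpha_i) / |mean(alpha_i)|` over the three linear
#' parameters `alpha = (K, mu, k1)`, where standard deviation and mean are
#' taken across the deformation states at the linear identification
#' performed with the candidate `k2`. The population standard deviation
#' (divide by the number of states) is used. At the generating `k2` all
#' states must yield the same parameters, so `f_rel` vanishes there up to
#' solver tolerances; a wrong `k2` mis-attributes the fiber nonlinearity
#' and the per-state identifications scatter.
#'
#' If a parameter mean is below `1e-12` MPa in magnitude, the term is
#' guarded (divided by `1e-12` instead of the mean) so the objective flags
#' the degeneracy rather than dividing by zero.
#'
#' @param model Eye model (stress-free reference).
#' @param states List of `(U, f_ext)` states, `m >= 3` recommended.
#' @param k2 Candidate fiber nonlinearity.
#' @return A list: `f_rel` (scalar), `params` (the per-state tibble).
#' @export
f_rel <- function(model, states, k2) {
  tab <- identify_states(model, states, k2)
  f_rel_from_params(tab)
}

f_rel_from_params <- function(tab) {
  val <- 0
  for (p in c("K", "mu", "k1")) {
    x <- tab[[p]]
    m <- mean(x)
    denom <- if (abs(m) < .zero_mean_guard) .zero_mean_guard else abs(m)
    val <- val + pop_sd(x) / denom
  }
  list(f_rel = val, params = tab)
}

#' Grid search for the nonlinear fiber parameter k2
#'
#' Evaluates the relative-scatter objective on a grid of `k2` values
#' (default 10 to 400 in steps of 10) and returns the grid argmin together
#' with the full curve. The objective is typically non-convex with a
#' secondary local minimum toward `k2 -> 0`, so a grid over the whole
#' physiological range is used rather than a local descent.
#'
#' When the identified fiber stiffness is negligible (averaged
#' `k1 < k1_threshold`), the fiber term of the energy is switched off and
#' `k2` has no influence on the residual; the result is then flagged
#' unidentifiable.
#'
#' @param model Eye model (stress-free reference).
#' @param states List of `(U, f_ext)` states (`m >= 3` for a meaningful
#'   scatter; fewer states raise an error).
#' @param k2_grid Numeric grid of candidate values.
#' @param k1_threshold Identifiability threshold on the averaged `k1`
#'   (MPa).
#' @param ambiguity_tol Relative band for flagging near-equal multiple
#'   local minima.
#' @return A `"k2_search"`: `curve` tibble (`k2`, `f_rel`, per-state
#'   parameters nested), `k2_hat`, `params_at_min` (tibble),
#'   `params_mean`, `identifiable`, `ambiguous`.
#' @export
grid_search_k2 <- function(model, states, k2_grid = seq(10, 400, by = 10),
                           k1_threshold = 1e-3, ambiguity_tol = 0.05) {
  stopifnot(length(k2_grid) >= 1)
  if (length(states) < 3)
    stop("k2 identification requires at least 3 deformation states",
         call. = FALSE)
  evals <- lapply(k2_grid, function(k2) f_rel(model, states, k2))
  fr <- vapply(evals, `[[`, 1, "f_rel")
  imin <- which.min(fr)
  params_at_min <- evals[[imin]]$params
  params_mean <- c(K = mean(params_at_min$K), mu = mean(params_at_min$mu),
                   k1 = mean(params_at_min$k1))
  identifiable <- params_mean[["k1"]] >= k1_threshold
  # local minima of the sampled curve (interior points)
  n <- length(fr)
  loc <- if (n >= 3) {
    which(fr[2:(n - 1)] <= fr[1:(n - 2)] & fr[2:(n - 1)] <= fr[3:n]) + 1L
  } else integer(0)
  near <- loc[fr[loc] <= fr[imin] * (1 + ambiguity_tol) + 1e-30]
  ambiguous <- length(unique(c(near, imin))) > 1
  structure(list(
    curve = tibble::tibble(k2 = k2_grid, f_rel = fr,
                           params = lapply(evals, `[[`, "params")),
    k2_hat = k2_grid[imin],
    f_rel_min = fr[imin],
    params_at_min = params_at_min,
    params_mean = params_mean,
    identifiable = identifiable,
    ambiguous = ambiguous,
    k1_threshold = k1_threshold),
    class = "k2_search")
}

#' @export
print.k2_search <- function(x, ...) {
  cat(sprintf("<k2_search>  k2_hat = %g  (f_rel = %.3e)\n",
              x$k2_hat, x$f_rel_min))
  cat(sprintf("  mean linear parameters at argmin: K = %.5g, mu = %.5g, k1 = %.5g MPa\n",
              x$params_mean[["K"]], x$params_mean[["mu"]],
              x$params_mean[["k1"]]))
  if (!x$identifiable)
    cat("  NOTE: averaged k1 below", x$k1_threshold,
        "MPa -- k2 is not identifiable (fiber term inactive)\n")
  if (x$ambiguous)
    cat("  NOTE: multiple near-minimal local minima on the grid\n")
  invisible(x)
}

#' @method tidy k2_search
#' @export
tidy.k2_search <- function(x, ...) {
  x$curve[, c("k2", "f_rel")]
}

#' @method glance k2_search
#' @export
glance.k2_search <- function(x, ...) {
  tibble::tibble(k2_hat = x$k2_hat, f_rel_min = x$f_rel_min,
                 K = x$params_mean[["K"]], mu = x$params_mean[["mu"]],
                 k1 = x$params_mean[["k1"]],
                 identifiable = x$identifiable, ambiguous = x$ambiguous)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the relative-scatter curve of a k2 grid search
#'
#' @param object A [grid_search_k2()] result.
#' @param ... Unused.
#' @return A ggplot: `f_rel` over `k2` on a log scale with the argmin
#'   marked.
#' @method autoplot k2_search
#' @export
autoplot.k2_search <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k2, y = .data$f_rel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$k2_hat, linetype = 2,
                        colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(k[2]),
                  y = expression(f[rel]),
                  title = "Relative scatter of state-wise linear parameters",
                  subtitle = sprintf("argmin at k2 = %g", object$k2_hat)) +
    ggplot2::theme_minimal()
}

#' Full nested identification on a record
#'
#' Convenience wrapper: grid search for `k2` on the three deformation
#' states of a virtual tonometry record.
#'
#' @param record An `nct_record`.
#' @inheritParams grid_search_k2
#' @return A `"k2_search"`.
#' @export
egm_identify_k2 <- function(record, k2_grid = seq(10, 400, by = 10), ...) {
  states <- lapply(record$states, function(st) list(U = st$U,
                                                    f_ext = st$f_ext))
  grid_search_k2(record$model, states, k2_grid, ...)
}
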