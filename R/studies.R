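# Study runners: end-to-end record generation, the linear-parameter
# recovery study across material sets, and the displacement-noise study.

#' Generate a reference virtual tonometry record for a material set
#'
#' End-to-end generator: build the fixture with the requested material
#' set, recover the stress-free geometry, run the virtual tonometry
#' forward simulation and extract the three deformation states.
#'
#' @param set Material set name (`"H"`, `"KK-I"`, `"KK-II"`, `"KK-III"`)
#'   or a [material_parameters()] object.
#' @param params [eye_geometry_params()].
#' @param pulse [pulse_load()].
#' @param aux [auxiliary_materials()].
#' @param seed Seed recorded in the record (generation is deterministic;
#'   the seed matters for downstream noise studies).
#' @return An `nct_record`.
#' @export
generate_reference_record <- function(set = "H",
                                      params = eye_geometry_params(),
                                      pulse = pulse_load(),
                                      aux = auxiliary_materials(),
                                      seed = 1L) {
  mat <- if (inherits(set, "material_parameters")) set
         else reference_material(set)
  tag <- if (is.character(set)) set else NA_character_
  model <- build_eye_mesh(params, cornea_material = mat, aux = aux)
  pre <- prestress_eye(model)
  run_virtual_nct(pre, pulse, material_tag = tag, seed = seed)
}

#' Linear-parameter recovery study across material sets
#'
#' Generates (or takes) one record per material set, identifies the
#' linear parameters per deformation state at the generating `k2`, and
#' tabulates identified vs. generating values with relative errors.
#'
#' @param records Named list of `nct_record`s (names = set labels). If
#'   `NULL`, records for `sets` are generated with the given fixture
#'   settings.
#' @param sets Material set names to generate when `records` is `NULL`.
#' @param k2 Fixed nonlinearity used in the identifications.
#' @inheritParams generate_reference_record
#' @return A tibble with one row per set and state: identified `K`, `mu`,
#'   `k1`, generating values, and relative errors (`NA` where the
#'   generating value is zero); attribute `"seed"` records provenance.
#' @export
run_recovery_study <- function(records = NULL,
                               sets = c("H", "KK-I", "KK-II", "KK-III"),
                               k2 = 200,
                               params = eye_geometry_params(),
                               pulse = pulse_load(),
                               seed = 1L) {
  if (is.null(records)) {
    records <- lapply(sets, generate_reference_record, params = params,
                      pulse = pulse, seed = seed)
    names(records) <- sets
  }
  rows <- lapply(names(records), function(set) {
    rec <- records[[set]]
    gen <- rec$model$groups$cornea$material
    tab <- egm_identify(rec, k2 = k2)
    dplyr::mutate(tab[, c("state", "K", "mu", "k1", "rel_residual")],
                  set = set,
                  K_gen = gen$K, mu_gen = gen$mu, k1_gen = gen$k1,
                  K_err = (.data$K - gen$K) / gen$K,
                  mu_err = (.data$mu - gen$mu) / gen$mu,
                  k1_err = if (gen$k1 > 0) (.data$k1 - gen$k1) / gen$k1
                           else NA_real_,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "k2") <- k2
  out
}

#' Displacement-noise sensitivity study
#'
#' For each noise amplitude, runs `repetitions` seeded identifications of
#' the linear parameters on the (healthy) record with uniform noise added
#' to the stored displacement fields (external forces keep their paired
#' values), and summarizes the per-parameter mean and twofold standard
#' deviation over the repetitions.
#'
#' @param record An `nct_record` (typically the healthy set).
#' @param amplitudes Noise amplitudes (mm); the defaults are the 0.01 um
#'   and 0.1 um study levels.
#' @param repetitions Seeded repetitions per amplitude.
#' @param k2 Fixed nonlinearity.
#' @param seed Base seed; repetition `r` at amplitude index `a` uses
#'   `seed + 10000 * a + r`.
#' @return A `"noise_study"`: `summary` tibble (per amplitude and
#'   parameter: mean, `two_sd`, fraction of repetitions within +-10% of
#'   the generating value for all three parameters), `runs` tibble (every
#'   repetition), generating values.
#' @export
run_noise_study <- function(record, amplitudes = c(0, 1e-5, 1e-4),
                            repetitions = 10, k2 = 200, seed = 1L) {
  stopifnot(repetitions >= 1)
  if (repetitions == 1)
    warning("repetitions = 1: standard deviations are reported as 0")
  gen <- record$model$groups$cornea$material
  gvals <- c(K = gen$K, mu = gen$mu, k1 = gen$k1)
  runs <- list()
  for (a in seq_along(amplitudes)) {
    for (r in seq_len(repetitions)) {
      tab <- egm_identify(record, k2 = k2,
                          noise_amplitude = amplitudes[a],
                          noise_seed = seed + 10000L * a + r)
      est <- c(K = mean(tab$K), mu = mean(tab$mu), k1 = mean(tab$k1))
      within <- all(abs(est - gvals) / pmax(gvals, 1e-12) <= 0.10)
      runs[[length(runs) + 1]] <- tibble::tibble(
        amplitude = amplitudes[a], repetition = r,
        K = est[["K"]], mu = est[["mu"]], k1 = est[["k1"]],
        within_10pct = within)
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    tidyr::pivot_longer(cols = c("K", "mu", "k1"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$amplitude, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value),
                     two_sd = 2 * stats::sd(.data$value),
                     .groups = "drop")
  band <- runs |>
    dplyr::group_by(.data$amplitude) |>
    dplyr::summarise(frac_within_10pct = mean(.data$within_10pct),
                     .groups = "drop")
  structure(list(summary = dplyr::left_join(summary, band, by = "amplitude"),
                 runs = runs, generating = gvals,
                 repetitions = repetitions, k2 = k2, seed = seed),
            class = "noise_study")
}

#' @export
print.noise_study <- function(x, ...) {
  cat("<noise_study> ", x$repetitions, "repetitions per amplitude, k2 =",
      x$k2, "\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy noise_study
#' @export
tidy.noise_study <- function(x, ...) x$summary

#' Plot the noise study (mean +- 2 sd per parameter and amplitude)
#'
#' @param object A [run_noise_study()] result.
#' @param ... Unused.
#' @return A ggplot with one facet per parameter, the identified mean with
#'   twofold-standard-deviation error bars, and the +-10% band around the
#'   generating value.
#' @method autoplot noise_study
#' @export
autoplot.noise_study <- function(object, ...) {
  df <- object$summary
  gv <- tibble::tibble(parameter = names(object$generating),
                       gen = as.numeric(object$generating))
  df <- dplyr::left_join(df, gv, by = "parameter")
  df$amp_label <- factor(sprintf("%g", df$amplitude * 1000),
                         levels = sprintf("%g", sort(unique(df$amplitude)) * 1000))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amp_label, y = .data$mean)) +
    ggplot2::geom_rect(ggplot2::aes(ymin = 0.9 * .data$gen,
                                    ymax = 1.1 * .data$gen),
                       xmin = -Inf, xmax = Inf, fill = "orange",
                       alpha = 0.15) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$gen),
                        linetype = 2, colour = "orange") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$two_sd,
                                          ymax = .data$mean + .data$two_sd)) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = "noise amplitude (µm)",
                  y = "identified value (MPa)",
                  title = "Noise sensitivity of the linear identification",
                  subtitle = sprintf(
                    "mean ± 2 sd over %d repetitions; band: ±10%% of the generating value",
                    object$repetitions)) +
    ggplot2::theme_minimal()
}
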