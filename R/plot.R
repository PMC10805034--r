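#' Plot a simulated fermentation
#'
#' Two-panel view of a simulation: group biomasses on the pseudo-log10
#' bacteria/L scale and selected metabolites in mM, over time in days.
#'
#' @param object A `simulation_result`.
#' @param metabolites Metabolites to show (default: the main SCFAs present).
#' @param cell_mass Cell mass for the abundance conversion, g.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object,
                                       metabolites = NULL,
                                       cell_mass = 4.6e-12, ...) {
  if (is.null(metabolites)) {
    metabolites <- intersect(c("acetate", "propionate", "butyrate",
                               "lactate"), object$species$species)
  }
  mm <- stats::setNames(object$species$molar_mass, object$species$species)
  micro <- dplyr::mutate(object$groups,
                         panel = "microbes (log10 bacteria/L)",
                         value = gl_to_pseudolog10(.data$value_gL,
                                                   cell_mass),
                         series = .data$group)
  met <- dplyr::filter(object$trajectory,
                       .data$variable %in% metabolites)
  met <- dplyr::mutate(met,
                       panel = "metabolites (mM)",
                       value = gl_to_mM(.data$value_gL,
                                        unname(mm[.data$variable])),
                       series = .data$variable)
  dat <- dplyr::bind_rows(
    dplyr::select(micro, "time_h", "panel", "series", "value"),
    dplyr::select(met, "time_h", "panel", "series", "value")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h / 24,
                                    y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (days)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a model-versus-observation comparison report
#'
#' Bar chart of the per-variable RMSE, split by kind (genus pseudo-log10
#' scale vs SCFA mM scale).
#'
#' @param object A `comparison_report` from [compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$matched)
  dat <- dplyr::mutate(dat, variable = stats::reorder(.data$variable,
                                                      .data$rmse))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$variable, y = .data$rmse)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~kind, scales = "free",
                        labeller = ggplot2::as_labeller(
                          c(genus = "genera (log10 bacteria/L)",
                            scfa = "SCFA (mM)"))) +
    ggplot2::labs(x = NULL, y = "RMSE") +
    ggplot2::theme_minimal()
}

#' Tidy and glance methods for comparison reports
#'
#' `tidy()` returns the report as a plain tibble; `glance()` summarizes it
#' to one row (matched variable count, summed and mean RMSE).
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.comparison_report
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_matched = sum(x$matched),
    total_rmse = sum(x$rmse, na.rm = TRUE),
    mean_rmse = mean(x$rmse, na.rm = TRUE)
  )
}

#' @rdname tidy.comparison_report
#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, ...) x$trajectory

#' @rdname tidy.comparison_report
#' @method glance simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble::tibble(
    n_states = ncol(x$states),
    n_groups = length(unique(x$groups$group)),
    duration_h = max(x$time_h),
    final_total_biomass_gL = sum(x$states[nrow(x$states),
                                          seq_along(x$group_of)])
  )
}
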