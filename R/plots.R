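# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an impact report
#'
#' `type = "operation"` shows the signed relative changes of net fluxes and
#' metabolite concentrations caused by the KIEs (in percent);
#' `type = "isotopic"` shows the distribution of signed errors on the three
#' isotopic datasets per metabolite.
#'
#' @param object A `kie_impact`.
#' @param type `"operation"` or `"isotopic"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kie_impact
#' @export
autoplot.kie_impact <- function(object, type = c("operation", "isotopic"), ...) {
  type <- match.arg(type)
  if (type == "operation") {
    df <- dplyr::bind_rows(
      tibble::tibble(dataset = "net flux", id = object$fluxes$reaction,
                     value = 100 * object$fluxes$rel_change),
      tibble::tibble(dataset = "concentration",
                     id = object$concentrations$metabolite,
                     value = 100 * object$concentrations$rel_change))
    ggplot2::ggplot(df[!is.na(df$value), ],
                    ggplot2::aes(x = .data$id, y = .data$value)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~dataset, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "relative change with KIEs (%)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5, hjust = 1))
  } else {
    df <- dplyr::bind_rows(
      tibble::tibble(dataset = "isotopomer",
                     metabolite = object$isotopomers$metabolite,
                     value = object$isotopomers$error),
      tibble::tibble(dataset = "isotopologue",
                     metabolite = object$isotopologues$metabolite,
                     value = object$isotopologues$error),
      tibble::tibble(dataset = "enrichment",
                     metabolite = object$enrichments$metabolite,
                     value = object$enrichments$error))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$value)) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
      ggplot2::facet_wrap(~dataset, ncol = 1) +
      ggplot2::labs(x = NULL, y = "error with KIEs (fraction)") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5, hjust = 1))
  }
}

#' Plot the error distributions of a sensitivity scan
#'
#' Empirical cumulative distributions of the absolute KIE-induced errors,
#' one panel per isotopic dataset.
#'
#' @param object A `kie_sensitivity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kie_sensitivity
#' @export
autoplot.kie_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = abs(.data$error))) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~dataset, scales = "free_x") +
    ggplot2::labs(x = "|error| caused by KIEs",
                  y = "empirical cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Plot a labeling time course
#'
#' Pool-total concentrations (solid) over time; one facet per metabolite.
#'
#' @param object A `kie_trajectory` from [integrate_timecourse()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kie_trajectory
#' @export
autoplot.kie_trajectory <- function(object, ...) {
  totals <- object |>
    dplyr::group_by(.data$time, .data$metabolite) |>
    dplyr::summarise(concentration = sum(.data$concentration), .groups = "drop")
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(x = "time", y = "pool concentration") +
    ggplot2::theme_minimal()
}
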