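# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a steady-state result
#'
#' @param x A `kie_steady_state`.
#' @param ... Unused.
#' @return Tibble of isotopomer concentrations and per-pool fractions.
#' @method tidy kie_steady_state
#' @export
tidy.kie_steady_state <- function(x, ...) {
  x$iso[, c("metabolite", "pattern", "weight", "boundary",
            "concentration", "fraction")]
}

#' One-row summary of a steady-state result
#'
#' @inheritParams tidy.kie_steady_state
#' @return Tibble with convergence metadata and system sizes.
#' @method glance kie_steady_state
#' @export
glance.kie_steady_state <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual = x$residual,
                 time = x$time, kie_on = x$kie_on,
                 n_isotopomers = x$system$n_iso,
                 n_fluxomers = x$system$n_flux)
}

#' Tidy an impact report into one long table
#'
#' @param x A `kie_impact`.
#' @param ... Unused.
#' @return Tibble with `dataset` (flux, concentration, isotopomer,
#'   isotopologue, enrichment), `id` (reaction/metabolite plus pattern or
#'   mass shift where applicable), and `value`: the signed relative change
#'   for fluxes and concentrations, the signed absolute error for isotopic
#'   observables.
#' @method tidy kie_impact
#' @export
tidy.kie_impact <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(dataset = "flux", id = x$fluxes$reaction,
                   value = x$fluxes$rel_change),
    tibble::tibble(dataset = "concentration", id = x$concentrations$metabolite,
                   value = x$concentrations$rel_change),
    tibble::tibble(dataset = "isotopomer",
                   id = paste(x$isotopomers$metabolite, x$isotopomers$pattern),
                   value = x$isotopomers$error),
    tibble::tibble(dataset = "isotopologue",
                   id = paste0(x$isotopologues$metabolite, " M+",
                               x$isotopologues$mass_shift),
                   value = x$isotopologues$error),
    tibble::tibble(dataset = "enrichment", id = x$enrichments$metabolite,
                   value = x$enrichments$error))
}

#' One-row summary of an impact report
#'
#' @inheritParams tidy.kie_impact
#' @return Tibble of the maxima of absolute changes/errors per dataset.
#' @method glance kie_impact
#' @export
glance.kie_impact <- function(x, ...) {
  mx <- function(v) if (all(is.na(v))) NA_real_ else max(abs(v), na.rm = TRUE)
  tibble::tibble(max_flux_change = mx(x$fluxes$rel_change),
                 max_conc_change = mx(x$concentrations$rel_change),
                 max_isotopomer_error = mx(x$isotopomers$error),
                 max_isotopologue_error = mx(x$isotopologues$error),
                 max_enrichment_error = mx(x$enrichments$error))
}

#' Tidy a sensitivity scan
#'
#' @param x A `kie_sensitivity`.
#' @param ... Unused.
#' @return The long error tibble (set, dataset, metabolite, id, error).
#' @method tidy kie_sensitivity
#' @export
tidy.kie_sensitivity <- function(x, ...) x$errors

#' Summarize a sensitivity scan
#'
#' @inheritParams tidy.kie_sensitivity
#' @param thresholds Absolute-error thresholds at which to report the
#'   fraction of observables below each (per dataset).
#' @param ... Unused.
#' @return Tibble per dataset: number of records, quantiles of |error|, and
#'   one `frac_below_*` column per threshold; plus failure count.
#' @method glance kie_sensitivity
#' @export
glance.kie_sensitivity <- function(x, thresholds = c(0.002, 0.003), ...) {
  errs <- x$errors[!is.na(x$errors$error), ]  # undefined (empty-pool) observables
  out <- errs |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(n = dplyr::n(),
                     median_abs = stats::median(abs(.data$error)),
                     q99_abs = stats::quantile(abs(.data$error), 0.99),
                     max_abs = max(abs(.data$error)), .groups = "drop")
  for (th in thresholds) {
    col <- paste0("frac_below_", format(th))
    frac <- errs |>
      dplyr::group_by(.data$dataset) |>
      dplyr::summarise(v = mean(abs(.data$error) < th), .groups = "drop")
    out[[col]] <- frac$v[match(out$dataset, frac$dataset)]
  }
  out$n_failed <- x$n_failed
  out
}
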