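# Derived isotopic datasets: isotopomer fractions, isotopologue (mass-shift)
# distributions, molecular enrichments, fluxes, and with/without-KIE impact
# reports. All are recomputed from concentrations on the fly, never stored
# independently, so distributions are always consistently normalized.

# Accept a steady-state result or any data frame with columns
# metabolite/pattern/concentration; return per-pool fractions.
iso_concentrations <- function(x) {
  if (inherits(x, "kie_steady_state")) {
    return(x$iso[, c("metabolite", "pattern", "concentration")])
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("metabolite", "pattern", "concentration") %in% names(x)))
  x[, c("metabolite", "pattern", "concentration")]
}

#' Isotopomer fractions per pool
#'
#' @param x A `kie_steady_state` or a data frame with columns `metabolite`,
#'   `pattern`, `concentration`.
#' @param metabolite Optional filter (character vector of pool ids).
#' @return Tibble with `metabolite`, `pattern`, `fraction`. Pools with zero
#'   total concentration get `NA` fractions (undefined distribution).
#' @export
isotopomer_fractions <- function(x, metabolite = NULL) {
  tb <- iso_concentrations(x)
  if (!is.null(metabolite)) tb <- tb[tb$metabolite %in% metabolite, ]
  tb |>
    dplyr::mutate(concentration = pmax(.data$concentration, 0)) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::mutate(fraction = if (sum(.data$concentration) > 0)
      .data$concentration / sum(.data$concentration) else NA_real_) |>
    dplyr::ungroup() |>
    dplyr::select("metabolite", "pattern", "fraction")
}

#' Isotopologue (mass-shift) distribution
#'
#' Groups isotopomer fractions by their number of heavy atoms: `M+k` is the
#' summed fraction of all patterns carrying exactly k labels.
#'
#' @inheritParams isotopomer_fractions
#' @return Tibble with `metabolite`, `mass_shift` (0..n), `fraction`.
#' @export
isotopologue_distribution <- function(x, metabolite = NULL) {
  isotopomer_fractions(x, metabolite) |>
    dplyr::mutate(mass_shift = vapply(.data$pattern, pattern_weight,
                                      integer(1), USE.NAMES = FALSE)) |>
    dplyr::group_by(.data$metabolite, .data$mass_shift) |>
    dplyr::summarise(fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::arrange(.data$metabolite, .data$mass_shift)
}

#' Molecular enrichment
#'
#' Mean fraction of heavy atoms per molecule, `sum_k k * (M+k) / n` —
#' equivalently the positional labeling averaged over carbon positions.
#'
#' @inheritParams isotopomer_fractions
#' @return Tibble with `metabolite`, `enrichment` (in `[0, 1]`, `NA` for an
#'   empty pool).
#' @export
molecular_enrichment <- function(x, metabolite = NULL) {
  isotopologue_distribution(x, metabolite) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      enrichment = sum(.data$mass_shift * .data$fraction) / max(.data$mass_shift),
      .groups = "drop")
}

#' Per-reaction fluxes of a converged state
#'
#' Reports, per reaction, the unweighted unidirectional rates `v` of the rate
#' laws and the realized rates `sum_p alpha_r^p f_r^p` actually carried once
#' every fluxomer is weighted by its KIE factor, plus the nets
#' (forward - backward) of both. With all factors at 1 realized and
#' unweighted rates coincide.
#'
#' @param result A `kie_steady_state`.
#' @return Tibble with `reaction`, `forward`, `backward`, `net`,
#'   `realized_forward`, `realized_backward`, `realized_net`.
#' @export
net_fluxes <- function(result) {
  stopifnot(inherits(result, "kie_steady_state"))
  cc <- result$components
  fwd <- cc[cc$direction == "forward", ]
  bwd <- cc[cc$direction == "backward", c("reaction", "rate", "realized")]
  names(bwd) <- c("reaction", "backward", "realized_backward")
  out <- dplyr::left_join(
    tibble::tibble(reaction = fwd$reaction, forward = fwd$rate,
                   realized_forward = fwd$realized),
    bwd, by = "reaction")
  out$backward[is.na(out$backward)] <- 0
  out$realized_backward[is.na(out$realized_backward)] <- 0
  out |>
    dplyr::mutate(net = .data$forward - .data$backward,
                  realized_net = .data$realized_forward - .data$realized_backward) |>
    dplyr::select("reaction", "forward", "backward", "net",
                  "realized_forward", "realized_backward", "realized_net")
}

#' Quantify the system-level impact of KIEs
#'
#' Compares two converged states of the same model that differ only in
#' whether KIE factors were applied. Fluxes and concentrations are compared
#' as signed relative changes `(x_kie - x_ref) / x_ref` (undefined, `NA`,
#' where the reference is 0); isotopic observables (isotopomer fractions,
#' isotopologue fractions, enrichments) as signed absolute errors
#' `x_kie - x_ref`.
#'
#' @param with_kie,without_kie `kie_steady_state` results simulated with the
#'   model's KIE factors and with all factors set to 1.
#' @param check_convergence Error if either input did not converge.
#' @return A `kie_impact` object with tibbles `fluxes`, `concentrations`,
#'   `isotopomers`, `isotopologues`, `enrichments`. Boundary pools (clamped,
#'   hence identical by construction) are excluded.
#' @export
impact_report <- function(with_kie, without_kie, check_convergence = TRUE) {
  stopifnot(inherits(with_kie, "kie_steady_state"),
            inherits(without_kie, "kie_steady_state"))
  if (check_convergence && (!with_kie$converged || !without_kie$converged)) {
    stop("impact_report needs two converged states", call. = FALSE)
  }
  dyn <- with_kie$totals$metabolite[!with_kie$totals$boundary]

  rel <- function(x, ref) ifelse(ref == 0, NA_real_, (x - ref) / ref)
  fx_k <- net_fluxes(with_kie)
  fx_r <- net_fluxes(without_kie)
  fluxes <- tibble::tibble(reaction = fx_k$reaction,
                           with_kie = fx_k$realized_net,
                           without_kie = fx_r$realized_net,
                           rel_change = rel(fx_k$realized_net, fx_r$realized_net))
  conc <- tibble::tibble(metabolite = dyn,
                         with_kie = with_kie$totals$concentration[match(dyn, with_kie$totals$metabolite)],
                         without_kie = without_kie$totals$concentration[match(dyn, without_kie$totals$metabolite)])
  conc$rel_change <- rel(conc$with_kie, conc$without_kie)

  join_err <- function(a, b, by, col = "fraction") {
    out <- dplyr::inner_join(a, b, by = by, suffix = c("_kie", "_ref"))
    out$error <- out[[paste0(col, "_kie")]] - out[[paste0(col, "_ref")]]
    out
  }
  isos <- join_err(isotopomer_fractions(with_kie, dyn),
                   isotopomer_fractions(without_kie, dyn),
                   by = c("metabolite", "pattern"))
  logs <- join_err(isotopologue_distribution(with_kie, dyn),
                   isotopologue_distribution(without_kie, dyn),
                   by = c("metabolite", "mass_shift"))
  enr <- join_err(molecular_enrichment(with_kie, dyn),
                  molecular_enrichment(without_kie, dyn),
                  by = "metabolite", col = "enrichment")

  structure(list(fluxes = fluxes, concentrations = conc, isotopomers = isos,
                 isotopologues = logs, enrichments = enr),
            class = "kie_impact")
}

#' @export
print.kie_impact <- function(x, ...) {
  s <- function(v) if (all(is.na(v))) NA_real_ else max(abs(v), na.rm = TRUE)
  cat("<kie_impact> max |relative change|: fluxes ",
      format(s(x$fluxes$rel_change), digits = 3), ", concentrations ",
      format(s(x$concentrations$rel_change), digits = 3),
      "\n  max |error|: isotopomers ", format(s(x$isotopomers$error), digits = 3),
      ", isotopologues ", format(s(x$isotopologues$error), digits = 3),
      ", enrichments ", format(s(x$enrichments$error), digits = 3), "\n", sep = "")
  invisible(x)
}
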