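# Drivers for the package's computational experiments: impact of KIEs across
# standard glucose label inputs, the exchange-free model variant, and global
# sensitivity analysis over enzyme levels.

#' Standard glucose label inputs
#'
#' The seven glucose labelings commonly used in 13C labeling experiments:
#' natural abundance, U-13C, 80 % 1-13C + 20 % U-13C, an equimolar mixture of
#' 12C- and U-13C-glucose, 2,3,4,5,6-13C, 1,2-13C and 3,4-13C.
#'
#' @return Named list of tracer specifications for [build_label_input()]
#'   (6-carbon substrate).
#' @export
glucose_label_inputs <- function() {
  list("natural"                = c(natural = 1),
       "U-13C"                  = c(uniform = 1),
       "80% 1-13C + 20% U-13C"  = c("100000" = 0.8, uniform = 0.2),
       "50% 12C + 50% U-13C"    = c(unlabeled = 0.5, uniform = 0.5),
       "2,3,4,5,6-13C"          = c("011111" = 1),
       "1,2-13C"                = c("110000" = 1),
       "3,4-13C"                = c("001100" = 1))
}

# name of the single boundary pool, or error
single_boundary <- function(model) {
  b <- model$metabolites$id[model$metabolites$boundary]
  if (length(b) != 1) {
    stop("expected exactly one boundary pool, found ",
         length(b), call. = FALSE)
  }
  b
}

#' Impact of KIEs across several label inputs
#'
#' For each label input, integrates the model to steady state with the KIE
#' factors applied and with all factors set to 1, and summarizes their
#' [impact_report()]. Convergence failures are propagated per input, not
#' fatal for the whole comparison.
#'
#' @param model A `kie_network` with one boundary pool.
#' @param inputs Named list of tracer specifications (default
#'   [glucose_label_inputs()] when the boundary substrate has 6 carbons).
#' @param settings A [simulation_settings()].
#' @return Tibble with one row per input: `input`, `converged`, the maxima of
#'   the absolute relative flux/concentration changes and absolute isotopic
#'   errors, and the full `kie_impact` in list-column `impact`.
#' @export
compare_label_inputs <- function(model, inputs = NULL,
                                 settings = simulation_settings()) {
  bmet <- single_boundary(model)
  if (is.null(inputs)) {
    stopifnot(model$metabolites$n_atoms[model$metabolites$id == bmet] == 6L)
    inputs <- glucose_label_inputs()
  }
  rows <- lapply(names(inputs), function(nm) {
    m <- rlang::exec(set_label_input, model, !!bmet := inputs[[nm]])
    sys <- kie_system(m)
    res <- tryCatch({
      with_kie <- run_to_steady_state(sys, kie_on = TRUE, settings = settings)
      without <- run_to_steady_state(sys, kie_on = FALSE, settings = settings)
      list(ok = with_kie$converged && without$converged,
           impact = impact_report(with_kie, without, check_convergence = FALSE))
    }, error = function(e) list(ok = FALSE, impact = NULL, msg = conditionMessage(e)))
    mx <- function(v) if (is.null(res$impact) || all(is.na(v))) NA_real_ else max(abs(v), na.rm = TRUE)
    tibble::tibble(
      input = nm, converged = res$ok,
      max_flux_change = mx(res$impact$fluxes$rel_change),
      max_conc_change = mx(res$impact$concentrations$rel_change),
      max_isotopomer_error = mx(res$impact$isotopomers$error),
      max_isotopologue_error = mx(res$impact$isotopologues$error),
      max_enrichment_error = mx(res$impact$enrichments$error),
      impact = list(res$impact))
  })
  dplyr::bind_rows(rows)
}

#' Exchange-free model variant
#'
#' Returns a model in which bidirectional isotope exchange through reversible
#' reactions is ignored in the isotopomer balances: each reversible pair
#' carries only its net rate, assigned to the component of the current net
#' direction (the opposite component gets rate 0; sign flips during
#' integration simply reassign the carrying direction). The rate laws — and
#' hence all aggregate concentrations and net fluxes — are untouched, so the
#' variant isolates the role of isotope exchange. A model without reversible
#' reactions is returned unchanged; the operation is idempotent.
#'
#' @param model A `kie_network`.
#' @return The variant model.
#' @export
no_exchange_variant <- function(model) {
  if (!any(vapply(model$reactions, `[[`, logical(1), "reversible"))) return(model)
  model$exchange <- FALSE
  model
}

#' Design of a global sensitivity scan over enzyme levels
#'
#' @param n_sets Number of random enzyme-level sets (the full design uses
#'   10000; scale down for quick scans).
#' @param span Multiplicative sampling range around the nominal levels;
#'   multipliers are drawn log-uniformly over `[span[1], span[2]]` (default
#'   two orders of magnitude, 0.1 to 10).
#' @param seed Integer seed making the scan reproducible.
#' @param label_input Optional tracer specification applied to the boundary
#'   substrate before scanning.
#' @param parameters Character vector of parameter names to scan; default:
#'   the model's enzyme-level parameters (names starting `E_`, falling back
#'   to `Vmax`).
#' @return A `kie_sensitivity_design` list.
#' @export
sensitivity_design <- function(n_sets = 10000, span = c(0.1, 10), seed = 1,
                               label_input = NULL, parameters = NULL) {
  stopifnot(n_sets >= 1, length(span) == 2, all(span > 0), span[1] <= span[2])
  structure(list(n_sets = as.integer(n_sets), span = span,
                 seed = as.integer(seed), label_input = label_input,
                 parameters = parameters),
            class = "kie_sensitivity_design")
}

resolve_scan_parameters <- function(design, model) {
  pars <- design$parameters
  if (is.null(pars)) {
    pars <- grep("^E_", names(model$parameters), value = TRUE)
    if (!length(pars)) pars <- grep("^Vmax", names(model$parameters), value = TRUE)
  }
  if (!length(pars) || !all(pars %in% names(model$parameters))) {
    stop("no scannable enzyme-level parameters found", call. = FALSE)
  }
  pars
}

#' Draw random enzyme-level multipliers
#'
#' One independent log-uniform draw per scanned parameter per set:
#' `multiplier = 10^u` with `u ~ Uniform(log10 span)`, so every order of
#' magnitude is sampled in similar proportion.
#'
#' @param design A [sensitivity_design()].
#' @param model The model whose parameters are scanned.
#' @return Numeric matrix `n_sets x n_parameters` (columns named).
#' @export
sample_enzyme_levels <- function(design, model) {
  pars <- resolve_scan_parameters(design, model)
  set.seed(design$seed)
  u <- matrix(stats::runif(design$n_sets * length(pars),
                           log10(design$span[1]), log10(design$span[2])),
              nrow = design$n_sets)
  colnames(u) <- pars
  10^u
}

#' Global sensitivity of KIE-induced isotopic errors to enzyme levels
#'
#' For each random enzyme-level set, integrates the model to steady state
#' with and without KIE factors and records the absolute errors the KIEs
#' cause on every isotopomer fraction, isotopologue fraction and molecular
#' enrichment, plus the per-reaction net fluxes (systemic descriptors such as
#' substrate uptake or branch splits follow from these). Non-converged sets
#' are excluded from the error distributions and counted.
#'
#' @param model A `kie_network` with a kinetic parameter bundle.
#' @param design A [sensitivity_design()].
#' @param settings A [simulation_settings()].
#' @return A `kie_sensitivity` object: `errors` (tibble: set, dataset,
#'   metabolite, id, error), `fluxes` (tibble: set, reaction, net),
#'   `multipliers`, `n_failed`, `design`. See [glance.kie_sensitivity()].
#' @export
global_sensitivity <- function(model, design = sensitivity_design(),
                               settings = simulation_settings()) {
  check_parameters(model)
  if (!is.null(design$label_input)) {
    bmet <- single_boundary(model)
    model <- rlang::exec(set_label_input, model, !!bmet := design$label_input)
  }
  pars <- resolve_scan_parameters(design, model)
  mult <- sample_enzyme_levels(design, model)
  sys <- kie_system(model)
  base <- model$parameters[pars]

  err_rows <- vector("list", design$n_sets)
  flux_rows <- vector("list", design$n_sets)
  failed <- 0L
  for (s in seq_len(design$n_sets)) {
    for (j in seq_along(pars)) {
      assign(pars[j], unname(base[j] * mult[s, j]), envir = sys$rate_env)
    }
    res <- tryCatch({
      y0 <- initial_isotopomer_state(sys, settings)
      with_kie <- run_to_steady_state(sys, kie_on = TRUE, init = y0,
                                      settings = settings)
      without <- run_to_steady_state(sys, kie_on = FALSE, init = y0,
                                     settings = settings)
      if (!with_kie$converged || !without$converged) stop("not converged")
      list(with_kie = with_kie, without = without)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    imp <- impact_report(res$with_kie, res$without)
    err_rows[[s]] <- dplyr::bind_rows(
      tibble::tibble(set = s, dataset = "isotopomer",
                     metabolite = imp$isotopomers$metabolite,
                     id = imp$isotopomers$pattern,
                     error = imp$isotopomers$error),
      tibble::tibble(set = s, dataset = "isotopologue",
                     metabolite = imp$isotopologues$metabolite,
                     id = as.character(imp$isotopologues$mass_shift),
                     error = imp$isotopologues$error),
      tibble::tibble(set = s, dataset = "enrichment",
                     metabolite = imp$enrichments$metabolite,
                     id = NA_character_,
                     error = imp$enrichments$error))
    nf <- net_fluxes(res$with_kie)
    flux_rows[[s]] <- tibble::tibble(set = s, reaction = nf$reaction,
                                     net = nf$realized_net)
  }
  # restore nominal parameters in the shared environment
  for (j in seq_along(pars)) assign(pars[j], unname(base[j]), envir = sys$rate_env)

  structure(list(errors = dplyr::bind_rows(err_rows),
                 fluxes = dplyr::bind_rows(flux_rows),
                 multipliers = mult, n_failed = failed, design = design),
            class = "kie_sensitivity")
}

#' @export
print.kie_sensitivity <- function(x, ...) {
  cat("<kie_sensitivity> ", x$design$n_sets, " sets (", x$n_failed,
      " failed), ", nrow(x$errors), " error records\n", sep = "")
  invisible(x)
}
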