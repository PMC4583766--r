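#' Solver and convergence settings
#'
#' Defaults follow common practice for stiff isotopomer balance systems:
#' absolute/relative integration tolerances 1e-8/1e-6, an LSODE-class stiff
#' solver with sparse Jacobian treatment (`"lsodes"`; isotopomer Jacobians
#' are large and sparse), and a steady-state criterion on the residual
#' `max|dI/dt| < ss_tol * (1 + max|I|)` checked on integration horizons that
#' double until convergence or `max_time`.
#'
#' @param atol,rtol Absolute and relative integration error tolerances.
#' @param ss_tol Steady-state residual tolerance (see above).
#' @param max_time Hard cap on integrated time before reporting
#'   non-convergence.
#' @param t_first Length of the first integration horizon.
#' @param method deSolve integrator name (a stiff method; `"lsodes"`,
#'   `"lsoda"` or `"bdf"`).
#' @return A `kie_settings` list.
#' @export
simulation_settings <- function(atol = 1e-8, rtol = 1e-6, ss_tol = 1e-10,
                                max_time = 1e6, t_first = 50, method = "lsodes") {
  stopifnot(atol > 0, rtol > 0, ss_tol > 0, max_time > 0, t_first > 0)
  structure(list(atol = atol, rtol = rtol, ss_tol = ss_tol,
                 max_time = max_time, t_first = t_first, method = method),
            class = "kie_settings")
}

# Clamp small integration negatives to 0; real negatives are an error.
# The allowance scales with the solver's local error (atol + rtol * |y|):
# stiff integrators routinely undershoot 0 by a few multiples of it.
clamp_state <- function(y, atol, rtol = 1e-6, what = "state") {
  neg_tol <- 100 * (atol + rtol * max(abs(y)))
  if (any(y < -neg_tol)) {
    stop(what, " went negative beyond the solver error allowance (min ",
         format(min(y)), "); the model or tolerances are inconsistent",
         call. = FALSE)
  }
  y[y < 0] <- 0
  y
}

# Integrate dy/dt = rhs_fn(y) until the residual criterion is met, on
# doubling horizons (runsteady-style driver).
steady_loop <- function(rhs_fn, y0, settings) {
  y <- y0
  t <- 0
  horizon <- settings$t_first
  converged <- FALSE
  repeat {
    res <- rhs_fn(y)
    if (max(abs(res)) < settings$ss_tol * (1 + max(abs(y)))) {
      converged <- TRUE
      break
    }
    if (t >= settings$max_time) break
    horizon <- min(horizon, settings$max_time - t)
    sol <- deSolve::ode(y = y, times = c(0, horizon),
                        func = function(t, y, p) list(rhs_fn(y)),
                        parms = NULL, method = settings$method,
                        atol = settings$atol, rtol = settings$rtol)
    y <- clamp_state(sol[nrow(sol), -1], settings$atol, settings$rtol)
    t <- t + horizon
    horizon <- horizon * 2
  }
  list(y = y, t = t, residual = max(abs(rhs_fn(y))), converged = converged)
}

# Net stoichiometry per rate component (pool x component), boundary rows
# zeroed; identical for every fluxomer of a component, so read off the first.
component_stoichiometry <- function(sys) {
  first <- cumsum(c(1L, utils::head(vapply(sys$components, `[[`, integer(1),
                                           "n_flux"), -1L)))
  as.matrix((sys$agg %*% sys$U)[, first, drop = FALSE])
}

#' Steady state of the plain kinetic model
#'
#' Integrates the aggregate concentration system `dM/dt = N v(M)` (the model
#' without any isotopic dimension) to steady state from the declared initial
#' concentrations. This is also the reference the isotopic system must
#' reproduce pool-by-pool when all KIE factors are 1.
#'
#' @param model A `kie_network` or `kie_system`.
#' @param settings A [simulation_settings()] object.
#' @return List with `concentrations` (tibble: metabolite, concentration),
#'   `rates` (tibble: component, reaction, direction, rate), `converged`,
#'   `residual`, `time`.
#' @export
kinetic_steady_state <- function(model, settings = simulation_settings()) {
  sys <- if (inherits(model, "kie_system")) model else kie_system(model)
  check_parameters(sys$model)
  N <- component_stoichiometry(sys)
  mets <- sys$model$metabolites
  rhs <- function(M) as.vector(N %*% component_rates(sys, M))
  out <- steady_loop(rhs, stats::setNames(mets$initial_conc, mets$id), settings)
  v <- component_rates(sys, out$y)
  list(concentrations = tibble::tibble(metabolite = mets$id,
                                       concentration = unname(out$y)),
       rates = tibble::tibble(
         component = sys$component_ids,
         reaction = vapply(sys$components, `[[`, character(1), "reaction"),
         direction = vapply(sys$components, `[[`, character(1), "direction"),
         rate = unname(v)),
       converged = out$converged, residual = out$residual, time = out$t)
}

# Resolve the label distribution of every boundary pool (model default =
# all-light point mass) and build the initial isotopomer state: boundary
# pools at clamped concentration x label distribution, dynamic pools at the
# plain kinetic steady state concentrated on the all-light isotopomer, so the
# integration only has to relax the isotopic dimensions.
initial_isotopomer_state <- function(sys, settings = simulation_settings()) {
  model <- sys$model
  mets <- model$metabolites
  I0 <- numeric(sys$n_iso)
  kin <- NULL
  if (any(!mets$boundary)) {
    kin <- kinetic_steady_state(sys, settings)
    if (!kin$converged) {
      warning("plain kinetic model did not reach steady state (residual ",
              format(kin$residual), "); starting from its final state")
    }
  }
  offs <- pool_offsets(model)
  for (i in seq_len(nrow(mets))) {
    n <- mets$n_atoms[i]
    rows <- offs[[mets$id[i]]] + seq_len(2^n)
    if (mets$boundary[i]) {
      li <- model$label_input[[mets$id[i]]]
      dist <- numeric(2^n)
      if (is.null(li)) dist[1] <- 1
      else dist[match(names(li), iso_patterns(n))] <- li
      I0[rows] <- mets$initial_conc[i] * dist
    } else {
      I0[rows[1]] <- kin$concentrations$concentration[match(mets$id[i],
                                                            kin$concentrations$metabolite)]
    }
  }
  stats::setNames(I0, paste(sys$iso$metabolite, sys$iso$pattern, sep = "."))
}

#' Integrate the isotopomer system over a time grid
#'
#' @param model A `kie_network` or pre-compiled `kie_system`.
#' @param times Numeric time grid (first element = initial time).
#' @param kie_on Apply the model's KIE factors (`FALSE` sets all factors
#'   to 1).
#' @param init Optional initial state vector in [enumerate_isotopomers()]
#'   order; by default boundary pools are clamped at their label input and
#'   dynamic pools start at the plain kinetic steady state, all-light.
#' @param settings A [simulation_settings()] object.
#' @return A `kie_trajectory`: tidy tibble (time, metabolite, pattern,
#'   concentration) with the raw deSolve matrix in attribute `"matrix"`.
#' @export
integrate_timecourse <- function(model, times, kie_on = TRUE, init = NULL,
                                 settings = simulation_settings()) {
  sys <- if (inherits(model, "kie_system")) model else kie_system(model)
  check_parameters(sys$model)
  y0 <- init %||% initial_isotopomer_state(sys, settings)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, p) list(iso_rhs(sys, y, kie_on)),
                      parms = NULL, method = settings$method,
                      atol = settings$atol, rtol = settings$rtol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed (istate ", attr(sol, "istate")[1], ") at t = ",
         format(sol[nrow(sol), 1]), call. = FALSE)
  }
  long <- tibble::tibble(
    time = rep(sol[, 1], times = sys$n_iso),
    metabolite = rep(sys$iso$metabolite, each = nrow(sol)),
    pattern = rep(sys$iso$pattern, each = nrow(sol)),
    concentration = as.vector(sol[, -1, drop = FALSE]))
  structure(long, matrix = sol, class = c("kie_trajectory", class(long)))
}

#' Integrate the isotopomer system to steady state
#'
#' Runs the coupled kinetic + isotopic system until the residual criterion of
#' [simulation_settings()] is met. Non-convergence is reported explicitly
#' (`converged = FALSE` plus a warning), never silently.
#'
#' @inheritParams integrate_timecourse
#' @return A `kie_steady_state` object: isotopomer concentrations and
#'   fractions, pool totals, per-component and per-reaction fluxes (both
#'   unweighted and KIE-realized), the fluxomer vector, residual and
#'   convergence metadata. Use [tidy()][generics::tidy], [glance()]
#'   [net_fluxes()], [isotopologue_distribution()] and
#'   [molecular_enrichment()] on it.
#' @export
run_to_steady_state <- function(model, kie_on = TRUE, init = NULL,
                                settings = simulation_settings()) {
  sys <- if (inherits(model, "kie_system")) model else kie_system(model)
  check_parameters(sys$model)
  y0 <- init %||% initial_isotopomer_state(sys, settings)
  out <- steady_loop(function(y) iso_rhs(sys, y, kie_on), y0, settings)
  if (!out$converged) {
    warning("isotopomer system did not reach steady state within max_time (",
            "residual ", format(out$residual), ")")
  }
  new_steady_state(sys, out$y, kie_on, settings,
                   residual = out$residual, time = out$t,
                   converged = out$converged)
}

# Package a converged (or final) state into the result object.
new_steady_state <- function(sys, y, kie_on, settings, residual, time, converged) {
  ra <- relative_abundances(sys, y)
  f <- compute_fluxomers(sys, y)
  a <- if (kie_on) sys$alpha else rep(1, sys$n_flux)
  v <- component_rates(sys, ra$M)
  realized <- as.vector(rowsum(f * a, group = sys$comp_of_flux))

  comp_tbl <- tibble::tibble(
    component = sys$component_ids,
    reaction = vapply(sys$components, `[[`, character(1), "reaction"),
    direction = vapply(sys$components, `[[`, character(1), "direction"),
    rate = unname(v), realized = realized)

  iso <- sys$iso
  iso$concentration <- unname(y)
  iso$fraction <- unname(ra$ab)

  structure(list(system = sys, state = y, iso = iso,
                 totals = tibble::tibble(metabolite = sys$model$metabolites$id,
                                         boundary = sys$model$metabolites$boundary,
                                         concentration = ra$M),
                 components = comp_tbl, fluxomers = f, kie_on = kie_on,
                 residual = residual, time = time, converged = converged,
                 settings = settings),
            class = "kie_steady_state")
}

#' @export
print.kie_steady_state <- function(x, ...) {
  cat("<kie_steady_state> ", if (x$converged) "converged" else "NOT converged",
      " at t = ", format(x$time), ", residual ", format(x$residual),
      ", KIEs ", if (x$kie_on) "on" else "off", "\n", sep = "")
  print(x$totals, n = 6)
  invisible(x)
}
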