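#' Define a reaction with its rate law(s) and carbon-atom transitions
#'
#' A reaction is reversible when a `backward` rate expression is supplied; it
#' then contributes two unidirectional rate components to the model, otherwise
#' exactly one. The atom map is written in the forward direction; for
#' reversible reactions the backward map is its inverse, so the forward map
#' must be a bijection on carbon slots. Products whose ids are not declared as
#' metabolites are treated as external sinks (their carbon leaves the mapped
#' system, as for released CO2 or biomass drains).
#'
#' @param id Reaction identifier (unique within a model).
#' @param atoms Atom-transition string in the forward direction, e.g.
#'   `"FBP(abcdef) -> DHAP(cba) + GAP(def)"`. Slot letters pair substrate and
#'   product carbon positions; position 1 is the first letter in a molecule's
#'   parenthesis.
#' @param forward,backward Rate-law expressions as strings (or quoted
#'   expressions) in metabolite ids and parameter names. Each must evaluate to
#'   a nonnegative rate on the admissible concentration domain. `backward =
#'   NULL` declares the reaction irreversible.
#' @return A `kie_reaction` list.
#' @examples
#' reaction("ALD", "FBP(abcdef) -> DHAP(cba) + GAP(def)",
#'          forward = "kf * FBP", backward = "kb * DHAP * GAP")
#' @export
reaction <- function(id, atoms, forward, backward = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  map <- parse_atom_map(atoms, where = paste0("reaction '", id, "'"))
  as_expr <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) str2lang(x) else x
  }
  structure(list(id = id, atoms = atoms, map = map,
                 forward = as_expr(forward), backward = as_expr(backward),
                 reversible = !is.null(backward)),
            class = "kie_reaction")
}

#' Assemble a kinetic + isotopic network model
#'
#' Bundles metabolites, reactions (with unidirectional rate laws and atom
#' maps), kinetic parameter values, a table of kinetic-isotope-effect
#' fractionation factors, and the label input clamped on boundary pools.
#' The returned model is validated with [validate_network()].
#'
#' @param metabolites Data frame with columns `id`, `n_atoms`, `boundary`
#'   (logical), `initial_conc`. Boundary pools have both their concentration
#'   and their labeling fixed during simulation.
#' @param reactions List of [reaction()] objects; declaration order fixes all
#'   downstream enumeration orders.
#' @param parameters Named numeric vector of kinetic parameters.
#' @param kie Data frame with columns `reaction`, `metabolite`, `pattern`,
#'   `alpha`: the fractionation factor of one substrate isotopomer of one
#'   reaction, relative to the all-light isotopomer. Entries for singly
#'   labeled patterns are combined multiplicatively for multiply labeled
#'   substrates (cumulative KIEs); an entry for a multiply labeled pattern
#'   overrides the product rule for that exact pattern. `NULL` means no KIEs.
#' @param label_input Named list, one element per boundary metabolite: a
#'   numeric vector of isotopomer fractions named by pattern (see
#'   [build_label_input()]). Boundary pools without an entry default to the
#'   all-light point mass.
#' @param natural_abundance Heavy-isotope natural abundance used when label
#'   inputs request `"natural"` patterns (default 0.0107, the 13C value).
#' @return A validated `kie_network` object.
#' @seealso [toy_fixture()], [ecoli_fixture()], [validate_network()]
#' @export
network_model <- function(metabolites, reactions, parameters = numeric(),
                          kie = NULL, label_input = NULL,
                          natural_abundance = 0.0107) {
  metabolites <- tibble::as_tibble(metabolites)
  if (!all(c("id", "n_atoms", "boundary", "initial_conc") %in% names(metabolites))) {
    stop("metabolites needs columns id, n_atoms, boundary, initial_conc", call. = FALSE)
  }
  metabolites$n_atoms <- as.integer(metabolites$n_atoms)
  if (is.null(kie)) {
    kie <- tibble::tibble(reaction = character(), metabolite = character(),
                          pattern = character(), alpha = numeric())
  } else {
    kie <- tibble::as_tibble(kie)
  }
  model <- structure(list(metabolites = metabolites,
                          reactions = reactions,
                          parameters = parameters,
                          kie = kie,
                          label_input = label_input %||% list(),
                          natural_abundance = natural_abundance,
                          exchange = TRUE),
                     class = "kie_network")
  validate_network(model)
  model
}

#' @export
print.kie_network <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat("<kie_network> ", nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$boundary), " boundary), ",
      length(x$reactions), " reactions (", nrev, " reversible, ",
      length(x$reactions) - nrev, " irreversible), ",
      nrow(x$kie), " KIE entries",
      if (!x$exchange) ", exchange-free variant" else "", "\n", sep = "")
  invisible(x)
}

# Flatten reactions into ordered unidirectional rate components:
# reaction declaration order, forward before backward. Each component carries
# its own substrate/product atom slots; the backward component of a reversible
# reaction uses the inverted map.
rate_components <- function(model) {
  out <- list()
  for (rx in model$reactions) {
    out[[length(out) + 1L]] <- list(
      cid = paste0(rx$id, ".fwd"), reaction = rx$id, direction = "forward",
      rate = rx$forward,
      substrates = rx$map$substrates, products = rx$map$products)
    if (rx$reversible) {
      out[[length(out) + 1L]] <- list(
        cid = paste0(rx$id, ".bwd"), reaction = rx$id, direction = "backward",
        rate = rx$backward,
        substrates = rx$map$products, products = rx$map$substrates)
    }
  }
  out
}

#' Validate a network model
#'
#' Checks id uniqueness and resolution, atom-map consistency (slot counts
#' match declared carbon numbers, slot letters are unique on the substrate
#' side, product slots are drawn from substrate slots, reversible maps are
#' bijections), rate-law symbol resolution, KIE-table well-formedness
#' (positive factors, pattern lengths, all-light pattern fixed at 1), and
#' label-input normalization. The first hard failure raises an error; softer
#' issues are collected as warnings in the report, and external sink pools
#' (undeclared products whose carbon leaves the mapped system) are listed
#' informationally.
#'
#' @param model A `kie_network` (or the pieces of one, pre-construction).
#' @return Invisibly, a `kie_validation` list with counts and a tibble of
#'   warnings.
#' @export
validate_network <- function(model) {
  mets <- model$metabolites
  warnings <- character()
  fail <- function(...) stop(..., call. = FALSE)

  if (anyDuplicated(mets$id)) fail("duplicate metabolite ids: ",
                                   paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (any(mets$n_atoms < 1L)) fail("every metabolite needs n_atoms >= 1")
  if (any(!is.finite(mets$initial_conc) | mets$initial_conc < 0)) {
    fail("initial concentrations must be finite and nonnegative")
  }
  n_of <- stats::setNames(mets$n_atoms, mets$id)

  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) fail("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))

  comps <- rate_components(model)
  known <- c(mets$id, names(model$parameters))
  externals <- character()
  for (rx in model$reactions) {
    subs <- rx$map$substrates
    prods <- rx$map$products
    if (length(subs) == 0) fail("reaction '", rx$id, "' has no substrates")
    for (s in subs) {
      if (!s$met %in% mets$id) fail("reaction '", rx$id, "': substrate '", s$met,
                                    "' is not a declared metabolite")
      if (length(s$slots) != n_of[[s$met]]) {
        fail("reaction '", rx$id, "': '", s$met, "' written with ",
             length(s$slots), " atom slots but declared with ", n_of[[s$met]])
      }
    }
    sub_slots <- unlist(lapply(subs, `[[`, "slots"))
    if (anyDuplicated(sub_slots)) fail("reaction '", rx$id,
                                       "': duplicated substrate slot letters")
    prod_slots <- unlist(lapply(prods, `[[`, "slots"))
    if (anyDuplicated(prod_slots)) fail("reaction '", rx$id,
                                        "': a substrate slot is used by two product positions")
    if (!all(prod_slots %in% sub_slots)) {
      fail("reaction '", rx$id, "': product slots ",
           paste(setdiff(prod_slots, sub_slots), collapse = ","),
           " do not appear on the substrate side")
    }
    for (p in prods) {
      if (p$met %in% mets$id) {
        if (length(p$slots) != n_of[[p$met]]) {
          fail("reaction '", rx$id, "': '", p$met, "' written with ",
               length(p$slots), " atom slots but declared with ", n_of[[p$met]])
        }
      } else {
        externals <- c(externals, p$met)
      }
    }
    if (rx$reversible) {
      if (!setequal(sub_slots, prod_slots) || length(prod_slots) != length(sub_slots)) {
        fail("reaction '", rx$id, "' is reversible but its atom map is not a ",
             "bijection (carbon must be conserved to invert the map)")
      }
      if (any(!vapply(prods, function(p) p$met %in% mets$id, logical(1)))) {
        fail("reaction '", rx$id, "' is reversible but has an undeclared product")
      }
    }
  }
  for (cp in comps) {
    bad <- setdiff(all.vars(cp$rate), known)
    if (length(bad)) fail("rate law of component '", cp$cid,
                          "' references unknown symbols: ", paste(bad, collapse = ", "))
  }
  externals <- sort(unique(externals))

  kie <- model$kie
  if (nrow(kie)) {
    if (any(!is.finite(kie$alpha) | kie$alpha <= 0)) fail("KIE factors must be > 0")
    for (i in seq_len(nrow(kie))) {
      met <- kie$metabolite[i]
      if (!met %in% mets$id) fail("KIE entry ", i, ": unknown metabolite '", met, "'")
      if (!is_pattern(kie$pattern[i]) || nchar(kie$pattern[i]) != n_of[[met]]) {
        fail("KIE entry ", i, ": pattern '", kie$pattern[i],
             "' does not match the ", n_of[[met]], " carbons of ", met)
      }
      if (pattern_weight(kie$pattern[i]) == 0 && kie$alpha[i] != 1) {
        fail("KIE entry ", i, ": the all-light pattern has factor 1 by definition")
      }
      if (!kie$reaction[i] %in% rids) {
        warnings <- c(warnings, paste0("KIE entry for absent reaction '",
                                       kie$reaction[i], "' is ignored"))
      } else {
        is_sub <- any(vapply(comps, function(cp) {
          cp$reaction == kie$reaction[i] &&
            met %in% vapply(cp$substrates, `[[`, character(1), "met")
        }, logical(1)))
        if (!is_sub) warnings <- c(warnings, paste0(
          "KIE entry (", kie$reaction[i], ", ", met,
          "): metabolite is not a substrate of any component of that reaction"))
      }
    }
  }

  for (met in names(model$label_input)) {
    if (!met %in% mets$id) fail("label input for unknown metabolite '", met, "'")
    if (!mets$boundary[mets$id == met]) {
      warnings <- c(warnings, paste0("label input for non-boundary pool '", met,
                                     "' is ignored"))
      next
    }
    li <- model$label_input[[met]]
    pats <- iso_patterns(n_of[[met]])
    if (!all(names(li) %in% pats) || anyDuplicated(names(li))) {
      fail("label input for '", met, "': pattern names must be distinct ",
           n_of[[met]], "-bit strings")
    }
    if (any(li < 0)) fail("label input for '", met, "' has negative fractions")
    if (abs(sum(li) - 1) > 1e-12) {
      fail("label input for '", met, "' sums to ", format(sum(li)),
           ", not 1 (tolerance 1e-12)")
    }
  }

  res <- structure(list(valid = TRUE,
                        n_metabolites = nrow(mets),
                        n_reactions = length(model$reactions),
                        n_components = length(comps),
                        externals = externals,
                        warnings = tibble::tibble(message = warnings)),
                   class = "kie_validation")
  invisible(res)
}

#' @export
print.kie_validation <- function(x, ...) {
  cat("network valid: ", x$n_metabolites, " metabolites, ", x$n_reactions,
      " reactions, ", x$n_components, " unidirectional components, ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  if (nrow(x$warnings)) cat(paste0("  - ", x$warnings$message, collapse = "\n"), "\n")
  if (length(x$externals)) {
    cat("external sink pools (carbon leaves the map):",
        paste(x$externals, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Split a reversible net rate law into forward and backward components
#'
#' Convenience for the common family of reversible laws whose numerator has
#' the form `(S - P/Keq)` over a shared denominator, as in a reversible
#' Michaelis-Menten law. The expression tree is searched for the unique
#' subtraction whose right arm contains the equilibrium-constant symbol and
#' whose left arm does not; the forward (backward) component keeps only the
#' left (right) arm, leaving everything else — in particular the denominator —
#' untouched. Forward minus backward is then identically the net law. Rate
#' laws outside this family must be supplied as explicit components in
#' [reaction()].
#'
#' @param net Net rate law (string or quoted expression).
#' @param keq Name of the equilibrium-constant symbol in `net`.
#' @return List with quoted expressions `forward` and `backward`.
#' @examples
#' decompose_rate_law(
#'   "Vmax * (PG3 - PG2 / Keq) / (Km3 * (1 + PG2 / Km2) + PG3)", "Keq")
#' @export
decompose_rate_law <- function(net, keq) {
  e <- if (is.character(net)) str2lang(net) else net
  n_splits <- 0L

  rebuild <- function(x, keep) {
    if (is.call(x) && identical(x[[1]], as.name("-")) && length(x) == 3 &&
        keq %in% all.vars(x[[3]]) && !(keq %in% all.vars(x[[2]]))) {
      n_splits <<- n_splits + 1L
      return(if (keep == "f") x[[2]] else x[[3]])
    }
    if (is.call(x)) {
      for (i in seq_along(x)[-1]) x[[i]] <- rebuild(x[[i]], keep)
    }
    x
  }
  fwd <- rebuild(e, "f")
  nf <- n_splits
  n_splits <- 0L
  bwd <- rebuild(e, "b")
  if (nf != 1L || n_splits != 1L) {
    stop("cannot decompose: expected exactly one '(substrate term) - ",
         "(product term containing ", keq, ")' in the rate law; supply ",
         "forward and backward components explicitly", call. = FALSE)
  }
  list(forward = fwd, backward = bwd)
}

#' Build a full isotopomer distribution for a label input
#'
#' Expands a tracer mixture specification into fractions over all `2^n`
#' isotopomers of an n-carbon substrate. Tracers are positional bit patterns
#' (e.g. `"100000"` for a substrate labeled at position 1 only), `"uniform"`
#' (or `"U"`) for the fully labeled species, `"unlabeled"` for the all-light
#' species, or `"natural"` for independent heavy labeling of every position at
#' natural abundance. Commercial tracers are treated as isotopically pure.
#'
#' @param n_atoms Number of carbon positions of the substrate.
#' @param tracers Data frame with columns `tracer` (character) and `fraction`,
#'   or a named numeric vector (names = tracer descriptions). Fractions must
#'   be nonnegative and sum to 1.
#' @param natural_abundance Per-position heavy probability used by
#'   `"natural"` (default 0.0107 for 13C).
#' @return Named numeric vector of length `2^n_atoms` (names = patterns),
#'   summing to 1.
#' @examples
#' # 80 % 1-13C + 20 % U-13C glucose
#' li <- build_label_input(6, c("100000" = 0.8, uniform = 0.2))
#' li[li > 0]
#' @export
build_label_input <- function(n_atoms, tracers, natural_abundance = 0.0107) {
  if (is.data.frame(tracers)) {
    spec <- stats::setNames(tracers$fraction, tracers$tracer)
  } else {
    spec <- tracers
  }
  if (is.null(names(spec)) || any(!nzchar(names(spec)))) {
    stop("every tracer needs a description (pattern, 'uniform', 'unlabeled' ",
         "or 'natural')", call. = FALSE)
  }
  if (any(spec < 0)) stop("negative tracer fraction", call. = FALSE)
  if (abs(sum(spec) - 1) > 1e-9) {
    stop("tracer fractions sum to ", format(sum(spec)), ", not 1", call. = FALSE)
  }
  pats <- iso_patterns(n_atoms)
  out <- stats::setNames(numeric(length(pats)), pats)
  for (i in seq_along(spec)) {
    tr <- names(spec)[i]
    if (tr %in% c("uniform", "U")) {
      out[strrep("1", n_atoms)] <- out[strrep("1", n_atoms)] + spec[[i]]
    } else if (tr == "unlabeled") {
      out[strrep("0", n_atoms)] <- out[strrep("0", n_atoms)] + spec[[i]]
    } else if (tr == "natural") {
      w <- vapply(pats, pattern_weight, integer(1))
      out <- out + spec[[i]] * natural_abundance^w *
        (1 - natural_abundance)^(n_atoms - w)
    } else if (is_pattern(tr)) {
      if (nchar(tr) != n_atoms) {
        stop("tracer pattern '", tr, "' has ", nchar(tr), " positions, substrate has ",
             n_atoms, call. = FALSE)
      }
      out[tr] <- out[tr] + spec[[i]]
    } else {
      stop("unknown tracer description '", tr, "'", call. = FALSE)
    }
  }
  out / sum(out)
}

#' Replace the label input of a model
#'
#' @param model A `kie_network`.
#' @param ... Named arguments, one per boundary metabolite; each is either a
#'   full pattern-named fraction vector or a tracer specification passed to
#'   [build_label_input()].
#' @return The model with the new label input, revalidated.
#' @export
set_label_input <- function(model, ...) {
  li <- list(...)
  n_of <- stats::setNames(model$metabolites$n_atoms, model$metabolites$id)
  for (met in names(li)) {
    x <- li[[met]]
    n <- n_of[[met]]
    if (!(length(x) == 2^n && all(names(x) %in% iso_patterns(n)))) {
      x <- build_label_input(n, x, model$natural_abundance)
    }
    model$label_input[[met]] <- x
  }
  validate_network(model)
  model
}
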