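# Readers and writers: the structured-text network dialect (YAML), KIE
# tables (TSV), the incidence matrix (Matrix Market), result CSVs and the
# JSON run manifest, plus a minimal SBML Level 3 kinetics import.

#' Write a network model to the YAML dialect
#'
#' Sections: `metabolites` (id, atoms, boundary, conc), `reactions` (atoms,
#' forward, backward), `parameters`, `kie`, `label_input`,
#' `natural_abundance`. Numbers are serialized at full precision, so
#' write -> read round trips are exact.
#'
#' @param model A `kie_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, atoms = m$n_atoms, boundary = m$boundary,
           conc = m$initial_conc)
    }),
    reactions = lapply(model$reactions, function(rx) {
      out <- list(id = rx$id, atoms = rx$atoms,
                  forward = deparse1(rx$forward))
      if (rx$reversible) out$backward <- deparse1(rx$backward)
      out
    }),
    parameters = as.list(model$parameters),
    kie = lapply(seq_len(nrow(model$kie)), function(i) {
      k <- model$kie[i, ]
      list(reaction = k$reaction, metabolite = k$metabolite,
           pattern = k$pattern, alpha = k$alpha)
    }),
    label_input = lapply(model$label_input, function(li) {
      as.list(li[li != 0])
    }),
    natural_abundance = model$natural_abundance,
    exchange = model$exchange)
  yaml::write_yaml(doc, path, precision = 17L)
  invisible(path)
}

#' Read a network model from the YAML dialect
#'
#' @param path File written by [write_network()] or hand-authored in the same
#'   layout.
#' @return A validated `kie_network`.
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  mets <- dplyr::bind_rows(lapply(doc$metabolites, function(m) {
    tibble::tibble(id = m$id, n_atoms = as.integer(m$atoms),
                   boundary = isTRUE(m$boundary),
                   initial_conc = as.numeric(m$conc %||% 0))
  }))
  rxns <- lapply(doc$reactions, function(r) {
    reaction(r$id, r$atoms, r$forward, backward = r$backward)
  })
  kie <- if (length(doc$kie)) dplyr::bind_rows(lapply(doc$kie, function(k) {
    tibble::tibble(reaction = k$reaction, metabolite = k$metabolite,
                   pattern = as.character(k$pattern), alpha = as.numeric(k$alpha))
  })) else NULL
  li <- lapply(doc$label_input, function(x) {
    v <- unlist(x)
    stats::setNames(as.numeric(v), names(v))
  })
  model <- network_model(mets, rxns,
                         parameters = unlist(doc$parameters) %||% numeric(),
                         kie = kie, label_input = li,
                         natural_abundance = doc$natural_abundance %||% 0.0107)
  if (isFALSE(doc$exchange)) model <- no_exchange_variant(model)
  model
}

#' Read / write a KIE table as TSV
#'
#' Columns `reaction`, `metabolite`, `pattern`, `alpha`; patterns are read as
#' character so leading zeros survive.
#'
#' @param path TSV file path.
#' @return `read_kie_table()`: a tibble; `write_kie_table()`: `path`,
#'   invisibly.
#' @export
read_kie_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    reaction = readr::col_character(), metabolite = readr::col_character(),
    pattern = readr::col_character(), alpha = readr::col_double()))
}

#' @param kie Tibble with columns `reaction`, `metabolite`, `pattern`,
#'   `alpha`.
#' @rdname read_kie_table
#' @export
write_kie_table <- function(kie, path) {
  readr::write_tsv(kie, path)
  invisible(path)
}

#' Export the incidence matrix and system indices
#'
#' Writes the sparse incidence matrix as Matrix Market (`incidence.mtx`) with
#' row labels (`isotopomers.tsv`), and the fluxomer index with its KIE
#' factors (`fluxomers.tsv`).
#'
#' @param model A `kie_network` or `kie_system`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_incidence <- function(model, dir) {
  sys <- if (inherits(model, "kie_system")) model else kie_system(model)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sys$U, file.path(dir, "incidence.mtx"))
  readr::write_tsv(sys$iso, file.path(dir, "isotopomers.tsv"))
  fl <- sys$flux
  fl$alpha <- sys$alpha
  readr::write_tsv(fl, file.path(dir, "fluxomers.tsv"))
  invisible(dir)
}

#' Write simulation results to a directory
#'
#' Deterministic file set with stable row ordering and full-precision
#' numbers: `state.csv` (isotopomer concentrations and fractions),
#' `fluxes.csv`, `isotopologues.csv`, `enrichments.csv` and a JSON
#' `manifest.json` recording settings, seed, package version, convergence
#' diagnostics and a hash of the model — enough to re-execute the run.
#'
#' @param result A `kie_steady_state`.
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest (if any randomness was
#'   involved upstream).
#' @return The directory, invisibly.
#' @export
write_results <- function(result, dir, seed = NA_integer_) {
  stopifnot(inherits(result, "kie_steady_state"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) if (is.double(col)) format_full(col) else col)
    df
  }
  readr::write_csv(fmt(tidy(result)), file.path(dir, "state.csv"))
  readr::write_csv(fmt(net_fluxes(result)), file.path(dir, "fluxes.csv"))
  readr::write_csv(fmt(isotopologue_distribution(result)),
                   file.path(dir, "isotopologues.csv"))
  readr::write_csv(fmt(molecular_enrichment(result)),
                   file.path(dir, "enrichments.csv"))
  manifest <- list(
    tool = "kieflux",
    version = as.character(utils::packageVersion("kieflux")),
    model_hash = rlang::hash(result$system$model),
    seed = seed,
    settings = unclass(result$settings),
    kie_on = result$kie_on,
    converged = result$converged,
    residual = result$residual,
    integrated_time = result$time,
    n_isotopomers = result$system$n_iso,
    n_fluxomers = result$system$n_flux)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# ---- minimal SBML Level 3 import -------------------------------------------

# Convert a content-MathML node to an R expression (operators +, -, *, /,
# power only; enough for mass-action and Michaelis-Menten-type laws).
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    stopifnot(length(kids) == 1)
    return(mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    fold <- function(sym) Reduce(function(a, b) call(sym, a, b), args)
    return(switch(op,
                  plus = fold("+"),
                  times = fold("*"),
                  divide = fold("/"),
                  power = fold("^"),
                  minus = if (length(args) == 1) call("-", args[[1]]) else fold("-"),
                  stop("unsupported MathML operator '", op, "'", call. = FALSE)))
  }
  stop("unsupported MathML node '", nm, "'", call. = FALSE)
}

#' Import kinetics from an SBML Level 3 file
#'
#' Reads species (ids, initial concentrations, boundary flags), global and
#' reaction-local parameters, and kinetic laws (a MathML subset: `+ - * /`
#' and `power`) from SBML. SBML carries no carbon-atom maps, KIE factors or
#' label inputs, so those come from a sidecar file in the YAML dialect whose
#' reaction ids and species ids match the SBML ones: the sidecar supplies
#' `atoms` per reaction, each metabolite's `atoms` count, and optional `kie`
#' / `label_input` sections. Reversible SBML reactions must either provide
#' `forward`/`backward` expressions in the sidecar or name their
#' equilibrium-constant symbol as `keq`, in which case the net law is split
#' with [decompose_rate_law()].
#'
#' @param path SBML file.
#' @param sidecar YAML sidecar file (same layout as [read_network()], rate
#'   expressions optional).
#' @return A validated `kie_network`.
#' @export
read_sbml_kinetics <- function(path, sidecar) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  side <- yaml::read_yaml(sidecar)
  side_rx <- stats::setNames(side$reactions,
                             vapply(side$reactions, `[[`, character(1), "id"))
  side_met <- stats::setNames(side$metabolites,
                              vapply(side$metabolites, `[[`, character(1), "id"))

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- dplyr::bind_rows(lapply(sp, function(s) {
    id <- xml2::xml_attr(s, "id")
    if (is.null(side_met[[id]])) {
      stop("species '", id, "' has no atoms entry in the sidecar", call. = FALSE)
    }
    tibble::tibble(id = id,
                   n_atoms = as.integer(side_met[[id]]$atoms),
                   boundary = identical(xml2::xml_attr(s, "boundaryCondition"), "true"),
                   initial_conc = as.numeric(xml2::xml_attr(s, "initialConcentration") %||% 0))
  }))

  pars <- c()
  for (p in xml2::xml_find_all(doc, ".//listOfParameters/parameter")) {
    pars[xml2::xml_attr(p, "id")] <- as.numeric(xml2::xml_attr(p, "value"))
  }

  rxns <- lapply(xml2::xml_find_all(doc, ".//listOfReactions/reaction"), function(r) {
    id <- xml2::xml_attr(r, "id")
    sc <- side_rx[[id]]
    if (is.null(sc) || is.null(sc$atoms)) {
      stop("reaction '", id, "' has no atom map in the sidecar", call. = FALSE)
    }
    math <- xml2::xml_find_first(r, ".//kineticLaw/math")
    net <- if (!inherits(math, "xml_missing")) mathml_to_expr(math) else NULL
    reversible <- identical(xml2::xml_attr(r, "reversible"), "true")
    if (!is.null(sc$forward)) {
      fwd <- sc$forward
      bwd <- sc$backward
    } else if (reversible) {
      if (is.null(sc$keq)) {
        stop("reversible reaction '", id, "' needs sidecar forward/backward ",
             "expressions or a 'keq' symbol name", call. = FALSE)
      }
      parts <- decompose_rate_law(net, sc$keq)
      fwd <- parts$forward
      bwd <- parts$backward
    } else {
      fwd <- net
      bwd <- NULL
    }
    reaction(id, sc$atoms, fwd, backward = bwd)
  })

  network_model(mets, rxns, parameters = pars,
                kie = if (length(side$kie)) dplyr::bind_rows(lapply(side$kie, tibble::as_tibble)) else NULL,
                label_input = lapply(side$label_input, function(x) {
                  v <- unlist(x)
                  stats::setNames(as.numeric(v), names(v))
                }),
                natural_abundance = side$natural_abundance %||% 0.0107)
}

#' Load a network model from file
#'
#' Dispatches on format: the YAML dialect (`.yml`/`.yaml`) or SBML (`.xml`/
#' `.sbml`, which requires `sidecar`).
#'
#' @param path Model file.
#' @param sidecar Sidecar dialect file (SBML only).
#' @return A validated `kie_network`.
#' @export
load_model <- function(path, sidecar = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) return(read_network(path))
  if (ext %in% c("xml", "sbml")) {
    if (is.null(sidecar)) stop("SBML import needs a sidecar dialect file",
                               call. = FALSE)
    return(read_sbml_kinetics(path, sidecar))
  }
  stop("unknown model format '", ext, "'", call. = FALSE)
}
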