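#' Enumerate the isotopomers of a network
#'
#' Lists every binary labeling state of every pool, in the canonical order:
#' metabolite declaration order, then patterns ascending as binary integers.
#' The full index (boundary pools included) defines the layout of the state
#' vector; the dynamic counts exclude clamped boundary pools, matching how
#' model sizes are usually quoted (states whose dynamics are simulated).
#'
#' @param model A validated `kie_network`.
#' @return Tibble with columns `index`, `metabolite`, `pattern`, `weight`
#'   (number of heavy atoms) and `boundary`. Attributes: `n_isotopomers`
#'   and `n_isotopologues` (dynamic pools), `n_total` and
#'   `n_isotopologues_total` (all pools).
#' @examples
#' iso <- enumerate_isotopomers(toy_fixture())
#' attr(iso, "n_total")
#' @export
enumerate_isotopomers <- function(model) {
  mets <- model$metabolites
  pools <- lapply(seq_len(nrow(mets)), function(i) {
    pats <- iso_patterns(mets$n_atoms[i])
    tibble::tibble(metabolite = mets$id[i], pattern = pats,
                   weight = vapply(pats, pattern_weight, integer(1)),
                   boundary = mets$boundary[i])
  })
  out <- dplyr::bind_rows(pools)
  out <- tibble::add_column(out, index = seq_len(nrow(out)), .before = 1)
  dyn <- !mets$boundary
  attr(out, "n_isotopomers") <- as.integer(sum(2^mets$n_atoms[dyn]))
  attr(out, "n_isotopologues") <- as.integer(sum(mets$n_atoms[dyn] + 1L))
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_isotopologues_total") <- as.integer(sum(mets$n_atoms + 1L))
  out
}

# Pattern index tuples for one component, odometer order with the last
# substrate fastest. Returns an integer matrix (n_fluxomers x n_substrates)
# of pattern integers (0-based).
component_pattern_grid <- function(n_atoms_per_substrate) {
  sizes <- 2^n_atoms_per_substrate
  k <- prod(sizes)
  ns <- length(sizes)
  out <- matrix(0L, nrow = k, ncol = ns)
  if (ns == 0) return(out)
  each <- rev(cumprod(rev(c(sizes[-1], 1))))  # block length per substrate
  for (j in seq_len(ns)) {
    out[, j] <- rep(rep(0:(sizes[j] - 1L), each = each[j]),
                    length.out = k)
  }
  out
}

#' Enumerate the fluxomers of a network
#'
#' A fluxomer is one (unidirectional rate component, combination of substrate
#' isotopomers) pair: components with one n-carbon substrate contribute `2^n`
#' fluxomers, multi-substrate components the full cross product of their
#' substrate isotopomer sets. Ordering is deterministic: reaction declaration
#' order, forward before backward, then substrate patterns in odometer order
#' (last substrate fastest).
#'
#' @param model A validated `kie_network`.
#' @return Tibble with columns `index`, `component`, `reaction`, `direction`,
#'   `substrates` (ids joined by `+`) and `patterns` (substrate patterns
#'   joined by `+`, same order).
#' @examples
#' nrow(enumerate_fluxomers(toy_fixture()))
#' @export
enumerate_fluxomers <- function(model) {
  n_of <- stats::setNames(model$metabolites$n_atoms, model$metabolites$id)
  comps <- rate_components(model)
  blocks <- lapply(comps, function(cp) {
    smet <- vapply(cp$substrates, `[[`, character(1), "met")
    na <- n_of[smet]
    grid <- component_pattern_grid(na)
    pat_str <- lapply(seq_along(smet), function(j) {
      iso_patterns(na[j])[grid[, j] + 1L]
    })
    tibble::tibble(component = cp$cid, reaction = cp$reaction,
                   direction = cp$direction,
                   substrates = paste(smet, collapse = "+"),
                   patterns = do.call(paste, c(pat_str, sep = "+")))
  })
  out <- dplyr::bind_rows(blocks)
  tibble::add_column(out, index = seq_len(nrow(out)), .before = 1)
}
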