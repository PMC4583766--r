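# Assembly of the isotopomer balance system: the sparse incidence matrix U
# (rows = isotopomers, columns = fluxomers), the KIE factor vector a, and the
# machinery evaluating the fluxomer vector f so that dI/dt = U (f o a).

# 0-based row offset of each pool in the isotopomer index
pool_offsets <- function(model) {
  n <- model$metabolites$n_atoms
  stats::setNames(cumsum(c(0L, 2^n[-length(n)])), model$metabolites$id)
}

# bits (MSB-first) of the 0-based pattern integers `g` of an n-atom pool:
# matrix length(g) x n
int_bits <- function(g, n) {
  out <- matrix(0L, nrow = length(g), ncol = n)
  for (i in seq_len(n)) out[, i] <- (g %/% 2^(n - i)) %% 2L
  out
}

# Per-component structural data shared by U / alpha / rate assembly.
component_structure <- function(model) {
  n_of <- stats::setNames(model$metabolites$n_atoms, model$metabolites$id)
  offs <- pool_offsets(model)
  comps <- rate_components(model)
  lapply(comps, function(cp) {
    smet <- vapply(cp$substrates, `[[`, character(1), "met")
    na <- unname(n_of[smet])
    grid <- component_pattern_grid(na)
    k <- nrow(grid)
    # substrate isotopomer rows, one column per substrate
    sub_rows <- matrix(0L, nrow = k, ncol = length(smet))
    for (j in seq_along(smet)) sub_rows[, j] <- offs[[smet[j]]] + grid[, j] + 1L
    # bit values by slot letter
    slot_bits <- do.call(cbind, lapply(seq_along(smet), function(j) {
      b <- int_bits(grid[, j], na[j])
      colnames(b) <- cp$substrates[[j]]$slots
      b
    }))
    # product isotopomer rows (declared pools only)
    prods <- Filter(function(p) p$met %in% model$metabolites$id, cp$products)
    prod_rows <- matrix(0L, nrow = k, ncol = length(prods))
    for (j in seq_along(prods)) {
      p <- prods[[j]]
      np <- length(p$slots)
      g <- rep(0L, k)
      for (i in seq_len(np)) g <- g + slot_bits[, p$slots[i]] * 2L^(np - i)
      prod_rows[, j] <- offs[[p$met]] + g + 1L
    }
    list(cid = cp$cid, reaction = cp$reaction, direction = cp$direction,
         rate = cp$rate, smet = smet, n_atoms = na, grid = grid,
         n_flux = k, sub_rows = sub_rows, prod_rows = prod_rows)
  })
}

#' Assemble the sparse isotopomer/fluxomer incidence matrix
#'
#' Each column describes one fluxomer: -1 at every consumed substrate
#' isotopomer and +1 at every product isotopomer obtained by pushing the
#' substrate patterns through the component's atom map (entries at identical
#' positions are summed). Rows of boundary pools are zeroed: their state is
#' clamped, so no fluxomer changes them. Carbon carried by undeclared
#' (external) products leaves the mapped system.
#'
#' @param model A validated `kie_network`.
#' @param iso,flux Optional pre-computed [enumerate_isotopomers()] /
#'   [enumerate_fluxomers()] indices of the same model (used for dimnames).
#' @return A `Matrix::dgCMatrix` of size n_isotopomers x n_fluxomers.
#' @export
assemble_incidence <- function(model, iso = enumerate_isotopomers(model),
                               flux = enumerate_fluxomers(model)) {
  str <- component_structure(model)
  n_iso <- nrow(iso)
  ii <- jj <- xx <- vector("list", 2L * length(str))
  col0 <- 0L
  for (s in seq_along(str)) {
    cp <- str[[s]]
    cols <- col0 + seq_len(cp$n_flux)
    ii[[2L * s - 1L]] <- as.vector(cp$sub_rows)
    jj[[2L * s - 1L]] <- rep(cols, times = ncol(cp$sub_rows))
    xx[[2L * s - 1L]] <- rep(-1, length(cp$sub_rows))
    if (ncol(cp$prod_rows)) {
      ii[[2L * s]] <- as.vector(cp$prod_rows)
      jj[[2L * s]] <- rep(cols, times = ncol(cp$prod_rows))
      xx[[2L * s]] <- rep(1, length(cp$prod_rows))
    }
    col0 <- col0 + cp$n_flux
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  keep <- !iso$boundary[i]  # clamp boundary pools
  U <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                            dims = c(n_iso, col0))
  dimnames(U) <- list(paste(iso$metabolite, iso$pattern, sep = "."),
                      paste(flux$component, flux$patterns, sep = ":"))
  U
}

# KIE factor of every pattern of one (reaction, substrate) pair:
# product of single-position entries over labeled positions (cumulative KIEs),
# with exact multi-labeled entries overriding the product rule.
alpha_pattern_vector <- function(kie, reaction, met, n) {
  out <- rep(1, 2^n)
  sub <- kie[kie$reaction == reaction & kie$metabolite == met, , drop = FALSE]
  if (!nrow(sub)) return(out)
  pos_alpha <- rep(1, n)
  singles <- sub[vapply(sub$pattern, pattern_weight, integer(1)) == 1L, , drop = FALSE]
  for (i in seq_len(nrow(singles))) {
    pos_alpha[which(pattern_bits(singles$pattern[i]) == 1L)] <- singles$alpha[i]
  }
  bits <- int_bits(0:(2^n - 1L), n)
  for (p in seq_len(2^n)) out[p] <- prod(pos_alpha[bits[p, ] == 1L])
  multi <- sub[vapply(sub$pattern, pattern_weight, integer(1)) > 1L, , drop = FALSE]
  for (i in seq_len(nrow(multi))) {
    out[pattern_int(multi$pattern[i]) + 1L] <- multi$alpha[i]
  }
  out
}

#' Assemble the vector of KIE factors per fluxomer
#'
#' The factor of a fluxomer is the product, over its substrates, of the
#' pattern's KIE factor for that (reaction, substrate) pair; the factor of a
#' multiply labeled pattern is the product of its single-position table
#' entries (cumulative KIEs). Pairs absent from the table contribute 1, so an
#' empty table yields the all-ones vector and the all-light combination is
#' always exactly 1.
#'
#' @inheritParams assemble_incidence
#' @return Numeric vector aligned with [enumerate_fluxomers()].
#' @export
assemble_alphas <- function(model, flux = enumerate_fluxomers(model)) {
  str <- component_structure(model)
  out <- vector("list", length(str))
  for (s in seq_along(str)) {
    cp <- str[[s]]
    a <- rep(1, cp$n_flux)
    for (j in seq_along(cp$smet)) {
      av <- alpha_pattern_vector(model$kie, cp$reaction, cp$smet[j], cp$n_atoms[j])
      a <- a * av[cp$grid[, j] + 1L]
    }
    out[[s]] <- a
  }
  stats::setNames(unlist(out), paste(flux$component, flux$patterns, sep = ":"))
}

#' Compile a network into a ready-to-integrate isotopic system
#'
#' Builds, once, everything needed to evaluate the isotopomer balances:
#' indices, the sparse incidence matrix, KIE factors, and fast lookups from
#' fluxomers to their substrate isotopomers.
#'
#' @param model A validated `kie_network`.
#' @return A `kie_system` list; see [compute_fluxomers()] and [iso_rhs()].
#' @export
kie_system <- function(model) {
  iso <- enumerate_isotopomers(model)
  flux <- enumerate_fluxomers(model)
  str <- component_structure(model)
  n_iso <- nrow(iso)
  n_flux <- nrow(flux)
  offs <- pool_offsets(model)
  mets <- model$metabolites

  pool_of_iso <- rep(seq_len(nrow(mets)), times = 2^mets$n_atoms)
  agg <- Matrix::sparseMatrix(i = pool_of_iso, j = seq_len(n_iso), x = 1,
                              dims = c(nrow(mets), n_iso))
  unlabeled_idx <- unname(offs) + 1L

  comp_of_flux <- rep(seq_along(str), times = vapply(str, `[[`, integer(1), "n_flux"))
  max_s <- max(vapply(str, function(cp) ncol(cp$sub_rows), integer(1)))
  sub_idx <- matrix(n_iso + 1L, nrow = n_flux, ncol = max_s)  # pad -> abundance 1
  row0 <- 0L
  for (cp in str) {
    rows <- row0 + seq_len(cp$n_flux)
    sub_idx[rows, seq_len(ncol(cp$sub_rows))] <- cp$sub_rows
    row0 <- row0 + cp$n_flux
  }

  cids <- vapply(str, `[[`, character(1), "cid")
  rev_pairs <- NULL
  for (rx in model$reactions) {
    if (rx$reversible) {
      rev_pairs <- rbind(rev_pairs, c(match(paste0(rx$id, ".fwd"), cids),
                                      match(paste0(rx$id, ".bwd"), cids)))
    }
  }

  env <- new.env(parent = baseenv())
  for (p in names(model$parameters)) assign(p, model$parameters[[p]], envir = env)

  structure(list(model = model, iso = iso, flux = flux,
                 n_iso = n_iso, n_flux = n_flux,
                 U = assemble_incidence(model, iso, flux),
                 alpha = unname(assemble_alphas(model, flux)),
                 components = str,
                 component_ids = cids,
                 comp_of_flux = comp_of_flux,
                 sub_idx = sub_idx,
                 pool_of_iso = pool_of_iso,
                 agg = agg,
                 unlabeled_idx = unlabeled_idx,
                 boundary_pool = mets$boundary,
                 rev_pairs = rev_pairs,
                 rate_env = env),
            class = "kie_system")
}

#' @export
print.kie_system <- function(x, ...) {
  cat("<kie_system> ", x$n_iso, " isotopomers x ", x$n_flux, " fluxomers, ",
      length(x$components), " rate components, ",
      length(x$U@x), " nonzeros in U\n", sep = "")
  invisible(x)
}

# Relative isotopomer abundances from a (clamped-nonnegative) state vector.
# A pool with zero total mass gets the all-light point mass, so downstream
# products are well defined; its consuming rate laws vanish there anyway.
relative_abundances <- function(sys, I) {
  Ic <- pmax(I, 0)
  M <- as.vector(sys$agg %*% Ic)
  ab <- Ic / M[sys$pool_of_iso]
  zero <- M <= 0
  if (any(zero)) {
    ab[zero[sys$pool_of_iso]] <- 0
    ab[sys$unlabeled_idx[zero]] <- 1
  }
  list(ab = ab, M = M)
}

# Unidirectional component rates at pool totals M. In the exchange-free model
# variant each reversible pair is collapsed onto its net rate, assigned to the
# component of the current net direction (the other one gets 0).
component_rates <- function(sys, M) {
  env <- sys$rate_env
  ids <- sys$model$metabolites$id
  for (i in seq_along(ids)) assign(ids[i], M[i], envir = env)
  v <- vapply(sys$components, function(cp) eval(cp$rate, envir = env), numeric(1))
  if (!isTRUE(sys$model$exchange) && !is.null(sys$rev_pairs)) {
    net <- v[sys$rev_pairs[, 1]] - v[sys$rev_pairs[, 2]]
    v[sys$rev_pairs[, 1]] <- pmax(net, 0)
    v[sys$rev_pairs[, 2]] <- pmax(-net, 0)
  }
  v
}

#' Evaluate the fluxomer vector at a state
#'
#' The fluxomer of component r and substrate combination p is the absolute
#' rate `f_r^p = v_r(M) * prod(relative abundances of the combination's
#' patterns)`: the component rate is distributed over substrate isotopomer
#' combinations in proportion to their joint relative abundance, so the
#' fluxomers of a component always sum back to its rate. KIE factors are not
#' applied here; they enter as the element-wise product in [iso_rhs()].
#'
#' @param sys A `kie_system` (or a `kie_network`, compiled on the fly).
#' @param state Numeric state vector in [enumerate_isotopomers()] order.
#' @return Numeric vector of fluxomer rates aligned with
#'   [enumerate_fluxomers()].
#' @export
compute_fluxomers <- function(sys, state) {
  if (inherits(sys, "kie_network")) sys <- kie_system(sys)
  ra <- relative_abundances(sys, state)
  v <- component_rates(sys, ra$M)
  f <- v[sys$comp_of_flux]
  ab_ext <- c(ra$ab, 1)
  for (j in seq_len(ncol(sys$sub_idx))) f <- f * ab_ext[sys$sub_idx[, j]]
  f
}

#' Right-hand side of the isotopomer balance system
#'
#' Computes `dI/dt = U (f o a)`: the fluxomer vector at the current state,
#' weighted element-wise by the KIE factors, then mapped onto isotopomer
#' balances by the sparse incidence matrix. Rows of boundary pools are zero
#' (their concentration and labeling are clamped).
#'
#' @inheritParams compute_fluxomers
#' @param kie_on If `FALSE`, all KIE factors are replaced by 1.
#' @return Numeric vector of isotopomer time derivatives.
#' @export
iso_rhs <- function(sys, state, kie_on = TRUE) {
  if (inherits(sys, "kie_network")) sys <- kie_system(sys)
  f <- compute_fluxomers(sys, state)
  w <- if (kie_on) f * sys$alpha else f
  dI <- as.vector(sys$U %*% w)
  if (any(!is.finite(dI))) {
    bad <- which(!is.finite(dI))
    stop("non-finite isotopomer derivatives at rows ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (state dump: ", paste(format(utils::head(state[bad], 5)), collapse = ", "),
         ")", call. = FALSE)
  }
  dI
}
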