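# Independent brute-force oracle for the toy network: the isotopomer
# balances written out one by one with explicit loops over labeling states,
# coded directly from the per-pool balance equations (production by each
# feeding fluxomer weighted by its fractionation factor, minus consumption).
# Deliberately shares no code with the package's matrix assembly.

# fractionation factor of (reaction, metabolite, bits) under the cumulative
# rule, from a table of singly labeled entries
oracle_alpha <- function(kie, rx, met, bits) {
  a <- 1
  rows <- which(kie$reaction == rx & kie$metabolite == met)
  for (i in rows) {
    entry_bits <- as.integer(strsplit(kie$pattern[i], "")[[1]])
    pos <- which(entry_bits == 1L)
    if (length(pos) == 1L && bits[pos] == 1L) a <- a * kie$alpha[i]
  }
  a
}

# state: named vector "MET.pattern" over the toy network's 38 isotopomers.
# Returns the derivative vector in the same order.
toy_oracle_rhs <- function(state, pars, kie) {
  g <- function(met, bits) state[[paste0(met, ".", paste(bits, collapse = ""))]]
  bits3 <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  tot <- function(met, nb) {
    s <- 0
    if (nb == 3) for (r in seq_len(8)) s <- s + g(met, unlist(bits3[r, ]))
    if (nb == 2) for (a in 0:1) for (b in 0:1) s <- s + g(met, c(a, b))
    if (nb == 1) s <- g(met, 0) + g(met, 1)
    s
  }
  S <- tot("S", 3); A <- tot("A", 3); B <- tot("B", 3)
  C <- tot("C", 1); D <- tot("D", 2); E <- tot("E", 3)
  v1 <- pars[["Vmax1"]] * S / (pars[["Km1"]] + S)
  v2 <- pars[["Vmax2"]] * A / (pars[["Km2"]] + A)
  v3f <- pars[["k3f"]] * B
  v3b <- pars[["k3b"]] * C * D
  v4 <- pars[["Vmax4"]] * B / (pars[["Km4"]] + B)
  v5 <- pars[["Vmax5"]] * C / (pars[["Km5"]] + C)
  v6 <- pars[["Vmax6"]] * D / (pars[["Km6"]] + D)
  v7 <- pars[["Vmax7"]] * E / (pars[["Km7"]] + E)
  rb <- function(met, bits, total) if (total > 0) g(met, bits) / total else 0
  al <- function(rx, met, bits) oracle_alpha(kie, rx, met, bits)

  d <- setNames(numeric(length(state)), names(state))
  # S clamped
  for (r in seq_len(8)) {
    p <- unlist(bits3[r, ])  # (a, b, c)
    # A balance: produced from S (same pattern), consumed by v2
    d[[paste0("A.", paste(p, collapse = ""))]] <-
      al("v1", "S", p) * v1 * rb("S", p, S) -
      al("v2", "A", p) * v2 * rb("A", p, A)
    # B_{x,y,z}: from A_{x,z,y} (v2 inverts positions 2 and 3), from C+D
    # through the backward cleavage, out through v3 forward and v4
    x <- p[1]; y <- p[2]; z <- p[3]
    d[[paste0("B.", paste(c(x, y, z), collapse = ""))]] <-
      al("v2", "A", c(x, z, y)) * v2 * rb("A", c(x, z, y), A) +
      al("v3", "C", x) * al("v3", "D", c(y, z)) * v3b *
        rb("C", x, C) * rb("D", c(y, z), D) -
      al("v3", "B", c(x, y, z)) * v3f * rb("B", c(x, y, z), B) -
      al("v4", "B", c(x, y, z)) * v4 * rb("B", c(x, y, z), B)
    # E from B (pattern preserved), out through v7
    d[[paste0("E.", paste(p, collapse = ""))]] <-
      al("v4", "B", p) * v4 * rb("B", p, B) -
      al("v7", "E", p) * v7 * rb("E", p, E)
  }
  for (x in 0:1) {
    acc <- 0
    for (y in 0:1) for (z in 0:1) {
      acc <- acc + al("v3", "B", c(x, y, z)) * v3f * rb("B", c(x, y, z), B) -
        al("v3", "C", x) * al("v3", "D", c(y, z)) * v3b *
          rb("C", x, C) * rb("D", c(y, z), D)
    }
    d[[paste0("C.", x)]] <- acc - al("v5", "C", x) * v5 * rb("C", x, C)
  }
  for (y in 0:1) for (z in 0:1) {
    acc <- 0
    for (x in 0:1) {
      acc <- acc + al("v3", "B", c(x, y, z)) * v3f * rb("B", c(x, y, z), B) -
        al("v3", "C", x) * al("v3", "D", c(y, z)) * v3b *
          rb("C", x, C) * rb("D", c(y, z), D)
    }
    d[[paste0("D.", paste(c(y, z), collapse = ""))]] <-
      acc - al("v6", "D", c(y, z)) * v6 * rb("D", c(y, z), D)
  }
  d
}

# slow independent recount of the fluxomer total: per unidirectional
# component, the product over its substrates of 2^(carbon count)
slow_fluxomer_count <- function(model) {
  n_of <- setNames(model$metabolites$n_atoms, model$metabolites$id)
  total <- 0
  for (rx in model$reactions) {
    sides <- strsplit(rx$atoms, "->", fixed = TRUE)[[1]]
    count_side <- function(side) {
      terms <- regmatches(side, gregexpr("[A-Za-z0-9_]+\\(", side))[[1]]
      mets <- sub("\\($", "", terms)
      prod(2^n_of[mets])
    }
    total <- total + count_side(sides[1])
    if (rx$reversible) total <- total + count_side(sides[2])
  }
  total
}

# random strictly positive toy state in enumeration order
random_toy_state <- function(sys) {
  setNames(runif(sys$n_iso, 0.01, 1),
           paste(sys$iso$metabolite, sys$iso$pattern, sep = "."))
}
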