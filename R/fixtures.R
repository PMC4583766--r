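# Built-in networks: a small fully parameterized toy network and the
# structure of the E. coli glucose-uptake / glycolysis / pentose-phosphate
# network with published 13C fractionation factors.

#' Toy network fixture
#'
#' A six-pool example network: a clamped boundary substrate S feeds A (v1),
#' A is converted to B with carbon inversion (v2), B is reversibly cleaved
#' into C + D (v3, the only reversible step), B is also converted to E (v4),
#' and C, D, E leave through saturable sink reactions (v5-v7). Carbon counts
#' are 3,3,3,1,2,3 for S,A,B,C,D,E. Irreversible steps use irreversible
#' Michaelis-Menten kinetics; v3 uses a reversible mass-action law
#' `k3f*B - k3b*C*D`, which decomposes exactly into nonnegative components.
#' Parameters are chosen to give a unique strictly positive stable steady
#' state with substantial bidirectional exchange through v3 (backward rate
#' about 60 % of the forward rate). No KIE entries are attached by default;
#' see [toy_kie_table()] for an example set.
#'
#' @param kie Optional KIE table to attach (e.g. [toy_kie_table()]).
#' @param label_input Tracer specification for S passed to
#'   [build_label_input()]; default all-light.
#' @return A validated `kie_network`.
#' @examples
#' toy_fixture()
#' @export
toy_fixture <- function(kie = NULL, label_input = c(unlabeled = 1)) {
  mets <- tibble::tibble(
    id = c("S", "A", "B", "C", "D", "E"),
    n_atoms = c(3L, 3L, 3L, 1L, 2L, 3L),
    boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    initial_conc = c(1, 0.5, 0.5, 0.2, 0.2, 0.3))
  rxns <- list(
    reaction("v1", "S(abc) -> A(abc)", "Vmax1 * S / (Km1 + S)"),
    reaction("v2", "A(abc) -> B(acb)", "Vmax2 * A / (Km2 + A)"),
    reaction("v3", "B(abc) -> C(a) + D(bc)", "k3f * B", backward = "k3b * C * D"),
    reaction("v4", "B(abc) -> E(abc)", "Vmax4 * B / (Km4 + B)"),
    reaction("v5", "C(a) -> SINK_C(a)", "Vmax5 * C / (Km5 + C)"),
    reaction("v6", "D(ab) -> SINK_D(ab)", "Vmax6 * D / (Km6 + D)"),
    reaction("v7", "E(abc) -> SINK_E(abc)", "Vmax7 * E / (Km7 + E)"))
  pars <- c(Vmax1 = 2, Km1 = 1, Vmax2 = 3, Km2 = 1,
            k3f = 4, k3b = 8, Vmax4 = 2, Km4 = 1,
            Vmax5 = 2, Km5 = 0.5, Vmax6 = 2, Km6 = 0.5,
            Vmax7 = 2, Km7 = 1)
  network_model(mets, rxns, pars, kie = kie,
                label_input = list(S = build_label_input(3, label_input)))
}

#' Example KIE table for the toy network
#'
#' Illustrative fractionation factors (not measured values) exercising both
#' map directions: entries on the forward substrates of v1-v5 and on the
#' backward substrates (C, D) of the reversible cleavage v3.
#'
#' @return Tibble with columns `reaction`, `metabolite`, `pattern`, `alpha`.
#' @export
toy_kie_table <- function() {
  tibble::tribble(
    ~reaction, ~metabolite, ~pattern, ~alpha,
    "v2", "A", "100", 0.980,
    "v2", "A", "010", 0.970,
    "v3", "B", "100", 0.985,
    "v3", "C", "1",   0.990,
    "v3", "D", "10",  0.995,
    "v4", "B", "001", 0.990,
    "v5", "C", "1",   0.982)
}

#' Measured 13C kinetic isotope effects of five central metabolic enzymes
#'
#' Fractionation factors (rate with the given substrate isotopomer over the
#' rate with the all-light isotopomer) measured in vitro for singly labeled
#' isotopomers: 6-phosphogluconate dehydrogenase (GND), glucose-6-phosphate
#' dehydrogenase (G6PDH), fructose-1,6-bisphosphate aldolase (ALD),
#' ribulose-5-phosphate epimerase (RPE) and pyruvate dehydrogenase (PDH).
#' Factors of multiply labeled isotopomers follow by the cumulative
#' (multiplicative) rule applied in [assemble_alphas()].
#'
#' @return Tibble with columns `reaction`, `metabolite`, `pattern`, `alpha`
#'   (11 entries, 5 enzymes).
#' @export
ecoli_kie_table <- function() {
  tibble::tribble(
    ~reaction, ~metabolite, ~pattern,  ~alpha,
    "GND",     "PGN",       "100000",  0.9905,
    "G6PDH",   "G6P",       "100000",  0.9837,
    "ALD",     "FBP",       "001000",  0.9843,
    "RPE",     "RU5P",      "01000",   0.9931,
    "RPE",     "RU5P",      "00100",   0.9818,
    "RPE",     "RU5P",      "00010",   0.9852,
    "RPE",     "RU5P",      "00001",   0.9980,
    "PDH",     "PYR",       "100",     0.9908,
    "PDH",     "PYR",       "010",     0.9791,
    "PDH",     "PYR",       "001",     0.9969)
}

# The 17 intracellular metabolites of the E. coli glycolysis/PPP model with
# their carbon counts, plus the clamped extracellular glucose pool.
ecoli_metabolites <- function() {
  tibble::tibble(
    id = c("GLCx", "G6P", "F6P", "FBP", "GAP", "DHAP", "PGP", "PG3", "PG2",
           "PEP", "PYR", "PGN", "RU5P", "X5P", "R5P", "S7P", "E4P", "G1P"),
    n_atoms = c(6L, 6L, 6L, 6L, 3L, 3L, 3L, 3L, 3L,
                3L, 3L, 6L, 5L, 5L, 5L, 7L, 4L, 6L),
    boundary = c(TRUE, rep(FALSE, 17)),
    initial_conc = c(1, rep(0.5, 17)))
}

#' Synthetic kinetic parameter bundle for the E. coli network
#'
#' A synthetic, internally consistent set of kinetic constants for
#' [ecoli_fixture()]: saturable (Michaelis-Menten) laws for irreversible
#' enzymes, mass-action forward/backward laws for the 13 reversible ones,
#' first-order growth dilution, and one enzyme-level multiplier `E_*` per
#' enzymatic reaction (the quantities scanned in sensitivity analyses).
#' These values are NOT the published kinetic parameters of the underlying
#' E. coli model (which live in that model's supplementary material); they
#' are chosen to give a strictly positive steady state with a realistic
#' glycolysis / pentose-phosphate split and substantial bidirectional
#' exchange, so the full pipeline can run on the real network structure.
#' Quantitative predictions therefore characterize this synthetic kinetic
#' state, not E. coli itself.
#'
#' @return Named numeric parameter vector.
#' @export
ecoli_synthetic_parameters <- function() {
  c(# uptake
    Vmax_PTS = 1.2, Km_PTS_glc = 0.1, Km_PTS_pep = 0.1,
    # reversible mass action (kf, kb)
    kf_PGI = 20, kb_PGI = 15, kf_PGM = 1, kb_PGM = 2,
    kf_ALD = 10, kb_ALD = 8, kf_TIS = 20, kb_TIS = 25,
    kf_GAPDH = 15, kb_GAPDH = 10, kf_PGK = 20, kb_PGK = 15,
    kf_GPM = 20, kb_GPM = 15, kf_ENO = 20, kb_ENO = 15,
    kf_RPE = 10, kb_RPE = 8, kf_R5PI = 10, kb_R5PI = 8,
    kf_TKA = 8, kb_TKA = 6, kf_TKB = 8, kb_TKB = 6, kf_TA = 8, kb_TA = 6,
    # irreversible Michaelis-Menten
    Vmax_G6PDH = 0.6, Km_G6PDH = 0.5, Vmax_PFK = 2, Km_PFK = 0.3,
    Vmax_PK = 1.5, Km_PK = 0.3, Vmax_PDH = 1.5, Km_PDH = 0.3,
    Vmax_PPC = 0.3, Km_PPC = 0.3, Vmax_SYNTH1 = 0.1, Km_SYNTH1 = 0.3,
    Vmax_SYNTH2 = 0.1, Km_SYNTH2 = 0.3, k_DAHPS = 0.05,
    Vmax_G3PDH = 0.05, Km_G3PDH = 0.3, Vmax_GND = 0.7, Km_GND = 0.3,
    Vmax_MURSYNTH = 0.02, Km_MURSYNTH = 0.3, Vmax_RPPK = 0.05, Km_RPPK = 0.2,
    Vmax_G1PAT = 0.02, Km_G1PAT = 0.2, Vmax_SERSYNTH = 0.1, Km_SERSYNTH = 0.3,
    # growth dilution
    mu = 0.001,
    # enzyme levels (one per enzymatic reaction)
    stats::setNames(rep(1, 28),
                    paste0("E_", c("PTS", "PGI", "PGM", "G6PDH", "PFK", "ALD",
                                   "TIS", "GAPDH", "PGK", "GPM", "ENO", "PK",
                                   "PDH", "PPC", "SYNTH1", "SYNTH2", "DAHPS",
                                   "G3PDH", "GND", "RPE", "R5PI", "TKA", "TKB",
                                   "TA", "MURSYNTH", "RPPK", "G1PAT", "SERSYNTH"))))
}

#' E. coli glycolysis / pentose-phosphate network fixture
#'
#' The central carbon network of Escherichia coli used throughout the
#' package: clamped extracellular glucose plus 17 intracellular metabolites,
#' 45 reactions (13 reversible and 32 irreversible, 17 of which are
#' first-order growth-dilution losses), standard carbon-atom transitions, and
#' the measured 13C fractionation factors of [ecoli_kie_table()] attached to
#' GND, G6PDH, ALD, RPE and PDH. Enumeration yields 616 dynamic isotopomers
#' (94 isotopologues) and 7376 fluxomers over 58 unidirectional rate
#' components.
#'
#' The network structure is always available; rate laws reference a kinetic
#' parameter bundle that must be supplied to simulate. Pass
#' [ecoli_synthetic_parameters()] (a synthetic stand-in bundle, see its
#' documentation) or your own transcription of published kinetic constants.
#'
#' @param parameters Named numeric kinetic parameter bundle, or `NULL` for
#'   the structure-only model (enumeration and matrix assembly work;
#'   simulation raises an informative error).
#' @param label_input Tracer specification for extracellular glucose, passed
#'   to [build_label_input()]; default natural 13C abundance.
#' @param kie KIE table (default [ecoli_kie_table()]); use `NULL` for none.
#' @return A validated `kie_network`.
#' @examples
#' attr(enumerate_isotopomers(ecoli_fixture()), "n_isotopomers")
#' @export
ecoli_fixture <- function(parameters = NULL,
                          label_input = c(natural = 1),
                          kie = ecoli_kie_table()) {
  mm <- function(id, S) sprintf("E_%s * Vmax_%s * %s / (Km_%s + %s)", id, id, S, id, S)
  rev_ma <- function(id, subs, prods) {
    list(f = sprintf("E_%s * kf_%s * %s", id, id, paste(subs, collapse = " * ")),
         b = sprintf("E_%s * kb_%s * %s", id, id, paste(prods, collapse = " * ")))
  }
  rxns <- list(
    reaction("PTS", "GLCx(abcdef) + PEP(ghi) -> G6P(abcdef) + PYR(ghi)",
             "E_PTS * Vmax_PTS * GLCx / (Km_PTS_glc + GLCx) * PEP / (Km_PTS_pep + PEP)"),
    with(rev_ma("PGI", "G6P", "F6P"),
         reaction("PGI", "G6P(abcdef) -> F6P(abcdef)", f, b)),
    with(rev_ma("PGM", "G6P", "G1P"),
         reaction("PGM", "G6P(abcdef) -> G1P(abcdef)", f, b)),
    reaction("G6PDH", "G6P(abcdef) -> PGN(abcdef)", mm("G6PDH", "G6P")),
    reaction("PFK", "F6P(abcdef) -> FBP(abcdef)", mm("PFK", "F6P")),
    with(rev_ma("ALD", "FBP", c("DHAP", "GAP")),
         reaction("ALD", "FBP(abcdef) -> DHAP(cba) + GAP(def)", f, b)),
    with(rev_ma("TIS", "DHAP", "GAP"),
         reaction("TIS", "DHAP(abc) -> GAP(cba)", f, b)),
    with(rev_ma("GAPDH", "GAP", "PGP"),
         reaction("GAPDH", "GAP(abc) -> PGP(abc)", f, b)),
    with(rev_ma("PGK", "PGP", "PG3"),
         reaction("PGK", "PGP(abc) -> PG3(abc)", f, b)),
    with(rev_ma("GPM", "PG3", "PG2"),
         reaction("GPM", "PG3(abc) -> PG2(abc)", f, b)),
    with(rev_ma("ENO", "PG2", "PEP"),
         reaction("ENO", "PG2(abc) -> PEP(abc)", f, b)),
    reaction("PK", "PEP(abc) -> PYR(abc)", mm("PK", "PEP")),
    reaction("PDH", "PYR(abc) -> CO2(a) + ACCOA(bc)", mm("PDH", "PYR")),
    reaction("PPC", "PEP(abc) -> OAA(abc)", mm("PPC", "PEP")),
    reaction("SYNTH1", "PEP(abc) -> BIOSYN1(abc)", mm("SYNTH1", "PEP")),
    reaction("SYNTH2", "PYR(abc) -> BIOSYN2(abc)", mm("SYNTH2", "PYR")),
    reaction("DAHPS", "E4P(abcd) + PEP(efg) -> DAHP(efgabcd)",
             "E_DAHPS * k_DAHPS * E4P * PEP"),
    reaction("G3PDH", "DHAP(abc) -> GLYC3P(abc)", mm("G3PDH", "DHAP")),
    reaction("GND", "PGN(abcdef) -> CO2G(a) + RU5P(bcdef)", mm("GND", "PGN")),
    with(rev_ma("RPE", "RU5P", "X5P"),
         reaction("RPE", "RU5P(abcde) -> X5P(abcde)", f, b)),
    with(rev_ma("R5PI", "RU5P", "R5P"),
         reaction("R5PI", "RU5P(abcde) -> R5P(abcde)", f, b)),
    with(rev_ma("TKA", c("R5P", "X5P"), c("S7P", "GAP")),
         reaction("TKA", "R5P(abcde) + X5P(fghij) -> S7P(fgabcde) + GAP(hij)", f, b)),
    with(rev_ma("TKB", c("X5P", "E4P"), c("F6P", "GAP")),
         reaction("TKB", "X5P(abcde) + E4P(fghi) -> F6P(abfghi) + GAP(cde)", f, b)),
    with(rev_ma("TA", c("GAP", "S7P"), c("E4P", "F6P")),
         reaction("TA", "GAP(abc) + S7P(defghij) -> E4P(ghij) + F6P(defabc)", f, b)),
    reaction("MURSYNTH", "F6P(abcdef) -> MUREIN(abcdef)", mm("MURSYNTH", "F6P")),
    reaction("RPPK", "R5P(abcde) -> PRPP(abcde)", mm("RPPK", "R5P")),
    reaction("G1PAT", "G1P(abcdef) -> ADPGLC(abcdef)", mm("G1PAT", "G1P")),
    reaction("SERSYNTH", "PG3(abc) -> SER(abc)", mm("SERSYNTH", "PG3")))
  mets <- ecoli_metabolites()
  intra <- mets$id[!mets$boundary]
  dil <- lapply(intra, function(m) {
    n <- mets$n_atoms[mets$id == m]
    reaction(paste0("DIL_", m),
             sprintf("%s(%s) -> BIOMASS_%s(%s)", m,
                     paste(letters[seq_len(n)], collapse = ""), m,
                     paste(letters[seq_len(n)], collapse = "")),
             sprintf("mu * %s", m))
  })
  rxns <- c(rxns, dil)

  pars <- parameters
  if (is.null(pars)) {
    # structure-only model: declare the parameter symbols so rate laws
    # validate, but poison their values so simulation cannot run silently
    syms <- unique(unlist(lapply(rxns, function(r) {
      c(all.vars(r$forward), if (!is.null(r$backward)) all.vars(r$backward))
    })))
    syms <- setdiff(syms, mets$id)
    pars <- stats::setNames(rep(NA_real_, length(syms)), syms)
  }
  model <- network_model(mets, rxns, pars, kie = kie,
                         label_input = list(GLCx = build_label_input(6, label_input)))
  model
}

# error early when a structure-only model (NA-valued parameters) is simulated
check_parameters <- function(model) {
  if (length(model$parameters) && !all(is.finite(model$parameters))) {
    stop("this model has no kinetic parameter bundle (parameters are NA); ",
         "supply one, e.g. ecoli_fixture(ecoli_synthetic_parameters())",
         call. = FALSE)
  }
  invisible(model)
}
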