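# Network definition, rate-law decomposition, validation, label inputs.

test_that("reversible Michaelis-Menten law splits into the published components", {
  net <- "Vmax * (PG3 - PG2 / Keq) / (Km3 * (1 + PG2 / Km2) + PG3)"
  parts <- decompose_rate_law(net, "Keq")
  # hand-written forward/backward components of the mutase law
  f_ref <- function(PG3, PG2, Vmax, Keq, Km3, Km2)
    Vmax * PG3 / (Km3 * (1 + PG2 / Km2) + PG3)
  b_ref <- function(PG3, PG2, Vmax, Keq, Km3, Km2)
    Vmax * (PG2 / Keq) / (Km3 * (1 + PG2 / Km2) + PG3)
  pars <- list(Vmax = 1.3, Keq = 5.7, Km3 = 0.2, Km2 = 0.4)
  set.seed(42)
  for (i in 1:20) {
    env <- c(list(PG3 = runif(1, 0, 3), PG2 = runif(1, 0, 3)), pars)
    fwd <- eval(parts$forward, env)
    bwd <- eval(parts$backward, env)
    net_val <- eval(str2lang(net), env)
    expect_gte(fwd, 0)
    expect_gte(bwd, 0)
    # forward - backward reproduces the net law
    expect_equal(fwd - bwd, net_val, tolerance = 1e-12)
    expect_equal(fwd, do.call(f_ref, env), tolerance = 1e-12)
    expect_equal(bwd, do.call(b_ref, env), tolerance = 1e-12)
  }
})

test_that("non-separable laws are rejected with advice to supply components", {
  expect_error(decompose_rate_law("Vmax * S / (Km + S)", "Keq"),
               "supply.*components", ignore.case = TRUE)
  # two candidate subtractions -> ambiguous
  expect_error(decompose_rate_law("(S - P/Keq) * (S2 - P2/Keq)", "Keq"),
               "supply.*components", ignore.case = TRUE)
})

test_that("the toy fixture validates cleanly", {
  report <- validate_network(toy_fixture())
  expect_true(report$valid)
  expect_identical(report$n_reactions, 7L)
  expect_identical(report$n_components, 8L)
  expect_identical(nrow(report$warnings), 0L)
})

test_that("structural violations are caught", {
  mets <- tibble::tibble(id = c("S", "A"), n_atoms = c(3L, 3L),
                         boundary = c(TRUE, FALSE), initial_conc = c(1, 1))
  # atom-count mismatch on the product side
  expect_error(network_model(mets, list(reaction("v1", "S(abc) -> A(ab)", "k * S"),
                                        reaction("v2", "A(abc) -> OUT(abc)", "k * A")),
                             c(k = 1)),
               "atom slots")
  # duplicate metabolite ids
  expect_error(network_model(tibble::tibble(id = c("A", "A"), n_atoms = 1L,
                                            boundary = FALSE, initial_conc = 1),
                             list(reaction("v1", "A(a) -> OUT(a)", "k * A")),
                             c(k = 1)),
               "duplicate")
  # unknown rate-law symbol
  expect_error(network_model(mets, list(reaction("v1", "S(abc) -> A(abc)", "kk * S")),
                             c(k = 1)),
               "unknown symbols")
  # unnormalized label input
  expect_error(network_model(mets, list(reaction("v1", "S(abc) -> A(abc)", "k * S")),
                             c(k = 1),
                             label_input = list(S = c("000" = 0.5, "111" = 0.4))),
               "sums to")
  # non-bijective atom map on a reversible reaction
  expect_error(network_model(mets,
                             list(reaction("v1", "S(abc) -> A(abc) + X(a)",
                                           "k * S", backward = "k * A")),
                             c(k = 1)),
               "slot")
})

test_that("KIE table validation enforces the normalization convention", {
  mets <- tibble::tibble(id = c("S", "A"), n_atoms = c(3L, 3L),
                         boundary = c(TRUE, FALSE), initial_conc = c(1, 1))
  rxns <- list(reaction("v1", "S(abc) -> A(abc)", "k * S"))
  # all-light pattern must carry factor 1
  expect_error(network_model(mets, rxns, c(k = 1),
                             kie = tibble::tibble(reaction = "v1", metabolite = "S",
                                                  pattern = "000", alpha = 0.9)),
               "all-light")
  # wrong pattern length
  expect_error(network_model(mets, rxns, c(k = 1),
                             kie = tibble::tibble(reaction = "v1", metabolite = "S",
                                                  pattern = "10", alpha = 0.9)),
               "carbons")
  # entry for an absent reaction is a warning in the report, not an error
  m <- network_model(mets, rxns, c(k = 1),
                     kie = tibble::tibble(reaction = "nope", metabolite = "S",
                                          pattern = "100", alpha = 0.9))
  expect_match(validate_network(m)$warnings$message, "absent reaction",
               all = FALSE)
})

test_that("label inputs expand to normalized isotopomer distributions", {
  u <- build_label_input(6, c(uniform = 1))
  expect_equal(unname(u["111111"]), 1)
  expect_equal(sum(u), 1)

  mix <- build_label_input(6, c("100000" = 0.8, uniform = 0.2))
  expect_equal(unname(mix["100000"]), 0.8)
  expect_equal(unname(mix["111111"]), 0.2)
  expect_equal(sum(mix != 0), 2L)

  nat <- build_label_input(6, c(natural = 1), natural_abundance = 0.0107)
  expect_equal(unname(nat["000000"]), (1 - 0.0107)^6, tolerance = 1e-12)
  expect_equal(unname(nat["100000"]), 0.0107 * (1 - 0.0107)^5, tolerance = 1e-12)
  expect_equal(sum(nat), 1, tolerance = 1e-12)

  expect_error(build_label_input(6, c("10" = 1)), "positions")
  expect_error(build_label_input(6, c("100000" = -0.2, uniform = 1.2)), "negative")
  expect_error(build_label_input(6, c("100000" = 0.5)), "sum")
})

test_that("every stored label input sums to one per pool", {
  for (li in glucose_label_inputs()) {
    v <- build_label_input(6, li)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
  }
})

test_that("forward - backward of reversible components equals the net law on random states", {
  m <- toy_fixture()
  sys <- kie_system(m)
  set.seed(7)
  for (i in 1:25) {
    M <- runif(nrow(m$metabolites), 0.01, 2)
    v <- kieflux:::component_rates(sys, M)
    names(v) <- sys$component_ids
    net <- v[["v3.fwd"]] - v[["v3.bwd"]]
    ref <- with(as.list(c(setNames(M, m$metabolites$id), m$parameters)),
                k3f * B - k3b * C * D)
    expect_equal(net, ref, tolerance = 1e-10)
  }
})
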