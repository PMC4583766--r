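# Experiment drivers: label-input comparison, the exchange-free variant,
# and the enzyme-level sensitivity scan (toy network for speed).

test_that("the exchange-free variant is idempotent and trivial without reversibility", {
  m <- toy_fixture()
  v1 <- no_exchange_variant(m)
  expect_false(v1$exchange)
  expect_identical(no_exchange_variant(v1), v1)
  # irreversible-only model maps to itself
  irr <- network_model(
    tibble::tibble(id = c("S", "A"), n_atoms = c(2L, 2L),
                   boundary = c(TRUE, FALSE), initial_conc = c(1, 0.5)),
    list(reaction("in", "S(ab) -> A(ab)", "k1 * S"),
         reaction("out", "A(ab) -> SINK(ab)", "k2 * A")),
    c(k1 = 1, k2 = 2))
  expect_identical(no_exchange_variant(irr), irr)
})

test_that("the exchange-free variant preserves aggregate steady states exactly", {
  m <- toy_fixture(label_input = c("100" = 0.8, uniform = 0.2))
  m2 <- no_exchange_variant(m)
  ss1 <- run_to_steady_state(m, kie_on = FALSE)
  ss2 <- run_to_steady_state(m2, kie_on = FALSE)
  expect_true(ss1$converged && ss2$converged)
  expect_equal(ss2$totals$concentration, ss1$totals$concentration,
               tolerance = 1e-6)
  nf1 <- net_fluxes(ss1); nf2 <- net_fluxes(ss2)
  expect_equal(nf2$net, nf1$net, tolerance = 1e-6)
  # but the carrying directions differ: no backward rate remains
  expect_true(all(nf2$backward[nf2$reaction == "v3"] == 0))
  expect_gt(nf1$backward[nf1$reaction == "v3"], 0.1)
})

test_that("dropping exchange changes labeling and KIE errors but not aggregates", {
  kie <- toy_kie_table()
  m <- toy_fixture(kie = kie, label_input = c("100" = 0.8, uniform = 0.2))
  pair <- function(model) {
    sys <- kie_system(model)
    on <- run_to_steady_state(sys, kie_on = TRUE)
    off <- run_to_steady_state(sys, kie_on = FALSE)
    list(on = on, off = off, imp = impact_report(on, off))
  }
  with_ex <- pair(m)
  without_ex <- pair(no_exchange_variant(m))
  # without KIEs the rate laws are untouched, so the aggregate operation of
  # the two variants is identical
  expect_equal(without_ex$off$totals$concentration,
               with_ex$off$totals$concentration, tolerance = 1e-6)
  # ... but genuinely different isotope routing: backward KIE entries (C, D
  # through the cleavage) stop binding, so the error pattern shifts
  d <- abs(without_ex$imp$isotopologues$error - with_ex$imp$isotopologues$error)
  expect_gt(max(d), 1e-5)
  # the backward-substrate factors no longer act on any realized flux
  nf <- net_fluxes(without_ex$on)
  expect_identical(nf$realized_backward[nf$reaction == "v3"], 0)
})

test_that("label-input comparison runs the full with/without pipeline per input", {
  m <- toy_fixture(kie = toy_kie_table())
  inputs <- list(unlabeled = c(unlabeled = 1),
                 mix = c("100" = 0.5, uniform = 0.5),
                 full = c(uniform = 1))
  cmp <- compare_label_inputs(m, inputs)
  expect_identical(cmp$input, names(inputs))
  expect_true(all(cmp$converged))
  # all-light input: factors never bind, zero impact
  expect_lt(cmp$max_isotopomer_error[1], 1e-9)
  expect_lt(cmp$max_flux_change[1], 1e-9)
  # mixed input produces real isotopic errors
  expect_gt(cmp$max_isotopomer_error[2], 1e-6)
  # fully labeled input saturates patterns: isotopic errors vanish again,
  # while fluxes and concentrations shift the most
  expect_lt(cmp$max_isotopomer_error[3], 1e-9)
  expect_gt(cmp$max_conc_change[3], cmp$max_conc_change[1])
  expect_s3_class(cmp$impact[[2]], "kie_impact")
})

test_that("enzyme-level multipliers are log-uniform, bounded and reproducible", {
  m <- toy_fixture()
  des <- sensitivity_design(n_sets = 2000, span = c(0.1, 10), seed = 99,
                            parameters = c("Vmax2", "Vmax4", "k3f"))
  mult <- sample_enzyme_levels(des, m)
  expect_identical(dim(mult), c(2000L, 3L))
  expect_true(all(mult >= 0.1 & mult <= 10))
  # log10 multipliers uniform on [-1, 1]
  ks <- suppressWarnings(stats::ks.test(log10(mult[, 1]), "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # seed-reproducible
  expect_identical(mult, sample_enzyme_levels(des, m))
  # a different seed changes the draw
  des2 <- sensitivity_design(n_sets = 2000, seed = 100,
                             parameters = c("Vmax2", "Vmax4", "k3f"))
  expect_false(identical(mult, sample_enzyme_levels(des2, m)))
})

test_that("a degenerate span repeats the nominal steady state", {
  m <- toy_fixture(kie = toy_kie_table(),
                   label_input = c("100" = 0.8, uniform = 0.2))
  des <- sensitivity_design(n_sets = 3, span = c(1, 1), seed = 4,
                            parameters = c("Vmax2", "k3f"))
  sens <- global_sensitivity(m, des)
  expect_identical(sens$n_failed, 0L)
  expect_true(all(sens$multipliers == 1))
  # all sets give the same error for each observable (point mass)
  spread <- sens$errors |>
    dplyr::group_by(dataset, metabolite, id) |>
    dplyr::summarise(r = diff(range(error)), .groups = "drop")
  expect_lt(max(spread$r), 1e-9)
})

test_that("sensitivity scans are reproducible under a fixed seed", {
  m <- toy_fixture(kie = toy_kie_table())
  des <- sensitivity_design(n_sets = 4, span = c(0.5, 2), seed = 11,
                            label_input = c("100" = 0.8, uniform = 0.2),
                            parameters = c("Vmax2", "Vmax4", "k3f"))
  s1 <- global_sensitivity(m, des)
  s2 <- global_sensitivity(m, des)
  expect_identical(s1$errors, s2$errors)
  expect_identical(s1$fluxes, s2$fluxes)
  expect_identical(s1$n_failed, 0L)
  # normalization holds inside every sampled steady state: isotopologue
  # fractions per (set, metabolite) sum to 1 on both sides, so the errors
  # per pool sum to ~0
  sums <- s1$errors |>
    dplyr::filter(dataset == "isotopologue") |>
    dplyr::group_by(set, metabolite) |>
    dplyr::summarise(s = sum(error), .groups = "drop")
  expect_lt(max(abs(sums$s)), 1e-9)
  gl <- glance(s1)
  expect_identical(sort(gl$dataset), c("enrichment", "isotopologue", "isotopomer"))
  expect_s3_class(autoplot(s1), "ggplot")
})
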