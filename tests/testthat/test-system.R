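# Incidence matrix, KIE factor vector, fluxomer evaluation and the matrix
# right-hand side, checked against hand-derived columns and the independent
# brute-force oracle.

toy_sys <- function(kie = NULL) kie_system(toy_fixture(kie = kie))

col_of <- function(sys, label) {
  j <- match(label, colnames(sys$U))
  expect_false(is.na(j), info = label)
  v <- sys$U[, j]
  v[v != 0]
}

test_that("carbon inversion and cleavage columns match hand-applied atom maps", {
  sys <- toy_sys()
  # v2 maps A(abc) -> B(acb): consuming A.011 produces B with bits (a,c,b) = 0,1,1
  cc <- col_of(sys, "v2.fwd:011")
  expect_identical(cc, c(A.011 = -1, B.011 = 1))
  # and A.010 -> B.001 (label moves from position 2 to position 3)
  cc <- col_of(sys, "v2.fwd:010")
  expect_identical(cc, c(A.010 = -1, B.001 = 1))
  # v3 forward cleaves B(abc) -> C(a) + D(bc): B.101 -> C.1 + D.01
  cc <- col_of(sys, "v3.fwd:101")
  expect_identical(cc, c(B.101 = -1, C.1 = 1, D.01 = 1))
  # v3 backward condenses C.1 + D.01 -> B.101
  cc <- col_of(sys, "v3.bwd:1+01")
  expect_identical(cc, c(B.101 = 1, C.1 = -1, D.01 = -1))
  # boundary rows are clamped: the v1 column only shows the produced A
  cc <- col_of(sys, "v1.fwd:110")
  expect_identical(cc, c(A.110 = 1))
})

test_that("every incidence column conserves labeled atoms (atom-conserving maps)", {
  for (model in list(toy_fixture(), ecoli_fixture())) {
    sys <- kie_system(model)
    w <- sys$iso$weight
    # net labeled atoms created per fluxomer; boundary rows are clamped and
    # external sinks drop carbon, so conservation is an inequality <= 0 on
    # columns touching those, equality elsewhere. Reconstruct the full
    # balance by adding back boundary rows for the check.
    Ufull <- assemble_incidence(model)
    # boundary rows were zeroed; rebuild substrate contributions by using a
    # model whose boundary flags are cleared
    m2 <- model
    m2$metabolites$boundary <- FALSE
    m2$label_input <- list()
    U2 <- assemble_incidence(m2)
    net_label <- as.vector(w %*% U2)
    expect_true(all(net_label <= 1e-12))
    # columns of fully mapped components conserve exactly
    fl <- enumerate_fluxomers(model)
    full_map <- !(fl$reaction %in% c("PDH", "GND", "PTS")) &
      !grepl("^DIL|^v[567]$|SYNTH|PPC|DAHPS|G3PDH|MUR|RPPK|G1PAT", fl$reaction)
    if (any(full_map)) expect_true(all(abs(net_label[full_map]) < 1e-12))
  }
})

test_that("cumulative KIE factors multiply across positions and substrates", {
  m <- ecoli_fixture()
  fl <- enumerate_fluxomers(m)
  a <- assemble_alphas(m, fl)
  pick <- function(comp, pat) unname(a[paste0(comp, ":", pat)])
  # singly labeled entries are read back exactly
  expect_equal(pick("PDH.fwd", "100"), 0.9908)
  expect_equal(pick("PDH.fwd", "010"), 0.9791)
  # cumulative rule: PYR 110 = product of the two single-position factors
  expect_equal(pick("PDH.fwd", "110"), 0.9908 * 0.9791, tolerance = 1e-15)
  expect_equal(pick("PDH.fwd", "111"), 0.9908 * 0.9791 * 0.9969, tolerance = 1e-15)
  # all-light combinations always 1
  expect_equal(pick("PDH.fwd", "000"), 1)
  expect_equal(pick("RPE.fwd", "00000"), 1)
  # fully labeled pentose through the epimerase: product of the four
  # measured factors, about a 4.1 % rate reduction
  rpe_full <- 0.9931 * 0.9818 * 0.9852 * 0.9980
  expect_equal(pick("RPE.fwd", "11111"), rpe_full, tolerance = 1e-15)
  expect_equal(rpe_full, 0.9587, tolerance = 1e-4)
  # unlisted pairs contribute 1 (backward epimerase has no measured entries)
  expect_true(all(a[grep("^RPE.bwd", names(a))] == 1))
  # all factors positive, none above 1 for this table
  expect_true(all(a > 0))
})

test_that("multi-labeled table entries override the product rule", {
  kie <- tibble::tibble(reaction = c("v2", "v2", "v2"),
                        metabolite = "A",
                        pattern = c("100", "010", "110"),
                        alpha = c(0.98, 0.97, 0.90))
  m <- toy_fixture(kie = kie)
  a <- assemble_alphas(m)
  expect_equal(unname(a["v2.fwd:110"]), 0.90)
  expect_equal(unname(a["v2.fwd:111"]), 0.98 * 0.97, tolerance = 1e-15)
})

test_that("fluxomers distribute component rates over substrate abundances", {
  sys <- toy_sys()
  set.seed(11)
  st <- random_toy_state(sys)
  f <- compute_fluxomers(sys, st)
  names(f) <- colnames(sys$U)
  ra <- kieflux:::relative_abundances(sys, st)
  v <- kieflux:::component_rates(sys, ra$M)
  names(v) <- sys$component_ids
  # single-substrate: f = v * abundance
  SA <- sum(st[paste0("S.", iso_patterns(3))])
  expect_equal(unname(f["v1.fwd:000"]), unname(v["v1.fwd"] * st[["S.000"]] / SA),
               tolerance = 1e-12)
  # two-substrate: product of abundances
  Ctot <- st[["C.0"]] + st[["C.1"]]
  Dtot <- sum(st[paste0("D.", c("00", "01", "10", "11"))])
  expect_equal(unname(f["v3.bwd:1+01"]),
               unname(v["v3.bwd"] * (st[["C.1"]] / Ctot) * (st[["D.01"]] / Dtot)),
               tolerance = 1e-12)
  # fluxomers of every component sum back to its rate
  sums <- rowsum(f, sys$comp_of_flux)
  expect_equal(as.vector(sums), unname(v), tolerance = 1e-12)
})

test_that("worked fluxomer examples evaluate as expected", {
  # v = 2, abundance 0.25 -> fluxomer 0.5; and v = 1 with abundances
  # 0.5 and 0.2 -> 0.1
  m <- network_model(
    tibble::tibble(id = c("S", "C", "D", "B"), n_atoms = c(3L, 1L, 2L, 3L),
                   boundary = c(TRUE, FALSE, FALSE, FALSE),
                   initial_conc = c(1, 1, 1, 1)),
    list(reaction("u1", "S(abc) -> B(abc)", "vS"),
         reaction("u2", "C(a) + D(bc) -> B(abc)", "vCD"),
         reaction("u3", "B(abc) -> OUT(abc)", "k * B")),
    c(vS = 2, vCD = 1, k = 1))
  sys <- kie_system(m)
  st <- setNames(numeric(sys$n_iso), paste(sys$iso$metabolite, sys$iso$pattern, sep = "."))
  st[c("S.000", "S.001", "S.010", "S.011")] <- 0.25   # S.000 abundance 0.25
  st["C.1"] <- 0.5; st["C.0"] <- 0.5                  # C.1 abundance 0.5
  st["D.01"] <- 0.2; st["D.00"] <- 0.8                # D.01 abundance 0.2
  st["B.000"] <- 1
  f <- compute_fluxomers(sys, st)
  names(f) <- colnames(sys$U)
  expect_equal(unname(f["u1.fwd:000"]), 0.5, tolerance = 1e-14)
  expect_equal(unname(f["u2.fwd:1+01"]), 0.1, tolerance = 1e-14)
})

test_that("matrix right-hand side equals the brute-force oracle at 100 random states", {
  kie <- toy_kie_table()
  m <- toy_fixture(kie = kie)
  sys <- kie_system(m)
  set.seed(123)
  worst <- 0
  for (i in 1:100) {
    st <- random_toy_state(sys)
    d_pkg <- iso_rhs(sys, st, kie_on = TRUE)
    d_orc <- toy_oracle_rhs(st, m$parameters, kie)
    worst <- max(worst, max(abs(d_pkg - unname(d_orc))))
  }
  expect_lt(worst, 1e-12)
})

test_that("with unit KIE factors the per-pool sums of the rhs give the kinetic ODE", {
  sys <- toy_sys(kie = toy_kie_table())
  N <- kieflux:::component_stoichiometry(sys)
  set.seed(5)
  for (i in 1:20) {
    st <- random_toy_state(sys)
    d <- iso_rhs(sys, st, kie_on = FALSE)
    ra <- kieflux:::relative_abundances(sys, st)
    dM_kinetic <- as.vector(N %*% kieflux:::component_rates(sys, ra$M))
    expect_equal(as.vector(sys$agg %*% d), dM_kinetic, tolerance = 1e-12)
  }
})

test_that("with all factors <= 1 realized component rates never exceed the rate law", {
  sys <- toy_sys(kie = toy_kie_table())
  expect_true(all(sys$alpha <= 1))
  set.seed(9)
  for (i in 1:20) {
    st <- random_toy_state(sys)
    f <- compute_fluxomers(sys, st)
    realized <- rowsum(f * sys$alpha, sys$comp_of_flux)
    ra <- kieflux:::relative_abundances(sys, st)
    v <- kieflux:::component_rates(sys, ra$M)
    expect_true(all(as.vector(realized) <= v + 1e-12))
  }
})

test_that("labeled inflow into an empty pool is strictly positive", {
  m <- toy_fixture(label_input = c(uniform = 1))
  sys <- kie_system(m)
  st <- setNames(numeric(sys$n_iso), paste(sys$iso$metabolite, sys$iso$pattern, sep = "."))
  st["S.111"] <- 1  # fully labeled boundary pool, everything else empty
  d <- iso_rhs(sys, st)
  expect_gt(d[match("A.111", names(st))], 0)
  expect_true(all(d >= 0))
})
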