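# kieflux

Simulation of isotope labeling experiments (ILEs) on kinetic models of
metabolic networks, with kinetic isotope effects (KIEs) included at the
system level.

Some enzymes react measurably slower with isotopically heavy substrates.
For anyone running ¹³C (or ²H, ¹⁵N, ¹⁸O) labeling experiments —
fluxomics, ¹³C-MFA, tracer-based metabolomics — the practical question is
whether these local rate perturbations bias the measured labeling patterns,
metabolite concentrations and fluxes once they propagate through a whole
network. `kieflux` answers that question by simulation: it couples an
ordinary kinetic model to a complete isotopomer model and quantifies the
difference between steady states computed with and without KIEs.

## The model

Every reversible rate law is split into nonnegative unidirectional
components (forward/backward), because reversibility exchanges label in both
directions. For a component with rate $v_r(M)$ and substrate isotopomer
combination $p$, the **fluxomer**

$$ f_r^p \;=\; v_r(M)\,\prod_{s} \bar{x}^{p_s}_s $$

is the absolute rate at which that specific combination of substrate
labeling patterns reacts ($\bar{x}^{p_s}_s$ = relative abundance of pattern
$p_s$ in pool $s$). A KIE enters as a factor $\alpha_r^p$ — the rate ratio
of combination $p$ to the all-light combination, cumulative (multiplicative)
over labeled positions and over co-substrates. With a sparse incidence
matrix $U$ mapping fluxomers to isotopomer balances through the carbon-atom
transitions, the coupled system is

$$ \frac{dI}{dt} \;=\; U\,\bigl(f(t)\circ a\bigr), $$

integrated with stiff LSODE-class solvers to isotopic steady state. Setting
$a \equiv 1$ recovers the plain kinetic model exactly, which makes
with/without-KIE comparisons clean: same model, same label input, only $a$
differs.

The package ships two networks: a fully parameterized toy network (boundary
substrate, carbon inversion, reversible carbon–carbon cleavage, sinks) and
the *Escherichia coli* glucose-uptake/glycolysis/pentose-phosphate structure
— 17 intracellular metabolites, 13 reversible + 32 irreversible reactions,
616 isotopomers, 7376 fluxomers — with measured ¹³C fractionation factors of
five enzymes (G6PDH, GND, ALD, RPE, PDH). Published kinetic constants for
that scaffold are not redistributed; `ecoli_synthetic_parameters()` provides
a clearly labeled synthetic bundle so the full pipeline runs end-to-end (see
the methods vignette for what that does and does not let you conclude).

## Worked example

Steady states of the toy network on a mixture of 80 % 1-¹³C + 20 %
U-¹³C substrate, with and without KIEs:

```r
library(kieflux)

model <- toy_fixture(kie = toy_kie_table(),
                     label_input = c("100" = 0.8, uniform = 0.2))
model
#> <kie_network> 6 metabolites (1 boundary), 7 reactions (1 reversible,
#> 6 irreversible), 7 KIE entries

with_kie <- run_to_steady_state(model)
without  <- run_to_steady_state(model, kie_on = FALSE)
glance(with_kie)
#> # A tibble: 1 × 6
#>   converged residual  time kie_on n_isotopomers n_fluxomers
#>   <lgl>        <dbl> <dbl> <lgl>          <int>       <int>
#> 1 TRUE      3.80e-12    50 TRUE              38          54

impact <- impact_report(with_kie, without)
impact
#> <kie_impact> max |relative change|: fluxes 0.00778, concentrations 0.0406
#>   max |error|: isotopomers 0.00492, isotopologues 0.00492, enrichments 0.00328

head(dplyr::arrange(tidy(impact), -abs(value)), 5)
#> # A tibble: 5 × 3
#>   dataset       id      value
#>   <chr>         <chr>   <dbl>
#> 1 concentration A     0.0406
#> 2 concentration C     0.0190
#> 3 concentration B     0.0122
#> 4 concentration E     0.00971
#> 5 flux          v4    0.00778
```

Reading this: the KIEs slow the consumption of pool A, whose concentration
rises 4.1 %, while every flux shifts by less than 0.8 % — the attenuation
of local rate perturbations by distributed network control. Errors on the
isotopic observables themselves stay below 0.005 (absolute fraction), far
below typical MS/NMR precision. Isotopologue distributions, enrichments and
fluxes are tibbles throughout:

```r
isotopologue_distribution(with_kie, "E")
#> # A tibble: 4 × 3
#>   metabolite mass_shift fraction
#>   <chr>           <int>    <dbl>
#> 1 E                   0    0
#> 2 E                   1    0.801
#> 3 E                   2    0
#> 4 E                   3    0.199
```

`compare_label_inputs()` repeats the comparison over the seven standard
glucose labelings, `no_exchange_variant()` isolates the contribution of
bidirectional isotope exchange, and `global_sensitivity()` scans random
enzyme levels (log-uniform over two orders of magnitude) to test the
robustness of the conclusions across metabolic states. `autoplot()` methods
plot impact reports, sensitivity scans and time courses; a thin CLI
(`inst/cli/kieflux`) exposes validate/simulate/compare/sensitivity/
export-matrix for shell use.

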