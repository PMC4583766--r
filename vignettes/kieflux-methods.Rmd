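---
title: "Modeling kinetic isotope effects in metabolic isotope labeling experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinetic isotope effects in metabolic isotope labeling experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kieflux)
```

## The problem

Isotope labeling experiments (ILEs) feed cells an isotopically enriched
substrate — most commonly ¹³C-glucose — and read the resulting labeling
patterns of intracellular metabolites by MS or NMR. Their interpretation
assumes that the tracer is chemically silent. It is not quite: several
enzymes show kinetic isotope effects (KIEs), reacting measurably slower with
heavy-substituted substrates. A KIE acts locally on one rate constant, but
its consequences are systemic: it perturbs concentrations and fluxes
throughout the network, and it fractionates the isotope distributions that
ILEs measure. `kieflux` simulates these system-level consequences by coupling
a kinetic model (ordinary rate laws in pool concentrations) to a full
isotopomer model, with KIEs entering as per-isotopomer rate factors.

## The model

**States.** A metabolite with $n$ mapped carbons has $2^n$ *isotopomers*
(binary labeling patterns, written position 1 to position $n$, e.g. `011`).
The state vector $I$ stacks the isotopomer concentrations of every pool, in
metabolite declaration order and pattern order ascending as binary integers.
Boundary pools (e.g. extracellular glucose) are clamped: concentration and
labeling fixed at the *label input*.

**Unidirectional components.** Because reversible reactions exchange label in
both directions, every reversible rate law is decomposed into nonnegative
forward and backward components, each with its own atom map direction; an
irreversible reaction contributes one component. `decompose_rate_law()`
automates the common `(S − P/Keq)/D` family by splitting the unique
subtraction on the equilibrium symbol, which leaves the shared denominator in
both parts and reproduces the net law identically; anything fancier is
supplied as explicit components.

**Fluxomers.** For a component $r$ with rate $v_r(M)$ (a function of pool
totals $M$ and kinetic parameters), and one substrate isotopomer combination
$p$, the *fluxomer* is the absolute local rate

$$ f_r^p = v_r(M) \prod_{s \in \text{substrates}} \bar{x}^{p_s}_s, $$

where $\bar{x}^{p_s}_s$ is the relative abundance of pattern $p_s$ in pool
$s$: in the absence of KIEs each substrate isotopomer reacts in proportion to
its share of the pool, so $\sum_p f_r^p = v_r$ always. Multi-substrate
components enumerate the full cross product of their substrate isotopomer
sets.

**KIE factors.** Each fluxomer carries a factor $\alpha_r^p$: the rate of
component $r$ with substrate combination $p$ relative to the all-light
combination (which has $\alpha \equiv 1$). Measured values exist for singly
labeled substrates of five central enzymes (shipped as `ecoli_kie_table()`);
factors of multiply labeled substrates are approximated as *cumulative*,
i.e. the product of the single-position factors, and multi-substrate
combinations multiply across substrates. Unmeasured (reaction, substrate)
pairs default to 1 — in particular the backward components of reactions whose
KIEs were measured on the forward substrates, since no backward values have
been measured; this default is a modeling choice, not a physical claim.

**Balances.** With a sparse incidence matrix $U$ (rows = isotopomers, columns
= fluxomers; −1 per consumed substrate isotopomer, +1 per product isotopomer
obtained by pushing the substrate patterns through the atom map) the whole
system is

$$ \frac{dI}{dt} = U \,(f(t) \circ a), $$

$\circ$ the element-wise product. Rows of boundary pools are zeroed (clamped
state). Summing the balances over the patterns of each pool recovers the
plain kinetic ODE $dM/dt = N v(M)$ exactly when $a \equiv 1$ — the reduction
the test suite checks against a separately integrated kinetic model.

Atom maps are written as slot-letter strings
(`"FBP(abcdef) -> DHAP(cba) + GAP(def)"`), so carbon inversion and
carbon–carbon cleavage are explicit. Products not declared as metabolites
are external sinks: their carbon leaves the mapped system (released CO₂,
biomass drains). Reversible maps must be bijections so the backward map is
the inverse.

## What a simulation does

`run_to_steady_state()` integrates the stiff system with deSolve's
LSODE-family solvers until `max |dI/dt| < ss_tol (1 + max |I|)`, checked on
doubling integration horizons. Defaults, all overridable via
`simulation_settings()`:

| parameter | default | why |
|---|---|---|
| `atol`, `rtol` | 1e-8, 1e-6 | standard tolerances for isotopomer systems of this size |
| `method` | `"lsodes"` | stiff solver with sparse Jacobian treatment; the 616-state *E. coli* Jacobian is large and sparse, and sparse column grouping cuts its numerical evaluation severalfold |
| `ss_tol` | 1e-10 | residual criterion; isotopic relaxation is exponential near the fixed point, so the criterion is reachable well below the integration tolerance |
| `t_first` | 50 | first horizon of the doubling schedule, of the order of the slowest pool turnover in the shipped fixtures; shorter horizons waste Jacobian factorizations |
| `max_time` | 1e6 | hard cap; hitting it reports `converged = FALSE`, never a silent partial state |

Numerical policies worth knowing:

* **Initialization.** Dynamic pools start at the plain kinetic model's steady
  state, concentrated on the all-light pattern, so only the isotopic
  dimensions relax; boundary pools are set to label input × clamped
  concentration.
* **Negative clamping.** Stiff integrators undershoot zero by a few multiples
  of their local error allowance; values above
  $-100\,(atol + rtol\,\max|y|)$ are clamped to 0 at horizon ends, anything
  below is an error (a genuinely diverging model, not solver noise).
* **Empty pools.** The relative abundance of a zero-total pool is defined as
  the all-light point mass. This avoids 0/0; it cannot bias steady states
  because every consuming rate law vanishes with the pool.
* **Ties and ordering.** All enumerations are deterministic: metabolite and
  reaction declaration order, forward before backward, substrate patterns in
  odometer order with the last substrate fastest. Serialization round trips
  reproduce the system exactly.

Derived observables are always renormalized from concentrations:
isotopomer fractions, isotopologue (mass-shift) distributions $M{+}k$, and
molecular enrichment $\sum_k k\,(M{+}k)/n$, defined as the mean labeled
fraction per position (the standard ¹³C definition; an equivalent
per-position average is tested against it). `impact_report()` compares two
steady states differing only in whether $a$ was applied: signed *relative*
changes for fluxes and concentrations, signed *absolute* errors for isotopic
observables (summaries take magnitudes).

## The shipped networks

**Toy network.** Six pools (carbons 3,3,3,1,2,3), a clamped substrate, a
carbon inversion, a reversible cleavage (the only reversible step) and three
saturable sinks. The reversible step uses mass action `k3f*B − k3b*C*D`
(exactly decomposable); irreversible steps use irreversible
Michaelis–Menten. Parameters were chosen once so that a unique strictly
positive steady state exists with substantial bidirectional exchange
(backward ≈ 60 % of forward through the cleavage) — exchange is the
phenomenon of interest, so a fixture without it would test nothing. This
network is small enough that every balance equation is also hand-coded in
the test suite as an independent oracle for the matrix assembly.

**E. coli glucose uptake / glycolysis / pentose phosphate.** The full
structure of the published kinetic scaffold this field uses for central
carbon metabolism: 17 intracellular metabolites (616 dynamic isotopomers, 94
isotopologues), 13 reversible + 32 irreversible reactions (17 of them
first-order growth dilutions) = 58 unidirectional components and 7376
fluxomers, with standard carbon transitions (aldolase inversion,
transketolase/transaldolase two-carbon and three-carbon transfers,
decarboxylations at the oxidative PPP entry and pyruvate dehydrogenase) and
the measured ¹³C fractionation factors of five enzymes. Which two of the
scaffold's non-dilution reactions to omit is fixed by the published model
dimensions: only dropping the two constant amino-acid drains reproduces
exactly 58 components and 7376 fluxomers.

**The synthetic parameter bundle.** The scaffold's published kinetic
constants live in its supplementary material and are not redistributed here;
`ecoli_fixture()` therefore takes any named parameter bundle, and the
package ships `ecoli_synthetic_parameters()` — an internally consistent
synthetic bundle (saturable irreversible laws, mass-action reversible pairs,
one enzyme-level multiplier per reaction, first-order dilution) chosen once
to give a strictly positive steady state with a realistic glycolysis/PPP
split (~17 % of glucose-6-phosphate flux entering the oxidative branch) and
substantial exchange. Everything structural (state counts, matrix assembly,
KIE algebra) is parameter-free; every quantitative simulation result in this
package documents the *synthetic* kinetic state. On it, the qualitative
published findings reproduce — flux and concentration shifts of at most a
few percent with the maximum on fully labeled glucose, isotopic errors
concentrated on pyruvate through the pyruvate-dehydrogenase KIE, errors far
smaller than analytical precision for nearly all other observables — while
exact printed magnitudes (e.g. a −1.7 % epimerase flux shift, or the
tenfold error inflation without exchange, which is emergent from the
published near-equilibrium exchange fluxes) should not be expected from a
different kinetic state, and the tests that assert them say so.

## Experiments

* `compare_label_inputs()` runs the with/without-KIE pair for a list of
  tracer mixtures (default: the seven standard glucose labelings, from
  natural abundance to fully labeled) and tabulates impact maxima per input.
* `no_exchange_variant()` keeps every rate law — hence the entire aggregate
  operation — identical but lets the isotopomer balances carry only the
  *net* rate of each reversible pair, assigned to the current net direction
  (sign flips simply reassign it). Comparing its KIE errors with the full
  model isolates what bidirectional isotope exchange contributes to the
  robustness of labeling patterns.
* `global_sensitivity()` scans enzyme levels: multipliers $10^u$,
  $u \sim \mathrm{Uniform}(\log_{10} 0.1, \log_{10} 10)$, drawn
  independently per enzyme per set from a single integer seed (all draws
  taken up front, so results are reproducible and independent of execution
  order), one with/without-KIE steady-state pair per set, non-converged sets
  counted and excluded from the error distributions. The published design
  uses 10,000 sets; the test suite runs the identical design at a dozen sets
  to stay within a minutes-scale runtime (a full scan is hours on one CPU
  with this pure-R right-hand side) — the scan's *sampling law* is tested at
  full size since it costs nothing.

## What the tests do and do not show

The suite checks the machinery exhaustively on the toy network (oracle
equivalence of the matrix balances at random states to 1e-12, conservation
and normalization properties, the unit-factor reduction to the kinetic
model, label saturation and all-light invariance at the input extremes,
serialization round trips) and the structure of the *E. coli* model against
its published dimensions. Simulated ILEs here are noiseless and stationary:
no measurement error, no natural-abundance correction, no non-stationary
sampling — so passing tests certify the solver and the formalism, not
agreement with any wet experiment. Numeric case-study assertions run on the
synthetic bundle and are expected to agree with published magnitudes only
approximately, as discussed above.

## Known limitations

* One binary tracer element at a time (covers ¹³C, ²H, ¹⁵N, ¹⁸O singly);
  no multi-element labeling.
* Full isotopomer space — no cumomer/EMU reduction — so cost grows as
  $\sum 2^n$; fine at glycolysis/PPP scale, heavy beyond ~10-carbon pools.
* No symmetric-molecule pattern averaging (no such species in the shipped
  networks).
* Integration-to-steady-state only; no algebraic (Newton) solver.
* The backward-KIE default of 1 is an assumption forced by available
  measurements.
* No thermodynamic consistency checking of equilibrium constants, and no
  inference of atom maps from structures: maps are user input.
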