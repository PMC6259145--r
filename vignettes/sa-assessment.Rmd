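---
title: "Specific-radioactivity assessment of reactor-produced radioisotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specific-radioactivity assessment of reactor-produced radioisotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saforge)
```

## The problem

Targeted radiopharmaceuticals need radioisotopes of the highest possible
specific radioactivity (SA): the fraction of the product element's atoms
that are the wanted radioisotope.  Reaction *yield* alone is a poor guide
to irradiation planning, because the processes that build yield also
destroy it and dilute it -- target burn-up, decay of the product during
bombardment, isotopic impurities in the target, stable carrier grown in
by side chains, and post-irradiation decay.  `saforge` implements the
closed-form machinery to assess both yield and SA for reactor
(n,&gamma;) production, with ¹⁷⁷Lu as the worked system: the direct
¹⁷⁶Lu(n,&gamma;)¹⁷⁷Lu route and the indirect
¹⁷⁶Yb(n,&gamma;)¹⁷⁷Yb(&beta;⁻)¹⁷⁷Lu route.

## Model

### Burn-up and yield

Each reaction channel *i* on a target nuclide has an effective
cross-section

&Omega;ᵢ = &sigma;_eff + R_fast &sigma;_fast,

where &sigma;_eff = &sigma;₀ + f_H I₀(&alpha;) for 1/v nuclides (Hogdahl
convention, f_H = &phi;_epi/&phi;_th) and &sigma;_eff = k &sigma;₀ for
non-1/v nuclides such as ¹⁷⁶Lu, whose Westcott k-factor bundles the
g(T_n), r and S₀(&alpha;) spectral detail into one measured constant.
The target isotope burns up with constant &Delta;_S = &phi;_th
&Sigma;ᵢ&Omega;ᵢ, so N_S(t) = N₀ e^{-&Delta;_S t}, and the half-burn-up
time is ln 2/&Delta;_S.

The product R (decay constant &lambda;, optional neutron-destruction
constant &Delta;_R, depression factor &Lambda; = &lambda; + &Delta;_R)
follows the first-order Bateman solution

N_R(t) = &phi;&Omega;_prod N₀ (e^{-&Delta;_S t} - e^{-&Lambda;t}) /
(&Lambda; - &Delta;_S),

with activity A = &lambda; N_R, and peaks at t\* =
ln(&Lambda;/&Delta;_S)/(&Lambda; - &Delta;_S).  The maximum yield can
equivalently be written through the dimensionless auxiliaries D =
&Lambda;/&Delta;_S, p = ln D/(D-1), h = D p, q = (1-D)⁻¹; the package
implements both routes and tests force them to agree to 1e-9.

### Specific activity

With impurity isotopes S_g (elemental depletion constants &Delta;_g,
zero whenever their captures keep the atoms inside the element),

SA(t) = 100 · N_R / (&Sigma;_g N_g(t) + N_R)  [atom %].

Cooling decays the hot atoms only.  Three regimes matter:

* **one-isotope target** (P₂ = 0): SA rises monotonically, there is no
  optimal irradiation time -- yield and SA must be traded off;
* **two-isotope target**: SA has an interior maximum at a time
  `time_of_max_sa()` that differs from the yield optimum; the ratio of
  the two times peaks near 3·10¹⁴ n cm⁻² s⁻¹ for the Lu system;
* **heavily burning impurity**: the impurity pool disappears and the
  system reverts to one-isotope behaviour.

Unit conversions follow Bq/mol = (atom%/100) &lambda; N_Av and Bq/g =
Bq/mol / M, with M of a multi-isotope material the weight-percent
harmonic combination &Sigma;P / &Sigma;(P/M).

### Chains, in-growth, mixtures

The indirect route S(n,&gamma;)R_x(&beta;⁻)R_i is the three-exponential
Bateman solution in (&Delta;_S, &Lambda;_x, &Lambda;_i); alone it is
carrier-free (SA = 100 atom %).  Impurity chains such as
¹⁷⁴Yb(n,&gamma;)¹⁷⁵Yb(&beta;⁻)¹⁷⁵Lu deposit *stable* carrier: during
irradiation the in-growth is the time integral of the feed activity, and
after EOB the surviving intermediate keeps converting, so SA keeps
falling with cooling time -- the reason post-irradiation processing
should be as short as the chemistry allows.  When several sources of
the same radioisotope coexist (chain product plus directly activated
elemental impurity), the mixture SA is pooled-atom isotopic dilution,
SA_mix = &Sigma;A_j / &Sigma;(A_j/SA_j), valid for any quantity unit
proportional to hot atoms and bounded by the constituent SAs.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| k-factor (¹⁷⁶Lu) | 1.74 | tabulated Westcott factor at typical rig temperature; reported range 1.67 (10&deg;C) to 1.9 (40&deg;C) |
| f_H = R_epi | 0.02 | measured epithermal/thermal ratio of the reference irradiation rig |
| E_Cd | 0.55 eV | cadmium cut-off convention |
| &alpha; | 0 | ideal 1/E epithermal spectrum; practical range [-0.15, +0.3] enters only via &xi;(&alpha;) and, with a user-supplied effective resonance energy, I₀(&alpha;) |
| R_fast | 0 | fast flux is orders of magnitude below thermal in a moderated reactor and the fast cross-sections are milli-barn; the term is carried for generality |
| &Delta;_Ri, &Delta;_int | 0 | product/intermediate destruction during irradiation is negligible against decay for the Lu/Yb system and its cross-sections are not tabulated; both are settable |
| cooling default (indirect) | 24 h | lets essentially all ¹⁷⁷Yb (T&frac12; = 1.911 h) convert to ¹⁷⁷Lu before the product is reported |
| flux-scan grid | 12 log-spaced points in [5·10¹³, 10¹⁵] | brackets the expected ratio optimum at desk-scale cost |
| atomic masses | integer mass numbers | matches the published atom-number formulas; the <0.1 % deviation is far below cross-section uncertainty |
| Avogadro | CODATA, `replication = TRUE` switches to 6.02·10²³ | digit-level replication of hand calculations must be possible; the difference is <0.04 % |

Target compositions are transcribed enrichment certificates.  Isotopes
certified only as "<0.01 %" are stored at the interval midpoint
0.005 % with the bound recorded in the fixture file.  Elemental
impurities are ppm by mass of the target *element*; oxide target
weights are converted with `element_mass_from_oxide()` (M₂O₃
stoichiometry).

## What the fixtures and toy systems emulate -- and what they do not

The bundled fixtures state a fixed nuclear-data world: one enriched Lu
target, one enriched Yb target, natural Lu.  The randomized test systems
draw rate constants log-uniformly over [1e-9, 1e-3] s⁻¹, covering
half-lives from minutes to decades and burn-up from negligible to
severe.  A green suite establishes that the closed forms solve their
stated ODE systems (to 1e-8 against an independent matrix-exponential
oracle) and that the scenario features hold in this stated world.  It
does **not** establish: neutron self-shielding (assumed unity),
temperature dependence of the Westcott factor (k is an input), flux
gradients or power history, chemistry losses during separation, or the
absolute accuracy of the tabulated cross-sections.

## Numerical choices

* The Bateman brackets are evaluated as divided differences of
  e^{-xt} built on `expm1`, so the removable singularities
  (&Lambda; = &Delta;, repeated chain rates) need no caller-side special
  casing; the confluent branch engages below a 1e-5 relative node gap
  and the D = 1 auxiliaries below 1e-10.
* The in-growth integral is the same three-node kernel with one zero
  rate, which keeps irradiation in-growth and chain production on one
  code path.
* `time_of_max_sa()` scans the sign of the *analytic* SA derivative
  (using dN_R/dt from the ODE, not numeric differentiation) on a
  400-point log grid out to 20 half-burn-up times, then refines with
  `uniroot` to 1e-6 relative.  The horizon is a design choice: beyond
  20 half-burn-ups the target is gone for every practical purpose.  A
  pure target (P₂ = 0) or an absent sign change returns `NA`.
* Post-EOB in-growth holds the end-of-bombardment intermediate
  inventory as the initial condition of free decay; the oracle confirms
  this treatment is exact (1e-8) for the two-step chain, not an
  approximation.
* The isomer channel ¹⁷⁶Lu(n,&gamma;)¹⁷⁷ᵐLu is carried in the fixture
  (it contributes to burn-up) but its slow IT feed of ¹⁷⁷Lu is excluded
  from the ¹⁷⁷Lu balance, consistent with treating the 160.7 d isomer
  as an effectively unchanged Lu pool during production-scale
  irradiations.
* SA denominators include the hot atoms themselves; captured-but-
  undecayed impurity atoms ("not really burned") are not added back --
  the amounts are insignificant at the stated cross-sections.

## Known limitations

Chains longer than parent &rarr; intermediate &rarr; product are
supported only by the oracle, not by closed forms.  The &alpha;
correction of resonance integrals requires a user-supplied effective
resonance energy; without it the uncorrected I₀ is used with a warning.
Figure-level curve reproduction is out of scope: published plots were
drawn on unstated time grids, so only their printed features (optimum
locations, monotonicities, maxima existence) are asserted.

## A worked direct-route example

```{r direct}
dr <- direct_route(enrichment = 74.1, phi_th = 2.5e14)
dr
```

```{r flux-scan}
scan <- flux_scan(enrichments = 74.1)
attr(scan, "argmax")   # flux maximizing t_SA-max / t_yield-max
```
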