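---
title: "Quantifying mixotrophic carbon flow in methylotrophic methanogens from SIP incubations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mixotrophic carbon flow in methylotrophic methanogens from SIP incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misosip)
```

## The problem

Methylotrophic methanogens such as *Methanococcoides* spp. gain energy by
disproportionating methanol,

$$4\,\mathrm{CH_3OH} \rightarrow 3\,\mathrm{CH_4} + \mathrm{CO_2} + 2\,\mathrm{H_2O},$$

so the textbook expectation is that their methane carbon is methyl carbon. In
anoxic marine sediments, however, these "obligate" methylotrophs sit in a
large pool of dissolved inorganic carbon (DIC), and stable-isotope probing
(SIP) incubations with one substrate ¹³C-labeled reveal two things the
stoichiometry alone does not predict: a measurable share of the methane
carbon comes from the DIC pool (mixotrophic methanogenesis), and most of the
carbon in biomass (RNA, lipids) is DIC-derived. `misosip` implements the
quantitative machinery needed to make and check those statements: isotope
bookkeeping, two-end-member mixing estimators, an atom-resolved provenance
model of the biosynthesis pathways, and a forward simulator of the
incubations so that every estimator is validated by parameter recovery
without any laboratory data.

## Isotope bookkeeping

All internal arithmetic uses the ¹³C atom fraction
$F = R/(1+R)$ with $R = (\delta/1000 + 1) \cdot 0.011180$, where $\delta$ is
the per-mil value against VPDB. Mass balance is linear in $F$ (never in
$\delta$), which is why the estimators convert at the boundaries and work on
fractions internally; percent appears only in printed reports. The VPDB
ratio is fixed at 0.011180 — the conventional value in SIP mixing
calculations — rather than a more precise modern figure, so that atom
fractions derived from reported $\delta$ values are bit-reproducible.

Unlabeled pools default to $\delta^{13}\mathrm{C} = -30$‰, a typical
biogenic organic-matter composition. The default is a convenience for
simulation setups; every estimator takes its background composition
explicitly, so no analysis silently depends on it.

### The mixing estimators

With methane as the target, harvest-time DIC as the labeled source and the
methanol fed at the start as background, the two-end-member model

$$f_{\mathrm{DIC}/\mathrm{CH_4}}
  = \frac{F_{\mathrm{CH_4}} - F_{\mathrm{MeOH}}}
         {F_{\mathrm{DIC}} - F_{\mathrm{MeOH}}}$$

is implemented by `two_pool_source_fraction()`. For biomass, parallel
single-label incubations give incorporation ratios
$X = (F_{t_\mathrm{end}} - F_{t_0})/F_{\mathrm{label}}$ per substrate, and
`dic_lipid_fraction()` combines them into
$f_{\mathrm{DIC/lipid}} = X_{\mathrm{DIC}}/(X_{\mathrm{DIC}} + X_{\mathrm{MeOH}})$,
valid because the paired incubations share identical amendments.

Numerical policies, chosen once:

* **Clamping.** Measurement noise can push estimates slightly outside
  $[0,1]$. The raw value is preserved (`$raw`), a clamped copy is reported
  (`$f_source`) and a flag records that clamping occurred; replicate
  mean ± SD reporting needs the raw values.
* **Degenerate end members.** $|F_\mathrm{source} - F_\mathrm{background}| <
  10^{-6}$ — below realistic GC-IRMS resolution in fraction space — is an
  error, not a huge unstable number.
* **Label strengths.** The methanol term uses the composition at the start;
  the DIC term uses the harvest-time measurement, which automatically
  accounts for dilution of the amendment by ambient porewater DIC. The model
  neglects kinetic isotope fractionation during methanogenesis; nothing in
  the estimator corrects for it, and this is a known, documented bias shared
  with the underlying mixing model.

## Atom-resolved provenance

Whether a ¹³C label can reach RNA or lipids at all is a question about atom
fates, not fluxes. `misosip` encodes the two relevant biosynthesis networks
as JSON documents in which every reaction maps each product carbon either to
a specific reactant atom or to one of two source pools (`MEOH`, the methanol
methyl group entering via methyl-H₄SPT; `DIC`). `propagate()` walks the
network in topological order; an atom's provenance vector is inherited
unchanged along the map, so the model is purely stoichiometric — no
thermodynamics, no flux ratios, no fractionation.

```{r provenance}
nuc <- propagate(load_pathway(pathway_file("nucleotide")))
lip <- propagate(load_pathway(pathway_file("lipid")))
round(100 * rbind(
  ribose     = nuc$aggregate["ribose_5_phosphate", ],
  pyrimidine = nuc$aggregate["pyrimidine_base", ],
  purine     = nuc$aggregate["purine_base", ],
  IPP        = lip$aggregate["ipp", ],
  GGPP       = lip$aggregate["geranylgeranyl_diphosphate", ]
), 1)
```

The terminal fractions — one methanol carbon of five in ribose-5-phosphate,
25% and 40% methyl carbon in the pyrimidine and purine rings, and 60%
methanol carbon in IPP/GGPP and hence the phytanyl chains of archaeol-type
lipids — emerge from standard biosynthetic atom fates: CODH/ACS acetyl-CoA
synthesis (methyl + CO₂), pyruvate carboxylation, gluconeogenesis with the
reverse ribulose-monophosphate cleavage releasing the methanol-derived
hexose C1 as formaldehyde, the aspartate route to the pyrimidine ring, two
formyl units plus glycine plus CO₂ for the purine ring, and the mevalonate
pathway with decarboxylation of a CO₂-derived carboxyl. Where the literature
leaves an intermediate fate open, we committed to the standard assignment
that is consistent with all terminal fractions simultaneously; each bundled
reaction carries a `note` naming its basis. Two such open points deserve
mention:

* the purine C2/C8 formyl carbons are taken from the methanol-fed one-carbon
  pool (formyl-H₄SPT produced by oxidizing methyl-H₄SPT), which is what the
  40% purine endpoint requires;
* ribose is encoded through the reverse ribulose-monophosphate route. The
  alternative non-oxidative pentose-phosphate arrangement would reshuffle
  which atom is methanol-derived but, for the purposes of a bulk fraction,
  the committed route carries the defensible endpoint, and the network keeps
  the "each compound made by exactly one reaction" determinism that makes
  propagation unambiguous.

The carbon-to-methyl reactions are reversible in vivo (CO₂ can be reduced to
methyl-H₄SPT); the provenance graph deliberately stays acyclic and encodes
only the assimilatory direction. Mixotrophic back-flux is a flux phenomenon
and is handled in the simulator, not in the atom maps.

`predict_fraction_13c()` turns provenance into an observable: the expected
atom fraction of a compound is affine in each source pool's composition.
`aggregate_macromolecule()` assembles carbon-weighted means, e.g. a purine
ribonucleotide (ribose + base) carries $(1+2)/10 = 30\%$ methanol carbon.
This is the quantitative basis of the RNA-SIP design result: RNA carbon is
roughly three-quarters DIC-derived, so labeling DIC (or both substrates)
shifts RNA much further in a density gradient than labeling methanol.

## The incubation simulator

`incubation_config()` fixes the study conditions; its defaults are the
sediment setting this package models: 1 mM methanol, 10 mM amended
bicarbonate (one of the two labeled at $F = 0.99$), an ambient DIC pool of
2 mM at −30‰ (the order of magnitude implied by observed dilution of the
amendment to ~84 atom-%), triplicates, 43 days, Gaussian measurement noise
of 0.5‰ on exported δ values (typical GC-IRMS precision), and a DIC-derived
methane share `f_mix = 0.103`. Scenario presets (`scenario_config()`) adjust
these to the methanogenic-zone, pure-culture (30 mM methanol, 50 mM DIC, 5%
labels) and autoclaved-slurry settings.

Each step of `simulate_incubation()` consumes methanol first-order (by
default `k` is set so 99% is consumed by harvest — only the harvest-time
isotope states matter to the estimators, so the exact kinetic form is
deliberately simple). Of the consumed methyl carbon, a small assimilated
share (5%) builds biomass, split between a lipid pool and an RNA pool whose
compositions follow the provenance model evaluated at the *current* pool
compositions; the rest is dissimilated at the 3 CH₄ : 1 CO₂
disproportionation stoichiometry, with the produced CO₂ joining the DIC pool
at the methanol composition. On top of the methyl-derived methane, a
fraction `f_mix` of total methane carbon is drawn from the DIC pool at its
current composition. Carbon and ¹³C are conserved exactly at every step;
`budget_closure()` recomputes both budgets from the recorded series and is
asserted at $10^{-9}$ relative in the test suite.

Two deliberate simplifications: a single well-mixed DIC pool (no
headspace/dissolved partitioning — the mixing model uses a single measured
DIC composition, so partitioning would be invisible to the estimators), and
no microbial population dynamics (amendment effects enter only through their
isotopic consequences, `f_mix` and the rate).

Design choices worth recording:

* **Constant-composition DIC runs.** Estimator-recovery theory wants a DIC
  pool whose composition does not drift. `hold_dic_f = TRUE` pins the pool
  composition and tracks all exchange with the implied infinite reservoir in
  an explicit ledger, so the conservation checks still close exactly instead
  of being waived for that mode.
* **Rate-dependent mixotrophy.** The observation that slower methanogenesis
  produces proportionally more CO₂-derived methane is reproduced by an
  optional mode $f(t) = f_{\max} e^{-r/r_0}$ with $f_{\max} = 0.12$ (the
  upper end of observed DIC-derived methane) and $r_0 = 1$ mmol L⁻¹ d⁻¹,
  chosen once so the slow and fast treatments span the observed ~2–10%
  range. No mechanistic form is claimed; the correlation sign and strength
  are the modeled content.
* **Noise in δ-space.** Instrument precision is quoted in ‰ by convention,
  so noise is Gaussian on δ, applied only at export; the forward model
  itself is deterministic and replicates share the trajectory.
* **Seeding.** One integer seed; replicate substreams are derived from it
  deterministically and recorded in the export, so tables are byte-stable.
* **Buoyant density.** `rna_density()` is the linear model
  $BD = 1.7785 + 0.035\,(F - F_{\mathrm{nat}})$ g mL⁻¹, anchored at the
  light-window midpoint for unlabeled RNA and reaching 1.813 g mL⁻¹ —
  inside the heavy window (1.803–1.823 g mL⁻¹) — at full labeling.

## Inference on replicate tables

`estimate_methane_sources()` consumes the package's TSV measurement dialect
(one row per pool × replicate × time). The point estimate uses replicate
means; uncertainty is reported two ways because they answer different
questions. The across-replicate SD is the familiar triplicate mean ± SD.
The seeded Monte-Carlo propagation perturbs *every* measured pool — CH₄,
DIC, and the methanol background when it is read off the table — in δ-space.
The draw scale prefers the table's stated per-row measurement `sd`
(instrument precision) over the across-replicate SD: with triplicates the
sample SD has two degrees of freedom and occasionally collapses by chance,
which would understate the propagated uncertainty exactly when it matters.
With the stated precision as the scale, the calibration property (truth
inside estimate ± 3 SD in at least 99 of 100 seeded trials) holds with
margin.

`rate_fraction_correlation()` reports Pearson's r, a two-sided t-test
p-value and a Fisher-z 95% CI via `stats::cor.test()`; the test suite
cross-checks it against a from-first-principles implementation. Rates in
`rate_sweep_experiment()` are two-point finite differences of methane
between consecutive sampling days — the simplest estimator consistent with
how such rates are usually plotted.

## What the synthetic data do and do not show

The simulator emulates the features the estimators are sensitive to: the
disproportionation stoichiometry, label dilution by an ambient pool, drift
of the DIC composition as unlabeled methanol-derived CO₂ accumulates,
provenance-consistent biomass labeling, replicate structure and δ-space
noise. Passing recovery tests therefore shows that the estimators are
algebraically correct, unbiased when their assumptions hold (constant source
composition), and honestly calibrated under the stated noise model. It does
not show robustness to what the simulator omits: kinetic isotope
fractionation, community effects (competing methylotrophs, homoacetogens),
spatial heterogeneity, headspace partitioning, or instrument drift beyond
i.i.d. Gaussian noise. The drift-bias test quantifies the one violation the
simulator can produce — a drifting source composition — and bounds the
estimator's bias by the drift magnitude.

## Problem sizes

The shipped tests and the acceptance script use the sizes a desk check
needs, not more: simulations at a 0.1 d step over 14–43 d, Monte-Carlo at
10³–10⁴ draws, the calibration property at 100 seeded trials, and the
treatment sweep at 6 × 3 incubations. The full suite runs in well under a
minute on one core.
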