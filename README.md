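# misosip

Carbon-flow analysis for stable-isotope probing (SIP) of methylotrophic
methanogens.

"Obligate" methylotrophic methanogens (e.g. *Methanococcoides* spp. in
anoxic marine sediments) disproportionate methanol,
4 CH₃OH → 3 CH₄ + CO₂ + 2 H₂O, so their methane should carry methyl carbon.
SIP incubations with ¹³C-labeled methanol or bicarbonate tell a richer
story: part of the methane carbon is drawn from the dissolved inorganic
carbon (DIC) pool, and most biomass carbon (RNA, lipids) is DIC-derived.
`misosip` is for microbial ecologists and biogeochemists who need to turn
replicate δ¹³C measurement tables from such incubations into source
apportionments — and to know how much to trust them.

The package implements four connected pieces:

1. **Isotope arithmetic** on the VPDB scale:
   R = (δ/1000 + 1) · 0.011180, F = R/(1+R), with all mixing done in atom
   fractions (mass balance is linear in F, not δ).
2. **Two-end-member mixing estimators**: the DIC-derived methane share
   f_DIC/CH₄ = (F_CH₄ − F_MeOH)/(F_DIC − F_MeOH); and for biomass, label
   incorporation ratios X = (F_tend − F_t0)/F_label from parallel
   single-label incubations combined into
   f_DIC/lipid = X_DIC/(X_DIC + X_MeOH).
3. **An atom-resolved provenance model** of methanogen nucleotide and
   isoprenoid-lipid biosynthesis: each reaction maps every product carbon to
   a reactant atom or a source pool (methanol methyl vs DIC), and
   propagation yields per-compound source fractions — 1 of 5 ribose
   carbons, 25% of pyrimidine, 40% of purine, and 60% of IPP/GGPP (hence
   phytanyl-chain) carbon is methanol-derived.
4. **A forward simulator** of SIP incubations with exact carbon and ¹³C
   mass balance (disproportionation stoichiometry, label dilution into an
   ambient DIC pool, a mixotrophic DIC→CH₄ share `f_mix`,
   provenance-consistent biomass labeling, triplicates, Gaussian δ-noise),
   used to validate every estimator by parameter recovery.

## Worked example

Sulfate-reduction-zone style numbers: harvest DIC at 83.6 atom-% ¹³C,
methane at 9.6 atom-%, methanol near natural abundance:

```r
library(misosip)
two_pool_source_fraction(0.0960, 0.836, delta_to_fraction(0))
#> Two-end-member mixing estimate: f_source = 0.1030 (10.3%)
```

10.3% of the methane carbon came from the DIC pool. The same estimator run
against a fully synthetic incubation, noise and replicates included:

```r
sim <- simulate_replicates(scenario_config("sediment-SRZ", seed = 1))
estimate_methane_sources(sim$table, n_mc = 10000, seed = 1)
#> Two-end-member mixing estimate: f_source = 0.1040 (10.4%)
#>   propagated sd = 8.38e-06 (10000 MC draws)
#>   across-replicate sd = 2.68e-06
#>   95% CI [0.10400, 0.10404]
```

The scenario's true `f_mix` is 0.103; the small excess is the documented
harvest-time bias from DIC-pool drift (unlabeled CO₂ produced from methanol
dilutes the source label over the run), which the test suite bounds
analytically. How far was the 10 mM labeled amendment diluted by ambient
porewater DIC to end at 83.6 atom-%?

```r
infer_ambient_pool(10, 0.99, 0.836, natural_abundance())
#> [1] 1.866052
```

Provenance of biomass carbon under any labeling scheme:

```r
lip <- propagate(load_pathway(pathway_file("lipid")))
compound_source_fraction(lip, "geranylgeranyl_diphosphate", "MEOH")
#> [1] 0.6
```

and the rate dependence of mixotrophy, across a simulated six-treatment
sweep:

```r
rate_sweep_experiment(seed = 1)$report
#> Pearson's r = -0.963, P = 1.66e-10, CI(0.95) = [-0.986, -0.901], n = 18
```

A command-line front end over the same functions ships at
`inst/scripts/misosip` (subcommands `convert`, `provenance`, `mix`,
`lipids`, `correlate`, `simulate`, `replay`). The methods vignette
(`vignettes/carbon-flow-sip.Rmd`) documents the models, their assumptions
and the numerical policies.

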