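# ligeff — unit-aware ligand efficiency metrics and their alternatives

Ligand efficiency (LE) is the most widely used size-normalized design
parameter in drug discovery: the standard binding free energy divided by the
number of non-hydrogen (heavy) atoms,

    Δg = −ΔG°/N_nH,   ΔG° = RT ln(K_D / C°),

or equivalently in log units, η_bind = −log10(K_D/C°)/N_nH = Δg/(RT ln 10).
Both contain the standard concentration C° — the arbitrary unit (by
convention 1 M) that makes the argument of the logarithm dimensionless.
Because the resulting constant shift log10(C°) is divided by a
compound-specific N_nH, changing the concentration unit changes compounds'
efficiencies by *different* amounts: rankings flip, plateaus masquerade as
decay, and a fragment can look more or less efficient than a clinical
candidate depending on nothing but the unit choice.

`ligeff` is a toolkit for medicinal and computational chemists to compute
these metrics *with their unit dependence made explicit*, to audit how
conclusions respond to the choice of C°, and to use replacements that do not
depend on it:

- **Dimensional algebra** (`dim_quantity`, `energy_term`): equilibrium
  constants carry a concentration-dimension exponent (including fractional
  dimensions such as M^(1/N) for per-atom constants defined by
  K_D = k^N_nH), and free-energy terms carry their stoichiometric ΔN tag, so
  every re-expression at a new C° is exact and every free-energy
  decomposition can be checked for stoichiometric consistency
  (`check_decomposition`).
- **Metrics** (`eta_bind`, `dg_per_atom`, `bei`, `lean`, `lle`, `fq`,
  `enthalpic_efficiency`): each result records the C° it used, or declares
  independence from it.
- **Sensitivity analysis** (`metric_grid`, `rank_stability`,
  `linear_plateau_response`): efficiency tables over a C° grid, rank
  inversions with exact crossing concentrations, and the linear-plateau
  demonstration of how the η_bind transform distorts affinity–size
  relationships.
- **Group efficiency** (`group_efficiency`, `compose_edges`,
  `additivity_check`): GE = −ΔΔG/ΔN_nH over structural transformations —
  C°-independent because ΔΔG has ΔN = 0 — with composite-edge bookkeeping,
  additivity cycles, and the zero-size-affinity assumption for prototype GE
  made explicit and never a default.
- **Fragment-to-lead analysis** (`pair_mse`, `pair_lip_eff`,
  `grid_paired_test`, `quartile_map`, `rule_audit`): unit-independent
  per-pair measures ΔpK_D/ΔN_nH and ΔpK_D − ΔlogP, matched-pair t tests of
  start-finish Δη_bind across a C° grid, quartile reference slopes, and
  Ro3/Ro5 property audits.
- **Residual normalization** (`fit_affinity_model`, `residual_normalize`,
  `refit_excluding`): the C°-independent alternative — regress affinity on
  molecular size (and optionally other risk factors) and rank compounds by
  their residuals.

## Worked example

```r
library(ligeff)

trio <- make_table1_trio()   # fragment (10 atoms, 1 mM), lead (20, 1 uM),
                             # candidate (30, 1 nM)
metric_grid(trio, cstd_grid(c(0.1, 1, 10)))
#>          id n_nh pkd   eta_0.1 eta_1    eta_10
#> 1  fragment   10   3 0.2000000   0.3 0.4000000
#> 2      lead   20   6 0.2500000   0.3 0.3500000
#> 3 candidate   30   9 0.2666667   0.3 0.3333333
```

All three compounds are exactly equally ligand-efficient at the
conventional C° = 1 M (η_bind = 0.30). Quote affinities against 0.1 M and
the candidate looks best; against 10 M and the fragment does. The ranking
is a property of the unit, not of the compounds:

```r
rank_stability(trio, cstd_grid(c(0.1, 1, 10)))
#> <rank_stability_report>
#>   C° grid (M): 0.1, 1, 10
#>   inversions between consecutive grid points: 1, 2
#>   pairs whose ranking flips on the grid:
#>      id_a      id_b cross_cstd_molar
#>  fragment      lead                1
#>  fragment candidate                1
#>      lead candidate                1
```

The C°-independent alternative — normalize affinity by regressing it on
molecular size and rank by residuals:

```r
recs <- make_linear_series(a0 = 0.9, a1 = 0.45, sigma = 0, n = 7,
                           planted_residuals = c("4" = -1.7))
fit <- fit_affinity_model(recs)          # -dG ~ n_nh, ordinary least squares
residual_normalize(recs, fit)[, c("id", "residual", "cliff")]
# cmpd04 carries the large negative residual and is flagged; its rank is
# identical whatever concentration unit the affinities were quoted in
```

Group efficiency of adding a five-atom substituent that improves ΔG° from
−5.9 to −10.6 kcal/mol:

```r
e <- transformation_edge("parent", "child", 5, ddg = -10.6 - (-5.9))
group_efficiency(e)
#> <metric_value> GE = 0.9 (C°-independent)
```

A command-line wrapper (`inst/cli/ligeff.R`) exposes the subcommands
`metrics`, `sensitivity`, `ge`, `f2l`, `fit` and `simulate` over CSV
tables; every output file carries an audit header recording the C°,
temperature and unit conventions in effect.

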