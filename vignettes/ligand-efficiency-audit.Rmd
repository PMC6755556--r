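---
title: "Auditing ligand efficiency: why the concentration unit matters and what to use instead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ligand efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligeff)
```

## The problem

The standard free energy of binding of a 1:1 protein–ligand complex is

$$\Delta G^\circ(T, P, C^\circ) = RT \ln\!\frac{K_D(T,P)}{C^\circ},$$

where $C^\circ$ is the standard concentration — conventionally 1 M, but
arbitrary: it exists only so the logarithm has a dimensionless argument. A
tenfold increase in $C^\circ$ lowers $\Delta G^\circ$ by $RT\ln 10$
(1.36 kcal/mol at 298 K). That shift is the same for every compound, so
*differences* $\Delta\Delta G$ are unaffected; but ligand efficiency divides
by a compound-specific size,

$$\eta_{bind} = -\frac{\log_{10}(K_D/C^\circ)}{N_{nH}}
             = \frac{\Delta g}{RT \ln 10},
  \qquad \Delta g = -\frac{\Delta G^\circ}{N_{nH}},$$

so the shift becomes $\log_{10}(C^\circ_2/C^\circ_1)/N_{nH}$ — different
for every compound size. Perception of relative efficiency therefore
depends on the concentration unit: a fragment (10 atoms, 1 mM), a lead
(20 atoms, 1 µM) and a candidate (30 atoms, 1 nM) are exactly equally
efficient at 1 M, yet rank in opposite orders at 0.1 M and at 10 M.

```{r trio}
trio <- make_table1_trio()
metric_grid(trio, cstd_grid(c(0.1, 1, 10)))
```

This package makes that dependence explicit everywhere (every metric value
records the $C^\circ$ it used, or declares independence from it), provides
the machinery to audit how conclusions respond to the unit choice, and
implements the alternatives that do not depend on it.

## The dimensional algebra

`dim_quantity` attaches a concentration-dimension exponent to a number.
The exponent is stored as an exact integer fraction, because per-atom
equilibrium constants defined by $K_D = k^{N_{nH}}$ carry the fractional
dimension $1/N_{nH}$ and must survive arithmetic without floating drift.
Re-expressing a quantity in a new unit multiplies its value by
$(s_{old}/s_{new})^{d}$; quantities of dimension zero are invariant.

The fractional dimension is why per-atom constants cannot be compared
across compounds: X (1 mM, 10 atoms) and Y (1 µM, 20 atoms) both have
$k = 0.501$ in molar units, but in millimolar X becomes 1.000 while Y
becomes 0.708 — the numerical tie was an artifact of the unit.

```{r knh}
k_nh(dim_quantity(1e-3, 1, "M"), 10)
convert_unit(k_nh(dim_quantity(1e-3, 1, "M"), 10), "mM")
k_nh(convert_unit(dim_quantity(1e-6, 1, "M"), "mM"), 20)
```

The package represents such terms without asserting that a fractional
stoichiometry has physical meaning; they exist precisely to demonstrate
the dimensional inconsistency of treating per-atom efficiencies as
thermodynamic quantities.

`energy_term` tags each free energy with its change in number of species,
$\Delta N$ (−1 for formation of a binary complex, +1 for dissociation, 0
for a difference between compounds). Re-expression at a new $C^\circ$
shifts the value by $\Delta N \, RT \ln(C^\circ_{new}/C^\circ_{old})$ and
composes exactly. `check_decomposition` validates free-energy
decompositions on two independent axes: the $\Delta N$ values of the
components must sum to the $\Delta N$ of the total (otherwise the equality
cannot hold at every $C^\circ$), and the values must sum numerically
(default tolerance 1e-6 kcal/mol) after re-expression at a common
$C^\circ$. Energy terms deliberately do not carry a temperature field —
temperature enters through the `thermo_context`, and mixing temperatures
within one analysis is outside this package's scope.

Numerical conventions, chosen once: $R = 1.987204 \times 10^{-3}$
kcal/(mol K); temperature is always an explicit parameter with default
298.15 K (worked values in the literature use both 298 K and 300 K, so no
single hard-coded temperature is correct); recognized unit tokens are M,
mM, uM/µM, nM, pM, case-insensitive, and anything else is a parse error
rather than a silent molar assumption.

## Metrics and their audit trail

`eta_bind`, `dg_per_atom`, `bei` (pIC50 per kDa), `lean` (pIC50 per heavy
atom) and `fq` (ratio of $\Delta g$ to a size-dependent reference) all
depend on the concentration convention and record it. `lle`
(pK − logP) and `enthalpic_efficiency` (−ΔH/N) do not: an *offset* by a
risk factor survives a common unit change (for differences between
compounds), and enthalpy carries no standard-state dependence at all.
IC50-derived inputs are accepted wherever $K_D$ appears, with an
approximation flag that propagates to every output. p-scale inputs are
taken relative to 1 M unless a reference unit is supplied.

Displayed values are rounded (two decimals for η_bind, one for kcal/mol)
only in printing; stored values are full precision.

`fq` takes the reference LE curve as a user-supplied function of
$N_{nH}$: no published functional form is bundled, and the result is
flagged as a C°-dependent ratio — dividing two $\Delta G^\circ$ values
does not cancel their shared $C^\circ$ shift.

The named-but-undefined composites SILE and LELP are not built in; they
are slots a user can compute from the record fields if they have a
definition they trust.

## Sensitivity analysis

`metric_grid` tabulates η_bind over a $C^\circ$ grid (default
0.001–10 M). Because η_bind is *affine* in $\log_{10} C^\circ$ with slope
$1/N_{nH}$, everything about the grid is exact: `rank_stability` counts
rank inversions between grid points and solves for each flipped pair's
crossing concentration in closed form,
$\log_{10} C^* = (p_i N_j - p_j N_i)/(N_i - N_j)$. Ties are broken by
compound id and reported as ties.

`linear_plateau_response` constructs the canonical demonstration: an
affinity–size response that is linear (slope 0.3 pK per atom) up to a
breakpoint and flat beyond it. Changing $C^\circ$ shifts the *affinity*
curve rigidly; the η_bind transform changes shape — the plateau decays as
$1/N$ — which is why affinity–size relationships should be inspected
directly rather than through a per-atom transform.

## Group efficiency

$GE[A \to AX] = -\Delta\Delta G / \Delta N_{nH}$ is C°-independent because
$\Delta\Delta G$ has $\Delta N = 0$ — the one structural-efficiency number
in this family that survives a unit change. GE belongs to the
*transformation*, not to the added substructure: `group_efficiency` tags
every value with its edge identity, `compose_edges` sums energy and size
changes along chains (flagging composites, e.g. substitution plus chiral
resolution), and an optional racemate correction of $RT\ln 2$
(≈0.41 kcal/mol at 298 K, assuming a single binding enantiomer) is
available but off by default.

Prototype GE — the transformation from "nothing" to a structural
prototype — requires assigning a free energy to a species of zero
molecular size. That convention has no physical basis, so
`prototype_ge` refuses to run without an explicit assumption, and
`sweep_zero_size` exposes the resulting linearity: the GE value responds
to the assumed zero-size free energy with slope $1/N_{nH}$, i.e. the
assumption determines the answer as much as the measurement does.

`additivity_check` quantifies non-additivity on (A, AX, AY, AXY) cycles
in kcal/mol and pK units, at a default tolerance of 0.3 kcal/mol (typical
assay reproducibility). A missing corner yields an *indeterminate*
verdict naming the absent compound, never a silent number: per-group
contributions cannot be assigned consistently from an incomplete cycle.

## Fragment-to-lead analysis

For a fragment–lead pair, the package computes two unit-free measures:
the molecular size efficiency $\Delta pK_D/\Delta N_{nH}$ (affinity
gained per atom added) and the lipophilicity-corrected gain
$\Delta pK_D - \Delta \log P$ (zero when the affinity gain is fully
explained by added hydrophobic bulk). Both are ratios or differences of
differences, hence bit-identical under any common unit re-expression.

`grid_paired_test` reproduces the start–finish Δη_bind analysis across a
$C^\circ$ grid: per-C° mean, standard error, matched-pair t statistic and
two-sided p value. The closed form behind the table is

$$\overline{\Delta\eta}(C^\circ_2) - \overline{\Delta\eta}(C^\circ_1)
  = \log_{10}\!\frac{C^\circ_2}{C^\circ_1} \cdot
    \overline{\left(\tfrac{1}{N_L} - \tfrac{1}{N_F}\right)},$$

so whenever leads are larger than their fragments the apparent efficiency
change declines monotonically with $C^\circ$ and can reverse sign inside
the grid — the conclusion of the significance test is itself a function
of the unit. Reproducing any *published* numbers of this form requires
the underlying survey dataset, which is external; the package reproduces
the structure and the sign-reversal behaviour on synthetic cohorts.

`quartile_map` gives the five-number summary of pair slopes as reference
lines through the origin; quartiles use linear interpolation between
order statistics (type 7 — the convention is recorded in the output
because no single convention is universal). `rule_audit` applies the
purely numeric Ro5 (MW ≤ 500, logP ≤ 5, HBD ≤ 5, HBA ≤ 10) and Ro3
(≤ 300/3/3/3) filters with Lipinski hydrogen-bond counting (donors
NH+OH, acceptors N+O) and reports missing inputs as "not assessable".

## Residual normalization

The proposed replacement for LE: fit affinity against molecular size (and
optionally lipophilicity or indicator columns) by ordinary least squares,

$$-\Delta G^\circ = A_0 + A_1 N_{nH} + \dots,$$

and rank compounds by their residuals
$pK_{resd} = pK_{expt} - pK_{pred}$. A common unit change shifts the
response by a constant, which the intercept absorbs exactly: slopes,
residuals and residual rankings are invariant — the property LE lacks.

`fit_affinity_model` returns a classed fit object with
`print`/`summary`/`coef`/`predict`/`residuals`/`plot` methods; `summary`
uses the one-row layout familiar from small-n medicinal-chemistry
regression tables (n, coefficients with standard errors, RMSE, R²). RMSE
is the residual standard error with the $n - k - 1$ denominator.
Residuals beyond a threshold (default 1.0 in response units — large
enough that typical assay noise of a few tenths of a kcal/mol does not
trigger it) are flagged as activity-cliff-like. `refit_excluding`
implements the two-pass workflow: fit everything, identify the structural
outlier by its residual, exclude it, and refit so the remaining series is
normalized against its own trend; both models are reported side by side.
Fits with $R^2 < 0.3$ warn that normalization may be uninformative —
a weak trend can still be used, but it may equally suggest size need not
be corrected for at all. Only multivariate *linear* models are in scope;
weighting is uniform.

## Synthetic data: what it emulates and what it does not

The generators produce every input the tests need, as pure functions of
their parameters and an explicit seed (the global RNG stream is saved and
restored; identical spec + seed gives identical output):

- `make_table1_trio`, `make_xy_pair`: the fixed demonstration compounds.
- `make_linear_series`: $-\Delta G^\circ = a_0 + a_1 N_{nH}$ + gaussian
  noise + planted offsets. Defaults $a_0 = 0.87$, $a_1 = 0.44$ kcal/mol
  per atom, $\sigma = 0.42$, $n = 6$, sizes spread over 5–21 atoms —
  a tight fragment-growing series of the kind used to illustrate
  residual normalization.
- `make_f2l_cohort`: pair slopes log-normal with median 0.28 and
  quartiles near 0.18/0.37 (sdlog 0.412 ≈ log(0.37/0.28)/0.674, matching
  the reported interquartile spread of published fragment-to-lead
  optimizations); fragment sizes uniform on 8–16 heavy atoms, growth
  8–20 atoms, fragment pK_D normal(4.5, 0.8), logP growing mildly with
  size. The per-pair Δη_bind at any $C^\circ$ is computable in closed
  form from the draw, so cohort-level tests have exact expectations.
- `make_null_cohort`: equal-size pairs with i.i.d. mean-zero normal
  Δη_bind — the exact null of the matched-pair test, used for size
  calibration.
- `make_additivity_cycle`: four-corner cycles with controllable
  non-additivity.

What passing tests on these cohorts shows: the algebraic machinery
(affine shift law, unit invariance, closed-form means) is exact, and the
statistical machinery (t test size, CI coverage) is calibrated under its
own assumptions. What it does not show: real fragment-to-lead surveys
have correlated slopes, censored affinities, IC50/K_D mixtures and
project-level clustering that these independent draws do not emulate;
published survey tables can only be reproduced from their own data.

## Problem sizes and numerical choices

The test suite and the reproduction script use: 28-pair cohorts (the size
of the published survey whose structure the grid test mirrors), 200
simulation replicates for coverage, 1000 null cohorts for test-size
calibration, and 50 random small designs (n = 6–10, 1–2 predictors) for
the least-squares oracle comparison — sizes at which every check runs in
seconds while the binomial noise on the calibration rates stays well
inside the asserted bands. Unit round trips are asserted to 1e-12
relative error; OLS agreement with the normal-equations oracle to 1e-8;
crossing concentrations are computed in $\log_{10} C^\circ$ space where
the metric is affine, so no interpolation error enters.

## Known limitations

- No general unit system: concentrations only (no temperature or pressure
  unit handling); enthalpy is carried as a plain C°-independent number.
- logD is not substituted for logP in LLE; for significantly ionized
  ligands the transfer interpretation weakens, and the choice of
  lipophilicity scale is the user's.
- Matched-molecular-pair mining is out of scope: users supply ΔN_nH or
  structures from which heavy atoms are counted.
- The Ro3/Ro5 audit is purely numeric; no substructure logic (e.g. acidic
  bioisosteres) modifies the counts.
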