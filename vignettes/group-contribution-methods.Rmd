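---
title: "Second-order group contributions for alkane thermochemistry and hydroisomerization equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Second-order group contributions for alkane thermochemistry and hydroisomerization equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkaneGC)
```

## The model

Ideal-gas thermochemical properties of branched alkanes — the formation
Gibbs energy and enthalpy, and the Gibbs-energy and enthalpy functions
referenced to 0 K — are to a very good approximation additive over local
molecular fragments. `alkaneGC` implements a group-contribution model whose
descriptors are *second-order groups*: a central united atom (CH3, CH2, CH
or C; hydrogens are implicit) together with the multiset of the
united-atom types bonded to it. For each property $y$ and each temperature
$T$ separately, the model is an ordinary linear regression

$$ y \;=\; \alpha_0(T) \;+\; \sum_{k=1}^{N_\mathrm{desc}} x_k\,\alpha_k(T), $$

where $x_k$ counts the occurrences of group $k$ in the molecule. A
first-order variant (descriptors = the united atoms themselves) is kept for
comparison; because the first-order counts are the center-marginals of the
second-order counts, the first-order model is nested in the second-order
one, and the second-order training error can never be worse. The gain is
real: two CH2 sites with neighbor sets (CH3, CH) and (CH, CH) are
indistinguishable to a first-order model but carry different contributions
here, which is what separates, say, 2,3- from 2,4-dimethyl isomers.

There are exactly 69 second-order groups for acyclic alkanes — the
valence-consistent neighbor multisets number $\binom{4}{1}=4$ for CH3,
$\binom{5}{2}=10$ for CH2, $\binom{6}{3}=20$ for CH and $\binom{7}{4}=35$
for C — plus the special descriptor CH4 so that methane is representable.
A training set spanning all 150 constitutional isomers of C1–C10 covers 46
of these descriptors (45 non-methane groups plus CH4); we verified the
45/46 decomposition against an independent graph-library enumeration, and
the package's tests pin both numbers. The remaining groups occur only in
longer chains.

### Out-of-training groups

Predicting beyond C10 requires contributions for groups the training set
never exhibits. Each such group is mapped onto a *similar* in-training
group by the fewest single-neighbor demotions along
C → CH → CH2 → CH3. When several demotions land in the training set at the
same depth, we demote the **lowest-valence** neighbor first: replacing a
CH2 neighbor by CH3 merely terminates a chain, the mildest structural
change, whereas demoting a C neighbor un-branches a substituted carbon.
(Concretely, C(C)(CH2)(CH2)(CH2) maps to C(C)(CH2)(CH2)(CH3), not to
C(CH)(CH2)(CH2)(CH2), although both are one demotion away and both occur
in C10 isomers.) The map is total over the 69-group universe, ships as a
plain CSV, and can be replaced wholesale by a user-supplied table when an
authoritative approximation list is available. The groups affected belong
to heavily branched isomers that constraining-pore zeolites suppress
anyway, so approximate contributions suffice for equilibrium work.

### Temperature dependence

Regressions are performed on each temperature of the training grid
independently; every coefficient (and the intercept) is then refitted to a
quadratic $\alpha(T) = A + BT + CT^2$, which is what `predict()` evaluates
at arbitrary temperatures. The refit residual per coefficient is stored
and exported, so a coefficient whose temperature dependence is *not*
quadratic surfaces as a diagnostic rather than a silent bias. Predictions
outside the fitted range (0–1000 K by convention) warn.

### Numerical choices

The per-temperature solver centers the design, solves for the group
coefficients by SVD-based minimum-norm least squares (relative
singular-value cutoff $10^{-10}$), and recovers the intercept from the
means. Centering matters: tree-graph identities such as
$\#CH3 = \#CH + 2\#C + 2$ tie the constant direction to descriptor
columns, so a naive minimum-norm solution on the augmented design splits a
uniform shift of the data between the intercept and that collinear
combination. With centering, adding a constant $c$ to every training value
moves the intercept by exactly $c$ and no coefficient changes — an
invariant the test suite asserts. No regularization and no weighting are
applied; fitted values are invariant to any of these gauge choices. The
quadratic refit uses a QR solve on $[1, T, T^2]$.

## Molecules, names, isomers

Molecules are free trees over united atoms with degree ≤ 4 (constitutional
isomers only; alkanes have no stereochemistry at this resolution).
The SMILES parser accepts the acyclic carbon-only subset — rings,
heteroatoms, aromatic atoms and charges are rejected loudly. The writer is
canonical without any external toolkit: the tree is rooted at its centroid
(bicentroid ties resolved by the bytewise-smaller rooted signature) and
children are emitted in sorted subtree-signature order, so isomorphic
graphs produce identical strings. Compact names ("2,2,5-m-C7",
"3-e-2,2,4-m-C5", "4-ip-C7", "n-C14") follow the field's shorthand:
dash-separated locant/branch-code pairs before the parent chain, with
branch codes covering every alkyl substituent up to four carbons plus the
common pentyl shapes — branches never exceed five carbons. The inverse
(`molecule_name()`) picks the longest chain, preferring more branches and
then lower locants, and is exercised by round-trip tests.

Isomers of $\mathrm{C}_n\mathrm{H}_{2n+2}$ are enumerated by leaf
augmentation with canonical-signature deduplication: every $n$-carbon tree
arises from an $(n-1)$-carbon tree by deleting a leaf, so growing a leaf
at every open site and deduplicating canonical forms is provably complete.
We chose this over canonical free-tree generation for its simplicity; it
enumerates C10 (75 isomers) in well under a second and C14 (1858) in a few
seconds, which covers every size this package targets. Counts are tested
against a Prüfer-sequence brute-force oracle (labeled trees, degree
filter, graph-isomorphism bucketing) for $n \le 6$ and against the known
constitutional-isomer series up to C10. `filter_isomers()` implements the
steric pruning rules relevant inside narrow-pore frameworks: maximum
branch length, no geminal substitution, minimum locant separation.

## Synthetic training data

The paper-of-record training source for this kind of model is a Scott-style
table of C1–C10 isomer properties on a temperature grid; the reader
ingests tidy CSV or a workbook with one worksheet per property.
`generate_synthetic_table()` provides a fully controlled substitute whose
values are *exactly* group-additive with planted quadratic-in-$T$
coefficients, plus optional Gaussian noise. Defaults emulate the study
conditions: all 150 isomers of C1–C10, a 0–1000 K grid in 100 K steps, all
four properties, noiseless. Planted magnitudes are chemically plausible
and property-specific, chosen once: formation-enthalpy contributions vary
strongly with center type (about −40 kJ/mol per CH3, −20 kJ/mol per CH2),
formation Gibbs energies vary less (entropy compensates branching), and
the 0 K-referenced Gibbs/enthalpy functions vary only weakly between
isomers; neighbor-dependent perturbations of a few kJ/mol and mild
linear/quadratic temperature terms complete the model. The resulting
isomer spreads — tens of kJ/mol in formation enthalpy, a few kJ/mol in
the Gibbs function — resemble real tables, so equilibrium distributions
computed from synthetic tables span a realistic few orders of magnitude
in relative selectivity rather than collapsing onto one isomer.

What the generator does *not* emulate: real tables are produced by
statistical-mechanical correlations trained on experiment and are not
exactly group-additive, their residual structure is correlated rather than
i.i.d. Gaussian, and their temperature dependence is only approximately
quadratic. Passing the recovery and MAE-ordering tests therefore
demonstrates the correctness of the machinery (descriptor counting,
solver, polynomial refit, approximation routing), not the empirical
accuracy of the model on laboratory data — that claim belongs to the
original tables and cannot be re-established without them.

## Reaction equilibria

For isomers of one molecular formula at reaction equilibrium, equating
ideal-gas chemical potentials leaves Boltzmann weights over the per-isomer
exponent

$$ e_i \;=\; \bigl(G^0 - H^0(0\,\mathrm{K})\bigr)_i(T) \;+\;
   \Delta_f H^0_i(0\,\mathrm{K}), $$

every density, atomization and atomic-reference term cancelling between
isomers (the full $\mu = \mu_\mathrm{ref} + RT\ln(\rho/\rho_0)$ form, with
$\rho_0 = 1$ molecule Å$^{-3}$, and the atomization energy
$D_0 = a_C\,\Delta_f H^0_C + a_H\,\Delta_f H^0_H - \Delta_f H^0_i$ with
the 0 K atomic constants 711.185 and 216.035 kJ/mol are exposed for
completeness, and the constants are arguments rather than hard-coded
truth). Exponents are shifted by their minimum before exponentiation, so
distributions are overflow-safe and invariant to uniform shifts to within
$10^{-12}$; $R = 8.314462618\ \mathrm{J\,mol^{-1}K^{-1}}$. The adsorbed
phase at infinite dilution follows Henry's law,
$x_i \propto K_{H,i}\,y_i$, with Henry coefficients supplied as data (they
come from Widom-insertion Monte Carlo, outside this package's scope).
Selectivity is $s_i = y_i/(1-y_i)$ and relative selectivity divides by a
reference isomer, conventionally the linear alkane. Pressure effects are
ignored — at the ≥500 K temperatures where hydroisomerization equilibria
are studied the infinite-dilution treatment is the accepted regime — and
alkene/hydrogen intermediates are excluded from the network.

Because genuine Henry coefficients require Monte Carlo simulation, the
equilibrium layer is validated by its exact closed forms (equal properties
→ 50/50; an exponent gap of $RT\ln 2$ → 2:1; Henry ratio 3:1 at equal gas
fractions → 75/25), its invariances (normalization, uniform exponent
shifts, uniform Henry scaling), and a consistency experiment: on a noisy
synthetic table, the C10 gas-phase distribution at 500 K computed from the
table values and from the regression predictions agree to Spearman
$\rho > 0.99$.

## Force-field file generation

Adsorption simulations need every intramolecular interaction listed
explicitly, and the lists grow quickly with chain length — n-tetradecane
already carries 91 interactions: 13 bonds, 12 bends, 11 torsions and 55
intramolecular Lennard-Jones pairs. `enumerate_interactions()` derives all
four lists from the molecular graph; intramolecular LJ applies to pairs
separated by **more than three bonds** (1–5 and beyond, no scaled 1–4
term), the convention under which the 91 decomposition holds, and the one
this package documents prominently since the count is convention-
dependent. Tests check the tree-combinatoric identities ($n-1$ bonds,
$\sum_v \binom{\deg v}{2}$ bends, 3-edge simple paths as torsions, and the
partition of all $\binom{n}{2}$ pairs into ≤3-bond and LJ pairs) against a
brute-force path enumerator on random trees.

`write_raspa_files()` emits a RASPA2-dialect flexible molecule definition
plus `pseudo_atoms.def` and `force_field_mixing_rules.def` (Lennard-Jones,
truncated and shifted at 12 Å, no tail corrections, Lorentz–Berthelot
mixing), byte-deterministically. Parameters live in an editable CSV
bundled under `inst/extdata` carrying the standard united-atom alkane set
(after Dubbeldam et al.) and TraPPE-zeo zeolite atoms; these are nominal
published values intended to be audited or replaced before production
runs, not asserted ground truth. The bundled n-C14 golden file in the test
suite was generated by this writer and audited by hand once.

## Problem sizes and tunables

The defaults that matter, with units:

| parameter | default | meaning |
|---|---|---|
| `temperatures` | 0–1000 K step 100 | training grid; quadratic refit needs ≥ 3 points |
| `sigma` | 0 kJ/mol | synthetic-table noise |
| `rcond` | 1e-10 | relative SVD cutoff of the solver |
| `max_branch` | Inf (carbons) | isomer filter |
| LJ cutoff | 12 Å | truncated-and-shifted, no tail corrections |
| `R_KJ` | 8.314462618e-3 kJ/mol/K | gas constant |

Test and validation workloads use C6–C10 fits (up to 150 molecules × 11
temperatures), the full C10 isomer set for equilibrium checks, and random
trees up to C14 for property tests; these sizes keep the whole suite under
a minute while exercising every code path at the scale the package is
meant for.

## Known limitations

* Accuracy on real laboratory data is inherited from the training table
  supplied by the user; the bundled generator validates machinery only.
* The shorthand-name writer cannot encode three of the eight pentyl branch
  shapes (it returns `NA` and the canonical SMILES is used instead);
  the parser-side codes cover all branches that arise on main chains up to
  C14.
* The demotion-based approximation map is a reconstruction of "similar
  group" mapping; users with an authoritative list should load it via
  `read_approximation_map()`.
* Adsorbed-phase results are only as good as the supplied Henry
  coefficients, and finite-loading effects (mixture isotherms, IAST) are
  out of scope.
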