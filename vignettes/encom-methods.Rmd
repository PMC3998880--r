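---
title: "Sequence-sensitive elastic network models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-sensitive elastic network models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(encomr)
```

## The model

Coarse-grained normal mode analysis (NMA) approximates a protein's dynamics
around an equilibrium structure by a quadratic expansion of a potential over
one node per residue (the C&alpha; atom).  The eigenvectors of the resulting
stiffness (Hessian) matrix are collective motion directions; the eigenvalues
are their stiffnesses.  Classical elastic network models -- the anisotropic
network model (ANM, Hookean springs inside an 18 &#8491; cutoff) and the
Gaussian network model (GNM, an N&times;N Kirchhoff matrix) -- see only
backbone geometry, so two structures with the same C&alpha; trace are
indistinguishable no matter how their side chains differ.

The elastic network contact model (ENCoM) implemented here removes that
blindness.  It starts from the four-term Go-like potential of the spring
generalized tensor model (STeM),

$$
V = \alpha_1 \sum_{\mathrm{bonds}} (r - r_0)^2
  + \alpha_2 \sum_{\mathrm{angles}} (\theta - \theta_0)^2
  + \alpha_3 \sum_{\mathrm{torsions}} \Big[(1 - \cos\Delta\phi)
      + \tfrac12 (1 - \cos 3\Delta\phi)\Big]
  + \alpha_4 \sum_{|i-j| \ge 2} \beta_{ij}
      \Big[5\big(\tfrac{r_0}{r}\big)^{12} - 6\big(\tfrac{r_0}{r}\big)^{10}\Big],
$$

and modulates the long-range term by a residue-pair weight built from the
atoms of the two residues:

$$
\beta_{ij} \;=\; \sum_{a \in i}\sum_{b \in j} \varepsilon_{T(a),T(b)}\,
S(a,b),
$$

where $S(a,b)$ is the surface in contact between atoms $a$ and $b$
(&#8491;&sup2;), $T(\cdot)$ maps each heavy atom to one of eight interaction
classes (hydrophilic, acceptor, donor, hydrophobic, aromatic, neutral,
neutral-donor, neutral-acceptor), and $\varepsilon$ is a symmetric
8&times;8 interaction matrix.  Setting every $\varepsilon$ entry to 1 gives
the *non-specific* variant (ENCoM_ns), which is sensitive to side-chain
packing but blind to chemistry.  All heavy atoms of both residues enter the
double sum (backbone included); there is no additive constant, so residue
pairs without atomic contact carry no long-range spring.

Every term of $V$ is a function $f(c(\mathbf{x}))$ of a single internal
coordinate with $f'(c_0) = 0$ at the reference geometry, so the exact
Hessian at the reference is the positive-semidefinite sum of rank-one
contributions $f''(c_0)\, \nabla c\, \nabla c^{\mathsf T}$ with

* bonds: $f'' = 2\alpha_1$,
* angles: $f'' = 2\alpha_2$,
* torsions: $f'' = (1 + 9/2)\,\alpha_3$,
* long range: $f'' = 120\,\alpha_4 \beta_{ij} / r_0^2$.

`build_hessian()` assembles exactly this sum; the tests verify it against
central finite differences of `potential_energy()` to better than $10^{-5}$
relative.  Rigid modes are identified *by count* (the six smallest
eigenvalues for 3D models, one for GNM), never by thresholding, and any
eigenvalue below $-10^{-8}\lambda_{\max}$ aborts with an error since the
construction guarantees positive semidefiniteness.

## Surfaces in contact

The cited analytic contact-surface algorithm is not specified by formulas
in the sources this package follows, so the construction is defined here
and shipped with its own oracle.  Every atom is a sphere of radius
$r + p$ with a probe $p = 1.4$ &#8491; (water); fixed per-element radii are
used (C 1.7, N 1.55, O 1.52, S 1.8 &#8491;).  The surface of each sphere is
partitioned among the neighbouring spheres that overlap it by the *power
diagram* rule: a surface point belongs to the neighbour of smallest power
distance $\lVert p - c\rVert^2 - R^2$, provided that power is negative.
$S(a,b)$ is the mean of the area $b$ wins on $a$'s sphere and vice versa.

Because every membership or power comparison is a half-space, each region
is an intersection of spherical caps.  The analytic method computes its
area exactly by Gauss&ndash;Bonnet over the circular-arc arrangement
(turning angles at arc vertices, geodesic curvature $\cos\theta_k$ per
arc, Euler characteristic $2 - \#\mathrm{loops}$), falling back to a
deterministic Fibonacci-lattice estimate if the arrangement is numerically
degenerate.  The `numeric` method evaluates the same definition purely by
lattice sampling and serves as the independent oracle: the suite requires
agreement within 5% on random two- and three-sphere configurations and on
helix fixtures (observed: &le; 1.5%).  Atoms of the same residue compete
for surface but intra-residue areas are never reported, and bonded
neighbours ($|i-j| \le 1$) are excluded from the long-range term
downstream.

## Atom types and the interaction matrix

The eight-class atom typing follows the published contact classification
scheme; since the original per-atom table is not printed in the sources
used here, the bundled `(residue, atom)` table is a documented
reconstruction from the class definitions (e.g. backbone N donor --
except proline -- carbonyl O acceptor, serine OG hydrophilic, aromatic
ring carbons aromatic, histidine ring nitrogens as the tautomer-dependent
neutral-donor/neutral-acceptor classes).  Unknown pairs become
`"unassigned"` with a warning and are treated as neutral in
$\beta$ computation.

The numeric $\varepsilon$ matrix was likewise never published.
`eps_matrix_default()` is an explicitly labelled chemistry-motivated
reconstruction (complementary pairs 2, clashes 0.5, everything else 1) and
can be replaced by any TSV via `read_eps_matrix()`; `eps_matrix_ones()`
defines ENCoM_ns.  Conclusions that depend on the *specific* numbers in
the default matrix should be treated with corresponding caution.

## Force-constant weights

The published description reports its optimal $\alpha$ set only
graphically, noting that parameter sets with large bond/angle weights and
$\alpha_4 < 1$ favour conformational overlap and mutation prediction while
$\alpha_4 > 1$ favours crystallographic b-factors.  The package therefore
ships two labelled reconstructions selectable via
`enc_params(profile = ...)`:

| profile   | $\alpha_1$ | $\alpha_2$ | $\alpha_3$ | $\alpha_4$ | intended use |
|-----------|-----------|-----------|-----------|-----------|--------------|
| `overlap` (default) | $10^3$ | $10^4$ | $10^4$ | $10^{-2}$ | overlap, mutation ddG |
| `bfactor` | $10^2$ | $10^3$ | $10^3$ | $10$ | fluctuation profiles |

STeM uses the classical Go-potential constants $(100, 20, 1, 1)$.  The
model is deliberately robust to these choices: scaling all four weights by
a constant scales every eigenvalue by that constant and leaves b-factor
correlations, overlaps and entropy differences unchanged (tested exactly),
and the mini grid searches in the test suite reproduce the qualitative
$\alpha_4$ split.  Unit node masses are used throughout (no mass
weighting).

## Observables

**Predicted b-factors** (`predict_bfactors`): $b_i = \sum_{n=7}^{3N}
(v_{n,ix}^2 + v_{n,iy}^2 + v_{n,iz}^2)/\lambda_n$, i.e. the per-residue
block trace of the Hessian pseudoinverse restricted to internal modes;
the GNM variant is the diagonal of the Kirchhoff pseudoinverse.  Values
are shape-only; Pearson correlation against the experimental B column is
the reported comparison.

**Overlap** (`overlap`, `conformational_overlap`): the target conformation
is first superposed on the start by a least-squares rigid fit over
matched C&alpha; (match key: chain + author residue number + insertion
code; unmatched residues are dropped and the network is rebuilt on the
common subset).  Residual rigid-body components of the displacement are
projected out with the decomposition's own rigid eigenvectors (default
`project_rigid = TRUE`) so that squared overlaps over the internal basis
sum to exactly 1.  $O_n = |v_n \cdot \Delta r| / \lVert\Delta r\rVert$,
and the summary is the best overlap within the 10 slowest internal modes.
Identical conformations make the overlap undefined and raise an error.

**Vibrational entropy and mutation scores** (`entropy_difference`,
`predict_ddg`): in units with $k_B = 1$,
$\Delta S_{a \to b} = \tfrac12 \sum_n (\ln\lambda_{a,n} -
\ln\lambda_{b,n})$ over paired, sorted internal modes -- positive when
$b$'s spectrum is softer, exactly antisymmetric and additive.  A mutation
is scored as $\tfrac12\sum_n(\ln\lambda_{\mathrm{mut},n} -
\ln\lambda_{\mathrm{wt},n})$, so a stiffer (entropy-poorer) folded mutant
state scores positive, i.e. predicted destabilizing.  No absolute
calibration to kcal/mol is attempted: the through-origin regression slope
absorbs the scale.  Because ANM and STeM see only the backbone, they score
every side-chain-only mutation exactly zero -- reproducing the known
artifact that geometric models "predict" neutral mutations well.

**&Delta;B profiles** (`delta_b_profile`): per-residue difference of
z-scored predicted b-factors between mutant and wild type, sign-inverted
so the profile tracks NMR $S^2$ order-parameter differences (a residue
made more flexible gets a negative value).  The z-score-plus-inversion
form is a documented interpretation of the "inverse normalized
difference" convention; the published formula is not explicit.  Since
&Delta;B is a fluctuation observable, the `bfactor` weight profile is the
appropriate one; under the `overlap` profile the long-range term
contributes too little stiffness for side-chain changes to move the
profile appreciably.

## Evaluation machinery

*Through-origin regression* (`rmse_through_origin`): $k = \sum xy /
\sum x^2$, RMSE of $y - kx$.  The zero intercept encodes that a null
mutation must predict a null change.

*Bootstrap* (`bootstrap`): resampling with replacement, 10000 replicates
at benchmark scale (caller-sized in tests), deterministic under the seed
argument, for means, medians, through-origin RMSEs and correlations.

*Self-consistency* (`self_consistency`): for forward/back prediction
pairs, with $d = \Delta\Delta G_{A\to B} + \Delta\Delta G_{B\to A}$, bias
$= \overline{d}/\sqrt2$ and error $= \sqrt{\overline{d^2}}/\sqrt2$ -- the
signed mean and RMS distances from the line $y = -x$.  The $\sqrt2$
normalisation is this package's documented choice for the geometric
description; error &ge; |bias| always.

*Model combination* (`combine_models`): per bootstrap replicate, each
model's predictions (and a seeded reshuffled-experimental baseline) are
rescaled onto the experimental scale by their through-origin slopes; the
two-coefficient combination is fitted by SVD least squares (minimum-norm
with a warning under collinearity); reported are the RMSE difference
against the random baseline and the coefficient ratio measuring the
entropic model's relative contribution.

*Parameter search* (`parameter_search`): a sparse exhaustive integer
search of the base-10 logarithms of the four weights ($13^4 = 28561$
combinations at published scale; caller-sized here).  Stage 1 ranks grid
points by the summed Z-scores (over the grid population) of the
bootstrapped-median through-origin RMSEs on stabilizing and destabilizing
mutation tasks; the best `keep_frac` advance to stage 2 where mean
best-of-10 overlap Z-scores for domain and loop tasks are added.  The
published description is ambiguous about the stage-2 set size (2000
vs 1000 sets), so the fraction is an explicit parameter.

## Synthetic data: what it does and does not emulate

`make_structure()` builds deterministic toys: straight bead chains
(3.8 &#8491; spacing), ideal helices (rise 1.5 &#8491;, 100&deg; twist --
consecutive C&alpha; distances come out at 3.83 &#8491;), and hinged
two-domain helices.  Single-sphere pseudo side chains keep contact areas
near closed form so the contact oracle stays simple.
`make_conformer_pair()` produces targets displaced along internal mode 7
(best overlap 1 by construction), by a rigid hinge bend, or randomly;
`make_mutation_pair()` changes exactly one side-chain sphere's class
and/or radius and injects an "experimental" ddG by the stated generative
rule $\Delta\Delta G = c\,\mathrm{score} + \mathcal N(0, \sigma)$, making
slope/RMSE recovery checkable (slope recovered within 1% and RMSE
&asymp; 0 at $\sigma = 0$).

The `synthetic_*` table generators reproduce the *layout and composition*
of the published benchmarks -- 303 mutations splitting 45/84/174 at the
&plusmn;0.5 kcal/mol thresholds (closed neutral interval), 65
forward/back pairs reducing to 57 after the proline and server-failure
exclusions, and 368 conformation pairs (124 domain, 244 loop) giving 736
directed changes -- but every identifier and value in them is synthetic.
Passing tests on these fixtures therefore demonstrates that the
machinery (thresholds, exclusion handling, directed expansion,
regression, bootstrap) is correct, *not* that the package reproduces
benchmark accuracy on real proteins: toy structures lack realistic
packing density, rotamer chemistry, crystallographic noise and the
modelling error of real mutant structures.  The DHFR order-parameter
worked example likewise requires external experimental data and a
modelled mutant and is not reproduced offline.

## Numerical choices and degenerate inputs

* Collinear angle triples (and degenerate torsions) return zero gradients
  and are skipped as energy terms, so straight bead chains remain usable;
  the 3-bead chain then reduces to the classic two-spring system with
  nonzero eigenvalues $\{2\alpha_1, 6\alpha_1\}$, used as a closed-form
  oracle in the tests.
* Alternate locations resolve to the highest occupancy (ties to the first
  altloc label); MSE is remapped to MET; other non-standard residues,
  hydrogens, waters and heteroatoms are dropped; residues without a
  C&alpha; are dropped with a warning.  Multi-model files use model 1 by
  default.  These policies are this package's documented choices; the
  benchmark sources do not state theirs.
* Coincident atoms are a hard error naming the atoms; a disconnected
  interaction network only warns (extra zero modes are then expected).
* Power-comparison ties between concentric competitor spheres break to
  the lower atom index, deterministically.
* Test problem sizes (5&ndash;12-residue toys, $\le 3^4$ search grids,
  $10^2$&ndash;$10^4$ bootstrap replicates) were chosen so the whole
  suite exercises every code path in well under a minute per file while
  keeping all stated tolerances sharp.

## Known limitations

* The $\varepsilon$ matrix, atom-type table and $\alpha$ defaults are
  reconstructions (see above); quantitative agreement with the original
  implementation's spring strengths is not guaranteed.
* Entropy scores are relative, unitless quantities; only rank orderings
  and regression-rescaled values are meaningful.
* The contact construction reports pairwise surfaces only -- no
  solvent-accessible areas, no ligand or heteroatom contacts.
* Mutant structures are consumed as input (as in the original protocol);
  no side-chain repacking or backbone repair is attempted.
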