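---
title: "Electron-conformational 4D-QSAR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-conformational 4D-QSAR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecga4d)
```

## The problem

A flexible drug-like molecule does not present one geometry to its receptor
but an ensemble of thermally accessible conformers, each with its own
electronic distribution. Two consequences follow for structure-activity
modelling. First, the feature responsible for binding — the pharmacophore —
must be sought across conformers, not in a single optimized structure.
Second, predicted activity should weight each conformer by its Boltzmann
population, because a pharmacophore carried only by a high-energy conformer
contributes little. `ecga4d` implements both ideas for conformer ensembles
carrying atomic charges, bond descriptors and 3D coordinates, together with
the descriptor-selection and machine-learning layers used around them.

## The electron-conformational matrix of contiguity (ECMC)

Each conformer of an n-atom compound is encoded as a symmetric n x n
matrix: diagonal entries hold an atomic electronic property, off-diagonal
entries hold a bond descriptor for bonded pairs and the interatomic
Euclidean distance for nonbonded pairs. The defaults are partial atomic
charge (e) on the diagonal and bond order for bonded pairs, with distances
in Angstrom; both properties are configurable (`atomic_props` arrays and
the bond table's `wiberg`, `bond_energy` and `bond_polarizability` columns)
because other members of the same family — valence, polarizability,
frontier-orbital energies, Wiberg indices — are equally admissible. Which
atomic property populated the diagonal of the published reference matrices
is not stated by their source; their magnitudes are consistent with partial
charges, and that is the default here. Bonded C–H entries are masked from
all comparisons: they are essentially identical in every organic compound
and carry no discriminating information. Hydrogen atoms themselves remain
eligible pharmacophore members (the packaged 6-atom reference pattern
includes one).

## Pharmacophore mining (ECSA)

The pharmacophore is a k x k principal submatrix of a reference active
compound's ECMC that recurs, within elementwise tolerances, in every active
compound and in no inactive one. `find_ecsa()` takes the reference
compound's lowest-energy conformer as the pattern source and enumerates
candidate atom subsets by deterministic breadth-first growth: all seed
pairs, each extended by atoms later in the (label-sorted) reference order,
within a configurable size range (default 3–8). Each candidate is scored by
screening the lowest-energy conformer of every compound under the initial
uniform tolerances — defaults 0.25 e on the diagonal, 1.30 Angstrom
off-diagonal, the conventional upper limits for this family of methods —
and computing the contingency statistics

$$P_a = \frac{h_1 + 1}{h_1 + h_2 + 2}, \qquad
\alpha_a = \frac{h_1 h_4 - h_2 h_3}{\sqrt{k_1 k_2 k_3 k_4}},$$

where $h_1$/$h_2$ count actives with/without the feature, $h_3$/$h_4$ the
same for low-activity compounds, and $k_1 = h_1+h_2$, $k_2 = h_3+h_4$,
$k_3 = h_1+h_3$, $k_4 = h_2+h_4$. $\alpha_a$ is written here with the
square root over the marginal product: this is the standard phi coefficient
bounded in $[-1, 1]$, and the only form under which published values of the
statistic on series of this size (about 0.83) are attainable at all — the
bare product would put the statistic several orders of magnitude lower.
The winning subset maximizes $\alpha_a$, with ties broken by higher $P_a$,
then smaller size, then lexicographic atom labels. Degenerate marginals
(some $k_i = 0$) leave $\alpha_a$ undefined; such candidates are skipped,
and a series in which no subset discriminates at all raises an error.

Two exactness devices keep the search honest without changing its result:
a compound that fails to match a subset is never re-tested on that subset's
supersets (matching is antitone under submatrix growth), and the
backtracking matcher itself (`match_submatrix()`) is checked in the test
suite against an exhaustive-enumeration oracle (`brute_force_match()`) on
instances of up to 10 atoms.

Matching details that matter for reproducibility: candidate atoms are tried
in increasing index order and the first complete assignment wins; element
compatibility is enforced (a reference N only maps onto an N); tolerance
comparison is inclusive, because derived tolerance matrices are attained
maxima of deviations and the conformers that attain them must themselves
match. Inclusivity is implemented with an absolute floating-point guard of
1e-9 on top of the tolerance so that a deviation of exactly one tolerance
survives rounding. `derive_tolerances()` reports per-element attained
maxima over any matching conformer subset — the package's analogue of the
published class-wise tolerance matrices — and re-screening the derivation
subset with its own derived tolerances is a tested self-consistency
invariant.

## The Boltzmann-weighted activity model

Predicted activity of compound $n$ with conformers $i = 1..m_n$:

$$A_n = A_0 \, \frac{\sum_{i=1}^{m_n} \delta_{ni}\, e^{-S_{ni}}\,
e^{-E_{ni}/RT}}{\sum_{i=1}^{m_n} e^{-E_{ni}/RT}}, \qquad
S_{ni} = \sum_{j=1}^{N} \kappa_j\, a_{ni}^{(j)}.$$

Both sums run over the retained conformers of compound $n$; the
pharmacophore indicator $\delta_{ni}$ gates the numerator only. This is the
only reading of the formula consistent with its intended limiting
behaviour: a compound in which no conformer carries the pharmacophore
predicts exactly zero activity. The printed form of this equation in the
literature this package follows is typographically garbled around the
summation bounds, and the surrounding prose once describes the dependence
as $e^{+S}$; the equation's $e^{-S}$ is taken as normative, since the sign
is absorbed by the fitted $\kappa_j$ anyway.

Conventions:

* **$A_0$ is fixed, not fitted**, to the reference compound's experimental
  pIC50. In the degenerate case — every conformer matching, zero shielding
  — the model then reproduces the reference activity exactly, which is the
  behaviour reference tables display for the reference compound.
* **$RT$** uses the gas constant $R = 1.9872 \times 10^{-3}$ kcal mol$^{-1}$
  K$^{-1}$; the default temperature is 298.15 K (the sources leave $T$
  unstated; it is a configurable argument everywhere).
* **Energies** are relative (kcal/mol) and re-referenced to the ensemble
  minimum on every read and after every filtering step, so predictions are
  invariant under a uniform energy shift (a tested property).
* **Compounds with all $\delta = 0$** stay in the fitting objective by
  default, contributing $(A^{exp}_n - 0)^2$: the model claims the
  pharmacophore is necessary, so an active compound without it should hurt
  the fit. `include_nonmatching = FALSE` excludes them; a warning is
  emitted either way.
* **pIC50** is defined on the molar scale ($9 - \log_{10} \mathrm{IC_{50}[nM]}$),
  and the high/low classification threshold defaults to 7.61, inclusive.
  The packaged 54-compound activity fixture keeps its printed class labels
  verbatim; `read_activity_table(label_mode = "verbatim")` reports
  label/threshold disagreements instead of silently recomputing them,
  because the printed labels (27 high / 27 low) and the printed class
  counts of that series' text (28 / 26) cannot both be right and the
  package refuses to adjudicate.

$\kappa$ is fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`) with an analytic Jacobian, initialized at
$\kappa = 0$, convergence tolerance $10^{-10}$ on the objective, optional
seeded multistart (default one start). No descriptor scaling is applied
internally: published $\kappa$ magnitudes spanning $-17.6$ to $10^{-3}$
indicate the original fits ran on unscaled descriptors, and scaling is the
caller's choice.

## Descriptor selection

`ga_search()` evolves fixed-cardinality descriptor index sets under
leave-one-out PRESS fitness (evaluations are memoized by sorted subset). The chromosome is a set of exactly N indices rather than a free
binary mask because the subset size is a modelling constraint (the 5:1
compounds-to-descriptors guideline), not an objective. Uniform crossover
pools parent indices and repairs to cardinality N; per-gene mutation swaps
an index for an unused one; selection is tournament of size 2 with elitism
of 1 — the selection operator is unspecified in the sources, and this
choice is standard, reproducible and makes the best-so-far trace provably
non-increasing (asserted on every run). Defaults mirror the reference
configuration (population 500, 500 generations, crossover 0.5, mutation
0.01, N = 12); the test suite runs reduced budgets (population ≤ 40,
generations ≤ 50), which are configuration values, not different
algorithms. `exhaustive_search()` provides the oracle for small instances
(guarded at $10^5$ combinations) and the GA is tested to agree with it.

Per-descriptor influence uses $E_j = \mathrm{PRESS}_N /
\mathrm{PRESS}_{N-1,\,-j}$: eliminating an influential descriptor inflates
the reduced model's PRESS, driving $E_j$ down. On forward-simulated data
the signal descriptors' $E$ values sit orders of magnitude below the noise
descriptors' (which hover near 1); the packaged E-statistic fixture shows
the same ranking structure on the reference series, with its minimum
(0.624) at the bond-angle parameter of the pharmacophore triad.

## Validation statistics

`press`, `q2_loo` ($1 - \mathrm{PRESS}/\mathrm{SSY}$), the two external
variants ($q^2_{ext1}$ with the training-mean denominator, $q^2_{ext2}$
with the test-mean denominator — identical when the two means coincide, a
tested identity), correlation-based $R^2$, MSE/MAE/RMSE, and seeded k-fold
$Q^2$ with pooled out-of-fold residuals against the full-sample mean.
$R^2$ is reported as squared Pearson correlation; coefficient-of-
determination style quantities are exposed through the $q^2$/$Q^2$ fields,
so the two conventions are never conflated. The k-fold repetition count
defaults to 1 and is configurable.

## The hybrid ML layer

Z-scoring uses training-set statistics only (population denominator n,
matching the scaler convention of the common Python implementation) and is
re-fit inside each cross-validation training fold. Recursive feature
elimination wraps a random forest, dropping the lowest node-impurity
feature one at a time (step 1) to a default of 30 retained descriptors.

The gradient-boosting machine is implemented in-package on `rpart`
regression trees — squared-error loss, stage-0 constant equal to the
training mean (the argmin of squared error over constants), residual
fitting, shrinkage 0.1, depth 3, 100 stages — so the textbook stagewise
contract is directly inspectable: the tests assert the stage-0 closed form
and the monotone descent of training RSS. The random forest is
`randomForest` with 100 trees, sqrt feature sampling, minimum leaf size 1.
The stacked hybrid feeds the GBM score to a random-forest meta-learner as
one appended column (`|features| + 1` meta inputs — "used as input" is
ambiguous between appending and replacing, and a score-only mode is
available behind a flag). The default stacking mode is **out-of-fold**: GBM
scores for the training rows come from a seeded 5-fold split, and the
full-data GBM is refit for inference, so the meta-learner never sees
in-sample scores of its own training targets. The **naive** mode trains the
meta-learner on in-sample scores; it reproduces the near-perfect training
statistics such stacking yields (a tested demonstration: naive training
$R^2 \geq$ out-of-fold $Q^2$) and is retained, clearly labelled, precisely
because reported values like $R^2 = 0.99978$ on 54 compounds are most
plausibly of this kind. The ANN baseline (single hidden layer of 100
units, 200 iterations) is optional, requires `nnet`, and sits outside the
determinism guarantees beyond seeding; its optimizer (BFGS) differs from
the Adam convention of the Python stack.

## The synthetic generators

All three generators are pure functions of a `synthetic_spec` (same spec,
identical bytes — a tested invariant).

**Planted pharmacophore sets** (`gen_pharmacophore_set`) build compounds of
8–14 atoms around a k-atom reference pattern with charges in [-0.4, 0.4] e
and pairwise distances in [1.2, 6] Angstrom. Every conformer of every
active embeds the pattern under a random rigid motion plus perturbations
bounded by `tolerance_scale` times the screening tolerances; with the
default `tolerance_scale = 0.5` the triangle inequality guarantees any two
active instances agree within one full tolerance, so separability is
structural, not statistical (and is verified by screening inside the
generator, which regenerates an offending inactive up to 60 times). Each
inactive violates one planted atom's charge by at least 3 tolerances, and
the violated atom cycles over the k positions so that no proper subset of
the pattern separates the classes — this is what makes exact recovery of
the full planted atom set the unique optimum. Decoy atoms are given
charges in [0.6, 1.5] e, outside the diagonal tolerance of any planted
atom, so subsets containing decoys cannot tie the planted pattern;
real descriptor panels are of course not this clean, so a recovered
synthetic pharmacophore demonstrates the search's correctness, not the
discriminating power to be expected on experimental series. Default
screening tolerances (0.1 e diagonal, 0.5 Angstrom off-diagonal) sit well
inside the conventional 0.25/1.30 upper limits.

**Forward-model activity data** (`gen_activity_data`) draws per-conformer
descriptors as standard normals, computes activities through the
Boltzmann-weighted formula with known `kappa_true`, and adds Gaussian
noise. Because the model is exponential in S, activities are heavy-tailed
relative to a real pIC50 column; parameter-recovery and PRESS-based tests
state the seeds and sample sizes they use (for instance n = 60 compounds
for the E-statistic stability check) and those sizes were chosen for
statistical stability of the respective statistic at desk scale.

**Nonlinear regression tables** (`gen_ml_table`) use
$y = 2\sin x_{s_1} + 0.5\, x_{s_2} x_{s_3} + 1.5\,[x_{s_4} > 0] + \epsilon$.
The smooth term and the step dominate the signal variance and are
well within reach of depth-3 boosted trees at n = 200, while the
deliberately modest interaction keeps the surface genuinely non-additive;
the high-SNR benchmark configuration (n = 200, p = 10, noise sd 0.1) is
the package's frozen reference condition for the stacked model's
out-of-fold performance, and a weaker learner is readily exposed by
raising the noise or the interaction weight.

## Numerical choices and degenerate inputs

* Boltzmann factors are computed after subtracting the minimum energy, so
  overflow cannot occur and weights sum to 1 within 1e-12.
* Tolerance comparisons carry a 1e-9 absolute guard (see above); matrix
  symmetry is validated to 1e-12.
* `fit_kappa` warns when fewer than N + 1 training compounds are available
  and when non-matching compounds are present; it errors when no compound
  matches at all. Non-convergence returns the best iterate, flagged.
* Zero-variance feature columns are centred only (with a warning) during
  z-scoring; constant responses raise degenerate-target errors in
  `q2_loo`, `q2_kfold` and the stacking trainer rather than NaN.
* Ties in the GA's tournament and the RFE's importance ordering resolve by
  index order, keeping runs bit-reproducible under a fixed seed.

## Known limitations

* The package consumes precomputed conformer ensembles and electronic
  properties; it performs no quantum-chemical or force-field calculations,
  and SDF ingest supplies geometry only.
* The assignment search is plain deterministic backtracking; highly
  symmetric molecules with many equivalent atoms could make it slow, and
  no graph-canonicalization shortcut is attempted.
* Published dataset-bound statistics for the reference pyrazole series
  (stacked-model $R^2$ of 0.99978, $P_a = 0.8402$, $\alpha_a = 0.8261$,
  the per-descriptor $R^2$/$q^2$ columns) are not reproducible here: they
  require the original 204- and 273-descriptor panels and an unpublished
  4-compound test split, and no integer contingency even reproduces the
  printed $P_a$ under its own formula with 28 actives. The package ships
  those numbers as fixtures and documentation, not as targets.
* The packaged all-conformer tolerance fixture is not the elementwise
  maximum of the two class-wise fixtures, implying it was derived over
  conformers not printed; it is kept as a fixture only.
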