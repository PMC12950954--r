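---
title: "Fragment sensitiser screening and co-administration analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment sensitiser screening and co-administration analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsens)
```

# The problem

Chemoresistance limits what a cytotoxic drug such as gemcitabine can achieve
in pancreatic ductal adenocarcinoma. One response is to pair the drug with a
small, intrinsically non-toxic chemical fragment — a "binary drug" sensitiser
— that re-opens the apoptotic route the tumour has closed. Candidate
fragments are found computationally: a Rule-of-3 fragment library is ranked
by fingerprint similarity against two reference panels, one of known pathway
inhibitors (so the fragment can plausibly act on the target pathway) and one
of natural metabolites (so it can plausibly ride an existing cellular uptake
route). The shortlisted fragment is then validated on viability plates where
it is co-administered with the drug over a dose grid.

`fragsens` implements both halves of that computation: the chemistry
(structures, descriptors, Rule-of-3, fingerprints, Tanimoto similarity,
exact maximum common substructure) and the plate analysis (normalisation,
enhancement, dose-sparing, hormesis detection, group comparison), plus a
synthetic-data module that generates both kinds of input with known ground
truth.

# Structures

`parse_structure()` reads SMILES into a heavy-atom graph. Aromaticity is
taken as written (lowercase atoms) rather than re-perceived, formal charges
are preserved (trigonelline stays a zwitterion, protonated serotonin keeps
its +1), and hydrogens stay implicit. Stereo descriptors are accepted and
ignored — every computation here is two-dimensional. Unparsable input
raises an error naming the offending character position.

Standard physico-chemical descriptors (molecular weight, cLogP, TPSA,
H-bond donors and acceptors) are delegated to OpenBabel through ChemmineOB;
re-deriving them would add nothing. The rotatable-bond count comes from the
package's own graph (acyclic, non-aromatic single bonds between two
non-terminal heavy atoms), and the Rule-of-3 filter is native logic:
MW ≤ 300 g/mol, cLogP ≤ 3, donors ≤ 3, acceptors ≤ 3, rotatable bonds ≤ 3,
TPSA ≤ 60 Å², all boundaries inclusive and all violations reported, not
just the first. These are the community thresholds for fragment decks of
the Maybridge type; each limit is configurable through `ro3_thresholds()`.

# Similarity

The Tanimoto coefficient between two fingerprints with $a$ and $b$ set bits
and $c$ bits in common is

$$T_c = \frac{c}{a + b - c},$$

implemented natively on the bit vectors and reported half-up at two
decimals, the convention of published similarity panels.

Three standard fingerprint schemes are supported: 166 MACCS structural keys
(`structural-keys-166`, the default), a hashed linear-path fingerprint
(`path-based`, 1024 bits) and an extended-connectivity circular fingerprint
of radius 2 (`circular-r2`, 4096 bits). Published similarity tables rarely
name the fingerprint that produced them, so `calibrate_scheme()` evaluates
all three on a table of reference pairs with printed values and keeps the
scheme with the smallest maximum absolute deviation after rounding, ties
broken alphabetically.

A note on what calibration can and cannot do: for the packaged reference
panels (BD B10 against five Akt-pathway inhibitors and five natural
metabolites) none of the three schemes reproduces the printed values — the
best achieves a maximum deviation of 0.42, and printed values near 0.6 for
molecules sharing only scattered features are simply not attainable with
these standard bit definitions. The workflow that produced those tables
used an unnamed fingerprint that cannot be recovered from the numbers
alone. The package therefore treats such tables as calibration input,
reports the achieved deviation honestly, and leans on rank structure
rather than absolute values; under the calibrated scheme the top inhibitor
(trigonelline) is reproduced, while in the metabolite panel
N-methylserotonin edges tryptamine by 0.02 — within the resolution one can
expect when the generating fingerprint is unknown.

# Maximum common substructure

MCS evidence answers "what exactly do these two molecules share?". The
package computes the exact maximum common *induced*, by default
*connected*, substructure via the modular product construction: vertices
are atom pairs that match (element plus aromaticity by default; charge
optionally), and two vertices are adjacent when their bond relations
agree — both bonded with compatible types (a *strong* edge) or both
non-bonded. Cliques of this graph are precisely the common induced
subgraph mappings; cliques connected through strong edges are the
connected ones, matching how MCS panels are drawn. Atom matching ignores
formal charge by default so a zwitterionic aromatic nitrogen can match a
neutral one; `any_bond_order` relaxes bond-type matching.

The search is a branch-and-bound over this product graph: the connected
mode uses a c-clique variant in the style of Koch's algorithm (candidates
split into connected and not-yet-connected sets, the latter migrating as
strong neighbours join the clique), the unconstrained mode classic
Bron–Kerbosch with pivoting. Pivoting is deliberately not used in the
connected mode — it is unsound for the connected-candidate partition — so
that mode relies on the size bound alone. Both modes prune on
`|clique| + |candidates|` against the best size found, collect all
co-optimal cliques up to a cap, and are deterministic: vertices are
ordered lexicographically by atom-index pair, and results are returned in
lexicographic order. Ties among equal-sized solutions are broken by bond
count, then by the lexicographically smallest mapping. Graphs above 4000
vertices are refused with advice to pre-filter, and a node-count guard
turns pathological searches into errors rather than hangs.

Every result carries a SMARTS pattern written from the mapped subgraph
with explicit bond symbols; tests verify post hoc, via an independent
substructure matcher, that the pattern matches both parent molecules. The
test suite also compares the clique search against `igraph`'s clique
number on random graphs and the full MCS against an exhaustive
subset-enumeration oracle on all pairs of a small-molecule fixture set —
the oracle shares no code with the implementation.

# Plate analysis

`normalize_viability()` aggregates replicates per dose cell (mean, SEM)
and expresses everything as percent of the untreated-control mean, which
maps to exactly 100 %; SEMs are scaled by the same factor. Aggregation
precedes normalisation, and multiplying all raw signals by any constant
leaves the summary unchanged.

Three quantities sit on top of the normalised surface:

* **Enhancement** (`enhancement_delta`): viability at (drug dose, 0) minus
  viability at (drug dose, sensitiser dose), in percentage points.
  Negative values — antagonism — are reported, never clipped.
* **Dose-sparing** (`dose_sparing`): both the drug-alone column and a
  sensitiser column are interpolated piecewise-linearly on log10(dose)
  (dose grids are geometric; the 0-dose anchor is excluded) to find the
  doses reaching a common target viability; the sparing fraction is
  $1 - D_{combo}/D_{alone}$. A target outside a column's range errors with
  the achievable interval; a target bracketed only by a rising segment
  errors with advice to inspect for hormesis. Because a single target
  inherits the noise of the two cells bracketing it,
  `dose_sparing_profile()` averages the estimate over a grid of targets
  (default 20–80 % in steps of 5) along the monotone overlap of the two
  columns; this is the recommended summary.
* **Hormesis** (`detect_hormesis`): a column is flagged when some higher
  dose's mean viability exceeds a lower dose's by more than
  $k\sqrt{sem_1^2 + sem_2^2}$ (default $k = 2$), over all ordered dose
  pairs, each offending pair reported. The default $k$ is a sensitive
  screen, not a calibrated test: with 7–8 dose points there are ~21–28
  correlated pair comparisons and few replicate degrees of freedom, so on
  pure noise the family-wise flag rate at $k = 2$ is large (roughly half).
  Treat a flag as an invitation to look at the curve; raise $k$ to ~3.5,
  or restrict to adjacent pairs, when a conservative call is needed.

Group comparisons use one-way ANOVA with Tukey's HSD correction
(`stats::aov` / `TukeyHSD`) with the usual star convention; a degenerate
all-equal input returns $F = 0$, $p = 1$ rather than NaN.

# The synthetic-data generator

`generate_dose_response()` simulates plates from a Hill inhibition model
with a pure potency-shift sensitiser:

$$v(g, b) = e_0 - e_{max}\frac{g^h}{g^h + (EC_{50}\,s(b))^h}
          + A\,\mathbf{1}[g = g_{top}], \qquad
  s(b) = \frac{1}{1 + \rho\, b/(b + k_b)},$$

with i.i.d. Gaussian replicate noise. The implied true sparing at
sensitiser dose $b$ is $1 - s(b)$, exposed as `hill_true_sparing()` so
estimator error is measurable. Hormesis is modelled as an additive bump
$A$ at the top drug dose only — the phenomenon as reported is a
terminal-dose rebound, and a single-knot bump keeps the ground truth
unambiguous. The sensitiser has no intrinsic toxicity in the model,
mirroring the biology it emulates.

Defaults (chosen once, as a realistic gemcitabine-like condition, and
documented rather than revisited): $e_0 = 100$, $e_{max} = 100$,
$EC_{50} = 0.3\ \mu M$, $h = 1.5$, $\rho = 0.15$, $k_b = 3\ \mu M$ (implied
sparing at 10 µM sensitiser ≈ 0.104), noise SD 3 percentage points, 4
replicates, over a 7-point half-log drug grid (0.003–3 µM) crossed with
sensitiser 0/3/10/30 µM. What the generator does *not* emulate: edge
effects, plate drift, heteroscedastic or correlated replicate noise,
intrinsic sensitiser toxicity, and mixed mechanisms (efficacy plus potency
shifts). Passing recovery tests on this generator therefore demonstrates
estimator correctness under clean assumptions, not robustness to real
plate artefacts.

A precision note: with 4 replicates at 3 % noise on a half-log grid, the
log-linear interpolation estimator has an irreducible statistical error
floor — across 200 simulated plates the median absolute sparing error is
about 0.026 even when averaging over the full target grid, and roughly
16 replicates would be needed to reach ~0.014. Single-target estimates
also carry a small deterministic chord bias (the estimator linearises the
Hill curve between grid points), which the multi-target profile largely
cancels.

`generate_fragment_library()` assembles fragments from scaffold ×
substituent templates; every member of the compliant pool passes the
default Rule-of-3 thresholds and every member of the non-compliant pool
fails at least one, so the requested compliant fraction is exact in
expectation. All generators run under a local RNG seed and restore the
caller's RNG state; fixed seeds give bitwise-identical output.

# Numerical and design choices

* Tc rounding is half-up at 2 decimals (`round_tc`); full precision is
  retained in JSON reports, 2 dp in CSV.
* Two empty fingerprints compare as 0 with a warning, avoiding 0/0.
* Ranking ties are broken by fragment id, making library order irrelevant.
* The dual-panel selection ranks by the *minimum* of the two best-Tc
  values — a candidate must resemble both panels, so the weaker
  resemblance is the binding one.
* Ro3 filtering precedes ranking by default (fragment decks are
  pre-filtered); disable with `apply_ro3 = FALSE`.
* Salts and charges are kept as written; no largest-fragment stripping is
  applied.
* Problem sizes in the test suite (a 16–20 molecule MCS oracle set, 200
  simulated plates for recovery, 1000 for the null calibration, a
  1000-fragment library) were chosen so the full suite runs in well under
  a minute on one core while keeping Monte-Carlo error small relative to
  the tolerances tested.

# Known limitations

* Printed similarity panels from other toolkits are generally not
  bit-for-bit reproducible (see the calibration note above); treat
  absolute Tc values across toolkits as incommensurable.
* The SMILES reader covers the organic subset plus bracket atoms; it does
  not kekulise or re-perceive aromaticity, so Kekulé-written aromatic
  rings are handled as written (fingerprints and descriptors, which go
  through OpenBabel's perception, are unaffected).
* Exact MCS is exponential in the worst case; the vertex and node guards
  make failure explicit rather than silent. Molecules beyond ~25 heavy
  atoms with high symmetry may need the relaxed limits or pre-filtering.
* Dose-sparing assumes the two columns share a monotone window around the
  target; strong hormesis inside that window is surfaced as an error, by
  design, rather than interpolated through.
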