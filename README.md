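# fragsens

Fragment-based drug **sens**itiser screening and co-administration
dose–response analysis.

Pancreatic cancers resist gemcitabine; one counter-strategy pairs the drug
with a small, non-toxic chemical fragment (a "binary drug" sensitiser) that
restores the tumour's sensitivity. Such fragments are shortlisted *in
silico* — a Rule-of-3 fragment library is ranked by Tanimoto fingerprint
similarity against a panel of pathway inhibitors (for mechanism) and a
panel of natural metabolites (for cellular uptake) — and then validated on
viability plates where the fragment is co-administered with the drug over a
dose grid. `fragsens` implements that whole computation as a tested R
package:

* **Chemistry** — a SMILES reader producing heavy-atom graphs with
  aromaticity and formal charges as written; physico-chemical descriptors
  and the Rule-of-3 fragment filter (MW ≤ 300, cLogP ≤ 3, HBD ≤ 3,
  HBA ≤ 3, RotB ≤ 3, TPSA ≤ 60 Å², boundaries inclusive); three standard
  fingerprint schemes (166 structural keys, path-based, circular radius-2);
  the Tanimoto coefficient `Tc = c / (a + b − c)` with half-up 2-decimal
  reporting.
* **Exact MCS** — maximum common (induced, by default connected)
  substructure via the modular product graph and an exact branch-and-bound
  clique search (Rcpp), with SMARTS output of the shared substructure.
* **Screening** — library ranking against reference panels, dual-panel
  candidate selection, fingerprint-scheme calibration against printed
  similarity tables, CSV/JSON reports.
* **Combination analysis** — plate normalisation to untreated control
  (= 100 %), sensitiser enhancement in percentage points, dose-sparing by
  log-dose interpolation (`1 − D_combo/D_alone` at equal effect), hormesis
  (biphasic response) detection, one-way ANOVA with Tukey correction.
* **Synthetic data** — Hill-model plate simulation with a potency-shift
  sensitiser and known ground truth, plus template-based fragment-library
  generation with a controlled Rule-of-3 pass fraction.

## Worked example

Rank the sensitiser fragment BD B10 against the packaged Akt-inhibitor
panel, inspect the shared substructure with the top reference, and check
its fragment-likeness:

```r
library(fragsens)
fx <- fixture_structures(as_molecules = TRUE)
panel <- reference_panel("akt_inhibitors",
  fx[c("trigonelline", "sc66", "honokiol", "loureirin_a", "isc4")])
hits <- rank_library(list(fx$bd_b10), panel, apply_ro3 = FALSE)
hits[[1]]$per_reference_tc
#> trigonelline         sc66     honokiol  loureirin_a         isc4
#>         0.30         0.26         0.12         0.13         0.24
hits[[1]]$mcs_vs_best
#> <MCS> 6 atoms, 6 bonds (connected)
#>   pattern: c:1:c:c:c:n:c:1
compute_descriptors(fx$bd_b10)
#> <descriptors> MW 204.29 g/mol | cLogP 2.92 | HBD 1 | HBA 2 | RotB 3 | TPSA 53.2 A^2
ro3_filter(compute_descriptors(fx$bd_b10))$pass
#> [1] TRUE
```

Trigonelline tops the panel (Tc 0.30 under the default structural keys)
and the MCS is the shared pyridine ring — the structural basis of the
similarity call. BD B10 itself is Rule-of-3 compliant.

On the plate side, simulate a co-administration experiment with a known
potency shift and recover it:

```r
m <- generate_dose_response(p = hill_params(seed = 42))   # 3 % noise, 4 reps
v <- normalize_viability(m)
enhancement_delta(v, dose_a = 0.1, dose_b = 10)   # percentage points
#> [1] 3.96
dose_sparing_profile(v, sensitiser_dose = 10)$sparing
#> [1] 0.088
hill_true_sparing(hill_params(), 10)              # ground truth
#> [1] 0.103
```

A command-line wrapper (`inst/scripts/fragsens-cli`) exposes the same
functionality as `screen`, `calibrate`, `mcs`, `ro3`, `combo` and
`simulate` subcommands.

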