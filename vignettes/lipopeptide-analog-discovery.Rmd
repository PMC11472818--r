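---
title: "Dereplicating acylated siderophore analogs from tandem MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating acylated siderophore analogs from tandem MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delftiMS)
```

## The problem

Under iron starvation, many bacteria secrete metallophores — small chelators
that scavenge Fe(III). *Delftia* species produce delftibactin, an NRPS/PKS
peptide whose hydroxamate groups bind ferric iron. Acylated (lipopeptide)
analogs of such scaffolds are a recurring theme in natural-product discovery:
the peptide core stays constant while a fatty-acyl tail of varying length and
unsaturation is attached to a terminal amine. delftiMS implements the
computational chain that discovers and characterises such analog series from
LC-MS/MS data: exact mass arithmetic, mass-difference tail inference,
fragment-ladder annotation, molecular networking, condition-differential
feature analysis, and metal-adduct screening.

## Mass arithmetic

All masses are monoisotopic, computed from a single CODATA/AME-style atomic
mass table (`massConstants()`, values at 7–10 decimal places). Cation m/z
subtracts the electron mass:

$$ m/z \;=\; \frac{M + m_\mathrm{added} - n_\mathrm{H}\, m_\mathrm{H} - z\, m_e}{z} $$

The electron correction matters at the fourth decimal place for singly
charged ions around 1200 Da and is required to match high-resolution
"calculated" values:

```{r}
ionMz(parseFormula("C54H92N14O19"), "[M+H]+")
ionMz(parseFormula("C54H92N14O19"), "[M-2H+Fe]+")
```

Adducts are data, not code: `adductRegistry()` reads a plain-text table
shipping \[M+H\]+, \[M+Na\]+, \[M+2H\]2+, the ferric complex \[M−2H+Fe\]+,
and copper/gold screening hypotheses. The Fe-for-2H substitution shifts any
neutral formula by a constant +52.9115 Da relative to its \[M+H\]+, which is
the diagnostic spacing the metal screen exploits.

`rdbe()` implements the standard ring/double-bond equivalent
(C − H/2 + (N+P)/2 + 1). Some literature unsaturation counts for
hydroxamate-bearing cations run one unit higher than this convention; the
package deliberately keeps the standard formula.

## The scaffold and tail inference

The built-in scaffold (`buildDelftibactinScaffold()`) is a fixed data object:
nine residue compositions, N to C — Ahmpa, β-OH-Asp, Thr, Gly, Dhb, fOH-Orn,
Ser, Arg, cyclic N-OH-Orn — whose elementwise sum must equal the neutral
parent formula C40H68N14O18. Because the C-terminus is a macrolactam, the
residue sum *is* the neutral formula: there is no terminal water. This
closure is validated at construction, so a typo in any residue composition
is a hard error.

Two reference \[M+H\]+ values coexist by design. The literature constant
(1033.4914) is the default so that residual masses reproduce published
difference arithmetic exactly; it was evidently computed without electron
correction, so it sits ~0.0005 Da above the package's own value (1033.4909).
`buildDelftibactinScaffold(useComputedReference = TRUE)` switches to the
self-computed reference for internally consistent pipelines (the round-trip
property tests use it).

`inferTail()` subtracts the reference from an observed precursor and scans a
Cn:d grid (default n ∈ [8, 20], d ∈ [0, 3] — odd chains are allowed on
purpose: restricting to even chains would bake the expected conclusion into
the method). Tolerance is expressed in ppm of the *precursor* (default
10 ppm), because that is the scale on which the instrument error lives.
Ties prefer fewer double bonds, then fewer carbons: the simpler hypothesis.

```{r}
inferTail(1241.6730, buildDelftibactinScaffold())[1, ]
```

## Fragment ladders and annotation

`fragmentLadder()` generates singly charged b/y ions for the 8 backbone
amide cleavages, under the macrolactam convention (neutral mass = residue
sum, no terminal water): b_i is the proton-bearing N-terminal prefix
(carrying the acyl tail whenever the prefix covers the acylation site), and
y_j = M + 2·proton − b_(9−j). Complementarity b_i + y_(9−i) = \[M+H\]+ +
proton holds identically, and the ladder is tested against an independent
brute-force oracle that sums residue-formula prefixes directly. Because the
tail sits on the N-terminal residue, every b ion of an acylated analog
shifts by exactly the acyl mass while the y series is invariant — the formal
reason analog spectra share their y ions with the unacylated parent.

Only b/y singly charged ions are generated, with no neutral losses: this
matches the fragment set the analog series is identified by, and keeps the
false-annotation surface small. `annotateAnalog()` chains tail inference →
ladder generation → greedy one-to-one peak matching, reporting backbone
coverage (fraction of the 8 cleavages with any matched ion; annotation
threshold 0.5) and the count of tail-bearing matches. One published backbone
ion (374.2152) sits 1.5 ppm above the computed y3 (374.2146) while the other
five shared ions agree to ≤ 0.1 mDa; the 10 ppm default tolerance absorbs
it, and the tests assert the computed value, not the printed one.

## Molecular networking

`modifiedCosine()` is the networking similarity: square-root intensity
weighting, peak pairs either direct (|Δm/z| ≤ 0.02 Da by default) or offset
by the precursor mass difference, one use per peak. The default pairing is
greedy by descending pair score — a documented approximation of the optimal
assignment; `method = "exact"` solves small instances exhaustively and the
tests assert it never scores below greedy. Tie-breaks use symmetric keys
(sum, then absolute difference, of the paired m/z) so the score is exactly
symmetric in its arguments.

`buildNetwork()` applies the study parameters as defaults: cosine ≥ 0.55,
≥ 6 matched peaks per edge, families = connected components with ≥ 2 nodes.
The minimum-cluster-size parameter is interpreted as a component-size floor
because the package assumes one MS/MS spectrum per feature and performs no
spectral pre-clustering. No top-K edge pruning is applied. The fragment
tolerance is configurable because published parameter sets often leave it
unstated; 0.02 Da is the conventional choice.

## Differential features and the metal screen

`labelConditions()` implements presence/absence logic, not fold change: a
feature is present in a condition if any replicate shows intensity above the
threshold (default 0, i.e. any nonzero signal). `differentialFeatures()`
returns the low-iron-exclusive subset ranked by maximum intensity — the
candidate siderophore list.

`screenMetalReaction()` compares before/after feature lists around a metal
incubation. The verdict is total: apo ion retained → `no-reaction`; apo lost
and a holo hypothesis newly present → `stable-complex`; apo lost otherwise →
`degradation/unassigned`, with the new unassignable ions reported. Copper
and gold adduct entries in the registry are screening hypotheses only — the
screen is designed to reproduce a *negative* result as "unassigned" rather
than force an assignment. An optional isotope check requires the
minor-isotope partner peak (Fe: −1.9953 Da; Cu: +1.9982 Da); it is off by
default because the synthetic data carry monoisotopic peaks only.

## The synthetic-data generator

`simulateExperiment()` emulates the targeted study design, and its defaults
are the experiment's conditions, not tuning knobs: four planted analogs
(C14:1, C14:0, C12:1, C12:0) present only in iron-depleted runs, duplicate
cultures per condition, Gaussian m/z jitter of 2 ppm (multiplicative, the
way instrument error behaves), log-normal intensities with the planted
fragment median ~50× the decoy median, 20 decoy spectra per sample, 30 decoy
peaks per spectrum, 5% fragment dropout, and retention times drawn from a
0–23 min window as plumbing metadata. Decoy spectra are rejection-sampled so
that no decoy shares ≥ 3 peak spacings with the scaffold ladder, and decoy
*features* are rejection-sampled so that none is exclusively present in
low-iron samples: real chromatographic noise is rarely condition-exclusive,
and without this constraint the ground truth of the differential test would
be ill-defined. Everything is driven by one integer seed; identical
config + seed reproduces identical outputs.

What the generator does **not** emulate: chromatographic peak shapes,
isotope envelopes, co-eluting chimeric spectra, intensity drift between
runs, and real biological variation in analog abundance. Green tests on
synthetic data therefore demonstrate the correctness of the arithmetic and
the logic of the discovery chain — not instrument-grade robustness on raw
profile data, which would need peak picking and alignment that are out of
scope here.

## Numerical choices and problem sizes

* Display rounding is half-up to 4 decimal places for m/z and 1 for ppm;
  all comparisons in tests use absolute tolerances (±0.0005 Da for exact
  masses), never string equality.
* The differential-recovery property is checked across 20 seeds of the
  default design (30 features × 4 samples each); fragment recall is
  measured over ≥ 1000 simulated fragments; tail round-trips run the full
  Cn:d grid. These sizes make the whole suite run in well under a minute
  while keeping the binomial properties (≥ 95% recovery, ≥ 99% recall)
  meaningfully testable.
* `inferTail()` returns an empty table (not an error) for precursors at or
  below the reference mass; `modifiedCosine()` refuses empty spectra; a
  condition with zero samples is a domain error in the labeller.

## Known limitations

Charge states above 2 and multiply charged fragments are unsupported;
spectra arrive as MGF only (no mzML); stereochemistry is invisible to mass
arithmetic; the copper adduct identities are placeholders pending a
confirmed assignment; and the scaffold model treats residue compositions as
fixed data — it infers tails, not sequences.
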