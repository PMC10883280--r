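---
title: "Scoring and validating predicted domain–motif interfaces with fragscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating predicted domain-motif interfaces with fragscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragscore)
```

## The problem

Many protein–protein interactions are mediated not by two folded domains
(domain–domain interfaces, DDIs) but by a short linear motif (SLiM) in an
intrinsically disordered region binding a folded domain of the partner
(domain–motif interfaces, DMIs). Complex structure predictors can propose
atomic models for such interfaces, but they behave very differently
depending on the length of the submitted sequences: minimal interacting
fragments are modelled far more reliably than full-length proteins, whose
long disordered regions and extra domains dilute and mislead the
prediction. `fragscore` implements the computational workflow around such a
predictor: it designs fragment libraries from disordered-region
annotations, scores the predictor's output models with interface-confidence
metrics, evaluates them against solved reference structures, builds
positive and random benchmark sets to calibrate confidence cutoffs, and
analyses the BRET (bioluminescence resonance energy transfer) titration
experiments used to validate predicted interfaces in cells. The predictor
itself is an external black box; `fragscore` consumes its PDB models (with
per-residue pLDDT stored in the B-factor field) and score files.

## Fragment design

Disordered regions are fragmented into sliding windows of 10, 20 and 30
residues. For each size `s`, a primary series tiles the region from its
start with step `s`, and a second series shifted by `s/2` restores the
sequence continuity that the cuts break, so every residue is seen in at
least two windows (coverage and exact half-window overlap are tested
properties). A window that would run past the region is replaced by a
single terminal window anchored at the region end; this choice (one of
several admissible conventions) guarantees full coverage without emitting
sub-size fragments. The unfragmented region itself is always kept as a
candidate. Fragments and whole disordered regions of one protein are paired
with the ordered regions of the partner and vice versa, and the ordered
regions of both proteins are paired with each other.

Region boundaries are deliberately manual input: automated
boundary detection (e.g. clustering the predicted aligned error matrix)
tends to shave residues off domain edges, which badly misleads fragment
predictions. `suggest_regions()` therefore only proposes spans from a
smoothed pLDDT profile (running mean, default window 5 residues, cutoff 70)
for human review, and manual annotations always override suggestions.
Coiled-coil regions are annotated as ordered; a low-pLDDT loop inside a
domain may be annotated disordered *in addition* to its membership in the
ordered span, since it may carry a motif of its own.

## Extension schedules

To study how prediction quality degrades with sequence length, minimal
motifs are extended stepwise: levels 1–4 pad the motif of length `n` by
`n`, `2n`, `4n` and `6n` residues on each side (cumulative schedule), level
5 extends the minimal motif to include its neighbouring domains, and level
6 is the full-length protein. Domains extend in three steps: through the
flanking disorder up to the neighbouring domain boundaries, including the
neighbouring domains, and full length. Spans are clipped to the protein;
terminal motifs/domains extend on one side only. A step that adds fewer
than 20 residues on both sides of the previous step is excluded
(`minimal_extension_filter()`), since it provides no meaningful new
condition.

One subtlety: levels 1–4 are nested by construction and level 6 contains
everything, but level 5 is defined from the *minimal* span and its
neighbouring domains, so it need not contain level 4 (a neighbouring
domain may sit closer than `6n` residues). We kept the definition rather
than forcing artificial nesting; the monotonicity tests assert
containment along 1→2→3→4 and 5→6 only.

## Interface metrics

All metrics operate on heavy atoms (hydrogens are dropped at parse time)
and use strict inequalities at their distance cutoffs, matching the
"less than 5 Å" interface definition:

* **Interface residues** — any heavy atom strictly within 5 Å of the
  partner chain; per-chain and pooled ("average") interface pLDDT are plain
  arithmetic means over those residues.
* **Model confidence** — `0.8·ipTM + 0.2·pTM`, recomputed from the score
  bundle when not stored.
* **pDockQ** — sigmoid of (mean pLDDT of Cβ-contacting residues) × ln(Cβ
  contact pairs), Cβ (Cα for glycine) within 8 Å; the sigmoid constants
  (L = 0.724, k = 0.052, x₀ = 152.611, b = 0.018) are frozen from the
  reference implementation and exposed as `PDOCKQ_CONSTANTS`. Zero contacts
  define x = 0, i.e. the baseline score ≈ 0.018.
* **iPAE** — median predicted aligned error over residue pairs whose
  minimal heavy-atom distance is below 3.5 Å, pooling both matrix
  directions. Whether the original description intends Cα or heavy-atom
  distances is ambiguous; we use heavy atoms (the more inclusive reading)
  and document it here.

A model is called **confident** when the disordered-fragment chain's
interface pLDDT is ≥ 70 (DMI case) or the average interface pLDDT is ≥ 70
for ordered–ordered pairs (75 is the ROC-derived alternative for DDI
screens); an optional stricter mode additionally requires model confidence
≥ 0.7 for ordered–ordered pairs. All thresholds are inclusive.

## Evaluation against reference structures

Models are superposed on the native structure using all shared heavy atoms
of the mapped *domain* residues (Kabsch least squares; identifier-based
atom pairing, no outlier rejection, no refinement cycles), and the
all-atom RMSD of the mapped *motif* residues is measured in that frame.
Accuracy categories use inclusive upper bounds: ≤ 2 Å correct side chain,
≤ 5 Å correct backbone, ≤ 15 Å correct pocket, > 15 Å wrong pocket; a
model is *accurate* at ≤ 5 Å. Residue numbering is taken as-is; when model
and native constructs differ, the user supplies per-chain residue offsets
in the chain mapping — no automatic sequence mapping is attempted.

DockQ is computed from its published components — fnat (5 Å heavy-atom
contacts), interface RMSD over the 10 Å interface backbone, and ligand
RMSD after receptor superposition, with the 1.5 Å/8.5 Å scaling
constants — and classified with inclusive-at-0.80 boundaries
(< 0.23 incorrect, 0.23–0.49 acceptable, 0.49–0.80 medium, ≥ 0.80 high).
Ensemble agreement of the top five ranked models is the mean DockQ over
all pairs, the higher-ranked model serving as reference.

## Benchmark construction and statistics

Random reference sets are built two ways. *Shuffling*: domain assignments
are permuted so that no motif is paired with a domain type its class (or
any class sharing a domain type) is known to bind; the permutation is
seeded and found by rejection sampling. *Mutagenesis*: the defined (key)
positions of a motif are those whose regex element is not a wildcard —
operationally, a position is defined iff some amino-acid substitution
there breaks the anchored regex match, which handles character classes,
alternations and quantified wildcards uniformly through the regex engine
itself. One or two key residues are substituted by the amino acid at
maximal Miyata distance (1979 physico-chemical distance over polarity and
side-chain volume, reconstructed from the published formula with
differences normalized by the standard deviation of all pairwise
differences; ties broken alphabetically; first-k-left-to-right default
policy with explicit positions as override).

ROC/PR analysis sweeps every observed score as a threshold (orientation
aware: iPAE is lower-is-better), computes AUROC by the trapezoid rule
(equal to the Mann–Whitney concordant-pair statistic, which the tests
verify by brute force) and AUPRC by step-wise interpolation. The "optimal"
cutoff maximizes Youden's J = TPR − FPR, with ties resolved towards the
stringent side; the underlying derivation rule of published "ideal
cutoffs" is not documented, and Youden's J is our explicit choice.
The fragmentation summary aggregates per-model confidence calls per
protein pair: sensitivity is the fraction of positive pairs with a model
that is both confident and accurate, the false positive rate the fraction
of random pairs with at least one confident model.

Pairwise domain sequence identity uses a global alignment with match 1,
mismatch 0 and zero gap penalties (equivalently, the longest common
subsequence), divided by the longer sequence length.

## BRET analysis

The raw BRET ratio is long-wavelength over short-wavelength luminescence
(GREEN1/BLUE1 filters in the source protocol; the assignment is
configurable since instruments differ). The corrected BRET subtracts the
maximal ratio of the two single-tag control pairs. An interaction is
*detected* when, at the configured transfection ratio (default 2:50 ng
donor:acceptor, with per-pair overrides), cBRET ≥ 0.05, fluorescence ≥ 500
units and total luminescence ≥ 50 000 units — expression thresholds that
guard against calling absence of signal for unexpressed constructs.

Donor-saturation titrations are fitted with the 1:1 binding model
`BRET = (A/D)·BRETmax / (BRET50 + A/D)` by Levenberg–Marquardt least
squares. Standard errors are
`sqrt(diag((JᵀJ)⁻¹ · s²))` with `J` the analytic Jacobian and `s²` the
residual variance — i.e. the fractional covariance matrix scaled by the
residual variance. BRET50, the acceptor/donor ratio at half-maximal BRET,
proxies binding affinity; its accurate estimation requires observed
saturation, so non-saturating designs converge with an honest, wide
standard error rather than a hidden failure. Trajectories that
systematically deviate from the 1:1 model (e.g. BRET rising again at high
A/D) keep their fit but are flagged `reliable = FALSE` by a runs test on
the residual signs. Technical replicates are pooled into one fit;
biological replicates are fitted separately.

## Synthetic fixtures

`make_complex_pair()` builds a rigid two-chain complex: a poly-alanine-like
domain trace with backbone atoms and one pocket-facing Cβ per residue, and
a shorter motif chain docked against it, with the model copy's motif
displaced by a prescribed vector. This closes the loop through the full
stack — file IO, interface detection, superposition — reproducing the
displacement norm as the motif RMSD to 10⁻⁶ Å in memory (and to PDB
coordinate precision, 10⁻³ Å, through files). Prescribed pLDDT profiles
and a constant PAE matrix exercise the metric paths; Gaussian score sets
and noisy titrations (defaults: pLDDT 90/80 for domain/motif, benchmark
means 75 vs 55 with sd 10 emulating an interface-pLDDT-like metric, A/D
grid 0.25–16 spanning about two orders of magnitude, noise sd 0.02)
emulate the study conditions at desk scale. What the fixtures do *not*
emulate: real side-chain packing, flexible conformational error,
predictor-correlated pLDDT/PAE noise, or multi-domain architecture — so
passing tests demonstrate correctness of the computations, not predictor
performance on real proteins.

Test problem sizes were chosen to keep the whole suite in the
tens-of-seconds range on one CPU: interface oracles on ≤ 200-atom models,
superposition oracles on ≤ 50 atoms, 100 seeded titration replicates,
20–40-residue synthetic chains.

## Known limitations

* mmCIF is read for native references only; no mmCIF writing.
* Nucleic-acid chains are skipped with a warning; only the 20 standard
  amino acids are handled in sequence-space operations.
* No automated model/native residue mapping (the chain-mapping file is
  user input), no coiled-coil detection, no secondary-structure
  assignment of motifs, and no submission of prediction jobs.
* Motif probabilities are carried through from the motif resource as an
  input field, never computed.
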