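# fragscore

Fragment-based scoring and evaluation of predicted protein interface
models.

Short linear motifs (SLiMs) in intrinsically disordered regions mediate a
large share of the human protein interactome through domain–motif
interfaces (DMIs), yet complex structure predictors model them well only
when fed short interacting fragments rather than full-length sequences.
`fragscore` is a toolkit for the computational workflow around such a
predictor — for structural bioinformaticians running fragment-based
interface screens and for wet-lab groups validating the resulting
predictions:

* **Fragment design** — sliding-window fragmentation of disordered regions
  (sizes 10/20/30, half-window offset series, anchored terminal windows),
  fragment–region pairing for prediction jobs, and motif/domain extension
  schedules with the <20-residue exclusion rule.
* **Interface confidence metrics** — interface residues at the strict 5 Å
  heavy-atom rule; motif-chain / domain-chain / average interface pLDDT;
  model confidence = 0.8·ipTM + 0.2·pTM; pDockQ
  (σ-transform of mean interface pLDDT × ln Cβ-contacts at 8 Å); iPAE
  (median PAE over 3.5 Å contacts); confidence calls at the inclusive
  pLDDT ≥ 70 cutoffs.
* **Evaluation against solved structures** — Kabsch superposition on the
  domain chain, all-atom motif RMSD with accuracy categories
  (≤2 / ≤5 / ≤15 / >15 Å), DockQ with its published components and
  classes, ensemble similarity of top-ranked models.
* **Benchmark construction and statistics** — key-position detection from
  motif class regexes, maximal-Miyata-distance mutagenesis,
  cognate-avoiding shuffled pairings, gap-penalty-free sequence identity,
  ROC/PR curves with Youden-J optimal cutoffs, and the fragmentation
  sensitivity / false-positive-rate summary.
* **BRET analysis** — corrected BRET, expression-aware interaction
  detection calls, and 1:1 hyperbolic saturation fits returning BRETmax
  and BRET50 with standard errors.
* **Synthetic fixtures** — seeded generators for two-chain complexes with
  controlled motif displacement, benchmark score sets and noisy
  titrations, so the whole stack is testable offline.

## Worked example

```r
library(fragscore)

# A synthetic native/model pair: the model's motif chain is displaced by
# (1.2, 1.6, 0), a vector of norm 2 A.
spec  <- synthetic_complex_spec(displacement = c(1.2, 1.6, 0), motif_plddt = 78)
paths <- make_complex_pair(spec, dir = "demo")

model  <- read_model(paths$model, predicted = TRUE)   # pLDDT from B-factors
scores <- read_scores(paths$scores)                   # ipTM/pTM/PAE bundle
report <- score_interface(model, scores)
report
#> interface A:B (< 5 A): 11 | 8 interface residues, 32 residue and 424 atom contacts
report$chain_plddt
#>  A  B
#> 90 78
classify_confident(report, model, "disordered-ordered", disordered_chain = "B")
#> [1] TRUE
```

The motif-chain interface pLDDT (78) clears the ≥ 70 confidence cutoff, so
this model would be kept for inspection in a fragment screen. Against the
native reference, the 2 Å rigid displacement is recovered exactly and
falls on the correct-sidechain category boundary:

```r
native <- read_model(paths$native)
map <- chain_mapping(c("A", "B"), c("A", "B"), c("domain", "motif"))
motif_all_atom_rmsd(model, native, map)
#> motif RMSD 2.000 A over 40 atoms: correct_sidechain (accurate)
compute_dockq(model, native, map)
#> DockQ 0.887 (high): fnat 1.000, iRMS 0.95 A, LRMS 2.00 A
```

Benchmark statistics and a BRET titration fit:

```r
bench <- make_benchmark_scores(n_pos = 50, n_neg = 50, seed = 42)
r <- roc_auc(bench$value, bench$label, metric_name = "motif interface pLDDT")
r
#> roc_analysis [motif interface pLDDT]: AUROC 0.897, AUPRC 0.925 (50 positive, 50 random, higher_is_better)
optimal_cutoff(r)$threshold
#> [1] 66.49092

fit <- fit_titration(make_titration(bretmax = 0.42, bret50 = 1.8,
                                    noise_sd = 0.02, seed = 7))
fit
#> bret_fit (7 points): BRETmax 0.4252 (SE 0.0317), BRET50 2.0691 (SE 0.4803)
```

The fitted BRETmax/BRET50 recover the simulated truth (0.42 / 1.8) within
the reported standard errors; BRET50 — the acceptor/donor ratio at
half-maximal BRET — proxies binding affinity.

A thin command-line dispatcher over the same functions is installed as
`exec/fragscore` (subcommands `fragment`, `score`, `evaluate`,
`motif-props`, `benchmark`, `bret`, `simulate`).

See `vignettes/fragscore-methods.Rmd` for the full account of the methods,
parameter choices and limitations.

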