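---
title: "Methods: paired alignments, interface confidence and docking quality in ppikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired alignments, interface confidence and docking quality in ppikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppikit)
```

## Scope

`ppikit` implements the scaffolding that surrounds deep-learning
structure predictors when they are applied to heterodimeric
protein–protein complexes: preparation of the multiple sequence
alignments (MSAs) the predictor consumes, extraction of interface
metrics from the two-chain models it produces, the pDockQ confidence
score built from those metrics, a self-contained DockQ implementation
for scoring models against natives, and the evaluation calculus
(ROC/AUC, PPV/FDR, success rate, coupling-signal precision, stratified
breakdowns) used to benchmark all of it. The neural predictor itself,
the sequence-database searches that feed it, and coupling inference
(DCA) are out of scope: the package consumes their outputs (a3m
alignments, PDB models with plDDT in the B-factor column, DSSP
annotation strings, coupling matrices).

## Alignment preparation

Two per-chain alignments in a3m format are normalized at parse time:
lowercase letters and `.`, which mark insertions relative to the query
columns, are deleted, so every row has the query's width. This is the
standard a3m-to-matrix convention; column-level information in
insertions is discarded deliberately, since both downstream
constructions operate on query columns only.

Rows with more than 90% gaps are removed before pairing
(`max_gap_fraction = 0.9`, strict inequality, so a row with exactly 90%
gaps survives). The query row is exempt: it defines the coordinate
system, and pairing and fusion need it as an anchor even in degenerate
alignments.

**Organism pairing.** Interchain coevolutionary signal only exists in
rows whose two halves come from the same genome. `pair_by_organism()`
therefore concatenates, for every organism (taxonomy `OX=` token)
present among the hits of both chains, the highest-ranked hit of one
chain with the highest-ranked hit of the other. Rank is the row index
in the source file, since alignment tools emit hits in E-value order.
One pair per organism is produced — rank-k-with-rank-k pairing for
deeper organisms is a known variant and deliberately not implemented.
Hits without an `OX=` token cannot be placed and are ignored. The query
pair is included as row 0 of the output.

**Block diagonalization.** The complementary, pairing-free
construction stacks the two alignments over the concatenated query:
chain-A rows are elongated with gaps on the right, chain-B rows on the
left. It conserves every residue of both inputs and asserts no
inter-chain correspondence. `fuse_msas()` concatenates the paired and
block alignments over their shared query, which is the configuration
that works best as predictor input.

**Neff.** Alignment depth is summarized as the number of clusters at
62% sequence identity. Clustering is greedy and single-pass: rows are
visited by decreasing ungapped length (stable on ties); a row joins the
first cluster whose *representative* it matches at ≥ 62% identity with
≥ 90% coverage of the shorter sequence, else it founds a new cluster.
Identity and coverage are computed on the aligned rows as given
(identical residues in shared non-gap columns, and shared non-gap
columns, each divided by the shorter ungapped length) rather than by
re-aligning ungapped sequences as CD-HIT does. This makes the statistic
deterministic and dependency-free; the word-size pre-filter of CD-HIT
is an accelerator, not a different definition, and is not reproduced.
Consequently Neff values can differ slightly from CD-HIT output on real
alignments with long insertions. Greedy cluster counts are
order-dependent in general; with the fixed visiting order above the
result is reproducible.

## Interface metrics

The interface of a two-chain model is defined by Cβ–Cβ distance: every
residue pair with Cβ atoms from different chains within 8 Å is a
contact. From the contact set the package derives `IF_contacts` (number
of contacts, counting each unordered pair once), `IF_residues` (number
of residues participating in ≥ 1 contact, summed over both chains),
`IF_plDDT` (mean plDDT over those residues), the minimum over chains of
the chain-mean plDDT, and the overall mean plDDT.

Residues without a CB atom (glycine, incomplete side chains) receive a
virtual Cβ constructed from N/CA/C with ideal tetrahedral geometry
(falling back to CA when the backbone is incomplete) and are flagged.
`strict = TRUE` instead drops such residues, for fidelity with
benchmark protocols that excluded Cβ-less inputs. Alternate locations
keep the highest-occupancy copy; only the first MODEL of a multi-model
file is read; residue numbering gaps between chains (chain-break
offsets of ~200 are common in predictor output) are tolerated because
residues are keyed per chain.

## pDockQ

The confidence score is a four-parameter sigmoid of the combined
interface metric

$$x = \mathrm{IF\_plDDT} \cdot \log_{10}(\mathrm{IF\_contacts}),
\qquad
\mathrm{pDockQ} = \frac{L}{1 + e^{-k (x - x_0)}} + b,$$

with default parameters $L = 0.724$, $x_0 = 152.611$, $k = 0.052$,
$b = 0.018$. The log base is not fixed by the defining text; base 10 is
the default here because the fitted midpoint $x_0 \approx 153$ is what
plDDT in $[0,100]$ times $\log_{10}$ of typical contact counts
(tens to hundreds) produces, whereas natural log would push typical
$x$ well past 300. The base is a parameter (`log_base`) and is recorded
in fitted parameter sets.

A model with zero interface contacts scores 0 rather than the sigmoid
floor $b$: "no predicted interface" is the signal used to call
non-interactors, and conflating it with a weak interface would blunt
that use.

**Refitting.** `fit_pdockq()` re-estimates the parameters from
observed $(x, \mathrm{DockQ})$ pairs by Levenberg–Marquardt nonlinear
least squares (`minpack.lm::nlsLM`, the same algorithm family as the
SciPy `curve_fit` used for the original fit). Initialization is
data-driven — $L = \max(\mathrm{DockQ})$, $x_0 = \mathrm{median}(x)$,
$k = 0.05$, $b = \min(\mathrm{DockQ})$ — with box constraints
$L \in (0, 1.5]$, $k \in (0, 1]$, $b \in [0, 0.5]$ and parameter-step
tolerance $10^{-9}$. On noiseless sigmoid data the generator parameters
are recovered to $10^{-6}$; degenerate inputs (fewer than 8 points,
constant $x$, constant DockQ) are refused.

## DockQ

Model quality against a native is the standard continuous combination
of three CAPRI measures,

$$\mathrm{DockQ} = \tfrac{1}{3}\left( F_\mathrm{nat}
 + \frac{1}{1 + (\mathrm{iRMS}/1.5)^2}
 + \frac{1}{1 + (\mathrm{LRMS}/8.5)^2} \right),$$

with a model called *acceptable* at DockQ ≥ 0.23. Internals:

* $F_\mathrm{nat}$: fraction of native inter-chain residue contacts
  (any atom pair within 5 Å) preserved in the model.
* iRMS: backbone RMSD over the native interface residues (interface
  defined at 10 Å) after least-squares superposition on those residues.
* LRMS: ligand backbone RMSD after superposition on the receptor
  backbone; the receptor is the longer native chain (ties go to chain
  A).

The atom set is backbone N, CA, C plus Cβ — the atoms this pipeline
carries, and the atoms predictors reliably emit — not all heavy atoms.
This is a documented deviation from the reference DockQ binary; on
backbone-only models the two agree by construction, elsewhere
$F_\mathrm{nat}$ can differ slightly. Superposition is the Kabsch
algorithm via SVD with the determinant correction, so reflections are
never returned; it is cross-checked in the test suite against an
independent rotation-grid + simplex oracle.

## Evaluation calculus

Confusion matrices treat "score ≥ threshold" as positive — the
boundary is inclusive to match the DockQ ≥ 0.23 convention. Rates are
TPR = TP/(TP+FN), FPR = FP/(FP+TN), PPV = TP/(TP+FP), FDR = 1 − PPV,
with zero-denominator rates returned as `NA`. ROC curves sweep all
distinct scores (plus a +∞ sentinel); AUC is trapezoidal, which equals
the Mann–Whitney concordant-pair probability with half credit for
ties. Operating points (`tpr_at_fpr`) use conservative step
interpolation: the reported TPR is one the curve actually achieves at
an FPR no larger than requested, never an interpolation between
points. Success rate is the fraction of models at or above DockQ 0.23.

Coupling-signal precision takes a chain-A × chain-B score matrix, picks
the N strongest cells with N the number of true interface contacts
(ties broken deterministically in row-major order), and reports the
fraction that are true contacts; the statistic is invariant under any
strictly monotone transform of the scores. DSSP 8-state strings
collapse to helix {H, G, I}, sheet {E, B}, loop (rest), and an
interface is classified by residue majority, ties broken toward the
more structured class (helix > sheet > loop). Tertile binning uses the
1/3 and 2/3 empirical quantiles (R's default quantile type), flagging
the degenerate all-equal case.

## Synthetic fixtures

Every input format has a seeded generator, so the full pipeline is
testable offline. The design goal is provability, not realism:

* **Toy complexes** place residues on an 8 Å lattice with contact
  partners 6 Å apart across the interface and all other inter-chain
  Cβ pairs at ≥ 10 Å, so an 8 Å scan finds *exactly* the planted
  number of one-to-one contacts. Residues are alanines with a rigid
  four-atom geometry (N, CA, C, CB); plDDT profiles are clamped
  normals, rounded to the two decimals the PDB B-factor field stores,
  so values survive the round trip exactly. Chain B is numbered with a
  200-residue offset to exercise chain-break tolerance.
* **Decoy series** rigidly translate chain B along +y; offset 0 is the
  native, and DockQ is non-increasing in offset.
* **Toy MSA pairs** mutate a random query (default 30% substitution,
  10% gaps per position) and stamp `OX=` tokens from caller-supplied
  organism lists, emitting the expected pairing count as metadata.
* **Sigmoid datasets** sample $x$ uniformly (default $[50, 250]$, the
  observed range of the combined metric), evaluate the sigmoid, add
  Gaussian noise (default sd 0.1, comparable to the published fit's
  residual error) and clip to the valid DockQ range $[0, 1]$.
  Clipping — rather than rejection resampling — is the milder and more
  common reading of "truncated"; rejection would bias the low plateau
  upward even more strongly.

What these fixtures do **not** emulate: real protein geometry, contact
clustering, correlated plDDT errors, phylogenetic structure in MSAs,
or the heteroscedastic, multimodal residual scatter of real
DockQ-vs-confidence data. Passing tests demonstrate algorithmic
correctness of the operations, not predictive performance on real
complexes.

A consequence worth stating: with noise sd 0.1 clipped at 0, points on
the low plateau (true value ≈ $b = 0.018$) have their mean shifted up
by roughly $+0.03$, and the least-squares fit absorbs that shift almost
entirely into the baseline $b$. Parameter-recovery runs (20 replicates
of n = 1481; see `scripts/acceptance.R` and the test suite) recover
$L$, $x_0$ and $k$ close to the generator but report $b \approx 0.045$
— a property of the clipped-noise generating process, not of the
fitting code, which recovers all four parameters to $10^{-6}$ when the
noise is turned off. The replicate count and problem size (20 × 1481)
are chosen to match the size of the dataset behind the published fit
while keeping the whole experiment under a minute on one CPU.

## Defaults worth knowing

| parameter | default | unit | where |
|---|---|---|---|
| interface cutoff | 8 | Å (Cβ–Cβ) | `interface_contacts` |
| gap filter | 0.9 | fraction | `filter_gapped_rows` |
| Neff identity / coverage | 0.62 / 0.9 | fraction | `compute_neff` |
| pDockQ parameters | 0.724, 152.611, 0.052, 0.018 | — | `pdockq_params` |
| log base | 10 | — | `pdockq_params` |
| Fnat cutoff | 5 | Å | `dockq_score` |
| iRMS interface | 10 | Å | `dockq_score` |
| acceptable DockQ | 0.23 | — | `dockq_score`, `success_rate` |
| interaction call | 0.5 | pDockQ | `run_config` |

The interaction-call threshold 0.5 is a placeholder operating point,
not a calibrated value: calibrate it on your own labelled data with
`roc_curve()` (e.g. maximizing TPR − FPR) before treating calls as
decisions.

## Known limitations

* Only two-chain complexes; no chain-mapping search for permuted
  homomers.
* a3m and PDB only (no Stockholm, no mmCIF).
* Fnat is computed over N/CA/C/Cβ, so exact parity with all-heavy-atom
  DockQ implementations is not guaranteed.
* Neff deviates from CD-HIT in the ways described above.
* The evaluation functions provide no confidence intervals on AUC or
  other rates.
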