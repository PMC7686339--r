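---
title: "Predicting lysine crotonylation sites from sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine crotonylation sites from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcrpred)
```

## The problem and the model

Lysine crotonylation (Kcr) marks lysine side chains in histone and
non-histone proteins. Verified sites are sparse: in a typical proteome-scale
dataset a few percent of lysines are annotated positive and every other
lysine is a presumptive negative. `kcrpred` treats site prediction as
imbalanced binary classification of peptide windows. Every lysine with at
least $n = 15$ residues of clean flank on each side yields a $2n+1 = 31$-mer
window centered on that lysine; the window is positive iff its center is an
annotated site. Lysines closer than 15 residues to a terminus, or whose
window contains a nonstandard letter (B, J, O, U, X, Z), are dropped and
counted in a report — no padding is performed, because padded columns would
leak terminus information into composition features.

The classifier itself is conventional (RBF-kernel SVM or probability random
forest); the modelling substance is in the sequence encodings, the class
balancing, and the evaluation protocol, which is why those are the
package's first-class, individually tested operations.

## Data preparation

**Coordinates.** Annotations are 1-based and inclusive; a window spans
$[p-15, p+15]$. Loading rejects — with reasons, never silently — rows whose
id is unknown, whose position is out of range, or whose position is not a
lysine.

**Redundancy reduction.** Homologous training/test sequences inflate
performance estimates. `reduce_redundancy()` applies the greedy incremental
rule at the core of CD-HIT: proteins are visited longest-first and each
joins the first retained representative with pairwise identity at or above
the threshold (default 0.30), computed as matches over alignment length of
a Needleman–Wunsch global alignment (match +2, mismatch −1, gap open 10,
gap extend 0.5 — an identity-style scoring; the exact scheme barely matters
at a 30% cut-off). CD-HIT's word-filter heuristics are not reproduced; for
pre-clustered input the step can simply be skipped (`cluster = FALSE` in the
run configuration). The identity function is injectable, which keeps the
greedy rule independently testable.

**Splitting and balancing.** The 80/20 train/test split is stratified per
class at the window level with train counts $\lfloor 0.8 \cdot
n_\text{class}\rfloor$, matching the per-site accounting used in this
protocol family. Window-level splitting lets near-identical windows from
homologous proteins land on both sides; a protein-level split
(`level = "protein"`) is available to prevent that and is recommended when
redundancy reduction is skipped. Training negatives are then randomly
undersampled to the positive count; the test set keeps its natural
imbalance. All draws are seeded, and pipeline stages derive their streams
from one master seed via `kcr_stage_seed()`.

## Encoders

All encoders use the alphabetic residue order `ACDEFGHIKLMNPQRSTVWY` for
every dimension, and all dimension names are explicit
(`"CKSAAP:k=2:AK"`, `"BE:pos-3:C"`, ...), so selected subsets remain
interpretable.

* **AAC** — residue frequencies over the window, $P_x(k) = n_x(k)/n$,
  $n = 31$. Sums to 1.
* **AAPC** — 400 ordered dipeptide frequencies. The printed denominator
  $n(n-1)$ in the source formula does not normalise adjacent-pair counts
  (there are only $n-1$ of them), so two readings are defensible. The
  default mode counts adjacent dipeptides normalised by $n-1$; a strict
  `"allpairs"` mode counts every ordered position pair $(i,j), i \ne j$
  normalised by $n(n-1)$. Both sum to 1; the mode is recorded in the output.
* **BE** — per-position one-hot, 31 × 20 = 620 dimensions, exactly 31 ones.
* **CKSAAP** — for gap $k$, frequencies of residue pairs at positions
  $(i, i+k+1)$. $k = 0$ would duplicate adjacent AAPC, so $k = 1..4$ is
  used, 4 × 400 = 1600 dimensions. No normalisation is stated in the source;
  each $k$-block is divided by its pair count $n-k-1$ (common practice, and
  it makes blocks comparable across $k$); `normalize = FALSE` yields raw
  counts.
* **EAAC / EGAAC** — AAC (or 5-group grouped AAC) inside a length-5 window
  sliding N→C. Only full 5-mers are used — 27 of them — which reproduces the
  canonical 540/135 dimensions; truncated terminal sub-windows are not
  emitted. The default grouping is the standard five physicochemical
  classes (aliphatic GAVLMI, aromatic FYW, positively charged KRH,
  negatively charged DE, uncharged STCPNQ); any user grouping that
  partitions the 20 residues into 5 groups is accepted.
* **PSSM** — the window's 31 × 20 position-specific score matrix, squashed
  elementwise by $\Phi(S) = 1/(1 + e^{-S/w})$ with $w = 31$ and flattened
  position-major to 620 dimensions. A description elsewhere of summing
  profile rows into a 20 × 20 matrix is incompatible with every printed
  dimension count (620, and 3935 for the concatenation), so the flattened
  form is canonical here and the row-summed 400-dimensional variant is
  available as `variant = "rowsum"`.
* **Incorporated** — concatenation in the fixed order AAC, AAPC, BE,
  CKSAAP, EAAC, EGAAC, PSSM: 3935 dimensions, or 3315 without a PSSM
  source.

### PSSM sources

Real deployments read per-protein PSI-BLAST ASCII profiles
(`-out_ascii_pssm`, first log-odds block, columns re-ordered to
alphabetic) and slice the 31 rows around each window center. When PSI-BLAST
output is unavailable, `build_internal_profile()` supplies a corpus-level
fallback: positional log-odds of the positive training windows against the
corpus background with pseudo-count 1,
$S(i,j) = \log_2\frac{(c_{ij}+1)/(N+20)}{b_j}$. Note its limitation
honestly: the fallback is one table per corpus, so every window receives
identical PSSM features — the block carries positional corpus signal but no
per-window discrimination, and on synthetic data it contributes nothing to
classification. Only per-protein profiles make the PSSM block
discriminative. The profile source is recorded in metadata.

## Feature ranking

* **Chi-square.** The source protocol computes a chi-square p-value per
  dimension but leaves the handling of continuous features unstated. Each
  feature is binarised at its global mean (quantile binarisation available
  via `binarize = "median"`), crossed with the class label in a 2×2 table,
  and scored by the 1-df statistic without continuity correction,
  $N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$. Constant features score 0
  with p = 1. Tests verify the closed form against the textbook
  $\sum (O-E)^2/E$ and against `chisq.test(correct = FALSE)`.
* **Gradient-boosted-tree importance.** A seeded xgboost ensemble (binary
  logistic, depth 6, η = 0.3, 100 rounds, single thread for determinism)
  ranks features by total split gain; the subset with importance above the
  all-feature average is reported alongside the full ranking.
* **MRMD.** Score = |Pearson correlation with the label| + mean pairwise
  distance to the other feature columns, on columns min-max scaled to
  [0, 1]. With raw Euclidean distance the second term grows as
  $\sqrt{n_\text{samples}}$ and drowns the bounded relevance term, reducing
  the "composite" to a distance ranking; the Euclidean distance is
  therefore RMS-normalised (divided by $\sqrt{n}$) so both terms are O(1)
  and genuinely balance relevance against redundancy. Cosine and Tanimoto
  distances are bounded and used as-is. Zero-variance features get
  relevance 0 by definition.

Selection is either top-$k$ (default $k = 100$ on the incorporated
features) or p < 0.05 in threshold mode; ties were already broken by
original column order, so selections are deterministic. Per-dataset
selected counts are never hard-coded — the mechanism, not any particular
outcome, is the contract.

## Classifiers and evaluation

The SVM grid is exactly $C \in \{2^0..2^{10}\}$, $\gamma \in
\{2^{-10}..2^0\}$ (121 points); the forest grid is tree counts 1400–2400 in
steps of 200. The selection criterion inside `kcr_train()` — unstated in
the source — is stratified 5-fold CV accuracy over the grid, with
deterministic tie-breaks: smaller C, then larger γ; fewer trees. Decision
thresholds are 0 for SVM decision values (oriented so larger = more
positive) and 0.5 for forest probabilities. Classes are unweighted because
balancing is done by undersampling.

`cross_validate()` runs seeded stratified k-fold CV (default k = 10),
refitting the full grid search inside every fold. Confusion counts are
pooled over folds; AUC is reported both from the pooled out-of-fold scores
(primary, one number per run) and as the per-fold mean (in the fold
table) — the two differ when fold score scales differ, and both views are
kept because protocols in this area rarely state which they print. ROC is a
threshold sweep over tie-grouped unique scores with trapezoid integration,
which equals pairwise concordance with ties counted ½ (verified
exhaustively in tests). MCC is defined as 0 when a denominator factor
vanishes, with a degeneracy flag.

Cross-species transfer trains on dataset A (undersampled, as in
within-species training) and evaluates on the whole of dataset B with
identical mechanics to the independent test; column names and order must
match exactly, and mismatches are reported by the first offending column.

## Position-specific composition statistics

`position_frequency_matrix()` gives the numeric content of a sequence logo
(positions −15..+15 by 20 residues; rows sum to 1).
`two_sample_position_test()` compares two window sets per (position,
residue) cell with a two-proportion z-test and Bonferroni correction across
the 620 cells. The continuity-corrected form of the z statistic is the
default: per-cell counts are small fractions of the sample, the uncorrected
asymptotic test is anti-conservative there (measured familywise error
around 8–12% at nominal 5% across null simulations), and the Yates
correction restores calibration (~3% measured) without costing detection of
a δ = 0.3 enrichment. `correct = FALSE` recovers the plain test. Output is
tabular (Δ frequency, p, adjusted p, enriched/depleted flag); rendering a
logo from it is deliberately out of scope.

## The synthetic generator: what it emulates and what it does not

`kcr_generate()` draws proteins i.i.d. from a background residue
distribution (default uniform 1/20, lengths 50–400), plants a
Poisson(1.5)-distributed number of positive sites per protein at lysines
with full flanks, and re-samples positive-site flank residues from the
tilted distribution

$$q_j \propto p_j + \delta\,[j \in \{K, E\}],$$

so that at $\delta = 0$ positive and negative flanks are *identically*
distributed by construction — the null calibrations are exact. The enriched
residues default to K and E because those dominate real crotonylation-site
neighbourhoods, and the tilt is applied only within ±7 of the site: real
site logos show enrichment concentrated near the modified lysine, and a
local signal is also what separates the sliding-window encoders (EAAC,
EGAAC) from whole-window AAC — with a uniformly tilted flank the three
would be nearly equivalent and the encoder comparison would be
uninformative. `species_shift = TRUE` moves the enrichment to A/G to
emulate a species with a divergent motif for transfer experiments, and
`motif_mode = TRUE` plants a position-specific motif at offsets ±1..±3
instead of a compositional tilt, for exercising position-aware encoders
(BE, PSSM).

What the generator does **not** emulate: real amino-acid background
frequencies, sequence autocorrelation, homologous families (every protein
is independent, so redundancy reduction removes nothing), hydrophobicity or
disorder structure, and any per-window PSSM signal. Passing tests therefore
demonstrate that the pipeline recovers a planted compositional signal and
is calibrated under its null — not that any particular performance level
will transfer to real proteomes.

**Expected tilt arithmetic.** With uniform background $p = 1/20$ and
enrichment $\delta$, the enriched-residue flank probability is
$(0.05+\delta)/(1+2\delta)$ (≈ 0.219 at $\delta = 0.3$), an excess of
$\delta(1-2p)/(1+2\delta)$ ≈ 0.169. The measured positive-minus-negative
frequency difference in extracted windows is smaller (≈ 0.12–0.14) because
negative windows overlapping a positive site share its enriched flanks;
tests assert the exact expectation on isolated single-site proteins and a
clearly positive measured enrichment on windows.

## Problem sizes and numerical choices

The evaluation experiments shipped with the package use 150 generated
proteins (~200 positive sites, ~416 balanced training windows after
undersampling) for the signal-recovery study at $\delta = 0.3$; 10-fold CV
with a fixed forest of 2000 trees (the grid midpoint) rather than the full
tree-count search, since forest size is flat in that range on these data;
20 seeds for each null calibration; and 100 repetitions of the
planted-feature ranking experiment at a 1.5σ mean shift among 50 noise
features. At these sizes EGAAC reaches a pooled CV AUC around 0.78–0.82,
EAAC slightly higher, AAC around 0.65–0.71 (the whole-window average
dilutes the local signal), shifted-species transfer falls to ≈ 0.3–0.45,
and permuted-label CV sits at 0.47–0.51 — the qualitative ordering that
motivates sliding-window composition encoders, reproduced from scratch by
`scripts/acceptance.R`.

Other numerical conventions: feature matrices are dense doubles; SVM
features are not re-scaled internally (encoder outputs live in [0, 1]
already; binary/PSSM blocks included); one-row-per-window CSV/TSV formats
keep `protein_id`, `center_pos`, `label` as key columns; JSON reports carry
full double precision.

## Known limitations

* The greedy clustering is quadratic in the number of proteins and meant
  for datasets of thousands, not millions, of sequences.
* The internal PSSM fallback adds no per-window information (above); use
  PSI-BLAST profiles for a meaningful PSSM block.
* Chi-square on mean-binarised continuous features discards within-side
  variation; it is the protocol's ranking, not an optimal one.
* Window-level splitting can leak homologous windows when redundancy
  reduction is skipped; prefer the protein-level split in that case.
* The two-proportion test treats windows as independent observations;
  windows from the same protein are mildly correlated, which the test
  ignores.
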