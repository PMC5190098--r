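---
title: "Sequence-coupled prediction of hydroxylation sites: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-coupled prediction of hydroxylation sites: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hydroxylation is a post-translational modification of proline (giving
hydroxyproline, HyP) and lysine (hydroxylysine, HyL), prominent in collagen
biology and relevant to disease. Given a protein sequence with many P or K
residues, the task is to predict which of them can be hydroxylated.
`hydroxysite` treats this as binary classification of peptide windows: a
candidate site is the window

$$R_{-\xi} \cdots R_{-2} R_{-1} \circledast R_{+1} R_{+2} \cdots R_{+\xi}$$

of $2\xi + 1$ residues centered on the candidate ($\circledast$ = P or K),
with window slots falling outside the protein filled by the dummy residue
X. The default half-width is $\xi = 10$ (21-residue windows), the value
that preliminary window-size screens in this family of predictors have
favored; `select_window_size()` reruns such a screen on any dataset.

## The sequence-coupled encoding

The modeling idea is that the residues flanking a true site are not
independent: each flank position is coupled to its nearest neighbor toward
the center. Each class $c \in \{+,-\}$ (true sites / non-sites) is
summarized by first-order conditional probability tables estimated from the
training windows of that class:

* marginal distributions $p^c_{-1}(R_{-1})$ and $p^c_{+1}(R_{+1})$ for the
  two innermost positions (their inner neighbor is always $\circledast$, so
  conditioning on it carries no information), and
* conditionals $p^c_{-k}(R_{-k} \mid R_{-(k-1)})$ and
  $p^c_{+k}(R_{+k} \mid R_{+(k-1)})$ for $k = 2, \dots, \xi$.

A window is encoded as the $2\xi$-vector of differences

$$\phi_j = p^+_j(\cdot) - p^-_j(\cdot), \qquad j = -\xi, \dots, -1, +1,
\dots, +\xi,$$

each probability looked up with the residue (pair) actually present in the
window. Every component lies in $[-1, 1]$; positive components mark flank
context more typical of true sites. This is a general pseudo amino acid
composition mode: a fixed-length vector that retains local order
information. The vector feeds a random forest
(majority vote over Gini-impurity decision trees), and the vote fraction
for the positive class is the site score; a residue is called hydroxylated
when the score reaches the decision threshold (default 0.5, configurable,
and swept to produce ROC curves).

```{r}
library(hydroxysite)
proteins <- annotate_proteins(read_fasta("proteins.fasta"),
                              read_site_annotations("sites.tsv"))
ds <- build_benchmark(proteins, target = "P", xi = 10)
model <- fit_model(ds)
enc <- encode_dataset(ds, model)
forest <- train_forest(enc$features, enc$labels, forest_config(seed = 1))
```

## Benchmark construction

`build_benchmark()` slides the window over every protein, keeps the windows
centered on the target residue, labels them by the site annotations, then
screens the result: duplicate windows within a subset are removed (the
first occurrence in input order survives), and any self-conflict window —
one occurring in both the positive and the negative subset — is removed
from both. The screening statistics are kept on the dataset object, and
count conservation (survivors + removals = windows extracted) is asserted
in the test suite. Window length is always $2\xi + 1$; site coordinates
are 1-based on the full protein sequence.

On-disk benchmark files use either a FASTA dialect
(`>source_id|center_position|pos` / `|neg` headers) or a four-column TSV
(`window`, `label`, `source_id`, `center_position`), auto-detected by the
first character. These dialects are this package's convention: the
supplementary peptide files of the original study are only described as
positive/negative 21-mer lists, not as a concrete format.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `xi` | 10 | window half-width; features are $2\xi$-dimensional |
| `smoothing` | `"none"` | probability estimation; `"laplace(a)"` adds pseudo-count `a` |
| `n_trees` | 100 | ensemble size; scores are vote fractions in $\{0, 1/T, \dots, 1\}$ |
| `max_features` | `sqrt` | candidate features per split, the standard RF heuristic |
| `class_weighting` | `"none"` | no rebalancing: class imbalance expresses itself as high Sp / low Sn |
| `threshold` | 0.5 | vote fraction above which a site is called |

With `smoothing = "none"`, an unseen conditioning residue yields an
identically-zero conditional column, and an unseen pair a probability of
exactly 0 — a pure frequency derivation. This keeps single-observation
examples exactly 0/1 and makes the counting-oracle tests exact; Laplace
smoothing is exposed for users who prefer proper distributions everywhere.
X (terminal padding, and the sink for non-standard letters such as B, J,
O, U, Z) is a first-class 21st alphabet symbol, so windows near protein
termini are encoded without special cases. The random-forest
hyperparameters are deliberately the plain defaults of the method; they
were not tuned, and all of them are exposed in `forest_config()`.

## Evaluation: metrics and protocols

`compute_metrics()` reports the four standard binary metrics in their
intuitive totals-and-errors form ($N^+$, $N^-$ totals; $N^+_-$ missed
sites; $N^-_+$ false positives):

$$\mathrm{Sn} = 1 - \frac{N^+_-}{N^+}, \quad
\mathrm{Sp} = 1 - \frac{N^-_+}{N^-}, \quad
\mathrm{Acc} = 1 - \frac{N^+_- + N^-_+}{N^+ + N^-},$$

$$\mathrm{MCC} = \frac{1 - \left(\frac{N^+_-}{N^+} + \frac{N^-_+}{N^-}\right)}
{\sqrt{\left(1 + \frac{N^-_+ - N^+_-}{N^+}\right)
       \left(1 + \frac{N^+_- - N^-_+}{N^-}\right)}}.$$

This MCC is algebraically identical to the standard Matthews coefficient;
the test suite verifies the identity over a thousand random confusion
tables to $10^{-12}$. When the denominator vanishes (every prediction in
one class) MCC is reported as 0 with a warning — the usual convention for
the undefined case. ROC curves sweep the decision threshold over all
distinct scores plus sentinels; AUC is the trapezoidal area, which equals
the Mann–Whitney concordant-pair statistic (ties counted one half).

`jackknife()` implements leave-one-out evaluation in two protocols, because
descriptions of this predictor family leave open whether the probability
tables were refit inside each fold:

* **`strict`** (default): both the coupling tables and the forest are refit
  on the $n - 1$ training samples of every fold. This is the statistically
  sound protocol.
* **`paper_style`** (reproduction mode): the tables are fitted once on the
  full dataset and only the forest is refit per fold.

The difference is not cosmetic. Because each training window contributes
counts to its own class's tables, features encode a trace of class
membership; when the tables have seen the test sample (`paper_style`),
that trace leaks into evaluation and inflates the scores — on
zero-coupling synthetic data, `paper_style` jackknife AUC saturates near 1
while `strict` stays at chance (the null-calibration test asserts AUC in
[0.4, 0.6] under `strict`). Reported accuracies under `paper_style` should
therefore be read as upper bounds; `strict` is the honest estimate.

`kfold()` stratifies folds by label (each fold's positive count within one
of $n^+/k$) and reduces exactly to the jackknife at $k = n$, where the
folds are taken as the singletons in sample order (ordinary stratified
assignment is meaningless for singleton folds).

## The synthetic generator

`generate_proteins()` emulates precisely the statistical structure the
encoder assumes, so that every stage of the pipeline can be validated
without external data. Per class it draws one marginal and one conditional
table (Dirichlet draws over the flank alphabet) and writes the flanks of
each planted candidate outward from the center: $R_{-1}$ from the
marginal, $R_{-2}$ conditioned on $R_{-1}$, and so on — the exact
conditioning direction the encoder fits, which makes parameter recovery
well-posed. `coupling_strength` interpolates entry-wise between one shared
table set (0: classes indistinguishable, the null) and independent
class-specific tables (1).

Design choices, made once:

* **Defaults.** `site_density = 0.2` mirrors the roughly 1:4
  positive:negative imbalance of curated hydroxyproline benchmarks;
  lengths 200–400 and uniform background are generic globular-protein
  stand-ins.
* **Candidate spacing.** Candidate centers are planted every $2\xi + 2$
  residues, so windows never overlap and no window needs X-padding; flank
  statistics of one candidate cannot contaminate another.
* **Flanks exclude the target letter**, so every occurrence of the target
  in a generated protein is a deliberate candidate with known class. The
  generator uses the same conditional matrix at every flank position;
  recovery checks therefore average the fitted per-position conditionals
  before comparing against the truth.
* **Dirichlet concentration.** The default (5) gives smooth tables without
  vanishingly rare symbols — the regime for parameter-recovery checks.
  High-signal experiments (separability, planted-site recovery, window-
  radius screens) use a sharper 0.3, giving near-deterministic neighbor
  preferences akin to strongly stereotyped motifs.

What the generator does **not** emulate: real collagen motif structure
(G-X-Y repeats), compositional bias, homology between proteins, annotation
noise, or longer-range dependencies. Passing the synthetic validation
therefore shows that the pipeline recovers the model class it assumes —
not that real hydroxylation data satisfies that model class.

## Validation scales

The test suite generates everything it needs at run time: counting-oracle
equivalence on fixtures of up to 50 windows; parameter recovery on ~5,000
windows per class (max-abs table error below 0.05); null calibration on
~430 windows under strict jackknife; a strongly coupled ~200-window
benchmark for separability (Acc ≥ 0.95); and an imbalanced ~300-window
benchmark for the high-Sp/low-Sn profile that class imbalance without
reweighting produces. Those sizes keep the default check complete in a few
minutes on one core while leaving the stochastic margins wide.

## Known limitations

* The published benchmark peptide files for HyP (851/3,505) and HyL
  (142/980) must be obtained from the original publisher; a drop-in
  location (`inst/extdata/supplementary/`) and both file dialects are
  supported, and the corresponding dataset-size check stays failing until
  the files are supplied.
* The original predictor's random-forest hyperparameters and its exact
  table-refit protocol are unpublished, so published headline accuracies
  can be approached with `--protocol paper-style` but not guaranteed
  exactly.
* Scores are vote fractions on a grid of $1/T$; with small ensembles, ROC
  curves are coarse and ties at the threshold are resolved as positive
  (`score >= threshold`).
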