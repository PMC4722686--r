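---
title: "Structured prediction of hierarchically consistent ontology annotations: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ontostruct` treats gene–phenotype annotation as hierarchical multilabel
classification over the is-a DAG of one subontology. A gene's label is the
binary vector of its (true-path-expanded, filtered) term set. The model is
a structured SVM with compatibility function

$$ f(x, y) \;=\; \langle w,\; \phi(x) \otimes y \rangle, $$

linear in the tensor product of input features and the label vector, so in
dual form everything is expressed through the joint product kernel
$K((x_1,y_1),(x_2,y_2)) = K_X(x_1,x_2)\,K_Y(y_1,y_2)$ with a linear label
kernel $K_Y(y,y') = y^\top y'$. Prediction is
$\hat y = \arg\max_{y \in \mathcal{Y}_c} f(x,y)$ over the **candidate
catalog** $\mathcal{Y}_c$: the distinct label vectors observed among
training genes. We read "combinations of terms in the training set" as the
observed label sets rather than a constructed power set — the power set is
exponential, and restricting inference to biologically realized
combinations is also what performed best in the source methodology.
Because every catalog member is an expanded training label, every
prediction is hierarchically consistent by construction; no reconciliation
step exists or is needed.

## Input kernel

Each feature source yields a linear kernel that is cosine-normalized,
$K^{\mathrm{norm}}(i,j) = K(i,j)/\sqrt{K(i,i)K(j,j)}$, and sources are
added unweighted. Two numerical conventions:

* The normalization is printed in the source text without the square
  root; we use the standard cosine form because only it yields a unit
  diagonal (the sqrt-free form is read as a rendering loss, flagged, not
  silently adopted).
* Genes with an all-zero feature row in one source get a zeroed kernel
  row/column with diagonal 1 in that source — neutral under addition —
  rather than being dropped, because a gene absent from one source is
  usually present in others.

## Training

Margin rescaling with Hamming loss
$\Delta(y,y') = \lVert y - y' \rVert_1$: for each training gene $i$ and
candidate $\hat y$,

$$ f(x_i, y_i) \;\ge\; f(x_i, \hat y) + \Delta(y_i,\hat y) - \xi_i, \qquad
   \xi_i \ge 0, $$

minimizing $\tfrac12\lVert w\rVert^2 + C\sum_i \xi_i$. The reference
implementation named in the source text is a library whose defaults are
not recoverable, so the optimizer here is the textbook **n-slack
cutting plane**: loss-augmented inference is an exhaustive scan of the
finite catalog (exact), the most-violated candidate joins the gene's
working set whenever it exceeds the current slack by more than
$\varepsilon$, and the restricted dual QP is re-solved by blockwise
pairwise coordinate ascent (per-gene simplex blocks
$\alpha_i \ge 0,\ \sum \alpha_i \le C$; Gauss–Seidel with exact rank-1
maintenance of all compatibilities, so gradients are never stale).
Termination: no catalog constraint violated by more than $\xi_i +
\varepsilon$. Defaults $C = 1$, $\varepsilon = 0.01$, 100 outer passes —
conventional, configurable, and recorded in every run manifest. The model
stores the working-set slack $\xi_i$, so a brute-force scan of the full
catalog is a genuine audit of termination rather than a tautology.

## Per-term confidence

Term-centric evaluation needs a per-term, cross-gene-comparable score.
The design here deviates deliberately from the simpler
$\max_{y \ni t} f(x,y)$: that quantity carries a gene-specific additive
scale (the overall magnitude of $f(x,\cdot)$), and with a perfect
compatibility oracle ($f(x,y) = -\Delta(y_{\mathrm{true}},y)$) its macro
AUC on the recovery fixture plateaus near 0.81 — it cannot meet the
package's own 0.9 recovery bar, so the simpler form is demonstrably
inadequate at desk scale. We use the containing/excluding margin

$$ \mathrm{conf}(t \mid x) \;=\; \max_{y \ni t} f(x,y) \;-\;
   \max_{y \not\ni t} f(x,y), $$

which cancels the gene-specific scale. Over a hierarchically consistent
catalog it remains monotone along the hierarchy (labels containing a
child also contain its parent, so the first max is over a superset;
labels missing the parent also miss the child, so the second is over a
subset), and a term absent from every catalog label scores $-\infty$
(ranked last). A term present in *every* catalog label scores $+\infty$;
such terms have no negatives among training genes and are typically
excluded from macro AUC anyway.

# Baselines and evaluation

* **Binary SVMs**: one biasless kernel C-SVM per term ($C = 1$) on the
  same combined kernel, solved by exact per-coordinate descent on the
  box-constrained dual. Terms single-classed in a training fold are
  skipped and logged. No SVM library is available in the target
  environment; the in-package solver is checked against an independent
  high-precision box-QP solve.
* **Macro AUC**: rank-based (Mann–Whitney, ties half-credit) per term,
  averaged over terms with a defined AUC. Held-out scores are pooled
  across folds into a single table per method (pooled rather than
  per-fold averaging: better defined for rare terms; the source protocol
  does not specify).
* **Protein-centric**: per-gene precision/recall on predicted vs true
  sets; F-max over a 101-point threshold grid with the CAFA convention —
  precision averaged over genes with non-empty predictions, recall over
  all genes with non-empty truth. The source text relegates exact
  definitions to a supplement not available here; the CAFA convention is
  used and documented, not claimed identical.
* **Cross-validation**: seeded, gene-level, size-balanced five-fold
  partition. Each fold's catalog, structured model and binary SVMs are
  built from that fold's training genes only (leakage-audited in tests).
* **Ablation**: leave-one-source-out percent change,
  $100\,(\mathrm{AUC}_{-s} - \mathrm{AUC}_{\mathrm{all}})/\mathrm{AUC}_{\mathrm{all}}$.
* **Significance**: two-sided paired t-test on per-term AUC differences;
  zero-variance differences give an NA sentinel.
* Grouping-only terms (e.g. onset/pace-of-progression umbrellas) can be
  excluded from metric computation via `grouping_terms`.

# The synthetic world

The generator emits a complete fixture in the exact dialects the loaders
parse: a random single-root is-a DAG (each term draws 1–3 parents among
earlier terms), per-gene Poisson(3)∨1 leaf annotations expanded by the
true-path rule, and four sources whose informativeness is one
`signal_strength` knob each:

* network: edge probability `noise + signal * Jaccard(labels)^2`, split
  over two edge-list files (a baseline `noise` rate keeps the union
  non-empty at zero signal);
* go: per-term indicators present with probability `max(signal, noise)`
  for annotated genes and `noise` otherwise (the max prevents
  anti-correlation at zero signal), written as GAF with experimental
  evidence plus pure-noise IEA decoy rows the loader must discard;
* literature: one signal word per term with Poisson(1 + 2·signal) counts
  for annotated genes plus Poisson(noise) background vocabulary;
* variant: diseases are label-set clusters around prototype genes; genes
  link to their most similar prototype's disease with probability
  `signal`, else to a random disease; variants hang off diseases.

Defaults — 120 genes, 40 terms, signal 0.75, noise 0.05 — are chosen once
as a plausible mid-signal regime that keeps a full five-fold train/evaluate
under ~2 minutes on one CPU. Identical config and seed give byte-identical
files.

**What a green test does and does not establish.** The generator's GO-like
source ties each indicator to a single ontology term, which makes the
per-term binary baseline unrealistically strong: with informative GO
features, binary SVMs can match or beat the structured model on these
fixtures, unlike on genome-scale corpora where per-term supervision is
scarce and indirect. Recovery tests therefore establish that the
structured machinery works (consistency, inference exactness, constraint
satisfaction, signal recovery, ablation direction), not that it dominates
the baseline on every synthetic world. Real term-frequency distributions,
annotation incompleteness, and literature-scale vocabularies are not
emulated.

The one-percent document-frequency word filter of the source pipeline is
calibrated to a ~3000-gene corpus; on a 120-gene fixture it would mean
"words co-occurring with exactly one gene" and delete all shared signal.
The loader keeps the strict 1% default; the pipeline exposes
`max_doc_freq` and uses 0.5 on desk-scale fixtures.

# Numerical choices and degenerate inputs

* Term order is lexicographic everywhere; catalog order is lexicographic
  on the 0/1 pattern; argmax ties break to the lowest catalog index.
* Kernel symmetry is enforced to 1e-8 relative tolerance and
  symmetrized; normalization treats zero diagonals as described above.
* `auc` returns NA on single-class input; macro AUC skips NA terms and
  errors only when no term is scorable.
* Annotation filtering requires expanded sets (ancestor counts then
  dominate descendant counts, so the min-gene filter cannot create
  inconsistency); genes left with empty label sets are dropped — they
  carry no supervision. Whether the source pipeline kept root-only genes
  is unknown; dropping is this package's choice.
* Training errors on non-positive `C` or `epsilon`; hitting the outer
  iteration cap warns and returns the best-so-far model with its slack.
* Random partitions and the generator restore the caller's RNG state
  (`with_seed`), so identical configs are reproducible regardless of
  surrounding code.

# Known limitations

* The candidate catalog restricts predictions to training-observed label
  sets; genuinely novel term combinations are unreachable (the
  approximate all-combinations inference the source text reports as
  slightly harmful is deliberately out of scope).
* Exhaustive inference is exact but scales linearly in catalog size; the
  package targets desk-scale and subontology-scale problems, not
  genome-scale catalogs with tens of thousands of distinct labels.
* The binary-SVM dual has no bias term (standard for normalized kernels
  with unit diagonal, and what keeps the solver exact and dependency-free);
  decision values are therefore not probability-calibrated.
* Only is-a edges are parsed; other OBO relationship types are ignored by
  design.
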