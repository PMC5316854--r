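---
title: "Haploinsufficiency-weighted network scoring: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haploinsufficiency-weighted network scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Somatic copy-number alterations (SCNAs) are called per gene on the GISTIC
scale: −2 (homozygous deletion), −1 (monoallelic loss), 0, +1 (gain), +2
(high amplification). A pathway is represented as the subgraph of a
protein–protein interactome induced by its gene set, and disruption is
accumulated over *interactions*, not genes: a deletion matters more when it
hits a gene whose products work with other perturbed partners, and more
again when independent evidence says the gene is dose-sensitive.

Each gene carries a gene dose-sensitivity (GDS) weight: 1 with no
evidence, 2 when a yeast orthologue is haploinsufficient/haploproficient, 3
when mouse data support dose sensitivity (mouse overrides yeast). For an
edge between genes with calls $(c_1, c_2)$ and weights $(g_1, g_2)$:

$$
s(c_1,c_2) =
\begin{cases}
\min(c_1,0)\,g_1 + \min(c_2,0)\,g_2 & \text{if } \min(c_1,c_2) < 0
\text{ (deletion branch)}\\
c_1 g_1 + c_2 g_2 & \text{otherwise (gain branch)}
\end{cases}
$$

The published description of this score gives the branch conditions, the
sign semantics (deletions score negative, amplifications positive), the GDS
weighting, and the normalization anchor, but the algebraic display itself
is not recoverable from the text we derived this implementation from. The
formula above is the simplest one satisfying every stated constraint. It is
a **pluggable strategy** (`edge_scorer()`): the `"gds_linear_mixed"`
alternative keeps the amplified partner's positive term inside the deletion
branch, which changes mixed ("antagonistic") edges only. The active
scorer's name is recorded in every output header and manifest.

A tumour's raw module score is the sum of edge scores over the pathway
network. It is normalized by the absolute *minimum possible
haploinsufficient score* — the module score when every pathway gene is set
to call −1, i.e. $-\sum_{(i,j) \in E}(g_i + g_j)$ under the default scorer
— so a cohort in which every gene carries a monoallelic loss scores exactly
−1. This anchor makes scores comparable across pathways of different size
and connectivity.

## Edge-retention modes

* **intrinsic** (default): both endpoints inside the pathway set — the
  pan-pathway screening mode.
* **cross_pathway**: one endpoint may lie in a companion pathway universe,
  used when inter-pathway coupling (e.g. among proteostasis pathways) is
  part of the question.
* **expand1 / expand2**: add first- (second-) step interactors from the
  whole supplied interactome. These exist to reproduce the ablation showing
  that indiscriminate expansion dilutes driver recovery; candidates are
  drawn from the entire supplied interaction set, the most literal reading
  of "direct interactors" (the restricted-universe alternative was a
  genuinely open choice).

Genes present in a network but absent from the copy-number matrix are
scored as call 0 and counted in the run report: absence of evidence must
not simulate alteration.

## The permutation null and significance

Cancer types differ enormously in SCNA burden, so raw module scores are not
comparable to a global reference. The null here is **tumour-paired**:
within each tumour, the multiset of gene calls is kept and reassigned to
genes uniformly at random, preserving that tumour's burden exactly (the
per-sample call histogram is asserted unchanged on every replicate). For
each of `n_reps` (default 1,000) replicates the whole cohort is reshuffled
once and *all* pathways are scored against the same shuffle, making a
pan-pathway run O(n_reps) in shuffles and reproducible regardless of
pathway iteration order.

Per replicate, observed and null per-sample normalized scores are compared
with a two-sided t-test (Welch by default — robust to unequal variances;
the pooled-variance Student variant is available via `var_equal = TRUE`
and recorded in output). The aggregated p is the back-transform of the
mean of the per-replicate $\log_{10} p$ values — the geometric mean of p —
with each replicate p floored at the smallest representable double before
taking logs. Bonferroni correction uses m = pathways tested by default;
presets of 187 (all distinct human KEGG pathways) and 126 (6 proteostasis
pathways × 21 cancer types) mirror the published analyses. Direction is the
sign of (mean observed − mean null), reported as a call only when q ≤ α;
the raw means are always emitted. Degenerate replicates (zero variance in
both groups, e.g. an all-zero cohort) contribute p = 1 and are counted.

### Calibration: what the aggregation does and does not give you

The geometric-mean aggregation is **conservative, not calibrated**, under
the null. With exchangeable data each replicate p is uniform, but the mean
of $\log_{10} p$ over many replicates concentrates near
$\mathbb{E}[\log_{10} U] = -1/\ln 10 \approx -0.434$, so the aggregated p
concentrates near 0.37 for a typical null cohort and rarely drops below
0.05. We measured the realized type-I rate at α = 0.05 as ≈ 0.007 in a
Gaussian mock-up (2,000 simulations) and ≈ 0.007–0.02 through the full
pipeline on null synthetic cohorts — far below α, never above it. The test
is therefore *valid* (it never anti-conservatively inflates discoveries)
but strictly conservative; our module test suite asserts the one-sided
property (type-I ≤ α + 3 MC SE), while the acceptance suite retains the
stricter two-sided calibration criterion, which fails honestly. Users
should read aggregated p-values as conservative bounds, and should not
expect near-α rejection rates on null data.

A related, intended behaviour of the tumour-paired null: when one pathway
in a cohort is heavily deleted, shuffling redistributes those deletions
over all genes, so *unaffected* pathways score slightly less negative than
their nulls and can be called weakly `amplification_enriched`. This is
relative-to-burden enrichment, not a bug; calibration statements above
refer to cohorts with no planted signal.

## The synthetic-data generator

`simulate_cohort()` emulates a GISTIC-called cohort with known ground
truth. Defaults state the world the method was described in:

* **Background noise**: each background gene × sample cell is altered
  independently with probability 0.1 (a moderate pan-cancer per-gene SCNA
  rate); conditional on alteration, 95% of events are monoallelic (±1) and
  5% biallelic (±2), split symmetrically between loss and gain — matching
  the observed dominance of single-copy changes in tumours.
* **Planted pathways**: 20 genes, internal Erdős–Rényi edge density 0.3
  (sparse but connected, like curated pathway subgraphs), monoallelic
  deletion penetrance 0.6, half the genes GDS-annotated with an even
  yeast/mouse split. An optional hub gene gets elevated degree (≥ 4),
  penetrance 0.7 and a mouse GDS weight — the TP53-like configuration.
* **Mutation frequencies** are drawn Uniform(0, 0.05): mutations are
  visualization-only in this method and no mutation model is described, so
  the default deliberately stays below the 10% display cut.

What it does **not** emulate: chromosome/arm linkage (genes are
independent, so real arm-level co-deletion correlation is absent), GISTIC
segmentation artefacts, subclonality, and purity. A green detection test
on this generator therefore establishes sensitivity to *pathway-coherent
dose loss against independent noise*, not robustness to correlated
arm-level events.

## Numerical and design choices

* **Log2 discretization cuts** (continuous input): ±0.3 and ±1.3,
  boundaries assigned outward so a value exactly at a cut is called
  altered; the rule is monotone and explicit because the original
  discretization was unstated.
* **Tie-breaking** in impact ranks: |score| descending, then gene symbol
  ascending — deterministic and order-stable.
* **QC "possible hits"**: reference ∩ universe by default; the
  table-capacity denominator is reported alongside whenever it differs.
* **Visualization cuts**: ">33%" is strict (> 1/3); node alteration
  prevalence counts any nonzero call; the edge threshold applies to
  *either* endpoint by default (`"both"` available); mutation green
  overrides SCNA colours, and mutation-qualified edges are drawn even
  without SCNA qualification (a gene mutated in 12% of patients shows
  green incident edges). Precedence of green over a simultaneous >33%
  SCNA on the same edge follows the phrasing order of the published rules
  and is flagged as our reading, not an asserted fact about the original
  tool.
* **Determinism**: every command derives all randomness from one seed;
  replicate r uses sub-seed r, so results are invariant to replicate and
  pathway ordering. Manifests record config, seed, scorer, version and
  input checksums; identical manifests imply bit-identical outputs.
* **Missing copy-number cells** are imputed to 0 with a logged count —
  conservative, creates no artificial disruption.

## Known limitations

* The edge-score algebra is a reconstruction (see above); all conclusions
  that depend only on its stated properties (branching, signs, GDS
  monotonicity, the −1 anchor) are invariant to the admissible variants,
  but exact score magnitudes on mixed edges are not.
* The aggregated p is conservative (see Calibration) — pathway rankings
  are informative, absolute p magnitudes are bounds.
* No FDR alternative is wired in as default (Bonferroni matches the
  described procedure); no GSEA comparison is implemented — only the QC
  efficiency metric both were benchmarked with.
* The generator's independence assumptions understate null variance for
  physically linked genes; calibration claims are for the stated synthetic
  world.
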