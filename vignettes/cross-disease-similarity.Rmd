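---
title: "Methods: quantifying cross-disease functional similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cross-disease functional similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`simlink` asks a single question of two diseases, each observed through
replicated case/control transcriptomes: *are the genes perturbed in disease
A functionally the same genes — in ontology space and in interaction space —
as the genes perturbed in disease B, even when the two DEG lists barely
overlap?* This vignette documents the statistical machinery, every tunable
parameter, the synthetic data the package validates itself on, and the
limitations of both.

## Differential expression

Each dataset is a log2-scale gene-by-sample matrix (microarray intensity,
or log2(FPKM+1) for RNA-seq; `log2_transform()` uses offset 0 for the
former and +1 for the latter, the standard pseudo-count that keeps zero
counts finite). Probe-level arrays are first collapsed with
`collapse_probes()`: probes with ambiguous gene assignment are removed
outright, replicate probes of one gene are averaged. Cross-platform
analysis is restricted to genes present in every dataset
(`restrict_to_common_genes()`), because platform gene coverage differs.

Per gene, `call_degs()` computes

* `log2fc` = mean(case) − mean(control) on the log2 scale, and
* a two-sided Mann–Whitney rank-sum p-value with midrank tie handling.

A gene is a DEG when |log2fc| > log2(1.5) ≈ 0.585 **and** p < 0.05 (both
raw; multiple-testing correction is deliberately absent at this stage — it
enters only in enrichment). The fold-change gate is interpreted on the
linear scale, stated once in the config and applied everywhere. A disease's
DEG set is the exact intersection of its datasets' DEG sets
(`intersect_deg_sets()`), which trades sensitivity for reproducibility
across platforms.

The rank test switches implementation at group size 8: when both groups
have ≤ 8 samples, all `choose(n1+n2, n1)` assignments of the pooled
midranks are enumerated and the p-value is the exact fraction of
assignments whose U statistic is at least as far from its null mean as
observed; otherwise the normal approximation with tie correction and a
0.5 continuity correction is used. Exactness is cheap precisely where the
approximation is weakest. Zero-variance genes get p = 1; genes whose test
fails are excluded from the DEG set with a warning.

A calibration note: the rank-sum test is discrete, so its attained level at
nominal α = 0.05 depends on the group sizes. At 10 vs 10 the
continuity-corrected approximate test attains ≈ 0.043; at 20 vs 20 it
attains ≈ 0.049. The package's calibration checks therefore assess the
"type-I ≈ 0.05" property at 20 + 20 samples, where the approximation regime
makes the nominal level meaningful; at smaller sizes the test is
conservative, never anti-conservative.

## Ontology, information content, and the five similarity measures

`ontology_dag()` holds a rooted acyclic DAG with typed child→parent edges
(`is_a`, `part_of`), a gene→term annotation map, and precomputed ancestor
closures (each term's closure includes itself). A minimal OBO 1.2 reader
(`read_obo()`) and a TSV/GAF annotation reader are provided; relationship
types other than the two supported ones are ignored with a count, obsolete
terms are skipped, and a single namespace per run is assumed (pairs that
share no root score 0).

Information content is annotation-derived: each gene's direct terms are
propagated to all ancestors, counting the gene once per term even when it
reaches the term via several paths; then p(t) = count(t)/count(root) and
IC(t) = −ln p(t) (natural log, the convention of the established GO
similarity tooling). IC is 0 at the root and non-decreasing down every
edge. Terms with zero propagated count have undefined IC and are excluded
from IC-based similarity with a warning.

With MICA(t₁,t₂) the common ancestor maximizing IC (ties broken by
lexicographically smallest id, making runs deterministic), `term_sim()`
implements:

| measure | definition | range |
|---|---|---|
| resnik | IC(MICA) | [0, ∞) |
| lin | 2·IC(MICA) / (IC(t₁)+IC(t₂)), 0 when the denominator is 0 | [0, 1] |
| jiang | 1 − min(1, IC(t₁)+IC(t₂)−2·IC(MICA)) | [0, 1] |
| rel | lin · (1 − p(MICA)) | [0, 1] |
| wang | Σ_{t∈A₁∩A₂}(S₁(t)+S₂(t)) / (SV₁+SV₂) | [0, 1] |

For Wang, Sᵢ(t) is the maximal product of edge weights along any upward
path from term i to ancestor t (Sᵢ(term i) = 1) and SVᵢ the sum of Sᵢ over
term i's closure; edge weights default to the method's published 0.8
(`is_a`) / 0.6 (`part_of`) and are configurable. S-values are computed by
fixed-point relaxation over the ancestor closure, which converges in at
most depth-many passes.

Resnik is reported unnormalized by default (its set-level scores live on
the IC scale, not in [0,1]); an option to divide by the maximum IC exists
but is off. The Jiang distance is mapped to a similarity by 1 − min(1, d),
keeping [0, 1].

Gene-level similarity is the best-match average (BMA) over the two genes'
direct term sets: the mean of every row maximum and every column maximum of
the term-pair matrix. Set-level similarity applies BMA again over the
gene-pair matrix. BMA is the pipeline default (and the default of the
field's reference implementations); `max` and `avg` are available in the
API (`combine_sim()`). Scores are invariant to gene order and duplication;
unannotated genes are dropped with a logged count, and a fully unannotated
set is an error. `gene_sim_matrix()` deduplicates genes with identical term
signatures and is the precomputation that makes the permutation null cheap.

## Monte-Carlo significance

Both the similarity score and the network connectivity are tested with the
same resampling scheme (`permute_statistic()`): each replicate draws two
*disjoint* gene sets of the observed sizes uniformly without replacement
from the background pool and re-evaluates the statistic. The p-value is

p = (m + 1) / (n + 1),

with m the number of replicates whose statistic is ≥ the observed one
(ties count toward m; the +1 includes the observed value in the reference
distribution, so p ∈ [1/(n+1), 1] and is never 0). Disjoint draws mirror
the observed structure — the two disease DEG sets are disjoint. Each
replicate is seeded as `seed + replicate_index`, which makes runs
bit-reproducible and stream-stable: increasing n leaves the first
replicates unchanged. Replicates whose statistic errors are dropped with a
count; more than 1% dropped aborts the run.

Defaults follow the workflow the package implements: 10,000 replicates for
the similarity null and 1,000 for the connectivity null; both are config
keys (`n_perm_ss`, `n_perm_net`), and the package's own validation uses
n = 999 to keep run times in seconds. The resampling pool for the
similarity null is the set of *annotated* detected genes — unannotated
genes would be silently discarded inside the statistic and would shrink the
effective set sizes; the connectivity null resamples from all detected
genes, matching the procedure of drawing random DEG-sized sets from the
detected background and rebuilding the induced network each time (no edge
rewiring).

## Interaction network

`build_network()` keeps interactions whose confidence score is **strictly**
greater than the threshold (default 0.4), drops self-loops, stores each
pair once in canonical order (keeping the maximal duplicate score), and
retains isolated genes as degree-0 nodes. STRING-style integer scores
(0–1000) are auto-detected and divided by 1000 on read. Degree counts
distinct neighbors; hub lists are the top-k per disease, ties broken by
gene symbol so output is deterministic. Because drawn figures often omit
isolated nodes, the report carries both the all-input-genes node count and
the non-isolated count. `write_network()` exports edge-list TSV, SIF and a
node-attribute table (disease tag, degree, regulation direction) for
external viewers.

## Enrichment

`enrich_terms()` scores each term by the upper-tail hypergeometric
probability of the query/term overlap, P(X ≥ t) with population n
(background), m successes (term size in background), k draws (query size) —
evaluated through the stable distribution functions of base R — and adjusts
across terms with Benjamini–Hochberg. Gene annotations are propagated to
ancestor terms first (standard ontology enrichment semantics; the root then
trivially has p = 1). Terms annotating fewer than `min_term_size = 3`
background genes are skipped. A flat pathway→gene map works through the
same operation without a DAG.

## Synthetic studies and what they do (not) show

`synth_scenario()` fixes the ground truth; its defaults are the study
conditions the package validates itself under:

* 2000 genes; 50 planted DEGs per disease, disjoint between diseases;
  log2 effect 1.0, half up / half down; observation noise sd 0.5;
* four datasets with case/control sizes 12/10, 22/8 (disease A) and 39/18,
  9/54 (disease B) — the replicated two-platform design the pipeline
  targets;
* an ontology of 4 branches (depth-2 is_a chains, 6 leaves each, every
  third leaf attached by part_of) over a root; 400 annotated background
  genes with 1–3 leaves of a single branch each; both planted sets
  annotate branch 1 when `shared_branch = TRUE`, branches 1 and 2
  otherwise;
* background interactions with probability 0.01 and scores U(0.41, 1),
  2 planted cross-disease edges per planted A-gene at scores U(0.9, 1),
  plus 50 sub-threshold decoy edges.

Two generator choices deserve a note. First, background annotations fill
branches toward *equal totals* including the planted branch: without this,
planting 100 genes under one branch doubles its annotation frequency,
halves its IC, and the IC-only measures (Resnik, Rel) would see lower
observed similarity than their own null — an artifact of the fixture, since
real ontology term frequencies are corpus-wide properties, not inflated by
one study's DEG selection. Second, background edge scores start above the
0.4 cutoff so the edge probability directly controls retained density,
while decoys exercise the cutoff.

Both "platforms" are generated from the same Gaussian log-intensity model;
the platform tag drives only the I/O transform path. Consequently the
synthetic validation demonstrates correctness of the *statistics* —
recovery of planted DEGs, calibration and power of the permutation nulls,
ranking of planted hubs, discrimination of shared vs disjoint annotation —
but not robustness to count-distribution effects, probe-level artifacts,
batch effects, or annotation bias in real GO/STRING data. Real analyses
should treat the usual caveats of those resources as out of the package's
hands.

Validation problem sizes were chosen to make the checks sharp at desk
scale: permutation nulls at n = 999, the nested calibration study at
500 × 199, discrimination over 20 paired seeds, type-I calibration over
5000 null genes.

## Numerical and degenerate-input choices

* Similarity of terms with no common ancestor (different namespaces) is 0;
  `lin`/`rel` with IC(t₁)+IC(t₂) = 0 are 0 by definition.
* MICA ties and hub-degree ties break lexicographically; all outputs are
  deterministic given the config seed.
* Empty DEG intersection is a warning at the set stage and a hard,
  stage-named error when the pipeline needs the set downstream.
* Scores outside [0,1], self-loops and malformed rows are rejected with
  logged counts, never silently.
* p-value gates are strict (`<` for DEG p, `>` for interaction score),
  matching their stated definitions.

## Limitations

* Gene identifiers are case-sensitive symbols; no alias resolution.
* One ontology namespace per run; no evidence-code filtering, no GO-slim
  mapping, no term-redundancy trimming.
* The enrichment is overlap-based (hypergeometric), not rank-based (no
  GSEA).
* No network drawing; exports target external viewers.
* Normalization of raw data (RMA, FPKM computation) is upstream of this
  package: it consumes already-normalized matrices.
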