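---
title: "Consolidating redundant pathway collections into SuperPaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating redundant pathway collections into SuperPaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Multi-source pathway corpora are redundant: independent curators describe
the same biological process with overlapping but non-identical gene sets,
under names whose similarity is a poor guide to content. `superpathr`
consolidates a corpus by clustering on gene content alone. A pathway is a
set of gene symbols; topology and small molecules are deliberately ignored
(most sources provide only the gene roster, and gene-content overlap is a
good proxy for more elaborate alignment). Pathway similarity is the Jaccard
coefficient *J* = |intersection| / |union|.

Clustering proceeds in four edge-generating stages whose union's connected
components are the SuperPaths:

* **absorption**: a pathway under `small_max = 20` genes is linked to every
  pathway that has at least as many but fewer than `large_max = 200` genes
  and contains at least `c_min = 0.9` of it. Jaccard punishes size mismatch,
  so a 12-gene pathway wholly inside a 150-gene one would otherwise never
  connect; the cap at 200 stops hub-like giants from absorbing everything.
* **identical sets**: exactly equal gene sets are joined outright, and are
  excluded as nearest-neighbor candidates (otherwise mutual best edges
  between duplicates would satisfy the rule vacuously).
* **cores at T₂**: all pairs with *J* ≥ T₂, i.e. single-linkage merging at
  the upper cutoff.
* **best edges at T₁**: each pathway joins its highest-scoring
  non-identical neighbor(s) if that score reaches the lower cutoff; ties
  all join. This nearest-neighbor step lets moderately similar satellites
  attach to a core without transitively chaining everything the way a low
  global cutoff would.

Both directions matter: pure single linkage at a low threshold produces one
enormous component (uninformative annotation), at a high threshold it
strands near-duplicates. The hybrid keeps clusters compact but complete.

### Determinism and tie-breaking

The result is independent of input order: edges are defined set-wise, never
"first match wins". Remaining ties are resolved by explicit rules — cluster
ids are assigned by the lexicographically smallest member id; the hub (the
member with the largest intra-cluster degree, which names the SuperPath) is
tie-broken toward the larger gene set and then the smallest id. Absorption
and identical-set edges count toward hub degree by default (they are real
co-membership evidence); `hub_edges = "similarity"` restricts degree to
core/best edges. Equality of best scores is exact floating-point equality,
which is safe because equal rationals computed by one division are equal
doubles. A small pathway absorbs into *all* qualifying larger partners, not
one of them; choosing a single partner would need an arbitrary tie rule and
break order independence. Absorption adds connectivity only — the small
pathway remains a member and keeps contributing to support counts.

## Threshold selection

Uniqueness of a SuperPath *s* with gene union *G(s)*:

U(s) = log₁₀( mean over g in G(s) of 1 / N(g) ),

where N(g) counts SuperPaths whose union contains *g*. Informativeness of a
gene *g*:

I(g) = log₁₀( mean over the SuperPaths s containing g of 1 / |G(s)| ).

Both are ≤ 0. U(s) = 0 exactly when every gene of *s* occurs nowhere else;
it falls as redundancy persists. I(g) is −1 for a gene annotated by a single
10-gene SuperPath and tends to log₁₀(1/|universe|) when everything merges
into one cluster. Aggregation uses unweighted means (U_S over SuperPaths,
I_S over annotated genes); log-mean aggregation of reciprocals admits
several algebraically similar readings, and this one is used because it
reproduces the limiting behaviors just described — consolidation raises
U_S, overgrowth drives I_S down — which is what makes the two antagonistic
and their sum a usable objective. Merging any two clusters can only raise
U_S and can only lower I_S (asserted by a property test), so maximizing
U_S + I_S genuinely trades redundancy removal against annotation
specificity. N(g) is counted against SuperPaths, not input pathways:
counting input pathways would make U_S blind to the clustering it is
supposed to score.

`grid_search()` scores every admissible (T₁, T₂) pair, default step 0.1 on
(0, 1]; the T₁ = T₂ diagonal is pure single-linkage clustering. Argmax ties
are broken toward the largest thresholds, i.e. the least-merged optimum.

`stability_scan()` fine-tunes T₂ by dilution resampling: cluster the full
corpus, then repeatedly recluster random subsets (default dilutions 0.75 and
0.9, default 100 replicates; 25 is plenty for routine use and is what the
test suite runs) and measure the fraction of full-data co-cluster pairs,
restricted to the sampled pathways, that are recovered. Replicates with no
restricted pairs are skipped and counted in `n_skipped`; recovery at
dilution 1.0 is identically 1; the standard deviation uses the sample
(n − 1) formula; per-replicate ratios are averaged rather than pooling pairs
across replicates, so each replicate contributes equally. Everything is
reproducible from one integer seed.

## Name similarity

Name/content concordance uses the Jaccard of stemmed token sets: names are
lower-cased, split on non-alphanumeric runs, stripped of single characters
and stopwords, and stemmed with a Porter-style English stemmer implemented
in the package. The default stopword list holds only articles, prepositions
and conjunctions; domain words like "pathway" and "signaling" are kept
because they carry weak but real signal, and the list is a plain argument
for anyone who disagrees. Two empty token sets score 0, not 1 — no evidence
is not evidence of similarity. Because any stopword list and stemmer
convention is somewhat arbitrary, concordance tables on real corpora should
be read qualitatively; the package's quantitative claims about concordance
percentages are computed from fixed published contingency counts, not from
a re-tokenization.

## Evaluation statistics

`novel_gene_pairs()` extracts the pairs that consolidation creates: pairs
inside some SuperPath union but inside no single pathway.
`pseudo_superpaths()` builds the null: for each SuperPath, a uniform random
gene set of identical size from the annotated universe, with member pathway
sizes mirrored inside it, so the novel-pair extraction is well defined on
the control. `ks_compare()` downsizes the control to the test size and runs
a one-sided two-sample KS test of "test stochastically greater" (in R's
convention, `alternative = "less"`; the orientation was checked by
simulation). Fold-ratio readouts per histogram bin substitute a pseudo-count
of 1 for empty control bins. With count data the KS test faces heavy ties
and uses the asymptotic approximation, which is conservative — acceptable
here because it only understates significance. At desk scale the pseudo
control can come out *smaller* than the test set (the pseudo-sets mirror
the real size profile exactly), in which case `evidence_enrichment_test()`
downsamples the test side instead, seeded.

Over-representation uses the hypergeometric upper tail (`ora_pvalue()`),
the standard one-sided Fisher form. `enrichment_delta()` compares
−log₁₀ *p* of a SuperPath union against the mean across its constituents;
the comparison cohort (`comparison_cohort()`) is SuperPaths with exactly
two members of pairwise *J* below 0.6 — dissimilar constituents are where a
union can genuinely outperform. No multiple-testing correction is applied
across queries: the deltas are paired per-query differences, not a
discovery screen.

## The synthetic corpus generator

`generate_collection()` plants base modules (gene sets) in a universe and
ships each through pseudo-sources as variants: every module gene kept with
`keep_rate`, background genes admixed at `noise_rate` (as a fraction of
module size), names drawn from a module-specific word pool plus
source-specific decorations so that name similarity correlates imperfectly
with content. Unplanted noise pathways are added on top. The full argument
list including the seed is echoed into the truth object, and
`regenerate_collection()` rebuilds the corpus bit-for-bit from that echo.

Three presets define the study conditions used throughout the tests:

* `clean` — keep rate 0.8, noise 0.05, 10 disjoint modules, 2–4 variants:
  a well-curated corpus. Here the grid optimum recovers the planted
  partition essentially perfectly (adjusted Rand ≥ 0.9 is the acceptance
  bar), which validates correctness, not difficulty.
* `heterogeneous` — keep rate 0.65, noise 0.1, chained modules sharing half
  their genes, 3–6 variants: pairwise similarities straddle both cutoffs,
  which is what makes threshold choice (and the stability scan's interior
  optimum in T₂) meaningful. On corpora this small the recovery curve
  saturates near 1, so the test asserts the peak's interiority on
  seed-averaged curves and its consistency across dilutions rather than an
  exact argmax.
* `power` — exactly two variants per module, keep rate 0.7, noise 0.02:
  the evidence-power design. Consolidation-created pairs are then
  overwhelmingly module-internal, i.e. exactly the pairs whose planted
  evidence is elevated. With admixed background genes (as in `clean`) the
  novel-pair set is diluted by pairs that are unrelated *by construction*,
  and no amount of evidence multiplier makes those informative — a
  generator property, not a method failure.

`generate_pair_evidence()` draws shared-publication counts from a negative
binomial (over-dispersed, mimicking the heavy tail of real literature
counts; dispersion is an argument) with the mean multiplied for
within-module pairs, and PPI scores from Beta distributions with a
within-module upward shift; zero/negligible entries are omitted since
absent pairs score 0. With `signal_multiplier = 1` within-module pairs are
indistinguishable from background, which is the null used to calibrate the
KS readout (the acceptance run checks p > 0.05 in ≥ 90% of 50 replicate
evidence tables). What the generator does *not* emulate: hierarchical
source structure (parent/child pathways within one source), source-specific
curation styles, and correlated evidence noise (hub genes accumulating
publications regardless of pathway membership). Passing tests therefore
demonstrate algorithmic correctness and calibration under planted
structure, not performance guarantees on any particular real corpus.

## Numerical and interface choices

* Gene sets are compared exactly; identity means set equality, which
  coincides with *J* = 1 (integer intersection equals integer union).
* The similarity graph is built through an inverted gene-to-pathway index;
  disjoint pairs are never enumerated, and the graph stores only weights at
  or above its `j_min`. A graph reused across thresholds must satisfy
  `j_min ≤ T₁`, which the functions enforce.
* Per-source size standard deviation defaults to the population formula
  (divisor n), with `sd_type = "sample"` available.
* GMT is the exchange format; the description field carries
  `"source|name"` because plain GMT has no source column and the method is
  multi-source by nature. Inputs are assumed pre-symbolized; only optional
  upper-casing is offered. Duplicate gene symbols within a line collapse;
  duplicate pathway ids are an error; pathways identical in content are
  *not* deduplicated at load — identity handling belongs to the clustering.
* Test-suite problem sizes: corpora of 38–60 pathways over universes of
  250–1200 genes, grids at step 0.1, 25 stability replicates, 50-replicate
  null calibrations. These sizes were chosen so the whole suite exercises
  every stage end to end in about a minute while keeping every stochastic
  assertion comfortably inside its noise margin.

## Known limitations

* All-pairs statistics (`name_content_contingency()`) are quadratic in the
  number of pathways; fine for thousands, unwise for millions.
* Per-source "% of singletons" style summaries are not reproduced: the
  quantity is ambiguous (singleton SuperPaths per source? source-unique
  genes?) and no behavior here depends on resolving it.
* Best-edge search is applied to every pathway, including members of T₂
  cores; their best edges land inside their component or legitimately
  extend it, so this is harmless, but it is a convention, not a theorem
  about the only possible reading.
* De novo naming, hierarchical SuperPath nesting and topological pathway
  alignment are out of scope; hub naming is the only naming offered.
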