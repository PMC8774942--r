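---
title: "From cohort exomes to a candidate-gene interaction subnetwork: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From cohort exomes to a candidate-gene interaction subnetwork: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affnet)
```

## The problem

Atypical femoral fractures (AFF) are rare fragility fractures of the
subtrochanteric femur associated with long-term bisphosphonate (BP) therapy.
A candidate-gene view of AFF susceptibility starts from whole-exome
sequencing of a small case series (here the design is 12 BP-treated cases and
4 BP-treated, fracture-free controls), filters each patient's variant calls
down to rare, well-supported, predicted-damaging protein changes, asks which
genes recur across unrelated patients, and then places the recurrent
bone-related genes on an integrated protein-interaction network to see how
they talk to each other. `affnet` implements that chain as a set of small,
separately testable stages, together with synthetic-data generators that
plant a known truth through every stage.

## The variant filter cascade

A call enters as a per-sample observation with read depth (DP), genotype
quality (GQ), consequence class, ExAC and CSVS population frequencies,
SIFT/PolyPhen(HumDiv) calls and a CADD phred score. The cascade applies:

1. **Control subtraction** — any case variant whose (chrom, pos, ref, alt)
   identity was called in any control, at any zygosity, is removed. Identity
   is exact-match on pre-normalised alleles; the package performs no
   left-alignment and rejects multi-allelic records, so inputs must arrive
   decomposed.
2. **Quality** — DP ≥ 10 and GQ ≥ 30, both inclusive; a call with missing DP
   or GQ fails (quality must be demonstrated).
3. **Consequence** — synonymous changes are removed.
4. **Rarity** — each panel frequency must be ≤ 0.005 *or absent*. An allele
   a reference panel has never seen is rare, not common; mapping absence to
   zero would be wrong in the other direction for the panel-specific CSVS
   resource, which simply lacks many alleles. We adopt the inclusive ≤ 0.005
   boundary and expose it as configuration.
5. **Prioritization** — exclusion is a *disjunction*: CADD < 20 (when
   scored), or SIFT "tolerated", or PolyPhen "benign" each suffices to drop
   a call. "Possibly damaging" is retained. The disjunctive reading is fixed
   by the worked DAAM2 p.(K776T) example: a variant with damaging PolyPhen
   and CADD but a tolerated SIFT call must fall. Absent predictions pass by
   default (`missing_prediction_policy = "pass"`) because truncating
   variants are often unscored by SIFT/PolyPhen; the strict policy is
   available.

Stages 2–4 (and 5) are pure per-call predicates, so they commute; the fixed
order exists only to give the stage-count report a stable meaning. The suite
property-tests commutation, idempotence and threshold monotonicity on
randomized tables against an independent row-by-row predicate scan.

## Recurrence across cases

Surviving calls are aggregated per gene. A **carrier** is a distinct case
with at least one qualifying call in the gene — a patient carrying two LRP5
variants counts once (yielding the "4 variants (3 carriers)" shape), and a
homozygote counts once with a separate homozygote tally (the
"3 (3, one homoz)" shape). Categories follow the published tabulation:
more than two carriers; exactly two carriers sharing one identical variant;
exactly two carriers with different variants; singletons. A gene with two
carriers is classified by the shared variant when one exists; the
`shared_variant` flag is carried separately so either the shared-variant or
same-gene-different-variant view can be reconstructed. Neither count
inequality holds in general — shared variants give more carriers than
variants, multi-variant carriers the reverse — and the tests exercise both
directions.

The packaged transcription of the published recurrence table sums to 270
variants while the source text reports 272; the per-category arithmetic
discrepancy is in the source itself, so the fixture preserves the printed
per-gene counts verbatim and documents, rather than resolves, the gap.

## Gene-set operations

Gene sets are case-insensitively unique, deterministically ordered symbol
collections with intersection/union/difference. Candidate selection is the
intersection of the recurrent genes with a bone-metabolism/AFF literature
list. The packaged bone list is a *fixture*: it is reverse-assembled from
the published candidate table plus canonical bone-biology genes
deliberately absent from the recurrence table, so the intersection is
well-defined for tests; it is not a faithful reconstruction of the cited
literature lists. Likewise the prior-study (3-sisters) 34-gene list and the
full mutated-gene list ship only as synthetic stand-ins with the published
overlap structure planted (9 shared genes, 4 of them damaging).

Enrichment is the hypergeometric upper tail $P(X \ge k)$ with parameters
$(N, K, n)$ via `stats::phyper`, Benjamini–Hochberg adjusted across terms
(`stats::p.adjust`). The published workflow used external Cytoscape apps for
this step; a transparent hypergeometric test is the package's replacement,
and the BH choice (the apps report only "adjusted" scores) is configurable.
Tests pin the p-values to exhaustive probability-mass enumeration for all
universes up to $N = 20$ at $10^{-12}$.

## Skeleton extraction on the interactome

Edge lists (BioGRID-tab-like, STRING-link-like dialects) are integrated into
a directed graph in which every undirected interaction is stored as both
arcs — the representation that makes pairwise shortest-path machinery
uniform. Duplicate edges across sources merge with provenance union;
self-loops are dropped. Weights default to 1 per arc (the source procedure
mentions none); an optional STRING mode uses $1 - \text{score}/1000$ clamped
to $[0.001, 1]$ so high-confidence interactions are shorter.

For every unordered pair of seed genes, single-source Dijkstra runs with
full predecessor sets. "All possible pair-wise shortest paths" is read as:
all unordered seed pairs and, by default, **all tied minimum paths per
pair**, collected by traversing the shortest-path predecessor DAG
(`ties = "all"`); `ties = "one"` reproduces the classic single-path reading
with a lexicographic tie-break, and its output is always a subgraph of the
tie-union. Both readings are exposed because the original implementation's
behaviour is not documented. Tied-path counts come from the standard DP over
the predecessor DAG in distance order. Tie detection uses an absolute
tolerance of $10^{-9}$ on path weights, which is exact for unit weights and
safe for the clamped STRING weights at realistic graph diameters. Seeds
missing from the graph are reported and skipped; disconnected or
beyond-`max_len` pairs land in `unreachable_pairs`.

The `direct_subnet` view — only seed genes and the edges among them, with
isolated seeds listed — corresponds to the simplified published display;
the skeleton with intermediates is the full view. Node annotation maps the
gnomAD-style observed/expected LoF ratio, clamped to $[0, 2]$, linearly onto
a node-size range (constrained genes draw small; unannotated nodes take the
midpoint), carries a constraint-outlier flag and border class, and fills
nodes from the expression overlay. Export formats are GraphML (lossless
round-trip via igraph), SIF, and a Cytoscape-JS elements JSON.

Correctness rests on oracle equivalence: distances against igraph (an
independent implementation) and Floyd–Warshall on graphs up to 200 nodes;
tie unions against exhaustive simple-path enumeration on graphs up to 12
nodes; and exhaustively checked minimality — removing any non-seed skeleton
node lengthens some seed-pair distance or destroys a tied geodesic.

## Expression overlay

The overlay emulates a two-group osteoclast-precursor contrast (BP-treated
vs untreated). Intensities are `log2(x + 1)`-transformed unless flagged
logged. Per gene, the log2 fold change is the treated-minus-untreated mean
difference, with a pooled variance $s^2$ on $d = n_1 + n_2 - 2$ degrees of
freedom. With moderation, gene variances shrink toward a prior,
$s^2_{\text{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$, and the moderated $t$
uses $d_0 + d$ degrees of freedom. The hyperparameters $(d_0, s_0^2)$ are
estimated by the method of moments on $\log s^2$: under the scaled-inverse-
chi-square model, $\operatorname{Var}[\log s^2] = \psi'(d/2) + \psi'(d_0/2)$
and the trigamma equation is inverted by Newton's method; when the observed
spread does not exceed $\psi'(d/2)$ the variances are consistent with a
single common value and $d_0 = \infty$ (all genes share $s_0^2$). This
empirical-Bayes machinery is implemented in the package; the limma package
serves in the test suite as an independent cross-check, where the two agree
to numerical precision.

The overlay colour ramps linearly in RGB from yellow (logFC 0) to red at
+cap and to dark blue (#00008B) at −cap, clamping outside and mapping
missing values to grey. The cap defaults to ±1 log2 unit. The scale encodes
fold change, not a statistic: the display semantics speak of over/under-
expression, and fold change is the quantity with those units.

## Synthetic data and what passing tests mean

The generators define the study conditions. The cohort generator defaults to
12 cases and 4 controls at a 140× mean depth, planting recurrent genes of
every category — including one LRP5-shaped gene (4 variants, 3 carriers,
one carrier with two) and one DAAM2-shaped gene (3 carriers, one homozygous,
plus a fourth carrier whose SIFT-tolerated variant must fall at
prioritization) — singletons, and, per failure mode, variants that each fail
exactly one stage (low DP, low GQ, synonymous, common in either panel,
present in a control, low CADD, tolerated, benign). Passing calls draw
Poisson(140) depth floored at 10, GQ in 30–99, mostly missense
consequences, panel frequencies below 0.005 or absent, and CADD in 20–45.
The interactome generator joins every seed pair by a unique planted geodesic
through fresh intermediates and confines random background edges to filler
nodes that touch neither seeds nor intermediates, so no background edge can
shortcut or tie a planted path; construction is re-verified at generation
time by re-running shortest paths. The expression generator draws gene
variances from the scaled-inverse-chi-square prior the moderation assumes
(defaults $d_0 = 4$, $s_0^2 = 0.25$, 5 samples per group, log2 baselines
uniform on 4–12).

Each generator consumes its own RNG stream derived from the base seed, so
reconfiguring one component does not perturb the others, and reruns are
byte-identical under a fixed seed.

These fixtures establish that the *machinery* is exact: filter logic,
counting, set algebra and path extraction recover planted truth perfectly.
They do not establish robustness to what real data add — annotation
versioning and symbol drift, mis-normalised indels, population stratification
in frequency panels, correlated expression noise, or the scale and topology
of a real interactome (tens of thousands of nodes, heavy-tailed degrees).
The headline counts of the motivating cohort (1006 variants in 455 genes,
272 in 132 after prioritization) derive from patient exomes that are not
public and are therefore *inputs* here, shipped as transcriptions, not
quantities the package can recompute.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately small
scales, chosen as the smallest sizes at which each property is
discriminating: graphs up to 200 nodes for distance oracles and up to 12
nodes for exhaustive path enumeration; 50 planted-interactome instances;
1,000–2,000 genes for expression recovery (planted logFC 2, sd 0.5, 5+5
samples — sign recovery ≥ 99% and mean logFC within ±0.15 follow from the
per-gene standard error of 0.32 averaged over 1,000 genes); exhaustive
hypergeometric enumeration for all $N \le 20$. Determinism everywhere:
lexicographic (C-locale) ordering for symbols, nodes and tie-breaks; no
randomness outside the generators.

## Known limitations

* Gene identity is symbol-based (case-insensitive); cross-namespace mapping
  is out of scope beyond a two-column alias file at the reader level.
* DP/GQ are applied per sample-observation; a site-level reading of the
  original pipeline cannot be ruled out, and per-sample is the stricter,
  better-defined choice.
* Whether CSVS absence was distinguished from frequency 0 originally is
  unknown; both are treated as rare here.
* The direct-interaction figure of the motivating study cannot be
  reproduced without the release-exact interactome; the package reproduces
  the *procedure* on declared inputs.
* No multi-factor expression designs; one treated-vs-untreated contrast.
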