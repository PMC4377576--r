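---
title: "Methods: scoring, screening and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, screening and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

`herbnet` chains four stages: compound→target likelihood scoring, herb-level
profiling, topological screening of the target network, and gene-set
over-representation. This vignette documents the model behind each stage,
the tunable parameters and their defaults, the design decisions taken where
the methodology is genuinely open, and what the synthetic-data generator
does and does not emulate.

## The concordance score

The scoring rests on two assumptions: (i) compounds with similar chemical
structure tend to bind functionally related proteins, and (ii) functional
relatedness of proteins can be proxied by their distance in a
protein–protein interaction (PPI) network. Both are heuristics: they hold
in aggregate across drug–target databases but fail for individual cases
(activity cliffs, sparse or biased interaction data).

For a query compound with fingerprint $q$ and a reference panel
$d_1,\dots,d_p$ ($p \ge 2$):

* chemical similarity: $\mathrm{CS}_i(q) = T(q, d_i)$, the Tanimoto
  coefficient on binary fingerprint bit sets (the field's standard choice
  for 2-D similarity; values in $[0,1]$; two empty fingerprints score 0
  with a warning rather than NaN);
* functional similarity of protein $g$:
  $\mathrm{FS}_i(g) = \sum_{t \in \mathrm{targets}(d_i)} K(\mathrm{dist}(g,t))$
  with the Gaussian-of-distance kernel $K(d) = e^{-d^2}$ on unweighted
  shortest-path distances. Unreachable targets contribute $K(\infty)=0$;
  targets absent from the network contribute 0 and are counted in the log.

The drug–target interaction likelihood is the Pearson correlation
$\mathrm{score}(q,g) = \mathrm{cor}(\mathrm{CS}(q), \mathrm{FS}(g))$. The
kernel is one fixed choice among many admissible ones; any strictly
decreasing kernel with $K(0)=1$ and $K(\infty)=0$ can be plugged in through
`gaussian_kernel(fn = ...)`, and on two-drug panels the ranking provably
depends only on the sign structure, not the kernel shape (a property the
test suite exercises). The kernel's unit is "squared hops", so one hop
contributes $e^{-1}\approx0.37$ and two hops $e^{-4}\approx0.018$: the
score is dominated by the 1–2-hop neighbourhood, which matches the locality
assumption and keeps the proximity profile peaked rather than diffuse.

Degenerate cases are flagged, not fatal: if either vector is constant
(e.g. a protein in a component that contains no panel target) the
correlation is undefined, the score is `NA`, and the protein ranks last.
Rankings are sorted by score descending with ties broken by symbol, after
snapping scores to 10 decimals — analytically tied scores (a two-point
correlation is exactly $\pm 1$) would otherwise be separated by
floating-point noise and make runs irreproducible across BLAS builds.

## Herb profiles and the putative target space

Per-herb target profiles keep the top $k$ proteins (default
$k = 100$, the depth at which this family of methods is usually
benchmarked) under **max-aggregation**: a protein's herb-level score is the
maximum over the herb's compounds. The aggregation rule is this package's
choice — the methodology literature does not fix one — and max is the most
permissive option: one strong compound suffices, which fits the
multi-compound formula setting but inflates profiles of compound-rich herbs
relative to mean-aggregation. Profiles feed the herb-overlap reports
(`profile_overlap_matrix()`, `common_targets()`,
`overlap_with_drug_targets()`, which reports the shared symbols and
$100\times|\mathrm{overlap}|/|\mathrm{putative}|$ to two decimals).

The **putative target space** of the pipeline is the full ranked proteome
(optionally restricted to a supplied druggable list), not the profile
union: published analyses of this kind rank a druggable proteome and treat
all of it as the putative-target table, and the overlap percentages they
print use that denominator. Consequently, when no druggable list is given,
every network protein is putative and the candidate set equals the
major-hub set.

## Topological screening

On the induced subgraph of the PPI network over putative ∪ known disease
targets (isolated members kept as degree-0 nodes):

* **hubs**: degree strictly greater than $2\times$ the median degree of all
  nodes. A strict inequality means regular graphs have no hubs and
  degree-0 nodes never qualify.
* **major hubs**: on the hub subnetwork, recompute degree, node
  betweenness, closeness and the k-core index, and keep hubs strictly above
  the median of all four. Medians are taken over the hub subnetwork (the
  published wording points to hubs-only medians; this is flagged as an
  interpretation, not a documented procedure).
* **candidates**: major hubs ∩ putative targets.

Normalisation choices (the published scales are not defined; screening is
invariant under any strictly increasing per-feature rescaling, which the
tests verify): betweenness is divided by $(n_c-1)(n_c-2)/2$ with $n_c$ the
node's component size (0 when $n_c<3$); closeness is
$(\text{reachable}-1)/\text{farness}$ within the component, reported
$\times 100$; the k-core index is the largest $k$ surviving recursive
deletion of degree-$<k$ vertices. The closeness form is the per-component
ratio rather than the fully size-corrected variant (the two coincide on
connected graphs, and the screen is scale-invariant either way). All four
features are checked exactly against brute-force oracles (path enumeration,
exhaustive peeling) on random small graphs.

## Enrichment

`enrich()` is a one-sided hypergeometric over-representation test
(equivalently Fisher's exact, greater), the default family of the common
annotation servers. The universe defaults to all PPI nodes and is
overridable; sets and query are intersected with the universe first, and
out-of-universe query symbols are dropped with a logged count. Bonferroni
multiplicity is the number of sets with a non-empty universe intersection.
The EASE penalisation (testing $k-1$) is available behind `ease = TRUE` but
off by default. Tail probabilities use the stable log-space routine of
`phyper`; tests compare them with direct probability-mass summation for
every case with universe size up to 30.

The test suite also checks null calibration: with a fixed collection
(universe 5000, 100 sets of 50–500 genes) and uniformly random queries of
250 genes, the fraction of raw p-values below 0.05 must sit in
$0.05 \pm 0.02$. The collection dimensions were chosen analytically so
that the discrete test can achieve a level near 0.05 (the expected rate for
this design is 0.039; much smaller sets or queries make the test so
discrete that the achievable level collapses).

## The synthetic study design

`synthetic_config(preset = "paper_scale")` generates a study of the scale
of a five-herb formula analysis: 5 herbs with 22/122/39/65/203 compounds
(451 total), 1746 proteins, a 100-drug reference panel with 3 targets per
drug, 208 disease targets, 50 gene sets of 10–100 genes. One root seed
spawns fixed per-stage substreams, so the bundle is a pure function of the
configuration and changing, say, `n_gene_sets` does not perturb the
network.

The generator encodes, as planted ground truth, exactly the structure the
analysis assumes — that is its purpose, and what "passing" means should be
read accordingly:

* **Network.** The paper-scale PPI is a 16-block stochastic block model
  whose within-block densities follow a geometric gradient (0.02→0.35,
  between-block 0.004). Functional modules of heterogeneous density are
  what merged interaction databases look like, and the gradient gives the
  network a layered k-core structure; a preferential-attachment graph, by
  contrast, has near-constant coreness (almost every node sits in the
  $m$-core), which makes a k-core screen degenerate. A scale-free
  generator (`ppi_model = "scale-free"`) is available and is the default
  for small ad-hoc configurations.
* **Drug target modules.** Each panel drug gets a module: a seed node plus
  `target_module_size - 1` of its neighbours, so module members are
  pairwise within distance 2 ("functional relatedness as network
  locality"). Seeds are drawn from the top-decile-degree nodes with
  probability proportional to degree, and the seed is always one of the
  drug's targets: drug targets are empirically concentrated on
  well-connected, well-studied proteins, and this bias is the premise that
  makes hub screening meaningful at all.
* **Compounds.** Each compound is a noisy copy of one parent drug:
  every fingerprint bit flips independently with probability
  `bit_flip_rate` (default 0.05 on 256-bit fingerprints with expected
  on-bit density 0.1, i.e. a Tanimoto of roughly 0.6–0.7 to the parent
  against a background of ~0.05).
* **Disease targets.** A fraction `disease_module_overlap` (default 0.5)
  is drawn from the union of the planted drug target sets — mirroring
  disease-target lists compiled from drug–target and pathway databases —
  and the rest uniformly from the remaining proteome. The gene-set
  collection always contains the disease member set as the positive
  control `PLANTED_DISEASE`.

With these defaults the planted signal survives the full chain: parent-drug
targets outrank size-matched random sets for essentially all 451 compounds,
and `PLANTED_DISEASE` ranks first in the end-to-end enrichment of the
candidate targets (verified across many root seeds during design).

What the generator does **not** emulate: real chemistry (fingerprints are
abstract bit sets, no scaffolds or activity cliffs), literature bias and
false positives in PPI edges, identifier-mapping noise between databases,
promiscuous compounds binding several unrelated modules, and disease genes
that are *not* drug targets driving the screen. A pipeline that recovers
the planted structure here is internally consistent; that is necessary, not
sufficient, for it to recover biology from real snapshots.

## Problem sizes and runtime

The test suite runs brute-force comparisons on 100 random graphs of ≤ 8
nodes, exhaustive hypergeometric enumeration to universe size 30, a
1000-replicate calibration, and two full paper-scale runs; the whole suite
takes well under a minute on one CPU, and `scripts/acceptance.R` a few
seconds. Scoring a full catalogue is one BFS per distinct panel target
plus one correlation matrix (proteins × compounds), so paper scale is far
from any memory or time limit; the quadratic distance matrix in
`topology()` is the first thing to revisit for networks beyond ~10⁴ nodes.

## Known limitations

* Gene identifiers are case-normalised symbols; no cross-database identifier
  mapping is attempted, because no mapping procedure is documented for the
  merged sources this emulates.
* The compound→herb aggregation rule (max) and the hubs-only median scope
  are this package's documented choices where the methodology is silent.
* Printed headline numbers from database-snapshot-dependent analyses
  (e.g. specific major-hub counts or enrichment p-values from 2011–2013
  snapshots) are not reproducible from scratch and are treated as report
  fields, not targets.
* Edge provenance is carried as labels and never weights the analysis; an
  edge supported by eight databases counts exactly as much as one supported
  by a single database.
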