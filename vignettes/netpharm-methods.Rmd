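---
title: "Methods: screening, enrichment and network assembly in netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, enrichment and network assembly in netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## Scope and model

netpharm implements the standard systems-pharmacology workflow used to
dissect how a multi-herb formula acts on a disease through many compounds
and many protein targets at once. The pipeline is a chain of set- and
graph-valued operations:

1. **ADME screening.** Each herbal constituent carries three absorption/
   distribution-type scores: oral bioavailability (OB, the percentage of an
   oral dose reaching circulation unmodified), a drug-likeness index (DL)
   and a Caco-2 permeability score (a passive intestinal-transport model in
   which negative values indicate poor permeability). A compound is *active*
   iff OB &ge; 30%, DL &ge; 0.18 and Caco-2 &ge; 0 (all floors inclusive),
   or it is rescued by an explicit whitelist (compounds with established
   pharmacological activity that fail the desk screen, e.g. astragaloside IV
   or danshensu).
2. **Target mapping.** Compound&rarr;target interactions come from curated
   databases and from structure-based predictors; predicted edges are kept
   only when their prediction probability is *strictly* greater than 0.40.
   The target universe of the active compounds is intersected with a
   disease gene list; active compounds with no edge into that overlap are
   discarded.
3. **Over-representation analysis.** The overlap genes are tested against
   GO biological-process and pathway collections with the one-sided
   Fisher's exact test (hypergeometric upper tail), and sets are retained
   at Benjamini-Hochberg FDR *strictly* below 0.01.
4. **Network analytics.** The compound-target (C-T) and target-pathway
   (T-P) bipartite graphs are built over exactly the entities with at least
   one qualifying edge; degree is the sole importance measure.
5. **Pathway integration.** Retained pathways are assigned to therapeutic
   modules (proliferation / apoptosis / inflammation) through a declarative
   module configuration, and each target inherits the union of its adjacent
   pathways' labels.

## The drug-likeness index

DL is the Tanimoto similarity between a compound's molecular-descriptor
vector $A$ and the mean descriptor vector $B$ of a drug-like reference
database:

$$T(A,B) = \frac{A \cdot B}{\lVert A\rVert^2 + \lVert B\rVert^2 - A \cdot B}.$$

For non-negative vectors $T \in [0,1]$, is symmetric, and equals 1 iff
$A = B \ne 0$; two all-zero vectors return 0 by convention. Raw molecular
descriptors live on wildly different natural scales (molecular weight vs.
logP, say), and no normalization convention is universal, so netpharm
min-max scales every descriptor against the *reference set's* range before
applying the formula and clamps query compounds into $[0,1]$. Consequently
DL values depend on the reference set; database-reported `dl` columns are
therefore taken as-is by default and recomputation is opt-in. The
conventional 0.18 floor is itself a calibration — the mean DL of a
drug-like reference against its own profile — and
`reference_dl_threshold()` recomputes that calibration for any reference
table instead of treating 0.18 as universal truth.

```{r dl}
compute_dl(c(1, 2, 2), c(2, 1, 0))   # worked example: 4 / (9 + 5 - 4)
ref <- generate_reference_descriptor_set(200, 8, seed = 1)
round(reference_dl_threshold(ref)$threshold, 3)
```

## Tunable parameters

| parameter        | default | units    | comparison | meaning |
|------------------|---------|----------|------------|---------|
| `ob_min`         | 30      | percent  | `>=`       | oral bioavailability floor |
| `dl_min`         | 0.18    | unitless | `>=`       | drug-likeness floor |
| `caco2_min`      | 0       | unitless | `>=`       | Caco-2 permeability floor |
| `confidence_min` | 0.40    | probability | `>` (strict) | predicted-edge cut ("more than 40%") |
| `fdr_max`        | 0.01    | q-value  | `<` (strict) | enrichment retention |

The screening floors are inclusive (a compound at exactly 30 / 0.18 / 0
passes); the confidence and FDR cuts are strict. These polarities matter at
boundaries — oleanolic acid at OB 29.02 fails, a predicted edge at exactly
0.40 is dropped — and the tests pin them.

## Enrichment: test form, background and FDR

The over-representation p-value for a set with $K$ members in a universe of
$N$, a query of $n$ and an overlap of $k$ is the exact hypergeometric upper
tail $P(X \ge k)$, computed via `stats::phyper` (log-space stable) and
verified in the test suite against exhaustive enumeration of all draws for
every configuration with $N \le 12$. The plain overlap count $k$ is used —
not the EASE-style deflated $k-1$ used by some annotation servers; this is
a deliberate, documented divergence. The default background is the union of
all genes in the loaded collection (the annotation-background convention),
overridable per call or via the config; published background choices are
rarely stated, so the default is the reproducible one. FDR control is
Benjamini-Hochberg step-up (`stats::p.adjust`), again a specific choice
where published methods often say only "FDR"; results from servers using
other variants will differ accordingly.

## Network conventions

Bipartite graphs never contain isolated nodes: a compound or gene exists in
the C-T network iff it has a qualifying edge, which is why node counts
equal the sum of the retained compounds and overlap targets. Side mean
degrees are reported as edge count divided by side size to two decimals.
For a 677-edge network over 82 compounds and 146 targets this gives 8.26
edges per compound and a mean target degree of 4.64; note that published
narratives sometimes attach these two numbers to the opposite sides — only
this division reproduces both printed values, so netpharm fixes the side
assignment and documents the ambiguity rather than resolving it. Hub
rankings break degree ties lexicographically by node id so reports are
deterministic, and GraphML/SIF exports order nodes by (type, id) so
repeated exports are byte-identical.

## Pathway integration as declarative curation

Published pathway selection mixes an FDR filter with manual literature
curation. netpharm formalizes the manual step as a versioned
`module_config`: a mapping from pathway id to therapeutic-module labels.
Only pathways that are both FDR-retained and present in the config enter
the integrated disease pathway; retained-but-unassigned pathways are listed
explicitly. The default configuration encodes the nine canonical gastric
precancerous-lesion pathways — pathways in cancer (hsa05200), PI3K-Akt
(hsa04151), MAPK (hsa04010), Ras (hsa04014), FoxO (hsa04068), HIF-1
(hsa04066), TNF (hsa04668), p53 (hsa04115) and NF-kappa B (hsa04064) —
with hsa05200 spanning all three modules, MAPK shared between
proliferation and inflammation, and TNF between apoptosis and
inflammation. Target annotation is the union of adjacent pathway labels,
so adding a pathway edge can only ever add labels.

## What the synthetic generators emulate

`generate_paper_shape_fixture()` builds a complete input bundle shaped
like a six-herb formula study: per-herb compound tables of sizes
87/25/55/202/81/37 with 55 cross-herb duplicate memberships (432 unique
compounds, seeded with the 24 bundled representative constituents and
their database-reported ADME values), ADME distributions straddling the
screening floors so that exactly 88 compounds pass (20.37%), the
5-compound rescue whitelist (93 active), an edge list whose
confidence-filtered restriction to active compounds touches 306 targets,
a 1261-gene disease list with a 146-gene overlap, 11 target-less actives
(82 final), a 677-edge C-T network containing a degree-104 quercetin-like
hub, and GO/pathway collections with planted enrichment yielding 26 and
21 retained sets, the pathways covering 97 of the 146 targets with a
dominant set of in-overlap size 57. Every pinned count is realized by
explicit counting patterns (partitioning and cyclic tiling), not
rejection sampling, so generation is linear-time and exact; only
non-pinned quantities (the ADME spread, the disease-list order) are
sampled, under a single recorded seed. The fixture is validated by
running the *real* pipeline stages on the generated files, not by
construction bookkeeping.

What the fixture does **not** emulate: real chemical descriptor
correlations, real pathway topology or gene multi-functionality, database
noise (conflicting ADME entries, synonym collisions), or the literature
curation that removes disease-irrelevant pathways. Passing the fixture
therefore demonstrates that the pipeline machinery is correct and exactly
reproduces pinned stage counts on inputs of realistic shape — not that the
biological conclusions of any particular study are independently
re-derivable, which would require the era-specific database snapshots.

`generate_enrichment_scenario()` supplies stochastic ground truth for the
statistics: `n_planted` sets receive exactly `fold_enrichment` times their
expected-by-chance number of query members (drawn from genes exclusive to
each planted set so the truth record is exact), and the remaining query
genes are drawn from outside all planted sets. The defaults
(40 sets of 200 genes over a 5000-gene universe, query 50, 4 planted sets)
were chosen so that the expected-by-chance overlap is 2: at fold 5 a
planted set carries 10 query genes, deep enough in the tail that recovery
at FDR < 0.01 is essentially certain, while null sets stay at chance
level. With 100-gene sets the expected overlap would be 1 and a fold-5
planting (5 genes, p &asymp; 0.004) cannot clear a strict 0.01 FDR after
multiplicity adjustment across ~40 tested sets — a useful reminder that
"fold enrichment" alone does not determine detectability; set size and
universe size enter through the tail.

## Numerical choices and degenerate inputs

* Parenthesized negatives in ADME columns (`(2.22)`) are parsed as
  negative numbers, matching database-export conventions.
* Duplicate compound records across herbs must agree in ADME values to
  within 1e-9 (they originate from one database); disagreement is an error,
  not a silent average.
* Duplicate compound-target pairs collapse keeping the maximum confidence;
  a curated duplicate wins over a predicted one.
* Min-max scaling of a descriptor that is constant over the reference set
  maps to 0 with a warning; values outside the reference range clamp to
  [0, 1].
* `compute_dl` of two all-zero vectors is 0; `hypergeometric_tail(0, ...)`
  is exactly 1; BH on an empty vector is empty.
* An empty disease list or empty edge list produces a warning and a valid
  degenerate run (0 final compounds, empty networks), never a crash; a
  failing stage writes a `FAILED` marker naming the stage.

## Problem sizes used in validation

The statistical suites run at desk scale chosen once: the null
calibration uses 500 replicate random queries against a fixed 40-set
collection (asserting the retained fraction at FDR < 0.01 stays within
0.01 + 3 standard errors); planted-set recovery uses 200 replicates at
fold 5 (and 60 at fold 3 with 500-gene sets), asserting &ge; 95%
recovery; the hypergeometric tail is checked against exhaustive
enumeration for every configuration with a universe of 12 or fewer genes.
The fixture pipeline itself runs in seconds.

## Known limitations

* OB, Caco-2 and target-prediction scores are consumed as inputs; the
  upstream predictors are out of scope, as are live database clients.
* Gene identity is the uppercased symbol string; identifier mapping is
  assumed done upstream (accessions are carried as annotation only).
* No GO-DAG ancestry propagation, pathway topology, or centrality measures
  beyond degree.
* Headline counts from published studies depend on database snapshots and
  are reproduced here only through the engineered fixture, with the two
  genuinely snapshot-independent checks (the Tanimoto worked example and
  the 24-row representative screen) asserted directly.
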