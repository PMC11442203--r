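---
title: "Cellular function fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular function fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfp)
library(dplyr)
```

## The problem

Multi-component preparations (traditional Chinese medicines among them)
act through many compounds, each hitting many protein targets. A useful
way to ask "which marketed drugs does this preparation resemble?" is to
compare compounds not by chemical structure but by the *cellular
functions* their targets participate in. `cellfp` implements that
comparison as a pipeline over a compound-target-pathway heterogeneous
network:

1. build a tripartite network from predicted compound-target
   interactions (confidence-scored) and target-to-function-term
   annotations (GO biological process, Reactome, KEGG, WikiPathways);
2. summarize each compound as a **cellular function fingerprint** — its
   profile over function terms reachable through its targets — and
   score every compound pair with **PathSim** meta-path similarity;
3. cluster all compounds hierarchically on the fingerprint distance and
   cut the tree into mechanism groups;
4. screen, per indication, the comparator drugs whose distance to at
   least one preparation component falls strictly below a threshold
   (by default the global median cross distance);
5. quantify how much of each indication's pharmacology the preparation
   spans (ATC-code, GO-term, drug and cluster-group coverage, plus a
   combined ratio);
6. transfer mechanism annotations (ATC codes, shared GO terms) from
   each component's most similar drug, and call the regulation
   direction of drugs on the shared biological processes from
   expression z-score signatures.

## The similarity model

For the symmetric meta-path compound → target → term → target →
compound, let $M$ be the compound-by-term matrix with
$M_{cp} = |\{t : (c,t) \in E_{CT},\ (t,p) \in E_{TP}\}|$, the number of
distinct targets linking compound $c$ to term $p$. The meta-path count
matrix is $P = M M^\top$ and PathSim is

$$s(x, y) = \frac{2\,P_{xy}}{P_{xx} + P_{yy}}, \qquad
  d(x, y) = 1 - s(x, y).$$

$s$ lies in $[0,1]$, equals 1 on the diagonal for any compound with at
least one compound-target-term path, and rewards pairs whose *shared*
path mass is large relative to their own connectivity — a compound with
a huge promiscuous fingerprint is not automatically similar to
everything.

Two fingerprint readings are supported. `mode = "count"` (the default)
uses true path counts, so a term reachable through three targets weighs
more than one reachable through one. `mode = "binary"` reduces the
fingerprint to term presence/absence, a set-based reading of "pathway
fingerprint". Whether count or incidence profiles are the better
operationalization is genuinely open; results should state the mode
used, and both are first-class here. Compounds with *no* path at all
carry no fingerprint information: they receive similarity 0 to
everything (including themselves, avoiding 0/0) and are flagged, which
mirrors their exclusion from downstream screens.

All annotation sources are pooled into one fingerprint by default; a
`sources` filter produces per-source fingerprints when wanted.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 20 | strict (`>`) cutoff on compound-target prediction confidence. Prediction services publish scores on an arbitrary scale; 20 is a conservative operating point and 10 a looser one that admits more targets. Both appear in practice, so this is a config key, never hard-coded. |
| `linkage` | complete | agglomeration rule for `hclust`; complete linkage is that function's own default and gives compact groups. |
| `k_main` | 16 | number of groups the compound tree is cut into. No principled automatic choice is attempted (see Non-goals); pick by inspecting the dendrogram. |
| `k_filter` | off | cut used by the drug-library consistency filter; drugs in groups smaller than `min_cosize` (default 2) are removed. The filter is defined qualitatively ("not under the same branch as any other drug"), so it is operationalized as singleton removal at a configured cut. |
| `atc_level` | 3 | ATC truncation level for code comparison. Level 3 (pharmacological subgroup, e.g. `M01A`) matches the granularity of "pharmacological category" talk; levels 1–5 are available. |
| `threshold_mode` | global_median | the similar-drug screen threshold: the median over all component-drug cross distances, computed once globally (a single published operating point), with strict `<` at the boundary. A fixed threshold (e.g. a previously published median such as 0.53) is available via `fixed_threshold`. |
| `similarity_floor` | 0.5 | minimum similarity for a component-drug "most similar" pairing to be reported. |
| `tau` | 0.5 | direction-call threshold on the mean signature z-score over a term's genes. Scores above `+tau` call "up", below `-tau` "down", else "flat". |
| `min_overlap` | 3 | minimum genes shared between a signature and a term to score at all; below it the result is a *no-call*, reported distinctly from "flat". |

## Coverage statistics

For an indication treated by $D$ marketed drugs carrying $N$ distinct
(truncated) ATC codes and reaching $M$ distinct function terms, with
the drugs occupying $G$ cluster groups:

- **ATC coverage** $n/N$: predicted component ATC codes intersected
  with the indication's codes;
- **GO term coverage** $m/M$: predicted component terms intersected
  with the indication's term reach;
- **drug coverage** $d/D$: indication drugs that screened as similar;
- **group coverage** $g/G$: cluster groups containing at least one
  similar drug;
- **CombinedRatio** $= (n/N + m/M + d/D)/3$.

The canonical worked example — 32 drugs for one indication in 7 cluster
groups, 23 similar at the 0.53 screen — gives drug coverage
$23/32 = 0.72$ and group coverage $7/7 = 1$. Published summaries
sometimes label the $7/7$ ratio "GO term coverage" although it is
arithmetically the cluster-group ratio; this package computes **both**
$m/M$ and $g/G$ and reports them side by side under unambiguous names,
preferring neither silently.

```{r worked-example}
fx <- worked_example_fixture()
run <- run_pipeline(
  fx$network, fx$indications,
  pipeline_config(k_main = fx$k, threshold_mode = "fixed",
                  fixed_threshold = fx$threshold))
tidy(run) |> select(indication_id, d, D, g, G, drug_coverage, group_coverage)
```

## Mechanism transfer and direction calls

Each component's most similar drug (argmax similarity above the floor,
ties to the lexicographically smallest drug id) lends it two things:
its ATC codes (truncated to `atc_level`) and the GO terms the two
compounds *share* — the intersection of their fingerprint supports,
which is exactly the set of terms sitting on a meta-path joining them.
"Common biological processes" generalize this to sets: terms reachable
from at least one similar drug and at least one component.

The direction of a drug on a process is scored as the mean of its
signature z-scores over the process's genes. The scoring rule for
signature data is not prescribed anywhere authoritative, so the mean
was chosen for transparency: it is linear (so sign antisymmetry is
exact), its sampling error is $\sigma/\sqrt{k}$ for $k$ genes, and a
threshold on it has an obvious unit (standard deviations of expression
change). A group of drugs gets the direction of the *mean of its
members' scores*, thresholded at the same `tau`; members without
sufficient gene overlap are no-calls and excluded from the group mean.

## The synthetic-data generator

Real inputs for this analysis come from target-prediction services,
annotation databases and perturbation-signature libraries. To make
every stage testable offline, `generate_synthetic()` plants the
statistical structure those inputs are assumed to have:

- $K$ mechanism groups (default 4), each with its own pool of
  `terms_per_group` = 10 function terms, plus 5 background terms;
- per group, 3 preparation components and 5 comparator drugs, each
  with 8 predicted targets scoring uniformly in (21, 40);
- each target annotates to 2 terms: an in-group term with probability
  $1 - \texttt{noise\_rate}$ (default noise 0.1), otherwise a uniformly
  random out-of-group or background term;
- group-aligned ATC level-3 codes (one code family per group, keeping
  the coverage arithmetic transparent);
- indications spanning 2 groups each;
- per-drug signatures: standard-normal z-scores over the full gene
  (target) universe — signature libraries are genome-wide, so coverage
  of term genes is ample — shifted by $\pm\delta$ (default 2) on the
  genes of the drug's group terms according to a planted per-(group,
  term) direction.

Defaults were chosen once as a compact benchmark a practitioner would
call realistic in shape: tens of compounds, single-digit targets per
compound, ~10% annotation noise, 2-sigma perturbation effects. At these
settings the problem sizes are: 32 compounds, 256 targets, 45 terms,
20 signatures of 256 genes — every stage runs in well under a second,
and the acceptance analyses (100 oracle networks, 20 clustering seeds,
100 signature seeds) complete in seconds.

What the generator does **not** emulate: real prediction-score
distributions, the GO DAG's nesting (terms here are flat and mostly
disjoint), shared targets between compounds (each compound gets private
target ids, so similarity flows through terms only), and correlated
noise across a signature's genes. Passing tests therefore demonstrate
the pipeline's correctness and its recovery of planted structure under
idealized noise — not performance on any real database. One knowing
artifact: a gene annotated to two planted terms with opposite
directions receives both shifts and cancels; with
`annotations_per_target = 1` every gene belongs to one term and shifts
are clean.

`worked_example_fixture()` is fully deterministic (no RNG): 7 groups
whose core/private term construction pins the three distance levels
(component-similar ≈ 0.08, component-dissimilar ≈ 0.71, cross-group 1),
so the 23/32 screen at 0.53 and the 7/7 group spread are reproduced
end-to-end, not asserted. The fixture uses the fixed 0.53 threshold
rather than its own global median: its distance distribution is
discrete by construction, and its median (1.0, dominated by cross-group
pairs) is not a meaningful operating point.

## Numerical choices and degenerate inputs

- **Strict inequalities** at both the score cutoff (`> 20`) and the
  screen (`< threshold`), following the usual wording of both rules;
  the boundary cases are tested.
- **Duplicate compound-target rows** keep the maximum score: the most
  confident prediction, monotone under re-export of prediction files.
- **Determinism**: the distance matrix is sorted by compound id before
  `hclust`, so merge order does not depend on input row order; with
  continuous distances exact merge ties have measure zero. Group
  labels are assigned by leftmost-leaf order, so "group 1" is the
  leftmost branch of the plotted tree.
- **Even cross-pair counts**: the median averages the central pair.
- **Empty sets**: empty reference sets for any coverage ratio are
  errors (a 0/0 coverage is meaningless); an empty similar set is a
  valid 0.
- **No-call vs flat**: insufficient gene overlap never silently becomes
  a flat call.

## Known limitations

- PathSim is unweighted: edge confidence scores gate inclusion but do
  not weight paths. A confidence-weighted variant is deliberately out
  of scope.
- No automatic choice of the number of cluster groups; `k_main` and
  `k_filter` are the analyst's call.
- Coverage ratios are descriptive; no permutation null or significance
  ranking is attached.
- Signature aggregation across cell lines / doses is out of scope: one
  signature per drug is assumed (pre-aggregate upstream if needed).
- GO ancestor propagation and cross-namespace gene-id mapping are not
  performed; inputs are taken at face value.
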