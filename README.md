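# cellfp

Cellular function fingerprint similarity for multi-component drug
repositioning.

`cellfp` is for pharmacology and cheminformatics researchers who want
to ask: *which marketed drugs does a multi-component preparation (for
example a traditional Chinese medicine) pharmacologically resemble, and
how much of a given indication's drug arsenal does it span?* It answers
by comparing compounds on their **cellular function fingerprints** —
profiles over the biological-function terms (GO-BP, Reactome, KEGG,
WikiPathways) reachable through each compound's predicted protein
targets — rather than on chemical structure.

## Method

On a compound-target-pathway heterogeneous network, let
`M[c, p]` be the number of distinct targets linking compound *c* to
function term *p*. Along the symmetric meta-path
compound → target → term → target → compound, with `P = M Mᵀ`,
similarity is PathSim:

    s(x, y) = 2 P[x, y] / (P[x, x] + P[y, y]),    d(x, y) = 1 − s(x, y)

Compounds are clustered hierarchically on `d`, the tree is cut into
mechanism groups, and for each indication the comparator drugs with
`d < threshold` (by default the global median of all component-drug
cross distances, strict inequality) are screened as **similar drugs**.
Per-indication coverage statistics follow:

- ATC-code coverage `n/N`, GO-term coverage `m/M`, drug coverage
  `d/D`, cluster-group coverage `g/G`;
- `CombinedRatio = (n/N + m/M + d/D) / 3`.

Mechanism annotations (ATC codes, shared GO terms) transfer from each
component's most similar drug, and the regulation direction of drugs on
shared biological processes is called from gene-level expression
z-score signatures (mean z over term genes, thresholded at ±tau).

A synthetic-data generator (`generate_synthetic()`) plants mechanism
groups, group-aligned ATC codes, indications and signed signature
shifts so the whole pipeline is testable without database access. See
`vignette("cellular-function-fingerprints")` for the model, parameter
and design discussion.

## Worked example

A deterministic fixture reproduces the canonical screening arithmetic:
one indication ("LDH") with 32 comparator drugs spread over 7 cluster
groups, screened at distance 0.53 against 7 preparation components.

```r
library(cellfp)

fx <- worked_example_fixture()
run <- run_pipeline(
  fx$network, fx$indications,
  pipeline_config(k_main = fx$k, threshold_mode = "fixed",
                  fixed_threshold = fx$threshold))
#> similarity: 7 components vs 32 drugs
#> screen: threshold 0.53
#> screen: 23 of 32 drugs similar

run
#> <cfp_run> fingerprint similarity pipeline
#>   compounds clustered: 39 into 7 groups
#>   screening threshold: 0.53 -> 23 similar drugs
#>   indications covered: 1

dplyr::select(tidy(run), indication_id, d, D, g, G,
              drug_coverage, group_coverage)
#> # A tibble: 1 × 7
#>   indication_id     d     D     g     G drug_coverage group_coverage
#>   <chr>         <int> <int> <int> <int>         <dbl>          <dbl>
#> 1 LDH              23    32     7     7         0.719              1
```

23 of the 32 indication drugs sit strictly below the 0.53 fingerprint
distance to at least one component (drug coverage 23/32 = 0.72 at two
decimals), and those similar drugs appear in all 7 of the 7 cluster
groups the indication's drugs occupy (group coverage 1): the
preparation spans every pharmacological module of this indication's
drug library, not just most of its drugs.

`tidy()` on a run returns the full coverage table (including ATC and
GO-term coverage and the combined ratio), `glance()` a one-row summary,
and `autoplot()` a coverage bar chart; `autoplot()` on
`run$dendrogram` draws the cluster tree.

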