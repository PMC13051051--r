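# agentsoc

Statistical detection of **homophily** — the tendency of ties to form
between similar individuals — in engagement networks of autonomous agents,
such as populations of character-playing chatbots on a simulated
micro-blogging platform.

Given a dyadic event log (one row per follow / like / dislike / mention:
source, target, type, day), per-agent language labels and per-agent content
embeddings, the package builds cumulative weighted undirected engagement
graphs, detects structural communities, and tests whether that structure
(a) exceeds chance under a degree-preserving rewiring null and (b) aligns
with agent attributes and content similarity.

## What it computes

| Stage | Function(s) | Statistic |
|---|---|---|
| Graph construction | `build_graph`, `prune_low_degree` | edge weight = pairwise engagement frequency |
| Community detection | `label_propagation`, `greedy_modularity` | weighted partitions |
| Stability filter | `consistency_check`, `overlap_rate` | mean overlap rate o(A), keep at ≥ 0.80 |
| Structure tests | `modularity_weighted`, `attribute_assortativity`, `pairwise_assortativity` | Q = (1/2m) Σᵢⱼ (wᵢⱼ − sᵢsⱼ/2m) δ(cᵢ,cⱼ); r = (Σeᵢᵢ − Σaᵢ²)/(1 − Σaᵢ²) |
| Significance | `rewire_preserving_degrees`, `null_distribution` | bootstrapped p = P(null ≥ observed), CI = obs ± 1.96·sd(null) |
| Attribute alignment | `contingency_alignment` | Pearson χ², Cramér's V |
| Content alignment | `centroid_distance_test`, `distance_by_engagement_bins`, `mrqap_correlation` | paired t with Cohen's d = t/√n; binned cosine distances; QAP dyadic r |
| Validation world | `generate_society`, `planted_partition` | synthetic society with planted language (`h_L`) and content (`h_C`) homophily |

The synthetic-society generator is first-class: every stage of the pipeline
is validated by parameter recovery against planted ground truth (see the
methods vignette, `vignettes/homophily-pipeline.Rmd`, for the generative
model and all numerical choices).

## Worked example

```r
library(agentsoc)

cfg <- run_config(
  society = society_config(
    n_agents = 400, lang_homophily = 0.8, content_homophily = 2,
    events_per_day = 0.5, seed = 1
  ),
  day_cutoffs = c(14, 28), n_consistency = 20, n_null = 100, seed = 1
)
report <- run_pipeline(cfg)
report$days[["28"]]$full$language_assortativity
#> <null_result> language_assortativity = 0.9054, 95% CI [0.8731, 0.9376], bootstrapped p < 0.01 (100 rewires)
report$days[["28"]]$full$contingency
#> <contingency_result> chi2(9, N = 363) = 1064.59, Cramer's V = 0.99, p < .001
emit_tables(report, "run1")   # CSV tables + schema.json
```

Reading the output: the day-28 graph's engagement ties fall
overwhelmingly within language groups (assortativity 0.90 where 0 is
random mixing and 1 is perfect segregation), no rewired graph out of 100
reached the observed value (bootstrapped p < 1/100), and the detected
communities map almost one-to-one onto the planted languages
(Cramér's V = 0.99) — the pipeline recovers the homophily that the
synthetic society planted (`h_L = 0.8`).

A command-line front end with `simulate` and `run-all` subcommands lives at
`inst/cli/agentsoc.R`:

```sh
Rscript inst/cli/agentsoc.R simulate --n-agents 500 --h-lang 0.8 --seed 1 --out-dir sim1
Rscript inst/cli/agentsoc.R run-all --events sim1/events.csv --agents sim1/agents.csv \
    --embeddings sim1/embeddings.csv --n-null 200 --seed 1 --out-dir run1
```

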