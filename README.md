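# imena — interdomain molecular ecological network analysis

`imena` analyses how multi-kingdom sediment microbiomes (prokaryotes, fungi,
cercozoan protists) organise into co-occurrence networks, and how those
networks relate to environmental gradients and methane (CH4) flux. It is
aimed at microbial ecologists who have OTU count tables and per-sample
environmental metadata and want the full molecular-ecological-network (MEN)
workflow as reproducible, tested R functions rather than a web pipeline.

## What it computes

Starting from OTU × sample count tables (TSV) it provides:

* **Preprocessing** — seeded rarefaction to fixed depth, strict `> 80%`
  prevalence filtering, alpha diversity (Shannon, Pielou, observed richness,
  bias-corrected Chao1 `S + F1(F1−1)/(2(F2+1))`), taxonomy-rule guild
  annotation (methanogens/methanotrophs), inundation-group assignment.
* **Association networks** — pairwise Spearman ρ on relative abundances;
  edges where `|ρ| ≥ t` with signed weights; interdomain networks that pool
  kingdoms over shared samples and treat methane guilds as their own node
  categories. The threshold `t` is either fixed per kingdom or selected by
  **random matrix theory**: the smallest threshold at which the
  nearest-neighbour spacing distribution of the unfolded eigenvalue spectrum
  stops looking like the Gaussian orthogonal ensemble (Wigner surmise,
  `P(d) = (πd/2)·exp(−πd²/4)`, level repulsion = noise) and becomes Poisson
  (`P(d) = e^(−d)`, uncorrelated levels = modular structure), by chi-square
  goodness of fit.
* **Topology** — clustering, path length, density, modularity; vulnerability
  `V = max_i (E − E_i)/E` on global efficiency `E = mean(1/d_ij)`; robustness
  under random or hub-targeted node removal with secondary extinctions.
* **Modules and keystones** — fast-greedy modularity partitions; within-module
  degree `Zi` and among-module connectivity `Pi = 1 − Σ_t (k_it/k_i)²` with
  the standard role cutoffs (module hub: Zi > 0.25, Pi ≤ 0.62; connector:
  Zi ≤ 0.25, Pi > 0.62; network hub: both); SVD **module eigengenes** (first
  principal component of the standardised module abundance matrix) and their
  Pearson correlations with sediment traits and CH4 flux.
* **Community statistics** — presence/absence Jaccard distances, Mantel tests
  (exact by enumeration at small n), PCA ordination, MRPP/ANOSIM/PERMANOVA,
  one-way ANOVA, flux-vs-gene-copy regression.
* **Synthetic communities** — a seeded generator with planted cross-kingdom
  correlation modules, methane guilds, a 7/12/8 three-level inundation
  design, and CH4 flux linked to a planted module's eigengene, so every
  stage is testable end to end.

Everything is tidyverse-shaped: tables in and out are tibbles, results have
`tidy()`/`glance()` methods, networks are igraph objects with `tidy_nodes()`
/`tidy_edges()` accessors, and `autoplot()`/`plot_*()` give ggplot2 figures.
Networks export as Cytoscape-ready edge lists, node attribute tables and
GraphML.

## Worked example

Simulate a 27-sample, 200-OTU three-kingdom community with four planted
modules (within-module latent ρ = 0.9) and CH4 flux tied to module 1, then
recover the structure:

```r
library(imena)

sim <- simulate_community(n_samples = 27, seed = 42)
rar <- rarefy(sim$counts,
              c(prokaryote = 50000, fungus = 51591, cercozoa = 33548),
              seed = 43)
filt <- dplyr::bind_rows(lapply(split(rar, rar$kingdom), prevalence_filter))

net <- build_interdomain_network(filt, threshold = 0.85)
part <- detect_modules(net)
part
#> module partition: 4 modules, 77 nodes, Q = 0.657

roles <- zi_pi(net, part)
table(roles$role)
#> module hub peripheral
#>         33         44

egs <- module_eigengenes(filt, part)
glance(egs)
#> # A tibble: 4 × 3
#>   module explained_variance n_otus
#>    <int>              <dbl>  <dbl>
#> 1      1              0.832     20
#> 2      2              0.896     20
#> 3      3              0.858     19
#> 4      4              0.817     18

eigengene_trait_correlation(egs, sim$metadata, traits = "ch4_flux")
#> # A tibble: 4 × 6
#>   module trait         r      p_value  p_adjusted stars
#>    <int> <chr>     <dbl>        <dbl>       <dbl> <chr>
#> 1      1 ch4_flux  0.858 0.0000000110 0.000000132 "***"
#> 2      2 ch4_flux -0.393 0.0427       0.256       "*"
#> 3      3 ch4_flux -0.182 0.365        0.776       ""
#> 4      4 ch4_flux -0.187 0.350        0.776       ""

truth_mod <- sim$truth$otus$module[match(part$membership$node,
                                         sim$truth$otus$otu_id)]
adjusted_rand_index(part$membership$module, truth_mod)
#> [1] 1
```

The detected partition matches the planted one exactly (adjusted Rand
index 1), each module's eigengene captures 82–90% of its members' variance,
and the flux-linked module is the one — and only one — strongly positively
correlated with CH4 flux (r = 0.86, three stars), which is exactly how the
planted signal was wired.

The whole analysis, from simulation through networks, topology, robustness,
eigengene–trait tables and community statistics, also runs as one call with
a YAML config and writes every artifact plus a run manifest:

```r
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "imena"))
run_pipeline(cfg, "demo-output")
```

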