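# spreadis

Who spreads information, and who is spread to? `spreadis` is an R toolkit
for studying peer-to-peer contagion on social diffusion networks with
heterogeneous node-level behavioral traits. It is aimed at computational
social scientists and network epidemiologists who have multi-cascade event
logs (who reshared what from whom, when) and want to go beyond centrality:
to estimate each user's **influence** and **susceptibility**, test how those
traits sit in the network, and predict the next window's superspreaders.

## The model and the algorithm

The generative assumption is the product transmission model on a directed
diffusion network *A* (edge *i* → *j* iff at least one recorded spreading
event from *i* to *j*):

```
p_ij = A_ij · I_i · S_j
```

where `I_i ∈ [0,1]` is *i*'s influence and `S_j ∈ [0,1]` is *j*'s
susceptibility. From an event log the per-edge contagion rate
`ω_ij` — the fraction of *i*'s pieces subsequently reshared by *j* — gives
the node totals `f̂_i = Σ_j A_ij ω_ij` and `ĝ_j = Σ_i A_ij ω_ij`, and the
traits solve the coupled nonlinear fixed-point system

```
Î_i = f̂_i / Σ_j A_ij Ŝ_j        Ŝ_j = ĝ_j / Σ_i A_ij Î_i
```

solved iteratively by `run_is()` (robust alternating scheme by default, the
literal simultaneous scheme as an option, brute-force root-finding oracle
for small instances, explicit gauge handling). Around the core algorithm
the package provides: cascade log I/O and validation (TSV / JSON-lines),
diffusion-network construction, an independent-cascade simulator with
ground-truth traits, time windowing and event subsampling, centralities and
assortativity statistics with degree-preserving randomized nulls, stylized-
fact checks, and a windowed random-forest superspreader prediction pipeline
evaluated with AUPRC and precision-at-k.

## Worked example

Simulate cascades with known traits, reconstruct them, and inspect the
result (all numbers below are the code's actual output):

```r
library(spreadis)

net    <- generate_network(150, mean_degree = 5, seed = 1)
traits <- generate_traits(network_nodes(net), rank_correlation = -0.5, seed = 2)
log    <- simulate_cascades(net, traits, n_cascades = 1000, seed = 3)
log
#> # A tibble: 14,412 × 4
#>   piece_id user_id parent_id timestamp
#>   <chr>      <int>     <int>     <dbl>
#> 1 c1             5        NA         0
#> 2 c1            14         5         1
#> 3 c1            40         5         1
#> # i 14,409 more rows

dn     <- build_diffusion_network(log)
scores <- run_is(estimate_contagion_rates(log, dn))
glance(scores)
#> # A tibble: 1 × 5
#>   scheme      iterations converged      residual n_nodes
#>   <chr>            <int> <lgl>             <dbl>   <int>
#> 1 alternating         45 TRUE      0.00000000579     150
```

The iteration converged in 45 sweeps. How well were the latent traits
recovered, and do the reconstructed scores show the planted
influence–susceptibility anticorrelation?

```r
recovery_report(traits, scores, dn)
#> # A tibble: 1 × 5
#>   rho_influence rho_susceptibility n_influence n_susceptibility rms_edge_product
#>           <dbl>              <dbl>       <int>            <int>            <dbl>
#> 1         0.956              0.895         147              147           0.0841

node_correlations(scores, centralities(dn))
#> # A tibble: 6 × 4
#>   var1      var2               rho n_pairs
#>   <chr>     <chr>            <dbl>   <int>
#> 1 k_in      k_out           0.0512     144
#> 2 k_in      influence       0.0162     144
#> 3 k_in      susceptibility -0.0386     147
#> 4 k_out     influence       0.0985     147
#> 5 k_out     susceptibility -0.0115     144
#> 6 influence susceptibility -0.416      144
```

Spearman correlations of 0.96 (influence) and 0.90 (susceptibility) against
ground truth from 1000 cascades; the traits are nearly orthogonal to degree
while the planted trait anticorrelation (−0.5) reappears at −0.42. From
here, `stylized_facts()`, `neighbor_assortativity()` and
`randomized_null()` probe the network positions of the scores, and
`compute_features()` / `train_eval()` / `rolling_experiment()` run the
superspreader prediction experiment. A command-line front end
(`inst/cli/spreadis.R`) wraps the same functions as `simulate`, `infer`,
`validate`, `predict` and `demo` subcommands. The methods vignette
(`vignettes/influence-susceptibility.Rmd`) documents the model, the
numerical choices and the benchmark designs.

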