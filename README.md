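# antagosim

Do phages and plasmids reshape microbial communities less when there are
*more* of them? `antagosim` is an R package for ecologists and
microbiologists who want to explore that question *in silico*. It models a
competitive bacterial community under a layer of antagonists (phages,
plasmids, other mobile genetic elements), each imposing a random growth
cost on each host taxon, and measures how far the community's equilibrium
composition moves from its antagonist-free state.

## The model in brief

All `N = n + m` species (n focal bacteria, m antagonists) follow
competitive Lotka–Volterra dynamics

    dx_i/dt = r_i x_i (1 − Σ_j α_ij x_j)

with a randomly assembled interaction matrix: focal–focal off-diagonals
~ Uniform(0, A/n), antagonist impacts on focal species ~ half-normal
N⁺(0, σ), focal effects on antagonists all 0, self- and
antagonist–antagonist terms all 1, and growth rates ~ N⁺(0, 1). Each
focal species' combined antagonist burden β = Σθ has

    CV(β) = √(σ_θ² m) / (E(θ) m) = √(π/2 − 1) / √m,

so relative differences in burden shrink as 1/√m: many antagonists tend
to cancel each other's compositional fingerprints. The package's sweep
engine quantifies this with Bray–Curtis dissimilarity and Kendall rank
correlation between paired with/without-antagonist equilibria.

## Worked example

```r
library(antagosim)

# one community: 10 focal species, 3 antagonists
spec <- community_spec(n = 10, m = 3, sigma = 0.3, A = 0.5, seed = 1)
paired_run(spec)
#> Bray-Curtis = 0.0972, Kendall tau-a = 0.1556 (literal 0.7000)

# a slice of the sweep: divergence shrinks as antagonists accumulate
g <- sweep_grid(10, c(1, 5, 10), 0.3, 0.5, replicates = 500, root_seed = 1)
run_sweep(g)
#>    n  m sigma   A mean_bray_curtis mean_kendall replicates_used degenerate_count
#> 1 10  1   0.3 0.5           0.1153        0.104             500                0
#> 2 10  5   0.3 0.5           0.0562        0.199             500                0
#> 3 10 10   0.3 0.5           0.0358        0.291             500                0

# the analytic reason: CV of the combined burden falls as 1/sqrt(m)
sapply(1:4, function(m) cv_combined_effect(0.3, m))
#> [1] 0.7555 0.5342 0.4362 0.3778

# diversity of one equilibrium composition
sys <- assemble_system(spec)
p <- focal_relative_abundances(integrate_system(sys), sys)
c(H = shannon_diversity(p), J = evenness(p))
#>      H      J
#> 2.2739 0.9876
```

Reading the sweep table: with a single antagonist the community ends up
about 12% dissimilar (Bray–Curtis 0.115) from its antagonist-free twin
and species ranks are heavily shuffled (tau 0.10); with ten antagonists
dissimilarity drops threefold (0.036) and rank order is better preserved
(tau 0.29) — more antagonists, smaller net effect on structure.

## Command line

```sh
Rscript inst/cli/antagosim simulate --n 10 --m 3 --sigma 0.3 --A 0.5 --seed 1 --out run.json
Rscript inst/cli/antagosim sweep --config config.json --out tiles.csv
Rscript inst/cli/antagosim cv --sigma 0.3 --m-max 10
Rscript inst/cli/antagosim diversity --composition "0.5,0.25,0.25"
```

A config file is flat JSON (`n_values`, `m_values`, `sigma_values`,
`A_values`, `replicates`, `root_seed`, integrator settings, ...); unknown
keys are rejected and defaulted keys are logged. Identical config + seed
produces byte-identical output files.

## Package tour

| area | functions |
|---|---|
| model assembly | `community_spec`, `assemble_system`, `sample_focal_block`, `sample_antagonist_impacts`, `sample_growth_rates`, `lv_derivative` |
| dynamics | `integration_settings`, `integrate_system`, `integrate_euler`, `focal_relative_abundances` |
| metrics | `bray_curtis`, `kendall_rank`, `shannon_diversity`, `evenness` |
| analytics | `half_normal_moments`, `cv_combined_effect`, `symmetric_equilibrium` |
| experiment | `sweep_grid`, `headline_grid`, `full_grid`, `paired_run`, `paired_divergence`, `run_sweep`, `replicate_seed`, `trend_holds` |
| I/O & CLI | `load_config`, `write_config`, `write_tile_table`, `read_tile_table`, `generate_fixture`, `antago_cli` |

The methods vignette
(`vignettes/multi-antagonist-communities.Rmd`) documents the model's
assumptions, every place the construction required an interpretation
(Kendall normalization, integration horizon, initial conditions, seeding)
and what a green test does and does not establish.
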