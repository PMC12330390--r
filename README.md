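# sodalake

Biogeography of soda-lake microbial communities, from metagenomic
read-recruitment summaries to Bayesian inference of cross-continent
transition rates.

Soda lakes — hypersaline, high-pH (9–12) lakes dominated by sodium carbonate
— occur in isolated inland basins on several continents, making their
microbiomes a natural experiment in microbial dispersal limitation. This
package is for microbial ecologists who have (or want to simulate)
marker-gene community profiles, genome-similarity tables and a species
phylogeny from such systems, and want to quantify three things:

1. **Who is everywhere, and who is endemic?** Species abundances in TPM
   (mapped bases normalized by reference length and sequencing effort,
   renormalized to 10^6 per sample), occupancy classes (core = present in
   every region, endemic = one region), and a species range-size index
   `R = 1 − sd(f_1, …, f_K)` over the species' abundance fractions across
   `K` regions — for `K = 4` the index runs from 0.5 (confined to one
   region) to 1.0 (perfectly even spread).
2. **Does similarity decay with distance?** Bray–Curtis / Euclidean
   dissimilarity matrices, log–log distance-decay regressions, one-way
   PERMANOVA, and within- vs between-region contrasts of genome-wide ANI at
   species (all pairs) and strain (ANI ≥ 95%) tiers, with
   Benjamini–Hochberg adjustment.
3. **How often did lineages move between continents?** A K-state Mk
   (MultiState) model on a rooted phylogeny: generator matrix `Q` with
   constraint masks (free / tied `q_ij = q_ji` / fixed-zero rates),
   Felsenstein pruning likelihood in compiled code, Metropolis–Hastings
   sampling under uniform / exponential / gamma priors and their
   hyper-prior versions, stepping-stone marginal likelihoods
   (`β_k = (k/n)^{1/0.4}` schedule) for log-Bayes-factor model comparison,
   and Gelman–Rubin congruence checks across repeated runs.

A synthetic-data generator (`sim_config()`, `generate_abundance_inputs()`,
`generate_tree()`, `simulate_tip_states()`, `generate_ani_pairs()`,
`generate_genome_sizes()`) emulates every input with known ground truth —
occupancy classes, decay scales, ANI region effects, true rate matrices — so
the entire pipeline is testable end to end without sequence data.

## Worked example

Simulate the 51-sample, 4-region study design, profile it, and test for
distance decay:

```r
library(sodalake)

cfg <- sim_config(n_species = 300, seed = 7)
gen <- generate_abundance_inputs(cfg)
tab <- build_abundance_table(gen$mapping, gen$metadata)
tab
#> TPM abundance table: 300 species x 51 samples, 4 regions

occ <- classify_occupancy(tab, presence_threshold = 0)
attr(occ, "class_counts")
#>         core intermediate      endemic       absent
#>           49          148          103            0
attr(occ, "endemic_by_region")
#> Africa Canada  China Russia
#>     19     26     34     24

ddr_fit(ddr_pairs(tab, "braycurtis"))
#> Distance-decay fit (log10-log10): slope = -0.3461, R2_adj = 0.506, p = 1.48e-197
#> 1275 pairs used, 0 excluded (non-positive axis values)

pm <- permanova(dissimilarity_matrix(tab, "braycurtis"),
                tab$metadata$region, n_permutations = 999, seed = 7)
#> PERMANOVA: R2 = 0.202, pseudo-F = 3.96, p = 0.001
```

The negative log–log slope says community similarity falls off with
geographic distance (the generator seeded presence with a 3,000-km decay
scale, so it should); PERMANOVA confirms region explains ~20% of
community variation, with `p` at the floor `1/(999+1)` for 999
permutations. The range-size index hits its analytic anchors:

```r
range_size(c(1, 0, 0, 0))             # 0.5  (restricted to one region)
range_size(c(0.25, 0.25, 0.25, 0.25)) # 1.0  (even spread)
```

Infer transition rates on a 200-tip tree simulated with uneven truth
(`q(Asia↔NorthAmerica) = 0.5`, `q(Africa↔·) = 0.05`, tied directions):

```r
states <- c("Africa", "Asia", "NorthAmerica")
sym <- mk_constraints(states, "symmetric")
tr  <- scale_tree(generate_tree(200, 1, seed = 7))   # mean branch length 0.1
tips <- simulate_tip_states(tr, rate_model(
  c(qAfrica.Asia = 0.05, qAfrica.NorthAmerica = 0.05,
    qAsia.NorthAmerica = 0.5), sym), seed = 8)
fit <- mcmc_sample(tr, tips, sym, prior = mk_prior("exponential"),
                   iterations = 4000, burn_in = 1000, thinning = 5, seed = 9)
summary(fit)
#>              parameter median  mean ci_lower ci_upper
#> 1         qAfrica.Asia  0.043 0.066  0.00092     0.21
#> 2 qAfrica.NorthAmerica  0.074 0.087  0.01785     0.22
#> 3   qAsia.NorthAmerica  0.380 0.399  0.20644     0.67
```

The posterior recovers the uneven pattern: the Asia–North-America rate is an
order of magnitude above the Africa rates, and every 95% credible interval
covers its true value. Compare constrained models with
`stepping_stone_logml()` + `compare_models()` (|log BF| ≥ 10 = very strong
evidence), and check repeated runs with `run_congruence()` (PSRF < 1.1).

`run_pipeline()` (or the thin CLI at `inst/scripts/sodalake.R`) chains the
stages — generate → profile → biogeo/ani → transition — from one YAML
config, writing seed-stamped TSVs and a run manifest; identical config +
seed reproduce byte-identical outputs.

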