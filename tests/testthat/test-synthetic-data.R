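# Synthetic-data generators: determinism, forced designs, and agreement with
# closed-form expectations of the simulated processes.

test_that("generate_tree produces valid Yule trees of the requested size", {
  tr2 <- generate_tree(2, 1, seed = 7)
  expect_s3_class(tr2, "phylo")
  expect_equal(length(tr2$tip.label), 2)
  expect_equal(tr2$Nnode, 1)

  tr <- generate_tree(100, 1, seed = 1)
  expect_equal(length(tr$tip.label), 100)
  expect_equal(tr$Nnode, 99) # rooted binary: n - 1 internal nodes
  expect_true(all(tr$edge.length > 0))
  expect_false(anyDuplicated(tr$tip.label) > 0)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))

  expect_error(generate_tree(1, 1, seed = 1), "n_tips")
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_tree(40, 1, seed = 3), generate_tree(40, 1, seed = 3))
  cfg <- sim_config(n_species = 60, seed = 5)
  expect_identical(generate_abundance_inputs(cfg), generate_abundance_inputs(cfg))
  expect_identical(generate_ani_pairs(seed = 2, n_pairs_per_group = 30),
                   generate_ani_pairs(seed = 2, n_pairs_per_group = 30))
  rs <- runif(50)
  expect_identical(generate_genome_sizes(rs, seed = 4),
                   generate_genome_sizes(rs, seed = 4))
  # a generator call does not disturb the global RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_tree(10, 1, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("tip-state simulation freezes when all rates are zero", {
  m0 <- rate_model(c(qA.B = 0), mk_constraints(c("A", "B"), "symmetric"))
  tp <- simulate_tip_states(generate_tree(60, 1, seed = 1), m0, seed = 2)
  expect_true(all(colSums(tp) %in% c(0, 60)))
})

test_that("tip states reach the stationary distribution on long branches", {
  # star tree, branches long enough that P(t) ~ stationary; asymmetric rates
  tr <- ape::stree(2000, "star")
  tr$edge.length <- rep(40, nrow(tr$edge))
  states <- c("A", "B", "C")
  mask <- mk_constraints(states, "all-free")
  rates <- c(qA.B = 0.4, qA.C = 0.2, qB.A = 0.1, qB.C = 0.3, qC.A = 0.5, qC.B = 0.2)
  mdl <- rate_model(rates, mask)
  ev <- eigen(t(mdl$Q))
  pi_stat <- Re(ev$vectors[, which.min(abs(ev$values))])
  pi_stat <- pi_stat / sum(pi_stat)
  tp <- simulate_tip_states(tr, mdl, seed = 11)
  obs <- colSums(tp)
  expect_gt(stats::chisq.test(obs, p = pi_stat)$p.value, 0.001)
})

test_that("two-state chain matches the closed-form switch probability", {
  # root pinned in state A, 10,000 independent branches of length t:
  # P(tip != A) = (1 - exp(-2qt)) / 2
  q <- 0.6; t <- 0.8
  tr <- ape::stree(10000, "star")
  tr$edge.length <- rep(t, nrow(tr$edge))
  mdl <- rate_model(c(qA.B = q), mk_constraints(c("A", "B"), "symmetric"),
                    root_frequencies = c(1, 0))
  tp <- simulate_tip_states(tr, mdl, seed = 21)
  p_hat <- mean(tp[, "B"] == 1)
  p_true <- (1 - exp(-2 * q * t)) / 2
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("forced occupancy designs propagate to the generated tables", {
  cfg_end <- sim_config(n_species = 50, core_fraction = 0, endemic_fraction = 1,
                        seed = 3)
  gen <- generate_abundance_inputs(cfg_end)
  expect_true(all(gen$truth$occupancy_class == "endemic"))
  tab <- build_abundance_table(gen$mapping, gen$metadata)
  occ <- classify_occupancy(tab, 0)
  expect_true(all(occ$occupancy_class == "endemic"))

  cfg_core <- sim_config(n_species = 50, core_fraction = 1, endemic_fraction = 0,
                         seed = 3)
  occ2 <- classify_occupancy(build_abundance_table(
    generate_abundance_inputs(cfg_core)$mapping,
    generate_abundance_inputs(cfg_core)$metadata), 0)
  expect_true(all(occ2$occupancy_class == "core"))
})

test_that("mapping summaries respect their count invariants", {
  gen <- generate_abundance_inputs(sim_config(n_species = 80, seed = 9))
  expect_true(all(gen$mapping$mapped_bases >= 1))
  expect_true(all(gen$mapping$mapped_bases <= gen$mapping$sample_total_bases))
  expect_true(all(gen$mapping$ref_length_bp > 0))
  expect_true(all(gen$mapping$sample_id %in% gen$metadata$sample_id))
  expect_equal(nrow(gen$metadata), 51) # 14 + 18 + 15 + 4 study design
})

test_that("short decay scales give steeper distance-decay than flat ones", {
  slope_mag <- function(decay, seed) {
    cfg <- sim_config(n_species = 120, core_fraction = 0.1, endemic_fraction = 0.2,
                      decay_scale_km = decay, seed = seed)
    gen <- generate_abundance_inputs(cfg)
    tab <- build_abundance_table(gen$mapping, gen$metadata)
    abs(ddr_fit(ddr_pairs(tab, "braycurtis"))$slope)
  }
  for (s in 1:5) {
    expect_gt(slope_mag(10, s), slope_mag(1e6, s))
  }
})

test_that("ANI generator honours truncation and the null design", {
  # extreme parameters cannot escape [70, 100]
  x <- generate_ani_pairs(within_mean = 72, between_decay_per_km = 0.01,
                          noise_sd = 30, n_pairs_per_group = 150, seed = 1)
  expect_true(all(x$ani_percent >= 70 & x$ani_percent <= 100))
  # no decay, vanishing noise: within and between means agree
  y <- generate_ani_pairs(within_mean = 90, between_decay_per_km = 0,
                          noise_sd = 1e-9, n_pairs_per_group = 50, seed = 2)
  within <- y$region_a == y$region_b
  expect_equal(mean(y$ani_percent[within]), mean(y$ani_percent[!within]),
               tolerance = 1e-6)
})

test_that("genome-size generator supports exact and calibrated recovery", {
  rs <- runif(100, 0.5, 1)
  gs <- generate_genome_sizes(rs, slope = 0.8, intercept = 3, noise_sd = 0, seed = 1)
  fit <- suppressWarnings(genome_size_regression(rs, gs)) # noiseless fit
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)
  expect_equal(fit$r2_adjusted, 1, tolerance = 1e-8)
  # floor
  low <- generate_genome_sizes(rep(0.5, 20), slope = 0, intercept = -5,
                               noise_sd = 0.1, seed = 2)
  expect_true(all(low >= 0.5))
})

test_that("null-slope genome sizes give a calibrated slope test", {
  set.seed(77)
  rej <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    rs <- runif(60, 0.5, 1)
    gs <- generate_genome_sizes(rs, slope = 0, intercept = 3, noise_sd = 0.5,
                                seed = 1000 + s)
    rej <- rej + (genome_size_regression(rs, gs)$p_value <= 0.05)
  }
  expect_gt(rej / n_sim, 0.01)
  expect_lt(rej / n_sim, 0.10)
})

test_that("slope credible recovery: confidence interval covers the truth", {
  set.seed(88)
  cover <- 0
  for (s in 1:60) {
    rs <- runif(300, 0.5, 1)
    gs <- generate_genome_sizes(rs, slope = 0.8, intercept = 3, noise_sd = 0.5,
                                seed = 2000 + s)
    ci <- genome_size_regression(rs, gs)$conf_int
    cover <- cover + (ci[1] <= 0.8 && 0.8 <= ci[2])
  }
  expect_gte(cover, 0.9 * 60 - 6) # >= 48/60, loose binomial bound on 95% CI
})

test_that("sim_config rejects inconsistent designs", {
  expect_error(sim_config(core_fraction = 0.7, endemic_fraction = 0.5), "<= 1")
  expect_error(sim_config(decay_scale_km = 0), "decay_scale_km")
  expect_error(sim_config(regions = default_regions()[1, ]), "2 regions")
})
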