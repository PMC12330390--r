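# Mk transition engine: tree scaling, transition probabilities, pruning
# likelihood, tip-state encoding, MCMC contracts, stepping-stone sampler,
# model comparison and run congruence.

test_that("scale_tree rescales to the target mean and preserves ratios", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.1,c:0.2);")
  sc <- scale_tree(tr, 0.1)
  expect_equal(mean(sc$edge.length), 0.1, tolerance = 1e-15)
  expect_equal(sc$edge.length / tr$edge.length,
               rep(0.1 / mean(tr$edge.length), length(tr$edge.length)))
  # worked example: edges (0.05, 0.05, 0.10), target 0.1 -> scale by 1.5
  tr3 <- ape::read.tree(text = "(a:0.05,b:0.05,c:0.1);")
  sc3 <- scale_tree(tr3, 0.1)
  expect_equal(sort(sc3$edge.length), c(0.075, 0.075, 0.15))
  # fixed point
  expect_equal(scale_tree(sc, 0.1)$edge.length, sc$edge.length)
  tr0 <- tr; tr0$edge.length[] <- 0
  expect_error(scale_tree(tr0), "zero")
})

test_that("transition probabilities obey analytic forms and limits", {
  states <- c("A", "B", "C")
  q <- 0.37
  er <- mk_constraints(states, "all-free")
  er[er != ""] <- "q"
  mdl <- rate_model(c(q = q), er)
  expect_equal(transition_probabilities(mdl, 0), diag(3))
  for (t in c(0.1, 0.7, 2.5)) {
    P <- transition_probabilities(mdl, t)
    pii <- 1 / 3 + (2 / 3) * exp(-3 * q * t)
    expect_equal(unname(diag(P)), rep(pii, 3), tolerance = 1e-12)
    expect_equal(unname(P[1, 2]), (1 - pii) / 2, tolerance = 1e-12)
    expect_equal(rowSums(P), setNames(rep(1, 3), states), tolerance = 1e-12)
    expect_true(all(P >= 0))
  }
  # ergodic limit: rows converge to the stationary distribution
  set.seed(31)
  Q <- random_Q(3)
  Pinf <- transition_probabilities(Q, 500)
  expect_lt(max(abs(sweep(Pinf, 2, colMeans(Pinf)))), 1e-8)
  expect_error(transition_probabilities(mdl, -1), "t")
})

test_that("Chapman-Kolmogorov holds for random generators", {
  set.seed(32)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    Q <- random_Q(k)
    t1 <- runif(1, 0, 2); t2 <- runif(1, 0, 2)
    P12 <- transition_probabilities(Q, t1 + t2)
    P1P2 <- transition_probabilities(Q, t1) %*% transition_probabilities(Q, t2)
    expect_lt(max(abs(P12 - P1P2)), 1e-10)
  }
})

test_that("pruning likelihood matches analytic star-tree cases", {
  tr <- ape::stree(5, "star")
  tr$edge.length <- rep(0, 5)
  states <- c("A", "B", "C")
  mdl <- model_from_Q(random_Q(3), states)
  tips <- matrix(0L, 5, 3, dimnames = list(tr$tip.label, states))
  tips[, 2] <- 1L # every tip in state B, frozen chain => root must be B
  expect_equal(pruning_log_likelihood(tr, tips, mdl), log(1 / 3))
  # all-ambiguous tips carry no information: likelihood is exactly 1
  tipsA <- matrix(1L, 5, 3, dimnames = list(tr$tip.label, states))
  tr$edge.length <- runif(5, 0.1, 2)
  expect_equal(pruning_log_likelihood(tr, tipsA, mdl), 0, tolerance = 1e-12)
})

test_that("pruning likelihood equals exhaustive enumeration on 4-tip trees", {
  set.seed(33)
  for (i in 1:25) {
    tr <- ape::rtree(4)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 1.5)
    Q <- random_Q(3)
    mdl <- model_from_Q(Q)
    tips <- random_tips(tr$tip.label, 3)
    expect_equal(pruning_log_likelihood(tr, tips, mdl),
                 enum_mk_loglik(tr, tips, Q), tolerance = 1e-10)
  }
})

test_that("pruning likelihood ignores child order and tip-row order", {
  set.seed(34)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  mdl <- model_from_Q(random_Q(3))
  tips <- random_tips(tr$tip.label, 3)
  ll <- pruning_log_likelihood(tr, tips, mdl)
  rot <- ape::rotate(tr, node = 10) # swap children of one internal node
  expect_equal(pruning_log_likelihood(rot, tips, mdl), ll, tolerance = 1e-12)
  shuf <- tips[sample(nrow(tips)), , drop = FALSE]
  expect_equal(pruning_log_likelihood(tr, shuf, mdl), ll, tolerance = 1e-12)
  bad <- tips; rownames(bad)[1] <- "nonexistent"
  expect_error(pruning_log_likelihood(tr, bad, mdl), "labels")
})

test_that("impossible data under fixed-zero constraints yield -Inf with warning", {
  tr <- ape::read.tree(text = "(t1:0.3,t2:0.3);")
  mask <- mk_constraints(c("A", "B"), "all-free", zero = c("A->B"))
  mdl <- rate_model(c(qB.A = 0.5), mask, root_frequencies = c(1, 0)) # root A, can't leave
  tips <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                 dimnames = list(c("t1", "t2"), c("A", "B"))) # t1 = B: impossible
  expect_warning(ll <- pruning_log_likelihood(tr, tips, mdl), "impossible")
  expect_identical(ll, -Inf)
})

test_that("tip-state encoding applies thresholds with an argmax fallback", {
  ab <- rbind(sp1 = c(1, 0, 0), sp2 = c(0.5, 0.4, 0.1), sp3 = c(0.05, 0.05, 0.9))
  colnames(ab) <- c("Africa", "Asia", "NorthAmerica")
  expect_equal(unname(encode_tip_states(ab, 0.1)["sp1", ]), c(1L, 0L, 0L))
  expect_equal(unname(encode_tip_states(ab, 0.2)["sp2", ]), c(1L, 1L, 0L))
  expect_equal(unname(encode_tip_states(ab, 0.95)["sp3", ]), c(0L, 0L, 1L))
  expect_true(all(rowSums(encode_tip_states(ab, 0.99)) >= 1))
  expect_error(encode_tip_states(rbind(c(0, 0, 0))), "all-zero")
})

test_that("model comparison reports log-Bayes factors with the 10-unit rule", {
  expect_equal(compare_models(-50, -50)$log_bayes_factor, 0)
  expect_equal(compare_models(-50, -50)$favoured, "none")
  r <- compare_models(-40, -50)
  expect_equal(r$log_bayes_factor, 10)
  expect_equal(r$verdict, "very strong")
  expect_equal(r$favoured, "a")
  expect_equal(compare_models(-50, -41)$verdict, "not very strong")
  # antisymmetry
  expect_equal(compare_models(-12.3, -45.6)$log_bayes_factor,
               -compare_models(-45.6, -12.3)$log_bayes_factor)
})

test_that("constraint masks tie and zero out the intended rates", {
  states <- c("A", "B", "C")
  sym <- mk_constraints(states, "symmetric")
  expect_equal(sym["A", "B"], sym["B", "A"])
  expect_equal(length(setdiff(unique(as.vector(sym)), c("", "0"))), 3)
  z <- mk_constraints(states, "all-free", zero = c("A->B"))
  expect_equal(z["A", "B"], "0")
  mdl <- rate_model(c(qB.A = 1, qA.C = 2, qC.A = 3, qB.C = 4, qC.B = 5), z)
  expect_equal(mdl$Q["A", "B"], 0)
  expect_error(mk_constraints(states, zero = "A->D"), "known states")
})

test_that("MCMC respects tied constraints and samples the 1-D posterior correctly", {
  tr <- ape::read.tree(text = "(t1:0.5,t2:0.8);")
  mask <- mk_constraints(c("A", "B"), "symmetric")
  tips <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  pr <- mk_prior("uniform", min = 0, max = 20)
  fit <- mcmc_sample(tr, tips, mask, pr, iterations = 60000, burn_in = 5000,
                     thinning = 1, seed = 9)
  expect_equal(setdiff(colnames(fit$trace), "logLik"), "qA.B") # one tied parameter
  # grid quadrature of the 1-D posterior as the oracle
  q <- seq(1e-6, 20, length.out = 4001)
  ll <- vapply(q, function(x)
    pruning_log_likelihood(tr, tips, rate_model(c(qA.B = x), mask)), numeric(1))
  dens <- exp(ll)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  samp <- sort(fit$trace[, "qA.B"])
  Fs <- approx(q, cdf, xout = samp, rule = 2)$y
  ks <- max(abs(Fs - (seq_along(samp) - 0.5) / length(samp)))
  expect_lt(ks, 0.05)
})

test_that("hyper-prior MCMC samples the prior hyper-parameters too", {
  tr <- ape::read.tree(text = "(t1:0.5,t2:0.8);")
  mask <- mk_constraints(c("A", "B"), "symmetric")
  tips <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  fit <- mcmc_sample(tr, tips, mask, mk_prior("hyper-gamma"),
                     iterations = 2000, burn_in = 500, thinning = 2, seed = 10)
  expect_true(all(c("hyper_shape", "hyper_scale") %in% colnames(fit$trace)))
  expect_true(all(fit$trace[, "hyper_shape"] > 0 & fit$trace[, "hyper_shape"] < 10))
  expect_true(all(fit$trace[, "qA.B"] > 0))
})

test_that("stepping-stone marginal likelihood passes its sanity anchors", {
  states <- c("A", "B", "C")
  er <- mk_constraints(states, "all-free"); er[er != ""] <- "q"
  tr <- scale_tree(generate_tree(6, 1, seed = 5), 0.3)
  # constant likelihood (all tips ambiguous): log ML identically 0
  tipsA <- matrix(1L, 6, 3, dimnames = list(tr$tip.label, states))
  for (fam in c("uniform", "exponential", "gamma")) {
    ss <- stepping_stone_logml(tr, tipsA, er, mk_prior(fam), n_stones = 15,
                               iterations_per_stone = 40, seed = 1)
    expect_lt(abs(ss$log_marginal_likelihood), 1e-12)
  }
  # beta schedule contract
  ss <- stepping_stone_logml(tr, tipsA, er, mk_prior("exponential"),
                             n_stones = 12, iterations_per_stone = 20, seed = 2)
  expect_equal(ss$beta_schedule[1], 1)
  expect_equal(ss$beta_schedule[length(ss$beta_schedule)], 0)
  expect_true(all(diff(ss$beta_schedule) < 0))
})

test_that("more iterations per stone reduce stepping-stone variance", {
  states <- c("A", "B", "C")
  er <- mk_constraints(states, "all-free"); er[er != ""] <- "q"
  tr <- scale_tree(generate_tree(6, 1, seed = 5), 0.3)
  tips <- simulate_tip_states(tr, rate_model(c(q = 0.7), er), seed = 6)
  est <- function(iters, seeds) vapply(seeds, function(s)
    stepping_stone_logml(tr, tips, er, mk_prior("exponential"), n_stones = 20,
                         iterations_per_stone = iters, initial_burn_in = 200,
                         seed = s)$log_marginal_likelihood, numeric(1))
  sd_small <- sd(est(50, 1:10))
  sd_big <- sd(est(200, 1:10))
  expect_lt(sd_big, sd_small)
})

test_that("run congruence passes identical chains and fails divergent ones", {
  set.seed(41)
  tr1 <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "q"))
  same <- run_congruence(list(tr1, tr1, tr1))
  expect_equal(unname(same$psrf[["q"]]), 1, tolerance = 0.01)
  expect_true(same$pass)

  far <- matrix(rnorm(500, 10), ncol = 1, dimnames = list(NULL, "q"))
  bad <- run_congruence(list(tr1, far))
  expect_gt(bad$psrf[["q"]], 3)
  expect_false(bad$pass)

  chains <- lapply(1:3, function(i)
    matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "q")))
  expect_true(run_congruence(chains)$pass)
  expect_error(run_congruence(list(tr1)), "two runs")
})

test_that("mk_mcmc methods expose the posterior summaries", {
  states <- c("A", "B")
  tr <- generate_tree(12, 1, seed = 2)
  mdl <- rate_model(c(qA.B = 0.5), mk_constraints(states, "symmetric"))
  tips <- simulate_tip_states(scale_tree(tr), mdl, seed = 3)
  fit <- mcmc_sample(scale_tree(tr), tips, mk_constraints(states, "symmetric"),
                     mk_prior("exponential"), iterations = 1200, burn_in = 300,
                     thinning = 3, seed = 4)
  expect_s3_class(fit, "mk_mcmc")
  sm <- summary(fit)
  expect_true(all(c("median", "ci_lower", "ci_upper") %in% names(sm)))
  expect_true(all(sm$ci_lower <= sm$median & sm$median <= sm$ci_upper))
  expect_named(coef(fit), "qA.B")
  expect_output(print(fit), "Mk transition-rate MCMC")
  expect_s3_class(logLik(fit), "logLik")
})
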