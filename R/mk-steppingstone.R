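# Stepping-stone estimation of the log marginal likelihood, and log-Bayes
# factor model comparison.

#' Stepping-stone log marginal likelihood
#'
#' Path-sampling estimate of the marginal likelihood of an Mk transition model
#' by the stepping-stone method: power posteriors proportional to
#' `L(theta)^beta * prior(theta)` are sampled along a decreasing beta schedule
#' given by quantiles of Beta(0.4, 1) (`beta_k = ((K - k)/K)^(1/0.4)`), and
#' each adjacent pair contributes the log of the importance-sampling mean of
#' `L^(beta_{k-1} - beta_k)` computed from the chain at the smaller beta. The
#' chain is warm-started stone to stone from beta = 1 down to beta = 0.
#'
#' @inheritParams mcmc_sample
#' @param n_stones number of stones (default 100).
#' @param iterations_per_stone sweeps retained per stone (default 1000).
#' @param warmup_per_stone extra sweeps discarded at each stone after the beta
#'   change (default 10% of `iterations_per_stone`).
#' @param initial_burn_in sweeps used to reach the posterior before the first
#'   stone (default 1000).
#' @return object of class `stepping_stone`: list with
#'   `log_marginal_likelihood`, `beta_schedule`, `n_stones`,
#'   `iterations_per_stone`, per-stone contributions `stone_log_ratio`.
#' @export
stepping_stone_logml <- function(tree, tips, constraints = NULL,
                                 prior = mk_prior("gamma"),
                                 n_stones = 100, iterations_per_stone = 1000,
                                 warmup_per_stone = NULL,
                                 initial_burn_in = 1000,
                                 seed = NULL, root_frequencies = NULL,
                                 init = NULL) {
  stop_if(n_stones < 2, "need at least 2 stones")
  stop_if(iterations_per_stone < 1, "iterations_per_stone must be >= 1")
  if (is.null(warmup_per_stone)) warmup_per_stone <- ceiling(iterations_per_stone / 10)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(constraints)) {
    stop_if(is.null(colnames(tips)), "need state names (tips colnames) or constraints")
    constraints <- mk_constraints(colnames(tips), "all-free")
  }
  eng <- mk_build_engine(tree, tips, constraints, root_frequencies)
  np <- length(eng$labels)
  hs <- prior_hyper_spec(prior)
  nh <- length(hs$names)
  hyper <- if (nh) setNames((hs$lower + hs$upper) / 2 * rep(1, nh), hs$names) else NULL

  # beta_0 = 1 > beta_1 > ... > beta_K = 0 (quantiles of Beta(0.4, 1))
  betas <- ((n_stones:0) / n_stones)^(1 / 0.4)

  rates <- if (!is.null(init)) as.numeric(init[eng$labels]) else rep(0.1, np)
  ll <- eng$loglik(rates)
  step <- rep(0.6, np)
  hstep <- rep((hs$upper - hs$lower) / 10, nh)

  one_sweep <- function(beta, adapt_state) {
    for (p in seq_len(np)) {
      prop <- rates
      prop[p] <- rates[p] * exp(rnorm(1, 0, step[p]))
      lpp <- prior_log_density(prior, prop[p], hyper)
      if (is.finite(lpp)) {
        llp <- eng$loglik(prop)
        lr <- beta * (llp - ll) +
          lpp - prior_log_density(prior, rates[p], hyper) +
          log(prop[p] / rates[p])
        if (is.finite(lr) && log(runif(1)) < lr) {
          rates <<- prop; ll <<- llp
          if (adapt_state) step[p] <<- min(5, step[p] * exp(0.02))
        } else if (adapt_state) step[p] <<- max(0.02, step[p] * exp(-0.01))
      } else if (adapt_state) step[p] <<- max(0.02, step[p] * exp(-0.01))
    }
    if (nh) {
      lp_all <- function(h) sum(vapply(rates, function(x)
        prior_log_density(prior, x, h), numeric(1)))
      for (h in seq_len(nh)) {
        hp <- hyper
        x <- hyper[h] + rnorm(1, 0, hstep[h])
        while (x < hs$lower || x > hs$upper) {
          if (x < hs$lower) x <- 2 * hs$lower - x
          if (x > hs$upper) x <- 2 * hs$upper - x
        }
        hp[h] <- x
        if (log(runif(1)) < lp_all(hp) - lp_all(hyper)) hyper <<- hp
      }
    }
    invisible(NULL)
  }

  for (i in seq_len(initial_burn_in)) one_sweep(1, adapt_state = TRUE)

  stone_log_ratio <- numeric(n_stones)
  for (k in seq_len(n_stones)) {
    b_hi <- betas[k]      # beta_{k-1}
    b_lo <- betas[k + 1]  # beta_k, the chain's power
    for (i in seq_len(warmup_per_stone)) one_sweep(b_lo, adapt_state = FALSE)
    lls <- numeric(iterations_per_stone)
    for (i in seq_len(iterations_per_stone)) {
      one_sweep(b_lo, adapt_state = FALSE)
      lls[i] <- ll
    }
    w <- (b_hi - b_lo) * lls
    mx <- max(w)
    stone_log_ratio[k] <- mx + log(mean(exp(w - mx)))
  }
  structure(list(
    log_marginal_likelihood = sum(stone_log_ratio),
    beta_schedule = betas,
    n_stones = n_stones,
    iterations_per_stone = iterations_per_stone,
    stone_log_ratio = stone_log_ratio,
    prior = prior,
    seed = seed), class = "stepping_stone")
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat("Stepping-stone marginal likelihood:",
      format(x$log_marginal_likelihood, digits = 8), "\n")
  cat(x$n_stones, "stones x", x$iterations_per_stone, "iterations,",
      x$prior$family, "prior\n")
  invisible(x)
}

#' Compare two models by log-Bayes factor
#'
#' `log BF = logML_a - logML_b`. A magnitude of at least 10 log marginal
#' likelihood units is reported as very strong evidence for one model over the
#' other.
#'
#' @param logml_a,logml_b log marginal likelihoods (numbers or
#'   `stepping_stone` objects).
#' @return list with `log_bayes_factor`, `verdict` (`"very strong"` or
#'   `"not very strong"`), `favoured` (`"a"`, `"b"` or `"none"`).
#' @export
#' @examples
#' compare_models(-40, -50)
compare_models <- function(logml_a, logml_b) {
  val <- function(x) if (inherits(x, "stepping_stone")) x$log_marginal_likelihood else x
  a <- check_number(val(logml_a), "logml_a")
  b <- check_number(val(logml_b), "logml_b")
  lbf <- a - b
  list(log_bayes_factor = lbf,
       verdict = if (abs(lbf) >= 10) "very strong" else "not very strong",
       favoured = if (lbf > 0) "a" else if (lbf < 0) "b" else "none")
}
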