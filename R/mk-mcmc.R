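# MCMC over constrained Mk transition-rate matrices.
#
# One iteration = one Metropolis-Hastings sweep: every free rate parameter is
# updated once with a multiplicative log-normal random walk (Hastings
# correction r'/r), then any hyper-parameters of a hyper-prior are updated
# with a reflected uniform random walk (these touch only the prior, not the
# likelihood). Proposal step sizes adapt toward 20-40% acceptance during
# burn-in only and are frozen afterwards, preserving detailed balance for the
# retained samples.

# internal: fast likelihood closure. Builds Q by direct indexing instead of
# rate_model() on every evaluation.
mk_build_engine <- function(tree, tips, mask, root_frequencies) {
  states <- rownames(mask)
  k <- length(states)
  tips <- as.matrix(tips)
  stop_if(is.null(rownames(tips)), "tip-state matrix must have row names")
  stop_if(!setequal(rownames(tips), tree$tip.label),
          "tip labels of the state matrix and the tree do not match")
  if (!is.null(colnames(tips))) tips <- tips[, states, drop = FALSE]
  tips <- tips[tree$tip.label, , drop = FALSE]
  storage.mode(tips) <- "double"
  if (is.null(root_frequencies)) root_frequencies <- rep(1 / k, k)
  po <- ape::reorder.phylo(tree, "postorder")
  labels <- setdiff(unique(as.vector(mask)), c("", "0"))
  pos <- lapply(labels, function(lb) which(mask == lb))
  names(pos) <- labels
  # self-test: an all-ambiguous tip matrix must give likelihood exactly 1
  ones <- matrix(1, nrow(tips), k)
  Q0 <- matrix(0, k, k)
  Q0[pos[[1]][1]] <- 0.5
  diag(Q0) <- -rowSums(Q0)
  self <- mk_loglik_cpp(Q0, po$edge, po$edge.length, ones, root_frequencies)
  stop_if(abs(self) > 1e-8, "internal self-test failed: ambiguous-tip likelihood != 1")
  list(
    labels = labels,
    k = k,
    loglik = function(rates) {
      Q <- matrix(0, k, k)
      for (i in seq_along(labels)) Q[pos[[i]]] <- rates[[i]]
      diag(Q) <- -rowSums(Q)
      mk_loglik_cpp(Q, po$edge, po$edge.length, tips, root_frequencies)
    })
}

#' Sample transition rates by Markov chain Monte Carlo
#'
#' Fits a K-state Mk transition model on a rooted phylogeny by
#' Metropolis-Hastings, under a constraint mask (free / tied / fixed-zero
#' rates) and one of the supported prior families. This is the package's
#' model-fitting entry point; the returned object has `print`, `summary`,
#' `coef`, `plot` and `logLik` methods.
#'
#' @param tree rooted [ape::phylo] with branch lengths (conventionally scaled
#'   to mean branch length 0.1 with [scale_tree()] first).
#' @param tips 0/1 tip-state matrix (see [encode_tip_states()]).
#' @param constraints constraint mask from [mk_constraints()]; default all
#'   ordered pairs free.
#' @param prior an [mk_prior()]; default gamma(shape 1, scale 1).
#' @param iterations total MCMC sweeps.
#' @param burn_in sweeps discarded (and used for proposal adaptation).
#' @param thinning keep every `thinning`-th post-burn-in sweep.
#' @param seed optional integer seed.
#' @param root_frequencies probability vector over states; default uniform.
#' @param beta power-posterior exponent on the likelihood (used by the
#'   stepping-stone sampler; leave at 1 for ordinary posterior sampling).
#' @param init optional named vector of starting rates.
#' @return object of class `mk_mcmc` with elements `trace` (matrix of retained
#'   samples: free rates, hyper-parameters, log-likelihood), `acceptance`
#'   (per-parameter rates), `states`, `mask`, `prior`, `config`.
#' @export
mcmc_sample <- function(tree, tips, constraints = NULL,
                        prior = mk_prior("gamma"),
                        iterations = 10000, burn_in = 2000, thinning = 10,
                        seed = NULL, root_frequencies = NULL, beta = 1,
                        init = NULL) {
  stop_if(!inherits(prior, "mk_prior"), "prior must come from mk_prior()")
  stop_if(burn_in >= iterations, "burn_in must be smaller than iterations")
  stop_if(thinning < 1, "thinning must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(constraints)) {
    stop_if(is.null(colnames(tips)), "need state names (tips colnames) or constraints")
    constraints <- mk_constraints(colnames(tips), "all-free")
  }
  eng <- mk_build_engine(tree, tips, constraints, root_frequencies)
  np <- length(eng$labels)
  stop_if(np < 1, "model has no free parameters")
  hs <- prior_hyper_spec(prior)
  nh <- length(hs$names)
  hyper <- if (nh) setNames((hs$lower + hs$upper) / 2 * rep(1, nh), hs$names) else NULL

  rates <- if (!is.null(init)) {
    stop_if(!all(eng$labels %in% names(init)), "init must name every free rate")
    as.numeric(init[eng$labels])
  } else rep(0.1, np)
  lp_rates <- function(r, h) sum(vapply(r, function(x)
    prior_log_density(prior, x, h), numeric(1)))
  stop_if(!is.finite(lp_rates(rates, hyper)),
          "invalid prior: initial rates have zero prior density")
  ll <- eng$loglik(rates)
  step <- rep(0.6, np)
  hstep <- rep((hs$upper - hs$lower) / 10, nh)
  acc <- numeric(np); try_n <- numeric(np)
  hacc <- numeric(nh); htry <- numeric(nh)
  awin_acc <- numeric(np); awin_try <- numeric(np)

  n_keep <- floor((iterations - burn_in) / thinning)
  trace <- matrix(NA_real_, n_keep, np + nh + 1,
                  dimnames = list(NULL, c(eng$labels,
                                          if (nh) paste0("hyper_", hs$names),
                                          "logLik")))
  kept <- 0L
  for (it in seq_len(iterations)) {
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
          rates <- prop; ll <- llp
          acc[p] <- acc[p] + 1; awin_acc[p] <- awin_acc[p] + 1
        }
      }
      try_n[p] <- try_n[p] + 1; awin_try[p] <- awin_try[p] + 1
    }
    if (nh) {
      for (h in seq_len(nh)) {
        hp <- hyper
        x <- hyper[h] + rnorm(1, 0, hstep[h])
        # reflect into the hyper range
        rng <- c(hs$lower, hs$upper)
        while (x < rng[1] || x > rng[2]) {
          if (x < rng[1]) x <- 2 * rng[1] - x
          if (x > rng[2]) x <- 2 * rng[2] - x
        }
        hp[h] <- x
        lr <- lp_rates(rates, hp) - lp_rates(rates, hyper)
        if (is.finite(lr) && log(runif(1)) < lr) {
          hyper <- hp; hacc[h] <- hacc[h] + 1
        }
        htry[h] <- htry[h] + 1
      }
    }
    # adapt during burn-in only
    if (it <= burn_in && it %% 50 == 0) {
      w <- awin_try > 0
      rate_w <- ifelse(w, awin_acc / pmax(awin_try, 1), 0.3)
      step <- pmin(5, pmax(0.02, step * exp(rate_w - 0.3)))
      awin_acc[] <- 0; awin_try[] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0 && kept < n_keep) {
      kept <- kept + 1L
      trace[kept, ] <- c(rates, if (nh) hyper, ll)
    }
  }
  structure(list(
    trace = trace[seq_len(kept), , drop = FALSE],
    acceptance = setNames(acc / pmax(try_n, 1), eng$labels),
    hyper_acceptance = if (nh) setNames(hacc / pmax(htry, 1), hs$names),
    states = rownames(constraints),
    mask = constraints,
    prior = prior,
    beta = beta,
    config = list(iterations = iterations, burn_in = burn_in,
                  thinning = thinning, seed = seed)),
    class = "mk_mcmc")
}

#' @export
print.mk_mcmc <- function(x, ...) {
  cat("Mk transition-rate MCMC (", x$prior$family, " prior)\n", sep = "")
  cat(nrow(x$trace), "retained samples;",
      x$config$iterations, "sweeps,", x$config$burn_in, "burn-in\n")
  print(round(coef(x), 5))
  invisible(x)
}

#' @export
summary.mk_mcmc <- function(object, prob = 0.95, ...) {
  tr <- object$trace
  pars <- setdiff(colnames(tr), "logLik")
  a <- (1 - prob) / 2
  out <- data.frame(
    parameter = pars,
    median = apply(tr[, pars, drop = FALSE], 2, median),
    mean = colMeans(tr[, pars, drop = FALSE]),
    ci_lower = apply(tr[, pars, drop = FALSE], 2, quantile, probs = a),
    ci_upper = apply(tr[, pars, drop = FALSE], 2, quantile, probs = 1 - a),
    row.names = NULL)
  attr(out, "acceptance") <- object$acceptance
  out
}

#' @export
coef.mk_mcmc <- function(object, ...) {
  pars <- setdiff(colnames(object$trace), "logLik")
  pars <- pars[!startsWith(pars, "hyper_")]
  apply(object$trace[, pars, drop = FALSE], 2, median)
}

#' @export
logLik.mk_mcmc <- function(object, ...) {
  ll <- max(object$trace[, "logLik"])
  attr(ll, "df") <- sum(!startsWith(colnames(object$trace), "hyper_")) - 1
  class(ll) <- "logLik"
  ll
}

#' @export
plot.mk_mcmc <- function(x, ...) {
  pars <- setdiff(colnames(x$trace), "logLik")
  old <- graphics::par(mfrow = c(length(pars) + 1, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in c(pars, "logLik")) {
    graphics::plot(x$trace[, p], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Gelman-Rubin congruence check across independent MCMC runs
#'
#' Computes the potential scale reduction factor (PSRF) for every free rate
#' parameter across independent chains, and passes when all PSRF < 1.1 --
#' the usual check that repeated runs of the transition analysis agree.
#'
#' @param runs list of `mk_mcmc` objects (or plain trace matrices) sharing the
#'   same parameters; at least 2.
#' @param threshold pass threshold on PSRF (default 1.1).
#' @return list with `psrf` (named vector), `pass` (logical), `threshold`.
#' @export
run_congruence <- function(runs, threshold = 1.1) {
  stop_if(length(runs) < 2, "need at least two runs")
  traces <- lapply(runs, function(r) {
    tr <- if (inherits(r, "mk_mcmc")) r$trace else as.matrix(r)
    tr[, setdiff(colnames(tr), "logLik"), drop = FALSE]
  })
  pars <- colnames(traces[[1]])
  stop_if(!all(vapply(traces, function(t) identical(colnames(t), pars), logical(1))),
          "runs do not share the same parameters")
  n <- min(vapply(traces, nrow, integer(1)))
  stop_if(n < 2, "runs are too short for a PSRF")
  m <- length(traces)
  psrf <- vapply(pars, function(p) {
    ch <- vapply(traces, function(t) t[seq_len(n), p], numeric(n))
    W <- mean(apply(ch, 2, var))
    B_over_n <- var(colMeans(ch))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B_over_n) / W)
  }, numeric(1))
  list(psrf = psrf, pass = all(psrf < threshold), threshold = threshold)
}
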