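#' Constraint masks for a K-state transition-rate matrix
#'
#' Builds the constraint mask used by [rate_model()] and [mcmc_sample()]. Each
#' ordered state pair (i, j), i != j, is either a free parameter, tied to
#' another pair (sharing one parameter), or fixed at zero. The presets cover
#' the model family compared in the continental transition analysis: all rates
#' free, forward and reverse rates tied (q_ij = q_ji), and single rates pinned
#' to zero.
#'
#' @param states character vector of state labels (e.g. continents).
#' @param type `"all-free"` (every ordered pair its own parameter) or
#'   `"symmetric"` (q_ij tied to q_ji).
#' @param zero character vector of ordered pairs to fix at zero, each written
#'   `"A->B"`.
#' @return character matrix K x K; `""` on the diagonal, `"0"` for fixed-zero
#'   entries, otherwise a parameter label (entries sharing a label are tied).
#' @export
#' @examples
#' mk_constraints(c("Africa", "Asia", "NorthAmerica"), type = "symmetric")
mk_constraints <- function(states, type = c("all-free", "symmetric"),
                           zero = character()) {
  type <- match.arg(type)
  k <- length(states)
  stop_if(k < 2, "need at least 2 states")
  stop_if(anyDuplicated(states) > 0, "state labels must be unique")
  mask <- matrix("", k, k, dimnames = list(states, states))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    mask[i, j] <- if (type == "symmetric") {
      paste0("q", paste(sort(c(states[i], states[j])), collapse = "."))
    } else {
      paste0("q", states[i], ".", states[j])
    }
  }
  for (z in zero) {
    ij <- strsplit(z, "->", fixed = TRUE)[[1]]
    stop_if(length(ij) != 2 || !all(ij %in% states),
            sprintf("zero constraint '%s' is not 'A->B' over known states", z))
    mask[ij[1], ij[2]] <- "0"
  }
  mask
}

#' Transition-rate model (generator matrix) for discrete geographic states
#'
#' Assembles the generator matrix Q of a continuous-time Markov chain over K
#' discrete states (continents) from named rate parameters and a constraint
#' mask. Rows of Q sum to zero (diagonal = minus the off-diagonal row sum).
#'
#' @param rates named numeric vector, one entry per free parameter label in
#'   `mask`; all values must be >= 0.
#' @param mask constraint mask from [mk_constraints()].
#' @param root_frequencies probability vector over states; default uniform.
#' @return object of class `rate_model`: list with `Q`, `mask`, `states`,
#'   `params`, `root_frequencies`.
#' @export
rate_model <- function(rates, mask, root_frequencies = NULL) {
  states <- rownames(mask)
  k <- length(states)
  labels <- setdiff(unique(as.vector(mask)), c("", "0"))
  stop_if(!all(labels %in% names(rates)),
          paste("missing rates for parameters:",
                paste(setdiff(labels, names(rates)), collapse = ", ")))
  stop_if(any(!is.finite(rates)) || any(rates < 0),
          "all rates must be finite and >= 0")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || mask[i, j] == "0") next
    Q[i, j] <- rates[[mask[i, j]]]
  }
  diag(Q) <- -rowSums(Q)
  if (is.null(root_frequencies)) root_frequencies <- rep(1 / k, k)
  stop_if(length(root_frequencies) != k || any(root_frequencies < 0) ||
            abs(sum(root_frequencies) - 1) > 1e-8,
          "root_frequencies must be a probability vector over the states")
  structure(list(Q = Q, mask = mask, states = states,
                 params = rates[labels],
                 root_frequencies = as.numeric(root_frequencies)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("K-state transition rate model (", length(x$states), " states)\n", sep = "")
  print(round(x$Q, 6))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes the matrix exponential of the generator scaled by elapsed branch
#' length. Uses eigendecomposition, falling back to scaling-and-squaring when
#' the generator is defective; rows are renormalized to sum to one (tolerance
#' 1e-12).
#'
#' @param model a [rate_model()] or a plain generator matrix Q.
#' @param t branch length (>= 0).
#' @return K x K row-stochastic matrix.
#' @export
#' @examples
#' m <- rate_model(c(qA.B = 1), mk_constraints(c("A", "B"), "symmetric"))
#' transition_probabilities(m, 0.5)
transition_probabilities <- function(model, t) {
  Q <- if (inherits(model, "rate_model")) model$Q else model
  stop_if(!is.matrix(Q) || nrow(Q) != ncol(Q), "Q must be square")
  check_number(t, "t", lower = 0)
  k <- nrow(Q)
  if (t == 0) return(diag(k))
  P <- NULL
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    V <- eg$vectors
    Vinv <- tryCatch(solve(V), error = function(e) NULL)
    if (!is.null(Vinv)) {
      recon <- Re(V %*% diag(eg$values, k) %*% Vinv)
      nq <- max(norm(Q, "F"), 1e-300)
      if (norm(recon - Q, "F") / nq <= 1e-9) {
        P <- Re(V %*% diag(exp(eg$values * t), k) %*% Vinv)
      }
    }
  }
  if (is.null(P)) P <- expm_ss(Q * t)
  P[P < 0 & P > -1e-12] <- 0
  rs <- rowSums(P)
  stop_if(any(abs(rs - 1) > 1e-6), "matrix exponential failed row-sum check")
  P <- P / rs
  dimnames(P) <- dimnames(Q)
  P
}

# scaling-and-squaring with Pade-free Taylor core; adequate for small K
expm_ss <- function(A) {
  k <- nrow(A)
  s <- max(0L, ceiling(log2(max(norm(A, "I"), 1e-300))) + 2L)
  As <- A / 2^s
  P <- diag(k)
  term <- diag(k)
  for (n in 1:20) {
    term <- term %*% As / n
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Scale a phylogeny to a target mean branch length
#'
#' Multiplies every branch length by one constant so that the mean branch
#' length over all edges equals `target_mean` exactly. Used before transition
#' inference to avoid numerically tiny rates (the conventional target is 0.1).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param target_mean positive target mean branch length (default 0.1).
#' @return the rescaled tree.
#' @export
scale_tree <- function(tree, target_mean = 0.1) {
  stop_if(!inherits(tree, "phylo"), "tree must be a 'phylo' object")
  stop_if(is.null(tree$edge.length), "tree has no branch lengths")
  check_number(target_mean, "target_mean", lower = .Machine$double.xmin)
  m <- mean(tree$edge.length)
  stop_if(m <= 0, "invalid tree: all branch lengths are zero")
  tree$edge.length <- tree$edge.length * (target_mean / m)
  tree
}

#' Encode continent tip states from relative abundances
#'
#' Converts a species-by-continent relative abundance table into 0/1 ambiguity
#' vectors: continent j is a compatible state for a species when the species'
#' abundance fraction on continent j is at least `ambiguity_threshold`. A
#' species whose fractions all fall below the threshold keeps its single
#' highest-abundance continent, so every tip has at least one compatible
#' state.
#'
#' @param abundance matrix or data.frame, species (rows) x continents
#'   (columns), nonnegative; rows are normalized to fractions internally.
#' @param ambiguity_threshold fraction in (0, 1]; default 0.05.
#' @return integer 0/1 matrix with the same dimnames (a tip-state matrix).
#' @export
#' @examples
#' encode_tip_states(rbind(sp1 = c(1, 0, 0), sp2 = c(0.5, 0.4, 0.1)),
#'                   ambiguity_threshold = 0.2)
encode_tip_states <- function(abundance, ambiguity_threshold = 0.05) {
  x <- as.matrix(abundance)
  stop_if(any(x < 0) || any(!is.finite(x)), "abundances must be finite and >= 0")
  check_number(ambiguity_threshold, "ambiguity_threshold",
               lower = .Machine$double.xmin, upper = 1)
  tot <- rowSums(x)
  stop_if(any(tot == 0), "species with all-zero abundance cannot be encoded")
  frac <- x / tot
  states <- (frac >= ambiguity_threshold) * 1L
  none <- rowSums(states) == 0L
  if (any(none)) {
    amax <- max.col(frac[none, , drop = FALSE], ties.method = "first")
    states[cbind(which(none), amax)] <- 1L
  }
  storage.mode(states) <- "integer"
  states
}

#' Prior specification for transition rates
#'
#' The prior families compared in the transition analysis: uniform,
#' exponential, gamma, and their hyper-prior versions in which the prior's own
#' parameters are sampled as extra MCMC dimensions from uniform hyper ranges.
#'
#' @param family one of `"uniform"`, `"exponential"`, `"gamma"`,
#'   `"hyper-uniform"`, `"hyper-exponential"`, `"hyper-gamma"`.
#' @param ... family parameters: `min`/`max` (uniform, defaults 0/100), `mean`
#'   (exponential, default 1), `shape`/`scale` (gamma, defaults 1/1),
#'   `hyper_max` (upper bound of the uniform hyper range; defaults 10, or 100
#'   for hyper-uniform).
#' @return object of class `mk_prior`.
#' @export
mk_prior <- function(family = c("uniform", "exponential", "gamma",
                                "hyper-uniform", "hyper-exponential",
                                "hyper-gamma"), ...) {
  family <- match.arg(family)
  dots <- list(...)
  take <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  spec <- switch(family,
    "uniform" = list(min = take("min", 0), max = take("max", 100)),
    "exponential" = list(mean = take("mean", 1)),
    "gamma" = list(shape = take("shape", 1), scale = take("scale", 1)),
    "hyper-uniform" = list(hyper_max = take("hyper_max", 100)),
    "hyper-exponential" = list(hyper_max = take("hyper_max", 10)),
    "hyper-gamma" = list(hyper_max = take("hyper_max", 10)))
  if (family == "uniform") stop_if(spec$max <= spec$min, "uniform prior needs max > min")
  structure(c(list(family = family), spec), class = "mk_prior")
}

# log prior density of one rate given (possibly sampled) prior parameters.
# 'hyper' is a named numeric vector of current hyper-parameter values.
prior_log_density <- function(prior, rate, hyper = NULL) {
  switch(prior$family,
    "uniform" = ifelse(rate >= prior$min & rate <= prior$max,
                       -log(prior$max - prior$min), -Inf),
    "exponential" = stats::dexp(rate, rate = 1 / prior$mean, log = TRUE),
    "gamma" = stats::dgamma(rate, shape = prior$shape, scale = prior$scale, log = TRUE),
    "hyper-uniform" = ifelse(rate >= 0 & rate <= hyper[["max"]],
                             -log(hyper[["max"]]), -Inf),
    "hyper-exponential" = stats::dexp(rate, rate = 1 / hyper[["mean"]], log = TRUE),
    "hyper-gamma" = stats::dgamma(rate, shape = hyper[["shape"]],
                                  scale = hyper[["scale"]], log = TRUE))
}

# names, support and initial values of the hyper-parameters (empty if none)
prior_hyper_spec <- function(prior) {
  switch(prior$family,
    "hyper-uniform" = list(names = "max", lower = 1e-8, upper = prior$hyper_max),
    "hyper-exponential" = list(names = "mean", lower = 1e-8, upper = prior$hyper_max),
    "hyper-gamma" = list(names = c("shape", "scale"), lower = 1e-8,
                         upper = prior$hyper_max),
    list(names = character(), lower = numeric(), upper = numeric()))
}
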