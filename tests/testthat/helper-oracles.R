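# Independent oracles used across the suite.

# Brute-force Mk likelihood: sum over all internal-node state assignments.
# Transition matrices via Matrix::expm (independent of the package's C++
# pruning path and of its eigendecomposition).
enum_mk_loglik <- function(tree, tips, Q, root_freq = rep(1 / nrow(Q), nrow(Q))) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_node)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_tip + n_node)
    st[n_tip + seq_len(n_node)] <- grid[g, ]
    prob <- root_freq[st[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- st[tree$edge[e, 1]]
      ch <- tree$edge[e, 2]
      prob <- prob * if (ch <= n_tip) {
        sum(P[[e]][par, tips[tree$tip.label[ch], ] == 1])
      } else {
        P[[e]][par, st[ch]]
      }
    }
    tot <- tot + prob
  }
  log(tot)
}

# Exact two-sided Mann-Whitney p by enumerating all group-label assignments.
enum_mw_p <- function(a, b) {
  pool <- c(a, b)
  m <- length(a)
  idx <- combn(length(pool), m)
  r <- rank(pool)
  us <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# random valid tip-state matrix: one state per tip, occasionally ambiguous
random_tips <- function(tip_labels, k, amb_prob = 0.2) {
  n <- length(tip_labels)
  m <- matrix(0L, n, k, dimnames = list(tip_labels, paste0("S", seq_len(k))))
  m[cbind(seq_len(n), sample.int(k, n, replace = TRUE))] <- 1L
  amb <- runif(n) < amb_prob
  if (any(amb)) {
    extra <- sapply(which(amb), function(i)
      sample(setdiff(seq_len(k), which(m[i, ] == 1L)), 1))
    m[cbind(which(amb), extra)] <- 1L
  }
  m
}

# random generator matrix over k states
random_Q <- function(k, lo = 0.05, hi = 1.5) {
  Q <- matrix(runif(k * k, lo, hi), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# rate_model from a plain Q matrix (all-free mask)
model_from_Q <- function(Q, states = paste0("S", seq_len(nrow(Q))),
                         root_freq = NULL) {
  dimnames(Q) <- list(states, states)
  mask <- mk_constraints(states, "all-free")
  rates <- numeric(0)
  for (i in seq_len(nrow(Q))) for (j in seq_len(ncol(Q)))
    if (i != j) rates[mask[i, j]] <- Q[i, j]
  rate_model(rates, mask, root_frequencies = root_freq)
}
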