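#' Pruning (Felsenstein) log-likelihood of tip states under an Mk model
#'
#' Computes the log-likelihood of discrete tip states on a rooted phylogeny
#' under a continuous-time Markov chain with generator Q, by post-order
#' pruning. Tip ambiguity is supported through 0/1 state-compatibility
#' vectors: a tip row of all ones contributes no information. The likelihood
#' is `sum_i root_freq_i * partial_root_i`, returned as a natural log
#' (`-Inf`, with a warning, when the data are impossible under the model, e.g.
#' under fixed-zero rate constraints).
#'
#' @param tree rooted [ape::phylo] tree with branch lengths (zero-length
#'   branches are allowed and contribute an identity transition matrix).
#' @param tips 0/1 matrix, rows named by tip label, one column per state;
#'   every row needs at least one 1. See [encode_tip_states()].
#' @param model a [rate_model()] whose states match `colnames(tips)` (column
#'   order is taken from the model when names are present).
#' @return log-likelihood (numeric scalar).
#' @export
pruning_log_likelihood <- function(tree, tips, model) {
  stop_if(!inherits(tree, "phylo"), "tree must be a 'phylo' object")
  stop_if(!inherits(model, "rate_model"), "model must be a 'rate_model'")
  stop_if(is.null(tree$edge.length), "tree has no branch lengths")
  tips <- as.matrix(tips)
  stop_if(is.null(rownames(tips)), "tip-state matrix must have row names")
  stop_if(!setequal(rownames(tips), tree$tip.label) ||
            nrow(tips) != length(tree$tip.label),
          "tip labels of the state matrix and the tree do not match")
  k <- length(model$states)
  stop_if(ncol(tips) != k, "tip-state matrix has wrong number of states")
  if (!is.null(colnames(tips))) {
    stop_if(!setequal(colnames(tips), model$states),
            "state names of the tip matrix and the model do not match")
    tips <- tips[, model$states, drop = FALSE]
  }
  stop_if(any(!tips %in% c(0, 1)), "tip states must be 0/1")
  stop_if(any(rowSums(tips) == 0), "every tip needs at least one compatible state")
  tips <- tips[tree$tip.label, , drop = FALSE]

  po <- ape::reorder.phylo(tree, "postorder")
  ll <- mk_loglik_cpp(model$Q, po$edge, po$edge.length,
                      matrix(as.numeric(tips), nrow(tips), k),
                      model$root_frequencies)
  if (identical(ll, -Inf)) {
    warning("likelihood is zero: tip data impossible under this model")
  }
  ll
}
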