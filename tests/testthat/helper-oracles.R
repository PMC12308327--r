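# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's compiled likelihood path:
# transition probabilities come from Matrix::expm and likelihoods from
# exhaustive sums over internal-node state assignments.

oracle_pmat <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# Exhaustive joint computation over all internal-node state assignments.
# Returns the total likelihood and the per-internal-node marginal matrix,
# so the same brute force checks both the pruning likelihood and the
# marginal ancestral reconstruction.
oracle_joint <- function(tree, tipliks, Q, prior) {
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  lens <- po$edge.length
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internals <- (ntip + 1L):nnode
  k <- nrow(Q)
  P <- lapply(seq_len(nrow(edge)), function(e) oracle_pmat(Q, lens[e]))

  A <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  colnames(A) <- internals
  p <- prior[A[, as.character(ntip + 1L)]]
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    sp <- A[, as.character(par)]
    if (ch <= ntip) {
      tipvec <- as.vector(P[[e]] %*% tipliks[, ch])
      p <- p * tipvec[sp]
    } else {
      p <- p * P[[e]][cbind(sp, A[, as.character(ch)])]
    }
  }
  total <- sum(p)
  marg <- vapply(as.character(internals), function(j) {
    as.vector(tapply(p, factor(A[, j], levels = seq_len(k)), sum)) / total
  }, numeric(k))
  list(loglik = log(total), marginals = t(marg))  # rows = internal nodes
}

oracle_loglik <- function(tree, tipliks, Q, prior) {
  oracle_joint(tree, tipliks, Q, prior)$loglik
}

# A random constrained rate matrix: random model, log-uniform rates.
random_sparse_q <- function(rate_range = c(0.05, 2)) {
  model <- sample(enumerate_models()$name, 1)
  tpl <- build_template(model)
  rates <- exp(runif(attr(tpl, "n_free"), log(rate_range[1]), log(rate_range[2])))
  build_q(tpl, rates)
}

# A random ultrametric tree with random tip states as a likelihood matrix.
random_tree_data <- function(n_tips) {
  tree <- ape::rcoal(n_tips)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  states <- sample(0:7, n_tips, replace = TRUE)
  tl <- matrix(0, 8, n_tips, dimnames = list(combined_states(), tree$tip.label))
  tl[cbind(states + 1L, seq_len(n_tips))] <- 1
  list(tree = tree, tipliks = tl, states = states)
}

# Two-state symmetric sub-model on Cry/Diu <-> Cry/Noc embedded in the
# 8-state space, with prior mass split over the two states.
symmetric_two_state <- function(q) {
  Q <- matrix(0, 8, 8, dimnames = list(combined_states(), combined_states()))
  i <- encode_state("Cry", "Diu") + 1L
  j <- encode_state("Cry", "Noc") + 1L
  Q[i, j] <- Q[j, i] <- q
  diag(Q) <- -rowSums(Q)
  pr <- rep(0, 8); pr[c(i, j)] <- 0.5
  list(Q = Q, prior = pr, i = i, j = j)
}

# Build an ape cherry ((t1,t2):0) with both branch lengths t.
cherry_tree <- function(t) {
  tree <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);", t, t))
  tree
}

make_tipliks <- function(tree, states) {
  tl <- matrix(0, 8, length(tree$tip.label),
               dimnames = list(combined_states(), tree$tip.label))
  tl[cbind(states + 1L, seq_along(states))] <- 1
  tl
}
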