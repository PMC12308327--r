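# Tree preparation, tip likelihoods and the pruning log-likelihood.

# Postorder edge matrix + lengths + counts, validated once per tree.
prep_tree <- function(tree, ultrametric_tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and nonnegative")
  }
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  depths <- ape::node.depth.edgelength(tree)
  tip_depths <- depths[seq_along(tree$tip.label)]
  spread <- diff(range(tip_depths)) / max(tip_depths, 1e-300)
  if (spread > ultrametric_tol) {
    warning(sprintf(
      "tree is not ultrametric (relative tip-depth spread %.3g); branch lengths are used as given",
      spread))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  list(
    edge = matrix(as.integer(po$edge), ncol = 2),
    lens = po$edge.length,
    ntip = length(tree$tip.label),
    nnode = length(tree$tip.label) + tree$Nnode,
    root = length(tree$tip.label) + 1L,
    tip_label = tree$tip.label,
    height = max(tip_depths)
  )
}

#' Per-tip state likelihood matrix
#'
#' Converts a trait table into the 8 x ntip matrix of per-tip state
#' likelihoods the pruning algorithm consumes: a 1 at the observed
#' combined state and 0 elsewhere. Fractional rows (ambiguous tips) can
#' be supplied directly to [mk_loglik()] as a matrix instead.
#'
#' @param tree An `ape::phylo` tree.
#' @param traits A trait table from [build_trait_table()] (columns
#'   `species` and `state`, or `colour` + `diel`).
#' @return An 8 x ntip numeric matrix, columns ordered as
#'   `tree$tip.label`, rows as [combined_states()].
#' @export
tip_likelihoods <- function(tree, traits) {
  if (!"state" %in% names(traits)) {
    traits$state <- encode_state(traits$colour, traits$diel)
  }
  idx <- match(tree$tip.label, traits$species)
  if (anyNA(idx)) {
    stop("tips missing from trait table: ",
         paste(utils::head(tree$tip.label[is.na(idx)], 5), collapse = ", "),
         if (sum(is.na(idx)) > 5) ", ...")
  }
  m <- matrix(0, n_states(), length(idx),
              dimnames = list(combined_states(), tree$tip.label))
  m[cbind(traits$state[idx] + 1L, seq_along(idx))] <- 1
  m
}

# Resolve tip input: trait table or prebuilt likelihood matrix.
resolve_tipliks <- function(tree, tips) {
  if (is.matrix(tips)) {
    if (nrow(tips) != n_states()) stop("tip likelihood matrix must have 8 rows")
    tips <- tips[, tree$tip.label, drop = FALSE]
    if (any(colSums(tips) <= 0)) stop("each tip needs a nonzero state likelihood")
    tips
  } else {
    tip_likelihoods(tree, tips)
  }
}

#' Build a rate matrix from a template and free rates
#'
#' Fills the free slots of a model template with nonnegative per-unit-time
#' rates and sets each diagonal entry to minus its row sum, giving a valid
#' CTMC generator with exact structural zeros.
#'
#' @param template An `mk_template` from [build_template()], or a model
#'   name.
#' @param rates Numeric vector of length `n_free`, ordered by parameter
#'   id (row-major scan of the template).
#' @return An 8 x 8 generator matrix with state labels.
#' @examples
#' tpl <- build_template("E22")
#' Q <- build_q(tpl, rep(0.2, attr(tpl, "n_free")))
#' rowSums(Q)  # all zero
#' @export
build_q <- function(template, rates) {
  if (is.character(template)) template <- build_template(template)
  nf <- attr(template, "n_free")
  if (length(rates) != nf) stop("need ", nf, " rates, got ", length(rates))
  if (any(!is.finite(rates)) || any(rates < 0)) stop("rates must be finite and >= 0")
  Q <- matrix(0, n_states(), n_states(), dimnames = dimnames(template))
  free <- which(template > 0)
  Q[free] <- rates[template[free]]
  diag(Q) <- -rowSums(Q)
  Q
}

# "From->To" labels for a template's free parameters, in parameter-id order.
param_labels <- function(template) {
  free <- which(template > 0, arr.ind = TRUE)
  ids <- template[free]
  lab <- character(length(ids))
  lab[ids] <- paste0(combined_states()[free[, 1]], "->", combined_states()[free[, 2]])
  lab
}

#' Root-state prior
#'
#' @param type `"flat"` (uniform over the 8 states, the default),
#'   `"stationary"` (stationary distribution of `Q`), or `"observed"`
#'   (tip state frequencies). A numeric length-8 vector is accepted
#'   as-is and normalized.
#' @param Q Generator matrix, required for `"stationary"`.
#' @param tipliks Tip likelihood matrix, required for `"observed"`.
#' @return A length-8 probability vector.
#' @export
root_prior <- function(type = "flat", Q = NULL, tipliks = NULL) {
  if (is.numeric(type)) {
    stopifnot(length(type) == n_states(), all(type >= 0), sum(type) > 0)
    return(type / sum(type))
  }
  switch(match.arg(type, c("flat", "stationary", "observed")),
    flat = rep(1 / n_states(), n_states()),
    stationary = stationary_dist(Q),
    observed = {
      f <- rowSums(tipliks / rep(colSums(tipliks), each = nrow(tipliks)))
      f / sum(f)
    }
  )
}

# Stationary distribution: left null vector of Q, pi Q = 0.
stationary_dist <- function(Q) {
  stopifnot(!is.null(Q))
  A <- rbind(t(Q), rep(1, ncol(Q)))
  b <- c(rep(0, ncol(Q)), 1)
  pi <- stats::lsfit(A, b, intercept = FALSE)$coefficients
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Pruning log-likelihood of tip states under a rate matrix
#'
#' Computes the Mk log-likelihood of the observed combined states on a
#' rooted tree by the post-order pruning recursion, with per-branch
#' transition probabilities `exp(Q t)` and a root prior over the eight
#' states.
#'
#' @param tree An `ape::phylo` tree with branch lengths (time units).
#' @param tips A trait table ([build_trait_table()]) or an 8 x ntip tip
#'   likelihood matrix with tip labels as column names.
#' @param Q An 8 x 8 generator matrix (see [build_q()]).
#' @param prior Root prior: a type string or length-8 vector, see
#'   [root_prior()].
#' @return The log-likelihood (a single number).
#' @examples
#' sim <- sim_study_dataset(n_tips = 40, seed = 1)
#' mk_loglik(sim$tree, sim$traits, sim$Q)
#' @export
mk_loglik <- function(tree, tips, Q, prior = "flat") {
  pt <- prep_tree(tree)
  tl <- resolve_tipliks(tree, tips)
  if (any(!is.finite(Q))) stop("Q must be finite")
  pr <- root_prior(prior, Q = Q, tipliks = tl)
  cpp_mk_loglik(pt$edge, pt$lens, tl, pt$nnode, Q, pr)
}
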