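# Marginal ancestral-state reconstruction by the up/down-pass algorithm.

#' Marginal ancestral states at every node
#'
#' For each node of the tree, computes the marginal probability of each
#' of the eight combined states given the tip data, the rate matrix and
#' the root prior: the product of the downward partial likelihood (data
#' in the node's subtree) and the outside likelihood (everything else),
#' normalized per node. The root marginal is the prior times the root
#' partials. Reconstruction conditions on a single rate matrix —
#' typically the MLE of the AIC-best model — not on a model average.
#'
#' @param fit An `mk_fit`, or an `ape::phylo` tree (then `tips` and `Q`
#'   are required).
#' @param tips Trait table or tip likelihood matrix (ignored when `fit`
#'   is an `mk_fit`).
#' @param Q Generator matrix (ignored when `fit` is an `mk_fit`).
#' @param prior Root prior (see [root_prior()]).
#' @return An object of class `mk_asr`: a tibble with columns `node`
#'   (ape node id), `type` (`"tip"`/`"internal"`), one probability per
#'   node/state row (`state`, `probability`). The nnode x 8 wide matrix
#'   is in `attr(, "matrix")`, the tree in `attr(, "tree")`. Rows sum
#'   to one within each node.
#' @examples
#' sim <- sim_study_dataset(n_tips = 40, seed = 2)
#' asr <- marginal_asr(sim$tree, sim$traits, sim$Q)
#' head(tidy(asr))
#' @export
marginal_asr <- function(fit, tips = NULL, Q = NULL, prior = "flat") {
  if (inherits(fit, "mk_fit")) {
    if (fit$status != "ok") stop("cannot reconstruct from a failed fit")
    tree <- fit$tree; tl <- fit$tipliks; Q <- fit$Q; prior <- fit$prior
  } else {
    tree <- fit
    tl <- resolve_tipliks(tree, tips)
  }
  pt <- prep_tree(tree)
  pr <- root_prior(prior, Q = Q, tipliks = tl)

  parts <- cpp_mk_partials(pt$edge, pt$lens, tl, pt$nnode, Q)
  down <- parts$partials          # 8 x nnode, scaled per node
  P <- parts$pmats                # 8 x 8 x nedge
  ne <- nrow(pt$edge)

  # outside ("up") vectors: up[, root] = prior; child given parent uses the
  # parent's up vector times the sibling subtrees' contributions
  up <- matrix(0, n_states(), pt$nnode)
  up[, pt$root] <- pr
  child_contrib <- purrr::map(seq_len(ne), ~ P[, , .x] %*% down[, pt$edge[.x, 2]])
  edges_by_parent <- split(seq_len(ne), pt$edge[, 1])

  for (e in rev(seq_len(ne))) {  # reverse postorder = parents before children
    p <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
    w <- up[, p]
    for (b in edges_by_parent[[as.character(p)]]) {
      if (b != e) w <- w * child_contrib[[b]]
    }
    v <- crossprod(P[, , e], w)[, 1]
    m <- max(v)
    up[, ch] <- if (m > 0) v / m else v
  }

  marg <- down * up
  cs <- colSums(marg)
  if (any(cs <= 0)) stop("zero marginal likelihood at some node; Q inconsistent with tip data")
  marg <- sweep(marg, 2, cs, "/")
  rownames(marg) <- combined_states()

  out <- tibble::tibble(
    node = rep(seq_len(pt$nnode), each = n_states()),
    type = rep(ifelse(seq_len(pt$nnode) <= pt$ntip, "tip", "internal"),
               each = n_states()),
    state = rep(combined_states(), pt$nnode),
    probability = as.vector(marg)
  )
  structure(out, matrix = t(marg), tree = tree, Q = Q, prior = pr,
            class = c("mk_asr", class(out)))
}

#' Marginalize an 8-state reconstruction to one trait
#'
#' Sums the combined-state marginals over the other trait, giving the
#' per-node probabilities of the colour states alone (`"colour"`) or the
#' diel states alone (`"diel"`).
#'
#' @param asr An `mk_asr`.
#' @param trait `"colour"` or `"diel"`.
#' @return A tibble `node`, `type`, `state`, `probability`.
#' @export
marginal_view <- function(asr, trait = c("colour", "diel")) {
  trait <- match.arg(trait)
  dec <- decode_state(match(asr$state, combined_states()) - 1L)
  asr |>
    dplyr::mutate(state = dec[[trait]]) |>
    dplyr::group_by(.data$node, .data$type, .data$state) |>
    dplyr::summarise(probability = sum(.data$probability), .groups = "drop")
}

#' @export
print.mk_asr <- function(x, ...) {
  ntip <- length(attr(x, "tree")$tip.label)
  cat("Marginal ancestral states:", max(x$node) - ntip, "internal nodes,",
      ntip, "tips, 8 states\n")
  root <- dplyr::filter(x, .data$node == ntip + 1L) |>
    dplyr::arrange(dplyr::desc(.data$probability))
  cat(sprintf("  root: P(%s) = %.3f, P(%s) = %.3f\n",
              root$state[1], root$probability[1],
              root$state[2], root$probability[2]))
  invisible(x)
}

#' @rdname tidy.mk_fit
#' @export
tidy.mk_asr <- function(x, ...) tibble::as_tibble(x)

#' Write an ancestral reconstruction to CSV
#'
#' One row per node/state with the marginal probability.
#'
#' @param asr An `mk_asr`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_asr_csv <- function(asr, path) {
  utils::write.csv(as.data.frame(tibble::as_tibble(asr)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
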