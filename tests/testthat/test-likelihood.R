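test_that("zero rates put all mass on the shared tip state", {
  tree <- ape::rcoal(6)
  Q <- build_q("E22", rep(0, 24))
  tl <- make_tipliks(tree, rep(encode_state("Cry", "Noc"), 6))
  expect_equal(mk_loglik(tree, tl, Q), log(1 / 8), tolerance = 1e-12)
})

test_that("two-tip symmetric sub-model matches the closed form", {
  q <- 0.7; t <- 0.9
  sub <- symmetric_two_state(q)
  tree <- cherry_tree(t)
  tl <- make_tipliks(tree, rep(encode_state("Cry", "Diu"), 2))
  p00 <- (1 + exp(-2 * q * t)) / 2
  p10 <- (1 - exp(-2 * q * t)) / 2
  expected <- log(0.5 * p00^2 + 0.5 * p10^2)
  expect_equal(mk_loglik(tree, tl, sub$Q, prior = sub$prior), expected,
               tolerance = 1e-10)
})

test_that("pruning equals the exhaustive assignment oracle on small trees", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(2:5, 1)
    dat <- random_tree_data(n)
    Q <- random_sparse_q()
    prior <- rep(1 / 8, 8)
    expect_equal(mk_loglik(dat$tree, dat$tipliks, Q),
                 oracle_loglik(dat$tree, dat$tipliks, Q, prior),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to tip ordering and child rotation", {
  set.seed(7)
  dat <- random_tree_data(8)
  Q <- random_sparse_q()
  ll <- mk_loglik(dat$tree, dat$tipliks, Q)

  perm <- sample(ncol(dat$tipliks))
  expect_equal(mk_loglik(dat$tree, dat$tipliks[, perm], Q), ll,
               tolerance = 1e-12)

  rotated <- ape::rotate(dat$tree, node = 10L)
  expect_equal(mk_loglik(rotated, dat$tipliks, Q), ll, tolerance = 1e-9)
})

test_that("splitting a branch with a degree-2 node preserves the likelihood", {
  # Chapman-Kolmogorov: P(t1) P(t2) = P(t1 + t2)
  set.seed(13)
  dat <- random_tree_data(4)
  Q <- random_sparse_q()
  ll <- mk_loglik(dat$tree, dat$tipliks, Q)

  tr <- dat$tree
  e <- which.max(tr$edge.length)
  child <- tr$edge[e, 2]
  len <- tr$edge.length[e]
  ntip <- length(tr$tip.label)
  # renumber internal nodes >= new singleton id, then splice it in
  new_node <- ntip + tr$Nnode + 1L
  edge <- tr$edge
  edge2 <- rbind(edge, c(new_node, child))
  edge2[e, 2] <- new_node
  lens2 <- c(tr$edge.length, 0.6 * len)
  lens2[e] <- 0.4 * len
  tr2 <- structure(list(edge = edge2, edge.length = lens2,
                        tip.label = tr$tip.label, Nnode = tr$Nnode + 1L),
                   class = "phylo")
  expect_equal(suppressWarnings(mk_loglik(tr2, dat$tipliks, Q)), ll,
               tolerance = 1e-9)
})

test_that("transition probability rows are stochastic across time scales", {
  set.seed(3)
  Q <- random_sparse_q()
  for (t in c(0.01, 1, 100)) {
    P <- dielmk:::cpp_pmats(Q, t)[, , 1]
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-10)
  }
})

test_that("input errors are caught", {
  tree <- ape::rcoal(4)
  tl <- make_tipliks(tree, rep(0L, 4))
  Q <- build_q("E22", rep(0.1, 24))
  expect_error(mk_loglik(tree, tl[, 1:3], Q), "undefined columns|missing|subscript")
  bad <- tl; colnames(bad)[1] <- "nope"
  expect_error(mk_loglik(tree, bad, Q))
  Qbad <- Q; Qbad[1, 2] <- NaN
  expect_error(mk_loglik(tree, tl, Qbad), "finite")
  traits_missing <- tibble::tibble(species = tree$tip.label[-1],
                                   colour = "Cry", diel = "Noc")
  expect_error(mk_loglik(tree, traits_missing, Q), "missing")
})

test_that("non-ultrametric trees warn but still evaluate", {
  tree <- ape::rtree(5)
  tl <- make_tipliks(tree, rep(1L, 5))
  Q <- build_q("E22", rep(0.1, 24))
  expect_warning(ll <- mk_loglik(tree, tl, Q), "ultrametric")
  expect_true(is.finite(ll))
})

test_that("likelihood agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(21)
  sim <- sim_study_dataset(n_tips = 40, seed = 21)
  tpl <- build_template("E22")
  index_mat <- unclass(tpl)
  attr(index_mat, "n_free") <- attr(index_mat, "spec") <- NULL
  # tip priors as a matrix pin the state ordering to the package's
  x <- t(tip_likelihoods(sim$tree, sim$traits))
  ref <- phytools::fitMk(sim$tree, x, model = index_mat, pi = rep(1 / 8, 8))
  im <- ref$index.matrix
  pos <- which(!is.na(im) & im > 0)
  Qref <- matrix(0, 8, 8)
  Qref[pos] <- ref$rates[im[pos]]
  diag(Qref) <- -rowSums(Qref)
  dimnames(Qref) <- list(combined_states(), combined_states())
  expect_equal(mk_loglik(sim$tree, sim$traits, Qref), as.numeric(ref$logLik),
               tolerance = 1e-4)
})

test_that("root priors are valid distributions", {
  expect_equal(root_prior("flat"), rep(1 / 8, 8))
  Q <- build_q("G11", rep(0.3, 30))
  pi <- root_prior("stationary", Q = Q)
  expect_equal(sum(pi), 1, tolerance = 1e-10)
  expect_equal(as.numeric(pi %*% Q), rep(0, 8), tolerance = 1e-8)
  tl <- make_tipliks(cherry_tree(1), c(0L, 5L))
  obs <- root_prior("observed", tipliks = tl)
  expect_equal(unname(obs[c(1, 6)]), c(0.5, 0.5))
  expect_equal(root_prior(c(rep(1, 4), rep(3, 4))),
               c(rep(1 / 16, 4), rep(3 / 16, 4)))
})
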