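test_that("zero-rate maps carry no events", {
  tree <- ape::rcoal(6)
  traits <- tibble::tibble(species = tree$tip.label, colour = "Cry", diel = "Noc")
  Q <- build_q("E22", rep(0, 24))
  maps <- sample_histories(tree, traits, Q, nsim = 5, seed = 1)
  expect_equal(nrow(maps$events), 0L)
  expect_true(all(maps$counts == 0))
  expect_true(all(maps$node_states == encode_state("Cry", "Noc")))
})

test_that("endpoint-forced paths have odd event counts", {
  sub <- symmetric_two_state(0.4)
  i <- sub$i; j <- sub$j
  mu <- max(-diag(sub$Q))
  R <- diag(8) + sub$Q / mu
  Rpow <- new.env(); Rpow$pow <- list(diag(8))
  P <- dielmk:::cpp_pmats(sub$Q, 1.3)[, , 1]
  set.seed(5)
  for (rep in 1:200) {
    path <- dielmk:::sample_uniformized_path(i, j, 1.3, mu, R, Rpow, P[i, j])
    changes <- sum(diff(path$states) != 0)
    expect_true(changes %% 2 == 1)
    expect_identical(path$states[1], i)
    expect_identical(path$states[length(path$states)], j)
  }
})

test_that("uniformized event counts match a rejection-sampling oracle", {
  # one branch, endpoint-conditioned: compare realized-change distributions
  sub <- symmetric_two_state(0.6)
  i <- sub$i; j <- sub$j
  t <- 1.5
  n <- 20000L

  set.seed(8)
  # oracle: forward-simulate unconditional paths, keep those hitting j
  forward_changes <- function() {
    s <- i; pos <- 0; changes <- 0L
    repeat {
      out <- -sub$Q[s, s]
      if (out <= 0) break
      pos <- pos + rexp(1, out)
      if (pos >= t) break
      s <- which(sub$Q[s, ] > 0)  # two-state: single target
      changes <- changes + 1L
    }
    if (s == j) changes else NA_integer_
  }
  oracle_counts <- stats::na.omit(vapply(seq_len(n), function(...) forward_changes(),
                                         integer(1)))

  mu <- max(-diag(sub$Q))
  R <- diag(8) + sub$Q / mu
  Rpow <- new.env(); Rpow$pow <- list(diag(8))
  P <- dielmk:::cpp_pmats(sub$Q, t)[, , 1]
  unif_counts <- vapply(seq_len(n), function(...) {
    path <- dielmk:::sample_uniformized_path(i, j, t, mu, R, Rpow, P[i, j])
    sum(diff(path$states) != 0)
  }, integer(1))

  lev <- 0:max(oracle_counts, unif_counts)
  p1 <- tabulate(oracle_counts + 1L, length(lev)) / length(oracle_counts)
  p2 <- tabulate(unif_counts + 1L, length(lev)) / length(unif_counts)
  tv <- sum(abs(p1 - p2)) / 2
  expect_lt(tv, 0.02)
})

test_that("sampled histories respect structural zeros and connect endpoints", {
  sim <- sim_study_dataset(n_tips = 25, seed = 51)
  maps <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 40, seed = 2)
  tpl <- build_template("E22")
  if (nrow(maps$events)) {
    from_i <- match(maps$events$from, combined_states())
    to_i <- match(maps$events$to, combined_states())
    expect_true(all(tpl[cbind(from_i, to_i)] > 0))
    # no dual jumps in particular
    dec_f <- decode_state(from_i - 1L); dec_t <- decode_state(to_i - 1L)
    expect_false(any(dec_f$colour != dec_t$colour & dec_f$diel != dec_t$diel))
    # event chains connect the sampled endpoint states on every branch
    chains <- maps$events |>
      dplyr::group_by(sim, edge) |>
      dplyr::arrange(time, .by_group = TRUE) |>
      dplyr::summarise(parent = parent[1], child = child[1],
                       first = from[1], last = to[dplyr::n()],
                       ok_chain = all(to[-dplyr::n()] == from[-1]),
                       .groups = "drop")
    expect_true(all(chains$ok_chain))
    ps <- maps$node_states[cbind(chains$parent, chains$sim)]
    cs <- maps$node_states[cbind(chains$child, chains$sim)]
    expect_equal(combined_states()[ps + 1L], chains$first)
    expect_equal(combined_states()[cs + 1L], chains$last)
  }
  # tip rows of node_states always reproduce the observed data
  ntip <- length(sim$tree$tip.label)
  expect_true(all(maps$node_states[seq_len(ntip), ] == sim$traits$state))
})

test_that("histories are reproducible given the seed", {
  sim <- sim_study_dataset(n_tips = 20, seed = 52)
  a <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 10, seed = 9)
  b <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 10, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$node_states, b$node_states)
  expect_identical(a$counts, b$counts)
})

test_that("transition-count summaries tally, flag and never conflate", {
  sim <- sim_study_dataset(n_tips = 25, seed = 53)
  maps <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 30, seed = 3)
  counts <- count_transitions(maps)
  expect_equal(nrow(counts), 56L)  # all ordered off-diagonal pairs
  # mean counts agree with the per-sample array
  for (r in sample(seq_len(nrow(counts)), 10)) {
    expect_equal(counts$mean_count[r],
                 mean(maps$counts[counts$from[r], counts$to[r], ]))
  }
  # tally agrees with the raw event table
  ev_tally <- maps$events |>
    dplyr::count(from, to) |>
    dplyr::mutate(mean_count = n / maps$nsim)
  for (r in seq_len(nrow(ev_tally))) {
    expect_equal(
      counts$mean_count[counts$from == ev_tally$from[r] &
                          counts$to == ev_tally$to[r]],
      ev_tally$mean_count[r])
  }
  expect_true(all(counts$low_credibility[grepl("Crep", counts$from) |
                                           grepl("Crep", counts$to)]))
  expect_setequal(unique(counts$path_type),
                  intersect(c("colour-change", "diel-change", "dual"),
                            counts$path_type))
  expect_true(all(counts$mean_count[counts$path_type == "dual"] == 0))
})

test_that("node-state frequencies converge to the marginal reconstruction", {
  sim <- sim_study_dataset(n_tips = 15, seed = 54)
  maps <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 400, seed = 4)
  freq <- node_state_frequencies(maps)
  asr <- attr(marginal_asr(sim$tree, sim$traits, sim$Q), "matrix")
  se <- sqrt(asr * (1 - asr) / maps$nsim)
  expect_true(all(abs(freq - asr) <= 4 * se + 1e-9))
})
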