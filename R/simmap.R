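# Stochastic character mapping: endpoint-conditioned history sampling by
# uniformization, and realized-transition counting.

# Sample the number of virtual jumps and the virtual chain of a
# uniformized CTMC path conditioned on endpoints (a, b) over time t.
# Rpow: lazily grown list of powers of R = I + Q/mu.
sample_uniformized_path <- function(a, b, t, mu, R, Rpow, p_ab) {
  # returns list(states = virtual chain incl. endpoints, times = jump times)
  if (p_ab <= 0) {
    stop("endpoint pair with zero transition probability; Q inconsistent with tip data")
  }
  lam <- mu * t
  u <- runif(1) * p_ab
  n <- -1L
  cum <- 0
  repeat {
    n <- n + 1L
    if (n + 1L > length(Rpow$pow)) {
      Rpow$pow[[n + 1L]] <- Rpow$pow[[n]] %*% R
    }
    term <- stats::dpois(n, lam) * Rpow$pow[[n + 1L]][a, b]
    cum <- cum + term
    if (cum >= u || n > 10000L) break
  }
  if (n == 0L) return(list(states = c(a, b), times = numeric(0)))
  times <- sort(runif(n)) * t
  states <- integer(n + 1L)
  states[1] <- a
  if (n > 1L) {
    for (j in seq_len(n - 1L)) {
      w <- R[states[j], ] * Rpow$pow[[n - j + 1L]][, b]  # R^(n-j)
      states[j + 1L] <- sample.int(n_states(), 1L, prob = w)
    }
  }
  states[n + 1L] <- b
  list(states = states, times = times)
}

#' Sample stochastic character maps
#'
#' Draws complete character histories conditional on the tip data and a
#' fitted rate matrix: node states are sampled from their joint
#' conditional distribution (root from the prior times the root
#' partials, then each child given its sampled parent), and each
#' branch's interior is filled in by exact endpoint-conditioned path
#' sampling via uniformization with dominating rate `max |Q_ii|`.
#' Histories are reproducible given `seed`.
#'
#' @inheritParams marginal_asr
#' @param nsim Number of histories to sample.
#' @param seed Integer seed.
#' @return An object of class `mk_simmap` with elements `events` (a
#'   tibble of all realized transitions: `sim`, `edge`, `parent`,
#'   `child`, `time` from branch start, `from`, `to`), `node_states`
#'   (nnode x nsim matrix of sampled state indices 0–7), `counts` (an
#'   8 x 8 x nsim array of per-sample transition counts), the tree, `Q`
#'   and `nsim`.
#' @examples
#' sim <- sim_study_dataset(n_tips = 30, seed = 3)
#' maps <- sample_histories(sim$tree, sim$traits, sim$Q, nsim = 10, seed = 1)
#' count_transitions(maps)
#' @export
sample_histories <- function(fit, tips = NULL, Q = NULL, prior = "flat",
                             nsim = 1000, seed = NULL) {
  if (inherits(fit, "mk_fit")) {
    if (fit$status != "ok") stop("cannot map histories from a failed fit")
    tree <- fit$tree; tl <- fit$tipliks; Q <- fit$Q; prior <- fit$prior
  } else {
    tree <- fit
    tl <- resolve_tipliks(tree, tips)
  }
  pt <- prep_tree(tree)
  pr <- root_prior(prior, Q = Q, tipliks = tl)
  parts <- cpp_mk_partials(pt$edge, pt$lens, tl, pt$nnode, Q)
  down <- parts$partials
  P <- parts$pmats
  ne <- nrow(pt$edge)
  preorder <- rev(seq_len(ne))

  mu <- max(-diag(Q))
  R <- diag(n_states()) + if (mu > 0) Q / mu else 0 * Q
  Rpow <- new.env()
  Rpow$pow <- list(diag(n_states()))

  if (!is.null(seed)) set.seed(seed)
  node_states <- matrix(0L, pt$nnode, nsim)
  counts <- array(0, c(n_states(), n_states(), nsim),
                  dimnames = list(combined_states(), combined_states(), NULL))
  ev_list <- vector("list", nsim)

  root_w <- pr * down[, pt$root]
  for (i in seq_len(nsim)) {
    st <- integer(pt$nnode)
    st[pt$root] <- sample.int(n_states(), 1L, prob = root_w)
    evs <- list()
    for (e in preorder) {
      p <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
      w <- P[st[p], , e] * down[, ch]
      st[ch] <- sample.int(n_states(), 1L, prob = w)
      if (mu > 0) {
        path <- sample_uniformized_path(st[p], st[ch], pt$lens[e], mu, R,
                                        Rpow, P[st[p], st[ch], e])
        real <- which(diff(path$states) != 0L)
        if (length(real)) {
          from <- path$states[real]; to <- path$states[real + 1L]
          for (k in seq_along(real)) counts[from[k], to[k], i] <-
              counts[from[k], to[k], i] + 1
          evs[[length(evs) + 1L]] <- tibble::tibble(
            sim = i, edge = e, parent = p, child = ch,
            time = path$times[real],
            from = combined_states()[from], to = combined_states()[to])
        }
      }
    }
    node_states[, i] <- st - 1L
    ev_list[[i]] <- if (length(evs)) dplyr::bind_rows(evs) else NULL
  }
  events <- dplyr::bind_rows(ev_list)
  if (!nrow(events)) {
    events <- tibble::tibble(sim = integer(), edge = integer(),
                             parent = integer(), child = integer(),
                             time = numeric(), from = character(),
                             to = character())
  }
  structure(list(events = events, node_states = node_states, counts = counts,
                 tree = tree, Q = Q, prior = pr, nsim = nsim, seed = seed),
            class = "mk_simmap")
}

#' Summarize realized transition counts
#'
#' Tallies, over all sampled histories, the realized number of
#' transitions per ordered state pair and reports the mean and sample
#' quantiles. Estimated instantaneous rates and realized counts are
#' distinct quantities — a path can carry a high rate yet few realized
#' events — so this summary is reported alongside, never instead of, the
#' fitted rates. Paths touching the crepuscular state are flagged
#' low-credibility: crepuscular species are few and their transitions
#' are estimated with little information.
#'
#' @param simmap An `mk_simmap` from [sample_histories()].
#' @param probs Quantile probabilities for the per-sample counts.
#' @return A tibble with one row per ordered off-diagonal state pair:
#'   `from`, `to`, `mean_count`, `q05`, `q95`, `path_type`
#'   (colour-change / diel-change / dual), `low_credibility` (TRUE for
#'   crepuscular paths). Structurally forbidden pairs have zero counts
#'   in every sample.
#' @export
count_transitions <- function(simmap, probs = c(0.05, 0.95)) {
  stopifnot(inherits(simmap, "mk_simmap"))
  cs <- combined_states()
  grid <- expand.grid(to = cs, from = cs, stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$from != grid$to, ]
  dec_f <- decode_state(match(grid$from, cs) - 1L)
  dec_t <- decode_state(match(grid$to, cs) - 1L)
  res <- purrr::map2_dfr(grid$from, grid$to, function(f, t) {
    x <- simmap$counts[f, t, ]
    tibble::tibble(from = f, to = t, mean_count = mean(x),
                   q05 = unname(quantile(x, probs[1])),
                   q95 = unname(quantile(x, probs[2])))
  })
  res$path_type <- dplyr::case_when(
    dec_f$colour != dec_t$colour & dec_f$diel != dec_t$diel ~ "dual",
    dec_f$colour != dec_t$colour ~ "colour-change",
    TRUE ~ "diel-change"
  )
  res$low_credibility <- dec_f$diel == "Crep" | dec_t$diel == "Crep"
  res
}

#' Node-state sampling frequencies
#'
#' The fraction of sampled histories assigning each state to each node;
#' converges to the marginal ancestral probabilities as `nsim` grows.
#'
#' @param simmap An `mk_simmap`.
#' @return An nnode x 8 matrix of frequencies.
#' @export
node_state_frequencies <- function(simmap) {
  freq <- t(apply(simmap$node_states, 1, function(s) {
    tabulate(s + 1L, n_states())
  })) / simmap$nsim
  colnames(freq) <- combined_states()
  freq
}

#' @export
print.mk_simmap <- function(x, ...) {
  cat("Stochastic character maps:", x$nsim, "sampled histories on",
      length(x$tree$tip.label), "tips\n")
  cat(sprintf("  mean realized transitions per history: %.2f\n",
              mean(apply(x$counts, 3, sum))))
  invisible(x)
}

#' @rdname tidy.mk_fit
#' @export
tidy.mk_simmap <- function(x, ...) count_transitions(x)

#' Write transition-count summary to CSV
#'
#' @param simmap An `mk_simmap`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_transition_csv <- function(simmap, path) {
  utils::write.csv(as.data.frame(count_transitions(simmap)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
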