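# Synthetic data: Yule trees and exact forward simulation of the
# combined character, emulating the statistical structure the analysis
# assumes so every stage is testable without external data.

#' Simulate an ultrametric Yule tree
#'
#' Draws a pure-birth tree with the requested number of tips and
#' rescales it to the given total height, so branch lengths are in the
#' same relative time units as a chronogram of unit depth.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed (the same seed always returns the same
#'   tree).
#' @param height Tree height after rescaling.
#' @return An ultrametric `ape::phylo` tree with tips `t1 ... tn`.
#' @examples
#' tr <- sim_yule_tree(10, seed = 1)
#' @export
sim_yule_tree <- function(n_tips, seed = NULL, height = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * height
  tree
}

# Gillespie simulation along one branch: exponential waiting times with
# total rate -Q[s,s], jump to j with probability Q[s,j] / -Q[s,s].
sim_branch <- function(s, t, Q) {
  times <- numeric(0); from <- integer(0); to <- integer(0)
  pos <- 0
  repeat {
    out_rate <- -Q[s, s]
    if (out_rate <= 0) break
    pos <- pos + rexp(1, out_rate)
    if (pos >= t) break
    j <- sample.int(ncol(Q), 1L, prob = pmax(Q[s, ], 0) * (seq_len(ncol(Q)) != s))
    times <- c(times, pos); from <- c(from, s); to <- c(to, j)
    s <- j
  }
  list(end = s, times = times, from = from, to = to)
}

#' Simulate a character history on a tree
#'
#' Evolves the eight-state combined character forward along every branch
#' with exact event times (exponential waiting times, jump probabilities
#' proportional to the off-diagonal rates). The complete history is
#' retained as ground truth; tip states become the trait table.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param Q An 8 x 8 generator (see [build_q()]).
#' @param root Root state: an index 0–7, a label like `"Cry/Noc"`, or a
#'   length-8 probability vector to sample from.
#' @param seed Integer seed.
#' @return An object of class `mk_sim`: `tree`, `traits` (species,
#'   colour, diel, state), `node_states` (length-nnode vector of
#'   indices 0–7), `history` (tibble `edge`, `parent`, `child`, `time`,
#'   `from`, `to`), and `Q`.
#' @examples
#' tr <- sim_yule_tree(20, seed = 1)
#' Q <- build_q("E22", rep(0.3, 24))
#' sim <- sim_character(tr, Q, root = "Cry/Noc", seed = 2)
#' table(sim$traits$colour)
#' @export
sim_character <- function(tree, Q, root = "Cry/Noc", seed = NULL) {
  stopifnot(nrow(Q) == n_states(), ncol(Q) == n_states())
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to zero")
  pt <- prep_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  root_idx <- if (is.character(root)) {
    match(root, combined_states())
  } else if (length(root) == n_states()) {
    sample.int(n_states(), 1L, prob = root)
  } else {
    as.integer(root) + 1L
  }
  if (is.na(root_idx) || root_idx < 1L || root_idx > n_states()) {
    stop("invalid root state")
  }

  st <- integer(pt$nnode)
  st[pt$root] <- root_idx
  ev <- vector("list", nrow(pt$edge))
  for (e in rev(seq_len(nrow(pt$edge)))) {  # preorder
    p <- pt$edge[e, 1]; ch <- pt$edge[e, 2]
    br <- sim_branch(st[p], pt$lens[e], Q)
    st[ch] <- br$end
    if (length(br$times)) {
      ev[[e]] <- tibble::tibble(edge = e, parent = p, child = ch,
                                time = br$times,
                                from = combined_states()[br$from],
                                to = combined_states()[br$to])
    }
  }
  history <- dplyr::bind_rows(ev)
  if (!nrow(history)) {
    history <- tibble::tibble(edge = integer(), parent = integer(),
                              child = integer(), time = numeric(),
                              from = character(), to = character())
  }
  tip_idx <- st[seq_len(pt$ntip)] - 1L
  dec <- decode_state(tip_idx)
  traits <- tibble::tibble(species = tree$tip.label, colour = dec$colour,
                           diel = dec$diel, state = tip_idx)
  structure(list(tree = tree, traits = traits, node_states = st - 1L,
                 history = history, Q = Q),
            class = "mk_sim")
}

#' Default per-path rates for study-like simulations
#'
#' Assigns each free slot of a template a rate (per unit tree height)
#' structured to reproduce the qualitative state-frequency pattern of a
#' curated moth dataset: nocturnal species dominate, diurnal species are
#' common in both colours, the day-and-night "All" state is labile (exit
#' rates well above entry rates) and therefore a minority, losses of
#' conspicuousness run somewhat faster than gains, and crepuscular paths
#' are slow so crepuscular tips are few and arise recently. Base rates:
#' colour change 0.45 (Cry to Con) / 0.55 (Con to Cry); diel change 0.5,
#' except 1.8 out of `All`; every crepuscular path `crep_rate`. Each
#' dataset jitters the base rates by a lognormal factor (sd 0.25 on the
#' log scale) so replicates differ.
#'
#' @param template An `mk_template` (or model name).
#' @param seed Integer seed for the jitter draws.
#' @param crep_rate Base rate for every crepuscular path.
#' @param jitter_sd Log-scale standard deviation of the per-path jitter.
#' @return A named rate vector in parameter-id order.
#' @export
default_study_rates <- function(template, seed = NULL, crep_rate = 0.02,
                                jitter_sd = 0.25) {
  if (is.character(template)) template <- build_template(template)
  if (!is.null(seed)) set.seed(seed)
  lab <- param_labels(template)
  from <- sub("->.*", "", lab); to <- sub(".*->", "", lab)
  fc <- sub("/.*", "", from); fd <- sub(".*/", "", from)
  tc <- sub("/.*", "", to); td <- sub(".*/", "", to)
  crep <- fd == "Crep" | td == "Crep"
  colch <- fc != tc & !crep
  base <- numeric(length(lab))
  base[crep] <- crep_rate
  base[colch & fc == "Cry"] <- 0.45
  base[colch & fc == "Con"] <- 0.55
  diel <- !crep & !colch
  base[diel] <- 0.5           # within-colour diel change, incl. into All
  base[diel & fd == "All"] <- 1.8  # the All state is labile
  rates <- base * exp(rnorm(length(base), 0, jitter_sd))
  setNames(rates, lab)
}

#' Generate a study-like synthetic dataset
#'
#' Produces a dataset with the structure the analysis assumes: an
#' ultrametric Yule tree, the combined character evolved under a
#' constrained model (default `"E22"`) from a cryptic-nocturnal root,
#' with crepuscular paths rare so crepuscular tips are few and recent.
#' Diagnostics (tip-state frequencies, crepuscular tip fraction, the
#' depth of crepuscular origins, realized transition counts) are
#' attached so simulations can be checked against these qualitative
#' features.
#'
#' @param n_tips Number of tips (default 322, the size of a typical
#'   curated moth dataset).
#' @param model Generating model name.
#' @param rates Named or plain rate vector for the model's free slots;
#'   default [default_study_rates()].
#' @param root Root state (default `"Cry/Noc"`).
#' @param tree_height Height of the simulated chronogram.
#' @param seed Integer seed driving tree, rates and character.
#' @return An `mk_sim` (see [sim_character()]) with extra elements
#'   `model`, `config` and `diagnostics`.
#' @examples
#' sim <- sim_study_dataset(n_tips = 50, seed = 1)
#' sim$diagnostics$state_freq
#' @export
sim_study_dataset <- function(n_tips = 322, model = "E22", rates = NULL,
                              root = "Cry/Noc", tree_height = 1, seed = NULL) {
  template <- build_template(model)
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  tree <- sim_yule_tree(n_tips, seed = seed, height = tree_height)
  if (is.null(rates)) rates <- default_study_rates(template, seed = seed + 1L)
  if (all(rates == 0) ) warning("all rates are zero; every tip will carry the root state")
  sim <- sim_character(tree, build_q(template, unname(rates)), root = root,
                       seed = seed + 2L)
  sim$model <- model
  sim$config <- list(n_tips = n_tips, model = model, rates = rates,
                     root = root, tree_height = tree_height, seed = seed)

  depths <- ape::node.depth.edgelength(tree)
  crep_tip <- sim$traits$diel == "Crep"
  crep_events <- dplyr::filter(sim$history, grepl("Crep", .data$to))
  sim$diagnostics <- list(
    state_freq = prop.table(table(factor(sim$traits$state, levels = 0:7,
                                         labels = combined_states()))),
    crep_tip_fraction = mean(crep_tip),
    # depth at which each crepuscular origin happened: parent node depth
    # plus the event's time along the branch
    crep_origin_depths = if (nrow(crep_events)) {
      depths[crep_events$parent] + crep_events$time
    } else numeric(0),
    realized_transitions = table(paste(sim$history$from, "->", sim$history$to))
  )
  sim
}

#' @export
print.mk_sim <- function(x, ...) {
  cat("Simulated dataset:", length(x$tree$tip.label), "tips,",
      nrow(x$history), "realized transitions\n")
  if (!is.null(x$model)) cat("  generating model:", x$model, "\n")
  print(prop.table(table(x$traits$colour, x$traits$diel)))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits the Newick tree, the trait CSV, the true-history CSV and a JSON
#' echo of the configuration into a directory.
#'
#' @param sim An `mk_sim` from [sim_study_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_trait_csv(sim$traits, file.path(dir, "traits.csv"))
  utils::write.csv(as.data.frame(sim$history), file.path(dir, "history.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(sim$config)) {
    jsonlite::write_json(sim$config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
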