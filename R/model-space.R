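#' The candidate model space: letters and digits
#'
#' A model name is a letter plus two digits, e.g. `"E22"`. The letter
#' says at which diel states transitions between cryptic and conspicuous
#' coloration are allowed; the two digits give the connectivity of diel
#' transitions among \{Diu, Noc, All\} within the cryptic (first digit)
#' and conspicuous (second digit) colour states. Crepuscular edges are
#' shared plumbing present in every model and never varied.
#'
#' `colour_letter_sets()` returns the letter -> diel-state-subset map:
#' A–C are the singletons \{Diu\}, \{Noc\}, \{All\}; D–F the pairs
#' \{Noc,All\}, \{Diu,Noc\}, \{Diu,All\}; G the full set.
#' `diel_digit_edges()` returns the digit -> edge-set map on
#' \{Diu, Noc, All\}: 1 is the complete graph; 2 routes everything
#' through All (All as intermediate between Diu and Noc); 3 through Noc;
#' 4 through Diu. Every edge is bidirectional with two separately
#' estimated rates.
#'
#' @return Named lists: character vectors of diel states per letter, or
#'   2-column matrices of edge endpoints per digit.
#' @examples
#' colour_letter_sets()$E
#' diel_digit_edges()[["2"]]
#' @export
colour_letter_sets <- function() {
  list(
    A = "Diu", B = "Noc", C = "All",
    D = c("Noc", "All"), E = c("Diu", "Noc"), F = c("Diu", "All"),
    G = c("Diu", "Noc", "All")
  )
}

#' @rdname colour_letter_sets
#' @export
diel_digit_edges <- function() {
  edge <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                               dimnames = list(NULL, c("from", "to")))
  list(
    `1` = edge("Diu", "Noc", "Noc", "All", "Diu", "All"),
    `2` = edge("Noc", "All", "All", "Diu"),
    `3` = edge("Diu", "Noc", "Noc", "All"),
    `4` = edge("Diu", "Noc", "Diu", "All")
  )
}

#' Parse a model name into its specification
#'
#' @param name A model name such as `"E22"`: a letter A–G and two digits
#'   1–4.
#' @return A list of class `mk_model_spec` with elements `name`,
#'   `letter`, `colour_set`, `cry_digit`, `con_digit`, `cry_edges`,
#'   `con_edges`.
#' @examples
#' parse_model_name("E23")
#' @export
parse_model_name <- function(name) {
  name <- toupper(trimws(name))
  if (!grepl("^[A-G][1-4][1-4]$", name)) {
    stop("invalid model name '", name, "' (expected letter A-G + two digits 1-4)")
  }
  letter <- substr(name, 1, 1)
  d1 <- substr(name, 2, 2)
  d2 <- substr(name, 3, 3)
  structure(
    list(
      name = name,
      letter = letter,
      colour_set = colour_letter_sets()[[letter]],
      cry_digit = as.integer(d1),
      con_digit = as.integer(d2),
      cry_edges = diel_digit_edges()[[d1]],
      con_edges = diel_digit_edges()[[d2]]
    ),
    class = "mk_model_spec"
  )
}

#' Enumerate all 112 candidate models
#'
#' Crosses the 7 colour-transition letters with the 4 x 4 diel
#' connectivity digits, giving the 112 models A11 ... G44 in
#' lexicographic order.
#'
#' @return A tibble with one row per model: `name`, `letter`,
#'   `cry_digit`, `con_digit`, `colour_set` (list-column) and `df`
#'   (number of free rate parameters).
#' @examples
#' nrow(enumerate_models())  # 112
#' @export
enumerate_models <- function() {
  grid <- expand.grid(
    con_digit = 1:4, cry_digit = 1:4, letter = LETTERS[1:7],
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, 3:1]
  tibble::tibble(
    name = paste0(grid$letter, grid$cry_digit, grid$con_digit),
    letter = grid$letter,
    cry_digit = grid$cry_digit,
    con_digit = grid$con_digit,
    colour_set = unname(colour_letter_sets()[grid$letter]),
    df = vapply(paste0(grid$letter, grid$cry_digit, grid$con_digit),
                count_params, integer(1), USE.NAMES = FALSE)
  )
}

#' Compile a model into a rate-matrix template
#'
#' Builds the 8 x 8 template of a model over the combined state space:
#' each allowed instantaneous transition gets a unique free-parameter id
#' (a positive integer), every forbidden transition is a structural zero.
#' The template encodes the model's constraints:
#'
#' * no dual transitions — no entry connects states differing in both
#'   colour and diel activity;
#' * colour changes (Cry <-> Con) only at the diel states in the model's
#'   letter subset, in both directions;
#' * diel changes among \{Diu, Noc, All\} within a colour only along the
#'   digit's edges, in both directions;
#' * crepuscular exchange with each of Diu/Noc/All within each colour is
#'   always allowed in both directions (12 parameters), never across
#'   colours.
#'
#' Every allowed direction has its own parameter (no rate equalities, no
#' irreversible paths). Parameter ids are assigned row-major over the
#' grid.
#'
#' @param spec A model name or an `mk_model_spec` from
#'   [parse_model_name()].
#' @return An integer 8 x 8 matrix of class `mk_template` with state
#'   labels as dimnames; 0 marks a structural zero (and the diagonal),
#'   positive entries are free-parameter ids. Attributes: `n_free`,
#'   `spec`.
#' @examples
#' tpl <- build_template("E22")
#' attr(tpl, "n_free")  # 24
#' @export
build_template <- function(spec) {
  if (is.character(spec)) spec <- parse_model_name(spec)
  stopifnot(inherits(spec, "mk_model_spec"))
  allowed <- matrix(FALSE, 8, 8,
                    dimnames = list(combined_states(), combined_states()))
  at <- function(c1, d1, c2, d2) {
    i <- encode_state(c1, d1) + 1L
    j <- encode_state(c2, d2) + 1L
    allowed[i, j] <<- TRUE
    allowed[j, i] <<- TRUE
  }
  for (d in spec$colour_set) at("Cry", d, "Con", d)
  for (colour in colour_states()) {
    edges <- if (colour == "Cry") spec$cry_edges else spec$con_edges
    for (k in seq_len(nrow(edges))) at(colour, edges[k, 1], colour, edges[k, 2])
    for (d in c("Diu", "Noc", "All")) at(colour, "Crep", colour, d)
  }
  # ids in row-major scan order: transpose, fill column-major, transpose back
  tplT <- matrix(0L, 8, 8)
  idx <- which(t(allowed))
  tplT[idx] <- seq_along(idx)
  tpl <- t(tplT)
  dimnames(tpl) <- dimnames(allowed)
  structure(tpl, n_free = sum(allowed), spec = spec, class = "mk_template")
}

#' Count the free rate parameters of a model
#'
#' The model's degrees of freedom: `2 * |colour set|` colour rates, the
#' diel rates of the two digit structures (6 for the complete graph,
#' 4 for a two-edge graph), plus the 12 crepuscular rates.
#'
#' @inheritParams build_template
#' @return Integer number of free parameters.
#' @examples
#' count_params("D22")  # 24
#' @export
count_params <- function(spec) {
  if (is.character(spec)) spec <- parse_model_name(spec)
  rates <- function(digit) if (digit == 1L) 6L else 4L
  as.integer(2L * length(spec$colour_set) +
               rates(spec$cry_digit) + rates(spec$con_digit) + 12L)
}

#' @export
print.mk_template <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Rate-matrix template for model ", spec$name,
      " (", attr(x, "n_free"), " free parameters)\n", sep = "")
  m <- unclass(x)
  attr(m, "n_free") <- attr(m, "spec") <- NULL
  print(m)
  invisible(x)
}

#' Export a template as JSON
#'
#' Writes the 8 x 8 slot grid (state names as row/column labels, 0 for
#' structural zeros, positive free-parameter ids) together with the
#' model name and parameter count.
#'
#' @param spec Model name or spec.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_template_json <- function(spec, path) {
  tpl <- build_template(spec)
  obj <- list(
    model = attr(tpl, "spec")$name,
    states = combined_states(),
    n_free = attr(tpl, "n_free"),
    template = unclass(tpl)[,]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
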