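#' Colour, diel and combined character states
#'
#' The analysis works on an eight-state combined character built from a
#' binary coloration trait and a four-level diel-activity trait:
#'
#' * colour: `"Cry"` (cryptic / camouflaged) or `"Con"` (conspicuous,
#'   warning-coloured);
#' * diel activity: `"Diu"` (diurnal), `"Noc"` (nocturnal), `"All"`
#'   (active both day and night) or `"Crep"` (crepuscular).
#'
#' The canonical orders are `Cry < Con` and `Diu < Noc < All < Crep`, and
#' every combined state carries a stable integer index
#' `4 * colour_rank + diel_rank` in `0:7`, so `Cry/Diu` is 0 and
#' `Con/Crep` is 7. All rate matrices, templates and probability vectors
#' in the package are ordered by this index.
#'
#' @return Character vectors of state labels, in canonical order.
#' @examples
#' combined_states()
#' encode_state("Con", "Crep")
#' @export
colour_states <- function() c("Cry", "Con")

#' @rdname colour_states
#' @export
diel_states <- function() c("Diu", "Noc", "All", "Crep")

#' @rdname colour_states
#' @export
combined_states <- function() {
  as.vector(t(outer(colour_states(), diel_states(), paste, sep = "/")))
}

n_states <- function() 8L

#' Encode and decode combined states
#'
#' `encode_state()` maps (colour, diel) pairs to the canonical integer
#' index in `0:7`; `decode_state()` inverts it. Both are vectorized and
#' the pair is a bijection over the eight states.
#'
#' @param colour Character vector of `"Cry"`/`"Con"`.
#' @param diel Character vector of `"Diu"`/`"Noc"`/`"All"`/`"Crep"`.
#' @param index Integer vector with values in `0:7`.
#' @return `encode_state()` an integer vector; `decode_state()` a tibble
#'   with columns `colour`, `diel` and `label`.
#' @examples
#' encode_state("Cry", "Diu")  # 0
#' decode_state(7L)
#' @export
encode_state <- function(colour, diel) {
  ci <- match(colour, colour_states())
  di <- match(diel, diel_states())
  if (anyNA(ci)) stop("unknown colour state: ",
                      paste(unique(colour[is.na(ci)]), collapse = ", "))
  if (anyNA(di)) stop("unknown diel state: ",
                      paste(unique(diel[is.na(di)]), collapse = ", "))
  as.integer(4L * (ci - 1L) + (di - 1L))
}

#' @rdname encode_state
#' @export
decode_state <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L | index > 7L)) {
    stop("state index must be in 0..7")
  }
  tibble::tibble(
    colour = colour_states()[index %/% 4L + 1L],
    diel = diel_states()[index %% 4L + 1L],
    label = combined_states()[index + 1L]
  )
}

state_label <- function(index) combined_states()[as.integer(index) + 1L]

#' Consensus colour classification from expert votes
#'
#' Each species is scored independently by four experts as cryptic
#' (`"Cry"`), conspicuous (`"Con"`) or `"Uncertain"`. A species enters
#' the dataset only when the experts agree: under
#' `mode = "three_of_four"` a colour wins when at least three of the four
#' votes name it; under `mode = "unanimous"` all four must agree.
#' `"Uncertain"` votes count toward the four but can never win — a
#' species whose majority vote is `"Uncertain"`, or with no qualifying
#' majority, is excluded.
#'
#' @param votes A data frame with columns `species`, `expert1` ...
#'   `expert4` (values `"Cry"`, `"Con"` or `"Uncertain"`).
#' @param mode Consensus rule: `"three_of_four"` (default) or
#'   `"unanimous"`.
#' @return A tibble with columns `species`, `colour` (`NA` when
#'   excluded), `n_agree` and `excluded_reason` (`NA` when kept).
#' @examples
#' votes <- tibble::tibble(
#'   species = c("a", "b"),
#'   expert1 = c("Cry", "Cry"), expert2 = c("Cry", "Cry"),
#'   expert3 = c("Cry", "Con"), expert4 = c("Con", "Con")
#' )
#' consensus_classify(votes)
#' @export
consensus_classify <- function(votes, mode = c("three_of_four", "unanimous")) {
  mode <- match.arg(mode)
  cols <- paste0("expert", 1:4)
  if (!all(c("species", cols) %in% names(votes))) {
    stop("`votes` needs columns species, expert1..expert4")
  }
  vm <- as.matrix(votes[cols])
  bad <- !vm %in% c(colour_states(), "Uncertain")
  if (any(bad)) stop("malformed votes: ", paste(unique(vm[bad]), collapse = ", "))
  threshold <- if (mode == "three_of_four") 3L else 4L
  res <- purrr::map(seq_len(nrow(vm)), function(i) {
    v <- vm[i, ]
    counts <- vapply(colour_states(), function(s) sum(v == s), integer(1))
    win <- names(counts)[counts >= threshold]
    if (length(win) == 1L) {
      list(colour = win, n_agree = unname(counts[win]), reason = NA_character_)
    } else {
      reason <- if (sum(v == "Uncertain") >= threshold) {
        "uncertain majority"
      } else {
        sprintf("no %s colour majority", if (threshold == 3L) "3-vote" else "unanimous")
      }
      list(colour = NA_character_, n_agree = max(counts), reason = reason)
    }
  })
  tibble::tibble(
    species = trimws(as.character(votes$species)),
    colour = purrr::map_chr(res, "colour"),
    n_agree = purrr::map_int(res, "n_agree"),
    excluded_reason = purrr::map_chr(res, "reason")
  )
}

#' Build the species trait table
#'
#' Joins per-species colour calls with per-species diel-activity calls
#' into the table the Mk machinery consumes. Species missing either
#' trait, excluded by the consensus rule, or polymorphic with forms in
#' different colour groups are dropped with a recorded reason; a
#' polymorphic species whose forms all fall in one colour group keeps
#' that colour. Species names are matched exactly (case-sensitive) after
#' whitespace trimming.
#'
#' @param colour_calls Data frame with columns `species` and `colour`
#'   (one row per form for polymorphic species; `colour` may be `NA`
#'   with an `excluded_reason` column, as produced by
#'   [consensus_classify()]).
#' @param diel_calls Data frame with columns `species` and `diel`.
#' @return A tibble with columns `species`, `colour`, `diel` and
#'   `state` (the 0–7 index), one row per retained species. Dropped
#'   species are attached as `attr(, "dropped")`, a tibble
#'   `species, reason`, also retrievable with [dropped_species()].
#' @export
build_trait_table <- function(colour_calls, diel_calls) {
  stopifnot(all(c("species", "colour") %in% names(colour_calls)),
            all(c("species", "diel") %in% names(diel_calls)))
  col <- tibble::as_tibble(colour_calls)
  diel <- tibble::as_tibble(diel_calls)
  col$species <- trimws(as.character(col$species))
  diel$species <- trimws(as.character(diel$species))
  if (anyDuplicated(diel$species)) {
    stop("duplicate species in diel calls: ",
         paste(unique(diel$species[duplicated(diel$species)]), collapse = ", "))
  }
  ok_diel <- diel$diel %in% diel_states()
  if (!all(ok_diel)) stop("unknown diel state: ",
                          paste(unique(diel$diel[!ok_diel]), collapse = ", "))

  dropped <- tibble::tibble(species = character(), reason = character())
  note <- function(sp, why) {
    dropped <<- dplyr::bind_rows(dropped, tibble::tibble(species = sp, reason = why))
  }

  # consensus exclusions carried in from consensus_classify()
  if ("excluded_reason" %in% names(col)) {
    ex <- dplyr::filter(col, is.na(.data$colour))
    if (nrow(ex)) note(ex$species, dplyr::coalesce(ex$excluded_reason, "excluded by consensus"))
    col <- dplyr::filter(col, !is.na(.data$colour))
  }
  ok_col <- col$colour %in% colour_states()
  if (!all(ok_col)) stop("unknown colour state: ",
                         paste(unique(col$colour[!ok_col]), collapse = ", "))

  # polymorphic species: one row per form; agreement keeps, conflict drops
  col <- col |>
    dplyr::distinct(.data$species, .data$colour) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(colour = if (dplyr::n() == 1L) .data$colour[1] else NA_character_,
                     .groups = "drop")
  poly <- dplyr::filter(col, is.na(.data$colour))
  if (nrow(poly)) note(poly$species, "polymorphic forms in different colour groups")
  col <- dplyr::filter(col, !is.na(.data$colour))

  only_col <- setdiff(col$species, diel$species)
  if (length(only_col)) note(only_col, "no diel record")
  only_diel <- setdiff(diel$species, c(col$species, dropped$species))
  if (length(only_diel)) note(only_diel, "no colour record")

  out <- dplyr::inner_join(col, diel[c("species", "diel")], by = "species") |>
    dplyr::mutate(state = encode_state(.data$colour, .data$diel)) |>
    dplyr::arrange(.data$species)
  attr(out, "dropped") <- dropped
  out
}

#' @rdname build_trait_table
#' @param traits A trait table from [build_trait_table()].
#' @export
dropped_species <- function(traits) {
  attr(traits, "dropped") %||% tibble::tibble(species = character(), reason = character())
}

#' Read or write a species trait table as CSV
#'
#' The on-disk format has columns `species,colour,diel` with the state
#' labels used throughout the package.
#'
#' @param path File path.
#' @param traits A trait table (columns `species`, `colour`, `diel`).
#' @return `read_trait_csv()` a validated trait tibble with the `state`
#'   column added; `write_trait_csv()` the path, invisibly.
#' @export
read_trait_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "colour", "diel") %in% names(df))) {
    stop("trait CSV needs columns species,colour,diel")
  }
  build_trait_table(df[c("species", "colour")], df[c("species", "diel")])
}

#' @rdname read_trait_csv
#' @export
write_trait_csv <- function(traits, path) {
  utils::write.csv(as.data.frame(traits[c("species", "colour", "diel")]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
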