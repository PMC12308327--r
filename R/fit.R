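# Maximum-likelihood fitting of the constrained Mk models and AIC model
# selection.

#' Fit one constrained Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free rates.
#' Optimization runs on log-transformed rates (bounded L-BFGS-B, default
#' bounds `[1e-6, 1e3]` per unit time) from a deterministic start plus
#' `restarts - 1` random restarts; the best optimum is kept. Rates well
#' above 1 per unit time are admitted because poorly informed paths can
#' take very large estimates. Optimizer failure or non-convergence is
#' recorded in the result, never raised: failed fits are data.
#'
#' @param tree An `ape::phylo` chronogram.
#' @param tips Trait table or tip likelihood matrix (see [mk_loglik()]).
#' @param model Model name (e.g. `"E22"`) or `mk_model_spec`.
#' @param prior Root prior passed to [root_prior()]; the default is flat
#'   over the eight states.
#' @param restarts Total optimizer starts (>= 1).
#' @param seed Integer seed controlling the random restarts.
#' @param bounds Length-2 numeric, lower/upper rate bounds.
#' @param control Extra `control` entries for [stats::optim()].
#' @param gradient `"central"` (optim's internal differences; most
#'   accurate) or `"forward"` (one-sided differences at roughly half
#'   the cost per iteration, useful for large model sweeps).
#' @return An object of class `mk_fit`: model spec and template, MLE
#'   `rates` (named `"From->To"`), `loglik`, `df`, `aic`, `converged`,
#'   `status` (`"ok"` or `"error"`), `n_restarts_used`, plus the tree,
#'   tip likelihoods and root prior used (so ancestral reconstruction
#'   and stochastic mapping can reuse them).
#' @examples
#' sim <- sim_study_dataset(n_tips = 60, seed = 7)
#' fit <- fit_mk(sim$tree, sim$traits, "E22", restarts = 1, seed = 1)
#' glance(fit)
#' @export
fit_mk <- function(tree, tips, model, prior = "flat", restarts = 5,
                   seed = NULL, bounds = c(1e-6, 1e3), control = list(),
                   gradient = c("central", "forward")) {
  gradient <- match.arg(gradient)
  spec <- if (is.character(model)) parse_model_name(model) else model
  template <- build_template(spec)
  nf <- attr(template, "n_free")
  pt <- prep_tree(tree)
  tl <- resolve_tipliks(tree, tips)

  lo <- log(bounds[1]); hi <- log(bounds[2])
  free <- which(template > 0)
  ids <- template[free]

  negll <- function(logr) {
    Q <- matrix(0, n_states(), n_states())
    Q[free] <- exp(logr)[ids]
    diag(Q) <- -rowSums(Q)
    pr <- root_prior(prior, Q = Q, tipliks = tl)
    ll <- cpp_mk_loglik(pt$edge, pt$lens, tl, pt$nnode, Q, pr)
    if (!is.finite(ll)) 1e10 else -ll
  }

  if (!is.null(seed)) set.seed(seed)
  # deterministic first start at a parsimony-flavoured scale: roughly one
  # change per unit of total tree length
  scale0 <- max(pt$ntip / sum(pt$lens), 1e-3)
  starts <- c(list(rep(log(scale0), nf)),
              purrr::map(seq_len(max(0, restarts - 1)),
                         ~ runif(nf, log(1e-2), log(2))))

  best <- NULL
  n_used <- 0L
  err_msg <- NA_character_
  for (s in starts) {
    n_used <- n_used + 1L
    gr <- if (gradient == "forward") {
      function(logr) {
        f0 <- negll(logr)
        h <- 1e-4
        vapply(seq_along(logr), function(i) {
          xi <- logr; xi[i] <- xi[i] + h
          (negll(xi) - f0) / h
        }, numeric(1))
      }
    } else NULL
    res <- tryCatch(
      optim(s, negll, gr = gr, method = "L-BFGS-B", lower = lo, upper = hi,
            control = utils::modifyList(list(maxit = 500L), control)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      err_msg <- conditionMessage(res)
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best) || best$value >= 1e10) {
    out <- list(
      model = spec$name, spec = spec, template = template,
      rates = setNames(rep(NA_real_, nf), param_labels(template)),
      Q = NULL, loglik = NA_real_, df = nf, aic = NA_real_,
      converged = FALSE, status = "error",
      message = err_msg %||% "no finite likelihood found",
      n_restarts_used = n_used,
      tree = tree, tipliks = tl, prior = prior
    )
    return(structure(out, class = "mk_fit"))
  }

  rates <- setNames(exp(best$par), param_labels(template))
  Q <- build_q(template, unname(rates))
  loglik <- -best$value
  out <- list(
    model = spec$name, spec = spec, template = template,
    rates = rates, Q = Q, loglik = loglik, df = nf,
    aic = 2 * nf - 2 * loglik,
    converged = best$convergence == 0, status = "ok",
    message = if (best$convergence == 0) NA_character_ else best$message %||% "optim did not converge",
    n_restarts_used = n_used,
    tree = tree, tipliks = tl, prior = prior
  )
  structure(out, class = "mk_fit")
}

#' Fit a set of candidate models
#'
#' Fits each named model with [fit_mk()] (each model gets its own seed
#' derived from `seed`) and assembles the AIC model-selection table.
#'
#' @inheritParams fit_mk
#' @param models `"all"` for the full 112-model space, or a character
#'   vector of model names.
#' @param .progress Print a one-line progress note per model.
#' @param ... Passed on to [fit_mk()] (e.g. `gradient`, `bounds`,
#'   `control`).
#' @return An object of class `mk_model_set`: a named list of `mk_fit`s
#'   plus the selection table (see [aic_table()]).
#' @export
fit_mk_models <- function(tree, tips, models = "all", prior = "flat",
                          restarts = 5, seed = NULL, .progress = FALSE, ...) {
  names_ <- if (identical(models, "all")) enumerate_models()$name else models
  fits <- purrr::imap(setNames(names_, names_), function(m, nm) {
    i <- match(nm, names_)
    if (.progress) message("fitting ", m, " (", i, "/", length(names_), ")")
    fit_mk(tree, tips, m, prior = prior, restarts = restarts,
           seed = if (is.null(seed)) NULL else
             as.integer((as.numeric(seed) + 1000 * i) %% 2147483647),
           ...)
  })
  structure(list(fits = fits, table = aic_table(fits)), class = "mk_model_set")
}

#' AIC model-selection table
#'
#' Computes, for every fitted model, `AIC = 2 df - 2 logLik`, the AIC
#' difference to the best model, and Akaike weights
#' `exp(-dAIC/2) / sum(exp(-dAIC/2))` normalized over the successfully
#' fitted subset. Failed fits keep their row (with `NA` score columns)
#' so they are surfaced, not silently dropped.
#'
#' @param fits A list of `mk_fit` objects or an `mk_model_set`.
#' @return A tibble sorted by ascending AIC with columns `model`,
#'   `loglik`, `df`, `aic`, `delta_aic`, `weight`, `converged`,
#'   `status`. The fitted model subset is recorded in
#'   `attr(, "models")`.
#' @examples
#' aic_table(list(
#'   list(model = "E22", loglik = -397.76, df = 24, aic = 843.51,
#'        converged = TRUE, status = "ok")
#' ))
#' @export
aic_table <- function(fits) {
  if (inherits(fits, "mk_model_set")) fits <- fits$fits
  if (inherits(fits, "mk_fit")) fits <- list(fits)
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      model = f$model, loglik = f$loglik, df = f$df,
      aic = if (is.na(f$loglik)) NA_real_ else 2 * f$df - 2 * f$loglik,
      converged = isTRUE(f$converged),
      status = f$status %||% "ok"
    )
  })
  ok <- !is.na(tab$aic)
  if (!any(ok)) stop("no successful fits to rank")
  tab$delta_aic <- tab$aic - min(tab$aic[ok])
  w <- exp(-tab$delta_aic / 2)
  w[!ok] <- NA_real_
  tab$weight <- w / sum(w, na.rm = TRUE)
  tab <- dplyr::arrange(tab, dplyr::desc(!is.na(.data$aic)), .data$aic) |>
    dplyr::select("model", "loglik", "df", "aic", "delta_aic", "weight",
                  "converged", "status")
  attr(tab, "models") <- tab$model
  tab
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Constrained Mk fit: model", x$model, "\n")
  if (x$status != "ok") {
    cat("  fit FAILED:", x$message, "\n")
  } else {
    cat(sprintf("  logLik %.3f  df %d  AIC %.3f  converged: %s\n",
                x$loglik, x$df, x$aic, x$converged))
    cat("  rate range:", sprintf("%.4g", min(x$rates)), "-",
        sprintf("%.4g", max(x$rates)), "per unit time\n")
  }
  invisible(x)
}

#' @export
print.mk_model_set <- function(x, ...) {
  cat("Mk model set:", length(x$fits), "models fitted\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Tidy methods for fitted Mk objects
#'
#' `tidy()` on an `mk_fit` returns one row per free rate (`from`, `to`,
#' `rate`); on an `mk_model_set` it returns the model-selection table.
#' `glance()` on an `mk_fit` returns the one-row model summary.
#'
#' @param x An `mk_fit` or `mk_model_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mk_fit <- function(x, ...) {
  parts <- strsplit(names(x$rates), "->", fixed = TRUE)
  tibble::tibble(
    model = x$model,
    from = purrr::map_chr(parts, 1),
    to = purrr::map_chr(parts, 2),
    rate = unname(x$rates)
  )
}

#' @rdname tidy.mk_fit
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, df = x$df,
                 aic = x$aic, converged = x$converged, status = x$status,
                 n_restarts_used = x$n_restarts_used)
}

#' @rdname tidy.mk_fit
#' @export
tidy.mk_model_set <- function(x, ...) x$table

#' Export fitted rates as JSON
#'
#' Writes the MLE rates keyed `"FromState->ToState"`, with the model
#' name and fit summary.
#'
#' @param fit An `mk_fit`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
export_rates_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model, loglik = fit$loglik, df = fit$df, aic = fit$aic,
         converged = fit$converged, rates = as.list(fit$rates)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
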