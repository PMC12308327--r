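test_that("the model space enumerates exactly the 112 named hypotheses", {
  m <- enumerate_models()
  expect_equal(nrow(m), 112L)
  expect_false(anyDuplicated(m$name) > 0)
  expect_true(all(grepl("^[A-G][1-4][1-4]$", m$name)))
  expect_identical(m$name, sort(m$name))  # lexicographic A11 ... G44
  expect_identical(m$name[1], "A11")
  expect_identical(m$name[112], "G44")
  expect_true(all(c("E22", "E23") %in% m$name))
})

test_that("letter and digit maps match their anchored structure", {
  sets <- colour_letter_sets()
  # seven letters biject to the seven nonempty subsets of {Diu, Noc, All}
  keys <- sapply(sets, function(s) paste(sort(s), collapse = "+"))
  expect_equal(length(unique(keys)), 7L)
  expect_true(all(lengths(sets[c("A", "B", "C")]) == 1))
  expect_setequal(sets$E, c("Diu", "Noc"))
  expect_setequal(sets$G, c("Diu", "Noc", "All"))

  edges <- diel_digit_edges()
  expect_equal(nrow(edges[["1"]]), 3L)
  expect_true(all(sapply(edges[c("2", "3", "4")], nrow) == 2L))
  # digit 2: All is the intermediate (no direct Diu-Noc edge)
  e2 <- apply(edges[["2"]], 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(e2, c("All-Noc", "All-Diu"))
  # digit 3: Noc is the hub (no direct Diu-All edge)
  e3 <- apply(edges[["3"]], 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(e3, c("Diu-Noc", "All-Noc"))
})

test_that("parameter counts reproduce the published degrees of freedom", {
  expect_identical(count_params("D22"), 24L)
  expect_identical(count_params("G32"), 26L)
  expect_identical(count_params("G21"), 28L)
  expect_identical(count_params("E13"), 26L)
  expect_identical(count_params("E12"), 26L)
  expect_identical(count_params("E42"), 24L)
  # derived by exhaustive scan of the built template
  tpl <- build_template("A11")
  expect_identical(sum(tpl > 0), 26L)
  expect_identical(count_params("A11"), 26L)
})

test_that("count_params equals the template's free-slot count for all 112 models", {
  m <- enumerate_models()
  for (nm in m$name) {
    tpl <- build_template(nm)
    ids <- tpl[tpl > 0]
    expect_identical(count_params(nm), length(unique(ids)))
    expect_identical(attr(tpl, "n_free"), length(ids))
    expect_identical(sort(unique(ids)), seq_along(ids))  # unique sequential ids
  }
  expect_identical(min(m$df), 22L)  # e.g. A22
  expect_identical(max(m$df), 30L)  # G11
  expect_identical(count_params("A22"), 22L)
  expect_identical(count_params("G11"), 30L)
})

test_that("templates forbid dual transitions and keep slots reversible", {
  dec <- decode_state(0:7)
  for (nm in c("A11", "C44", "E22", "E23", "G11", "D32", "F21")) {
    tpl <- build_template(nm)
    for (i in 1:8) for (j in 1:8) {
      if (i == j) next
      dual <- dec$colour[i] != dec$colour[j] & dec$diel[i] != dec$diel[j]
      if (dual) expect_identical(tpl[i, j], 0L)
      # reversibility with distinct parameter ids
      if (tpl[i, j] > 0) {
        expect_gt(tpl[j, i], 0)
        expect_false(tpl[i, j] == tpl[j, i])
      }
    }
    # crepuscular plumbing: within-colour exchange always free, never across
    for (cl in colour_states()) {
      for (d in c("Diu", "Noc", "All")) {
        expect_gt(tpl[paste0(cl, "/Crep"), paste0(cl, "/", d)], 0)
        expect_gt(tpl[paste0(cl, "/", d), paste0(cl, "/Crep")], 0)
      }
    }
    expect_identical(tpl["Cry/Crep", "Con/Crep"], 0L)
    expect_identical(tpl["Con/Crep", "Cry/Crep"], 0L)
  }
})

test_that("the E22 template places colour transitions at Diu and Noc only", {
  tpl <- build_template("E22")
  expect_gt(tpl["Cry/Noc", "Con/Noc"], 0)
  expect_gt(tpl["Cry/Diu", "Con/Diu"], 0)
  expect_identical(tpl["Cry/All", "Con/All"], 0L)
  expect_identical(tpl["Cry/Noc", "Con/Diu"], 0L)  # no dual transition
  expect_gt(tpl["Cry/Crep", "Cry/Diu"], 0)
  # digit 2 in both colours: no direct Diu <-> Noc edge
  expect_identical(tpl["Cry/Diu", "Cry/Noc"], 0L)
  expect_gt(tpl["Cry/Diu", "Cry/All"], 0)
  expect_identical(tpl["Con/Diu", "Con/Noc"], 0L)
  # E23: Noc-hub conspicuous structure restores Diu <-> Noc, drops Diu <-> All
  tpl23 <- build_template("E23")
  expect_gt(tpl23["Con/Diu", "Con/Noc"], 0)
  expect_identical(tpl23["Con/Diu", "Con/All"], 0L)
})

test_that("swapping the digits swaps the colour-specific structures", {
  for (nm in c("E23", "G41", "D12")) {
    swapped <- paste0(substr(nm, 1, 1), substr(nm, 3, 3), substr(nm, 2, 2))
    a <- build_template(nm)
    b <- build_template(swapped)
    expect_identical(attr(a, "n_free"), attr(b, "n_free"))
    cry <- 1:4; con <- 5:8
    expect_identical(unname(a[cry, cry] > 0), unname(b[con, con] > 0))
    expect_identical(unname(a[con, con] > 0), unname(b[cry, cry] > 0))
  }
})

test_that("model names parse and reject malformed input", {
  spec <- parse_model_name("E23")
  expect_equal(spec$colour_set, c("Diu", "Noc"))
  expect_equal(spec$cry_digit, 2L)
  expect_equal(spec$con_digit, 3L)
  expect_error(parse_model_name("H11"), "invalid")
  expect_error(parse_model_name("E50"), "invalid")
})

test_that("template JSON export carries the grid and parameter count", {
  path <- withr::local_tempfile(fileext = ".json")
  export_template_json("D22", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$model, "D22")
  expect_equal(obj$n_free, 24L)
  expect_equal(dim(obj$template), c(8L, 8L))
  expect_equal(sum(obj$template > 0), 24L)
})
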