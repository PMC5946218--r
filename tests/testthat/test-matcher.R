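# Level semantics, unit decomposition, ranking and the brute-force
# oracle.

test_that("the courgette worked example reproduces levels 0 and 1", {
  q <- courgette_query()
  expect_equal(match_level(q, pak_choi())$level, 0)
  m <- match_level(q, courgettes_raw())
  expect_equal(m$level, 1)
  expect_equal(m$unmatched_units$value, "0309")
  # dropping 0204 as well makes it a level 2 match
  expect_equal(match_level(q, courgettes_raw(terms = "0499"))$level, 2)

  db <- composition_table(list(pak_choi(), courgettes_raw()))
  res <- search(q, db)
  expect_equal(res$code, c("NL002", "NL001"))
  expect_equal(res$level, c(0L, 1L))
})

test_that("queries decompose into one unit per attribute", {
  q <- courgette_query()
  u <- attribute_units(q)
  expect_equal(nrow(u), 5)
  expect_equal(as.vector(table(u$kind)[c("name", "group", "descriptor")]),
               c(1L, 1L, 3L))

  m <- parse_query_string("Xmargarine, A039D, F10.A0B8M")
  expect_equal(nrow(attribute_units(m)), 3)

  expect_equal(nrow(attribute_units(parse_query_string("G02"))), 1)

  qs <- match_query(group = "G02", subgroups = c("G02.1", "G02.2"),
                    descriptors = "0499")
  u <- attribute_units(qs)
  expect_equal(sum(u$kind == "subgroup"), 2)
})

test_that("unit matching follows the at-least-one-name and descriptor rules", {
  q <- courgette_query()
  u <- attribute_units(q)
  name_unit <- u[u$kind == "name", ]
  expect_true(unit_matches(name_unit, pak_choi()))   # shares only "raw"
  expect_false(unit_matches(name_unit,
    composition_food("X", "Pumpkin soup", "G02")))

  d0309 <- u[u$value == "0309", ]
  expect_false(unit_matches(d0309, courgettes_raw()))
  expect_true(unit_matches(d0309, pak_choi()))
})

test_that("descriptor units match through crosswalk translation", {
  cw <- crosswalk(tibble::tibble(
    source_system = "GloboDiet", source_code = "0499",
    langual_codes = list(c("J0116", "J0117")), provenance = "curated"
  ))
  settings <- search_settings(crosswalk = cw)
  q <- match_query(group = "G02", descriptors = "0499", system = "GloboDiet")
  hit <- composition_food("A", "x", "G02", langual_terms = "J0117")
  miss <- composition_food("B", "x", "G02", langual_terms = "J0118")
  expect_equal(match_level(q, hit, settings)$level, 0)
  expect_equal(match_level(q, miss, settings)$level, 1)
})

test_that("hierarchical group credit is an explicit opt-in", {
  gv <- vocabulary("GloboDiet", tibble::tibble(
    code = c("G02", "G02.1"), label = c("veg", "leafy veg"), facet = "",
    parents = list(character(0), "G02"), attributes = ""
  ))
  q <- match_query(group = "G02", descriptors = "0499")
  cand <- composition_food("A", "x", "G02.1", langual_terms = "0499")
  expect_equal(match_level(q, cand)$level, 1)  # exact by default
  hier <- search_settings(hierarchical_group = TRUE, group_vocab = gv)
  expect_equal(match_level(q, cand, hier)$level, 0)
})

test_that("level equals the count of failing units, bounded by the unit count", {
  q <- courgette_query()
  # candidate sharing nothing at all: every unit fails
  stranger <- composition_food("Z", "stockfish", "G09",
                               langual_terms = "9999")
  m <- match_level(q, stranger)
  expect_equal(m$level, 5)
  expect_equal(nrow(m$matched_units), 0)

  set.seed(31)
  for (i in 1:25) {
    inst <- random_instance(seed = 1000 + i, max_candidates = 30)
    n_units <- nrow(attribute_units(inst$query))
    j <- sample(nrow(inst$db), 1)
    m <- match_level(inst$query, inst$db[j, ])
    expect_gte(m$level, 0)
    expect_lte(m$level, n_units)
    expect_equal(m$level, nrow(m$unmatched_units))
    expect_equal(nrow(m$matched_units) + nrow(m$unmatched_units), n_units)
  }
})

test_that("match_level is invariant to descriptor and token order", {
  cand <- pak_choi()
  q1 <- match_query(c("raw", "courgette"), "G02",
                    descriptors = c("0499", "0204", "0309"))
  q2 <- match_query(c("courgette", "raw"), "G02",
                    descriptors = c("0309", "0499", "0204"))
  expect_equal(match_level(q1, cand)$level, match_level(q2, cand)$level)
  expect_identical(attribute_units(q1), attribute_units(q2))
})

test_that("removing a matched attribute raises the level by exactly one; unrelated terms never change it", {
  set.seed(57)
  for (i in 1:15) {
    inst <- random_instance(seed = 2000 + i, max_candidates = 20)
    j <- sample(nrow(inst$db), 1)
    cand <- inst$db[j, ]
    m <- match_level(inst$query, cand)

    # strip one matched unit from the candidate
    if (nrow(m$matched_units) > 0) {
      u <- m$matched_units[sample(nrow(m$matched_units), 1), ]
      cand2 <- cand
      if (u$kind == "name") cand2$name_tokens <- list(character(0))
      if (u$kind == "group") cand2$group <- ""
      if (u$kind == "subgroup")
        cand2$subgroups <- list(setdiff(cand2$subgroups[[1]], u$value))
      if (u$kind == "descriptor")
        cand2$langual_terms <- list(setdiff(cand2$langual_terms[[1]],
                                            u$translated[[1]]))
      expect_equal(match_level(inst$query, cand2)$level, m$level + 1)
    }

    # padding with LanguaL terms foreign to the query leaves the level alone
    cand3 <- cand
    cand3$langual_terms <- list(c(cand3$langual_terms[[1]],
                                  c("ZZ01", "ZZ02", "ZZ03")))
    expect_equal(match_level(inst$query, cand3)$level, m$level)
  }
})

test_that("search matches the brute-force oracle on randomized instances", {
  for (i in 1:50) {
    inst <- random_instance(seed = 3000 + i, max_candidates = 120)
    settings <- search_settings(max_level = sample(0:4, 1),
                                max_per_level = sample(c(3, 10, 50), 1))
    a <- search(inst$query, inst$db, settings)
    b <- brute_force_search(inst$query, inst$db, settings)
    expect_identical(results_signature(a), results_signature(b), info = i)
    expect_identical(a$matched_units, b$matched_units)
  }
})

test_that("within-level ranking: name overlap descending, then code; duplicates co-ranked by code", {
  q <- match_query(c("apple", "pie"), "G01", descriptors = "0101")
  mk <- function(code, name) composition_food(code, name, "G01",
                                              langual_terms = "0101")
  db <- composition_table(list(
    mk("C3", "apple"), mk("C1", "plain scone"), mk("C2", "apple pie")
  ))
  res <- search(q, db, search_settings(max_level = 1))
  # level 0: overlap 2 beats overlap 1; the no-overlap record is level 1
  expect_equal(res$code, c("C2", "C3", "C1"))
  expect_equal(res$level, c(0L, 0L, 1L))

  # duplicate records under distinct codes: equal level, ordered by code
  db2 <- composition_table(list(mk("B2", "apple"), mk("B1", "apple")))
  res2 <- search(q, db2, search_settings(max_level = 1))
  expect_equal(res2$code, c("B1", "B2"))
  expect_equal(res2$level, c(0L, 0L))
  expect_equal(res2$rank, c(1L, 2L))
})

test_that("per-level caps limit the listing but totals report all candidates", {
  q <- match_query(group = "G01", descriptors = "0101")
  db <- composition_table(lapply(1:30, function(i)
    composition_food(sprintf("C%02d", i), "x", "G01", langual_terms = "0101")))
  res <- search(q, db, search_settings(max_level = 0, max_per_level = 5))
  expect_equal(nrow(res), 5)
  expect_equal(attr(res, "level_totals")[["0"]], 30L)
})

test_that("degenerate inputs: empty database and empty unit list", {
  q <- courgette_query()
  empty_db <- pak_choi()[0, ]
  expect_warning(res <- search(q, empty_db), "empty")
  expect_equal(nrow(res), 0)

  masked <- search_settings(mask = attribute_mask(use_group = TRUE,
                                                  use_names = FALSE,
                                                  use_subgroups = FALSE,
                                                  use_descriptors = FALSE))
  q2 <- match_query(name_tokens = "apple", system = "GloboDiet")
  expect_error(search(q2, composition_table(list(pak_choi())), masked),
               class = "fm_empty_query_error")
})
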