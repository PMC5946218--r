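# Loaders, validators and round-trips for the TSV interchange formats.

write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("vocabulary loading builds a validated facet index", {
  path <- write_lines_tsv(c(
    "code\tlabel\tfacet\tparents\tattributes",
    "0499\tPreservation method - fresh\tF01\t\tcore",
    "0204\tPhysical state - flesh\tF02\t\tcore",
    "0309\tCooking method - stir fried\tF03\t\tcore"
  ))
  v <- load_vocabulary(path, "GloboDiet")
  expect_s3_class(v, "fm_vocabulary")
  expect_equal(nrow(v$terms), 3)
  expect_equal(sort(names(v$facet_index)), c("F01", "F02", "F03"))
  expect_equal(v$facet_index[["F01"]], "0499")
})

test_that("vocabulary validation catches schema errors, duplicates and cycles", {
  bad_schema <- write_lines_tsv(c("code\tlabel", "A\tx"))
  expect_error(load_vocabulary(bad_schema, "LanguaL"), class = "fm_schema_error")

  dup <- write_lines_tsv(c(
    "code\tlabel\tfacet\tparents\tattributes",
    "A1\tx\tA\t\t", "A1\ty\tA\t\t"
  ))
  err <- expect_error(load_vocabulary(dup, "LanguaL"),
                      class = "fm_validation_error")
  expect_match(conditionMessage(err), "A1")

  cyc <- write_lines_tsv(c(
    "code\tlabel\tfacet\tparents\tattributes",
    "X\tx\tA\tY\t", "Y\ty\tA\tX\t"
  ))
  err <- expect_error(load_vocabulary(cyc, "LanguaL"),
                      class = "fm_validation_error")
  expect_match(conditionMessage(err), "cycle")

  empty <- write_lines_tsv("code\tlabel\tfacet\tparents\tattributes")
  expect_equal(nrow(load_vocabulary(empty, "LanguaL")$terms), 0)
})

test_that("vocabulary validation is independent of row order", {
  rows <- c("B1\tb1\tB\t\t", "B2\tb2\tB\tB1\t", "C1\tc1\tC\t\t",
            "C2\tc2\tC\tC1|B1\t")
  header <- "code\tlabel\tfacet\tparents\tattributes"
  v1 <- load_vocabulary(write_lines_tsv(c(header, rows)), "LanguaL")
  set.seed(7)
  v2 <- load_vocabulary(write_lines_tsv(c(header, sample(rows))), "LanguaL")
  expect_identical(v1$terms, v2$terms)
  expect_identical(v1$facet_index, v2$facet_index)
})

test_that("unresolved parents are reported as warnings, not dropped", {
  path <- write_lines_tsv(c(
    "code\tlabel\tfacet\tparents\tattributes",
    "B1\tb1\tB\tNOPE\t"
  ))
  expect_warning(v <- load_vocabulary(path, "LanguaL"), "NOPE")
  expect_equal(nrow(v$terms), 1)
  expect_equal(v$unresolved_parents, "NOPE")
})

test_that("composition rows round-trip field by field", {
  path <- write_lines_tsv(c(
    paste("code", "english_name", "group", "subgroups", "langual_terms",
          "CHO", "ENERC", "FAT", "PROT", "WATER", sep = "\t"),
    "NL001\tCourgettes raw\tG02\t\t0499|0204\t3.1\t94\t0.4\t1.2\t94.6"
  ))
  db <- load_composition_table(path)
  expect_equal(nrow(db), 1)
  expect_equal(db$code, "NL001")
  expect_equal(db$name_tokens[[1]], c("courgettes", "raw"))
  expect_equal(db$langual_terms[[1]], c("0499", "0204"))
  expect_equal(db$subgroups[[1]], character(0))
  expect_equal(db$CHO, 3.1)
  expect_equal(db$WATER, 94.6)

  out <- tempfile(fileext = ".tsv")
  write_composition_table(db, out)
  again <- load_composition_table(out)
  expect_identical(as.data.frame(db), as.data.frame(again))
})

test_that("composition loading tolerates empty names but rejects bad cells", {
  header <- paste("code", "english_name", "group", "subgroups",
                  "langual_terms", "CHO", "ENERC", "FAT", "PROT", "WATER",
                  sep = "\t")
  noname <- write_lines_tsv(c(header,
    "DE001\t\tG01\t\t0499\t1\t2\t3\t4\t5"))
  db <- load_composition_table(noname)
  expect_equal(db$english_name, "")
  expect_equal(db$name_tokens[[1]], character(0))

  expect_equal(nrow(load_composition_table(write_lines_tsv(header))), 0)

  dup <- write_lines_tsv(c(header,
    "A\tx\tG01\t\t\t1\t1\t1\t1\t1", "A\ty\tG01\t\t\t1\t1\t1\t1\t1"))
  expect_error(load_composition_table(dup), class = "fm_validation_error")

  bad <- write_lines_tsv(c(header,
    "A\tx\tG01\t\t\t1\t1\t1\t1\t1", "B\ty\tG01\t\t\tabc\t1\t1\t1\t1"))
  err <- expect_error(load_composition_table(bad), class = "fm_validation_error")
  expect_match(conditionMessage(err), "2")
})

test_that("unknown LanguaL codes are flagged but retained", {
  v <- vocabulary("LanguaL", tibble::tibble(
    code = "B0001", label = "b", facet = "B", parents = list(character(0)),
    attributes = ""
  ))
  header <- paste("code", "english_name", "group", "subgroups",
                  "langual_terms", "CHO", "ENERC", "FAT", "PROT", "WATER",
                  sep = "\t")
  path <- write_lines_tsv(c(header, "A\tx\tG01\t\tB0001|ZZZ\t1\t1\t1\t1\t1"))
  expect_warning(db <- load_composition_table(path, v), "ZZZ")
  expect_equal(db$langual_terms[[1]], c("B0001", "ZZZ"))
})

test_that("consumption tables load with system validation", {
  header <- paste("id", "english_name", "original_name", "group",
                  "subgroups", "descriptors", "system", sep = "\t")
  path <- write_lines_tsv(c(header,
    "Q1\tCourgette raw\tZucchini roh\tG02\t\t0499|0204|0309\tGloboDiet",
    "Q2\tMargarine\t\tA039D\t\tF10.A0B8M\tFoodEx2",
    "Q3\t\t\tG01\t\t\tGloboDiet"
  ))
  rec <- load_consumption_table(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$descriptors[[1]], c("0499", "0204", "0309"))
  expect_equal(rec$descriptors[[3]], character(0))
  expect_equal(rec$system[2], "FoodEx2")

  bad <- write_lines_tsv(c(header, "Q1\tx\t\tG02\t\t\tEpicSoft"))
  expect_error(load_consumption_table(bad), class = "fm_schema_error")
})

test_that("crosswalk loading: union semantics, identity merging, zero targets", {
  header <- "source_system\tsource_code\tlangual_codes\tprovenance"
  path <- write_lines_tsv(c(header,
    "GloboDiet\t0499\tJ0116\tcurated",
    "GloboDiet\t0499\tJ0117\tlearned"
  ))
  cw <- load_crosswalk(path)
  expect_equal(crosswalk_translate(cw, "GloboDiet", "0499"),
               c("J0116", "J0117"))
  # identity fallback for unmapped codes
  expect_equal(crosswalk_translate(cw, "GloboDiet", "0204"), "0204")
  expect_equal(crosswalk_translate(NULL, "GloboDiet", "0204"), "0204")

  # empty file: identity-only crosswalk
  cw0 <- load_crosswalk(write_lines_tsv(header))
  expect_equal(nrow(cw0$entries), 0)
  expect_equal(crosswalk_translate(cw0, "GloboDiet", "0499"), "0499")

  # implicit identity entries for codes shared with the LanguaL vocabulary
  lang <- vocabulary("LanguaL", tibble::tibble(
    code = c("0204", "J0116"), label = c("a", "b"), facet = "J",
    parents = list(character(0), character(0)), attributes = ""
  ))
  gd <- vocabulary("GloboDiet", tibble::tibble(
    code = c("0204", "0499"), label = c("a", "b"), facet = "F01",
    parents = list(character(0), character(0)), attributes = ""
  ))
  # J0117 is not in the tiny LanguaL vocabulary: flagged, retained
  expect_warning(
    cw1 <- load_crosswalk(path, langual_vocab = lang,
                          source_vocabs = list(GloboDiet = gd)),
    "J0117")
  ident <- cw1$entries[cw1$entries$provenance == "identity", ]
  expect_equal(ident$source_code, "0204")
  expect_equal(ident$langual_codes[[1]], "0204")

  bad <- write_lines_tsv(c(header, "GloboDiet\t0499\t\tcurated"))
  expect_error(load_crosswalk(bad), class = "fm_validation_error")
})

test_that("write_results orders rows by (query, level, rank)", {
  q <- courgette_query()
  db <- composition_table(list(
    pak_choi(), courgettes_raw(),
    composition_food("NL003", "Pumpkin raw", "G02", langual_terms = "0499")
  ))
  res <- search(q, db, search_settings(max_level = 3), query_id = "q1")
  path <- tempfile(fileext = ".tsv")
  write_results(res, path)
  out <- read.delim(path, colClasses = "character")
  expect_equal(names(out)[1:5],
               c("query_id", "rank", "level", "composition_code", "english_name"))
  expect_equal(out$level, sort(out$level))
  expect_equal(out$unmatched_units[out$level == "0"], "")

  # empty result set: header-only file
  empty <- res[0, ]
  path2 <- tempfile(fileext = ".tsv")
  write_results(empty, path2)
  expect_equal(nrow(read.delim(path2)), 0)
})

test_that("generated study tables round-trip through the loaders", {
  study <- generate_study(small_spec())
  d <- tempfile()
  write_study(study, d)
  lang <- load_vocabulary(file.path(d, "langual.tsv"), "LanguaL")
  expect_identical(lang$terms, study$vocabs$langual$terms)
  db <- load_composition_table(file.path(d, "composition.tsv"),
                               langual_vocab = lang)
  expect_identical(as.data.frame(db), as.data.frame(study$db))
  cons <- load_consumption_table(file.path(d, "consumption.tsv"))
  expect_identical(as.data.frame(cons), as.data.frame(study$consumption))
  cw <- load_crosswalk(file.path(d, "crosswalk.tsv"), langual_vocab = lang)
  expect_identical(cw$entries, study$vocabs$crosswalk$entries)
})
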