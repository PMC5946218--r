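## synthetic: deterministic generators for vocabularies, composition
## databases, queries with planted match levels and simulated expert
## judgments.  The generators make every other module testable without
## external data: per-descriptor crosswalk blocks are pairwise disjoint,
## so each query perturbation flips exactly one attribute unit and the
## planted level is exact by construction.

langual_facet_letters <- c("B", "C", "E", "F", "G", "H", "J", "K", "N", "P",
                           "R", "T")

#' Specification for a synthetic matching study
#'
#' Defaults describe the study conditions the package is exercised
#' under: a composition database at the scale of the smallest national
#' table used in practice (~800 foods), a test set of 45 queries with
#' match levels 0-4 planted evenly, and realistic data pathologies
#' (a tenth of composition records missing their English name, a
#' twentieth missing their group).
#'
#' @param seed Integer random seed; fully determines all generated data.
#' @param n_facets Number of descriptor facets per system (<= 12).
#' @param n_terms_per_facet Descriptors per facet.
#' @param n_groups Number of food groups.
#' @param n_subgroups_per_group Subgroups per group.
#' @param n_composition Composition records to generate.
#' @param n_queries Number of queries; must equal `sum(planted_levels)`.
#' @param planted_levels Named integer vector: target count of queries
#'   per planted level (names are levels `"0"`, `"1"`, ...).
#' @param name_vocabulary_size Size of the synthetic food-name lexicon.
#' @param missing_name_fraction Fraction of composition records with an
#'   empty English name.
#' @param missing_group_fraction Fraction with an empty group.
#' @param crosswalk_fanout LanguaL terms per source descriptor.
#' @param n_poly_parents Number of LanguaL terms given a second parent.
#' @param descriptors_per_record Inclusive range (length 2) of
#'   descriptors drawn per composition record.
#' @return An `fm_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 20180330L,
                           n_facets = 3L,
                           n_terms_per_facet = 8L,
                           n_groups = 6L,
                           n_subgroups_per_group = 3L,
                           n_composition = 800L,
                           n_queries = 45L,
                           planted_levels = c("0" = 9L, "1" = 9L, "2" = 9L,
                                              "3" = 9L, "4" = 9L),
                           name_vocabulary_size = 60L,
                           missing_name_fraction = 0.1,
                           missing_group_fraction = 0.05,
                           crosswalk_fanout = 2L,
                           n_poly_parents = 1L,
                           descriptors_per_record = c(3L, 6L)) {
  spec <- list(
    seed = as.integer(seed), n_facets = as.integer(n_facets),
    n_terms_per_facet = as.integer(n_terms_per_facet),
    n_groups = as.integer(n_groups),
    n_subgroups_per_group = as.integer(n_subgroups_per_group),
    n_composition = as.integer(n_composition),
    n_queries = as.integer(n_queries),
    planted_levels = stats::setNames(as.integer(planted_levels),
                                     names(planted_levels)),
    name_vocabulary_size = as.integer(name_vocabulary_size),
    missing_name_fraction = missing_name_fraction,
    missing_group_fraction = missing_group_fraction,
    crosswalk_fanout = as.integer(crosswalk_fanout),
    n_poly_parents = as.integer(n_poly_parents),
    descriptors_per_record = as.integer(descriptors_per_record)
  )
  counts <- unlist(spec[c("n_facets", "n_terms_per_facet", "n_groups",
                          "n_subgroups_per_group", "n_composition",
                          "n_queries", "name_vocabulary_size",
                          "crosswalk_fanout", "n_poly_parents")])
  if (any(counts < 0)) {
    fm_stop("fm_spec_error", "synthetic spec counts must be >= 0")
  }
  fracs <- c(spec$missing_name_fraction, spec$missing_group_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    fm_stop("fm_spec_error", "synthetic spec fractions must lie in [0, 1]")
  }
  if (spec$n_facets > length(langual_facet_letters)) {
    fm_stop("fm_spec_error", sprintf("n_facets must be <= %d",
                                     length(langual_facet_letters)))
  }
  if (spec$n_composition > 0 && spec$n_facets * spec$n_terms_per_facet == 0) {
    fm_stop("fm_spec_error",
            "composition records requested but no descriptor terms specified")
  }
  if (length(spec$planted_levels) > 0 && is.null(names(spec$planted_levels))) {
    fm_stop("fm_spec_error", "planted_levels must be named by level")
  }
  if (sum(spec$planted_levels) != spec$n_queries) {
    fm_stop("fm_spec_error", "planted_levels counts must sum to n_queries")
  }
  if (length(spec$descriptors_per_record) != 2 ||
      spec$descriptors_per_record[1] > spec$descriptors_per_record[2]) {
    fm_stop("fm_spec_error", "descriptors_per_record must be an increasing pair")
  }
  structure(spec, class = "fm_synthetic_spec")
}

## Pronounceable pseudowords for the food-name lexicon.
synthetic_words <- function(n) {
  syl <- c("ba", "ce", "do", "fi", "gu", "ka", "lo", "mi", "nu", "pa",
           "re", "si", "ta", "vo", "zu", "che", "pla", "tri", "sko", "mur")
  words <- character(0)
  while (length(words) < n) {
    w <- paste(sample(syl, sample(2:3, 1), replace = TRUE), collapse = "")
    words <- unique(c(words, w))
  }
  words[seq_len(n)]
}

gd_descriptor_code <- function(f, t) sprintf("%02d%02d", f, t)
fx_descriptor_code <- function(f, t) sprintf("F%02d.A%02d%02dM", f, f, t)

## LanguaL term block translated from descriptor (f, t).
langual_block <- function(f, t, fanout) {
  sprintf("%s%04d", langual_facet_letters[f], (t - 1L) * fanout + seq_len(fanout))
}

#' Generate vocabularies and a crosswalk
#'
#' Builds a LanguaL vocabulary (facet roots plus `crosswalk_fanout`
#' terms per source descriptor, with `n_poly_parents` terms carrying a
#' second parent), GloboDiet and FoodEx2 vocabularies (groups,
#' subgroups, facet descriptors in a shallow hierarchy), and a curated
#' crosswalk mapping every source descriptor to its disjoint LanguaL
#' block.
#'
#' @param spec An `fm_synthetic_spec`.
#' @return A list with elements `langual`, `globodiet`, `foodex2`
#'   (each `fm_vocabulary`) and `crosswalk` (`fm_crosswalk`).
#' @export
generate_vocabulary <- function(spec) {
  stopifnot(inherits(spec, "fm_synthetic_spec"))
  if (spec$n_poly_parents > 0 && spec$n_facets < 2) {
    fm_stop("fm_spec_error", "poly-parent terms require at least 2 facets")
  }
  nf <- spec$n_facets; nt <- spec$n_terms_per_facet
  fanout <- spec$crosswalk_fanout

  ## LanguaL: roots + blocks.
  lang_rows <- list()
  for (f in seq_len(nf)) {
    letter <- langual_facet_letters[f]
    root <- sprintf("%s0000", letter)
    lang_rows[[length(lang_rows) + 1L]] <- tibble::tibble(
      code = root, label = sprintf("facet %s root", letter),
      facet = letter, parents = list(character(0)), attributes = "hierarchy"
    )
    for (t in seq_len(nt)) {
      for (code in langual_block(f, t, fanout)) {
        lang_rows[[length(lang_rows) + 1L]] <- tibble::tibble(
          code = code, label = sprintf("term %s", code), facet = letter,
          parents = list(root), attributes = "core"
        )
      }
    }
  }
  lang <- do.call(rbind, lang_rows)
  ## Poly-hierarchy: give the first n_poly_parents non-root terms a
  ## second parent in the next facet.
  if (spec$n_poly_parents > 0 && nt > 0) {
    non_root <- which(!grepl("0000$", lang$code))[seq_len(spec$n_poly_parents)]
    for (i in non_root) {
      f <- match(lang$facet[i], langual_facet_letters)
      other_root <- sprintf("%s0000", langual_facet_letters[(f %% nf) + 1L])
      lang$parents[[i]] <- c(lang$parents[[i]], other_root)
    }
  }
  langual <- vocabulary("LanguaL", lang)

  ## Source-system vocabularies: groups, subgroups, descriptors.
  make_source <- function(system, group_code, sub_code, desc_code) {
    rows <- list()
    for (g in seq_len(spec$n_groups)) {
      gc <- group_code(g)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        code = gc, label = sprintf("group %s", gc), facet = "",
        parents = list(character(0)), attributes = "hierarchy"
      )
      for (s in seq_len(spec$n_subgroups_per_group)) {
        sc <- sub_code(gc, s)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          code = sc, label = sprintf("subgroup %s", sc), facet = "",
          parents = list(gc), attributes = "hierarchy"
        )
      }
    }
    for (f in seq_len(nf)) {
      first <- desc_code(f, 1L)
      for (t in seq_len(nt)) {
        code <- desc_code(f, t)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          code = code, label = sprintf("descriptor %s", code),
          facet = sprintf("F%02d", f),
          parents = list(if (t == 1L) character(0) else first),
          attributes = "core"
        )
      }
    }
    vocabulary(system, do.call(rbind, rows))
  }
  globodiet <- make_source("GloboDiet",
    function(g) sprintf("G%02d", g),
    function(gc, s) sprintf("%s.%d", gc, s),
    gd_descriptor_code)
  foodex2 <- make_source("FoodEx2",
    function(g) sprintf("A%03dD", g),
    function(gc, s) sprintf("%s.%d", gc, s),
    fx_descriptor_code)

  cw_rows <- list()
  for (f in seq_len(nf)) {
    for (t in seq_len(nt)) {
      block <- langual_block(f, t, fanout)
      cw_rows[[length(cw_rows) + 1L]] <- tibble::tibble(
        source_system = "GloboDiet", source_code = gd_descriptor_code(f, t),
        langual_codes = list(block), provenance = "curated"
      )
      cw_rows[[length(cw_rows) + 1L]] <- tibble::tibble(
        source_system = "FoodEx2", source_code = fx_descriptor_code(f, t),
        langual_codes = list(block), provenance = "curated"
      )
    }
  }
  cw <- crosswalk(if (length(cw_rows) > 0) do.call(rbind, cw_rows) else NULL)

  list(langual = langual, globodiet = globodiet, foodex2 = foodex2,
       crosswalk = cw)
}

## term -> GloboDiet descriptor lookup over the disjoint blocks.
term_to_descriptor <- function(spec) {
  out <- character(0)
  for (f in seq_len(spec$n_facets)) {
    for (t in seq_len(spec$n_terms_per_facet)) {
      block <- langual_block(f, t, spec$crosswalk_fanout)
      out[block] <- gd_descriptor_code(f, t)
    }
  }
  out
}

#' Generate a synthetic food composition database
#'
#' Records carry names drawn from the synthetic lexicon (a stated
#' fraction empty), a group and sometimes a subgroup (a stated fraction
#' of groups empty), LanguaL terms sampled from the crosswalk blocks of
#' 3-6 source descriptors, and nutrient values in plausible ranges
#' (g/100 g edible portion; ENERC 0-4000 kJ/100 g), occasionally
#' missing.
#'
#' @param spec An `fm_synthetic_spec`.
#' @param vocabs Output of [generate_vocabulary()].
#' @return An `fm_composition` tibble with `spec$n_composition` rows.
#' @export
generate_composition_db <- function(spec, vocabs) {
  stopifnot(inherits(spec, "fm_synthetic_spec"))
  n <- spec$n_composition
  all_desc <- as.character(outer(
    seq_len(spec$n_facets), seq_len(spec$n_terms_per_facet), gd_descriptor_code
  ))
  groups <- sprintf("G%02d", seq_len(spec$n_groups))
  with_seed(spec$seed + 1L, {
    words <- synthetic_words(spec$name_vocabulary_size)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nd <- sample(spec$descriptors_per_record[1]:spec$descriptors_per_record[2], 1)
      own <- sample(all_desc, min(nd, length(all_desc)))
      terms <- unlist(lapply(own, function(d) {
        f <- as.integer(substr(d, 1, 2)); t <- as.integer(substr(d, 3, 4))
        block <- langual_block(f, t, spec$crosswalk_fanout)
        sample(block, sample(seq_along(block), 1))
      }))
      name <- if (stats::runif(1) < spec$missing_name_fraction) "" else
        paste(sample(words, sample(1:3, 1)), collapse = " ")
      group <- if (stats::runif(1) < spec$missing_group_fraction) "" else
        sample(groups, 1)
      subgroups <- if (nzchar(group) && stats::runif(1) < 0.5) {
        sprintf("%s.%d", group, sample(seq_len(spec$n_subgroups_per_group), 1))
      } else character(0)
      nv <- c(CHO = stats::runif(1, 0, 80), ENERC = stats::runif(1, 0, 4000),
              FAT = stats::runif(1, 0, 60), PROT = stats::runif(1, 0, 40),
              WATER = stats::runif(1, 0, 95))
      nv <- round(nv, 1)
      nv[stats::runif(5) < 0.05] <- NA_real_
      rows[[i]] <- tibble::tibble(
        code = sprintf("C%04d", i), english_name = name,
        name_tokens = list(normalize_tokens(name)), group = group,
        subgroups = list(subgroups), langual_terms = list(sort(unique(terms))),
        CHO = nv[["CHO"]], ENERC = nv[["ENERC"]], FAT = nv[["FAT"]],
        PROT = nv[["PROT"]], WATER = nv[["WATER"]]
      )
    }
    out <- if (n > 0) do.call(rbind, rows) else composition_food("x")[0, ]
    class(out) <- c("fm_composition", class(out))
    validate_composition(out)
    out
  })
}

#' Generate a query with a planted match level
#'
#' Picks a base composition record carrying a name, group and at least
#' one descriptor, builds its exact query (level 0 against the record),
#' then perturbs exactly `k` attribute units on the query side: replace
#' the name tokens with a token the record lacks, switch the group code,
#' and/or add foreign descriptors whose crosswalk blocks are disjoint
#' from the record's terms.  Each perturbation flips exactly one unit,
#' so the base record's true level for the returned query is exactly
#' `k`.
#'
#' @param spec An `fm_synthetic_spec`.
#' @param db Composition database from [generate_composition_db()].
#' @param k Target level (>= 0).
#' @param vocabs Output of [generate_vocabulary()].
#' @param index Query index used to diversify the derived seed.
#' @return A list with `query` (`fm_query`), `planted_code` and `level`.
#' @export
generate_query_with_planted_level <- function(spec, db, k, vocabs, index = 0L) {
  stopifnot(inherits(spec, "fm_synthetic_spec"), k >= 0)
  t2d <- term_to_descriptor(spec)
  all_desc <- unique(unname(t2d))
  groups <- sprintf("G%02d", seq_len(spec$n_groups))
  eligible <- which(
    nzchar(db$english_name) & nzchar(db$group) &
      vapply(db$langual_terms, length, integer(1)) > 0
  )
  if (length(eligible) == 0) {
    fm_stop("fm_spec_error", "no eligible base record for query planting")
  }
  with_seed(spec$seed + 101L + 977L * as.integer(index) + as.integer(k), {
    base <- eligible[sample.int(length(eligible), 1)]
    own <- sort(unique(unname(t2d[db$langual_terms[[base]]])))
    foreign_pool <- setdiff(all_desc, own)
    ## Split the k perturbations between name/group and foreign
    ## descriptors; foreign descriptors absorb whatever remains.
    max_ng <- min(2L, k)
    n_ng <- if (k == 0) 0L else sample(0:max_ng, 1)
    if (k - n_ng > length(foreign_pool)) n_ng <- max_ng
    if (k - n_ng > length(foreign_pool)) {
      fm_stop("fm_spec_error", sprintf(
        "planted level %d exceeds available attribute units", k
      ))
    }
    ng_kinds <- if (n_ng > 0) sample(c("name", "group"), n_ng) else character(0)
    foreign <- if (k - n_ng > 0) sample(foreign_pool, k - n_ng) else character(0)

    tokens <- db$name_tokens[[base]]
    group <- db$group[[base]]
    if ("name" %in% ng_kinds) tokens <- sprintf("unmatched%04d", as.integer(index))
    if ("group" %in% ng_kinds) group <- sample(setdiff(groups, group), 1)

    list(
      query = match_query(tokens, group, db$subgroups[[base]],
                          sort(c(own, foreign)), "GloboDiet"),
      planted_code = db$code[[base]],
      level = as.integer(k)
    )
  })
}

#' Generate a complete synthetic matching study
#'
#' @param spec An `fm_synthetic_spec`.
#' @return A list with `spec`, `vocabs`, `db` (composition table),
#'   `consumption` (the queries as an `fm_consumption` table),
#'   `queries` (list of `fm_query`) and `manifest` (seed, spec and the
#'   planted ground truth: query id, planted code, planted level).
#' @export
generate_study <- function(spec = synthetic_spec()) {
  vocabs <- generate_vocabulary(spec)
  db <- generate_composition_db(spec, vocabs)
  levels <- rep(as.integer(names(spec$planted_levels)), spec$planted_levels)
  queries <- vector("list", length(levels))
  cons_rows <- vector("list", length(levels))
  planted <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    g <- generate_query_with_planted_level(spec, db, levels[i], vocabs,
                                           index = i - 1L)
    queries[[i]] <- g$query
    id <- sprintf("Q%04d", i)
    cons_rows[[i]] <- tibble::tibble(
      id = id,
      english_name = paste(g$query$name_tokens, collapse = " "),
      original_name = "",
      group = g$query$group,
      subgroups = list(g$query$subgroups),
      descriptors = list(g$query$descriptors),
      system = g$query$system
    )
    planted[[i]] <- tibble::tibble(id = id, planted_code = g$planted_code,
                                   level = g$level)
  }
  consumption <- do.call(rbind, cons_rows)
  class(consumption) <- c("fm_consumption", class(consumption))
  list(
    spec = spec, vocabs = vocabs, db = db, consumption = consumption,
    queries = queries,
    manifest = list(
      seed = spec$seed,
      spec = unclass(spec),
      planted = do.call(rbind, planted)
    )
  )
}

#' Write a synthetic study to disk
#'
#' Emits every interchange file (`langual.tsv`, `globodiet.tsv`,
#' `foodex2.tsv`, `crosswalk.tsv`, `composition.tsv`,
#' `consumption.tsv`), a `manifest.json` recording seed, spec and
#' planted ground truth, and a `config.yaml` run configuration pointing
#' at the files.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_vocabulary(study$vocabs$langual, p("langual.tsv"))
  write_vocabulary(study$vocabs$globodiet, p("globodiet.tsv"))
  write_vocabulary(study$vocabs$foodex2, p("foodex2.tsv"))
  write_crosswalk(study$vocabs$crosswalk, p("crosswalk.tsv"))
  write_composition_table(study$db, p("composition.tsv"))
  write_consumption_table(study$consumption, p("consumption.tsv"))
  manifest <- study$manifest
  manifest$planted <- as.data.frame(manifest$planted)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  yaml::write_yaml(list(
    langual_vocab = "langual.tsv", globodiet_vocab = "globodiet.tsv",
    foodex2_vocab = "foodex2.tsv", crosswalk = "crosswalk.tsv",
    composition = "composition.tsv", consumption = "consumption.tsv",
    knowledge_store = "knowledge.jsonl",
    settings = list(max_level = 2, max_per_level = 50,
                    hierarchical_group = FALSE),
    mask = list(use_names = TRUE, use_group = TRUE, use_subgroups = TRUE,
                use_descriptors = TRUE)
  ), p("config.yaml"))
  invisible(dir)
}

#' Simulate expert judgments over search results
#'
#' The simulated expert selects each query's top-ranked candidate and
#' grades it `good` when it matched every unit (level 0), `sufficient`
#' when the only unmatched units are the name or individual descriptors
#' (the group and subgroups held), and `poor` otherwise.  The planted
#' record serves as the manual match, so agreement statistics are
#' computable.  Deterministic: no randomness is involved.
#'
#' @param spec An `fm_synthetic_spec`.
#' @param study Output of [generate_study()].
#' @param results Combined `fm_results` over the study's queries, with
#'   `query_id` matching the consumption ids.
#' @return An `fm_judged` tibble.
#' @export
generate_judgments <- function(spec, study, results) {
  planted <- study$manifest$planted
  rows <- lapply(seq_len(nrow(study$consumption)), function(i) {
    id <- study$consumption$id[i]
    sub <- results[results$query_id == id, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(
        query_id = id, selected_code = "none available",
        tool_level = NA_integer_, quality = NA_character_,
        manual_code = planted$planted_code[planted$id == id],
        country_label = "synthetic"
      ))
    }
    top <- sub[order(sub$level, sub$rank), , drop = FALSE][1, ]
    kinds <- top$unmatched_units[[1]]$kind
    quality <- if (top$level == 0) "good"
      else if (all(kinds %in% c("name", "descriptor"))) "sufficient"
      else "poor"
    tibble::tibble(
      query_id = id, selected_code = top$code, tool_level = top$level,
      quality = quality,
      manual_code = planted$planted_code[planted$id == id],
      country_label = "synthetic"
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fm_judged", class(out))
  out
}
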