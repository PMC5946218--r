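## matcher: leveled matching of a query against composition records.
##
## A query decomposes into attribute units: one name unit (matched when
## at least one normalized token is shared), one group unit (exact code
## equality, optionally hierarchical), one unit per subgroup code, and
## one unit per facet descriptor (matched when any of the descriptor's
## crosswalk-translated LanguaL terms occurs among the candidate's
## terms).  A candidate's match level is the number of units it fails:
## level 0 is a perfect match, level 1 misses one unit, and so on; the
## number of levels is unbounded and depends only on how many attributes
## the query carries.  Attributes absent from the query contribute no
## unit and are simply not considered.

#' Search settings
#'
#' @param max_level Highest level reported (default 2; higher levels are
#'   counted but not listed, mirroring how result screens cut off).
#' @param max_per_level Cap on candidates listed per level (default 50;
#'   longer option lists are burdensome for the expert, and the
#'   per-level totals are still reported).
#' @param crosswalk An `fm_crosswalk` translating source descriptors to
#'   LanguaL terms; `NULL` means identity translation.
#' @param mask An `fm_mask` restricting which attribute groups form
#'   units.
#' @param hierarchical_group If `TRUE`, the group unit also matches when
#'   query and candidate groups are ancestor/descendant in
#'   `group_vocab`; off by default (exact code equality).
#' @param group_vocab Vocabulary used for hierarchical group matching.
#' @return An `fm_settings`.
#' @export
search_settings <- function(max_level = 2L, max_per_level = 50L,
                            crosswalk = NULL, mask = attribute_mask(),
                            hierarchical_group = FALSE, group_vocab = NULL) {
  stopifnot(max_level >= 0, max_per_level >= 1)
  structure(
    list(max_level = as.integer(max_level),
         max_per_level = as.integer(max_per_level),
         crosswalk = crosswalk, mask = mask,
         hierarchical_group = isTRUE(hierarchical_group),
         group_vocab = group_vocab),
    class = "fm_settings"
  )
}

## Internal unit list: each unit is list(kind, value, translated).
build_units <- function(query, settings) {
  mask <- settings$mask
  units <- list()
  if (length(query$name_tokens) > 0 && isTRUE(mask$use_names)) {
    units[[length(units) + 1L]] <- list(
      kind = "name", value = paste(query$name_tokens, collapse = " "),
      translated = query$name_tokens
    )
  }
  if (nzchar(query$group) && isTRUE(mask$use_group)) {
    units[[length(units) + 1L]] <- list(
      kind = "group", value = query$group, translated = query$group
    )
  }
  if (isTRUE(mask$use_subgroups)) {
    for (sg in query$subgroups) {
      units[[length(units) + 1L]] <- list(
        kind = "subgroup", value = sg, translated = sg
      )
    }
  }
  if (isTRUE(mask$use_descriptors)) {
    for (d in sort(query$descriptors)) {
      units[[length(units) + 1L]] <- list(
        kind = "descriptor", value = d,
        translated = crosswalk_translate(settings$crosswalk, query$system, d)
      )
    }
  }
  units
}

units_as_tibble <- function(units) {
  tibble::tibble(
    kind = vapply(units, `[[`, character(1), "kind"),
    value = vapply(units, `[[`, character(1), "value"),
    translated = lapply(units, `[[`, "translated")
  )
}

#' Decompose a query into attribute units
#'
#' @param query An `fm_query`.
#' @param settings An `fm_settings`; the mask selects units and the
#'   crosswalk supplies descriptor translations.
#' @return A tibble with one row per unit: `kind` (`name`, `group`,
#'   `subgroup` or `descriptor`), `value` (the query-side token set or
#'   code) and `translated` (list column; for descriptors, the LanguaL
#'   target set).
#' @export
attribute_units <- function(query, settings = search_settings()) {
  units_as_tibble(build_units(query, settings))
}

## Normalize a candidate (one-row fm_composition tibble or plain list)
## to a flat list of fields.
as_candidate <- function(candidate) {
  if (tibble::is_tibble(candidate) || is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1)
    list(
      code = candidate$code[[1]], english_name = candidate$english_name[[1]],
      name_tokens = candidate$name_tokens[[1]], group = candidate$group[[1]],
      subgroups = candidate$subgroups[[1]],
      langual_terms = candidate$langual_terms[[1]],
      CHO = candidate$CHO[[1]], ENERC = candidate$ENERC[[1]],
      FAT = candidate$FAT[[1]], PROT = candidate$PROT[[1]],
      WATER = candidate$WATER[[1]]
    )
  } else {
    candidate
  }
}

group_unit_matches <- function(q_group, cand_group, settings) {
  if (!nzchar(cand_group %||% "")) return(FALSE)
  if (identical(q_group, cand_group)) return(TRUE)
  if (settings$hierarchical_group && !is.null(settings$group_vocab)) {
    v <- settings$group_vocab
    return(q_group %in% vocab_ancestors(v, cand_group) ||
           cand_group %in% vocab_ancestors(v, q_group))
  }
  FALSE
}

unit_matches_one <- function(unit, cand, settings) {
  switch(unit$kind,
    name = length(intersect(unit$translated, cand$name_tokens)) > 0,
    group = group_unit_matches(unit$value, cand$group, settings),
    subgroup = unit$value %in% cand$subgroups,
    descriptor = any(unit$translated %in% cand$langual_terms),
    stop("unknown unit kind: ", unit$kind)
  )
}

#' Does a single attribute unit match a candidate?
#'
#' @param unit One row of [attribute_units()] output (or an equivalent
#'   list with `kind`, `value`, `translated`).
#' @param candidate A composition record (one-row `fm_composition` or
#'   list).
#' @param settings An `fm_settings`.
#' @return `TRUE` or `FALSE`.  A name unit matches when at least one
#'   token is shared; a group unit on code equality (or hierarchy when
#'   enabled); a subgroup unit when the code appears among the
#'   candidate's subgroups; a descriptor unit when any translated
#'   LanguaL term appears among the candidate's terms.
#' @export
unit_matches <- function(unit, candidate, settings = search_settings()) {
  if (tibble::is_tibble(unit) || is.data.frame(unit)) {
    stopifnot(nrow(unit) == 1)
    unit <- list(kind = unit$kind[[1]], value = unit$value[[1]],
                 translated = unit$translated[[1]])
  }
  unit_matches_one(unit, as_candidate(candidate), settings)
}

#' Match level of one candidate for a query
#'
#' @param query An `fm_query`.
#' @param candidate A composition record.
#' @param settings An `fm_settings`.
#' @return An `fm_match`: a list with `level` (count of failing units),
#'   `matched_units` and `unmatched_units` (tibbles partitioning the
#'   query's attribute units) and `name_overlap` (number of shared name
#'   tokens).
#' @export
match_level <- function(query, candidate, settings = search_settings()) {
  units <- build_units(query, settings)
  if (length(units) == 0) {
    fm_stop("fm_empty_query_error", "query has no attribute units after masking")
  }
  cand <- as_candidate(candidate)
  ok <- vapply(units, unit_matches_one, logical(1), cand = cand,
               settings = settings)
  utbl <- units_as_tibble(units)
  structure(
    list(
      code = cand$code,
      level = sum(!ok),
      matched_units = utbl[ok, , drop = FALSE],
      unmatched_units = utbl[!ok, , drop = FALSE],
      name_overlap = length(intersect(query$name_tokens, cand$name_tokens))
    ),
    class = "fm_match"
  )
}

#' @export
print.fm_match <- function(x, ...) {
  cat(sprintf("<match: %s at level %d (%d unmatched unit(s), name overlap %d)>\n",
              x$code, x$level, nrow(x$unmatched_units), x$name_overlap))
  invisible(x)
}

## Shared result formatting: keep candidates at level <= max_level,
## order by (level, -name_overlap, code), cap per level, attach unit
## breakdowns.  Level computation (the contract under test) happens
## before this in either the indexed or the brute-force path.
assemble_results <- function(db, units, level, overlap, matched_for,
                             settings, query_id) {
  keep <- which(level <= settings$max_level)
  totals <- table(factor(level[keep], levels = sort(unique(level[keep]))))
  ord <- keep[order(level[keep], -overlap[keep], db$code[keep])]
  rank_in_level <- if (length(ord) > 0) {
    stats::ave(seq_along(ord), level[ord], FUN = seq_along)
  } else integer(0)
  sel <- ord[rank_in_level <= settings$max_per_level]
  ranks <- rank_in_level[rank_in_level <= settings$max_per_level]

  utbl <- units_as_tibble(units)
  breakdowns <- lapply(sel, function(i) {
    ok <- matched_for(i)
    list(matched = utbl[ok, , drop = FALSE],
         unmatched = utbl[!ok, , drop = FALSE])
  })
  out <- tibble::tibble(
    query_id = rep(query_id, length(sel)),
    level = as.integer(level[sel]),
    rank = as.integer(ranks),
    code = db$code[sel],
    english_name = db$english_name[sel],
    name_overlap = as.integer(overlap[sel]),
    CHO = db$CHO[sel], ENERC = db$ENERC[sel], FAT = db$FAT[sel],
    PROT = db$PROT[sel], WATER = db$WATER[sel],
    matched_units = lapply(breakdowns, `[[`, "matched"),
    unmatched_units = lapply(breakdowns, `[[`, "unmatched")
  )
  attr(out, "level_totals") <- stats::setNames(as.integer(totals), names(totals))
  attr(out, "n_candidates") <- nrow(db)
  attr(out, "n_units") <- length(units)
  class(out) <- c("fm_results", class(out))
  out
}

#' Search a composition database for leveled matches
#'
#' Computes the match level of every record against the query using
#' vectorized per-unit passes over the database, then groups candidates
#' by ascending level.  Within a level, candidates are ranked by
#' descending shared-name-token count, then ascending composition code;
#' co-equal candidates stay co-equal and the choice among them belongs
#' to the human expert.
#'
#' @param query An `fm_query`.
#' @param db An `fm_composition` tibble.
#' @param settings An `fm_settings`.
#' @param query_id Identifier carried into the result rows.
#' @return An `fm_results` tibble (one row per listed candidate, ordered
#'   by `(level, rank)`), with attributes `level_totals` (candidate
#'   counts per level before the per-level cap), `n_candidates` and
#'   `n_units`.
#' @export
search <- function(query, db, settings = search_settings(),
                   query_id = NA_character_) {
  units <- build_units(query, settings)
  if (length(units) == 0) {
    fm_stop("fm_empty_query_error", "query has no attribute units after masking")
  }
  n <- nrow(db)
  if (n == 0) {
    warning("composition database is empty; no candidates to rank", call. = FALSE)
    return(assemble_results(db, units, integer(0), integer(0),
                            function(i) logical(0), settings, query_id))
  }
  ## One vectorized pass per unit.
  M <- matrix(FALSE, nrow = length(units), ncol = n)
  for (u in seq_along(units)) {
    unit <- units[[u]]
    M[u, ] <- switch(unit$kind,
      name = vapply(db$name_tokens, function(t)
        length(intersect(unit$translated, t)) > 0, logical(1)),
      group = if (settings$hierarchical_group && !is.null(settings$group_vocab)) {
        vapply(db$group, group_unit_matches, logical(1),
               q_group = unit$value, settings = settings)
      } else db$group == unit$value,
      subgroup = vapply(db$subgroups, function(s) unit$value %in% s, logical(1)),
      descriptor = vapply(db$langual_terms, function(t)
        any(unit$translated %in% t), logical(1))
    )
  }
  level <- length(units) - colSums(M)
  overlap <- if (length(query$name_tokens) > 0) {
    vapply(db$name_tokens, function(t)
      length(intersect(query$name_tokens, t)), integer(1))
  } else integer(n)
  assemble_results(db, units, level, overlap, function(i) M[, i],
                   settings, query_id)
}

#' Brute-force reference search
#'
#' Naive full scan: computes [match_level()] for every record with an
#' independent per-candidate loop, then applies the same grouping
#' contract as [search()].  This is the reference implementation that
#' [search()] must reproduce exactly; it exists as a test oracle and for
#' auditing individual levels.
#'
#' @inheritParams search
#' @return An `fm_results` tibble identical in contract to [search()].
#' @export
brute_force_search <- function(query, db, settings = search_settings(),
                               query_id = NA_character_) {
  units <- build_units(query, settings)
  if (length(units) == 0) {
    fm_stop("fm_empty_query_error", "query has no attribute units after masking")
  }
  n <- nrow(db)
  if (n == 0) {
    warning("composition database is empty; no candidates to rank", call. = FALSE)
    return(assemble_results(db, units, integer(0), integer(0),
                            function(i) logical(0), settings, query_id))
  }
  cands <- lapply(seq_len(n), function(i) list(
    code = db$code[[i]], name_tokens = db$name_tokens[[i]],
    group = db$group[[i]], subgroups = db$subgroups[[i]],
    langual_terms = db$langual_terms[[i]]
  ))
  oks <- lapply(cands, function(cand)
    vapply(units, unit_matches_one, logical(1), cand = cand, settings = settings))
  level <- vapply(oks, function(ok) sum(!ok), integer(1))
  overlap <- vapply(cands, function(cand)
    length(intersect(query$name_tokens, cand$name_tokens)), integer(1))
  assemble_results(db, units, level, overlap, function(i) oks[[i]],
                   settings, query_id)
}

#' @export
print.fm_results <- function(x, ...) {
  totals <- attr(x, "level_totals")
  cat(sprintf("<match results: %d candidate(s) listed over %d level(s); %d in db>\n",
              nrow(x), length(totals), attr(x, "n_candidates") %||% NA_integer_))
  if (length(totals) > 0) {
    cat("  per-level totals:",
        paste(sprintf("level %s: %d", names(totals), totals), collapse = ", "),
        "\n")
  }
  NextMethod()
}
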