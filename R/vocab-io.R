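## vocab_io: loaders, validators and writers for the delimited-text
## interchange formats.  All tables are UTF-8 TSV with a header row;
## multi-valued cells are pipe-separated; codes are case-sensitive.

#' Construct a vocabulary
#'
#' A vocabulary is a validated, poly-hierarchical code list for one food
#' description system (LanguaL, FoodEx2 or GloboDiet): facet terms,
#' group codes and their broader-term relations.
#'
#' @param system One of `"LanguaL"`, `"FoodEx2"`, `"GloboDiet"`.
#' @param terms A data frame with columns `code`, `label`, `facet`
#'   (empty string for group codes), `parents` (character vector per
#'   term, or a pipe-separated string column) and `attributes`
#'   (free-form flags such as `hierarchy`, `core`, `raw`).
#' @return An object of class `fm_vocabulary` with the term table
#'   (sorted by code), a facet index (facet id -> term codes) and the
#'   system tag.
#' @details Validation enforces unique codes, parent references that
#'   resolve within the vocabulary (unresolved parents are reported as a
#'   warning and kept), and an acyclic broader-term relation.  A term
#'   may have several parents: both LanguaL and FoodEx2 allow a concept
#'   to sit under more than one broader term.
#' @export
vocabulary <- function(system, terms = NULL) {
  system <- match.arg(system, fm_systems)
  if (is.null(terms) || nrow(terms) == 0) {
    terms <- tibble::tibble(
      code = character(0), label = character(0), facet = character(0),
      parents = list(), attributes = character(0)
    )
  } else {
    terms <- tibble::as_tibble(terms)
    require_columns(terms, c("code", "label", "facet", "parents"), "vocabulary table")
    if (!is.list(terms$parents)) {
      terms$parents <- lapply(terms$parents, split_pipes)
    }
    if (is.null(terms$attributes)) terms$attributes <- ""
    terms$attributes[is.na(terms$attributes)] <- ""
    terms$facet[is.na(terms$facet)] <- ""
  }

  dup <- sort(unique(terms$code[duplicated(terms$code)]))
  if (length(dup) > 0) {
    fm_stop("fm_validation_error", sprintf(
      "duplicate code(s) in %s vocabulary: %s", system, paste(dup, collapse = ", ")
    ))
  }

  all_codes <- terms$code
  unresolved <- sort(unique(setdiff(unlist(terms$parents), all_codes)))
  if (length(unresolved) > 0) {
    warning(sprintf(
      "%s vocabulary: %d parent reference(s) do not resolve: %s",
      system, length(unresolved), paste(unresolved, collapse = ", ")
    ), call. = FALSE)
  }

  cyc <- detect_cycle(terms$code, terms$parents)
  if (!is.null(cyc)) {
    fm_stop("fm_validation_error", sprintf(
      "cycle in parent relation of %s vocabulary: %s",
      system, paste(cyc, collapse = " -> ")
    ))
  }

  ## Sort by code so the index is independent of input row order.
  terms <- terms[order(terms$code), , drop = FALSE]
  facet_index <- split(terms$code, terms$facet)
  facet_index <- facet_index[nzchar(names(facet_index))]

  structure(
    list(system = system, terms = terms, facet_index = facet_index,
         unresolved_parents = unresolved),
    class = "fm_vocabulary"
  )
}

## Depth-first search for a cycle in the parent relation; returns the
## cycle as a code path, or NULL.
detect_cycle <- function(codes, parents) {
  idx <- stats::setNames(seq_along(codes), codes)
  state <- integer(length(codes)) # 0 unseen, 1 on stack, 2 done
  path <- character(0)
  visit <- function(i) {
    if (state[i] == 1L) return(c(path, codes[i]))
    if (state[i] == 2L) return(NULL)
    state[i] <<- 1L
    path <<- c(path, codes[i])
    for (p in parents[[i]]) {
      j <- idx[p]
      if (!is.na(j)) {
        res <- visit(j)
        if (!is.null(res)) return(res)
      }
    }
    path <<- path[-length(path)]
    state[i] <<- 2L
    NULL
  }
  for (i in seq_along(codes)) {
    res <- visit(i)
    if (!is.null(res)) {
      first <- match(res[length(res)], res)
      return(res[first:length(res)])
    }
  }
  NULL
}

#' @export
print.fm_vocabulary <- function(x, ...) {
  cat(sprintf("<%s vocabulary: %d terms, %d facets>\n",
              x$system, nrow(x$terms), length(x$facet_index)))
  invisible(x)
}

#' Load a vocabulary from a TSV file
#'
#' @param path Path to a TSV file with columns `code`, `label`, `facet`,
#'   `parents` (pipe-separated) and `attributes`.
#' @param system System tag (`"LanguaL"`, `"FoodEx2"` or `"GloboDiet"`).
#' @return An `fm_vocabulary` (see [vocabulary()]).
#' @export
load_vocabulary <- function(path, system) {
  df <- read_tsv_strict(path)
  require_columns(df, c("code", "label", "facet", "parents", "attributes"),
                  sprintf("vocabulary file %s", path))
  vocabulary(system, df)
}

#' Write a vocabulary to TSV
#' @param vocab An `fm_vocabulary`.
#' @param path Output path.
#' @export
write_vocabulary <- function(vocab, path) {
  df <- vocab$terms
  out <- data.frame(
    code = df$code, label = df$label, facet = df$facet,
    parents = vapply(df$parents, join_pipes, character(1)),
    attributes = df$attributes, stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

vocab_has <- function(vocab, codes) codes %in% vocab$terms$code

## Ancestor closure of a code in the (poly-)hierarchy.
vocab_ancestors <- function(vocab, code) {
  parents <- stats::setNames(vocab$terms$parents, vocab$terms$code)
  seen <- character(0)
  frontier <- code
  while (length(frontier) > 0) {
    nxt <- unique(unlist(parents[intersect(frontier, names(parents))]))
    nxt <- setdiff(nxt, c(seen, code))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## -------------------------------------------------------------------
## Composition table

nutrient_names <- c("CHO", "ENERC", "FAT", "PROT", "WATER")

#' Construct a single composition record
#'
#' A composition record is one food from a food composition database:
#' a code, an English name (possibly empty), a classification group and
#' subgroups, the set of LanguaL facet terms indexing the food, and the
#' five basic nutrient values (g/100 g edible portion; ENERC in
#' kJ/100 g), any of which may be missing.
#'
#' @param code Database identifier (non-empty).
#' @param english_name English food name; may be `""`.
#' @param group Classification group code; may be `""`.
#' @param subgroups Character vector of subgroup codes, ordered.
#' @param langual_terms Character vector of LanguaL facet-term codes.
#' @param CHO,ENERC,FAT,PROT,WATER Nutrient values; `NA` if missing.
#' @return A one-row `fm_composition` tibble; bind rows to form a table.
#' @export
composition_food <- function(code, english_name = "", group = "",
                             subgroups = character(0),
                             langual_terms = character(0),
                             CHO = NA_real_, ENERC = NA_real_,
                             FAT = NA_real_, PROT = NA_real_,
                             WATER = NA_real_) {
  stopifnot(is.character(code), length(code) == 1, nzchar(code))
  out <- tibble::tibble(
    code = code, english_name = english_name,
    name_tokens = list(normalize_tokens(english_name)),
    group = group, subgroups = list(as.character(subgroups)),
    langual_terms = list(as.character(langual_terms)),
    CHO = as.numeric(CHO), ENERC = as.numeric(ENERC), FAT = as.numeric(FAT),
    PROT = as.numeric(PROT), WATER = as.numeric(WATER)
  )
  class(out) <- c("fm_composition", class(out))
  out
}

#' Bind composition records into a table
#' @param ... One-row `fm_composition` records (or lists thereof).
#' @return An `fm_composition` tibble.
#' @export
composition_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 1 && is.list(rows[[1]]) && !tibble::is_tibble(rows[[1]])) {
    rows <- rows[[1]]
  }
  out <- do.call(rbind, rows)
  class(out) <- unique(c("fm_composition", class(out)))
  out
}

validate_composition <- function(df, langual_vocab = NULL) {
  dup <- sort(unique(df$code[duplicated(df$code)]))
  if (length(dup) > 0) {
    fm_stop("fm_validation_error", sprintf(
      "duplicate composition code(s): %s", paste(dup, collapse = ", ")
    ))
  }
  neg <- vapply(nutrient_names, function(nm) any(df[[nm]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    fm_stop("fm_validation_error", sprintf(
      "negative nutrient value(s) in component(s): %s",
      paste(nutrient_names[neg], collapse = ", ")
    ))
  }
  if (!is.null(langual_vocab)) {
    unknown <- sort(unique(setdiff(unlist(df$langual_terms),
                                   langual_vocab$terms$code)))
    if (length(unknown) > 0) {
      ## Retained, not dropped: real composition tables carry stray codes.
      warning(sprintf(
        "composition table: %d LanguaL code(s) not in vocabulary: %s",
        length(unknown), paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(df)
}

#' Load a food composition table
#'
#' @param path TSV with columns `code`, `english_name`, `group`,
#'   `subgroups`, `langual_terms` (pipe-separated) and the five nutrient
#'   components `CHO`, `ENERC`, `FAT`, `PROT`, `WATER`.
#' @param langual_vocab Optional LanguaL `fm_vocabulary`; if supplied,
#'   unknown facet-term codes are flagged with a warning but retained.
#' @return An `fm_composition` tibble, one row per food.  Rows with
#'   empty names or groups load without error; `name_tokens` is derived
#'   from `english_name` with [normalize_tokens()].
#' @export
load_composition_table <- function(path, langual_vocab = NULL) {
  df <- read_tsv_strict(path)
  require_columns(df, c("code", "english_name", "group", "subgroups",
                        "langual_terms", nutrient_names),
                  sprintf("composition file %s", path))
  if (nrow(df) == 0) {
    return(composition_food("placeholder")[0, ])
  }
  bad_rows <- integer(0)
  nums <- lapply(nutrient_names, function(nm) {
    raw <- df[[nm]]
    val <- suppressWarnings(as.numeric(raw))
    bad_rows <<- union(bad_rows, which(is.na(val) & nzchar(trimws(raw))))
    val
  })
  names(nums) <- nutrient_names
  if (length(bad_rows) > 0) {
    fm_stop("fm_validation_error", sprintf(
      "non-numeric nutrient value(s) in data row(s): %s",
      paste(sort(bad_rows), collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    code = df$code,
    english_name = df$english_name,
    name_tokens = lapply(df$english_name, normalize_tokens),
    group = df$group,
    subgroups = lapply(df$subgroups, split_pipes),
    langual_terms = lapply(df$langual_terms, split_pipes),
    CHO = nums$CHO, ENERC = nums$ENERC, FAT = nums$FAT,
    PROT = nums$PROT, WATER = nums$WATER
  )
  class(out) <- c("fm_composition", class(out))
  validate_composition(out, langual_vocab)
  out
}

#' Write a composition table to TSV
#' @param db An `fm_composition` tibble.
#' @param path Output path.
#' @export
write_composition_table <- function(db, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  out <- data.frame(
    code = db$code, english_name = db$english_name, group = db$group,
    subgroups = vapply(db$subgroups, join_pipes, character(1)),
    langual_terms = vapply(db$langual_terms, join_pipes, character(1)),
    CHO = fmt_num(db$CHO), ENERC = fmt_num(db$ENERC), FAT = fmt_num(db$FAT),
    PROT = fmt_num(db$PROT), WATER = fmt_num(db$WATER),
    stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

## -------------------------------------------------------------------
## Consumption table

#' Load a food consumption table
#'
#' @param path TSV with columns `id`, `english_name`, `original_name`,
#'   `group`, `subgroups`, `descriptors` (pipe-separated) and `system`
#'   (`GloboDiet` or `FoodEx2`).
#' @param vocab Optional source-system vocabulary; unknown descriptor
#'   codes are flagged with a warning but retained.
#' @return An `fm_consumption` tibble, one row per reported food.
#' @export
load_consumption_table <- function(path, vocab = NULL) {
  df <- read_tsv_strict(path)
  require_columns(df, c("id", "english_name", "original_name", "group",
                        "subgroups", "descriptors", "system"),
                  sprintf("consumption file %s", path))
  bad_sys <- setdiff(unique(df$system), c("GloboDiet", "FoodEx2"))
  if (length(bad_sys) > 0) {
    fm_stop("fm_schema_error", sprintf(
      "unknown system tag(s) in consumption table: %s",
      paste(bad_sys, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    id = df$id,
    english_name = df$english_name,
    original_name = df$original_name,
    group = df$group,
    subgroups = lapply(df$subgroups, split_pipes),
    descriptors = lapply(df$descriptors, split_pipes),
    system = df$system
  )
  if (any(!nzchar(out$id))) {
    fm_stop("fm_validation_error", "consumption table has empty id(s)")
  }
  if (!is.null(vocab)) {
    unknown <- sort(unique(setdiff(unlist(out$descriptors), vocab$terms$code)))
    if (length(unknown) > 0) {
      warning(sprintf(
        "consumption table: %d descriptor code(s) not in vocabulary: %s",
        length(unknown), paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  class(out) <- c("fm_consumption", class(out))
  out
}

#' Write a consumption table to TSV
#' @param records An `fm_consumption` tibble.
#' @param path Output path.
#' @export
write_consumption_table <- function(records, path) {
  out <- data.frame(
    id = records$id, english_name = records$english_name,
    original_name = records$original_name, group = records$group,
    subgroups = vapply(records$subgroups, join_pipes, character(1)),
    descriptors = vapply(records$descriptors, join_pipes, character(1)),
    system = records$system, stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

## -------------------------------------------------------------------
## Crosswalk

#' Construct a descriptor crosswalk
#'
#' A crosswalk maps a source system's facet descriptors to sets of
#' LanguaL terms.  Descriptors without an entry translate to themselves
#' (identity), which covers the case where a composition database is
#' indexed with the source system's own codes as well as
#' LanguaL-to-LanguaL matching.
#'
#' @param entries Data frame with columns `source_system`,
#'   `source_code`, `langual_codes` (character vector per row, or
#'   pipe-separated string) and `provenance` (`curated`, `learned` or
#'   `identity`).  `NULL` gives the empty (identity-only) crosswalk.
#' @return An `fm_crosswalk`.
#' @export
crosswalk <- function(entries = NULL) {
  if (is.null(entries) || nrow(entries) == 0) {
    entries <- tibble::tibble(
      source_system = character(0), source_code = character(0),
      langual_codes = list(), provenance = character(0)
    )
  } else {
    entries <- tibble::as_tibble(entries)
    require_columns(entries, c("source_system", "source_code",
                               "langual_codes", "provenance"), "crosswalk")
    if (!is.list(entries$langual_codes)) {
      entries$langual_codes <- lapply(entries$langual_codes, split_pipes)
    }
    empty <- vapply(entries$langual_codes, length, integer(1)) == 0
    if (any(empty)) {
      fm_stop("fm_validation_error", sprintf(
        "crosswalk row(s) mapping to zero targets: %s",
        paste(which(empty), collapse = ", ")
      ))
    }
    ## Union of targets for repeated (system, code) rows.
    key <- paste(entries$source_system, entries$source_code, sep = "\x1f")
    if (anyDuplicated(key)) {
      split_idx <- split(seq_len(nrow(entries)), key)
      entries <- do.call(rbind, lapply(split_idx, function(ix) {
        tibble::tibble(
          source_system = entries$source_system[ix[1]],
          source_code = entries$source_code[ix[1]],
          langual_codes = list(sort(unique(unlist(entries$langual_codes[ix])))),
          provenance = paste(sort(unique(entries$provenance[ix])), collapse = "+")
        )
      }))
    }
    entries <- entries[order(entries$source_system, entries$source_code), ]
  }
  lookup <- stats::setNames(
    entries$langual_codes,
    paste(entries$source_system, entries$source_code, sep = "\x1f")
  )
  structure(list(entries = entries, lookup = lookup), class = "fm_crosswalk")
}

#' Translate a descriptor code into LanguaL terms
#'
#' @param cw An `fm_crosswalk` (or `NULL` for pure identity).
#' @param system Source system of the code.
#' @param code Descriptor code.
#' @return Character vector of LanguaL term codes; the code itself when
#'   no entry exists (identity fallback).
#' @export
crosswalk_translate <- function(cw, system, code) {
  if (is.null(cw)) return(code)
  hit <- cw$lookup[[paste(system, code, sep = "\x1f")]]
  if (is.null(hit)) code else hit
}

#' Load a descriptor crosswalk from TSV
#'
#' @param path TSV with columns `source_system`, `source_code`,
#'   `langual_codes` (pipe-separated) and `provenance`.
#' @param langual_vocab Optional LanguaL vocabulary; target codes that
#'   do not resolve raise a warning.
#' @param source_vocabs Optional named list of source vocabularies
#'   (e.g. `list(GloboDiet = gd)`); codes present in both a source
#'   vocabulary and the LanguaL vocabulary gain implicit identity
#'   entries.
#' @return An `fm_crosswalk`.
#' @export
load_crosswalk <- function(path, langual_vocab = NULL, source_vocabs = list()) {
  df <- read_tsv_strict(path)
  require_columns(df, c("source_system", "source_code", "langual_codes",
                        "provenance"), sprintf("crosswalk file %s", path))
  df$langual_codes <- lapply(df$langual_codes, split_pipes)
  if (nrow(df) > 0) {
    empty <- vapply(df$langual_codes, length, integer(1)) == 0
    if (any(empty)) {
      fm_stop("fm_validation_error", sprintf(
        "crosswalk row(s) mapping to zero targets: %s",
        paste(which(empty), collapse = ", ")
      ))
    }
  }
  if (!is.null(langual_vocab) && length(source_vocabs) > 0) {
    for (sysname in names(source_vocabs)) {
      shared <- intersect(source_vocabs[[sysname]]$terms$code,
                          langual_vocab$terms$code)
      shared <- setdiff(shared, df$source_code[df$source_system == sysname])
      if (length(shared) > 0) {
        df <- rbind(df, tibble::tibble(
          source_system = sysname, source_code = shared,
          langual_codes = as.list(shared), provenance = "identity"
        ))
      }
    }
  }
  cw <- crosswalk(df)
  if (!is.null(langual_vocab) && nrow(cw$entries) > 0) {
    unknown <- sort(unique(setdiff(unlist(cw$entries$langual_codes),
                                   langual_vocab$terms$code)))
    if (length(unknown) > 0) {
      warning(sprintf(
        "crosswalk: %d target code(s) not in LanguaL vocabulary: %s",
        length(unknown), paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  cw
}

#' Write a crosswalk to TSV
#' @param cw An `fm_crosswalk`.
#' @param path Output path.
#' @export
write_crosswalk <- function(cw, path) {
  e <- cw$entries
  out <- data.frame(
    source_system = e$source_system, source_code = e$source_code,
    langual_codes = vapply(e$langual_codes, join_pipes, character(1)),
    provenance = e$provenance, stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

## -------------------------------------------------------------------
## Results

#' Write ranked match results to TSV
#'
#' @param results An `fm_results` tibble from [search()] (possibly row-
#'   bound over several queries, each tagged with `query_id`).
#' @param path Output path.
#' @return The path, invisibly.  Rows are ordered by
#'   `(query_id, level, rank)`; unit breakdowns are serialized as
#'   pipe-separated `kind:value` entries.
#' @export
write_results <- function(results, path) {
  fmt_units <- function(u) {
    if (is.null(u) || nrow(u) == 0) return("")
    join_pipes(paste(u$kind, u$value, sep = ":"))
  }
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  out <- data.frame(
    query_id = results$query_id,
    rank = results$rank,
    level = results$level,
    composition_code = results$code,
    english_name = results$english_name,
    CHO = fmt_num(results$CHO), ENERC = fmt_num(results$ENERC),
    FAT = fmt_num(results$FAT), PROT = fmt_num(results$PROT),
    WATER = fmt_num(results$WATER),
    matched_units = vapply(results$matched_units, fmt_units, character(1)),
    unmatched_units = vapply(results$unmatched_units, fmt_units, character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$query_id, out$level, out$rank), , drop = FALSE]
  write_tsv_plain(out, path)
}
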