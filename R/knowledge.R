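## knowledge: append-only store of expert-confirmed matches, used to
## re-rank future searches within levels and to learn crosswalk entries
## from co-occurrence of query descriptors with the confirmed
## candidate's LanguaL terms.  The co-occurrence counts are a cache:
## ground truth is always the confirmation log, and replaying the log
## reproduces the cache exactly.

#' Construct an expert confirmation
#'
#' @param query The `fm_query` the expert ran.
#' @param composition_code Code of the chosen composition record.
#' @param quality One of `"good"`, `"sufficient"`, `"poor"`.
#' @param expert_id Opaque expert label.
#' @param timestamp Timestamp string; supply explicitly for reproducible
#'   logs (defaults to the current UTC time).
#' @param candidate_terms LanguaL terms of the chosen record at
#'   confirmation time; these feed the descriptor/term co-occurrence
#'   counts and keep the log self-contained for replay.
#' @return An `fm_confirmation`.
#' @export
confirmed_match <- function(query, composition_code,
                            quality = c("good", "sufficient", "poor"),
                            expert_id = "expert",
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                               tz = "UTC"),
                            candidate_terms = character(0)) {
  quality <- match.arg(quality)
  stopifnot(is.character(composition_code), length(composition_code) == 1,
            nzchar(composition_code))
  structure(
    list(
      query_string = serialize_query(query),
      system = query$system,
      descriptors = sort(unique(query$descriptors)),
      composition_code = composition_code,
      quality = quality,
      expert_id = expert_id,
      timestamp = timestamp,
      candidate_terms = sort(unique(as.character(candidate_terms)))
    ),
    class = "fm_confirmation"
  )
}

#' Create an empty knowledge store
#'
#' @return An `fm_knowledge` with an empty confirmation log, empty
#'   (descriptor, term) co-occurrence counts and empty per-descriptor
#'   totals.
#' @export
knowledge_store <- function() {
  structure(
    list(
      confirmations = list(),
      keys = character(0),
      counts = integer(0),      # named "system\x1fdescriptor\x1fterm"
      desc_totals = integer(0)  # named "system\x1fdescriptor"
    ),
    class = "fm_knowledge"
  )
}

#' @export
print.fm_knowledge <- function(x, ...) {
  cat(sprintf("<knowledge store: %d confirmation(s), %d co-occurrence pair(s)>\n",
              length(x$confirmations), length(x$counts)))
  invisible(x)
}

confirmation_key <- function(m) {
  paste(m$query_string, m$composition_code, m$expert_id, m$timestamp,
        sep = "\x1f")
}

#' Record an expert confirmation
#'
#' Appends the confirmation to the log.  For `good` and `sufficient`
#' confirmations, every (query descriptor, candidate LanguaL term) pair
#' increments the co-occurrence cache once, and each query descriptor's
#' confirmation total increments once; `poor` confirmations are logged
#' but never feed learning.
#'
#' @param store An `fm_knowledge`.
#' @param match An `fm_confirmation`.
#' @return The updated store.  An identical (query, code, expert,
#'   timestamp) replay is rejected as a duplicate.
#' @export
record_confirmation <- function(store, match) {
  stopifnot(inherits(store, "fm_knowledge"), inherits(match, "fm_confirmation"))
  key <- confirmation_key(match)
  if (key %in% store$keys) {
    fm_stop("fm_duplicate_error", sprintf(
      "duplicate confirmation: %s -> %s by %s at %s",
      match$query_string, match$composition_code, match$expert_id,
      match$timestamp
    ))
  }
  store$confirmations[[length(store$confirmations) + 1L]] <- match
  store$keys <- c(store$keys, key)
  if (match$quality %in% c("good", "sufficient")) {
    for (d in match$descriptors) {
      dk <- paste(match$system, d, sep = "\x1f")
      store$desc_totals[dk] <- (store$desc_totals[dk] %|na|% 0L) + 1L
      for (t in match$candidate_terms) {
        pk <- paste(match$system, d, t, sep = "\x1f")
        store$counts[pk] <- (store$counts[pk] %|na|% 0L) + 1L
      }
    }
  }
  store
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Re-rank search results using confirmed matches
#'
#' Within each level only, candidates previously confirmed `good` or
#' `sufficient` for a query with the identical descriptor set move ahead
#' of unconfirmed ties (stable otherwise).  Levels never change: the
#' multiset of (candidate, level) pairs is preserved, and an empty store
#' leaves the results untouched.
#'
#' @param results An `fm_results` tibble from [search()].
#' @param store An `fm_knowledge`.
#' @param query The `fm_query` that produced `results`.
#' @return An `fm_results` tibble with ranks recomputed within levels.
#' @export
rerank_with_knowledge <- function(results, store, query) {
  stopifnot(inherits(store, "fm_knowledge"))
  if (length(store$confirmations) == 0 || nrow(results) == 0) return(results)
  qdesc <- sort(unique(query$descriptors))
  confirmed <- unique(vapply(
    Filter(function(m) {
      m$quality %in% c("good", "sufficient") &&
        identical(m$system, query$system) &&
        identical(m$descriptors, qdesc)
    }, store$confirmations),
    `[[`, character(1), "composition_code"
  ))
  if (length(confirmed) == 0) return(results)
  attrs <- attributes(results)
  new_order <- unlist(lapply(split(seq_len(nrow(results)), results$level), function(ix) {
    hit <- results$code[ix] %in% confirmed
    c(ix[hit], ix[!hit])
  }), use.names = FALSE)
  out <- results[new_order, , drop = FALSE]
  out$rank <- as.integer(stats::ave(seq_len(nrow(out)), out$level, FUN = seq_along))
  for (a in setdiff(names(attrs), c("row.names", "names")))
    attr(out, a) <- attrs[[a]]
  out
}

## Recompute (counts, desc_totals) from the log; used for learning and
## as the coherence oracle for the incremental cache.
recount_store <- function(store) {
  fresh <- knowledge_store()
  for (m in store$confirmations) fresh <- record_confirmation(fresh, m)
  fresh
}

#' Learn crosswalk entries from the confirmation log
#'
#' Emits `(source descriptor -> LanguaL term)` pairs supported by the
#' expert log: a pair qualifies when its co-occurrence count over
#' `good`/`sufficient` confirmations reaches `min_count`, and the count
#' divided by the number of such confirmations containing that
#' descriptor reaches `min_support`.  Thresholds default to repeated,
#' majority evidence (`min_count = 3`, `min_support = 0.5`).
#'
#' @param store An `fm_knowledge`.
#' @param min_count Minimum absolute co-occurrence count (>= 1).
#' @param min_support Minimum fraction in (0, 1].
#' @return A tibble in the crosswalk-entry schema (`source_system`,
#'   `source_code`, `langual_codes` list column, `provenance =
#'   "learned"`) plus `count` and `support` columns; deterministic,
#'   sorted by `(source_system, source_code)`.
#' @export
learn_crosswalk_entries <- function(store, min_count = 3L, min_support = 0.5) {
  stopifnot(min_count >= 1, min_support > 0, min_support <= 1)
  counts <- recount_store(store)
  if (length(counts$counts) == 0) {
    return(tibble::tibble(
      source_system = character(0), source_code = character(0),
      langual_code = character(0), count = integer(0), support = numeric(0),
      provenance = character(0)
    ))
  }
  parts <- strsplit(names(counts$counts), "\x1f", fixed = TRUE)
  df <- tibble::tibble(
    source_system = vapply(parts, `[[`, character(1), 1),
    source_code = vapply(parts, `[[`, character(1), 2),
    langual_code = vapply(parts, `[[`, character(1), 3),
    count = as.integer(counts$counts)
  )
  denom <- counts$desc_totals[paste(df$source_system, df$source_code, sep = "\x1f")]
  df$support <- df$count / as.integer(denom)
  df <- df[df$count >= min_count & df$support >= min_support, , drop = FALSE]
  df <- df[order(df$source_system, df$source_code, df$langual_code), , drop = FALSE]
  df$provenance <- rep("learned", nrow(df))
  df
}

#' Collapse learned entries into an `fm_crosswalk`
#' @param entries Output of [learn_crosswalk_entries()].
#' @return An `fm_crosswalk` with one entry per source descriptor.
#' @export
crosswalk_from_learned <- function(entries) {
  if (nrow(entries) == 0) return(crosswalk())
  key <- paste(entries$source_system, entries$source_code, sep = "\x1f")
  rows <- lapply(split(seq_len(nrow(entries)), key), function(ix) {
    tibble::tibble(
      source_system = entries$source_system[ix[1]],
      source_code = entries$source_code[ix[1]],
      langual_codes = list(sort(unique(entries$langual_code[ix]))),
      provenance = "learned"
    )
  })
  crosswalk(do.call(rbind, rows))
}

#' Write a knowledge store as a JSON-lines log
#'
#' One JSON object per confirmation, in append order; caches are not
#' serialized (they are rebuilt on load).  Rewriting an unchanged store
#' is byte-identical.
#'
#' @param store An `fm_knowledge`.
#' @param path Output path.
#' @export
write_knowledge_store <- function(store, path) {
  lines <- vapply(store$confirmations, function(m) {
    jsonlite::toJSON(list(
      query = m$query_string, system = m$system,
      descriptors = m$descriptors,
      composition_code = m$composition_code, quality = m$quality,
      expert_id = m$expert_id, timestamp = m$timestamp,
      candidate_terms = m$candidate_terms
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a knowledge store from a JSON-lines log
#'
#' Replays the log through [record_confirmation()], so the caches are
#' rebuilt from scratch and duplicates in the file are rejected.
#'
#' @param path Path to the log; a missing file yields an empty store.
#' @return An `fm_knowledge`.
#' @export
read_knowledge_store <- function(path) {
  store <- knowledge_store()
  if (!file.exists(path)) return(store)
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    o <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    m <- structure(list(
      query_string = o$query, system = o$system,
      descriptors = sort(unique(as.character(o$descriptors))),
      composition_code = o$composition_code, quality = o$quality,
      expert_id = o$expert_id, timestamp = o$timestamp,
      candidate_terms = sort(unique(as.character(o$candidate_terms)))
    ), class = "fm_confirmation")
    store <- record_confirmation(store, m)
  }
  store
}
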