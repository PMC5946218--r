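## evaluation: summary statistics of an expert validation exercise —
## average suggested-match counts per level, quality shares, the
## level-by-quality cross-tab, and agreement with previously made
## manual matches.

#' Load a judged-match table
#'
#' @param path TSV with columns `query_id`, `selected_code` (the code
#'   chosen by the expert, or `"none available"`), `tool_level` (level
#'   of the selected candidate as reported by the matcher), `quality`
#'   (`good`/`sufficient`/`poor`, possibly empty when nothing was
#'   selected), `manual_code` (previously assigned code, possibly
#'   empty) and `country_label`.
#' @return An `fm_judged` tibble.
#' @export
load_judged_table <- function(path) {
  df <- read_tsv_strict(path)
  require_columns(df, c("query_id", "selected_code", "tool_level", "quality",
                        "manual_code", "country_label"),
                  sprintf("judged-match file %s", path))
  bad <- setdiff(unique(df$quality[nzchar(df$quality)]),
                 c("good", "sufficient", "poor"))
  if (length(bad) > 0) {
    fm_stop("fm_validation_error", sprintf(
      "unknown quality grade(s): %s", paste(bad, collapse = ", ")
    ))
  }
  out <- tibble::tibble(
    query_id = df$query_id,
    selected_code = df$selected_code,
    tool_level = suppressWarnings(as.integer(df$tool_level)),
    quality = ifelse(nzchar(df$quality), df$quality, NA_character_),
    manual_code = ifelse(nzchar(df$manual_code), df$manual_code, NA_character_),
    country_label = df$country_label
  )
  class(out) <- c("fm_judged", class(out))
  out
}

#' Write a judged-match table to TSV
#' @param judged An `fm_judged` tibble.
#' @param path Output path.
#' @export
write_judged_table <- function(judged, path) {
  out <- data.frame(
    query_id = judged$query_id, selected_code = judged$selected_code,
    tool_level = judged$tool_level,
    quality = ifelse(is.na(judged$quality), "", judged$quality),
    manual_code = ifelse(is.na(judged$manual_code), "", judged$manual_code),
    country_label = judged$country_label, stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

#' Average number of suggested matches per level
#'
#' Averages, across queries, the number of candidates the matcher
#' offered at each level.  Counts recorded only as a crude lower bound
#' (e.g. ">50", carried as 50 with `censored = TRUE`) enter the average
#' at their bound, and the level's mean is flagged as a lower-bound
#' estimate.
#'
#' @param counts A data frame with columns `query_id`, `level`, `count`
#'   and optionally `censored` (logical).  A (query, level) pair absent
#'   from the table counts as zero for that query.
#' @return A tibble with `level`, `mean_count`, `lower_bound` (TRUE when
#'   any contributing count was censored) and `n_queries`.
#' @export
level_distribution <- function(counts) {
  counts <- tibble::as_tibble(counts)
  require_columns(counts, c("query_id", "level", "count"), "level-count table")
  if (nrow(counts) == 0) {
    fm_stop("fm_validation_error", "level-count table is empty")
  }
  if (!"censored" %in% names(counts)) counts$censored <- FALSE
  if (any(counts$count < 0)) {
    fm_stop("fm_validation_error", "negative suggested-match count")
  }
  qids <- unique(counts$query_id)
  levels <- sort(unique(as.integer(counts$level)))
  out <- lapply(levels, function(l) {
    sub <- counts[counts$level == l, , drop = FALSE]
    ## Queries with no row at this level contribute zero.
    total <- sum(sub$count)
    tibble::tibble(
      level = l,
      mean_count = total / length(qids),
      lower_bound = any(sub$censored),
      n_queries = length(qids)
    )
  })
  do.call(rbind, out)
}

## Selected judgments: rows where the expert actually chose a
## candidate.  "No acceptable item" rows (selected_code == "none
## available") are excluded unless the expert graded them.
selected_judgments <- function(judged) {
  none <- judged$selected_code %in% c("none available", "") |
    is.na(judged$selected_code)
  keep <- !none | !is.na(judged$quality)
  structure(judged[keep, , drop = FALSE], excluded = sum(!keep))
}

#' Quality shares of selected matches
#'
#' Percentage of selected matches the experts judged `good`,
#' `sufficient` and `poor`, per country label.
#'
#' @param judged An `fm_judged` tibble (or equivalent data frame).
#' @param digits Rounding digits for the percentages (default 0, i.e.
#'   whole-number percentages).
#' @return A tibble with `country_label`, `quality`, `n`, `share`
#'   (percent).  Rows with no selection and no grade are excluded; the
#'   excluded count is attached as attribute `excluded`.
#' @export
quality_shares <- function(judged, digits = 0) {
  judged <- tibble::as_tibble(judged)
  if (nrow(judged) == 0) {
    fm_stop("fm_validation_error", "no judgments supplied")
  }
  if (is.null(judged$country_label)) judged$country_label <- "all"
  sel <- selected_judgments(judged)
  excluded <- attr(sel, "excluded")
  sel <- sel[!is.na(sel$quality), , drop = FALSE]
  if (nrow(sel) == 0) {
    fm_stop("fm_validation_error", "no graded judgments supplied")
  }
  grades <- c("good", "sufficient", "poor")
  out <- do.call(rbind, lapply(split(sel, sel$country_label), function(g) {
    n_by_grade <- unname(vapply(grades, function(q) sum(g$quality == q),
                                integer(1)))
    tibble::tibble(
      country_label = g$country_label[1],
      quality = grades,
      n = n_by_grade,
      share = round(100 * n_by_grade / nrow(g), digits)
    )
  }))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Level-by-quality cross-tabulation
#'
#' Counts of selected matches by the level the matcher assigned and the
#' quality grade the expert gave.
#'
#' @param judged An `fm_judged` tibble.
#' @param top_bin Optional integer: levels `>= top_bin` are pooled into
#'   one `">=top_bin"` row (result screens typically pool high levels);
#'   `NULL` reports exact levels.
#' @return A list with `counts` (levels x qualities integer matrix),
#'   `level_marginals` and `quality_marginals`.
#' @export
crosstab_level_quality <- function(judged, top_bin = NULL) {
  judged <- tibble::as_tibble(judged)
  sel <- selected_judgments(judged)
  sel <- sel[!is.na(sel$quality) & !is.na(sel$tool_level), , drop = FALSE]
  if (nrow(sel) == 0) {
    fm_stop("fm_validation_error", "no graded judgments with a tool level")
  }
  lev <- sel$tool_level
  if (!is.null(top_bin)) {
    lab <- ifelse(lev >= top_bin, paste0(">=", top_bin), as.character(lev))
    lev_levels <- c(as.character(0:(top_bin - 1)), paste0(">=", top_bin))
  } else {
    lab <- as.character(lev)
    lev_levels <- as.character(sort(unique(lev)))
  }
  tab <- table(
    level = factor(lab, levels = lev_levels),
    quality = factor(sel$quality, levels = c("good", "sufficient", "poor"))
  )
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  list(
    counts = counts,
    level_marginals = rowSums(counts),
    quality_marginals = colSums(counts)
  )
}

#' Agreement with previously made manual matches
#'
#' Percentage of expert selections identical to the manual match
#' previously assigned to the same consumption item.
#'
#' @param judged An `fm_judged` tibble; only rows with a `manual_code`
#'   enter the calculation.
#' @param digits Rounding digits (default 0).
#' @return The agreement percentage (a single number), with attribute
#'   `n` (judgments compared).  Order-invariant.
#' @export
agreement_with_manual <- function(judged, digits = 0) {
  judged <- tibble::as_tibble(judged)
  sub <- judged[!is.na(judged$manual_code), , drop = FALSE]
  if (nrow(sub) == 0) {
    fm_stop("fm_validation_error", "no judgment carries a manual match code")
  }
  agree <- sum(sub$selected_code == sub$manual_code, na.rm = TRUE)
  structure(round(100 * agree / nrow(sub), digits), n = nrow(sub))
}

#' Full evaluation summary
#'
#' @param judged An `fm_judged` tibble.
#' @param level_counts Optional level-count table for
#'   [level_distribution()].
#' @param digits Rounding digits for percentages.
#' @param top_bin Optional top bin for the cross-tab.
#' @return An `fm_evaluation` list with components `quality_shares`,
#'   `crosstab`, `agreement` (NULL when no manual codes exist),
#'   `level_distribution` (NULL when no counts supplied) and `n`.
#' @export
evaluation_summary <- function(judged, level_counts = NULL, digits = 0,
                               top_bin = NULL) {
  shares <- quality_shares(judged, digits = digits)
  ct <- crosstab_level_quality(judged, top_bin = top_bin)
  agreement <- if (any(!is.na(judged$manual_code))) {
    agreement_with_manual(judged, digits = digits)
  } else NULL
  ld <- if (!is.null(level_counts)) level_distribution(level_counts) else NULL
  structure(
    list(quality_shares = shares, crosstab = ct, agreement = agreement,
         level_distribution = ld, n = nrow(judged)),
    class = "fm_evaluation"
  )
}

#' @export
print.fm_evaluation <- function(x, ...) {
  cat(sprintf("<evaluation summary over %d judgment(s)>\n", x$n))
  cat("quality shares (%):\n")
  print(as.data.frame(x$quality_shares))
  if (!is.null(x$agreement)) {
    cat(sprintf("agreement with manual matches: %s%% (n = %d)\n",
                format(unclass(x$agreement)), attr(x$agreement, "n")))
  }
  invisible(x)
}
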