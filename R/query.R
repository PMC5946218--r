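## query: the comma-separated "X"-prefix query syntax, token
## normalization, and query construction from consumption records.

#' Normalize free text into a token set
#'
#' Lowercases, replaces punctuation with spaces, splits on whitespace
#' and drops empty strings.  The result is a sorted, de-duplicated set,
#' so the operation is idempotent and order-insensitive.  Name matching
#' is exact on these tokens ("simple matching"); no stemming is applied,
#' so singular and plural forms are distinct tokens.
#'
#' @param text Character vector (concatenated before tokenizing); may be
#'   empty.
#' @return Character vector of normalized tokens (possibly empty).
#' @examples
#' normalize_tokens("Cabbage pak-choi, raw")
#' @export
normalize_tokens <- function(text) {
  if (length(text) == 0) return(character(0))
  text <- text[!is.na(text)]
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^[:alnum:]]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  sort(unique(toks[nzchar(toks)]))
}

#' Construct a match query
#'
#' @param name_tokens Normalized name tokens (see [normalize_tokens()]).
#' @param group Group code, or `""` when absent.
#' @param subgroups Ordered subgroup codes.
#' @param descriptors Facet-descriptor codes of the source system.
#' @param system `"GloboDiet"`, `"FoodEx2"` or `"LanguaL"`.
#' @return An `fm_query`.  At least one of names, group or descriptors
#'   must be non-empty.
#' @export
match_query <- function(name_tokens = character(0), group = "",
                        subgroups = character(0),
                        descriptors = character(0),
                        system = c("GloboDiet", "FoodEx2", "LanguaL")) {
  system <- match.arg(system)
  name_tokens <- sort(unique(as.character(name_tokens)))
  descriptors <- sort(unique(as.character(descriptors)))
  if (is.na(group)) group <- ""
  if (length(name_tokens) == 0 && !nzchar(group) && length(descriptors) == 0) {
    fm_stop("fm_empty_query_error",
            "query must contain at least one of: name tokens, group, descriptors")
  }
  structure(
    list(name_tokens = name_tokens, group = group,
         subgroups = as.character(subgroups), descriptors = descriptors,
         system = system),
    class = "fm_query"
  )
}

#' @export
print.fm_query <- function(x, ...) {
  cat(sprintf("<%s query> %s\n", x$system, serialize_query(x)))
  invisible(x)
}

## Code-shape patterns inferred from the two printed query forms:
## GloboDiet groups are a letter followed by digits (G02); GloboDiet
## descriptors are all-digit codes (0499); FoodEx2 groups are 5-char
## alphanumeric codes (A039D); FoodEx2 facet descriptors contain a dot
## (F10.A0B8M).
is_globodiet_group <- function(x) grepl("^[A-Za-z][0-9]+$", x)
is_foodex2_group <- function(x) {
  grepl("^[A-Z][0-9A-Z]{4}$", x) & !grepl("^[A-Z][0-9]{4}$", x)
}
is_foodex2_descriptor <- function(x) grepl(".", x, fixed = TRUE)

#' Parse a query string
#'
#' Parses the comma-separated query syntax in which tokens prefixed with
#' a capital `"X"` carry the food name, one token carries the group code
#' and the remaining tokens are facet descriptors; for example
#' `"XCourgette, Xraw, G02, 0499, 0204, 0309"` (GloboDiet) or
#' `"Xmargarine, A039D, F10.A0B8M"` (FoodEx2).
#'
#' @param text Non-empty query string; tokens separated by commas with
#'   optional whitespace.
#' @param system Declared source system; `NULL` (default) infers it from
#'   code shapes (a dotted or 5-character alphanumeric code implies
#'   FoodEx2, otherwise GloboDiet).
#' @return An `fm_query`.
#' @export
parse_query_string <- function(text, system = NULL) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    fm_stop("fm_parse_error", "query string is empty")
  }
  toks <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) {
    fm_stop("fm_parse_error", sprintf("no parseable tokens in query: %s", text))
  }
  is_name <- startsWith(toks, "X")
  name_tokens <- normalize_tokens(sub("^X", "", toks[is_name]))
  codes <- toks[!is_name]

  if (is.null(system)) {
    system <- if (any(is_foodex2_descriptor(codes)) || any(is_foodex2_group(codes)))
      "FoodEx2" else "GloboDiet"
  }
  system <- match.arg(system, c("GloboDiet", "FoodEx2", "LanguaL"))

  grp_mask <- switch(system,
    GloboDiet = is_globodiet_group(codes),
    FoodEx2 = is_foodex2_group(codes),
    LanguaL = rep(FALSE, length(codes))
  )
  if (sum(grp_mask) > 1) {
    fm_stop("fm_parse_error", sprintf(
      "ambiguous group code in query: %s",
      paste(codes[grp_mask], collapse = " and ")
    ))
  }
  group <- if (any(grp_mask)) codes[grp_mask] else ""
  descriptors <- codes[!grp_mask]
  if (length(name_tokens) == 0 && !nzchar(group) && length(descriptors) == 0) {
    fm_stop("fm_parse_error", sprintf("no parseable tokens in query: %s", text))
  }
  match_query(name_tokens, group, character(0), descriptors, system)
}

#' Serialize a query to the canonical query-string form
#'
#' Inverse direction of [parse_query_string()]: name tokens get the
#' `"X"` prefix, then the group, subgroups and descriptors follow,
#' comma-separated.  Parsing the serialization recovers the query for
#' any query without subgroups (the string syntax has no subgroup
#' marker, so serialized subgroup codes reparse as descriptors).
#'
#' @param query An `fm_query`.
#' @return A single string.
#' @export
serialize_query <- function(query) {
  parts <- c(
    paste0("X", query$name_tokens),
    if (nzchar(query$group)) query$group,
    query$subgroups,
    query$descriptors
  )
  paste(parts, collapse = ", ")
}

#' Construct an attribute mask
#'
#' Masks select which attribute groups of a record enter the query.
#' Restricting a query to fewer attributes is a documented strategy for
#' sparse data: dropping names and subgroups can move candidates from
#' high levels to levels 0-1 when the composition side lacks those
#' attributes.
#'
#' @param use_names,use_group,use_subgroups,use_descriptors Logical
#'   flags; at least one must be `TRUE`.
#' @return An `fm_mask`.
#' @export
attribute_mask <- function(use_names = TRUE, use_group = TRUE,
                           use_subgroups = TRUE, use_descriptors = TRUE) {
  flags <- c(use_names = use_names, use_group = use_group,
             use_subgroups = use_subgroups, use_descriptors = use_descriptors)
  stopifnot(is.logical(flags), !anyNA(flags))
  if (!any(flags)) {
    fm_stop("fm_validation_error", "attribute mask must enable at least one flag")
  }
  structure(as.list(flags), class = "fm_mask")
}

#' Build a query from a consumption record
#'
#' @param record A one-row `fm_consumption` tibble (or an equivalent
#'   list with fields `english_name`, `group`, `subgroups`,
#'   `descriptors`, `system`).
#' @param mask An `fm_mask`; masked-out attribute groups are omitted
#'   from the query.
#' @return An `fm_query`.  Name tokens are derived from `english_name`
#'   via [normalize_tokens()]; a record with an empty name simply yields
#'   a query without name tokens, which are then not considered for
#'   matching.
#' @export
query_from_consumption <- function(record, mask = attribute_mask()) {
  if (tibble::is_tibble(record) || is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- list(
      english_name = record$english_name[[1]],
      group = record$group[[1]],
      subgroups = record$subgroups[[1]],
      descriptors = record$descriptors[[1]],
      system = record$system[[1]]
    )
  }
  name_tokens <- if (isTRUE(mask$use_names)) normalize_tokens(record$english_name)
                 else character(0)
  group <- if (isTRUE(mask$use_group)) (record$group %||% "") else ""
  if (is.na(group)) group <- ""
  subgroups <- if (isTRUE(mask$use_subgroups)) record$subgroups else character(0)
  descriptors <- if (isTRUE(mask$use_descriptors)) record$descriptors else character(0)
  if (length(name_tokens) == 0 && !nzchar(group) && length(descriptors) == 0) {
    fm_stop("fm_empty_query_error", sprintf(
      "mask removes every attribute present on record %s",
      record$id %||% record$english_name %||% ""
    ))
  }
  match_query(name_tokens, group, subgroups, descriptors, record$system)
}
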