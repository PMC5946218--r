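## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

fm_systems <- c("LanguaL", "FoodEx2", "GloboDiet")

fm_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

## Split a pipe-separated multi-valued cell into a character vector.
split_pipes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- strsplit(x, "|", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

join_pipes <- function(x) paste(x, collapse = "|")

## Evaluate expr with a temporary RNG state seeded at `seed`, restoring
## the caller's stream afterwards.  All generators route randomness here
## so that a SyntheticSpec seed fully determines the output.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Strict column check for loaded tables.
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    fm_stop("fm_schema_error", sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", sprintf("file does not exist: %s", path))
  }
  as.data.frame(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  ))
}

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}
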