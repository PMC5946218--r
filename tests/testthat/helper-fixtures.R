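# Shared fixtures built in code: the printed worked-example query and
# candidates, random matching instances for oracle-equivalence checks,
# and a compact synthetic-study spec.

courgette_query <- function() {
  parse_query_string("XCourgette, Xraw, G02, 0499, 0204, 0309")
}

pak_choi <- function() {
  composition_food("NL002", "Cabbage pak-choi, raw", "G02",
                   langual_terms = c("0499", "0204", "0309"),
                   CHO = 1.2, ENERC = 54, FAT = 0.2, PROT = 1.5, WATER = 95.3)
}

courgettes_raw <- function(terms = c("0499", "0204")) {
  composition_food("NL001", "Courgettes, raw", "G02",
                   langual_terms = terms,
                   CHO = 3.1, ENERC = 94, FAT = 0.4, PROT = 1.2, WATER = 94.6)
}

small_spec <- function(seed = 42L) {
  synthetic_spec(
    seed = seed, n_composition = 120L, n_queries = 15L,
    planted_levels = c("0" = 3L, "1" = 3L, "2" = 3L, "3" = 3L, "4" = 3L)
  )
}

# Random (query, db) instance with identity descriptor translation.
# Up to 12 attribute units; candidate attributes drawn from small pools
# so all levels occur.
random_instance <- function(seed, max_candidates = 400) {
  set.seed(seed)
  token_pool <- c("apple", "pear", "raw", "dried", "juice", "soup", "baked")
  group_pool <- sprintf("G%02d", 1:4)
  subgroup_pool <- sprintf("SG%02d", 1:5)
  desc_pool <- sprintf("%04d", 101:130)

  n_names <- sample(0:2, 1)
  has_group <- runif(1) < 0.7
  n_sub <- sample(0:2, 1)
  n_desc <- sample(1:8, 1)
  query <- match_query(
    name_tokens = if (n_names > 0) sample(token_pool, n_names) else character(0),
    group = if (has_group) sample(group_pool, 1) else "",
    subgroups = if (n_sub > 0) sample(subgroup_pool, n_sub) else character(0),
    descriptors = sample(desc_pool, n_desc),
    system = "GloboDiet"
  )
  n <- sample(20:max_candidates, 1)
  rows <- lapply(seq_len(n), function(i) {
    composition_food(
      code = sprintf("C%04d", i),
      english_name = if (runif(1) < 0.1) "" else
        paste(sample(token_pool, sample(1:3, 1)), collapse = " "),
      group = if (runif(1) < 0.1) "" else sample(group_pool, 1),
      subgroups = if (runif(1) < 0.5) sample(subgroup_pool, sample(1:2, 1))
                  else character(0),
      langual_terms = sample(desc_pool, sample(0:10, 1)),
      CHO = round(runif(1, 0, 80), 1), ENERC = round(runif(1, 0, 4000)),
      FAT = round(runif(1, 0, 60), 1), PROT = round(runif(1, 0, 40), 1),
      WATER = round(runif(1, 0, 95), 1)
    )
  })
  list(query = query, db = composition_table(rows))
}

results_signature <- function(res) {
  list(code = res$code, level = res$level, rank = res$rank,
       overlap = res$name_overlap, totals = attr(res, "level_totals"))
}
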