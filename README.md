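# langualink

Linking what people report eating to what food composition tables know
about those foods is a recurring bottleneck in dietary assessment.
Consumption records from 24-h recall tools (GloboDiet) or exposure
coding (FoodEx2) describe a food by its English name, a food group and
subgroups, and a set of facet descriptors; composition databases
describe their foods with LanguaL facet terms and nutrient values per
100 g. `langualink` automates the candidate-finding half of that
matching task and leaves the decision to the human expert, the way
nutrition surveillance groups actually work.

## The method

A query decomposes into **attribute units**:

* one *name* unit — matched when the candidate shares **at least one**
  normalized name token with the query;
* one *group* unit — matched on exact group-code equality (hierarchical
  ancestor/descendant credit is an explicit opt-in);
* one unit per *subgroup* code;
* one unit per *facet descriptor* — matched when any of the
  descriptor's crosswalk-translated LanguaL terms occurs among the
  candidate's terms.

The **match level** of a candidate is the number of units it fails:

```
level(c, q) = |{ u in units(q) : u does not match c }|
```

Level 0 is a perfect match; level 1 misses one unit; and so on, without
an upper bound — the number of reachable levels depends only on how many
attributes the query carries. Attributes absent from the query (e.g. a
record with no English name) contribute no unit and are simply not
considered. Within a level, candidates are ranked by descending shared
name-token count, then by code; co-equal candidates stay co-equal, and
choosing among them is the expert's job.

Around the matcher the package provides: validated TSV loaders for
vocabularies, composition/consumption tables and descriptor crosswalks;
a parser for the compact `"X"`-prefix query syntax; an append-only
expert confirmation store with within-level re-ranking and thresholded
crosswalk learning; evaluation statistics (level distributions, quality
shares, level-by-quality cross-tabs, agreement with manual matches);
and a deterministic synthetic-study generator that plants known match
levels so the whole pipeline is testable end to end.

## Worked example

The query "courgette, raw; vegetables; fresh, flesh, stir-fried" in the
query syntax — `X` marks name tokens, `G02` is the group, the rest are
facet descriptors:

```r
library(langualink)

query <- parse_query_string("XCourgette, Xraw, G02, 0499, 0204, 0309")

db <- composition_table(list(
  composition_food("NL002", "Cabbage pak-choi, raw", "G02",
    langual_terms = c("0499", "0204", "0309"),
    CHO = 1.2, ENERC = 54, FAT = 0.2, PROT = 1.5, WATER = 95.3),
  composition_food("NL001", "Courgettes, raw", "G02",
    langual_terms = c("0499", "0204"),
    CHO = 3.1, ENERC = 94, FAT = 0.4, PROT = 1.2, WATER = 94.6)
))

res <- search(query, db)
res[, c("level", "rank", "code", "english_name", "name_overlap")]
#> <match results: 2 candidate(s) listed over 2 level(s); 2 in db>
#>   per-level totals: level 0: 1, level 1: 1
#> # A tibble: 2 × 5
#>   level  rank code  english_name          name_overlap
#>   <int> <int> <chr> <chr>                        <int>
#> 1     0     1 NL002 Cabbage pak-choi, raw            1
#> 2     1     1 NL001 Courgettes, raw                  1
```

"Cabbage pak-choi, raw" is the level-0 match: it shares a name token
("raw"), the group `G02`, and all three descriptors. "Courgettes, raw" —
the food a human would name-match — sits at level 1 because it lacks the
stir-fried descriptor:

```r
match_level(query, db[2, ])$unmatched_units
#> # A tibble: 1 × 3
#>   kind       value translated
#>   <chr>      <chr> <list>
#> 1 descriptor 0309  <chr [1]>
```

That inversion is exactly why the expert stays in the loop: the tool
surfaces descriptor-faithful candidates, the expert weighs them against
name evidence, and `cmd_confirm()` / `record_confirmation()` store the
decision so later searches can re-rank with it.

## Command line

A thin wrapper is installed at `inst/cli/langualink.R`:

```sh
Rscript langualink.R gen   --out-dir study --seed 7
Rscript langualink.R batch --config study/config.yaml --out study/results.tsv
Rscript langualink.R match --config study/config.yaml --query 'XCourgette, Xraw, G02, 0499, 0204, 0309'
Rscript langualink.R confirm --config study/config.yaml --query '...' --code NL002 --quality good
Rscript langualink.R eval  --config study/config.yaml --judged study/judged.tsv
```

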