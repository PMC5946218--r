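Package: langualink
Title: Leveled Matching of Food Consumption Records to LanguaL-Indexed
    Food Composition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links food consumption records described with GloboDiet or
    FoodEx2 groups, facets and facet descriptors to food composition
    records indexed with LanguaL facet terms.  Candidates are ranked by
    match level: the number of query attribute units (name, group,
    subgroups, individual facet descriptors) a composition record fails
    to match, with level 0 a perfect match.  Includes loaders and
    validators for vocabulary, composition, consumption and crosswalk
    tables; a query parser for the "X"-prefixed comma-separated query
    syntax; an expert confirmation store with within-level re-ranking
    and thresholded crosswalk learning; evaluation statistics (level
    distributions, quality shares, level-by-quality cross-tabs,
    agreement with manual matches); and a deterministic synthetic-study
    generator that plants known match levels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
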