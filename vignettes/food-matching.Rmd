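---
title: "Leveled matching of consumption records to LanguaL-indexed composition data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leveled matching of consumption records to LanguaL-indexed composition data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langualink)
```

## The matching problem

Dietary surveys and food composition tables describe foods in different
languages. A consumption record carries an English name, a food group
and subgroups, and facet descriptors from the collecting system
(GloboDiet's numeric descriptor codes, or FoodEx2's dotted facet codes
such as `F10.A0B8M`). A composition record carries an English name,
LanguaL facet terms, and nutrient values (the five basic EuroFIR
components CHO, ENERC, FAT, PROT and WATER per 100 g edible portion).
Matching the two is traditionally manual, slow, and dependent on scarce
expert knowledge of both databases. `langualink` automates candidate
retrieval and ranking while keeping the final decision with the expert.

## The level model

A query is decomposed into *attribute units*: at most one name unit, at
most one group unit, one unit per subgroup, and one unit per facet
descriptor. A candidate's **level** is the number of units it fails to
match. The matching rules per unit kind are:

* **name** — at least one shared normalized token. Tokens are
  lowercased, punctuation-split, de-duplicated; matching is exact
  ("simple matching"), so `courgette` and `courgettes` are different
  tokens. No stemming, fuzziness or multilingual handling is applied;
  richer name matching is a separate problem and out of scope here.
* **group** — exact code equality. Both GloboDiet and FoodEx2 organize
  groups hierarchically, so `search_settings(hierarchical_group = TRUE,
  group_vocab = ...)` optionally grants ancestor/descendant credit; it
  is off by default because exact grouping is the conservative reading
  and hierarchical credit changes level semantics.
* **subgroup** — code membership in the candidate's subgroup list. Each
  subgroup is its own unit: sparse composition tables that lack
  subgroups then degrade gracefully (each missing subgroup costs one
  level), and restricting a query to the main group alone is exactly the
  re-query strategy that helps on such data.
* **descriptor** — each descriptor is its own unit and is satisfied when
  *any* of its crosswalk-translated LanguaL terms occurs among the
  candidate's terms. Per-descriptor granularity (rather than one pooled
  "facet group" unit) is what makes the number of levels unbounded and
  lets heavily-described queries land at level 3 or higher; on the
  canonical courgette example both readings coincide (one missing
  descriptor, level 1).

Attributes the query does not carry contribute no unit: a query without
names is scored on groups and descriptors alone, which is essential for
composition sources that lack English names. Masking
(`attribute_mask()`) makes this an explicit, per-search choice.

Within a level, candidates are ordered by descending shared-name-token
count, then ascending code. The tie-break is deliberately shallow: when
several candidates are genuinely co-equal at level 0, the tool reports
them co-equal and the expert decides.

## Crosswalks

Nothing guarantees that the consumption system's descriptor codes and
the composition table's LanguaL terms share a code space. The
`fm_crosswalk` maps `(system, descriptor)` to a *set* of LanguaL terms,
with any-overlap satisfaction, because facet systems differ in
granularity and one-to-one mappings are generally impossible. A
descriptor without an entry translates to itself — the identity default
covers composition tables indexed with the source system's own codes and
the LanguaL-to-LanguaL matching mode. Crosswalk entries carry
provenance (`curated`, `identity`, `learned`).

## The expert loop

Every confirmed match is appended to a JSON-lines log
(`record_confirmation()` / `cmd_confirm()`), with its quality grade
(`good` / `sufficient` / `poor`), the expert label, the timestamp and
the candidate's LanguaL terms at confirmation time. Two conservative
uses are implemented:

* `rerank_with_knowledge()` moves candidates previously confirmed
  good/sufficient for the *identical descriptor set* ahead of
  unconfirmed ties, **within their level only**. Levels never change;
  with an empty store the results are returned untouched. Confirmation
  never alters candidate generation — the stored queries are not
  rewritten.
* `learn_crosswalk_entries()` emits `(descriptor, term)` pairs whose
  co-occurrence count over good/sufficient confirmations reaches
  `min_count` (default 3) and whose support — count divided by the
  number of such confirmations containing the descriptor — reaches
  `min_support` (default 0.5). The defaults demand repeated, majority
  evidence; both are tunable and the output is a reviewable table, not a
  silent model update.

The in-memory co-occurrence counts are a cache: replaying the log
reproduces them exactly, and the tests enforce byte-identical rewrite of
an unchanged log.

## Evaluation statistics

`level_distribution()` averages per-query suggested-candidate counts by
level; counts recorded only as a crude bound (">50") enter at the bound
and flag the mean as a lower-bound estimate rather than being dropped.
`quality_shares()` reports whole-number percentages by default
(`digits = 0`); rows where no candidate was selected and no grade given
are excluded with an explicit excluded-count, since their tabulation is
a protocol choice, not a computation. `crosstab_level_quality()` reports
exact levels with an optional pooled top bin (result screens typically
pool "level 2 or higher"). `agreement_with_manual()` is the share of
selections identical to the previously assigned manual match.

## The synthetic-study generator

Real national composition databases are proprietary, so the package
ships a generator whose defaults are the study conditions the test
suite and examples run under, chosen once:

* composition database of **800** records — the scale of the smallest
  national table in routine use (a few hundred to a few thousand
  foods);
* **45** queries with planted levels 0–4, nine each — a test set the
  size a single country's validation exercise uses, with levels beyond
  the usual reporting cap included deliberately;
* **10%** of records missing their English name and **5%** missing
  their group — the missing-information pathologies reported for real
  exports;
* crosswalk fanout of **2** LanguaL terms per descriptor, with
  per-descriptor blocks kept pairwise disjoint within a system.

Planting works on the query side: a base record's exact query (level 0
by construction) is perturbed in exactly `k` units — replace the name
tokens with a token the record lacks, switch the group code, add foreign
descriptors whose blocks are disjoint from the record's terms. Because
blocks are disjoint, each perturbation flips exactly one unit, so the
planted level is exact, and the generator's expectations derive from the
same per-descriptor unit model the matcher implements — if the pooled
facet-group reading were adopted instead, the planted levels would
change with it. Name perturbation replaces *all* shared tokens, since a
single surviving token would still satisfy the at-least-one-name rule.

Simulated judgments select each query's top-ranked candidate and grade
it good at level 0, sufficient when only name or descriptor units
failed, and poor otherwise. This is an operational reading of the
grading definitions used in validation exercises; real experts also
weigh generic-versus-specific relationships that no simulator captures.

What passing the synthetic suites shows: the level arithmetic, ranking
contract, persistence and statistics are implemented exactly. What it
does not show: retrieval quality on real food vocabularies — synthetic
names are pseudowords with no morphology or synonymy, nutrient values
are uncorrelated with descriptors, and descriptor co-assignment has no
real-world structure. Conclusions about expert workload or match
quality on national data cannot be drawn from these fixtures.

## Numerical and degenerate-input choices

* Determinism everywhere: generators restore the RNG state and derive
  per-query seeds from the spec seed; vocabularies sort terms by code so
  validation is independent of input row order; all rankings have total,
  deterministic orders.
* An empty composition database yields an empty result with a warning;
  a query whose units are all masked away is an error, as is a mask
  removing every attribute a record has.
* Duplicate codes, parent cycles and zero-target crosswalk rows are
  hard errors; unresolved parents, unknown facet codes and unknown
  LanguaL terms are warnings with the rows retained, because real
  datasets contain them and hard failure would block the primary use
  case.
* Missing nutrient values load as `NA` and propagate as empty cells in
  output; present values must be non-negative.
* `max_level = 2` and `max_per_level = 50` default the result listing:
  levels up to 2 are what result reviews typically present, and option
  lists beyond ~50 are burdensome; per-level totals are always reported
  so the cap loses no information.

## Problem sizes used in the checks

The oracle-equivalence suite compares the indexed search against the
brute-force scan on 200 randomized instances of up to 500 candidates and
up to 12 attribute units; the end-to-end planted-level check runs a
400-record, 200-query study through the file-based `gen → batch`
pipeline. Both sizes comfortably exercise every code path of the
matcher while keeping the default test run quick.

## Known limitations

* Name matching is exact-token only; the optional crosswalk learning
  does not extend to names.
* The FoodEx2 ingestion treats core/extended/hierarchy flags as opaque
  attributes; facet-specific semantics (e.g. implicit facets) are not
  modelled.
* The query string syntax cannot carry subgroups (no marker exists for
  them), so serialized queries with subgroups reparse those codes as
  descriptors; programmatic construction via `match_query()` or
  `query_from_consumption()` is the lossless path, and the knowledge
  store keys on explicit descriptor sets rather than reparsed strings.
* Brand names, counts and portion information present in real exports
  have no role in matching here.
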