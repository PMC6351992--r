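---
title: "Intensional versus extensional value sets over a concept hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensional versus extensional value sets over a concept hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenovset)
```

## The problem

Computable clinical phenotypes — "all patients with osteoporosis", "all
patients with chronic kidney disease stage 5" — are defined in EHR-derived
data by *value sets* of SNOMED CT concepts. Two styles exist:

* **Extensional** value sets enumerate every concept explicitly, the way
  ICD code lists have always been built. They are brittle: the terminology
  is updated twice a year, new subtype concepts appear, and a frozen list
  silently stops covering the condition it names.
* **Intensional** value sets are rules over the terminology's
  polyhierarchy: "concept X and all its descendants, but not subtype Y and
  its descendants". One or two hierarchy references can stand in for
  hundreds of enumerated codes, and new descendants are picked up
  automatically at each release.

`phenovset` implements both representations, the expansion that turns a
rule into its exactly-equivalent enumerated form on a given hierarchy, and
a comparison pipeline that scores the two styles on three axes:

1. **Conciseness** — concepts needed to define the set. For a downloaded
   list of size $n_\mathrm{dl}$ and a rule with $n_\mathrm{int}$ concept
   references expanding to $n_\mathrm{der}$ concepts, the *ratio to define*
   is $n_\mathrm{dl}/n_\mathrm{int}$ (download form) and
   $n_\mathrm{der}/n_\mathrm{int}$ (derived form).
2. **Creation time** — a linear cost model
   $\mathrm{minutes} = a \cdot n_\mathrm{concepts} + b$, fitted by ordinary
   least squares to stopwatch measurements; the shipped default is
   $a = 0.4177$, $b = 3.8707$ (about 25 s per concept on top of just under
   4 min of fixed setup).
3. **Completeness** — the *completeness ratio*
   $n_\mathrm{der}/n_\mathrm{dl}$ and the *percent included*
   $100\, n_\mathrm{dl}/n_\mathrm{der}$, computed at the level of concepts
   and again at the level of the EHR clinical terms (the clinician-facing
   diagnosis strings mapped many-to-one onto concepts) compiled from each
   set.

## The hierarchy model and its assumptions

A `concept_graph` keeps only the active is-a (supertype–subtype) fragment
of a terminology: nodes are concepts, edges run child → parent, and the
graph must be acyclic — a cycle would make "all descendants" meaningless,
so loading fails hard rather than silently breaking a cycle. Attribute
relationships (finding site, morphology, …) are out of scope, as is any
release-to-release diffing: a comparison pins one snapshot, so only the
`active` flag of RF2 rows is honoured and `effectiveTime` is ignored.
When both an International and a national edition matter, load one
snapshot at a time; merging modules is deliberately left to the caller.

Concept identifiers are opaque strings end to end. SCTIDs exceed 15
digits, past the exact-integer range of doubles, and real mistakes happen
when they travel as numbers. We do not *require* ids to be digit strings:
readable single-letter ids make worked examples and fixtures far clearer,
and nothing in the algorithms cares. A consequence is that the edge-table
reader cannot detect a header row by "first cell is non-numeric"; it keys
on recognised header names (`child_id`, `child`, `sourceId`, …) and takes
an explicit `header` argument for the rest.

Reachability queries (`descendants()`, `ancestors()`) are delegated to
igraph; tests check them against an independently written fixpoint
oracle, node by node, and verify the descendant/ancestor duality
exhaustively on graphs of a few hundred nodes.

## The rule language

`parse_ecl()` accepts the small Expression Constraint Language subset
that hierarchy-based phenotype rules actually use: `<<ID`
(descendant-or-self), `<ID` (descendants only), bare `ID` (self only),
`OR` between include terms, and `MINUS` to append exclusions (`AND NOT`
in Boolean clothing). Parentheses, refinements and attribute constraints
are not supported — rules of this family never need them.

Two semantic choices deserve a note:

* "Including descendants" means descendant **or self** (`<<`). The root
  concept of a phenotype (osteoporosis itself) is clinically part of the
  phenotype, so dropping it would be a trap; per-clause scope still lets a
  caller express descendants-only or self-only references where a rule
  mixes reference styles (an 8-reference rule expanding to only 36
  concepts is expressible either way).
* All exclusions apply **after** all inclusions, as one set difference.
  There is no clause-order-dependent semantics; a concept removed by an
  exclusion stays removed even if a second include clause also reaches it.
  Consequently every token after the first `MINUS` is an exclusion, and
  serialisation normalises a rule to "includes, then excludes" — parsing
  a serialised rule reproduces its clause table byte-for-byte.

Duplicate clauses are allowed and deduplicated at expansion, but
`n_defining_concepts()` counts them as written: conciseness is a property
of the rule text, not of its normal form. Expanding an already-extensional
set is the identity — a downloaded list carries no descendant semantics,
matching how such lists are implemented in an EHR "to exactly match" their
published contents.

## Rounding and summary conventions

All reported ratios are rounded half away from zero to one decimal and
percents to whole numbers (`round_half_up()`); base R's round-half-to-even
produces visible disagreements with the published table cells this
machinery mirrors (e.g. 441/89 must print 5.0, 131/5473 must print 2%).

Summary blocks report, per metric: an *overall* cell — the plain sum for
count columns, the **ratio of unrounded sums** for ratio/percent columns —
and the median, minimum, maximum and range across conditions. The median
(mean of the two central order statistics for an even count) is the
primary central tendency so that one huge condition cannot dominate.
Medians and overall ratios are always computed from unrounded
per-condition values: a median of rounded ratios need not equal the
rounded median, and creation-time medians differ visibly when computed
from whole-minute display values instead of the unrounded model estimates.
For the same reason `condition_metrics()` keeps both `ext_minutes`
(unrounded) and `ext_minutes_rounded`.

The shipped reference table (`cqm2018_conditions()`) transcribes the
published per-condition counts for 10 conditions drawn from 2018 CMS
high-priority eCQMs (11 rows — pregnancy appears in a narrow and a broad
form, with the broad row excluded from summaries to avoid
double-counting). Feeding it through `condition_metrics()` and
`summarize_comparison()` reproduces the published summary cells; the
acceptance tests pin them. Three published cells are deliberately *not*
matched: the overall ratio-to-define (printed as 7.5, not reproducible as
a ratio of the printed sums, which give 7.65 — the report footnotes the
ratio-of-sums convention instead), the per-row time difference and
time-ratio columns (internally inconsistent with their own rounded
operands; we compute them from our own unrounded values), and the
term-count summary block (the published term table prints only 9 of its
10 condition rows, so its summary cells cannot be recomputed from printed
inputs; term counts for the missing condition are `NA` here).

## The time model

`fit_time_model()` is ordinary least squares (`stats::lm`) of minutes on
concept count. A `measured` flag travels with timing observations so that
stopwatch-timed builds stay distinct from model-estimated ones; in the
pipeline, a measured time always overrides the estimate, and only
unmeasured extensional builds are priced by the model at the derived-set
size. Refitting the published coefficients from published whole-minute
times is not attempted: those times are rounded, so recovery could only be
approximate. The tests instead check exact recovery from noiseless
synthetic data (to 6 decimals), agreement with closed-form normal
equations, and slope recovery within ±0.05 under 1-minute Gaussian noise
at $n = 50$ across 30 seeds.

## What the synthetic generator emulates — and what it does not

No licensed terminology can ship with a package, so every pipeline stage
is exercised on synthetic structures built by `generate_ontology()` and
friends:

* **Polyhierarchy**: concepts are attached sequentially, each to one
  uniformly-sampled existing parent (depth-capped, default `max_depth`
  8); with probability `extra_parent_probability` (default 0.15) a
  concept gains a second parent sampled among already-created concepts at
  shallower-or-equal depth. Every edge points from newer to older, so the
  graph is acyclic by construction — cheaper than rejection sampling, at
  the cost of never producing "sideways" multiple inheritance between
  same-age branches.
* **Term map**: each concept receives $1 + \mathrm{Poisson}(\mu - 1)$
  terms (default mean 12, the order of magnitude of terms-per-concept in
  real interface terminologies; a mean of 1 degenerates to exactly one
  term each). No lexical content is imitated.
* **Rules**: one subtree include at an internal node with at least 5
  descendants, plus (probability ½) one child-subtree exclusion — the
  shape real phenotype rules take.
* **Stale downloads**: `degrade_to_extensional()` drops each derived
  concept independently with probability `degradation_fraction` (default
  0.65, so a simulated downloaded list retains ~35% of the derived
  concepts, the median retention observed for 2018 downloaded sets), but
  always keeps the rule's include-root concepts, since inspected real
  downloads invariably contain their condition's root.

Every generator output is a pure function of its configuration and seed
(the caller's RNG state is saved and restored). What passing tests on
these structures show is that the *machinery* is correct — expansion
equals brute-force set algebra, metrics recompose, generator truth is
recovered. What they cannot show is fidelity to real SNOMED CT: true
hierarchies have heavy-tailed branching, semantic-tag structure, and
non-random staleness (dropped concepts cluster in recently-refined
subtrees), none of which is modelled. Degradation here is independent
per concept; real list rot is correlated.

## Problem sizes and numerical choices

The test suite runs its oracle sweeps on graphs of 150–500 nodes with 100
random rules, duality checks exhaustively at 200 nodes, parameter-recovery
loops over 30 seeds, and the degradation-recovery check on ~400-concept
hierarchies — sizes chosen so each property is checked densely while the
whole suite stays comfortably interactive. Ties in OLS are impossible by
construction (two distinct concept counts are required); degenerate
inputs (empty downloaded sets, zero intensional time, all-equal design
points) raise typed errors rather than returning infinities.

## Limitations

* Only is-a semantics; no description-logic classification — the stated
  hierarchy is taken as given.
* One snapshot at a time; no historical-association resolution when
  concepts are inactivated or moved.
* The creation-time model has a single covariate; it says nothing about
  vetting or review effort.
* No statistical testing between the two value-set styles is performed;
  the pipeline reports descriptive comparisons only.
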