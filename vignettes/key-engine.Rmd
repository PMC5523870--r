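---
title: "Dichotomous keys as data: the dichokey engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomous keys as data: the dichokey engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichokey)
```

## The model

A single-access (dichotomous) identification key is modelled as two
objects:

* a **character ontology** — each character has a kind (`binary`,
  `categorical`, `ordinal`, `quantitative`), a state list (ordered for
  ordinals) or a unit, and optional figure-legend symbols; and
* a **couplet graph** — numbered decision points, each with exactly two
  leads.  A lead carries the verbatim statement, a machine-readable
  predicate expression, and a target: either another couplet or a terminal
  taxon occurrence.

The structural invariant is that the couplet graph is a rooted binary
tree: every couplet except the root is the target of exactly one lead, so
a key with $n$ couplets has $2n$ leads and $n + 1$ terminal occurrences.
`validate_key()` enforces this and additionally warns about couplets whose
two leads cannot be told apart by any shared character, taxa that key out
more than once, and leads that name the same occurrence twice.

Terminals are *occurrences*, not taxa: one taxon may key out at several
places (polymorphic species), and infraspecific qualifiers come in two
flavours.  Subspecies are taxa in their own right (non-autonym subspecies
get their own matrix rows), while free-text *forms* ("high elevation
form") qualify an occurrence without creating a taxon.  Species-level
counting collapses both.

## Predicates

Lead statements are encoded in a small expression language: a conjunction
of clauses separated by `;`, each clause a disjunction of atoms separated
by `|`.  Atoms compare one character against a state (`=`, `!=`), a state
set (`in {a,b}`), a number (`<`, `<=`, `>`, `>=`) or an interval
(`in a..b`, `in a..`, `in ..b`).  Disjunction exists because real keys
contain genuine "and/or" leads; conjunction because most leads stack
several observations.

Transcription of printed measurements follows fixed rules rather than
case-by-case judgement: "less than $x$" becomes the strict `<x`; a
printed range "$a$–$b$" becomes the closed interval `a..b`; "$a$–$b$+"
keeps only the lower bound (`a..`); "ca. $x$" becomes
`0.9x..1.1x`.  Closed-versus-open bookkeeping is kept exactly: interval
ends written with `..` are closed, and open bounds arise only from strict
comparisons.

```{r}
key <- load_fixture("syagrus_key")
parse_predicates("lamina_thickness<0.25", key)[[1]][[1]]$op
```

## The packaged fixture

The shipped key is a complete transcription of a published 71-couplet
anatomical key to the palm genus *Syagrus*, built on leaflet-margin
cross-section characters (fiber bundle extent and shape, minor vein
placement, hypodermis structure, lamina thickness) plus a handful of
non-anatomical characters (stem habit, rachis length, leaflet
dimensions).  The statements are verbatim; the 54-character ontology and
the coded predicates are this package's editorial encoding, with every
judgement call recorded in the `NOTES.md` file shipped next to the data
(see `attr(load_fixture("syagrus_key"), "notes")`).

```{r}
validate_key(key)
```

The fixture resolves 72 terminal occurrences into 65 species and two
non-autonym subspecies; four species key out more than once.  Every
couplet of the transcription keeps its two leads mutually exclusive on at
least one shared character (or through a fully contradicted disjunction),
which is what makes the traversal and inversion guarantees below hold on
the real key and not just on synthetic ones.

## Traversal semantics

`traverse_key()` evaluates each lead three-valuedly: a lead *matches* when
every clause evaluates true, *fails* when any clause evaluates false, and
is *undetermined* when an involved character is unanswered.  In `strict`
mode exactly one matching lead is followed; both leads matching is
reported as a `contradiction` with the couplet recorded (ties are never
broken silently); no matching lead stops with `ambiguous` and the couplet
in `unresolved`, which is what an interactive front-end needs in order to
prompt with the couplet's verbatim statements.  `explore` mode descends
every non-failing lead and returns the union of reachable terminals —
the field situation of a partial specimen.  An empty observation explores
to all 72 occurrences; a fully answered path identifies uniquely.

## Inverting the key into a matrix

`induce_matrix()` propagates predicates along every root-to-terminal
path.  At occurrence level the constraint on a character is the
intersection of everything the path asserts about it; state sets
intersect set-wise and quantitative constraints use a small interval
algebra whose unions are kept canonical (sorted, disjoint, open/closed
ends preserved).  Three design points deserve justification:

* **No complement inference.**  A lead's constraints come only from its
  own statement; the negation of the sibling lead is *not* added.
  Printed alternates are worded independently and are frequently not
  logical complements, so inferring complements would fabricate data.
* **Disjunctions stay disjunctions.**  A clause spanning several
  characters ("attached to both surfaces and/or hairy trichomes") cannot
  be reduced to per-character constraints; it is stored on the occurrence
  and honoured by the matcher and by `sample_observation()`.  The
  *S. itapebiensis* path is the worked example: couplet 53 admits it only
  through the trichome disjunct, because couplet 54 pins the vein
  attachment to the other side.
* **Unions at taxon level.**  A taxon's constraint is the union of its
  occurrences' constraints; the polymorphic flag is set when those are
  pairwise disjoint (the taxon sits on both sides of some couplet).  If
  any occurrence leaves a character unconstrained, the taxon-level result
  is unconstrained — a union with "anything" asserts nothing, and
  defaulting it would again fabricate data.  Occurrence-level rows are
  retained so the sharper statement is never lost.

Contradictory paths (empty intersections) are reported in
`$contradictions`, never dropped; the fixture has none.  The soundness
property — any assignment satisfying an occurrence's constraints
traverses back to that occurrence — is checked exhaustively on the
fixture and on generated keys.

## Polyclave matching and character selection

`polyclave_match()` turns the matrix into a multi-access key: the
mismatch count of a taxon is the number of observed characters whose
value falls outside the taxon's constraint, unconstrained characters are
always compatible, and polymorphic taxa accept any value inside their
union.  That last choice makes identification conservative: a variable
species is shortlisted rather than excluded on the strength of one
variable character.  All taxa within the tolerance are ranked by
mismatches, ties alphabetical.

`next_best_character()` scores unanswered characters by expected
information gain.  For categorical-like characters the answer space is
the state list; for quantitative characters it is the partition of the
line induced by the candidates' constraint endpoints, probing each
endpoint and each gap midpoint and merging answers no candidate can
distinguish (which also absorbs degenerate point intervals).  With
$C_a$ the candidates compatible with answer $a$ and
$p(a) = |C_a| / \sum_{a'} |C_{a'}|$,

$$\mathrm{gain}(c) = \log_2 |C| - \sum_a p(a) \log_2 |C_a|,$$

maximised with ties broken by character id.  Because constraints may
overlap, the gain is computed from compatibility counts rather than a
true partition; it is clipped at twelve decimal places to keep the
non-negativity invariant safe from floating-point noise.  A 2/2 split of
four candidates by a binary character yields exactly 1 bit.

## Clade and region congruence

The congruence module asks how well the key's *phenetic* branches line up
with reference (molecular) clades.  `crown_branch()` returns the deepest
lead subtree containing every group member (membership via any
occurrence; `ROOT` when only the whole key qualifies; co-deepest labels
all reported — possible only through multi-entry taxa).
`branch_purity()` gives species-level precision and recall of a named
branch against a group, and `region_homogeneity()` the fraction of branch
species whose region set meets the branch's modal region (ties broken
alphabetically, species without region data excluded from the
denominator and reported).

On the packaged tables the four former-*Lytocaryum* species crown exactly
at branch 53 with precision = recall = 1; the Rain-Forest molecular
members recall 7/8 in branch 57′ (*S. ruschiana* keys out elsewhere); the
Eastern Brazilian molecular clade spans both sides of couplet 1 and
crowns at the root.  The clade table keeps two membership columns because
the source table distinguishes them: `analyzed` marks members of the
molecular clade itself, `in_branch` the full similar-branch lists;
`clade_members()` switches between them.

## The synthetic generator

`generate_key()` is first-class, tested code, not a fixture: it produces
a random rooted binary key with a known truth table so that engine
properties can be checked against ground truth.  Each couplet splits on a
character unused on its path (so paths are always consistent) with
mutually exclusive predicates — a random bipartition of the state list,
or a numeric threshold with `<`/`>=` leads.  Split sizes are biased
toward balance with a configurable `skew` (0 gives perfectly balanced
keys; larger values exercise deep chains like the fixture's couplets
51→71), and splits are capped so the remaining characters always suffice,
making "insufficient characters" detectable up front
(`n_characters ≥ ⌈log₂ n_taxa⌉).  About 30 % of characters are
quantitative by default so the interval machinery is exercised in every
round-trip test.  All randomness flows through one seeded stream, and the
caller's RNG state is restored afterwards.

What the generator does *not* emulate: observation error, missing data
patterns, correlated characters, polymorphic taxa and disjunctive
leads — those are exactly the features the *Syagrus* fixture contributes,
which is why the test suite always runs both.  Passing the synthetic
properties therefore shows the engine is correct on clean keys; passing
the fixture checks shows the encoding conventions carry a real key.

## Numerical and edge-case choices

* Interval emptiness: `lo > hi`, or a point interval with an open end.
  Adjacent intervals merge only when at least one touching end is closed.
* Branch labels accept both the ASCII apostrophe and the Unicode prime
  (`57'` ≡ `57′`); output uses the ASCII form.
* Canonical key files: metadata lines first, couplets in numeric order
  with lead *a* before *b*, predicates re-rendered in a single canonical
  spelling — writing is byte-stable under re-parsing.
* Newick export sanitises occurrence labels (spaces and parentheses to
  underscores) since those characters are structural in Newick; every
  branch length is 1 and internal nodes are labelled `c<couplet>`.
* Observation values: `"?"` in files and `NA` in R both mean an explicit
  unknown, which evaluates predicates to *undetermined*, never to false.

## Problem sizes and limitations

The property-based tests run 20 generated keys per property at up to 25
taxa and 25 characters, plus exhaustive checks over all 72 fixture
occurrences; the whole suite completes in well under a minute.  Known
limitations: no probabilistic (Bayesian) identification — matching is
set/interval logic; no character cost or reliability weighting in the
gain criterion; no ancestral-state inference on the key tree; and the
clade congruence is deliberately limited to crown/purity/homogeneity
measures — the key is a phenetic object, and the package does not pretend
it is a phylogeny.
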