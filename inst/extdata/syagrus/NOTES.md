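# Transcription notes — Syagrus leaflet-margin anatomy key fixture

The couplet statements in `key.tsv` are transcribed verbatim from the
published key; the coded predicates and the 54-character ontology in
`characters.tsv` are an editorial encoding of those statements.  Rules and
judgement calls:

- Deterministic numeric transcription: "less than x" -> strict `<x`;
  printed ranges "a–b" -> closed intervals `a..b`; "a–b+" -> `a..` (lower
  bound only); "ca. x" -> `0.9x..1.1x` (couplet 59: ca. 100 cm -> 90..110).
  Under these rules the couplet-59 rachis intervals [90,110] and [167,440]
  are disjoint, which keeps the two leads mutually exclusive.
- "S. caerulescen" at couplet 14 is a typographical error in the source;
  transcribed as *S. caerulescens*.
- The couplet-22 terminal *S. comosa* is typeset unlike other terminals in
  the source; it is treated as a normal terminal.
- Couplet 51, alternate lead, reads "not usually opposite adaxial minor
  veins" where the first lead contrasts adaxial fiber bundles with
  *abaxial* minor veins; the statement is transcribed as printed and the
  coded predicate uses the single opposition character `adfb_opposite_abv`.
- Couplet 68, alternate lead, reads "along the abaxial surface" where the
  first lead contrasts the *adaxial* surface; transcribed as printed, coded
  on `adaxial_surface_fiber_abundance`.
- Qualitative abundance words (none / few / occasional / many) are coded as
  one ordinal scale per anatomical structure, because couplets 9, 11 and 30
  contrast them directly.
- Leaflet dimension statements such as "24–34 × 2–3 cm" (couplet 31) are
  coded as two characters (length, width).
- Elevation forms ("high elevation form", "low elevation form") are
  occurrence qualifiers of *S. harleyi*, not distinct taxa; the high
  elevation form keys out twice (couplets 27 and 52'), matching the
  discussion that it may also key out early when abaxial minor veins are
  read as mesophyll veins.
- `clades.tsv` transcribes the published clade/branch comparison table.
  `analyzed` = 1 marks members of the molecular clade (column 2 of the
  table); `in_branch` = 1 marks taxa listed in the similar key branch
  (column 4).  Asterisks in the extracted table text are garbled in places
  and were reconciled against column 2.  *S. ruschiana* (molecular Rain
  Forest member) does not key out in branch 57' — it terminates at couplet
  34 — and *S. flexuosa* (molecular cluster-stemmed member) keys out in
  branch 57'; both are recorded with `in_branch` = 0 under their molecular
  clade rows.
- The published branch-18 species list omits *S. evansiana* although it
  keys out under couplet 25'; the key itself is authoritative here, so
  `branch_membership(key, "18")` has 14 species where the table prints 13.
- `regions.tsv` is built from the region column of the same table (the
  per-taxon region codes of the key-outline figures exist only as colored
  letters in the images).  Compound entries are split ("E. & Central
  Brazil" -> Eastern Brazil + Central Brazil; "Andes/Amazon" -> Andes +
  Amazon); Brazilian state abbreviations in parentheses are dropped.
  *S. petraea* is kept as "Bolivia" as printed.  Species outside the table
  have no region row and are reported as missing by `read_regions()`.
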