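test_that("predicate DSL parses the documented forms", {
  key <- syagrus()
  p <- parse_predicates("lamina_thickness<0.25", key)
  expect_length(p, 1L)
  expect_equal(p[[1]][[1]]$op, "lt")
  expect_equal(p[[1]][[1]]$value, 0.25)

  p <- parse_predicates("abaxial_minor_vein_count in 9..", key)
  expect_equal(p[[1]][[1]]$op, "in_interval")
  expect_equal(p[[1]][[1]]$value, c(9, Inf))

  p <- parse_predicates("leaf_rachis_length in ..99", key)
  expect_equal(p[[1]][[1]]$value, c(-Inf, 99))

  p <- parse_predicates("adaxial_minor_veins in {absent,occasional}", key)
  expect_equal(p[[1]][[1]]$op, "in_set")

  # conjunction and disjunction structure
  p <- parse_predicates("most_veins_attachment=both|abaxial_trichomes=present;stem_habit=aerial",
                        key)
  expect_length(p, 2L)      # two clauses
  expect_length(p[[1]], 2L) # first clause has two disjuncts
})

test_that("predicate DSL rejects malformed and ill-typed input", {
  key <- syagrus()
  expect_error(parse_predicates("x<<3",
    list(x = dk_character("x", kind = "quantitative", units = "mm"))),
    "offset 2")
  expect_error(parse_predicates("wing_color=red", key), "unknown character")
  expect_error(parse_predicates("anatomy_symmetry<mirrored", key),
               "not allowed")
  expect_error(parse_predicates("lamina_thickness in {a,b}", key),
               "not allowed")
  expect_error(parse_predicates("lamina_thickness in 5..2", key),
               "lower bound")
  expect_error(parse_predicates("adaxial_minor_veins=purple", key),
               "unknown state")
})

test_that("predicate render/parse is an identity on every fixture lead", {
  key <- syagrus()
  for (cid in names(key$couplets)) for (slot in c("a", "b")) {
    cl <- key$couplets[[cid]]$leads[[slot]]$clauses
    txt <- render_predicates(cl)
    expect_identical(render_predicates(parse_predicates(txt, key)), txt)
  }
})

test_that("key files round-trip byte-stably and preserve statistics", {
  key <- syagrus()
  t1 <- write_key(key)
  key2 <- parse_key(t1$characters_text, t1$couplets_text)
  t2 <- write_key(key2)
  expect_identical(t1$characters_text, t2$characters_text)
  expect_identical(t1$couplets_text, t2$couplets_text)
  expect_identical(validate_key(key)$stats, validate_key(key2)$stats)
})

test_that("synthetic keys round-trip through the file format", {
  for (s in c(7, 11, 23)) {
    b <- generate_key(12, 8, seed = s)
    t1 <- write_key(b$key)
    key2 <- parse_key(t1$characters_text, t1$couplets_text)
    t2 <- write_key(key2)
    expect_identical(t1$couplets_text, t2$couplets_text)
    expect_identical(key_taxa(b$key, "occurrences"),
                     key_taxa(key2, "occurrences"))
  }
})

test_that("unicode form labels survive the round trip", {
  k <- parse_key(toy_characters, paste(
    "couplet\tslot\tstatement\tpredicates\ttarget",
    "1\ta\tred\tcolor=red\tT:Açaí dwarf|très petit#1",
    "1\tb\tblue\tcolor=blue\tT:B#1",
    sep = "\n"))
  t1 <- write_key(k)
  k2 <- parse_key(t1$characters_text, t1$couplets_text)
  expect_identical(key_taxa(k, "occurrences"), key_taxa(k2, "occurrences"))
})

test_that("parser rejects duplicate leads and unknown characters", {
  expect_error(parse_key(toy_characters, paste(
    "couplet\tslot\tstatement\tpredicates\ttarget",
    "1\ta\tred\tcolor=red\tT:A#1",
    "1\ta\tred again\tcolor=red\tT:B#1",
    sep = "\n")), "duplicate lead")
  expect_error(parse_key(toy_characters, paste(
    "couplet\tslot\tstatement\tpredicates\ttarget",
    "1\ta\tx\twing_color=red\tT:A#1",
    "1\tb\ty\tcolor=blue\tT:B#1",
    sep = "\n")), "unknown character")
})

test_that("Newick export matches the couplet graph", {
  expect_identical(export_newick(pair_key()), "(A#1:1,B#1:1)c1;")

  key <- syagrus()
  tr <- ape::read.tree(text = export_newick(key))
  expect_equal(length(tr$tip.label), 72L)
  expect_equal(tr$Nnode, 71L)
  # clade below every internal node c<id> agrees with the subtree of
  # couplet <id> (both leads)
  sanitize <- function(x) gsub("_+", "_", gsub("[^A-Za-z0-9#.-]+", "_", x))
  for (i in seq_len(tr$Nnode)) {
    id <- as.integer(sub("^c", "", tr$node.label[i]))
    tips <- ape::extract.clade(tr, node = length(tr$tip.label) + i)$tip.label
    expect_setequal(tips,
      sanitize(dichokey:::subtree_occurrences(key, id)))
  }
})

test_that("Newick leaf count equals occurrence count on random keys", {
  for (s in 1:20) {
    b <- generate_key(sample(2:25, 1), 25, seed = 100 + s)
    tr <- ape::read.tree(text = export_newick(b$key))
    expect_equal(length(tr$tip.label),
                 length(key_taxa(b$key, "occurrences")))
  }
})

test_that("observation, clade and region readers work", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("char_id\tvalue\nlamina_thickness\t0.2\nstem_habit\t?", f)
  obs <- read_observations(f, syagrus())
  expect_equal(obs$lamina_thickness, 0.2)
  expect_true(is.na(obs$stem_habit))

  clades <- load_fixture("clades")
  expect_length(unique(clades$clade), 3L)
  expect_length(attr(clades, "unmatched"), 0L)

  regions <- load_fixture("regions")
  expect_true(all(c("taxon", "region_codes") %in% names(regions)))
  # every fixture species is present or explicitly reported missing
  expect_setequal(c(regions$taxon, attr(regions, "missing")),
                  key_taxa(syagrus(), "species"))
})
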