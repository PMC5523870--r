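test_that("induced matrix reproduces printed quantitative thresholds", {
  key <- syagrus()
  mt <- induce_matrix(key, "taxon")
  mo <- induce_matrix(key, "occurrence")

  lam <- constraint_of(mt, "S. macrocarpa", "lamina_thickness")
  expect_equal(lam$intervals$hi, 0.25)
  expect_true(lam$intervals$hi_open)         # strictly less than 0.25 mm

  abv <- constraint_of(mo, "S. rupicola#1", "abaxial_minor_vein_count")
  expect_equal(abv$intervals$lo, 9)
  expect_false(abv$intervals$lo_open)        # 9-12+ is closed below

  rac <- constraint_of(mo, "S. romanzoffiana#2", "leaf_rachis_length")
  expect_equal(c(rac$intervals$lo, rac$intervals$hi), c(167, 440))
})

test_that("polymorphic taxa get the union of their occurrence constraints", {
  mt <- induce_matrix(syagrus(), "taxon")
  kel <- constraint_of(mt, "S. kellyana", "adaxial_fb_extent")
  expect_true(kel$polymorphic)
  # occurrences sit on opposite sides of couplet 1
  expect_true(all(c("over_one_third", "absent") %in% kel$allowed))
  # a character mentioned for only one occurrence stays unconstrained
  expect_identical(constraint_of(mt, "S. romanzoffiana", "leaf_rachis_length"),
                   "unconstrained")
})

test_that("characters never mentioned on a path stay unconstrained", {
  m <- induce_matrix(toy_key(), "taxon")
  expect_identical(constraint_of(m, "B", "size"), "unconstrained")
  expect_identical(constraint_of(m, "B", "spots"), "unconstrained")
  expect_equal(constraint_of(m, "A", "size")$intervals$hi, 5)
  expect_error(constraint_of(m, "Z", "size"), "unknown")
  expect_error(constraint_of(m, "A", "wingspan"), "unknown character")
})

test_that("taxon-level export has species plus non-autonym subspecies rows", {
  mt <- induce_matrix(syagrus(), "taxon")
  expect_length(mt$rows, 67L)   # 65 species + 2 subspecies rows
  expect_true("S. graminifolia" %in% names(mt$rows))
  expect_true("S. graminifolia subsp. cabraliensis" %in% names(mt$rows))
  expect_false("S. harleyi (high elevation form)" %in% names(mt$rows))
  expect_equal(nrow(mt$contradictions), 0L)
})

test_that("matrix CSV round-trips every constraint", {
  key <- syagrus()
  mt <- induce_matrix(key, "taxon")
  mt2 <- parse_matrix_csv(export_matrix(mt), key)
  expect_setequal(names(mt2$rows), names(mt$rows))
  for (r in names(mt$rows)) {
    expect_setequal(names(mt2$rows[[r]]), names(mt$rows[[r]]))
    for (ch in names(mt$rows[[r]]))
      expect_identical(format(mt2$rows[[r]][[ch]]),
                       format(mt$rows[[r]][[ch]]))
  }
})

test_that("induce->traverse soundness holds on every fixture occurrence", {
  key <- syagrus()
  mo <- induce_matrix(key, "occurrence")
  for (r in names(mo$rows)) {
    tr <- traverse_key(key, sample_observation(mo, r), "strict")
    expect_equal(tr$status, "identified")
    expect_equal(tr$outcomes, r)
  }
})

test_that("disjunctive clauses propagate as clauses, not forced predicates", {
  mo <- induce_matrix(syagrus(), "occurrence")
  # S. itapebiensis needs the trichome disjunct of couplet 53 to be true,
  # because couplet 54 pins most_veins_attachment to one_surface
  obs <- sample_observation(mo, "S. itapebiensis#1")
  expect_equal(obs$most_veins_attachment, "one_surface")
  expect_equal(obs$abaxial_trichomes, "present")
  expect_gte(length(mo$disjunctions[["S. itapebiensis#1"]]), 1L)
})

test_that("interval algebra canonicalises, intersects and unions correctly", {
  a <- dichokey:::iv_canonical(dichokey:::iv(c(1, 2), c(3, 5)))
  expect_equal(nrow(a), 1L)      # overlapping pieces merge
  expect_equal(c(a$lo, a$hi), c(1, 5))
  b <- dichokey:::iv_intersect(dichokey:::iv(-Inf, 0.25, TRUE, TRUE),
                               dichokey:::iv(0.1, 10))
  expect_equal(c(b$lo, b$hi), c(0.1, 0.25))
  expect_true(b$hi_open)
  expect_false(dichokey:::iv_contains(b, 0.25))
  expect_true(dichokey:::iv_contains(b, 0.1))
  # disjoint unions stay apart; touching open/closed ends merge
  u <- dichokey:::iv_union(dichokey:::iv(0, 1), dichokey:::iv(2, 3))
  expect_equal(nrow(u), 2L)
  u2 <- dichokey:::iv_union(dichokey:::iv(0, 1, FALSE, TRUE),
                            dichokey:::iv(1, 2))
  expect_equal(nrow(u2), 1L)
  # empty when bounds cross or a point is open
  expect_equal(nrow(dichokey:::iv_canonical(dichokey:::iv(2, 1))), 0L)
  expect_equal(nrow(dichokey:::iv_canonical(dichokey:::iv(1, 1, TRUE, FALSE))),
               0L)
})
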