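test_that("the former Lytocaryum species crown at branch 53 with full purity", {
  key <- syagrus()
  expect_identical(crown_branch(key, lytocaryum_group), "53")
  p <- branch_purity(key, lytocaryum_group, "53")
  expect_equal(p$precision, 1.0)
  expect_equal(p$recall, 1.0)
})

test_that("the Eastern Brazilian molecular clade spans both root branches", {
  key <- syagrus()
  eb <- c("S. cearensis", "S. coronata", "S. glaucescens", "S. kellyana",
          "S. oleracea")
  expect_identical(crown_branch(key, eb), "ROOT")
})

test_that("singleton groups crown at their terminal's parent lead", {
  key <- syagrus()
  expect_identical(crown_branch(key, "S. macrocarpa"), "12")
  # multi-entry species: deepest lead containing any occurrence
  expect_identical(crown_branch(key, "S. kellyana"), "26")
  expect_error(crown_branch(key, "S. nowhere"), "no member")
})

test_that("Rain Forest molecular members recall 7/8 in branch 57'", {
  key <- syagrus()
  clades <- load_fixture("clades")
  rf <- clade_members(clades, "Rain Forest", "molecular", branch = "57'")
  expect_length(rf, 8L)
  p <- branch_purity(key, rf, "57'")
  expect_equal(p$recall, 7 / 8)
  expect_false("S. ruschiana" %in% p$overlap)
  # any group recalls fully at the root
  expect_equal(branch_purity(key, rf, "ROOT")$recall, 1.0)
})

test_that("clade fixture normalises to exactly three clades", {
  clades <- load_fixture("clades")
  expect_setequal(unique(clades$clade),
                  c("Rain Forest", "Eastern Brazilian", "Cluster stemmed"))
  expect_true("Rain Forest/ Lytocaryum" %in% clades$clade_raw)
  # branch 43' list is fully molecular and pure
  m43 <- clade_members(clades, "Eastern Brazilian", "branch", branch = "43'")
  expect_setequal(m43, c("S. kellyana", "S. oleracea", "S. cearensis"))
  p <- branch_purity(syagrus(), m43, "43'")
  expect_equal(p$precision, 1.0)
  expect_equal(p$recall, 1.0)
})

test_that("region homogeneity is 1 on branch 53 and bounded everywhere", {
  key <- syagrus()
  regions <- load_fixture("regions")
  rh <- region_homogeneity(key, regions, "53")
  expect_equal(rh$homogeneity, 1.0)
  expect_equal(rh$modal_region, "Atlantic Forest")
  for (id in c("2", "18", "37", "57'", "1'")) {
    h <- region_homogeneity(key, regions, id)$homogeneity
    expect_true(is.nan(h) || (h >= 0 && h <= 1))
  }
  # two disjoint singleton regions -> 0.5
  toy_regions <- data.frame(taxon = c("A", "B"),
                            region_codes = c("North", "South"))
  expect_equal(region_homogeneity(pair_key(), toy_regions, "ROOT")$homogeneity,
               0.5)
})

test_that("crowns are unique along root-to-leaf chains", {
  key <- generate_key(12, 8, seed = 9)$key
  occ <- key_taxa(key, "occurrences")[1]
  sp <- sub("#\\d+$", "", occ)
  cr <- crown_branch(key, sp)
  expect_length(cr, 1L)   # single-occurrence taxon: one crown only
})

test_that("congruence report aggregates all table rows deterministically", {
  key <- syagrus()
  rep1 <- congruence_report(key, load_fixture("clades"),
                            load_fixture("regions"))
  rep2 <- congruence_report(key, load_fixture("clades"),
                            load_fixture("regions"))
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 5L)
  expect_true(all(rep1$precision >= 0 & rep1$precision <= 1))
  expect_true(all(rep1$recall >= 0 & rep1$recall <= 1))
  r53 <- rep1[rep1$branch == "53", ]
  expect_equal(r53$region_homogeneity, 1.0)
})
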