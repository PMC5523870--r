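test_that("strict traversal identifies S. macrocarpa along couplets 1,2,3,10,12", {
  key <- syagrus()
  obs <- list(adaxial_fb_extent = "over_one_third",
              mesophyll_minor_veins = "few",
              marginal_vein_exaggerated = "small",
              adaxial_minor_veins = "absent",
              lamina_thickness = 0.2)
  tr <- traverse_key(key, obs, "strict")
  expect_equal(tr$status, "identified")
  expect_equal(tr$outcomes, "S. macrocarpa#1")
  expect_equal(tr$path$couplet, c(1L, 2L, 3L, 10L, 12L))
})

test_that("explore mode with an empty observation reaches all 72 occurrences", {
  tr <- traverse_key(syagrus(), list(), "explore")
  expect_equal(tr$status, "ambiguous")
  expect_length(tr$outcomes, 72L)
})

test_that("strict mode halts at the first unanswerable couplet", {
  tr <- traverse_key(syagrus(), list(adaxial_fb_extent = "over_one_third"),
                     "strict")
  expect_equal(tr$status, "ambiguous")
  expect_equal(tr$unresolved, 2L)
  expect_equal(tr$path$couplet, 1L)
})

test_that("contradictory observations are reported, not resolved", {
  k <- toy_key()
  # forge a key where both leads can be true for one observation
  both <- parse_key(toy_characters, paste(
    "couplet\tslot\tstatement\tpredicates\ttarget",
    "1\ta\tsmallish\tsize<7\tT:A#1",
    "1\tb\tlargish\tsize>5\tT:B#1",
    sep = "\n"))
  tr <- traverse_key(both, list(size = 6), "strict")
  expect_equal(tr$status, "contradiction")
  expect_equal(tr$unresolved, 1L)
  # and an observation failing both leads is a dead end
  tr2 <- traverse_key(k, list(color = "red", size = NA), "strict")
  expect_equal(tr2$status, "ambiguous")
  expect_error(traverse_key(k, list(wingspan = 1)), "unknown character")
})

test_that("published paths are read off the fixture", {
  key <- syagrus()
  expect_equal(path_to(key, "S. cardenasii#1"),
               c(1L, 37L, 46L, 51L, 53L, 57L, 60L, 70L, 71L))
  expect_equal(path_to(key, "S. allagopteroides#1"), c(1L, 2L, 3L, 4L, 5L))
  expect_equal(path_to(toy_key(), "B#1"), 1L)
  expect_error(path_to(key, "S. imaginaria#1"), "unknown occurrence")
})

test_that("branch membership reproduces the published branch lists", {
  key <- syagrus()
  expect_setequal(branch_membership(key, "53", "species"), lytocaryum_group)
  expect_setequal(branch_membership(key, "57'", "species"),
    c("S. amara", "S. orinocensis", "S. stenopetala", "S. inajai",
      "S. botryophora", "S. stratincola", "S. cocoides", "S. flexuosa",
      "S. vermicularis", "S. pseudococos", "S. smithii", "S. sancona",
      "S. cardenasii"))
  # unicode prime accepted as slot mark
  expect_identical(branch_membership(key, "57′", "species"),
                   branch_membership(key, "57'", "species"))
  expect_setequal(union(branch_membership(key, "1", "species"),
                        branch_membership(key, "1'", "species")),
                  key_taxa(key, "species"))
  expect_setequal(branch_membership(key, "ROOT", "occurrences"),
                  key_taxa(key, "occurrences"))
  expect_error(branch_membership(key, "999"), "unknown branch")
})

test_that("subtrees conserve and partition occurrences at every couplet", {
  check <- function(key) {
    for (id in as.integer(names(key$couplets))) {
      a <- branch_membership(key, as.character(id), "occurrences")
      b <- branch_membership(key, paste0(id, "'"), "occurrences")
      expect_length(intersect(a, b), 0L)
      parent <- sort(c(a, b), method = "radix")
      whole <- dichokey:::subtree_occurrences(key, id)
      expect_identical(parent, sort(whole, method = "radix"))
    }
    # ancestors contain descendants
    occs <- key_taxa(key, "occurrences")
    p <- path_to(key, occs[1])
    sets <- lapply(p, function(id) dichokey:::subtree_occurrences(key, id))
    for (i in seq_along(sets)[-1])
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  check(syagrus())
  check(generate_key(16, 8, seed = 3)$key)
})

test_that("key metrics are consistent on fixture and random keys", {
  m <- key_metrics(syagrus())
  expect_gte(m$min_depth, 4)
  expect_true(m$min_depth <= m$mean_depth && m$mean_depth <= m$max_depth)
  expect_equal(m$expected_couplets, mean(m$depths))
  expect_equal(unname(m$subtree_sizes["1"]), 72)

  # perfectly balanced 8-taxon key has all depths 3
  b <- generate_key(8, 3, seed = 5, skew = 0)
  expect_true(all(key_metrics(b$key)$depths == 3))

  for (s in 1:20) {
    mm <- key_metrics(generate_key(sample(2:20, 1), 20, seed = 200 + s)$key)
    expect_true(mm$min_depth <= mm$mean_depth && mm$mean_depth <= mm$max_depth)
  }
})
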