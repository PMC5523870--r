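test_that("partial observations shortlist the right fixture species", {
  mt <- induce_matrix(syagrus(), "taxon")
  res <- polyclave_match(mt, list(lamina_thickness = 0.2,
                                  adaxial_minor_veins = "absent",
                                  mesophyll_minor_veins = "few"), 0)
  expect_true("S. macrocarpa" %in% res$taxon)
  expect_true(all(res$mismatches == 0))
})

test_that("tolerance is monotone: candidates(t) grows with t", {
  mt <- induce_matrix(syagrus(), "taxon")
  obs <- list(adaxial_fb_extent = "over_one_third",
              mesophyll_minor_veins = "throughout",
              stem_habit = "aerial", lamina_thickness = 0.3)
  prev <- character(0)
  for (t in 0:4) {
    cur <- polyclave_match(mt, obs, t)$taxon
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a taxon always matches its own constraint centroid at tolerance 0", {
  mt <- induce_matrix(syagrus(), "taxon")
  for (r in names(mt$rows)) {
    obs <- sample_observation(mt, r)
    expect_true(r %in% polyclave_match(mt, obs, 0)$taxon)
  }
})

test_that("full correct observations identify exactly the true taxon, 20 seeds", {
  for (s in 1:20) {
    b <- generate_key(sample(4:20, 1), 20, seed = 300 + s)
    m <- induce_matrix(b$key, "taxon")
    for (tx in rownames(b$truth)) {
      res <- polyclave_match(m, dichokey:::truth_observation(b, tx), 0)
      expect_identical(res$taxon, tx)
    }
  }
})

test_that("a 2/2 binary split of four candidates gains exactly one bit", {
  m <- induce_matrix(quad_key(), "taxon")
  nb <- next_best_character(m, c("A", "B", "C", "D"))
  expect_equal(nb$character, "c1")
  expect_equal(nb$gain, 1.0)
  # an unused character distinguishes nothing
  expect_equal(unname(nb$gains["c4"]), 0)
})

test_that("gain is non-negative and zero iff nothing separates", {
  for (s in 1:10) {
    b <- generate_key(sample(4:16, 1), 16, seed = 400 + s)
    m <- induce_matrix(b$key, "taxon")
    cand <- sample(names(m$rows), max(2, length(m$rows) %/% 2))
    nb <- next_best_character(m, cand)
    expect_true(all(nb$gains >= 0))
  }
  # all candidates identical w.r.t. every character -> explicit none result
  m <- induce_matrix(quad_key(), "taxon")
  nb <- next_best_character(m, c("A", "B"), answered = c("c1", "c2"))
  expect_false(nb$informative)
  expect_identical(nb$character, NA_character_)
  expect_equal(nb$gain, 0)
})

test_that("quantitative answer spaces come from candidate endpoints", {
  m <- induce_matrix(toy_key(), "taxon")
  nb <- next_best_character(m, c("A", "C"))
  expect_equal(nb$character, "size")  # the only separating character
  expect_gt(nb$gain, 0)
})

test_that("greedy questioning identifies every taxon within key depth", {
  for (s in 1:20) {
    b <- generate_key(sample(4:16, 1), 16, seed = 500 + s)
    m <- induce_matrix(b$key, "taxon")
    depth <- key_metrics(b$key)$max_depth
    for (tx in rownames(b$truth)) {
      g <- greedy_identify(m, dichokey:::truth_observation(b, tx))
      expect_identical(g$taxon, tx)
      expect_lte(length(g$asked), depth)
    }
  }
})

test_that("ranking is ascending by mismatches with alphabetical ties", {
  mt <- induce_matrix(syagrus(), "taxon")
  res <- polyclave_match(mt, list(stem_habit = "aerial",
                                  lamina_thickness = 0.5), 3)
  expect_true(!is.unsorted(res$mismatches))
  for (k in unique(res$mismatches)) {
    grp <- res$taxon[res$mismatches == k]
    expect_identical(grp, sort(grp, method = "radix"))
  }
})
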