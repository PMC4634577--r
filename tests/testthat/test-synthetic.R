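test_that("generation is deterministic under a fixed seed", {
  cfg <- syntheticConfig(seed = 42, nFamilies = 3, sitesPerFamily = 2)
  a <- makeSites(cfg)
  b <- makeSites(cfg)
  expect_identical(a$truth, b$truth)
  for (k in seq_along(a$sites)) {
    expect_identical(a$sites[[k]]@residues[[1]]@atoms,
                     b$sites[[k]]@residues[[1]]@atoms)
    expect_identical(goTerms(a$sites[[k]]), goTerms(b$sites[[k]]))
  }
  expect_identical(a$ontology@edges, b$ontology@edges)
  # different seed, different coordinates
  c <- makeSites(syntheticConfig(seed = 43, nFamilies = 3,
                                 sitesPerFamily = 2))
  expect_false(identical(a$sites[[1]]@residues[[1]]@atoms,
                         c$sites[[1]]@residues[[1]]@atoms))
})

test_that("zero pose noise gives exact within-family poses and distinct families", {
  sim <- makeSites(syntheticConfig(seed = 13, nFamilies = 3,
                                   sitesPerFamily = 2, poseNoise = 0,
                                   residuesPerSite = c(3, 4),
                                   multiSFFraction = 0))
  s <- sim$sites
  fam <- sim$truth$family
  for (f in unique(fam)) {
    idx <- which(fam == f)
    cmp <- compareSites(s[[idx[1]]], s[[idx[2]]], rmsdCutoff = 1)
    expect_equal(matchSize(bestMatch(cmp)), length(s[[idx[1]]]))
    expect_lt(matchRmsd(bestMatch(cmp)), 1e-6)
  }
  # between families, nothing superposes anywhere near zero
  cross <- compareSites(s[[1]], s[[3]], rmsdCutoff = 8)
  if (!is.null(bestMatch(cross))) {
    expect_gt(matchRmsd(bestMatch(cross)), 0.05)
  }
})

test_that("within-family RMSD under noise matches a Monte-Carlo expectation", {
  sigma <- 0.3
  sim <- makeSites(syntheticConfig(seed = 19, nFamilies = 4,
                                   sitesPerFamily = 2, poseNoise = sigma,
                                   residuesPerSite = c(3, 3),
                                   multiSFFraction = 0))
  s <- sim$sites
  fam <- sim$truth$family
  obs <- vapply(unique(fam), function(f) {
    idx <- which(fam == f)
    cmp <- compareSites(s[[idx[1]]], s[[idx[2]]], rmsdCutoff = 3)
    m <- bestMatch(cmp)
    expect_equal(matchSize(m), length(s[[idx[1]]]))
    matchRmsd(m)
  }, numeric(1))
  # Monte-Carlo oracle: two independently noised copies of an N-point cloud,
  # optimally fitted (bio3d), same per-coordinate sigma
  N <- sum(vapply(s[[1]]@residues, function(r) nrow(r@atoms), integer(1)))
  mc <- replicate(60, {
    X <- matrix(runif(3 * N, -6, 6), N, 3)
    oracleFitRmsd(X + rnorm(3 * N, 0, sigma), X + rnorm(3 * N, 0, sigma))
  })
  expect_gt(mean(obs), 0.7 * mean(mc))
  expect_lt(mean(obs), 1.3 * mean(mc))
})

test_that("superfamily planting and equivalence substitutions follow the config", {
  sim <- makeSites(syntheticConfig(seed = 29, nFamilies = 10,
                                   sitesPerFamily = 4,
                                   multiSFFraction = 0.5))
  perFam <- tapply(sim$truth$superfamily, sim$truth$family,
                   function(x) length(unique(x)))
  expect_equal(sum(perFam == 2L), 5L)
  expect_equal(sum(perFam == 1L), 5L)
  # planted isofunctional pairs across superfamilies are non-homologs
  f <- names(perFam[perFam == 2L])[1]
  rows <- sim$truth[sim$truth$family == as.integer(f), ]
  i <- match(rows$site_id[1], vapply(sim$sites, siteId, character(1)))
  j <- match(rows$site_id[which(rows$superfamily != rows$superfamily[1])[1]],
             vapply(sim$sites, siteId, character(1)))
  expect_false(identSupfam(sim$sites[[i]], sim$sites[[j]]))
  expect_equal(ecNumbers(sim$sites[[i]]), ecNumbers(sim$sites[[j]]))

  # substitutions at rate 1 replace every tyrosine by phenylalanine
  sub <- makeSites(syntheticConfig(seed = 29, nFamilies = 10,
                                   sitesPerFamily = 2,
                                   equivSubstitutionRate = 1))
  aas <- unlist(lapply(sub$sites, function(s)
    vapply(siteResidues(s), function(r) r@aa, character(1))))
  expect_false(any(aas %in% c("TYR", "ILE")))

  # impossible config
  expect_error(makeSites(syntheticConfig(seed = 1, nFamilies = 2,
                                         sitesPerFamily = 1,
                                         multiSFFraction = 1)),
               "two superfamilies")
})

test_that("generated sites satisfy the curated-site invariants", {
  sim <- makeSites(syntheticConfig(seed = 37))
  sizes <- vapply(sim$sites, length, integer(1))
  expect_true(all(sizes >= 2 & sizes <= 10))
  cur <- curateSites(sim$sites)
  expect_length(cur$retained, length(sim$sites))
  # labels in truth always match the sites
  ids <- vapply(sim$sites, siteId, character(1))
  expect_identical(sim$truth$site_id, ids)
  expect_identical(sim$truth$ec,
                   vapply(sim$sites, function(s) s@ec, character(1)))
  # residue types come from the catalytic pool
  aas <- unlist(lapply(sim$sites, function(s)
    vapply(siteResidues(s), function(r) r@aa, character(1))))
  expect_true(all(aas %in% CatPose:::AA_CATALYTIC_POOL))
})

test_that("same-function enzymes share MF/BP annotations; CC is function-blind", {
  sim <- makeSites(syntheticConfig(seed = 3, nFamilies = 6,
                                   sitesPerFamily = 3))
  g <- sim$ontology
  ids <- vapply(sim$sites, siteId, character(1))
  fam <- sim$truth$family
  sameF <- which(fam == fam[1])
  diffF <- which(fam != fam[1])[1]
  expect_equal(setSimilarity(goTerms(sim$sites[[sameF[1]]]),
                             goTerms(sim$sites[[sameF[2]]]), g,
                             domains = "MF"), 1)
  expect_lt(setSimilarity(goTerms(sim$sites[[sameF[1]]]),
                          goTerms(sim$sites[[diffF]]), g,
                          domains = "MF"), 1)
  # including the randomized CC domain lowers same-function scores on average
  sims <- sapply(seq_len(20), function(k) {
    f <- sample(unique(fam), 1)
    pair <- sample(which(fam == f), 2)
    c(bpmf = setSimilarity(goTerms(sim$sites[[pair[1]]]),
                           goTerms(sim$sites[[pair[2]]]), g,
                           domains = c("BP", "MF")),
      all3 = setSimilarity(goTerms(sim$sites[[pair[1]]]),
                           goTerms(sim$sites[[pair[2]]]), g,
                           domains = c("CC", "BP", "MF")))
  })
  expect_lt(mean(sims["all3", ]), mean(sims["bpmf", ]))
})
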