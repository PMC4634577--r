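test_that("residue representations produce the documented point lists", {
  ala <- residue("ALA", "A", 1, data.frame(
    name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
    x = c(-1.46, 0, 0.55, 0.35, 1.5), y = c(0, 0, 1.42, 2.55, 0),
    z = c(0, 0, 0, 0, 0)))
  # centroid of a one-atom side chain is that atom
  cen <- representResidue(ala, "CA_CENTROID")
  expect_equal(unname(cen[2, ]), c(1.5, 0, 0))
  expect_equal(rownames(cen), c("CA", "SC_CENTROID"))

  gly <- residue("GLY", "A", 2, data.frame(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = 0:3, y = c(0, 1, 0, 1), z = 0))
  expect_equal(nrow(representResidue(gly, "CA_CB")), 1L)
  expect_equal(nrow(representResidue(gly, "CA_CENTROID")), 1L)
  expect_equal(nrow(representResidue(gly, "ALL_ATOM")), 4L)

  # aspartate centroid = mean of the four side-chain atoms, computed here
  # directly from the raw coordinates
  asp <- idealRes("ASP")
  side <- asp@atoms[asp@atoms$name %in% c("CB", "CG", "OD1", "OD2"), ]
  cen <- representResidue(asp, "CA_CENTROID")
  expect_equal(unname(cen[2, ]),
               c(mean(side$x), mean(side$y), mean(side$z)))

  # missing required atom makes a residue unusable for the mode
  noCb <- residue("SER", "A", 3, data.frame(
    name = c("N", "CA", "C", "O", "OG"), element = c("N", "C", "C", "O", "O"),
    x = 1:5, y = 0, z = 0))
  expect_null(representResidue(noCb, "CA_CB"))
  expect_equal(nrow(representResidue(noCb, "CA")), 1L)
})

test_that("superposePoints returns the least-RMSD proper transform", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  fit <- superposePoints(tri, tri)
  expect_equal(fit$rmsd, 0)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)

  # rigid motion is recovered exactly
  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  set.seed(1)
  P <- matrix(rnorm(24), 8, 3)
  Q <- sweep(P %*% t(Rz), 2, c(1, 2, 3), "+")
  expect_lt(superposePoints(P, Q)$rmsd, 1e-9)

  # independent fitting oracle on random clouds
  for (k in 1:20) {
    P <- matrix(rnorm(15), 5, 3)
    Q <- matrix(rnorm(15), 5, 3)
    fit <- superposePoints(P, Q)
    expect_equal(fit$rmsd, oracleFitRmsd(P, Q), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # returned transform reproduces the reported rmsd
    moved <- sweep(Q %*% t(fit$rotation), 2, fit$translation, "+")
    expect_equal(sqrt(mean(rowSums((P - moved)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }

  # a mirrored cloud is never fitted with a reflection
  P <- matrix(rnorm(15), 5, 3)
  Q <- P %*% diag(c(-1, 1, 1))
  fit <- superposePoints(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.01)

  # degenerate (collinear) input still returns a minimizer
  L <- cbind(1:4, 0, 0)
  expect_lt(superposePoints(L, L[4:1, , drop = FALSE])$rmsd, 1e-9)
})

test_that("enumerateMatches finds exactly the qualifying mappings", {
  set.seed(11)
  A <- randomSite("A", 3, types = c("HIS", "ASP", "SER"))
  # identical site: the full identity mapping plus its size-2 sub-mappings
  ms <- enumerateMatches(A, A, rmsdCutoff = 1.0)
  expect_length(ms, 4L)
  sizes <- vapply(ms, matchSize, integer(1))
  expect_equal(sort(sizes), c(2L, 2L, 2L, 3L))
  expect_lt(min(vapply(ms, matchRmsd, numeric(1))), 1e-9)
  full <- ms[[which(sizes == 3L)]]
  expect_equal(full@mapping[order(full@mapping[, 1]), 2], 1:3)

  # no type-compatible pair
  B <- randomSite("B", 2, types = c("SER", "LYS"))
  C <- randomSite("C", 2, types = c("HIS", "ASP"))
  expect_length(enumerateMatches(C, B, rmsdCutoff = 5), 0L)

  # equivalence rules open additional correspondences: same geometry, one
  # site has TYR where the other has PHE; a 2-residue mapping needs the pair
  geo <- CatPose:::.templateCa(2)
  tyr <- makeSite("T", c("TYR", "HIS"), ca = geo)
  phe <- makeSite("P", c("PHE", "HIS"), ca = geo)
  expect_length(enumerateMatches(tyr, phe, rmsdCutoff = 5), 0L)
  withRules <- enumerateMatches(tyr, phe, rmsdCutoff = 5,
                                rules = equivalenceRules("YF_IV"))
  expect_gte(length(withRules), 1L)
  expect_lt(min(vapply(withRules, matchRmsd, numeric(1))), 1e-9)
})

test_that("enumeration equals the brute-force oracle on random pairs", {
  set.seed(23)
  pool <- c("HIS", "ASP", "SER", "GLU", "TYR")
  for (k in 1:10) {
    A <- randomSite("A", sample(2:5, 1), pool = pool)
    B <- randomSite("B", sample(2:5, 1), pool = pool)
    o <- oracleEnumerate(A, B, cutoff = 4.0)
    p <- packageEnumerate(A, B, cutoff = 4.0)
    expect_identical(o$key, p$key)
    if (nrow(o)) expect_equal(p$rmsd, o$rmsd, tolerance = 1e-6)
  }
})

test_that("pose comparison is invariant under rigid motion, symmetric, and cutoff-monotone", {
  set.seed(5)
  for (rep in c("CA", "CA_CB", "CA_CENTROID", "ALL_ATOM")) {
    A <- randomSite("A", 4)
    moved <- rigidMove(A)
    cmp <- compareSites(A, moved, rep = rep, rmsdCutoff = 1.0)
    expect_false(is.null(bestMatch(cmp)))
    expect_lt(matchRmsd(bestMatch(cmp)), 1e-6)
    expect_equal(matchSize(bestMatch(cmp)), length(A))
  }

  # raw rmsd of a mapping equals that of the inverse mapping
  A <- randomSite("A", 3, types = c("HIS", "ASP", "GLU"))
  B <- randomSite("B", 3, types = c("HIS", "ASP", "GLU"))
  mab <- enumerateMatches(A, B, rmsdCutoff = 8)
  mba <- enumerateMatches(B, A, rmsdCutoff = 8)
  keyAB <- vapply(mab, CatPose:::.mappingKey, character(1))
  inv <- vapply(mba, function(m) {
    mp <- m@mapping[, 2:1, drop = FALSE]
    mp <- mp[order(mp[, 1]), , drop = FALSE]
    paste(sprintf("%03d-%03d", mp[, 1], mp[, 2]), collapse = ";")
  }, character(1))
  expect_setequal(keyAB, inv)
  expect_equal(vapply(mab, matchRmsd, numeric(1))[order(keyAB)],
               vapply(mba, matchRmsd, numeric(1))[order(inv)],
               tolerance = 1e-9)

  # enlarging the cutoff never removes matches
  small <- packageEnumerate(A, B, cutoff = 1.5)
  large <- packageEnumerate(A, B, cutoff = 3.0)
  expect_true(all(small$key %in% large$key))
})

test_that("compareSites picks the minimal score with size and lexicographic tie-breaks", {
  set.seed(2)
  A <- randomSite("A", 3, types = c("HIS", "ASP", "SER"))
  cmp <- compareSites(A, A, rmsdCutoff = 1)
  expect_equal(matchSize(bestMatch(cmp)), 3L)
  expect_lt(cmp@scoreValue, 1e-9)

  none <- compareSites(randomSite("X", 2, types = c("HIS", "ASP")),
                       randomSite("Y", 2, types = c("SER", "LYS")),
                       rmsdCutoff = 5)
  expect_null(bestMatch(none))
  expect_true(is.na(none@scoreValue))

  # equal rmsd_n2: size 2 at rmsd 0.30 scores 0.30/1, size 3 at rmsd 0.90
  # scores 0.90/3 -- the tie goes to the larger match
  m2 <- new("SiteMatch", mapping = cbind(1:2, 1:2), rotation = diag(3),
            translation = numeric(3), rmsd = 0.30, size = 2L)
  m3 <- new("SiteMatch", mapping = cbind(1:3, 1:3), rotation = diag(3),
            translation = numeric(3), rmsd = 0.90, size = 3L)
  scores <- c(rmsdN2(0.30, 2), rmsdN2(0.90, 3))
  expect_equal(scores[1], scores[2])
  best <- CatPose:::.selectBest(list(m2, m3), scores)
  expect_equal(matchSize(best), 3L)
})

test_that("the candidate-mapping budget aborts oversized enumerations", {
  set.seed(9)
  A <- randomSite("A", 5, types = rep("HIS", 5))
  B <- randomSite("B", 5, types = rep("HIS", 5))
  expect_error(enumerateMatches(A, B, rmsdCutoff = 50, budget = 10),
               "budget")
})
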