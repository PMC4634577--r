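mkSite <- function(id, sf, ec) makeSite(id, c("HIS", "ASP"), sf = sf, ec = ec)

# A comparison table in compareAllSites() format.
cmpTable <- function(query, target, score, size = 2L, rmsd = score) {
  data.frame(query = query, target = target, size = size, rmsd = rmsd,
             score = score, stringsAsFactors = FALSE)
}

test_that("shared superfamily is detected by label equality", {
  a <- mkSite("a", "c.1.8", "1.1.1.1")
  b <- mkSite("b", "c.1.8", "2.1.1.1")
  c <- mkSite("c", "b.2.4", "1.1.1.1")
  expect_true(identSupfam(a, b))
  expect_false(identSupfam(a, c))
  d <- mkSite("d", NA, "1.1.1.1")
  expect_error(identSupfam(a, d), "superfamily")
})

test_that("best hits take the minimal score and honor mode and best-of-k", {
  sites <- list(mkSite("q", "c.1.8", "1.1.1.1"),
                mkSite("t1", "b.1.1", "1.2.3.4"),
                mkSite("t2", "b.2.2", "2.2.2.2"),
                mkSite("t3", "c.1.8", "3.3.3.3"))
  cmp <- cmpTable(rep("q", 3), c("t1", "t2", "t3"), c(0.2, 0.5, 0.1))
  hits <- bestHits(cmp, sites, mode = "all")
  expect_equal(hits$hit[hits$query == "q"], "t3")  # global minimum

  # DIFF_SF drops the same-superfamily candidate t3
  hits <- bestHits(cmp, sites, mode = "diff_sf")
  expect_equal(hits$hit[hits$query == "q"], "t1")
  expect_true(hits$agreeClass[hits$query == "q"])  # both EC class 1

  # all candidates homologous: query is dropped
  homol <- cmpTable("q", "t3", 0.1)
  expect_equal(nrow(bestHits(homol, sites, mode = "diff_sf")), 0L)

  # best-of-k: among the 2 lowest scores, the higher S_GO wins
  sgo <- matrix(NA_real_, 4, 4,
                dimnames = list(c("q", "t1", "t2", "t3"),
                                c("q", "t1", "t2", "t3")))
  sgo["q", "t1"] <- 0.1; sgo["q", "t2"] <- 0.9; sgo["q", "t3"] <- 0.2
  cmp2 <- cmpTable(rep("q", 2), c("t1", "t2"), c(0.20, 0.25))
  hits <- bestHits(cmp2, sites, mode = "all", k = 2, sgo = sgo)
  expect_equal(hits$hit, "t2")
  expect_equal(hits$sgo, 0.9)
  expect_error(bestHits(cmp2, sites, mode = "all", k = 2), "S_GO")
})

test_that("the cutoff-free protocol counts TP/FN by EC class of the best hit", {
  cc <- classifyBestHit(c(TRUE, TRUE, FALSE))
  expect_equal(unname(counts(cc)), c(2L, 0L, 0L, 1L))
  # EC 3.2.1.8 vs 3.1.3.48 share the class digit
  expect_true(substr("3.2.1.8", 1, 1) == substr("3.1.3.48", 1, 1))
})

test_that("thresholded classification follows the 4-way rule", {
  hits <- data.frame(query = "q", hit = "t", score = 0.50, size = 2L,
                     rmsd = 0.5, agreeClass = TRUE, agreeEC = TRUE,
                     sgo = 0.80, stringsAsFactors = FALSE)
  expect_equal(unname(counts(classifyThresholded(hits, 0.65,
                                                 agreement = "ec_class"))),
               c(1L, 0L, 0L, 0L))  # TP
  hits$score <- 0.70
  expect_equal(unname(counts(classifyThresholded(hits, 0.65,
                                                 agreement = "ec_class"))),
               c(0L, 0L, 0L, 1L))  # FN
  hits$score <- 0.50
  expect_equal(unname(counts(classifyThresholded(hits, 0.65, cuSgo = 0.88,
                                                 agreement = "go"))),
               c(0L, 1L, 0L, 0L))  # FP: similar pose, dissimilar GO sets
  # undefined S_GO excludes the query under GO agreement
  hits$sgo <- NA_real_
  expect_equal(sum(counts(classifyThresholded(hits, 0.65, cuSgo = 0.88,
                                              agreement = "go"))), 0L)
  expect_error(classifyThresholded(hits, 0.65, agreement = "go"), "cuSgo")
})

test_that("sensitivity and MCC reproduce their defining formulas", {
  expect_equal(roundHalfUp(sensitivity(confusionCounts(tp = 167, fn = 53))),
               0.76)
  expect_equal(sensitivity(confusionCounts(tp = 0, fn = 9)), 0)
  expect_equal(sensitivity(confusionCounts(tp = 61, fn = 159)), 61 / 220)
  expect_true(is.na(sensitivity(confusionCounts(fp = 3, tn = 4))))

  expect_equal(roundHalfUp(mcc(confusionCounts(61, 58, 417, 159))), 0.19)
  expect_equal(roundHalfUp(mcc(confusionCounts(5, 5, 607, 1))), 0.64)
  expect_equal(mcc(confusionCounts(1, 1, 1, 1)), 0)
  # zero-denominator convention
  expect_equal(mcc(confusionCounts(5, 0, 0, 0)), 0)
  expect_equal(mcc(confusionCounts(0, 0, 0, 0)), 0)
})

test_that("MCC and sensitivity stay within their ranges on random counts", {
  set.seed(31)
  for (k in 1:50) {
    cc <- confusionCounts(sample(0:50, 1), sample(0:50, 1),
                          sample(0:50, 1), sample(0:50, 1))
    m <- mcc(cc)
    expect_gte(m, -1); expect_lte(m, 1)
    s <- sensitivity(cc)
    if (!is.na(s)) { expect_gte(s, 0); expect_lte(s, 1) }
    expect_equal(sum(counts(cc)), cc@tp + cc@fp + cc@tn + cc@fn)
  }
})

test_that("grid search equals exhaustive recomputation and finds planted separations", {
  set.seed(17)
  n <- 40
  hits <- data.frame(
    query = paste0("q", 1:n), hit = "h",
    score = runif(n, 0.05, 1.4), size = 3L, rmsd = 0,
    agreeClass = sample(c(TRUE, FALSE), n, replace = TRUE),
    agreeEC = FALSE, sgo = runif(n), stringsAsFactors = FALSE)
  rg <- seq(0.05, 1.4, by = 0.05)
  sg <- seq(0.5, 1, by = 0.1)
  for (agr in c("ec_class", "go")) {
    got <- gridSearch(hits, agreement = agr, rmsdGrid = rg, sgoGrid = sg)
    # brute force over every grid point
    best <- NULL
    for (s in (if (agr == "go") sg else NA)) {
      for (r in rg) {
        cc <- classifyThresholded(hits, r, cuSgo = s, agreement = agr)
        cand <- list(r = r, s = s, m = mcc(cc))
        if (is.null(best) || cand$m > best$m + 1e-12) best <- cand
      }
    }
    expect_equal(got@mcc, best$m, tolerance = 1e-12)
    expect_equal(mcc(got@counts), got@mcc)
  }

  # planted separation: matching poses just below 0.5, others just above
  sep <- data.frame(
    query = paste0("q", 1:30), hit = "h",
    score = c(runif(15, 0.492, 0.499), runif(15, 0.501, 1.2)),
    size = 3L, rmsd = 0, agreeClass = rep(c(TRUE, FALSE), each = 15),
    agreeEC = FALSE, sgo = NA_real_, stringsAsFactors = FALSE)
  got <- gridSearch(sep, agreement = "ec_class",
                    rmsdGrid = seq(0.01, 1.5, by = 0.01))
  expect_equal(got@mcc, 1.0)
  expect_lte(abs(got@cuRmsd - 0.5), 0.01)

  # single grid point is returned as-is
  one <- gridSearch(sep, agreement = "ec_class", rmsdGrid = 0.5)
  expect_equal(one@cuRmsd, 0.5)
  expect_error(gridSearch(sep, agreement = "ec_class",
                          rmsdGrid = numeric()), "grid")
})

test_that("best-hit evaluation reports both sensitivity denominators", {
  hits <- data.frame(query = paste0("q", 1:4), hit = "h", score = 0.1,
                     size = 2L, rmsd = 0.1,
                     agreeClass = c(TRUE, TRUE, TRUE, FALSE),
                     agreeEC = FALSE, sgo = NA_real_,
                     stringsAsFactors = FALSE)
  ev <- evaluateBestHits(hits, nQueries = 10)
  expect_equal(unname(counts(ev$counts)), c(3L, 0L, 0L, 1L))
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$sensitivityAll, 0.3)
})
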