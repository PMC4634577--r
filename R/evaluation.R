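# From all-vs-all comparisons to function predictions and performance
# numbers: best-hit protocol, thresholded 4-way protocol, sensitivity, MCC,
# and the MCC-maximizing cutoff grid search.

#' Do two sites share a SCOP superfamily?
#'
#' The homology criterion: two enzymes are considered homologs iff their
#' sites carry the same SCOP superfamily label.
#'
#' @param A,B [CatalyticSite-class] objects with superfamily labels.
#' @return Logical.
#' @export
identSupfam <- function(A, B) {
  if (is.na(A@superfamily) || is.na(B@superfamily)) {
    stop("both sites need a superfamily label")
  }
  A@superfamily == B@superfamily
}

#' Per-query best hits from a comparison table
#'
#' For every query site, selects the most similar other site (minimal pose
#' score) among the allowed candidates. In `"diff_sf"` mode candidates from
#' the query's own SCOP superfamily are excluded, restricting the comparison
#' to likely non-homologs; in `"all"` mode every other site is a candidate.
#' With `k > 1`, the hit is the candidate with the highest S_GO to the query
#' among the `k` smallest-score candidates. Queries without any comparable
#' candidate are dropped (and excluded from downstream counts).
#'
#' @param comparisons data.frame from [compareAllSites()] (columns `query`,
#'   `target`, `size`, `rmsd`, `score`).
#' @param sites List of [CatalyticSite-class] objects (provides superfamily
#'   and EC labels).
#' @param mode `"diff_sf"` or `"all"`.
#' @param k Best-of-k selection width (default 1).
#' @param sgo Symmetric S_GO matrix from [sgoMatrix()]; required when
#'   `k > 1` and used to attach each hit's S_GO.
#' @return data.frame with one row per classified query: `query`, `hit`,
#'   `score`, `size`, `rmsd`, `agreeClass` (EC first digits equal),
#'   `agreeEC` (full EC equal), `sgo` (S_GO of query and hit, `NA` when
#'   unavailable or undefined).
#' @export
bestHits <- function(comparisons, sites, mode = c("diff_sf", "all"), k = 1L,
                     sgo = NULL) {
  mode <- match.arg(mode)
  ids <- vapply(sites, siteId, character(1))
  sf <- stats::setNames(vapply(sites, function(s) s@superfamily,
                               character(1)), ids)
  ecOf <- stats::setNames(lapply(sites, function(s) s@ec), ids)
  if (k > 1L && is.null(sgo)) stop("best-of-k selection needs an S_GO matrix")
  out <- list()
  for (q in ids) {
    cand <- comparisons[comparisons$query == q &
                        comparisons$target != q, , drop = FALSE]
    if (mode == "diff_sf") {
      cand <- cand[is.na(sf[cand$target]) |
                   sf[cand$target] != sf[[q]], , drop = FALSE]
    }
    if (!nrow(cand)) next
    cand <- cand[order(cand$score, -cand$size, cand$target), , drop = FALSE]
    pick <- 1L
    if (k > 1L) {
      top <- utils::head(cand, k)
      s <- sgo[q, top$target]
      if (any(!is.na(s))) {
        pick <- which.max(ifelse(is.na(s), -Inf, s))
      }
      cand <- top
    }
    hit <- cand[pick, , drop = FALSE]
    ecq <- ecOf[[q]]; ech <- ecOf[[hit$target]]
    agreeClass <- length(ecq) > 0 && length(ech) > 0 &&
      any(substr(ecq, 1, 1) %in% substr(ech, 1, 1))
    agreeEC <- length(ecq) > 0 && length(ech) > 0 && any(ecq %in% ech)
    s <- if (is.null(sgo)) NA_real_ else sgo[q, hit$target]
    out[[length(out) + 1L]] <- data.frame(
      query = q, hit = hit$target, score = hit$score, size = hit$size,
      rmsd = hit$rmsd, agreeClass = agreeClass, agreeEC = agreeEC,
      sgo = s, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(query = character(), hit = character(),
                      score = numeric(), size = integer(), rmsd = numeric(),
                      agreeClass = logical(), agreeEC = logical(),
                      sgo = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a best hit without a score cutoff
#'
#' The cutoff-free protocol: the prediction for a query is correct (TP) when
#' the first digits of the query's and the hit's EC numbers agree, and a
#' false negative otherwise. No FP/TN arise because every query is assigned
#' its best hit's function.
#'
#' @param agreeClass Logical vector: EC first digits of query and hit equal.
#' @return A [ConfusionCounts-class] with `tp` and `fn` filled.
#' @export
classifyBestHit <- function(agreeClass) {
  confusionCounts(tp = sum(agreeClass), fn = sum(!agreeClass))
}

#' Classify best hits under score/agreement cutoffs
#'
#' The thresholded 4-way protocol: a prediction is positive when the pose
#' score of the best hit is below `cuRmsd`. Positives are TP when the
#' functions agree and FP otherwise; non-positives are FN when the functions
#' agree and TN otherwise. Agreement is either equality of EC first digits
#' (`agreement = "ec_class"`) or S_GO at or above `cuSgo`
#' (`agreement = "go"`); under GO agreement, queries whose S_GO to their hit
#' is undefined are excluded.
#'
#' @param hits data.frame from [bestHits()].
#' @param cuRmsd Pose-score cutoff.
#' @param cuSgo S_GO cutoff (GO agreement only).
#' @param agreement `"ec_class"` or `"go"`.
#' @return A [ConfusionCounts-class].
#' @export
classifyThresholded <- function(hits, cuRmsd, cuSgo = NA,
                                agreement = c("ec_class", "go")) {
  agreement <- match.arg(agreement)
  if (agreement == "go") {
    if (is.na(cuSgo)) stop("GO agreement needs cuSgo")
    hits <- hits[!is.na(hits$sgo), , drop = FALSE]
    agree <- hits$sgo >= cuSgo
  } else {
    agree <- hits$agreeClass
  }
  pos <- hits$score < cuRmsd
  confusionCounts(tp = sum(pos & agree), fp = sum(pos & !agree),
                  tn = sum(!pos & !agree), fn = sum(!pos & agree))
}

#' Sensitivity
#'
#' `TP / (TP + FN)`; undefined (`NA`) when no positives exist.
#'
#' @param x A [ConfusionCounts-class].
#' @return Sensitivity in `[0, 1]`, or `NA`.
#' @examples
#' sensitivity(confusionCounts(tp = 167, fn = 53))
#' @export
sensitivity <- function(x) {
  if (x@tp + x@fn == 0L) return(NA_real_)
  x@tp / (x@tp + x@fn)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, with the
#' convention that a zero factor in the denominator gives MCC 0.
#'
#' @param x A [ConfusionCounts-class].
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(confusionCounts(61, 58, 417, 159))
#' @export
mcc <- function(x) {
  tp <- as.numeric(x@tp); fp <- as.numeric(x@fp)
  tn <- as.numeric(x@tn); fn <- as.numeric(x@fn)
  den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' MCC-maximizing cutoff grid search
#'
#' Evaluates [classifyThresholded()] at every grid point and returns the
#' point maximizing the MCC. Ties break toward the smaller pose-score cutoff
#' and then the larger S_GO cutoff. The default grids span every cutoff
#' combination of practical interest (pose score 0.01-1.50 in steps of 0.01;
#' S_GO 0.50-1.00 in steps of 0.01).
#'
#' @param hits data.frame from [bestHits()].
#' @param agreement `"ec_class"` or `"go"`.
#' @param rmsdGrid Sorted numeric grid of pose-score cutoffs.
#' @param sgoGrid Sorted numeric grid of S_GO cutoffs (GO agreement only).
#' @return A [GridSearchResult-class].
#' @export
gridSearch <- function(hits, agreement = c("ec_class", "go"),
                       rmsdGrid = seq(0.01, 1.50, by = 0.01),
                       sgoGrid = seq(0.50, 1.00, by = 0.01)) {
  agreement <- match.arg(agreement)
  if (!length(rmsdGrid)) stop("empty pose-score grid")
  if (agreement == "go") {
    if (!length(sgoGrid)) stop("empty S_GO grid")
    hits <- hits[!is.na(hits$sgo), , drop = FALSE]
  } else {
    sgoGrid <- NA_real_
  }
  best <- NULL
  for (s in sgoGrid) {
    agree <- if (is.na(s)) hits$agreeClass else hits$sgo >= s
    nAgree <- sum(agree)
    n <- length(agree)
    # counts at each rmsd cutoff via cumulative sums over sorted scores
    ord <- order(hits$score)
    scoreSorted <- hits$score[ord]
    agreeSorted <- agree[ord]
    nPos <- findInterval(rmsdGrid, scoreSorted, left.open = TRUE)
    cumAgree <- c(0L, cumsum(agreeSorted))
    tp <- cumAgree[nPos + 1L]
    fp <- nPos - tp
    fn <- nAgree - tp
    tn <- n - nPos - fn
    num <- tp * tn - fp * fn
    den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
    m <- ifelse(den == 0, 0, num / sqrt(den))
    b <- which.max(m)  # first maximum = smallest cutoff among ties
    cand <- list(cuRmsd = rmsdGrid[b], cuSgo = s, mcc = m[b],
                 counts = confusionCounts(tp[b], fp[b], tn[b], fn[b]))
    if (is.null(best) || .betterGridPoint(cand, best)) best <- cand
  }
  new("GridSearchResult", cuRmsd = best$cuRmsd, cuSgo = best$cuSgo,
      mcc = best$mcc, counts = best$counts)
}

# Tie rules: higher MCC, then smaller cu_rmsd, then larger cu_sgo.
.betterGridPoint <- function(a, b) {
  if (a$mcc > b$mcc + 1e-12) return(TRUE)
  if (a$mcc < b$mcc - 1e-12) return(FALSE)
  if (a$cuRmsd < b$cuRmsd) return(TRUE)
  if (a$cuRmsd > b$cuRmsd) return(FALSE)
  if (is.na(a$cuSgo) || is.na(b$cuSgo)) return(FALSE)
  a$cuSgo > b$cuSgo
}

#' Best-hit protocol evaluation
#'
#' Applies the cutoff-free best-hit protocol ([classifyBestHit()]) and
#' reports sensitivity under the two defensible query denominators: queries
#' with a valid hit (`sensitivity`) and all queries submitted
#' (`sensitivityAll`).
#'
#' @param hits data.frame from [bestHits()].
#' @param nQueries Total number of queries submitted (defaults to
#'   `nrow(hits)`).
#' @return List with `counts` ([ConfusionCounts-class]), `sensitivity` and
#'   `sensitivityAll`.
#' @export
evaluateBestHits <- function(hits, nQueries = nrow(hits)) {
  cc <- classifyBestHit(hits$agreeClass)
  list(counts = cc,
       sensitivity = sensitivity(cc),
       sensitivityAll = if (nQueries > 0) cc@tp / nQueries else NA_real_)
}
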