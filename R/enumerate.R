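# Enumeration of residue correspondences between two sites and selection of
# the best-scoring match.

#' @useDynLib CatPose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Precompute, for one site under one representation: per-residue point
# blocks (NULL when the representation cannot be built), C-alpha
# coordinates, and residue types.
.sitePrep <- function(site, rep) {
  res <- site@residues
  blocks <- lapply(res, representResidue, rep = rep)
  ca <- t(vapply(res, function(r) {
    i <- match("CA", r@atoms$name)
    if (is.na(i)) return(c(NA_real_, NA_real_, NA_real_))
    c(r@atoms$x[i], r@atoms$y[i], r@atoms$z[i])
  }, numeric(3)))
  list(blocks = blocks, ca = ca,
       types = vapply(res, function(r) r@aa, character(1)))
}

# Alternative atom-name labelings for residue type `aa`: a list of named
# character vectors mapping original -> relabeled names. Always includes the
# identity labeling first.
.altLabelings <- function(aa, names) {
  groups <- AA_SYMMETRIC_ATOMS[[aa]]
  base <- stats::setNames(names, names)
  if (is.null(groups)) return(list(base))
  # keep only flip groups fully present among the residue's atom names
  groups <- Filter(function(g) all(unlist(g) %in% names), groups)
  if (!length(groups)) return(list(base))
  out <- list(base)
  for (sel in seq_len(2^length(groups) - 1L)) {
    lab <- base
    bits <- which(bitwAnd(sel, 2^(seq_along(groups) - 1L)) > 0L)
    for (gi in bits) {
      for (pr in groups[[gi]]) {
        lab[pr[1]] <- pr[2]
        lab[pr[2]] <- pr[1]
      }
    }
    out <- c(out, list(lab))
  }
  out
}

# Build the fixed block (site A) and the variant blocks (site B) for one
# compatible residue pair. Points are paired on the intersection of atom
# labels; symmetric-atom flips of the B residue give alternative pairings.
# Returns NULL when the pair shares no representable point.
.pairBlocks <- function(blockA, blockB, aaB) {
  namesA <- rownames(blockA)
  namesB <- rownames(blockB)
  shared <- namesA[namesA %in% namesB]
  if (!length(shared)) return(NULL)
  A <- blockA[shared, , drop = FALSE]
  labs <- .altLabelings(aaB, namesB)
  variants <- list()
  seen <- character(0)
  for (lab in labs) {
    # row of B whose *relabeled* name equals each shared name
    idx <- match(shared, unname(lab[namesB]))
    if (anyNA(idx)) next
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    variants <- c(variants, list(blockB[idx, , drop = FALSE]))
  }
  if (!length(variants)) return(NULL)
  list(A = A, B = variants)
}

# Shared core: returns a list of plain-list matches (mapping/rmsd/rotation/
# translation) for sites A and B.
.enumerateCore <- function(A, B, rep, rules, rmsdCutoff, minSize, budget) {
  prepA <- .sitePrep(A, rep)
  prepB <- .sitePrep(B, rep)
  nA <- length(prepA$blocks)
  nB <- length(prepB$blocks)
  pairs <- list()
  blocksA <- list()
  blocksB <- list()
  maxRows <- 0L
  for (i in seq_len(nA)) {
    if (is.null(prepA$blocks[[i]])) next
    for (j in seq_len(nB)) {
      if (is.null(prepB$blocks[[j]])) next
      if (!.typesCompatible(prepA$types[i], prepB$types[j], rules)) next
      pb <- .pairBlocks(prepA$blocks[[i]], prepB$blocks[[j]],
                        prepB$types[j])
      if (is.null(pb)) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
      blocksA[[length(blocksA) + 1L]] <- pb$A
      blocksB[[length(blocksB) + 1L]] <- pb$B
      maxRows <- max(maxRows, nrow(pb$A))
    }
  }
  if (!length(pairs)) return(list())
  pairIdx <- do.call(rbind, pairs)
  dA <- as.matrix(stats::dist(prepA$ca))
  dB <- as.matrix(stats::dist(prepB$ca))
  dA[!is.finite(dA)] <- 0
  dB[!is.finite(dB)] <- 0
  # Exact pruning bound: for a mapping of N represented points with RMSD <=
  # cutoff, any two mapped C-alpha deviations d1, d2 satisfy d1 + d2 <=
  # cutoff * sqrt(2 N), hence |dA - dB| <= cutoff * sqrt(2 N).
  nBound <- min(nA, nB) * max(1L, maxRows)
  distTol <- rmsdCutoff * sqrt(2 * nBound)
  .cppEnumerateMatches(blocksA, blocksB, pairIdx, dA, dB, rmsdCutoff,
                       as.integer(minSize), distTol, budget)
}

#' Enumerate all residue correspondences between two sites
#'
#' Returns every injective, type-compatible residue mapping of at least
#' `minSize` residue pairs whose optimal rigid superposition of the
#' represented points (atom-paired by name; for equivalence-paired residue
#' types, on the intersection of atom names) has RMSD at or below
#' `rmsdCutoff`. Chemically symmetric side-chain labelings (carboxylate
#' oxygens, guanidinium nitrogens, aromatic ring flips) are both tried and
#' the lower RMSD kept. Enumeration is exhaustive; C-alpha distance pruning
#' only discards mappings that provably exceed the cutoff.
#'
#' @param A,B [CatalyticSite-class] objects.
#' @param rep Residue representation (see [representResidue()]).
#' @param rules Equivalence rules from [equivalenceRules()].
#' @param rmsdCutoff Positive RMSD cutoff in Angstrom.
#' @param minSize Minimum number of mapped residue pairs (default 2).
#' @param budget Maximum number of candidate mappings evaluated before the
#'   pair is abandoned with an error (default 1e6).
#' @return List of [SiteMatch-class] objects, ordered by decreasing size and
#'   then lexicographically by mapping.
#' @export
enumerateMatches <- function(A, B, rep = "ALL_ATOM",
                             rules = equivalenceRules("none"),
                             rmsdCutoff = 1.0, minSize = 2L,
                             budget = 1e6) {
  stopifnot(rmsdCutoff > 0, minSize >= 2L)
  raw <- .enumerateCore(A, B, rep, rules, rmsdCutoff, minSize, budget)
  if (!length(raw)) return(list())
  matches <- lapply(raw, function(m) {
    new("SiteMatch", mapping = m$mapping, rotation = m$rotation,
        translation = as.numeric(m$translation), rmsd = m$rmsd,
        size = nrow(m$mapping))
  })
  key <- vapply(matches, .mappingKey, character(1))
  sizes <- vapply(matches, function(m) m@size, integer(1))
  matches[order(-sizes, key)]
}

.mappingKey <- function(m) {
  mp <- m@mapping[order(m@mapping[, 1L]), , drop = FALSE]
  paste(sprintf("%03d-%03d", mp[, 1L], mp[, 2L]), collapse = ";")
}

# Pick the best match by (score, larger size, lexicographic mapping).
# Scores within 1e-9 are treated as tied so that floating noise cannot
# override the size tie-break.
.selectBest <- function(matches, scores) {
  if (!length(matches)) return(NULL)
  cand <- which(scores <= min(scores) + 1e-9)
  sizes <- vapply(matches[cand], function(m) m@size, integer(1))
  keys <- vapply(matches[cand], .mappingKey, character(1))
  matches[[cand[order(-sizes, keys)[1L]]]]
}

#' Compare two catalytic sites
#'
#' Enumerates all matches between `A` and `B` (see [enumerateMatches()]) and
#' selects the best under the named score; ties are broken toward the larger
#' match and then lexicographically on the mapping.
#'
#' @inheritParams enumerateMatches
#' @param scoreName Score ranking the matches (see [scoreMatch()]).
#' @return A [SiteComparison-class]; `bestMatch` is `NULL` when no mapping
#'   superposes below the cutoff.
#' @export
compareSites <- function(A, B, rep = "ALL_ATOM",
                         rules = equivalenceRules("none"), rmsdCutoff = 1.0,
                         scoreName = "rmsd_n2", minSize = 2L, budget = 1e6) {
  matches <- enumerateMatches(A, B, rep, rules, rmsdCutoff, minSize, budget)
  if (!length(matches)) {
    return(new("SiteComparison", queryId = A@siteId, targetId = B@siteId,
               bestMatch = NULL, scoreName = scoreName,
               scoreValue = NA_real_))
  }
  scores <- vapply(matches, scoreMatch, numeric(1), scoreName = scoreName,
                   siteA = A, siteB = B)
  best <- .selectBest(matches, scores)
  new("SiteComparison", queryId = A@siteId, targetId = B@siteId,
      bestMatch = best, scoreName = scoreName,
      scoreValue = scoreMatch(best, scoreName, A, B))
}

#' All-vs-all site comparison table
#'
#' Runs [compareSites()] for every unordered pair of sites and returns a
#' long-format table with one row per ordered pair that produced a match
#' (pose scores are symmetric, so each unordered pair is computed once and
#' mirrored).
#'
#' @param sites List of [CatalyticSite-class] objects with unique ids.
#' @inheritParams compareSites
#' @return data.frame with columns `query`, `target`, `size`, `rmsd`,
#'   `score`.
#' @export
compareAllSites <- function(sites, rep = "ALL_ATOM",
                            rules = equivalenceRules("none"),
                            rmsdCutoff = 1.0, scoreName = "rmsd_n2",
                            minSize = 2L, budget = 1e6) {
  ids <- vapply(sites, siteId, character(1))
  if (anyDuplicated(ids)) stop("site ids must be unique")
  n <- length(sites)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      raw <- .enumerateCore(sites[[i]], sites[[j]], rep, rules, rmsdCutoff,
                            minSize, budget)
      if (!length(raw)) next
      rmsds <- vapply(raw, `[[`, numeric(1), "rmsd")
      sizes <- vapply(raw, function(m) nrow(m$mapping), integer(1))
      sc <- switch(scoreName,
        rmsd = rmsds,
        rmsd_n1 = rmsdN1(rmsds, sizes),
        rmsd_n2 = rmsdN2(rmsds, sizes),
        stop("compareAllSites supports the built-in scores only")
      )
      tied <- which(sc <= min(sc) + 1e-9)
      b <- tied[order(-sizes[tied])[1L]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        query = c(ids[i], ids[j]), target = c(ids[j], ids[i]),
        size = sizes[b], rmsd = rmsds[b], score = sc[b],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!k) {
    return(data.frame(query = character(), target = character(),
                      size = integer(), rmsd = numeric(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}
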