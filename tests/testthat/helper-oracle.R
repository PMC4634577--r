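# Independent oracles. Superposition RMSD comes from bio3d (established
# fitting code, not the package's Kabsch); the enumeration oracle walks all
# injective type-compatible mappings by brute force with no pruning.

oracleFitRmsd <- function(P, Q) {
  fx <- as.vector(t(P))
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = fx, mobile = as.vector(t(Q))))
  sqrt(mean(rowSums(matrix(fx - as.vector(fit), ncol = 3, byrow = TRUE)^2)))
}

# All permutations of a vector (n <= 6 in the tests).
.perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Alternative-labeling variants of a point block, independent of the package
# internals: identity plus the joint flip of all symmetric pairs.
.oracleVariants <- function(block, aa) {
  flips <- list(
    ASP = list(c("OD1", "OD2")), GLU = list(c("OE1", "OE2")),
    ARG = list(c("NH1", "NH2")),
    PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
    TYR = list(c("CD1", "CD2"), c("CE1", "CE2")))
  fl <- flips[[aa]]
  rn <- rownames(block)
  out <- list(identity = rn)
  if (!is.null(fl) && all(unlist(fl) %in% rn)) {
    rn2 <- rn
    for (pr in fl) {
      rn2[rn == pr[1]] <- pr[2]
      rn2[rn == pr[2]] <- pr[1]
    }
    out$flipped <- rn2
  }
  out
}

# Brute-force enumeration: every injective, type-compatible mapping of size
# >= minSize with best-variant fitted RMSD <= cutoff. Returns a data.frame
# keyed like the package output for set comparison.
oracleEnumerate <- function(A, B, rep = "ALL_ATOM",
                            rules = equivalenceRules("none"),
                            cutoff = 1.0, minSize = 2L) {
  resA <- siteResidues(A)
  resB <- siteResidues(B)
  aaA <- vapply(resA, function(r) r@aa, character(1))
  aaB <- vapply(resB, function(r) r@aa, character(1))
  blkA <- lapply(resA, representResidue, rep = rep)
  blkB <- lapply(resB, representResidue, rep = rep)
  compat <- function(a, b) {
    a == b || any(vapply(rules, function(p) setequal(p, c(a, b)), logical(1)))
  }
  nA <- length(resA); nB <- length(resB)
  rows <- list()
  for (k in seq.int(minSize, min(nA, nB))) {
    subsA <- utils::combn(nA, k, simplify = FALSE)
    for (sa in subsA) {
      for (sb in utils::combn(nB, k, simplify = FALSE)) {
        for (pb in .perms(sb)) {
          ok <- all(mapply(function(i, j) {
            compat(aaA[i], aaB[j]) && !is.null(blkA[[i]]) &&
              !is.null(blkB[[j]])
          }, sa, pb))
          if (!ok) next
          # assemble shared-name point stacks, trying variant labelings
          variantLists <- mapply(function(i, j) {
            shared <- intersect(rownames(blkA[[i]]), rownames(blkB[[j]]))
            if (!length(shared)) return(NULL)
            vars <- .oracleVariants(blkB[[j]], aaB[j])
            Bv <- lapply(vars, function(rn2) {
              idx <- match(shared, rn2)
              if (anyNA(idx)) return(NULL)
              blkB[[j]][idx, , drop = FALSE]
            })
            Bv <- Filter(Negate(is.null), Bv)
            list(A = blkA[[i]][shared, , drop = FALSE], B = Bv)
          }, sa, pb, SIMPLIFY = FALSE)
          if (any(vapply(variantLists, is.null, logical(1)))) next
          P <- do.call(rbind, lapply(variantLists, `[[`, "A"))
          combos <- expand.grid(lapply(variantLists, function(v)
            seq_along(v$B)))
          best <- Inf
          for (ci in seq_len(nrow(combos))) {
            Q <- do.call(rbind, lapply(seq_along(variantLists), function(q)
              variantLists[[q]]$B[[combos[ci, q]]]))
            best <- min(best, oracleFitRmsd(P, Q))
          }
          if (best <= cutoff) {
            ordIdx <- order(sa)
            key <- paste(sprintf("%03d-%03d", sa[ordIdx], pb[ordIdx]),
                         collapse = ";")
            rows[[length(rows) + 1L]] <- data.frame(
              key = key, size = k, rmsd = best, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(key = character(), size = integer(),
                      rmsd = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$key), , drop = FALSE]
}

# Package enumeration result in the same keyed form.
packageEnumerate <- function(A, B, rep = "ALL_ATOM",
                             rules = equivalenceRules("none"),
                             cutoff = 1.0, minSize = 2L) {
  ms <- enumerateMatches(A, B, rep = rep, rules = rules,
                         rmsdCutoff = cutoff, minSize = minSize)
  if (!length(ms)) {
    return(data.frame(key = character(), size = integer(),
                      rmsd = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    key = vapply(ms, CatPose:::.mappingKey, character(1)),
    size = vapply(ms, matchSize, integer(1)),
    rmsd = vapply(ms, matchRmsd, numeric(1)), stringsAsFactors = FALSE)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
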