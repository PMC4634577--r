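# Topology-only GO semantic similarity (Wang-style) and the normalized
# term-set similarity S_GO.

WANG_WEIGHTS <- c(is_a = 0.8, part_of = 0.6)

# Semantic contributions of a term's ancestor DAG: named vector of S-values
# over the term and all its ancestors. S(term) = 1; walking an edge of
# relation r multiplies by WANG_WEIGHTS[r]; multiple paths keep the maximum.
.svalues <- function(term, graph, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[term]])) return(cache[[term]])
  edges <- graph@edges
  sv <- c(stats::setNames(1, term))
  frontier <- c(stats::setNames(1, term))
  while (length(frontier)) {
    nxt <- numeric(0)
    for (k in seq_along(frontier)) {
      ch <- names(frontier)[k]
      sel <- edges$child == ch
      if (!any(sel)) next
      w <- unname(WANG_WEIGHTS[edges$relation[sel]]) * frontier[[k]]
      pa <- edges$parent[sel]
      for (q in seq_along(pa)) {
        if (is.na(sv[pa[q]]) || w[q] > sv[pa[q]]) {
          sv[pa[q]] <- w[q]
          if (is.na(nxt[pa[q]]) || w[q] > nxt[pa[q]]) nxt[pa[q]] <- w[q]
        }
      }
    }
    frontier <- nxt[!is.na(nxt)]
  }
  sv <- sv[!is.na(sv)]
  if (!is.null(cache)) cache[[term]] <- sv
  sv
}

#' Semantic similarity of two ontology terms
#'
#' Topology-only Wang-style similarity: each term's ancestor DAG is scored
#' with semantic contributions decaying by 0.8 per `is_a` edge and 0.6 per
#' `part_of` edge (best path kept), and the similarity is the summed
#' contribution of the shared ancestors normalized by the two terms' total
#' semantic values. Independent of term frequencies in any corpus; 1 iff the
#' terms are identical, 0 when they live in different namespaces.
#'
#' @param t1,t2 Term ids (alt ids accepted).
#' @param graph An [OntologyGraph-class].
#' @return Similarity in `[0, 1]`.
#' @export
termSimilarity <- function(t1, t2, graph) {
  t1 <- .resolveTerms(t1, graph)
  t2 <- .resolveTerms(t2, graph)
  if (!identical(.termNamespace(t1, graph), .termNamespace(t2, graph))) {
    return(0)
  }
  if (t1 == t2) return(1)
  s1 <- .svalues(t1, graph)
  s2 <- .svalues(t2, graph)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

# Best-match-average over a term-similarity matrix.
.bma <- function(simMat) {
  (mean(apply(simMat, 1, max)) + mean(apply(simMat, 2, max))) / 2
}

#' Normalized GO term-set similarity S_GO
#'
#' Compares two enzymes' GO annotations restricted to the selected
#' annotation domains. Within each selected domain where both enzymes carry
#' terms, term sets are compared by best-match-average aggregation of
#' [termSimilarity()]; the final S_GO averages the per-domain scores.
#' Symmetric, in `[0, 1]`, and exactly 1 for identical non-empty restricted
#' annotations. When no selected domain has terms on both sides the
#' similarity is undefined (`NA`) and the pair is excluded from downstream
#' confusion counting.
#'
#' @param gi,gj Named lists of GO term vectors per domain (`MF`/`BP`/`CC`).
#' @param graph An [OntologyGraph-class].
#' @param domains Subset of `c("CC", "BP", "MF")` to compare.
#' @param cache Optional environment used to memoize per-term ancestor
#'   scores across many calls.
#' @return S_GO in `[0, 1]`, or `NA` when undefined.
#' @export
setSimilarity <- function(gi, gj, graph, domains = c("BP", "MF"),
                          cache = NULL) {
  domains <- match.arg(domains, c("CC", "BP", "MF"), several.ok = TRUE)
  scores <- numeric(0)
  for (d in domains) {
    ti <- unique(as.character(gi[[d]]))
    tj <- unique(as.character(gj[[d]]))
    if (!length(ti) || !length(tj)) next
    ti <- .resolveTerms(ti, graph)
    tj <- .resolveTerms(tj, graph)
    m <- matrix(0, length(ti), length(tj))
    for (a in seq_along(ti)) {
      for (b in seq_along(tj)) {
        m[a, b] <- .termSimilarityCached(ti[a], tj[b], graph, cache)
      }
    }
    scores <- c(scores, .bma(m))
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

.termSimilarityCached <- function(t1, t2, graph, cache) {
  if (identical(.termNamespace(t1, graph), .termNamespace(t2, graph))) {
    if (t1 == t2) return(1)
    s1 <- .svalues(t1, graph, cache)
    s2 <- .svalues(t2, graph, cache)
    shared <- intersect(names(s1), names(s2))
    if (!length(shared)) return(0)
    (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
  } else {
    0
  }
}

#' Pairwise S_GO matrix for a site collection
#'
#' @param sites List of [CatalyticSite-class] objects carrying GO
#'   annotations.
#' @param graph An [OntologyGraph-class].
#' @param domains Annotation domains compared (see [setSimilarity()]).
#' @return Symmetric numeric matrix (site ids as dimnames) with `NA` where
#'   S_GO is undefined; the diagonal is left `NA` (self-similarity is never
#'   used).
#' @export
sgoMatrix <- function(sites, graph, domains = c("BP", "MF")) {
  ids <- vapply(sites, siteId, character(1))
  n <- length(sites)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- setSimilarity(sites[[i]]@go, sites[[j]]@go, graph, domains,
                         cache = cache)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
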