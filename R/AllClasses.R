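# S4 classes for catalytic-site pose comparison.

#' Residue: one amino-acid residue with heavy-atom coordinates
#'
#' @slot aa Three-letter residue code (canonical or not; see
#'   [isCanonical()]).
#' @slot chainId Chain identifier.
#' @slot seqPos Author residue number as printed in the coordinate file,
#'   with any insertion code appended (kept as a character label).
#' @slot atoms data.frame with columns `name`, `element`, `x`, `y`, `z`;
#'   atom names are unique within the residue and coordinates are finite.
#' @export
setClass("Residue", representation(
  aa = "character", chainId = "character", seqPos = "character",
  atoms = "data.frame"
))

setValidity("Residue", function(object) {
  a <- object@atoms
  need <- c("name", "element", "x", "y", "z")
  if (!all(need %in% names(a))) {
    return("atoms must have columns name, element, x, y, z")
  }
  if (nrow(a) == 0L) return("residue has no atoms")
  if (anyDuplicated(a$name)) return("atom names must be unique in a residue")
  if (any(!nzchar(a$name))) return("atom names must be non-empty")
  if (!all(is.finite(c(a$x, a$y, a$z)))) return("coordinates must be finite")
  if (length(object@aa) != 1L) return("aa must be length 1")
  TRUE
})

#' Construct a Residue
#'
#' @param aa Three-letter residue code.
#' @param chainId Chain identifier.
#' @param seqPos Author residue number (integer or character; insertion
#'   codes may be appended).
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`.
#' @return A [Residue-class] object.
#' @examples
#' residue("GLY", "A", 1,
#'         data.frame(name = c("N", "CA", "C", "O"), element = c("N","C","C","O"),
#'                    x = c(-1.5, 0, 0.5, 0.3), y = c(0, 0, 1.4, 2.5),
#'                    z = 0))
#' @export
residue <- function(aa, chainId, seqPos, atoms) {
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  new("Residue", aa = as.character(aa), chainId = as.character(chainId),
      seqPos = as.character(seqPos), atoms = atoms)
}

#' CatalyticSite: the catalytic residues of one enzyme
#'
#' Houses one enzyme's catalytic residues with their 3D coordinates plus the
#' functional and evolutionary labels the pipeline compares: EC number(s),
#' SCOP superfamily, and GO term sets per annotation domain.
#'
#' @slot siteId Unique site identifier.
#' @slot structId Source structure identifier (e.g. PDB id).
#' @slot residues List of [Residue-class] objects.
#' @slot ec Character vector of EC number strings (may be empty).
#' @slot superfamily SCOP superfamily identifier (three sccs fields) or
#'   `NA_character_`.
#' @slot go Named list of GO term character vectors per namespace
#'   (`MF`, `BP`, `CC`); empty list when unannotated.
#' @export
setClass("CatalyticSite", representation(
  siteId = "character", structId = "character", residues = "list",
  ec = "character", superfamily = "character", go = "list"
))

setValidity("CatalyticSite", function(object) {
  if (length(object@siteId) != 1L || !nzchar(object@siteId)) {
    return("siteId must be a non-empty scalar")
  }
  if (!all(vapply(object@residues, is, logical(1), "Residue"))) {
    return("residues must all be Residue objects")
  }
  if (length(object@superfamily) != 1L) return("superfamily must be scalar")
  if (length(object@go) &&
      !all(names(object@go) %in% c("MF", "BP", "CC"))) {
    return("go must be named with MF/BP/CC")
  }
  TRUE
})

#' Construct a CatalyticSite
#'
#' @param siteId Unique site identifier.
#' @param structId Source structure identifier.
#' @param residues List of [Residue-class] objects.
#' @param ec Character vector of EC numbers (default none).
#' @param superfamily SCOP superfamily id or `NA`.
#' @param go Named list (`MF`/`BP`/`CC`) of GO term vectors.
#' @return A [CatalyticSite-class] object.
#' @export
catalyticSite <- function(siteId, structId, residues, ec = character(),
                          superfamily = NA_character_, go = list()) {
  new("CatalyticSite", siteId = as.character(siteId),
      structId = as.character(structId), residues = residues,
      ec = as.character(ec), superfamily = as.character(superfamily),
      go = go)
}

#' SiteMatch: one residue correspondence between two sites
#'
#' One injective residue-index mapping between two sites together with the
#' optimal proper rigid transform superposing the represented points and the
#' resulting RMSD.
#'
#' @slot mapping Two-column integer matrix; column 1 indexes residues of the
#'   first site, column 2 of the second.
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation Length-3 numeric translation (Angstrom).
#' @slot rmsd Non-negative RMSD (Angstrom) of the superposed points.
#' @slot size Number of matched residue pairs (`|ms|`).
#' @export
setClass("SiteMatch", representation(
  mapping = "matrix", rotation = "matrix", translation = "numeric",
  rmsd = "numeric", size = "integer"
))

setValidity("SiteMatch", function(object) {
  m <- object@mapping
  if (ncol(m) != 2L) return("mapping must have two columns")
  if (object@size != nrow(m)) return("size must equal nrow(mapping)")
  if (object@size < 2L) return("a match needs at least two residue pairs")
  if (anyDuplicated(m[, 1L]) || anyDuplicated(m[, 2L])) {
    return("mapping must be injective")
  }
  if (any(dim(object@rotation) != c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(object@rotation) - 1) > 1e-6) {
    return("rotation must be proper (det +1)")
  }
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

setClassUnion("MatchOrNULL", members = c("SiteMatch", "NULL"))

#' SiteComparison: best-scoring match for an ordered site pair
#'
#' @slot queryId,targetId Site identifiers.
#' @slot bestMatch The best [SiteMatch-class] under the chosen score, or
#'   `NULL` when no match fell below the RMSD cutoff.
#' @slot scoreName Name of the score that ranked the matches.
#' @slot scoreValue Score of `bestMatch` (`NA` when absent).
#' @export
setClass("SiteComparison", representation(
  queryId = "character", targetId = "character", bestMatch = "MatchOrNULL",
  scoreName = "character", scoreValue = "numeric"
))

#' ConfusionCounts: TP/FP/TN/FN tallies
#'
#' @slot tp,fp,tn,fn Non-negative integer counts.
#' @export
setClass("ConfusionCounts", representation(
  tp = "integer", fp = "integer", tn = "integer", fn = "integer"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
  TRUE
})

#' Construct ConfusionCounts
#'
#' @param tp,fp,tn,fn Non-negative integers.
#' @return A [ConfusionCounts-class] object.
#' @examples
#' confusionCounts(61, 58, 417, 159)
#' @export
confusionCounts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' GridSearchResult: MCC-maximizing cutoffs
#'
#' @slot cuRmsd Optimal pose-score cutoff (Angstrom-scaled score units).
#' @slot cuSgo Optimal GO-similarity cutoff, or `NA` for EC agreement.
#' @slot mcc Maximized Matthews correlation coefficient.
#' @slot counts [ConfusionCounts-class] at the optimum.
#' @export
setClass("GridSearchResult", representation(
  cuRmsd = "numeric", cuSgo = "numeric", mcc = "numeric",
  counts = "ConfusionCounts"
))

setValidity("GridSearchResult", function(object) {
  if (abs(object@mcc - mcc(object@counts)) > 1e-8) {
    return("mcc inconsistent with counts")
  }
  TRUE
})

#' OntologyGraph: a rooted acyclic ontology
#'
#' Directed acyclic graph of ontology terms with `is_a`/`part_of` edges
#' pointing from child to parent, one root per namespace.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot altIds Named character vector mapping alternative ids to primary
#'   ids.
#' @export
setClass("OntologyGraph", representation(
  terms = "data.frame", edges = "data.frame", altIds = "character"
))

setValidity("OntologyGraph", function(object) {
  if (!all(c("id", "namespace") %in% names(object@terms))) {
    return("terms must have id and namespace columns")
  }
  if (nrow(object@edges)) {
    if (!all(c("child", "parent", "relation") %in% names(object@edges))) {
      return("edges must have child, parent, relation columns")
    }
    g <- igraph::graph_from_data_frame(
      object@edges[, c("child", "parent")], directed = TRUE
    )
    if (!igraph::is_dag(g)) return("ontology graph must be acyclic")
  }
  TRUE
})
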