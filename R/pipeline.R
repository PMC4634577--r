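# End-to-end classification pipeline: all-vs-all comparison, best hits,
# MCC-maximizing grid search.

#' Pose-based function classification pipeline
#'
#' Convenience wrapper chaining [compareAllSites()], [sgoMatrix()] (for GO
#' agreement), [bestHits()] and [gridSearch()]: compares every site against
#' all others under one representation and score, picks each query's most
#' similar site, and finds the cutoff(s) maximizing the MCC of the
#' thresholded best-hit classification.
#'
#' @param sites List of annotated [CatalyticSite-class] objects.
#' @param graph [OntologyGraph-class]; required for GO agreement.
#' @param rep Residue representation (see [representResidue()]).
#' @param rules Equivalence rules (see [equivalenceRules()]).
#' @param rmsdCutoff Enumeration RMSD cutoff in Angstrom; queries whose best
#'   candidates all exceed it are dropped from the counts.
#' @param scoreName Pose score (see [scoreMatch()]).
#' @param mode `"diff_sf"` (only likely non-homologs compared) or `"all"`.
#' @param agreement `"ec_class"` or `"go"`.
#' @param domains GO annotation domains for S_GO (GO agreement only).
#' @param k Best-of-k hit selection width.
#' @param rmsdGrid,sgoGrid Grids for [gridSearch()].
#' @return List with `comparisons`, `hits`, `sgo` (matrix or `NULL`) and
#'   `result` (a [GridSearchResult-class]).
#' @export
classificationPipeline <- function(sites, graph = NULL, rep = "ALL_ATOM",
                                   rules = equivalenceRules("none"),
                                   rmsdCutoff = 4.0, scoreName = "rmsd_n2",
                                   mode = c("diff_sf", "all"),
                                   agreement = c("go", "ec_class"),
                                   domains = c("BP", "MF"), k = 1L,
                                   rmsdGrid = seq(0.01, 1.50, by = 0.01),
                                   sgoGrid = seq(0.50, 1.00, by = 0.01)) {
  mode <- match.arg(mode)
  agreement <- match.arg(agreement)
  comparisons <- compareAllSites(sites, rep = rep, rules = rules,
                                 rmsdCutoff = rmsdCutoff,
                                 scoreName = scoreName)
  sgo <- NULL
  if (agreement == "go" || k > 1L) {
    if (is.null(graph)) stop("GO agreement needs an ontology graph")
    sgo <- sgoMatrix(sites, graph, domains)
  }
  hits <- bestHits(comparisons, sites, mode = mode, k = k, sgo = sgo)
  result <- gridSearch(hits, agreement = agreement, rmsdGrid = rmsdGrid,
                       sgoGrid = sgoGrid)
  list(comparisons = comparisons, hits = hits, sgo = sgo, result = result)
}
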