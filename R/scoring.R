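# Pose-similarity scores over matches. Lower is more similar for all
# built-in scores.

.scoreRegistry <- new.env(parent = emptyenv())

#' Size-normalized RMSD scores
#'
#' Two normalizations of the superposition RMSD by the number of matched
#' residues `size` (`|ms|`), both rewarding larger matches:
#' `rmsdN1 = rmsd / (size - 1)` and
#' `rmsdN2 = rmsd / max(1, 3 * size - 6)`. `rmsdN2` decreases faster with
#' the match size, favoring extensive matches more strongly.
#'
#' @param rmsd Non-negative RMSD in Angstrom.
#' @param size Number of matched residues, at least 2.
#' @return Non-negative score.
#' @examples
#' rmsdN1(1.0, 3)  # 0.5
#' rmsdN2(1.2, 3)  # 0.4
#' @export
rmsdN1 <- function(rmsd, size) {
  .checkScoreArgs(rmsd, size)
  rmsd / (size - 1)
}

#' @rdname rmsdN1
#' @export
rmsdN2 <- function(rmsd, size) {
  .checkScoreArgs(rmsd, size)
  rmsd / pmax(1, 3 * size - 6)
}

.checkScoreArgs <- function(rmsd, size) {
  if (any(size < 2)) stop("score undefined for matches of fewer than 2 residues")
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  invisible(TRUE)
}

#' Register a plug-in pose score
#'
#' Additional scores (e.g. literature scores whose formulas live outside
#' this package) can be plugged in by name. A plug-in receives the
#' [SiteMatch-class] and both [CatalyticSite-class] objects and must return
#' a finite scalar; lower values mean more similar.
#'
#' @param name Score name; used as `plugin:<name>` in score specifications.
#' @param fun Function `(match, siteA, siteB) -> numeric(1)`.
#' @return Invisibly, the name.
#' @export
registerScore <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .scoreRegistry)
  invisible(name)
}

#' Score a match under a named score
#'
#' Dispatches to one of the built-in scores (`"rmsd"`, `"rmsd_n1"`,
#' `"rmsd_n2"`) or a registered plug-in (`"plugin:<name>"`).
#'
#' @param match A [SiteMatch-class].
#' @param scoreName Score name string.
#' @param siteA,siteB The compared sites (required by plug-in scores only).
#' @return Numeric score; lower is more similar.
#' @examples
#' m <- new("SiteMatch", mapping = cbind(1:2, 1:2), rotation = diag(3),
#'          translation = numeric(3), rmsd = 0.7, size = 2L)
#' scoreMatch(m, "rmsd_n2")
#' @export
scoreMatch <- function(match, scoreName, siteA = NULL, siteB = NULL) {
  if (scoreName == "rmsd") return(match@rmsd)
  if (scoreName == "rmsd_n1") return(rmsdN1(match@rmsd, match@size))
  if (scoreName == "rmsd_n2") return(rmsdN2(match@rmsd, match@size))
  if (startsWith(scoreName, "plugin:")) {
    nm <- sub("^plugin:", "", scoreName)
    if (!exists(nm, envir = .scoreRegistry, inherits = FALSE)) {
      stop("unknown plug-in score: ", nm)
    }
    return(get(nm, envir = .scoreRegistry)(match, siteA, siteB))
  }
  stop("unknown score name: ", scoreName)
}
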