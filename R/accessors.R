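# Accessor generics and show methods.

#' @rdname accessors
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))
#' @rdname accessors
#' @export
setGeneric("structId", function(x) standardGeneric("structId"))
#' @rdname accessors
#' @export
setGeneric("siteResidues", function(x) standardGeneric("siteResidues"))
#' @rdname accessors
#' @export
setGeneric("ecNumbers", function(x) standardGeneric("ecNumbers"))
#' @rdname accessors
#' @export
setGeneric("superfamily", function(x) standardGeneric("superfamily"))
#' @rdname accessors
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))
#' @rdname accessors
#' @export
setGeneric("matchSize", function(x) standardGeneric("matchSize"))
#' @rdname accessors
#' @export
setGeneric("matchRmsd", function(x) standardGeneric("matchRmsd"))
#' @rdname accessors
#' @export
setGeneric("bestMatch", function(x) standardGeneric("bestMatch"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' Accessors for CatPose classes
#'
#' Slot accessors for [CatalyticSite-class], [SiteMatch-class],
#' [SiteComparison-class], [ConfusionCounts-class] and
#' [GridSearchResult-class] objects.
#'
#' @param x An object of the documented classes.
#' @return The corresponding slot value; `counts()` returns a named integer
#'   vector `c(tp, fp, tn, fn)`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("siteId", "CatalyticSite", function(x) x@siteId)
#' @rdname accessors
#' @export
setMethod("structId", "CatalyticSite", function(x) x@structId)
#' @rdname accessors
#' @export
setMethod("siteResidues", "CatalyticSite", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("ecNumbers", "CatalyticSite", function(x) x@ec)
#' @rdname accessors
#' @export
setMethod("superfamily", "CatalyticSite", function(x) x@superfamily)
#' @rdname accessors
#' @export
setMethod("goTerms", "CatalyticSite", function(x) x@go)
#' @rdname accessors
#' @export
setMethod("matchSize", "SiteMatch", function(x) x@size)
#' @rdname accessors
#' @export
setMethod("matchRmsd", "SiteMatch", function(x) x@rmsd)
#' @rdname accessors
#' @export
setMethod("bestMatch", "SiteComparison", function(x) x@bestMatch)
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionCounts", function(x) {
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn)
})
#' @rdname accessors
#' @export
setMethod("counts", "GridSearchResult", function(x) counts(x@counts))

#' Number of residues in a site
#'
#' @param x A [CatalyticSite-class].
#' @return Integer residue count.
#' @export
setMethod("length", "CatalyticSite", function(x) length(x@residues))

#' Is a residue one of the 20 canonical amino acids?
#'
#' @param x A [Residue-class] object or character vector of three-letter
#'   codes.
#' @return Logical.
#' @export
isCanonical <- function(x) {
  aa <- if (is(x, "Residue")) x@aa else as.character(x)
  aa %in% AA_CANONICAL
}

setMethod("show", "Residue", function(object) {
  cat(sprintf("Residue %s %s/%s with %d atoms\n", object@aa, object@chainId,
              object@seqPos, nrow(object@atoms)))
})

setMethod("show", "CatalyticSite", function(object) {
  res <- vapply(object@residues, function(r)
    paste0(r@aa, r@seqPos), character(1))
  cat(sprintf("CatalyticSite %s (structure %s)\n", object@siteId,
              object@structId))
  cat(sprintf("  residues (%d): %s\n", length(res),
              paste(res, collapse = " ")))
  cat(sprintf("  EC: %s | superfamily: %s | GO domains: %s\n",
              if (length(object@ec)) paste(object@ec, collapse = ";")
              else "-",
              ifelse(is.na(object@superfamily), "-", object@superfamily),
              if (length(object@go)) paste(names(object@go), collapse = ",")
              else "-"))
})

setMethod("show", "SiteMatch", function(object) {
  cat(sprintf("SiteMatch of %d residue pairs, RMSD %.4f A\n",
              object@size, object@rmsd))
  cat("  mapping:",
      paste(sprintf("%d-%d", object@mapping[, 1], object@mapping[, 2]),
            collapse = " "), "\n")
})

setMethod("show", "SiteComparison", function(object) {
  cat(sprintf("SiteComparison %s vs %s\n", object@queryId, object@targetId))
  if (is.null(object@bestMatch)) {
    cat("  no match under cutoff\n")
  } else {
    cat(sprintf("  best match: size %d, rmsd %.4f, %s = %.4f\n",
                object@bestMatch@size, object@bestMatch@rmsd,
                object@scoreName, object@scoreValue))
  }
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts TP=%d FP=%d TN=%d FN=%d (MCC %.2f)\n",
              object@tp, object@fp, object@tn, object@fn,
              roundHalfUp(mcc(object), 2)))
})

setMethod("show", "GridSearchResult", function(object) {
  cat(sprintf("GridSearchResult: cu_rmsd=%.2f%s, MCC=%.2f\n",
              object@cuRmsd,
              ifelse(is.na(object@cuSgo), "",
                     sprintf(", cu_sgo=%.2f", object@cuSgo)),
              roundHalfUp(object@mcc, 2)))
  show(object@counts)
})

setMethod("show", "OntologyGraph", function(object) {
  ns <- table(object@terms$namespace)
  cat(sprintf("OntologyGraph with %d terms, %d edges\n",
              nrow(object@terms), nrow(object@edges)))
  for (n in names(ns)) cat(sprintf("  %s: %d terms\n", n, ns[[n]]))
})
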