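# Residue representations: the ordered point list a residue contributes to a
# superposition.

REPRESENTATIONS <- c("CA", "CA_CB", "CA_CENTROID", "ALL_ATOM")

.atomCoords <- function(res, names) {
  a <- res@atoms
  idx <- match(names, a$name)
  m <- cbind(a$x[idx], a$y[idx], a$z[idx])
  rownames(m) <- names
  m
}

#' Represent a residue as an ordered point list
#'
#' Converts a residue into the deterministic ordered point set used for
#' superposition under one of four representations:
#' \describe{
#'   \item{CA}{the C-alpha atom.}
#'   \item{CA_CB}{C-alpha plus C-beta (glycine contributes C-alpha only).}
#'   \item{CA_CENTROID}{C-alpha plus the unweighted centroid of the
#'     side-chain heavy atoms (glycine: C-alpha only).}
#'   \item{ALL_ATOM}{all heavy atoms in canonical PDB atom-name order;
#'     hydrogens are never included.}
#' }
#'
#' @param res A [Residue-class].
#' @param rep One of `"CA"`, `"CA_CB"`, `"CA_CENTROID"`, `"ALL_ATOM"`.
#' @return Numeric matrix (points x 3) with row names labeling each point;
#'   `NULL` if the residue lacks an atom the mode requires (the residue is
#'   then unusable under this representation).
#' @examples
#' r <- residue("ALA", "A", 1, data.frame(
#'   name = c("N", "CA", "C", "O", "CB"), element = c("N","C","C","O","C"),
#'   x = c(-1.46, 0, 1.52, 2.15, -0.54), y = c(0, 0, 0, 1, 1.4),
#'   z = 0))
#' representResidue(r, "CA_CB")
#' @export
representResidue <- function(res, rep = REPRESENTATIONS) {
  rep <- match.arg(rep)
  nm <- res@atoms$name
  if (!("CA" %in% nm)) return(NULL)
  if (rep == "CA") return(.atomCoords(res, "CA"))
  if (rep == "CA_CB") {
    if (res@aa == "GLY") return(.atomCoords(res, "CA"))
    if (!("CB" %in% nm)) return(NULL)
    return(.atomCoords(res, c("CA", "CB")))
  }
  if (rep == "CA_CENTROID") {
    if (res@aa == "GLY") return(.atomCoords(res, "CA"))
    side <- setdiff(intersect(.canonicalOrder(res@aa), nm),
                    c("N", "CA", "C", "O"))
    if (!length(side)) return(NULL)
    sc <- .atomCoords(res, side)
    out <- rbind(.atomCoords(res, "CA"), colMeans(sc))
    rownames(out) <- c("CA", "SC_CENTROID")
    return(out)
  }
  # ALL_ATOM: heavy atoms present in the residue, canonical order (file
  # order for non-canonical residue types)
  keep <- .representKeep(res)
  .atomCoords(res, keep)
}

# Canonical atom-name order; unknown residue types fall back to the order in
# which atoms appear (after backbone), so non-canonical residues read from a
# file remain representable.
.canonicalOrder <- function(aa) {
  ord <- AA_ATOM_ORDER[[aa]]
  if (is.null(ord)) return(character(0))
  ord
}

# For residues of unknown type, ALL_ATOM keeps file order.
.representKeep <- function(res) {
  ord <- .canonicalOrder(res@aa)
  nm <- res@atoms$name
  if (length(ord)) intersect(ord, nm) else nm
}
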