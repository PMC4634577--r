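# Idealized residue geometry for the synthetic-site generator: heavy-atom
# coordinates built from standard bond lengths/angles (no rotamer library).
# Good enough for RMSD behavior; not a physical model.

# Place atom D given reference atoms A-B-C, the C-D bond length, the B-C-D
# angle (degrees) and the A-B-C-D dihedral (degrees). Natural-extension
# (NeRF) construction.
.placeAtom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-9) {                       # collinear refs: pick any normal
    n <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * bc) * bc
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Planar regular ring attached at an anchor atom: first vertex is the anchor
# atom, the ring plane contains the stem direction. Returns vertex
# coordinates (excluding the anchor vertex itself).
.ringAtoms <- function(stem, anchor, nVertices, side) {
  u <- anchor - stem
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- a - sum(a * u) * u
  w <- w / sqrt(sum(w^2))
  radius <- side / (2 * sin(pi / nVertices))
  center <- anchor + radius * u
  theta <- 2 * pi * seq_len(nVertices - 1L) / nVertices
  t(vapply(theta, function(th) {
    center + radius * (cos(th) * (-u) + sin(th) * w)
  }, numeric(3)))
}

# Side-chain z-matrix rows per residue type: atom, three reference atoms,
# bond, angle, dihedral. Ring systems are closed analytically afterwards.
.SIDECHAIN_ZMAT <- list(
  ALA = NULL,
  GLY = NULL,
  SER = list(c("OG", "N", "CA", "CB", 1.42, 110.8, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.81, 114.0, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.43, 109.6, 180),
             c("CG2", "N", "CA", "CB", 1.52, 110.5, -60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.52, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.52, 110.5, 60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.53, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.53, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.52, 113.0, 180)),
  LEU = list(c("CG", "N", "CA", "CB", 1.53, 116.0, 180),
             c("CD1", "CA", "CB", "CG", 1.52, 110.5, 60),
             c("CD2", "CA", "CB", "CG", 1.52, 110.5, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("SD", "CA", "CB", "CG", 1.81, 112.0, 180),
             c("CE", "CB", "CG", "SD", 1.79, 100.0, 180)),
  ASP = list(c("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.25, 118.4, 90),
             c("OD2", "CA", "CB", "CG", 1.25, 118.4, -90)),
  ASN = list(c("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.23, 120.8, 90),
             c("ND2", "CA", "CB", "CG", 1.33, 116.4, -90)),
  GLU = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.25, 118.4, 90),
             c("OE2", "CB", "CG", "CD", 1.25, 118.4, -90)),
  GLN = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.23, 120.8, 90),
             c("NE2", "CB", "CG", "CD", 1.33, 116.4, -90)),
  LYS = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.0, 180),
             c("CE", "CB", "CG", "CD", 1.52, 111.0, 180),
             c("NZ", "CG", "CD", "CE", 1.47, 112.0, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.52, 111.0, 180),
             c("CD", "CA", "CB", "CG", 1.52, 111.0, 180),
             c("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.33, 124.0, 180),
             c("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180)),
  PHE = list(c("CG", "N", "CA", "CB", 1.51, 114.0, 180)),
  TYR = list(c("CG", "N", "CA", "CB", 1.51, 114.0, 180))
)

# Ring definitions: vertex order starting at CG (anchored on CB-CG stem).
.RING_ATOMS <- list(
  HIS = list(order = c("ND1", "CE1", "NE2", "CD2"), side = 1.37),
  PHE = list(order = c("CD1", "CE1", "CZ", "CE2", "CD2"), side = 1.39),
  TYR = list(order = c("CD1", "CE1", "CZ", "CE2", "CD2"), side = 1.39)
)

.ELEMENT_OF <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

#' Idealized heavy-atom coordinates of a residue
#'
#' Builds a residue's heavy atoms from standard internal coordinates in a
#' local frame (C-alpha at the origin). Supports the catalytic residue pool
#' plus the common hydrophobics; tryptophan and proline have no idealized
#' template here.
#'
#' @param aa Three-letter residue code.
#' @return Numeric matrix (atoms x 3) with atom-name row names.
#' @keywords internal
idealResidueCoords <- function(aa) {
  if (!aa %in% names(.SIDECHAIN_ZMAT)) {
    stop("no idealized geometry for residue type ", aa)
  }
  coords <- list(
    CA = c(0, 0, 0),
    N = c(-1.458, 0, 0),
    C = 1.525 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  )
  coords$O <- .placeAtom(coords$N, coords$CA, coords$C, 1.231, 120.5, 0)
  if (aa != "GLY") {
    coords$CB <- .placeAtom(coords$C, coords$N, coords$CA, 1.53, 110.4,
                            122.6)
  }
  for (row in .SIDECHAIN_ZMAT[[aa]]) {
    coords[[row[1]]] <- .placeAtom(coords[[row[2]]], coords[[row[3]]],
                                   coords[[row[4]]], as.numeric(row[5]),
                                   as.numeric(row[6]), as.numeric(row[7]))
  }
  ring <- .RING_ATOMS[[aa]]
  if (!is.null(ring)) {
    rc <- .ringAtoms(coords$CB, coords$CG, length(ring$order) + 1L,
                     ring$side)
    for (k in seq_along(ring$order)) coords[[ring$order[k]]] <- rc[k, ]
    if (aa == "TYR") {
      u <- coords$CG - coords$CB
      u <- u / sqrt(sum(u^2))
      coords$OH <- coords$CZ + 1.37 * u
    }
  }
  ord <- AA_ATOM_ORDER[[aa]]
  m <- t(vapply(ord, function(nm) coords[[nm]], numeric(3)))
  rownames(m) <- ord
  m
}

# A residue object in a local frame transformed by rotation R and
# translation t.
.buildResidue <- function(aa, chainId, seqPos, R, tr) {
  m <- idealResidueCoords(aa)
  xyz <- m %*% t(R)
  xyz <- sweep(xyz, 2, tr, "+")
  residue(aa, chainId, seqPos, data.frame(
    name = rownames(m), element = .ELEMENT_OF(rownames(m)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, sign-fixed).
.randomRotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q)
  d <- diag(sign(diag(qr.R(q))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
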