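# Fixture builders: residues and sites constructed in code.

# Residue with idealized geometry placed at `ca` with rotation `R`.
idealRes <- function(aa, seqPos = 1L, chain = "A", ca = c(0, 0, 0),
                     R = diag(3)) {
  CatPose:::.buildResidue(aa, chain, seqPos, R, ca)
}

# A site of idealized residues at given C-alpha positions.
makeSite <- function(id, types, ca = NULL, chain = "A", ec = character(),
                     sf = NA_character_, go = list(), rotations = NULL,
                     struct = id) {
  n <- length(types)
  if (is.null(ca)) ca <- cbind(5 * seq_len(n), 0, 0)
  res <- lapply(seq_len(n), function(i) {
    R <- if (is.null(rotations)) diag(3) else rotations[[i]]
    idealRes(types[i], seqPos = i, chain = chain, ca = ca[i, ], R = R)
  })
  catalyticSite(id, struct, res, ec = ec, superfamily = sf, go = go)
}

# Random site: random residue types, non-degenerate geometry, random
# per-residue orientations.
randomSite <- function(id, n, types = NULL, pool = CatPose:::AA_CATALYTIC_POOL) {
  if (is.null(types)) types <- sample(pool, n, replace = TRUE)
  ca <- CatPose:::.templateCa(n)
  rot <- replicate(n, CatPose:::.randomRotation(), simplify = FALSE)
  makeSite(id, types, ca = ca, rotations = rot)
}

randomRotation <- function() CatPose:::.randomRotation()

# Apply a rigid motion to every atom of a site.
rigidMove <- function(site, R = randomRotation(), tr = runif(3, -20, 20)) {
  site@residues <- lapply(site@residues, function(r) {
    xyz <- as.matrix(r@atoms[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, tr, "+")
    r@atoms$x <- xyz[, 1]; r@atoms$y <- xyz[, 2]; r@atoms$z <- xyz[, 3]
    r
  })
  site
}
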