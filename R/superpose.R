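# Optimal rigid-body superposition (Kabsch algorithm).

#' Least-RMSD proper rigid superposition of two point sets
#'
#' Computes the proper rigid transform (rotation + translation, no
#' reflection) that maps the points `Q` onto the points `P` with minimal
#' RMSD, via SVD of the cross-covariance matrix (Kabsch). Degenerate inputs
#' (collinear or coincident points) still return a minimizer; the sign of
#' the smallest singular vector is corrected so that a reflection is never
#' returned.
#'
#' @param P Fixed points, n x 3 numeric matrix.
#' @param Q Mobile points, n x 3 numeric matrix (same n >= 1).
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd`, such that `Q %*% t(rotation) + translation` best fits `P` and
#'   `rmsd = sqrt(mean(rowSums((P - fit)^2)))`.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' superposePoints(tri, tri)$rmsd
#' @export
superposePoints <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 1L)
  if (!all(is.finite(P)) || !all(is.finite(Q))) {
    stop("points must be finite")
  }
  n <- nrow(P)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Qc, Pc)                       # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1                           # rank-deficient: keep proper
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.vector(pc - R %*% qc)
  fit <- Qc %*% t(R)
  rmsd <- sqrt(sum((Pc - fit)^2) / n)
  list(rotation = R, translation = tr, rmsd = rmsd)
}
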