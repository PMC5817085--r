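# Least-squares rigid superposition (Kabsch) of paired point sets.

#' Superpose paired point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' point sets given in paired order, by singular value decomposition of the
#' cross-covariance matrix. Reflections are never returned: if the best
#' orthogonal transform is improper, the smallest singular direction is
#' flipped, giving the best proper rotation.
#'
#' @param ref_points k x 3 matrix of reference coordinates.
#' @param mov_points k x 3 matrix of moving coordinates, paired row-by-row.
#' @return List of class `phk_alignment` with elements `rotation` (3 x 3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom), `pairing`
#'   (integer identity map, kept for bookkeeping when callers reorder sites)
#'   and `degenerate` (TRUE when the moving set is collinear or coincident,
#'   in which case the rotation about the degenerate axis is arbitrary).
#'   The fitted transform maps moving points onto the reference:
#'   `x_ref ~ rotation %*% x_mov + translation`.
#' @export
align_to_reference <- function(ref_points, mov_points) {
  ref_points <- as.matrix(ref_points)
  mov_points <- as.matrix(mov_points)
  k <- nrow(ref_points)
  if (k < 3L) stop("superposition needs at least 3 paired points")
  if (!all(dim(ref_points) == dim(mov_points)))
    stop("ref_points and mov_points must have identical dimensions")

  cref <- colMeans(ref_points)
  cmov <- colMeans(mov_points)
  A <- sweep(ref_points, 2, cref)
  B <- sweep(mov_points, 2, cmov)

  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u)

  # collinear/coincident point sets leave one rotational degree of freedom
  degenerate <- sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)

  fitted <- B %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  translation <- as.numeric(cref - rot %*% cmov)

  structure(list(rotation = rot, translation = translation, rmsd = rmsd,
                 pairing = seq_len(k), degenerate = degenerate),
            class = "phk_alignment")
}

#' RMSD between paired point sets without refitting
#'
#' @param a,b k x 3 matrices in paired order.
#' @return Root-mean-square deviation in the given frames (no superposition).
#' @export
paired_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}

# random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
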