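# Small geometry helpers shared across modules. All coordinates are mm in
# world space and px in image space; frames are 0-based indices.

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps * 100) stop("cannot normalize a (near-)zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about unit axis `axis`.
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  a <- unitv(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform-ish random rotation from three Euler-like draws; adequate for
# invariance tests (exact uniformity on SO(3) is not needed).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Apply p' = s * R p + t to an n x 3 matrix of row points.
apply_similarity <- function(pts, R = diag(3), t = c(0, 0, 0), s = 1) {
  stopifnot(ncol(pts) == 3)
  sweep(s * (pts %*% t(R)), 2, t, "+")
}

#' Least-squares similarity alignment of two point sets
#'
#' Kabsch/Umeyama estimate of the rotation (det +1), translation and optional
#' isotropic scale mapping `from` onto `to`, minimizing the summed squared
#' distances. Row i of `from` corresponds to row i of `to`.
#'
#' @param from,to n x 3 matrices of corresponding points (n >= 3).
#' @param scale estimate an isotropic scale factor as well?
#' @return list with `R` (3x3), `t` (length 3), `s` (scalar), and `rmsd`.
#' @export
fit_similarity <- function(from, to, scale = TRUE) {
  from <- as.matrix(from); to <- as.matrix(to)
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3, nrow(from) >= 3)
  cf <- colMeans(from); ct <- colMeans(to)
  X <- sweep(from, 2, cf); Y <- sweep(to, 2, ct)
  S <- crossprod(X, Y)                      # 3x3 covariance
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (scale) {
    varX <- sum(X^2)
    if (varX < 1e-12) 1 else sum(diag(D) * sv$d) / varX
  } else 1
  t <- ct - s * as.vector(R %*% cf)
  fitted <- apply_similarity(from, R, t, s)
  list(R = R, t = t, s = s, rmsd = sqrt(mean(rowSums((fitted - to)^2))))
}

# Row-wise Euclidean distances between two n x 3 matrices.
row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

# Full pairwise distance matrix between rows of a (n x d) and b (m x d).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Derive a 32-bit sub-seed from a base seed and a stage name, so every
# stochastic stage of a run is reproducible from one global seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}
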