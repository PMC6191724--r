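# Small geometry helpers shared by the fixture generator, base-pair
# detection and decoy generation.

#' @keywords internal
rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), -sin(t), 0,
           sin(t),  cos(t), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# 180 degree rotation about the y axis: maps one duplex strand frame onto
# the antiparallel partner strand.
#' @keywords internal
rot_y180 <- function() {
  diag(c(-1, 1, -1))
}

#' @keywords internal
rot_x <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(t), -sin(t),
           0, sin(t),  cos(t)), 3, 3, byrow = TRUE)
}

# uniform random rotation matrix via normalized quaternion
#' @keywords internal
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# uniform random unit vector
#' @keywords internal
random_direction <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' @keywords internal
unit <- function(v) v / sqrt(sum(v^2))

# an orthonormal basis (u, p1, p2) given unit vector u
#' @keywords internal
orthobasis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p1 <- unit(pracma_cross(u, a))
  p2 <- pracma_cross(u, p1)
  list(u = u, p1 = p1, p2 = p2)
}

#' @keywords internal
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# least-squares plane normal of a point set (rows of m)
#' @keywords internal
plane_normal <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  sv <- svd(m)
  sv$v[, 3]
}

# minimal distance between two point sets (n x 3 matrices), blockwise
#' @keywords internal
min_cross_distance <- function(a, b) {
  sqrt(min(cross_dist2(a, b)))
}

# squared distance matrix between rows of a and rows of b
#' @keywords internal
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}
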