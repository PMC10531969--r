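#' Rigid transform (rotation + translation)
#'
#' A proper rigid motion of 3-space, `x -> R x + t`, with `R` a 3x3 rotation
#' matrix (orthonormal, det +1) and `t` a translation in mm.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation vector (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
#' @examples
#' rt <- rigid_transform(diag(3), c(1, 0, 0))
#' rt_apply(rt, matrix(0, 1, 3))
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal (R'R != I within 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    stop("rotation matrix is not proper (det != +1 within 1e-9)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to points
#'
#' @param rt A [rigid_transform()].
#' @param points n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(rt, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  sweep(p %*% t(rt$R), 2, rt$t, `+`)
}

#' Compose rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`
#' (i.e. the composition `a o b`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
rt_compose <- function(a, b) {
  rigid_transform(project_rotation(a$R %*% b$R), as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param rt A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
rt_invert <- function(rt) {
  rigid_transform(t(rt$R), as.numeric(-t(rt$R) %*% rt$t))
}

#' Rotation about an axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @param center optional point the axis passes through (default origin).
#' @return A [rigid_transform()].
#' @export
rt_axis_angle <- function(axis, angle_deg, center = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  R <- project_rotation(R)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Rotation angle of a rigid transform
#'
#' @param rt A [rigid_transform()].
#' @return Angle of the rotation part in degrees, in \[0, 180\].
#' @export
rt_angle_deg <- function(rt) {
  c_th <- (sum(diag(rt$R)) - 1) / 2
  acos(min(1, max(-1, c_th))) * 180 / pi
}

# Nearest rotation matrix in Frobenius norm (SVD projection); guards against
# numerical drift when composing many transforms.
#' @noRd
project_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  angle", sprintf("%.3f", rt_angle_deg(x)),
      "deg,  translation [",
      paste(sprintf("%.3f", x$t), collapse = ", "), "] mm\n")
  invisible(x)
}

#' @noRd
unit3 <- function(v) v / sqrt(sum(v^2))

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
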