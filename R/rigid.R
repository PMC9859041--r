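#' Rigid-body transforms and coordinate frames
#'
#' A rigid transform is a proper rotation plus a translation; applying it to
#' a point `x` gives `R %*% x + t`. A coordinate frame is an origin plus an
#' orthonormal, right-handed axis matrix (axes stored as columns x, y, z);
#' frame-local coordinates map to world coordinates through the frame's
#' rotation and origin.
#'
#' @name rigid
NULL

#' Construct a rigid transform
#'
#' @param R 3x3 proper rotation matrix (orthonormal, det +1).
#' @param t length-3 translation vector, Angstrom.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(identical(dim(R), c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  if (abs(det(R) - 1) > 1e-8)
    stop("rotation matrix must be proper (det +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf A `rigid_transform`.
#' @param x A 3-vector or an n x 3 matrix of coordinates.
#' @return Transformed coordinates with the shape of `x`.
#' @export
apply_transform <- function(tf, x) {
  if (is.matrix(x)) {
    sweep(x %*% t(tf$R), 2, tf$t, "+")
  } else {
    as.numeric(tf$R %*% x + tf$t)
  }
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first,
#' then `a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_transforms
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Construct a coordinate frame
#'
#' @param origin length-3 origin, Angstrom.
#' @param axes 3x3 matrix whose columns are the x, y, z unit axes.
#' @return An object of class `frame`.
#' @export
coordinate_frame <- function(origin, axes) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, identical(dim(axes), c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-8)
    stop("frame axes are not orthonormal")
  if (sum(vcross(axes[, 1], axes[, 2]) * axes[, 3]) < 0)
    stop("frame is not right-handed")
  structure(list(origin = origin, axes = axes), class = "frame")
}

#' @rdname coordinate_frame
#' @export
identity_frame <- function() coordinate_frame(c(0, 0, 0), diag(3))

#' Convert between frames and transforms
#'
#' A frame is equivalent to the rigid transform taking frame-local
#' coordinates to world coordinates.
#'
#' @param f A `frame`.
#' @return `frame_to_transform`: a `rigid_transform`;
#'   `transform_to_frame`: a `frame`.
#' @export
frame_to_transform <- function(f) rigid_transform(f$axes, f$origin)

#' @rdname frame_to_transform
#' @param tf A `rigid_transform`.
#' @export
transform_to_frame <- function(tf) coordinate_frame(tf$t, tf$R)

#' Transform a frame by a global rigid motion
#'
#' @param tf A `rigid_transform` (the global motion).
#' @param f A `frame`.
#' @return The moved `frame`.
#' @export
transform_frame <- function(tf, f) {
  coordinate_frame(apply_transform(tf, f$origin), tf$R %*% f$axes)
}

## --- small vector helpers ---------------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(x) sqrt(sum(x^2))

vunit <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  x / n
}

#' Rotation about an axis
#'
#' Rodrigues' formula; right-handed rotation by `angle` about unit `axis`.
#'
#' @param axis length-3 vector (normalized internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  k <- vunit(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Minimal rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    # antiparallel: rotate pi about any axis perpendicular to a
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(vcross(a, ref), pi))
  }
  rotation_about_axis(vcross(a, b), acos(max(-1, min(1, d))))
}

## Axis (unit) and angle of a rotation matrix. For angles near pi the axis is
## recovered from the symmetric part, with sign fixed by the skew part where
## it is nonzero.
rotation_axis_angle <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  skew <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(skew) > 1e-8) {
    axis <- vunit(skew)
  } else if (ang > 1) {
    # angle ~ pi: R ~ 2 a a^T - I
    M <- (R + diag(3)) / 2
    j <- which.max(diag(M))
    axis <- vunit(M[, j])
  } else {
    axis <- c(1, 0, 0)  # angle ~ 0: axis undefined
  }
  list(axis = axis, angle = ang)
}

#' Dihedral angle of four points
#'
#' Standard signed torsion of points `p1-p2-p3-p4` about the `p2->p3` axis,
#' in radians in (-pi, pi]. A right-handed rotation of `p4` about the
#' `p2->p3` axis increases the angle.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return Angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

## Wrap an angle into (-pi, pi].
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  ifelse(w <= -pi, w + 2 * pi, w)
}

#' Random rotation matrix
#'
#' Uniform over SO(3) via quaternions; uses the current RNG stream.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Random rigid transform
#'
#' @param max_translation Upper bound on the uniform translation magnitude.
#' @return A `rigid_transform`.
#' @export
random_transform <- function(max_translation = 20) {
  rigid_transform(random_rotation(), stats::runif(3, -max_translation, max_translation))
}
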