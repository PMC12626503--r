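# Package-wide tolerances: exact algebra at 1e-9 mm, on-plane snapping for
# discrete meshes at 1e-6 mm.  Discrete-mesh agreement scales with edge length
# and is reported by the fixture generators, not fixed here.
.tol_exact <- 1e-9
.tol_mesh <- 1e-6

#' Create a 3D point
#'
#' Points are plain numeric length-3 vectors in millimetres; this helper
#' validates finiteness.
#'
#' @param x,y,z Coordinates in mm, or `x` a length-3 numeric vector.
#' @return A numeric vector of length 3.
#' @export
point3 <- function(x, y = NULL, z = NULL) {
  p <- if (is.null(y)) as.numeric(x) else c(x, y, z)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop("point3: need three finite coordinates", call. = FALSE)
  }
  unname(p)
}

#' Normalize a vector to unit length
#'
#' @param v Numeric length-3 vector.
#' @return Unit vector.
#' @export
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .tol_exact) stop("unit3: zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Create an oriented infinite plane
#'
#' @param origin A point on the plane (mm).
#' @param normal Plane normal; normalized internally.
#' @return An object of class `condylo_plane` with fields `origin`, `normal`.
#' @export
plane3 <- function(origin, normal) {
  structure(list(origin = point3(origin), normal = unit3(as.numeric(normal))),
            class = "condylo_plane")
}

#' @export
print.condylo_plane <- function(x, ...) {
  cat(sprintf("<plane> origin (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

is_plane <- function(x) inherits(x, "condylo_plane")

#' Test whether two planes are parallel
#'
#' Parallel means |n1 . n2| > 1 - 1e-9.
#'
#' @param p1,p2 Planes.
#' @return Logical.
#' @export
planes_parallel <- function(p1, p2) {
  abs(sum(p1$normal * p2$normal)) > 1 - .tol_exact
}

#' Signed distance from a point to a plane
#'
#' Positive on the side the normal points to; the vertical height of a
#' landmark above the osteotomy plane is its signed distance to that plane.
#'
#' @param point A point (length-3) or an n x 3 matrix of points.
#' @param plane A `condylo_plane`.
#' @return Signed distance(s) in mm.
#' @export
signed_distance <- function(point, plane) {
  stopifnot(is_plane(plane))
  if (is.matrix(point)) {
    drop((point - matrix(plane$origin, nrow(point), 3, byrow = TRUE)) %*%
           plane$normal)
  } else {
    sum((point - plane$origin) * plane$normal)
  }
}

#' Orthogonally project points onto a plane
#'
#' @inheritParams signed_distance
#' @return Projected point(s), same shape as input.
#' @export
project_to_plane <- function(point, plane) {
  d <- signed_distance(point, plane)
  if (is.matrix(point)) {
    point - outer(d, plane$normal)
  } else {
    point - d * plane$normal
  }
}

#' Fit the Frankfort horizontal plane through bilateral porion and orbitale
#'
#' The cranial reference plane is the plane through the left and right porion
#' and the orbitale.  The measurement protocol fixes only parallelism of
#' downstream planes to this one, not its orientation, so the caller declares
#' the superior side
#' with a reference point: the normal is flipped so `superior_ref` has
#' positive signed distance.
#'
#' @param porion_left,porion_right,orbitale Landmark points (mm).
#' @param superior_ref A point on the superior (cranial) side of the plane.
#' @return A `condylo_plane` through the three landmarks.
#' @export
fit_frankfort_plane <- function(porion_left, porion_right, orbitale,
                                superior_ref) {
  pl <- point3(porion_left); pr <- point3(porion_right)
  ob <- point3(orbitale)
  n <- cross3(pr - pl, ob - pl)
  len <- sqrt(sum(n^2))
  scale <- max(sqrt(sum((pr - pl)^2)), sqrt(sum((ob - pl)^2)))
  if (len < .tol_exact * max(scale^2, 1)) {
    stop("fit_frankfort_plane: porions and orbitale are collinear",
         call. = FALSE)
  }
  pln <- plane3(pl, n / len)
  d <- signed_distance(point3(superior_ref), pln)
  if (abs(d) < .tol_exact) {
    stop("fit_frankfort_plane: superior reference lies on the plane",
         call. = FALSE)
  }
  if (d < 0) pln$normal <- -pln$normal
  pln
}

#' Create a rigid (proper orthogonal) transform
#'
#' @param rotation 3x3 rotation matrix, `R^T R = I`, `det = +1` within 1e-9.
#' @param translation Length-3 translation in mm.
#' @return An object of class `condylo_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      det(rotation) < 0) {
    stop("rigid_transform: rotation must be orthonormal with det +1",
         call. = FALSE)
  }
  structure(list(R = rotation, t = point3(translation)),
            class = "condylo_rigid")
}

#' Rotation about a coordinate axis or arbitrary axis
#'
#' @param axis Unit axis of rotation (length-3).
#' @param angle Rotation angle in radians (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- unit3(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

#' Apply a rigid transform to points, a plane, or a mesh
#'
#' @param x A point, n x 3 point matrix, `condylo_plane`, or `condylo_mesh`.
#' @param transform A `condylo_rigid`.
#' @return Object of the same type, rigidly moved.
#' @export
apply_rigid <- function(x, transform) {
  stopifnot(inherits(transform, "condylo_rigid"))
  R <- transform$R; tr <- transform$t
  if (is_plane(x)) {
    plane3(drop(R %*% x$origin) + tr, drop(R %*% x$normal))
  } else if (inherits(x, "condylo_mesh")) {
    v <- x$vertices %*% t(R)
    v <- sweep(v, 2, tr, "+")
    triangle_mesh(v, x$faces, validate = FALSE)
  } else if (is.matrix(x)) {
    sweep(x %*% t(R), 2, tr, "+")
  } else {
    drop(R %*% point3(x)) + tr
  }
}

#' Compose two rigid transforms (apply `b` then `a`)
#'
#' @param a,b `condylo_rigid` transforms.
#' @return The composed transform.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$R %*% b$R, drop(a$R %*% b$t) + a$t)
}

# Orthonormal in-plane basis (u, v) with u x v = normal.
plane_basis <- function(plane) {
  n <- plane$normal
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(seed - sum(seed * n) * n)
  v <- cross3(n, u)
  list(u = u, v = v)
}

# Map 3D points to 2D coordinates in the plane's intrinsic basis.
to_plane_coords <- function(points, plane, basis = plane_basis(plane)) {
  if (!is.matrix(points)) points <- matrix(points, 1, 3)
  rel <- sweep(points, 2, plane$origin)
  cbind(rel %*% basis$u, rel %*% basis$v)
}

from_plane_coords <- function(uv, plane, basis = plane_basis(plane)) {
  if (!is.matrix(uv)) uv <- matrix(uv, 1, 2)
  sweep(outer(uv[, 1], basis$u) + outer(uv[, 2], basis$v), 2,
        plane$origin, "+")
}
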