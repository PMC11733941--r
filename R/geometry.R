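# Low-level 3-D primitives: canonical placement of the first three vertices,
# three-sphere trilateration, plane-orientation bits and reflections.
# Points are plain numeric length-3 vectors (Angstrom); a plane reference is a
# 3 x 3 matrix whose rows are the three defining points.

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.norm3 <- function(v) sqrt(sum(v * v))

.check_ref <- function(ref, tol = 1e-9) {
  if (!is.matrix(ref) || nrow(ref) != 3L || ncol(ref) != 3L || !all(is.finite(ref)))
    stop("degenerate-reference: 'ref' must be a finite 3 x 3 matrix of points")
  a2 <- .norm3(.cross3(ref[2L, ] - ref[1L, ], ref[3L, ] - ref[1L, ]))
  if (a2 <= tol)
    stop("degenerate-reference: the three reference points are (near) collinear")
  invisible(a2)
}

#' Place the first three vertices in the canonical frame
#'
#' Fixes the global rigid motion of a DMDGP solution by pinning the first
#' three vertices: vertex 1 at the origin, vertex 2 on the negative x axis,
#' and vertex 3 in the upper (`y > 0`) half of the xy plane, with the angle at
#' vertex 1 given by the law of cosines.
#'
#' @param d12,d13,d23 Pairwise distances (Angstrom) between the three
#'   vertices. Must be positive and satisfy the triangle inequality strictly.
#' @return A 3 x 3 numeric matrix whose rows are the coordinates of vertices
#'   1, 2 and 3.
#' @examples
#' place_first_three(1, 1, 1)
#' @export
place_first_three <- function(d12, d13, d23) {
  if (!all(is.finite(c(d12, d13, d23))) || any(c(d12, d13, d23) <= 0))
    stop("infeasible-geometry: distances must be positive and finite")
  ct <- (d12^2 + d13^2 - d23^2) / (2 * d12 * d13)
  if (abs(ct) >= 1)
    stop("infeasible-geometry: triangle inequality violated for (",
         d12, ", ", d13, ", ", d23, ")")
  st <- sqrt(1 - ct^2)
  rbind(c(0, 0, 0),
        c(-d12, 0, 0),
        c(-d13 * ct, d13 * st, 0))
}

#' Intersect three spheres (trilateration)
#'
#' Closed-form intersection of the spheres centred at `a`, `b`, `c` with radii
#' `ra`, `rb`, `rc`, computed in a local orthonormal frame of the three
#' centres. Generic inputs yield two points, mirror images through the plane
#' of the centres; when the intersection lies in that plane (discriminant
#' within `tol^2` of zero) a single point is returned, and an empty list when
#' the spheres do not meet.
#'
#' @param a,b,c Sphere centres, numeric length-3 (must not be collinear).
#' @param ra,rb,rc Sphere radii (Angstrom).
#' @param tol Tolerance (Angstrom) deciding the degenerate single-point case
#'   and near-miss emptiness; the discriminant is clipped to zero when within
#'   `tol^2`.
#' @return A list of 0, 1 or 2 points. With two points the
#'   positive-orientation point (orientation bit 1 with respect to the plane
#'   `(a, b, c)`) comes first.
#' @seealso [orientation_bit()]
#' @export
trilaterate <- function(a, b, c, ra, rb, rc, tol = 1e-4) {
  ex <- b - a
  d <- .norm3(ex)
  if (d <= 0) stop("degenerate-reference: coincident sphere centres")
  ex <- ex / d
  ac <- c - a
  i <- sum(ex * ac)
  eyv <- ac - i * ex
  e <- .norm3(eyv)
  if (e <= 1e-9 * max(1, d))
    stop("degenerate-reference: collinear sphere centres")
  ey <- eyv / e
  ez <- .cross3(ex, ey)
  x <- (ra^2 - rb^2 + d^2) / (2 * d)
  y <- (ra^2 - rc^2 + i^2 + e^2 - 2 * i * x) / (2 * e)
  z2 <- ra^2 - x^2 - y^2
  if (z2 < -(tol^2)) return(list())
  base <- a + x * ex + y * ey
  if (z2 <= tol^2) return(list(base))
  z <- sqrt(z2)
  # (ex, ey, ez) is right handed, so +z has positive signed volume: bit 1 first
  list(base + z * ez, base - z * ez)
}

#' Orientation bit of a point relative to a reference plane
#'
#' Returns 1 when the signed volume `det[p2 - p1, p3 - p1, p - p1]` exceeds
#' `tol`, and 0 when below `-tol` or within the on-plane band (the on-plane
#' convention assigns bit 0).
#'
#' @param ref 3 x 3 matrix of reference points (rows `p1`, `p2`, `p3`), which
#'   must be non-collinear.
#' @param p Query point.
#' @param tol On-plane tolerance in signed-volume units (Angstrom^3). The
#'   default suits exact synthetic coordinates; around `1e-3` is recommended
#'   for experimental (PDB) coordinates.
#' @return Integer 0 or 1.
#' @export
orientation_bit <- function(ref, p, tol = 1e-7) {
  .check_ref(ref)
  v <- .signed_volume(ref, p)
  if (v > tol) 1L else 0L
}

.signed_volume <- function(ref, p) {
  u <- ref[2L, ] - ref[1L, ]
  v <- ref[3L, ] - ref[1L, ]
  w <- p - ref[1L, ]
  sum(.cross3(u, v) * w)
}

#' Reflect a point through a plane
#'
#' Mirror image of `p` through the plane spanned by the rows of `ref`.
#' An involution; points in the plane are fixed.
#'
#' @inheritParams orientation_bit
#' @return The reflected point (numeric length 3).
#' @export
reflect <- function(ref, p) {
  .check_ref(ref)
  n <- .cross3(ref[2L, ] - ref[1L, ], ref[3L, ] - ref[1L, ])
  n <- n / .norm3(n)
  p - 2 * sum((p - ref[1L, ]) * n) * n
}
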