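#' Incremental convex hull with running volume
#'
#' A small geometric engine used to accumulate ROC operating points and
#' report the volume of their convex hull after each batch, in
#' dimensions 2 to 4. The hull is grown by the beneath-beyond method: a
#' point outside the current hull replaces the facets it can "see" by
#' the cone over the horizon ridges, and the volume grows by the union
#' of pyramids over the removed facets, so the volume never decreases.
#'
#' All computation is exact: points are snapped to a lattice of spacing
#' `snap` and every geometric predicate is evaluated in integer
#' arithmetic, so the reported volume is the exact hull volume of the
#' snapped point set and is immune to floating-point degeneracies (the
#' operating-point clouds this engine is built for are full of coplanar
#' and duplicated points). Lattice coordinates must stay within
#' `65536 * snap` in absolute value.
#'
#' @param simplex A (d+1) x d matrix of affinely independent starting
#'   points (for ROC use: the unit vectors and the origin, whose hull
#'   volume 1/d! is the random-classifier floor).
#' @param snap Lattice spacing to which all coordinates are rounded.
#' @return An object of class `"incremental_hull"`.
#' @examples
#' h <- incremental_hull(rbind(diag(3), 0))
#' hull_volume(h)                       # 1/6
#' hull_insert(h, as.matrix(expand.grid(0:1, 0:1, 0:1)))
#' hull_volume(h)                       # 1: the unit cube
#' @export
incremental_hull <- function(simplex, snap = 1e-4) {
  simplex <- as.matrix(simplex)
  obj <- list(ptr = .hull_new(simplex, snap), d = ncol(simplex), snap = snap)
  class(obj) <- "incremental_hull"
  obj
}

#' @rdname incremental_hull
#' @param hull An `"incremental_hull"` object.
#' @param points Matrix of points (rows) to insert; points inside the
#'   current hull are ignored.
#' @return `hull_insert()` returns the updated volume, invisibly the
#'   hull; `hull_volume()` the current volume.
#' @export
hull_insert <- function(hull, points) {
  stopifnot(inherits(hull, "incremental_hull"))
  points <- as.matrix(points)
  if (ncol(points) != hull$d) stop("dimension mismatch")
  .hull_add(hull$ptr, points)
}

#' @rdname incremental_hull
#' @export
hull_volume <- function(hull) {
  stopifnot(inherits(hull, "incremental_hull"))
  .hull_volume(hull$ptr)
}

#' @export
print.incremental_hull <- function(x, ...) {
  cat(sprintf("Incremental convex hull in %d dimensions: %d points, %d facets, volume %.6g\n",
              x$d, .hull_n_points(x$ptr), .hull_n_facets(x$ptr),
              .hull_volume(x$ptr)))
  invisible(x)
}

#' Convex hull volume of a point set
#'
#' One-shot convenience wrapper around [incremental_hull()]. The snap
#' resolution defaults to about 1/60000 of the coordinate range, the
#' finest lattice the exact integer engine supports.
#'
#' @param points Matrix of points (rows); must span the full dimension.
#' @param snap Lattice spacing; default chosen from the coordinate range.
#' @return The d-dimensional volume of the convex hull (of the snapped
#'   points).
#' @export
convex_hull_volume <- function(points, snap = NULL) {
  points <- as.matrix(points)
  d <- ncol(points)
  if (is.null(snap)) {
    rng <- max(abs(points), 1e-12)
    snap <- rng / 60000
  }
  n <- nrow(points)
  if (n < d + 1) stop("need at least d + 1 points")
  # greedy affinely independent starting simplex
  idx <- 1L
  for (r in seq_len(d)) {
    base <- points[idx[1], ]
    if (length(idx) == 1L) {
      Q <- matrix(0, d, 0)
    } else {
      Q <- qr.Q(qr(t(points[idx[-1], , drop = FALSE] -
                       rep(base, each = length(idx) - 1L))))
    }
    R <- points - rep(base, each = n)
    proj <- R - R %*% Q %*% t(Q)
    rn <- sqrt(rowSums(proj * proj))
    rn[idx] <- -1
    j <- which.max(rn)
    if (rn[j] < 1e-12) stop("degenerate point set: no full-dimensional hull")
    idx <- c(idx, j)
  }
  h <- incremental_hull(points[idx, , drop = FALSE], snap = snap)
  hull_insert(h, points[-idx, , drop = FALSE])
}
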