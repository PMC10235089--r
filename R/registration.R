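# Piecewise-linear (control-point) co-registration of H&E and IF frames:
# Delaunay triangulation of the source control points with one affine map
# per triangle, exact at the control points.

#' Fit a piecewise-linear control-point transform
#'
#' Triangulates the source control points (Delaunay) and fits an exact
#' affine map per triangle from the corresponding destination points. The
#' transform is exact at the control points and defined over the convex
#' hull of the source points; query points outside the hull are mapped by
#' the nearest triangle's affine map and flagged.
#'
#' @param src_points,dst_points n x 2 matrices (or data frames with columns
#'   \code{x}, \code{y}) of corresponding control points; n >= 4,
#'   non-collinear, no duplicates.
#' @return object of class \code{piecewise_linear_transform}.
#' @export
fit_registration <- function(src_points, dst_points) {
  src <- as_xy_matrix(src_points)
  dst <- as_xy_matrix(dst_points)
  if (nrow(src) != nrow(dst)) {
    rlang::abort("src and dst must have the same number of points")
  }
  if (nrow(src) < 4L) {
    rlang::abort("degenerate geometry: need at least 4 control-point pairs")
  }
  if (anyDuplicated(src) || anyDuplicated(dst)) {
    rlang::abort("degenerate geometry: duplicate control points")
  }
  sv <- svd(scale(src, scale = FALSE))$d
  if (sv[2L] < 1e-9 * max(sv[1L], 1)) {
    rlang::abort("degenerate geometry: control points are collinear")
  }
  dd <- deldir::deldir(src[, 1], src[, 2], suppressMsge = TRUE)
  tri <- deldir::triang.list(dd)
  if (length(tri) == 0L) {
    rlang::abort("degenerate geometry: triangulation failed")
  }
  triangles <- lapply(tri, function(tt) {
    idx <- tt$ptNum
    s <- src[idx, , drop = FALSE]
    d <- dst[idx, , drop = FALSE]
    a <- cbind(s, 1)
    coef <- solve(a, d)                 # 3 x 2: maps (x, y, 1) -> (x', y')
    list(idx = idx, src = s, coef = coef,
         centroid = colMeans(s))
  })
  structure(list(src = src, dst = dst, triangles = triangles),
            class = "piecewise_linear_transform")
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- unname(as.matrix(p))
  stopifnot(ncol(p) == 2L)
  storage.mode(p) <- "double"
  p
}

# Barycentric coordinates of point pt in triangle s (3 x 2).
barycentric <- function(pt, s) {
  m <- cbind(s[2, ] - s[1, ], s[3, ] - s[1, ])
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) < 1e-14) return(c(-1, -1, -1))
  rhs <- pt - s[1, ]
  l2 <- (rhs[1] * m[2, 2] - rhs[2] * m[1, 2]) / det
  l3 <- (m[1, 1] * rhs[2] - m[2, 1] * rhs[1]) / det
  c(1 - l2 - l3, l2, l3)
}

#' Apply a piecewise-linear transform to points
#'
#' Each query point is located in the source triangulation (barycentric
#' membership with a small tolerance) and mapped by that triangle's affine
#' map; points outside the convex hull use the triangle with the nearest
#' centroid and are flagged \code{out_of_hull}.
#'
#' @param object a \code{piecewise_linear_transform}.
#' @param newdata n x 2 matrix or data frame of points (source frame).
#' @param ... unused.
#' @return tibble with \code{x}, \code{y} (mapped) and \code{out_of_hull}.
#' @export
predict.piecewise_linear_transform <- function(object, newdata, ...) {
  pts <- as_xy_matrix(newdata)
  n <- nrow(pts)
  out <- matrix(NA_real_, n, 2L)
  flag <- logical(n)
  cents <- t(vapply(object$triangles, function(tt) tt$centroid, numeric(2)))
  for (i in seq_len(n)) {
    pt <- pts[i, ]
    hit <- 0L
    for (k in seq_along(object$triangles)) {
      b <- barycentric(pt, object$triangles[[k]]$src)
      if (all(b >= -1e-9)) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      flag[i] <- TRUE
      hit <- which.min((cents[, 1] - pt[1])^2 + (cents[, 2] - pt[2])^2)
    }
    out[i, ] <- c(pt, 1) %*% object$triangles[[hit]]$coef
  }
  tibble::tibble(x = out[, 1], y = out[, 2], out_of_hull = flag)
}

#' @export
print.piecewise_linear_transform <- function(x, ...) {
  cat(sprintf("<piecewise_linear_transform> %d control points, %d triangles\n",
              nrow(x$src), length(x$triangles)))
  invisible(x)
}
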