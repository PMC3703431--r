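#' Represent a surface as a current
#'
#' Encodes a triangulated surface by its face barycenters and face normals,
#' the dual-space representation the currents metric acts on. With
#' `normals = "area"` (the default) normals are the half cross product of
#' the edge vectors, so their norms equal triangle areas and the
#' representation is stable under mesh refinement; `normals = "unit"`
#' normalizes each to unit length.
#'
#' @param surface a `lesion_surface`.
#' @param lambda_w Gaussian kernel scale of the test space W, in mm.
#'   Curvature at radii below `lambda_w` is invisible to the metric.
#' @param normals `"area"` (default) or `"unit"`.
#' @return An object of class `current_rep` with fields `centers` (M x 3),
#'   `normals` (M x 3) and `lambda_w`.
#' @export
surface_to_current <- function(surface, lambda_w, normals = c("area", "unit")) {
  normals <- match.arg(normals)
  if (!is.numeric(lambda_w) || lambda_w <= 0)
    stop("surface_to_current: lambda_w must be > 0")
  n <- face_normals(surface)
  a <- sqrt(rowSums(n^2))
  if (any(a <= 1e-12))
    stop("surface_to_current: degenerate (zero-area) face")
  if (normals == "unit") n <- n / a
  structure(list(centers = face_centers(surface), normals = n,
                 lambda_w = as.numeric(lambda_w)),
            class = "current_rep")
}

#' @export
print.current_rep <- function(x, ...) {
  cat(sprintf("<current_rep> %d faces, lambda_W = %g mm\n",
              nrow(x$centers), x$lambda_w))
  invisible(x)
}

#' Gaussian kernel of the currents test space
#'
#' `exp(-|x - y|^2 / lambda_w^2)`, in (0, 1]. Vectorized over rows when
#' `x` and `y` are matrices.
#'
#' @param x,y points (length-3 vectors or N x 3 matrices), mm.
#' @param lambda_w kernel scale, mm.
#' @return Kernel value(s).
#' @export
kernel_w <- function(x, y, lambda_w) {
  if (lambda_w <= 0) stop("kernel_w: lambda_w must be > 0")
  x <- rbind(x)
  y <- rbind(y)
  unname(exp(-rowSums((x - y)^2) / lambda_w^2))
}

#' RKHS inner product of two currents
#'
#' `sum_ij exp(-|x_i^A - x_j^B|^2 / lambda_W^2) (n_i^A . n_j^B)`, in mm^4
#' for area-weighted normals.
#'
#' @param A,B `current_rep` objects with identical `lambda_w`.
#' @return Scalar inner product.
#' @export
currents_inner <- function(A, B) {
  if (!isTRUE(all.equal(A$lambda_w, B$lambda_w)))
    stop("currents_inner: mismatched kernel scales")
  cpp_currents_inner(A$centers, A$normals, B$centers, B$normals, A$lambda_w)
}

#' Squared currents distance
#'
#' `<A,A> - 2<A,B> + <B,B>`; symmetric and non-negative, zero iff the two
#' representations coincide as currents. This is the data-fidelity metric
#' of the shape regression.
#'
#' @param A,B `current_rep` objects with identical `lambda_w`.
#' @return Scalar squared distance (>= 0 up to rounding).
#' @export
currents_dist2 <- function(A, B) {
  currents_inner(A, A) - 2 * currents_inner(A, B) + currents_inner(B, B)
}
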