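#' Voxelize a closed surface onto a regular grid
#'
#' Marks every voxel whose center lies inside the surface, by parity of
#' axis-parallel ray crossings. The default grid is the surface's bounding
#' box padded by `pad` mm at `spacing` mm isotropic resolution; an explicit
#' `origin`/`dims` pair voxelizes onto a caller-supplied grid so that two
#' surfaces can share one grid for overlap measures.
#'
#' @param surface a closed (watertight) `lesion_surface`.
#' @param spacing voxel size in mm (scalar or length-3), default 1 mm.
#' @param pad padding around the bounding box, mm (default 2).
#' @param origin optional mm center of voxel (0,0,0) of an explicit grid.
#' @param dims optional integer grid dimensions (required with `origin`).
#' @return A [lesion_mask()] on the chosen grid.
#' @export
voxelize <- function(surface, spacing = 1, pad = 2, origin = NULL,
                     dims = NULL) {
  validate_surface(surface)   # rejects open or inconsistently wound meshes
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("voxelize: spacing must be > 0")
  if (is.null(origin) != is.null(dims))
    stop("voxelize: supply both `origin` and `dims`, or neither")
  if (is.null(origin)) {
    lo <- apply(surface$vertices, 2, min) - pad
    hi <- apply(surface$vertices, 2, max) + pad
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
    origin <- lo + spacing / 2
  }
  vox <- cpp_voxelize(surface$vertices, surface$faces - 1L,
                      as.numeric(origin), spacing, as.integer(dims))
  lesion_mask(array(vox, dims), spacing = spacing, origin = as.numeric(origin))
}

#' Dice volumetric overlap index
#'
#' `2 |A & B| / (|A| + |B|)`, in [0, 1]: 1 for identical masks, 0 for
#' disjoint ones. Both masks must live on the identical grid.
#'
#' @param A,B `lesion_mask` objects with equal dims, spacing and origin.
#' @return Scalar Dice index; two empty masks give 0 with a warning.
#' @export
dice_index <- function(A, B) {
  if (!identical(dim(A$voxels), dim(B$voxels)) ||
      max(abs(A$spacing - B$spacing)) > 1e-9 ||
      max(abs(A$origin - B$origin)) > 1e-9)
    stop("dice_index: masks are not on the same grid")
  na <- sum(A$voxels)
  nb <- sum(B$voxels)
  if (na + nb == 0L) {
    warning("dice_index: both masks empty; returning 0")
    return(0)
  }
  2 * sum(A$voxels & B$voxels) / (na + nb)
}

#' Dice overlap of two closed surfaces on a shared grid
#'
#' Voxelizes both surfaces onto the joint bounding-box grid and applies
#' [dice_index()].
#'
#' @param A,B closed `lesion_surface` objects in the same frame.
#' @param spacing voxel size in mm (default 1).
#' @param pad grid padding in mm (default 2).
#' @return Scalar Dice index.
#' @export
dice_surfaces <- function(A, B, spacing = 1, pad = 2) {
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  v <- rbind(A$vertices, B$vertices)
  lo <- apply(v, 2, min) - pad
  hi <- apply(v, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  origin <- lo + spacing / 2
  dice_index(voxelize(A, spacing, origin = origin, dims = dims),
             voxelize(B, spacing, origin = origin, dims = dims))
}

#' Symmetric surface distance (mm)
#'
#' The mean, over the vertices of both surfaces, of the exact Euclidean
#' distance from each vertex to the closest point of the other surface:
#' `(sum_{x in B} d(x, A) + sum_{x in A} d(x, B)) / (|A| + |B|)`,
#' with vertex counts as the set sizes.
#'
#' @param A,B `lesion_surface` objects.
#' @return Non-negative scalar distance in mm.
#' @export
symmetric_distance <- function(A, B) {
  if (nrow(A$vertices) == 0L || nrow(B$vertices) == 0L)
    stop("symmetric_distance: empty surface")
  da <- cpp_min_dist(A$vertices, B$vertices, B$faces - 1L)
  db <- cpp_min_dist(B$vertices, A$vertices, A$faces - 1L)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' Time-resolved concordance of an evolving lesion with a final T2 lesion
#'
#' Evaluates the Dice index and the symmetric surface distance between the
#' scenario's surface at every time step and the static final-outcome T2
#' surface, and locates the best-match times: `t_dice` (earliest time of
#' maximum Dice) and `t_dsym` (earliest time of minimum symmetric
#' distance).
#'
#' @param scn an `evolution_scenario`.
#' @param t2 the final T2 `lesion_surface` in the same frame.
#' @param spacing voxelization spacing in mm (default 1, the preprocessed
#'   in-plane/slab-split resolution).
#' @param pad grid padding in mm (default 2).
#' @return A `concordance_curves` object: `times_hours`, `dice_t`,
#'   `dsym_t`, `t_dice`, `t_dsym`, and the summary means.
#' @export
concordance_curves <- function(scn, t2, spacing = 1, pad = 2) {
  validate_surface(t2)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  v <- rbind(t2$vertices,
             do.call(rbind, lapply(scn$surfaces_t, function(s) s$vertices)))
  lo <- apply(v, 2, min) - pad
  hi <- apply(v, 2, max) + pad
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  origin <- lo + spacing / 2
  m_t2 <- voxelize(t2, spacing, origin = origin, dims = dims)
  nt <- length(scn$surfaces_t)
  dice_t <- dsym_t <- numeric(nt)
  for (s in seq_len(nt)) {
    mesh <- scn$surfaces_t[[s]]
    dice_t[s] <- dice_index(voxelize(mesh, spacing, origin = origin,
                                     dims = dims), m_t2)
    dsym_t[s] <- symmetric_distance(mesh, t2)
  }
  structure(list(times_hours = scn$times_hours, dice_t = dice_t,
                 dsym_t = dsym_t,
                 t_dice = scn$times_hours[which.max(dice_t)],
                 t_dsym = scn$times_hours[which.min(dsym_t)],
                 max_dice = max(dice_t), min_dsym = min(dsym_t),
                 mean_dice = mean(dice_t), mean_dsym = mean(dsym_t)),
            class = "concordance_curves")
}

#' @export
print.concordance_curves <- function(x, ...) {
  cat(sprintf("<concordance_curves> %d steps: max dice %.3f at %g h; min d_sym %.2f mm at %g h\n",
              length(x$times_hours), x$max_dice, x$t_dice, x$min_dsym,
              x$t_dsym))
  invisible(x)
}

#' @export
as.data.frame.concordance_curves <- function(x, ...) {
  data.frame(time_hours = x$times_hours, dice = x$dice_t, dsym = x$dsym_t)
}
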