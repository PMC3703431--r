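#' Binary lesion mask on a regular voxel grid
#'
#' A voxelized lesion volume in scanner-aligned physical coordinates.
#' Voxel indices are 0-based internally for coordinate arithmetic; the
#' physical position of voxel (i, j, k) (0-based) is
#' `origin + c(i, j, k) * spacing`, i.e. coordinates refer to voxel centers.
#'
#' @param voxels 3D logical or 0/1 numeric array.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; all > 0.
#' @param origin numeric length-3, mm position of the center of voxel (0,0,0).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("lesion_mask: `voxels` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("lesion_mask: `spacing` must be 3 positive values (mm)")
  structure(
    list(voxels = array(as.logical(voxels), dim(voxels)),
         spacing = spacing, origin = as.numeric(origin)),
    class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %s voxels, spacing %.3g x %.3g x %.3g mm, %d foreground (%.2f cm^3)\n",
              paste(dim(x$voxels), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels), mask_volume(x) / 1000))
  invisible(x)
}

#' Physical foreground volume of a mask (mm^3)
#' @param mask a `lesion_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$voxels) * prod(mask$spacing)
}

#' Number of 6-connected foreground components
#' @param mask a `lesion_mask`.
#' @return Integer component count.
#' @export
n_components <- function(mask) {
  lab <- cpp_label_components(as.logical(mask$voxels),
                              as.integer(dim(mask$voxels)))
  attr(lab, "n")
}

#' Read a lesion mask from a NIfTI volume
#'
#' Values are binarized at > 0; voxel spacing is taken from the header.
#'
#' @param path path to a 3D NIfTI file (.nii or .nii.gz).
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_mask: expected a 3D volume, got ", length(dim(img)), "D")
  spacing <- attr(img, "pixdim")
  if (is.null(spacing)) spacing <- RNifti::pixdim(img)
  spacing <- as.numeric(spacing)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_mask: missing or invalid spacing metadata in header")
  vox <- array(as.array(img) > 0, dim(img))
  lesion_mask(vox, spacing = spacing, origin = c(0, 0, 0))
}

#' Write a lesion mask to a NIfTI volume
#' @param mask a `lesion_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.numeric(mask$voxels), dim(mask$voxels)),
                         reference = NULL)
  img <- RNifti::`pixdim<-`(img, mask$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split thick axial slices into thin subvoxels
#'
#' Replicates each z-slice `factor` times and divides the z-spacing by the
#' same factor, e.g. splitting each 6 mm slice into 6 subvoxels of 1 mm.
#' The foreground voxel count is multiplied exactly by `factor`, so the
#' physical foreground volume is conserved exactly.
#'
#' @param mask a `lesion_mask`.
#' @param factor integer >= 1, number of subvoxels per source voxel.
#' @return A new `lesion_mask` with `factor` times as many z-slices.
#' @export
z_subsample <- function(mask, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("z_subsample: `factor` must be an integer >= 1")
  if (factor == 1L) return(mask)
  d <- dim(mask$voxels)
  idx <- rep(seq_len(d[3]), each = factor)
  vox <- mask$voxels[, , idx, drop = FALSE]
  sp <- mask$spacing
  sp[3] <- sp[3] / factor
  # keep the slab's physical extent: first subvoxel center shifts back by
  # (factor - 1) / 2 thin voxels
  org <- mask$origin
  org[3] <- org[3] - (factor - 1) / 2 * sp[3]
  lesion_mask(vox, spacing = sp, origin = org)
}

#' Triangulated lesion surface
#'
#' A closed, consistently outward-oriented triangle mesh in physical mm
#' coordinates, optionally stamped with its acquisition time in hours from
#' stroke onset.
#'
#' @param vertices N x 3 numeric matrix of mm coordinates.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param t_hours acquisition time in hours from onset (NA if untimed).
#' @return An object of class `lesion_surface`.
#' @export
lesion_surface <- function(vertices, faces, t_hours = NA_real_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("lesion_surface: vertices must be N x 3")
  if (ncol(faces) != 3L) stop("lesion_surface: faces must be M x 3 (triangles)")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("lesion_surface: face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 t_hours = as.numeric(t_hours)[1]),
            class = "lesion_surface")
}

#' @export
print.lesion_surface <- function(x, ...) {
  cat(sprintf("<lesion_surface> %d vertices, %d faces, t = %s h, volume %.2f cm^3\n",
              nrow(x$vertices), nrow(x$faces),
              format(x$t_hours), enclosed_volume(x) / 1000))
  invisible(x)
}

#' Triangle barycenters of a surface
#' @param surface a `lesion_surface`.
#' @return M x 3 matrix of face centers (mm).
#' @export
face_centers <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Area-weighted face normals (half cross product)
#' @param surface a `lesion_surface`.
#' @return M x 3 matrix; row norms equal triangle areas (mm^2).
#' @export
face_normals <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Triangle areas (mm^2)
#' @param surface a `lesion_surface`.
#' @return Numeric vector of face areas.
#' @export
face_areas <- function(surface) {
  n <- face_normals(surface)
  sqrt(rowSums(n^2))
}

#' Total surface area (mm^2)
#' @param surface a `lesion_surface`.
#' @return Scalar area.
#' @export
surface_area <- function(surface) sum(face_areas(surface))

#' Signed enclosed volume (mm^3)
#'
#' Divergence-theorem volume; positive for consistently outward-oriented
#' closed surfaces.
#'
#' @param surface a `lesion_surface`.
#' @return Scalar signed volume.
#' @export
enclosed_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Mean edge length of a mesh (mm)
#' @param surface a `lesion_surface`.
#' @return Scalar mean edge length.
#' @export
mean_edge_length <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  mean(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                       v[e[, 2], , drop = FALSE])^2)))
}

# Undirected edge table with directed counts; internal helper for the
# validator and the smoother.
surface_edges <- function(surface) {
  f <- surface$faces
  dir_e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(dir_e[, 1], dir_e[, 2]), pmax(dir_e[, 1], dir_e[, 2]))
  list(directed = dir_e, key = key)
}

#' Validate a triangulated lesion surface
#'
#' Checks the structural invariants every surface in the pipeline must
#' satisfy: triangle faces with in-range indices, no degenerate (zero-area)
#' faces, and — when `check_closed` — a closed 2-manifold (each undirected
#' edge shared by exactly two faces, once in each direction) with outward
#' orientation (positive signed volume).
#'
#' @param surface a `lesion_surface`.
#' @param check_closed require closedness/orientation (default TRUE).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_surface <- function(surface, check_closed = TRUE) {
  if (!inherits(surface, "lesion_surface"))
    stop("validate_surface: not a lesion_surface")
  if (any(face_areas(surface) <= 1e-12))
    stop("validate_surface: degenerate (zero-area) face")
  if (check_closed) {
    ed <- surface_edges(surface)
    cnt <- table(ed$key)
    if (any(cnt != 2L))
      stop("validate_surface: surface is not closed (edge not shared by exactly 2 faces)")
    # consistent orientation: each undirected edge traversed once per direction
    dk <- paste(ed$directed[, 1], ed$directed[, 2])
    if (any(duplicated(dk)))
      stop("validate_surface: inconsistent face orientation")
    if (enclosed_volume(surface) <= 0)
      stop("validate_surface: inward orientation (signed volume <= 0)")
  }
  invisible(TRUE)
}

#' Light Laplacian smoothing of a surface
#'
#' Moves each vertex a fraction `factor` towards the mean of its edge
#' neighbours, `iterations` times. Connectivity is unchanged.
#'
#' @param surface a `lesion_surface`.
#' @param iterations number of smoothing passes.
#' @param factor relaxation factor in (0, 1).
#' @return Smoothed `lesion_surface`.
#' @export
laplacian_smooth <- function(surface, iterations = 2L, factor = 0.2) {
  v <- surface$vertices
  ed <- surface_edges(surface)$directed
  from <- c(ed[, 1], ed[, 2])
  to <- c(ed[, 2], ed[, 1])
  deg <- tabulate(from, nbins = nrow(v))
  for (it in seq_len(iterations)) {
    nb_sum <- rowsum(v[to, , drop = FALSE], from, reorder = TRUE)
    v <- v + factor * (nb_sum / deg - v)
  }
  lesion_surface(v, surface$faces, surface$t_hours)
}

#' Reconstruct a closed surface from a binary mask
#'
#' Extracts the 0.5 level set of the mask under nearest-neighbour
#' interpolation (the boundary faces between foreground and background
#' voxels, in physical mm), then applies light Laplacian smoothing to
#' remove staircase artifacts. The currents metric at its working scales
#' (lambda_W >= 5 mm) is insensitive to the sub-voxel detail removed here.
#'
#' @param mask a non-empty, single-component `lesion_mask`.
#' @param t_hours acquisition time stamped on the surface.
#' @param smooth_iterations,smooth_factor smoothing parameters
#'   (defaults 2 and 0.2).
#' @return A closed, outward-oriented `lesion_surface`.
#' @export
mask_to_surface <- function(mask, t_hours = NA_real_,
                            smooth_iterations = 2L, smooth_factor = 0.2) {
  vox <- mask$voxels
  if (!any(vox)) stop("mask_to_surface: empty mask")
  if (n_components(mask) != 1L)
    stop("mask_to_surface: mask has multiple connected components; ",
         "a single solitary lesion is required")
  d <- dim(vox)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox

  # quads between foreground voxels and background neighbours, with corner
  # ids on the (nx+1) x (ny+1) x (nz+1) voxel-corner lattice
  nxc <- d[1] + 1L
  nyc <- d[2] + 1L
  corner_id <- function(i, j, k) 1L + i + nxc * (j + nyc * k)

  quads <- vector("list", 6)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  core <- function(arr) arr[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  for (s in seq_along(dirs)) {
    dd <- dirs[[s]]
    shifted <- pad[2:(d[1] + 1) + dd[1], 2:(d[2] + 1) + dd[2],
                   2:(d[3] + 1) + dd[3], drop = FALSE]
    hit <- which(vox & !shifted, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    i <- hit[, 1] - 1L; j <- hit[, 2] - 1L; k <- hit[, 3] - 1L  # 0-based voxel
    # voxel corner offsets for the exposed face, ordered so the implied
    # normal points towards the background neighbour
    q <- switch(s,
      cbind(corner_id(i + 1L, j, k), corner_id(i + 1L, j + 1L, k),
            corner_id(i + 1L, j + 1L, k + 1L), corner_id(i + 1L, j, k + 1L)),
      cbind(corner_id(i, j, k), corner_id(i, j, k + 1L),
            corner_id(i, j + 1L, k + 1L), corner_id(i, j + 1L, k)),
      cbind(corner_id(i, j + 1L, k), corner_id(i, j + 1L, k + 1L),
            corner_id(i + 1L, j + 1L, k + 1L), corner_id(i + 1L, j + 1L, k)),
      cbind(corner_id(i, j, k), corner_id(i + 1L, j, k),
            corner_id(i + 1L, j, k + 1L), corner_id(i, j, k + 1L)),
      cbind(corner_id(i, j, k + 1L), corner_id(i + 1L, j, k + 1L),
            corner_id(i + 1L, j + 1L, k + 1L), corner_id(i, j + 1L, k + 1L)),
      cbind(corner_id(i, j, k), corner_id(i, j + 1L, k),
            corner_id(i + 1L, j + 1L, k), corner_id(i + 1L, j, k)))
    quads[[s]] <- q
  }
  q <- do.call(rbind, quads)
  used <- sort(unique(as.vector(q)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  q <- matrix(remap[q], nrow(q), 4)
  # corner lattice coordinates -> mm (corner (0,0,0) sits at voxel-center
  # origin minus half a voxel)
  u <- used - 1L
  ci <- u %% nxc
  cj <- (u %/% nxc) %% nyc
  ck <- u %/% (nxc * nyc)
  verts <- cbind(ci, cj, ck)
  verts <- sweep(sweep(verts, 2, mask$spacing, `*`), 2,
                 mask$origin - mask$spacing / 2, `+`)
  faces <- rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  out <- lesion_surface(verts, faces, t_hours)
  if (smooth_iterations > 0)
    out <- laplacian_smooth(out, smooth_iterations, smooth_factor)
  validate_surface(out)
  out
}

#' Read a triangle surface from PLY or legacy-VTK polydata
#'
#' Format is inferred from the extension (`.ply` or `.vtk`). Per-face scalar
#' fields written by [write_surface()] are returned in the
#' `face_scalars` attribute.
#'
#' @param path input path.
#' @param t_hours acquisition time to stamp on the surface.
#' @return A `lesion_surface`.
#' @export
read_surface <- function(path, t_hours = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") read_ply(path, t_hours)
  else if (ext == "vtk") read_vtk(path, t_hours)
  else stop("read_surface: unsupported extension '", ext, "' (use .ply or .vtk)")
}

#' Write a triangle surface to PLY or legacy-VTK polydata
#'
#' ASCII output. Optional per-face scalar fields (e.g. signed speeds or
#' region labels) are stored as extra face properties (PLY) or CELL_DATA
#' (VTK) so downstream viewers can colour the mesh.
#'
#' @param surface a `lesion_surface`.
#' @param path output path ending in .ply or .vtk.
#' @param face_scalars optional named list of numeric vectors, one value per
#'   face.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, face_scalars = NULL) {
  if (!is.null(face_scalars)) {
    face_scalars <- as.list(face_scalars)
    if (is.null(names(face_scalars)) || any(names(face_scalars) == ""))
      stop("write_surface: face_scalars must be a named list")
    for (nm in names(face_scalars))
      if (length(face_scalars[[nm]]) != nrow(surface$faces))
        stop("write_surface: scalar '", nm, "' must have one value per face")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_ply(surface, path, face_scalars)
  else if (ext == "vtk") write_vtk(surface, path, face_scalars)
  else stop("write_surface: unsupported extension '", ext, "' (use .ply or .vtk)")
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_ply <- function(path, t_hours) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("read_ply: not a PLY file")
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("read_ply: missing end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", hdr)))
    stop("read_ply: only ascii PLY is supported")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1)
    stop("read_ply: need one vertex and one face element")
  # face property names beyond the index list
  fprop_start <- grep("^element face ", hdr)
  fprops <- character(0)
  for (ln in hdr[(fprop_start + 1):length(hdr)]) {
    if (grepl("^property list", ln)) next
    if (grepl("^property ", ln))
      fprops <- c(fprops, utils::tail(strsplit(trimws(ln), "\\s+")[[1]], 1))
    if (grepl("^element ", ln)) break
  }
  vlines <- lines[hdr_end + seq_len(nv)]
  flines <- lines[hdr_end + nv + seq_len(nf)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
               nrow = nv, byrow = TRUE)
  ftoks <- strsplit(trimws(flines), "\\s+")
  cnt <- vapply(ftoks, function(t) as.integer(t[1]), integer(1))
  if (any(cnt != 3L))
    stop("read_ply: non-triangular face (only triangle meshes are supported)")
  fm <- t(vapply(ftoks, function(t) as.integer(t[2:4]), integer(3))) + 1L
  out <- lesion_surface(vm[, 1:3, drop = FALSE], fm, t_hours)
  if (length(fprops) > 0) {
    sc <- lapply(seq_along(fprops), function(s)
      vapply(ftoks, function(t) as.numeric(t[4 + s]), numeric(1)))
    names(sc) <- fprops
    attr(out, "face_scalars") <- sc
  }
  out
}

write_ply <- function(surface, path, face_scalars) {
  nv <- nrow(surface$vertices)
  nf <- nrow(surface$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices")
  if (!is.null(face_scalars))
    hdr <- c(hdr, sprintf("property double %s", names(face_scalars)))
  hdr <- c(hdr, "end_header")
  vl <- apply(surface$vertices, 1, function(r) paste(fmt_num(r), collapse = " "))
  f0 <- surface$faces - 1L
  fl <- paste(3L, f0[, 1], f0[, 2], f0[, 3])
  if (!is.null(face_scalars)) {
    extra <- do.call(cbind, lapply(face_scalars, fmt_num))
    fl <- paste(fl, apply(extra, 1, paste, collapse = " "))
  }
  writeLines(c(hdr, vl, fl), path)
}

read_vtk <- function(path, t_hours) {
  lines <- readLines(path)
  if (!any(grepl("^DATASET POLYDATA", lines)))
    stop("read_vtk: only legacy POLYDATA is supported")
  pl <- grep("^POINTS ", lines)
  np <- as.integer(strsplit(lines[pl], "\\s+")[[1]][2])
  toks <- numeric(0)
  i <- pl + 1
  while (length(toks) < 3 * np) {
    toks <- c(toks, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  vm <- matrix(toks[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  gl <- grep("^POLYGONS ", lines)
  hdr <- as.integer(strsplit(lines[gl], "\\s+")[[1]][2:3])
  nf <- hdr[1]
  ftoks <- integer(0)
  i <- gl + 1
  while (length(ftoks) < hdr[2]) {
    ftoks <- c(ftoks, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  fm <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (f in seq_len(nf)) {
    cnt <- ftoks[pos]
    if (cnt != 3L)
      stop("read_vtk: non-triangular face (only triangle meshes are supported)")
    fm[f, ] <- ftoks[pos + 1:3] + 1L
    pos <- pos + 1 + cnt
  }
  out <- lesion_surface(vm, fm, t_hours)
  cd <- grep("^CELL_DATA ", lines)
  if (length(cd) == 1) {
    sc <- list()
    sl <- grep("^SCALARS ", lines)
    sl <- sl[sl > cd]
    for (s in sl) {
      nm <- strsplit(lines[s], "\\s+")[[1]][2]
      vals <- numeric(0)
      i <- s + 2  # skip LOOKUP_TABLE
      while (length(vals) < nf) {
        vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        i <- i + 1
      }
      sc[[nm]] <- vals[seq_len(nf)]
    }
    if (length(sc) > 0) attr(out, "face_scalars") <- sc
  }
  out
}

write_vtk <- function(surface, path, face_scalars) {
  nv <- nrow(surface$vertices)
  nf <- nrow(surface$faces)
  f0 <- surface$faces - 1L
  out <- c("# vtk DataFile Version 3.0", "lesion4d surface", "ASCII",
           "DATASET POLYDATA",
           sprintf("POINTS %d double", nv),
           apply(surface$vertices, 1, function(r) paste(fmt_num(r), collapse = " ")),
           sprintf("POLYGONS %d %d", nf, 4L * nf),
           paste(3L, f0[, 1], f0[, 2], f0[, 3]))
  if (!is.null(face_scalars)) {
    out <- c(out, sprintf("CELL_DATA %d", nf))
    for (nm in names(face_scalars))
      out <- c(out, sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default",
               fmt_num(face_scalars[[nm]]))
  }
  writeLines(out, path)
}
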