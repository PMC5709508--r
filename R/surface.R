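#' Construct a surface model
#'
#' A `surface_model` holds the points of an initiating surface (um), unit
#' normals pointing into the soil domain, and the total surface area (mm^2).
#' Hairs are seeded on, and length profiles are binned away from, this
#' surface.
#'
#' @param points n x 3 matrix of surface point coordinates, um.
#' @param normals n x 3 matrix of inward unit normals.
#' @param area total surface area, mm^2.
#' @param reference `"cartesian-face"` or `"root-surface"`.
#' @param face optional list describing an exact planar face
#'   (`point`, `normal`, `u`, `v`, `extent`): used for continuous uniform
#'   seeding and analytic distances.
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(points, normals, area,
                          reference = c("cartesian-face", "root-surface"),
                          face = NULL) {
  reference <- match.arg(reference)
  points <- matrix(points, ncol = 3)
  normals <- matrix(normals, ncol = 3)
  stopifnot(nrow(points) == nrow(normals))
  if (nrow(points) > 0) {
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-9)) stop("normals must be unit length")
    if (area <= 0) stop("area must be positive for a non-empty surface")
  }
  structure(list(points = points, normals = normals, area = area,
                 reference = reference, face = face),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %s: %d points, area %.4f mm^2\n",
              x$reference, nrow(x$points), x$area))
  invisible(x)
}

#' Construct an exact planar initiating surface
#'
#' A free-standing rectangular surface (no volume required), used for
#' control scenarios in which hairs grow into an unbounded empty domain.
#' The plane passes through `point` with inward normal along `normal`;
#' `extent` gives the in-plane width and height in um.
#'
#' @param extent length-2 numeric, um.
#' @param point a point on the plane, um.
#' @param normal inward normal (normalised internally).
#' @return A [surface_model()].
#' @export
planar_surface <- function(extent, point = c(0, 0, 0),
                           normal = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  # orthonormal in-plane basis
  seed <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  ctr <- point + (extent[1] / 2) * u + (extent[2] / 2) * v
  surface_model(matrix(ctr, 1, 3), matrix(normal, 1, 3),
                area = prod(extent) / 1e6, reference = "cartesian-face",
                face = list(point = point, normal = normal, u = u, v = v,
                            extent = extent))
}

#' Extract an initiating surface from a phase volume
#'
#' For a cartesian face, returns the exact rectangular boundary face of the
#' domain with its constant inward normal and exact area. For the root
#' surface, returns the midpoints of voxel faces separating the root phase
#' from non-mineral soil, with inward normals estimated from the Gaussian
#' smoothed (sigma = 2 voxels) gradient of the root-phase distance
#' transform; the area is the projection-corrected sum of boundary face
#' areas.
#'
#' @param volume a [phase_volume()].
#' @param which `"root"` or `"face"`.
#' @param axis for faces: `"x"`, `"y"` or `"z"`.
#' @param side for faces: `"low"` (plane at the domain origin side) or
#'   `"high"`.
#' @return A [surface_model()].
#' @export
extract_surface <- function(volume, which = c("face", "root"),
                            axis = "z", side = c("low", "high")) {
  which <- match.arg(which)
  if (which == "face") {
    side <- match.arg(side)
    ax <- match(axis, c("x", "y", "z"))
    if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'")
    d <- dim(volume$labels)
    vs <- volume$voxel_size
    lo_corner <- volume$origin - vs / 2      # physical corner of the grid
    extent3 <- d * vs
    inplane <- setdiff(1:3, ax)
    normal <- rep(0, 3)
    normal[ax] <- if (side == "low") 1 else -1
    plane_pt <- lo_corner
    if (side == "high") plane_pt[ax] <- lo_corner[ax] + extent3[ax]
    # grid of face points (voxel-face centres) for interrogation
    g1 <- lo_corner[inplane[1]] + (seq_len(d[inplane[1]]) - 0.5) * vs
    g2 <- lo_corner[inplane[2]] + (seq_len(d[inplane[2]]) - 0.5) * vs
    gg <- expand.grid(g1, g2)
    pts <- matrix(plane_pt, nrow(gg), 3, byrow = TRUE)
    pts[, inplane[1]] <- gg[, 1]
    pts[, inplane[2]] <- gg[, 2]
    u <- rep(0, 3); u[inplane[1]] <- 1
    v <- rep(0, 3); v[inplane[2]] <- 1
    face_pt <- plane_pt
    face_pt[inplane] <- lo_corner[inplane]
    return(surface_model(
      pts, matrix(normal, nrow(pts), 3, byrow = TRUE),
      area = prod(extent3[inplane]) / 1e6, reference = "cartesian-face",
      face = list(point = face_pt, normal = normal, u = u, v = v,
                  extent = extent3[inplane])))
  }

  # root surface
  lab <- volume$labels
  if (!any(lab == PHASE_LABELS[["root"]]))
    stop("no ROOT phase present in volume")
  d <- dim(lab)
  vs <- volume$voxel_size
  root <- lab == PHASE_LABELS[["root"]]
  soil <- lab == PHASE_LABELS[["pore"]] | lab == PHASE_LABELS[["textural"]]

  # distance transform from the root, smoothed for normal estimation
  dist_vox <- array(cpp_edt3d(as.vector(root), d), dim = d)
  sm <- array(cpp_gauss_blur3d(as.vector(dist_vox), d, 2), dim = d)

  pts <- list(); nrm <- list(); wts <- list()
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      # root voxel with soil neighbour in +/- axis direction
      idx_r <- which(root)
      ijk <- arrayInd(idx_r, d)
      nb <- ijk
      nb[, ax] <- nb[, ax] + dir
      ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      if (!any(ok)) next
      lin_nb <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L + d[2] * (nb[ok, 3] - 1L))
      sel <- soil[lin_nb]
      if (!any(sel)) next
      here <- ijk[ok, , drop = FALSE][sel, , drop = FALSE]
      p <- voxel_centre(volume, here)
      p[, ax] <- p[, ax] + dir * vs / 2          # face midpoint
      soil_ijk <- here
      soil_ijk[, ax] <- soil_ijk[, ax] + dir
      n <- smoothed_gradient(sm, d, soil_ijk)
      pts[[length(pts) + 1]] <- p
      nrm[[length(nrm) + 1]] <- n
      wts[[length(wts) + 1]] <- abs(n[, ax])     # projection weight
    }
  }
  pts <- do.call(rbind, pts)
  nrm <- do.call(rbind, nrm)
  area_mm2 <- sum(unlist(wts)) * vs^2 / 1e6
  surface_model(pts, nrm, area = area_mm2, reference = "root-surface")
}

# Central-difference gradient of a smoothed scalar array at given voxel
# indices, normalised to unit vectors (fallback: +z when degenerate).
smoothed_gradient <- function(sm, d, ijk) {
  grad <- matrix(0, nrow(ijk), 3)
  for (ax in 1:3) {
    up <- ijk; up[, ax] <- pmin(ijk[, ax] + 1L, d[ax])
    dn <- ijk; dn[, ax] <- pmax(ijk[, ax] - 1L, 1L)
    lin_up <- up[, 1] + d[1] * (up[, 2] - 1L + d[2] * (up[, 3] - 1L))
    lin_dn <- dn[, 1] + d[1] * (dn[, 2] - 1L + d[2] * (dn[, 3] - 1L))
    grad[, ax] <- (sm[lin_up] - sm[lin_dn]) / (up[, ax] - dn[, ax])
  }
  nn <- sqrt(rowSums(grad^2))
  bad <- nn < 1e-12
  if (any(bad)) {
    grad[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
    nn[bad] <- 1
  }
  grad / nn
}

#' Export a surface to CSV
#'
#' Writes `x,y,z,nx,ny,nz` rows (um / unit vectors).
#'
#' @param surface a [surface_model()].
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  df <- data.frame(surface$points, surface$normals)
  names(df) <- c("x", "y", "z", "nx", "ny", "nz")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
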