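#' Distance map from an initiating surface
#'
#' Computes the Euclidean distance (um) of every voxel from the initiating
#' surface, used for shell-binned length profiles. For a cartesian face
#' the distance is the exact coordinate offset along the face normal; for
#' a root surface it is the exact Euclidean distance transform of the root
#' phase (zero inside the root, increasing into the soil).
#'
#' @param volume a [phase_volume()].
#' @param surface a [surface_model()].
#' @return An object of class `distance_map` with fields `distances`
#'   (3D array, um), `reference`, `voxel_size`, `origin`.
#' @export
distance_from_surface <- function(volume, surface) {
  if (nrow(surface$points) == 0) stop("surface is empty")
  d <- dim(volume$labels)
  if (surface$reference == "cartesian-face") {
    f <- surface$face
    ctr <- lapply(1:3, function(ax)
      volume$origin[ax] + (seq_len(d[ax]) - 1) * volume$voxel_size)
    # signed offset along the inward normal from the plane
    off <- lapply(1:3, function(ax) (ctr[[ax]] - f$point[ax]) * f$normal[ax])
    dist <- array(0, dim = d)
    dist <- outer(outer(off[[1]], off[[2]], "+"), off[[3]], "+")
  } else {
    root <- volume$labels == PHASE_LABELS[["root"]]
    if (!any(root)) stop("no ROOT phase present in volume")
    dist <- array(cpp_edt3d(as.vector(root), d), dim = d) * volume$voxel_size
  }
  structure(list(distances = dist, reference = surface$reference,
                 voxel_size = volume$voxel_size, origin = volume$origin),
            class = "distance_map")
}

#' Analytic planar distance reference
#'
#' A lightweight alternative to a [distance_from_surface()] map for control
#' scenarios without a volume: distance of a point is its offset along the
#' inward plane normal.
#'
#' @param surface a [surface_model()] with planar `face` metadata, or NULL
#'   when `point`/`normal` are given directly.
#' @param point,normal plane definition when no surface is supplied.
#' @return Object of class `planar_distance`.
#' @export
planar_distance <- function(surface = NULL, point = NULL, normal = NULL) {
  if (!is.null(surface)) {
    if (is.null(surface$face))
      stop("surface has no planar face metadata")
    point <- surface$face$point
    normal <- surface$face$normal
  }
  normal <- normal / sqrt(sum(normal^2))
  structure(list(point = point, normal = normal), class = "planar_distance")
}

#' Analytic cylindrical distance reference
#'
#' Distance of a point from an axis-aligned cylindrical root surface:
#' radial distance to the axis minus the root radius (clamped at 0).
#'
#' @param axis_point a point on the root axis, um.
#' @param axis_dir axis direction (normalised internally).
#' @param radius root radius, um.
#' @return Object of class `cylinder_distance`.
#' @export
cylinder_distance <- function(axis_point, axis_dir = c(0, 0, 1), radius) {
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  structure(list(point = axis_point, dir = axis_dir, radius = radius),
            class = "cylinder_distance")
}

#' Evaluate a distance reference at physical points
#'
#' @param dref a `distance_map`, `planar_distance` or `cylinder_distance`.
#' @param points n x 3 matrix, um.
#' @return Numeric vector of distances, um.
#' @export
surface_distance <- function(dref, points) {
  points <- matrix(points, ncol = 3)
  if (inherits(dref, "planar_distance")) {
    return(as.vector(sweep(points, 2, dref$point, "-") %*% dref$normal))
  }
  if (inherits(dref, "cylinder_distance")) {
    rel <- sweep(points, 2, dref$point, "-")
    along <- as.vector(rel %*% dref$dir)
    perp2 <- rowSums(rel^2) - along^2
    return(pmax(sqrt(pmax(perp2, 0)) - dref$radius, 0))
  }
  if (inherits(dref, "distance_map")) {
    d <- dim(dref$distances)
    idx <- sweep(points, 2, dref$origin, "-") / dref$voxel_size
    ijk <- matrix(as.integer(floor(idx + 0.5)) + 1L, ncol = 3)
    ijk[, 1] <- pmin(pmax(ijk[, 1], 1L), d[1])
    ijk[, 2] <- pmin(pmax(ijk[, 2], 1L), d[2])
    ijk[, 3] <- pmin(pmax(ijk[, 3], 1L), d[3])
    lin <- ijk[, 1] + d[1] * (ijk[, 2] - 1L + d[2] * (ijk[, 3] - 1L))
    return(dref$distances[lin])
  }
  stop("unsupported distance reference")
}
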