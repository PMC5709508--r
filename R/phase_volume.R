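#' Phase labels used in collision volumes
#'
#' The fixed label dialect of rhizohair: gaseous pore = 0, hydrated textural
#' phase = 1, primary mineral = 2, root = 3, outside-of-domain = 255. The
#' OUTSIDE label encodes the domain boundary so that the "within the domain"
#' validity test during growth is a plain label check.
#'
#' @format Named integer vector.
#' @export
PHASE_LABELS <- c(pore = 0L, textural = 1L, mineral = 2L, root = 3L,
                  outside = 255L)

#' Construct a labelled phase volume
#'
#' A `phase_volume` is the collision world of the growth model: a 3D integer
#' array of phase labels plus the metadata needed to map physical coordinates
#' (micrometres) onto voxels.
#'
#' @param labels 3D integer array with values from [PHASE_LABELS].
#' @param voxel_size edge length of the (isotropic) cubic voxels, um.
#' @param origin physical coordinate (um) of the centre of voxel (1,1,1).
#' @param geometry_kind `"cartesian"` or `"cylindrical"`.
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(labels, voxel_size, origin = c(0, 0, 0),
                         geometry_kind = c("cartesian", "cylindrical")) {
  geometry_kind <- match.arg(geometry_kind)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(PHASE_LABELS))
  if (length(bad))
    stop("unknown phase labels: ", paste(sort(bad), collapse = ", "))
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), geometry_kind = geometry_kind),
    class = "phase_volume")
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<phase_volume> %d x %d x %d voxels @ %g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size, x$geometry_kind))
  fr <- phase_fractions(x)
  cat("  interior phase fractions:",
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = " "), "\n")
  invisible(x)
}

#' Interior phase volume fractions
#'
#' Fractions of pore, textural, mineral and root over the interior domain
#' (voxels not labelled OUTSIDE). They sum to 1 when any interior voxel
#' exists.
#'
#' @param volume a [phase_volume()].
#' @return Named numeric vector over pore/textural/mineral/root.
#' @export
phase_fractions <- function(volume) {
  lab <- volume$labels
  inside <- lab != PHASE_LABELS[["outside"]]
  n <- sum(inside)
  vapply(c("pore", "textural", "mineral", "root"), function(ph) {
    if (n == 0) return(NA_real_)
    sum(lab[inside] == PHASE_LABELS[[ph]]) / n
  }, numeric(1))
}

# Nearest-voxel-centre index (1-based, per axis) of physical points.
# points: n x 3 matrix of um coordinates. Returns n x 3 integer matrix;
# indices may fall outside [1, dim] for points beyond the grid.
voxel_index <- function(volume, points) {
  points <- matrix(points, ncol = 3)
  idx <- sweep(points, 2, volume$origin, "-") / volume$voxel_size
  # round half up per axis, 0-based, then shift to R's 1-based indexing
  matrix(as.integer(floor(idx + 0.5)) + 1L, ncol = 3)
}

#' Phase label at physical points
#'
#' Looks up the phase label of the voxel containing each point
#' (nearest-voxel-centre rule). Points beyond the grid report OUTSIDE.
#'
#' @param volume a [phase_volume()] or `NULL` (an unbounded all-pore control
#'   domain: every point reports `pore`).
#' @param points n x 3 matrix of um coordinates (or length-3 vector).
#' @return Integer vector of labels.
#' @export
voxel_label <- function(volume, points) {
  points <- matrix(points, ncol = 3)
  if (is.null(volume))
    return(rep(PHASE_LABELS[["pore"]], nrow(points)))
  d <- dim(volume$labels)
  ijk <- voxel_index(volume, points)
  out <- rep(PHASE_LABELS[["outside"]], nrow(ijk))
  ok <- ijk[, 1] >= 1L & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1L & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1L & ijk[, 3] <= d[3]
  if (any(ok)) {
    lin <- ijk[ok, 1] + d[1] * (ijk[ok, 2] - 1L + d[2] * (ijk[ok, 3] - 1L))
    out[ok] <- volume$labels[lin]
  }
  out
}

# Physical coordinates (um) of voxel centres for 1-based index matrix.
voxel_centre <- function(volume, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep((ijk - 1) * volume$voxel_size, 2, volume$origin, "+")
}
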