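#' Generate an idealised sphere-packing soil volume
#'
#' Voxelises a body-centred cubic (BCC) or hexagonal close-packed (HCP)
#' lattice of identical touching spheres. Sphere interiors are labelled
#' primary mineral and the remainder gaseous pore. The lattice is
#' axis-aligned with the domain (HCP c-axis along z, the conventional
#' initiation-face normal), and each axis of the domain is snapped to a
#' whole number of unit cells (at least the requested edge) so that the
#' lattice fills the domain; spheres crossing a domain face are completed
#' by their periodic images, so the voxelised mineral fraction converges to
#' the analytic packing density (BCC: pi*sqrt(3)/8, HCP: pi/sqrt(18)) as
#' the voxel size shrinks.
#'
#' @param packing `"BCC"` or `"HCP"`.
#' @param sphere_diameter sphere diameter, um (90 and 270 are the canonical
#'   grain sizes: the mean inter-hair spacing and the lower range of primary
#'   mineral grain diameters).
#' @param domain_edge requested domain edge, um; scalar or length-3
#'   (x, y, z). Snapped up/down to whole unit cells per axis.
#' @param voxel_size voxel edge, um; must be at most `sphere_diameter / 10`.
#' @return A [phase_volume()] (cartesian).
#' @export
generate_sphere_packing <- function(packing = c("BCC", "HCP"),
                                    sphere_diameter, domain_edge,
                                    voxel_size) {
  packing <- match.arg(packing)
  if (sphere_diameter <= 0) stop("sphere_diameter must be positive")
  if (voxel_size > sphere_diameter / 10)
    stop(sprintf(
      "voxel_size %g um too coarse to resolve %g um spheres; minimum resolution is %g um",
      voxel_size, sphere_diameter, sphere_diameter / 10))
  domain_edge <- rep(domain_edge, length.out = 3)
  if (any(domain_edge < sphere_diameter))
    stop("domain_edge must be at least one sphere diameter")

  d <- sphere_diameter
  if (packing == "BCC") {
    cell <- rep(2 * d / sqrt(3), 3)                  # spheres touch along body diagonal
    basis <- rbind(c(0, 0, 0), cell / 2)
  } else {
    a <- d                                           # spheres touch in-layer
    cell <- c(a, sqrt(3) * a, sqrt(8 / 3) * a)
    basis <- rbind(
      c(0, 0, 0),
      c(a / 2, sqrt(3) * a / 2, 0),
      c(a / 2, a / (2 * sqrt(3)), cell[3] / 2),
      c(0, 2 * a / sqrt(3), cell[3] / 2))
  }
  ncell <- pmax(1L, as.integer(round_half_up(domain_edge / cell)))
  extent <- ncell * cell
  nv <- pmax(1L, as.integer(round_half_up(extent / voxel_size)))

  lab <- array(PHASE_LABELS[["pore"]], dim = nv)
  r <- d / 2
  rvox <- r / voxel_size
  # voxel centre at index i (1-based) sits at (i - 0.5) * voxel_size
  centre_coord <- function(i) (i - 0.5) * voxel_size

  # cells -1 .. ncell provide periodic images across every face
  for (cx in -1:ncell[1]) for (cy in -1:ncell[2]) for (cz in -1:ncell[3]) {
    shift <- c(cx, cy, cz) * cell
    for (b in seq_len(nrow(basis))) {
      ctr <- shift + basis[b, ]
      lo <- pmax(1L, as.integer(ceiling((ctr - r) / voxel_size + 0.5)))
      hi <- pmin(nv, as.integer(floor((ctr + r) / voxel_size + 0.5)))
      if (any(lo > hi)) next
      xi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; zi <- lo[3]:hi[3]
      dx2 <- (centre_coord(xi) - ctr[1])^2
      dy2 <- (centre_coord(yi) - ctr[2])^2
      dz2 <- (centre_coord(zi) - ctr[3])^2
      inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
      sub <- lab[xi, yi, zi, drop = FALSE]
      sub[inside] <- PHASE_LABELS[["mineral"]]
      lab[xi, yi, zi] <- sub
    }
  }
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3),
               geometry_kind = "cartesian")
}

# Smoothed standard-normal random field on a grid of dims nv. The noise is
# generated on a grid padded by 3 sigma and cropped after smoothing:
# blurring with reflecting boundaries would inflate the field variance at
# the faces and deplete the middle (textural) quantile band there.
smoothed_field <- function(nv, sigma_vox) {
  pad <- as.integer(ceiling(3 * sigma_vox))
  npad <- nv + 2L * pad
  field <- rnorm(prod(npad))
  field <- cpp_gauss_blur3d(field, npad, sigma_vox)
  field <- array(field, dim = npad)
  field[pad + seq_len(nv[1]), pad + seq_len(nv[2]), pad + seq_len(nv[3])]
}

# Shared helper: three-phase labelling of a set of voxels from a smoothed
# standard-normal random field, thresholded at empirical quantiles so the
# realised fractions match the requested (pore, textural, mineral) split.
# The textural phase occupies the field band directly below the mineral
# threshold, so it forms shells adjacent to the mineral blobs.
three_phase_labels_from_field <- function(field, fractions) {
  f_pore <- fractions[1]; f_text <- fractions[2]; f_min <- fractions[3]
  lab <- rep(PHASE_LABELS[["pore"]], length(field))
  if (f_min > 0) {
    q_min <- quantile(field, probs = 1 - f_min, names = FALSE, type = 8)
    lab[field >= q_min] <- PHASE_LABELS[["mineral"]]
  } else q_min <- Inf
  if (f_text > 0) {
    q_text <- quantile(field, probs = f_pore, names = FALSE, type = 8)
    lab[field >= q_text & field < q_min] <- PHASE_LABELS[["textural"]]
  }
  lab
}

#' Generate a correlated three-phase soil volume
#'
#' Synthetic stand-in for a segmented soil cube: a Gaussian random field
#' smoothed at the grain correlation length is double-thresholded into
#' primary mineral (upper tail, forming connected grain-like blobs), a
#' hydrated textural band directly adjacent to the mineral blobs, and
#' gaseous pore elsewhere. Thresholds are empirical quantiles of the field,
#' so realised volume fractions match the request to well within +/-1%.
#'
#' @param fractions length-3 numeric `(pore, textural, mineral)`, summing
#'   to 1. The canonical segmented-cube split is `c(0.35, 0.325, 0.325)`.
#' @param domain_edge domain edge, um; scalar or length-3.
#' @param voxel_size voxel edge, um.
#' @param correlation_length Gaussian smoothing length, um (default 100,
#'   the order of small grain diameters).
#' @param rng_seed integer seed; identical seeds give identical volumes.
#' @return A [phase_volume()] (cartesian).
#' @export
generate_three_phase_soil <- function(fractions, domain_edge, voxel_size,
                                      correlation_length = 100,
                                      rng_seed = NULL) {
  if (length(fractions) != 3 || any(fractions < 0))
    stop("fractions must be 3 non-negative numbers (pore, textural, mineral)")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1")
  domain_edge <- rep(domain_edge, length.out = 3)
  nv <- pmax(1L, as.integer(round_half_up(domain_edge / voxel_size)))
  lab <- with_seed(rng_seed, {
    field <- smoothed_field(nv, correlation_length / voxel_size)
    three_phase_labels_from_field(as.vector(field), fractions)
  })
  phase_volume(array(lab, dim = nv), voxel_size,
               origin = rep(voxel_size / 2, 3), geometry_kind = "cartesian")
}

#' Generate a cylindrical root-in-soil domain
#'
#' A z-axis-aligned cylindrical root surrounded by an annulus of
#' correlated three-phase soil; voxels beyond the soil extent are labelled
#' OUTSIDE. Defaults follow the canonical rice-root configuration: a
#' 600 um diameter root with soil extending ~600 um from its surface
#' (encompassing the maximal hair length of 500 um).
#'
#' @param root_diameter root diameter, um.
#' @param soil_extent radial soil thickness beyond the root surface, um.
#' @param voxel_size voxel edge, um.
#' @param axial_length domain length along the root axis, um.
#' @param fractions soil phase fractions `(pore, textural, mineral)` within
#'   the annulus; `c(1, 0, 0)` gives an all-pore annulus (a cylindrical
#'   control with an explicit root).
#' @param correlation_length soil smoothing length, um.
#' @param rng_seed integer seed.
#' @return A [phase_volume()] (cylindrical).
#' @export
generate_cylindrical_domain <- function(root_diameter = 600,
                                        soil_extent = 600,
                                        voxel_size = 10,
                                        axial_length = 600,
                                        fractions = c(0.35, 0.325, 0.325),
                                        correlation_length = 100,
                                        rng_seed = NULL) {
  if (root_diameter <= 0 || soil_extent <= 0)
    stop("root_diameter and soil_extent must be positive")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 non-negative numbers summing to 1")
  r_root <- root_diameter / 2
  r_out <- r_root + soil_extent
  nxy <- as.integer(ceiling(2 * r_out / voxel_size))
  nz <- max(1L, as.integer(round_half_up(axial_length / voxel_size)))
  nv <- c(nxy, nxy, nz)

  cx <- nxy * voxel_size / 2
  xc <- (seq_len(nxy) - 0.5) * voxel_size - cx
  rho <- sqrt(outer(xc^2, xc^2, "+"))              # radial distance per (x,y)
  lab2d <- ifelse(rho <= r_root, PHASE_LABELS[["root"]],
           ifelse(rho <= r_out, NA_integer_, PHASE_LABELS[["outside"]]))
  lab <- array(rep(lab2d, nz), dim = nv)
  soil_idx <- which(is.na(lab))
  soil_lab <- with_seed(rng_seed, {
    field <- smoothed_field(nv, correlation_length / voxel_size)
    three_phase_labels_from_field(as.vector(field)[soil_idx], fractions)
  })
  lab[soil_idx] <- soil_lab
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3),
               geometry_kind = "cylindrical")
}
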