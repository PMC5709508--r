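#' Remove small primary mineral grains
#'
#' Labels 26-connected components of the primary mineral phase and removes
#' every grain whose equivalent-sphere diameter `(6V/pi)^(1/3)` falls below
#' `min_equiv_diameter`. The growth model's step length must not exceed the
#' smallest surviving grain diameter (that is what prevents hairs from
#' tunnelling through grains), so collision volumes are filtered at the
#' step length (canonically 32 um) before growth.
#'
#' Removed grains are relabelled to the majority phase among their
#' face-adjacent non-mineral neighbour voxels (tie or no neighbour:
#' hydrated textural). All other voxels are untouched, and the operation
#' is idempotent.
#'
#' @param volume a [phase_volume()].
#' @param min_equiv_diameter threshold, um; must be at least one voxel.
#' @return A new [phase_volume()] with attribute `removed_grains` (count of
#'   grains removed).
#' @export
filter_small_grains <- function(volume, min_equiv_diameter) {
  if (min_equiv_diameter < volume$voxel_size)
    stop("min_equiv_diameter must be >= voxel_size")
  lab <- volume$labels
  d <- dim(lab)
  comp <- cpp_label_components_26(as.vector(lab), d, PHASE_LABELS[["mineral"]])
  ncomp <- attr(comp, "ncomp")
  if (ncomp == 0) {
    out <- volume
    attr(out, "removed_grains") <- 0L
    return(out)
  }
  counts <- tabulate(comp, nbins = ncomp)
  equiv_d <- (6 * counts * volume$voxel_size^3 / pi)^(1 / 3)
  small <- which(equiv_d < min_equiv_diameter)
  newlab <- lab
  for (g in small) {
    vox <- which(comp == g)
    repl <- majority_nonmineral_neighbour(lab, d, vox)
    newlab[vox] <- repl
  }
  out <- phase_volume(newlab, volume$voxel_size, volume$origin,
                      volume$geometry_kind)
  attr(out, "removed_grains") <- length(small)
  out
}

# Majority phase among face-adjacent non-mineral neighbours of a voxel set
# (linear indices into a 3D array); ties and isolated grains fall back to
# the hydrated textural phase.
majority_nonmineral_neighbour <- function(lab, d, vox) {
  k0 <- (vox - 1L) %/% (d[1] * d[2])
  rem <- (vox - 1L) %% (d[1] * d[2])
  j0 <- rem %/% d[1]
  i0 <- rem %% d[1]
  neigh <- integer(0)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (o in seq_len(nrow(offs))) {
    ii <- i0 + offs[o, 1]; jj <- j0 + offs[o, 2]; kk <- k0 + offs[o, 3]
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    if (!any(ok)) next
    lin <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1L
    v <- lab[lin]
    neigh <- c(neigh, v[v != PHASE_LABELS[["mineral"]] &
                        v != PHASE_LABELS[["outside"]]])
  }
  if (!length(neigh)) return(PHASE_LABELS[["textural"]])
  tab <- table(neigh)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) PHASE_LABELS[["textural"]] else top
}
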