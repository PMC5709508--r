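# Fixtures are built in code at test time; nothing is stored on disk.

# A volume containing a single voxelised sphere of the given diameter,
# centred in an all-pore cube.
single_sphere_volume <- function(diameter, voxel_size, pad = 2 * voxel_size,
                                 phase = "mineral") {
  edge <- diameter + 2 * pad
  nv <- as.integer(ceiling(edge / voxel_size))
  ctr <- rep(nv * voxel_size / 2, 3)
  g <- (seq_len(nv) - 0.5) * voxel_size
  d2 <- outer(outer((g - ctr[1])^2, (g - ctr[2])^2, "+"), (g - ctr[3])^2, "+")
  lab <- array(PHASE_LABELS[["pore"]], dim = rep(nv, 3))
  lab[d2 <= (diameter / 2)^2] <- PHASE_LABELS[[phase]]
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3))
}

# A volume with spheres at arbitrary centres (um) and per-sphere diameters.
spheres_volume <- function(centres, diameters, edge, voxel_size) {
  nv <- as.integer(ceiling(edge / voxel_size))
  g <- (seq_len(nv) - 0.5) * voxel_size
  lab <- array(PHASE_LABELS[["pore"]], dim = rep(nv, 3))
  for (i in seq_len(nrow(centres))) {
    d2 <- outer(outer((g - centres[i, 1])^2, (g - centres[i, 2])^2, "+"),
                (g - centres[i, 3])^2, "+")
    lab[d2 <= (diameters[i] / 2)^2] <- PHASE_LABELS[["mineral"]]
  }
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3))
}

# Uniform volume of one phase.
uniform_volume <- function(phase, edge, voxel_size) {
  nv <- as.integer(ceiling(edge / voxel_size))
  lab <- array(PHASE_LABELS[[phase]], dim = rep(nv, 3))
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3))
}

# Horizontal slab of a phase between physical z-coordinates [z0, z1).
slab_volume <- function(phase, z0, z1, edge, voxel_size,
                        base_phase = "pore") {
  nv <- as.integer(ceiling(edge / voxel_size))
  lab <- array(PHASE_LABELS[[base_phase]], dim = rep(nv, 3))
  zc <- (seq_len(nv) - 0.5) * voxel_size
  lab[, , zc >= z0 & zc < z1] <- PHASE_LABELS[[phase]]
  phase_volume(lab, voxel_size, origin = rep(voxel_size / 2, 3))
}

# Independent brute-force 26-connected component scan (BFS in plain R);
# oracle for filter_small_grains.
brute_components <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, dim = d)
  ncomp <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- integer(64)
    stack[1] <- start
    top <- 1L
    comp[start] <- ncomp
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      ai <- arrayInd(v, d)
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        ii <- ai[1] + di; jj <- ai[2] + dj; kk <- ai[3] + dk
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        w <- ii + d[1] * (jj - 1 + d[2] * (kk - 1))
        if (mask[w] && comp[w] == 0L) {
          comp[w] <- ncomp
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- w
        }
      }
    }
  }
  list(labels = comp, ncomp = ncomp)
}

# Small correlated three-phase fixture shared across growth tests.
small_three_phase <- function(seed = 7, edge = 600, voxel = 10) {
  generate_three_phase_soil(c(0.35, 0.325, 0.325), edge, voxel,
                            correlation_length = 100, rng_seed = seed)
}
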