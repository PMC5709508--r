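test_that("sphere packings reach analytic density within voxelisation tolerance", {
  # small domains keep runtime down; tolerance is the spec'd +/-2%
  hcp <- generate_sphere_packing("HCP", 90, 400, 9)
  expect_equal(phase_fractions(hcp)[["mineral"]], pi / sqrt(18),
               tolerance = 0.02)
  bcc <- generate_sphere_packing("BCC", 270, 700, 15)
  expect_equal(phase_fractions(bcc)[["mineral"]], pi * sqrt(3) / 8,
               tolerance = 0.02)
  # only pore and mineral labels present
  expect_setequal(unique(as.vector(hcp$labels)),
                  PHASE_LABELS[c("pore", "mineral")])
})

test_that("packing fraction error decreases as voxels shrink", {
  errs <- vapply(c(9, 4.5), function(vox) {
    v <- generate_sphere_packing("BCC", 90, 250, vox)
    abs(phase_fractions(v)[["mineral"]] - pi * sqrt(3) / 8)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("voxelised spheres have the requested equivalent diameter", {
  vox <- 9
  s <- single_sphere_volume(90, vox)
  nvox <- sum(s$labels == PHASE_LABELS[["mineral"]])
  equiv_d <- (6 * nvox * vox^3 / pi)^(1 / 3)
  expect_lt(abs(equiv_d - 90), vox)
})

test_that("too-coarse voxels are rejected with the minimum resolution named", {
  expect_error(generate_sphere_packing("BCC", 90, 400, 10),
               "minimum resolution is 9")
})

test_that("three-phase generator hits requested fractions and is deterministic", {
  fr <- c(0.35, 0.325, 0.325)
  v1 <- generate_three_phase_soil(fr, 400, 10, 100, rng_seed = 3)
  f1 <- phase_fractions(v1)
  expect_lt(abs(f1[["pore"]] - 0.35), 0.01)
  expect_lt(abs(f1[["textural"]] - 0.325), 0.01)
  expect_lt(abs(f1[["mineral"]] - 0.325), 0.01)
  v2 <- generate_three_phase_soil(fr, 400, 10, 100, rng_seed = 3)
  expect_identical(v1$labels, v2$labels)
  v3 <- generate_three_phase_soil(fr, 400, 10, 100, rng_seed = 4)
  expect_false(identical(v1$labels, v3$labels))

  allpore <- generate_three_phase_soil(c(1, 0, 0), 200, 10, 50, rng_seed = 1)
  expect_true(all(allpore$labels == PHASE_LABELS[["pore"]]))
  expect_error(generate_three_phase_soil(c(0.5, 0.5, 0.5), 200, 10),
               "sum to 1")
})

test_that("cylindrical domains bound soil distance and label the boundary", {
  cy <- generate_cylindrical_domain(600, 600, 10, 200,
                                    fractions = c(1, 0, 0))
  expect_true(any(cy$labels == PHASE_LABELS[["outside"]]))
  expect_true(any(cy$labels == PHASE_LABELS[["root"]]))
  # every soil voxel within soil_extent + voxel diagonal of the root surface
  d <- dim(cy$labels)
  ctr <- d[1] * cy$voxel_size / 2
  soil <- which(cy$labels == PHASE_LABELS[["pore"]])
  ijk <- arrayInd(soil, d)
  xy <- (ijk[, 1:2] - 0.5) * cy$voxel_size - ctr
  rho <- sqrt(rowSums(xy^2))
  expect_lte(max(rho - 300), 600 + sqrt(3) * cy$voxel_size)
  expect_gte(min(rho), 300 - sqrt(3) * cy$voxel_size)
})

test_that("small grains are filtered by equivalent diameter", {
  # 20 um sphere below a 32 um threshold disappears entirely
  v20 <- single_sphere_volume(20, 4)
  f20 <- filter_small_grains(v20, 32)
  expect_equal(sum(f20$labels == PHASE_LABELS[["mineral"]]), 0)
  expect_equal(attr(f20, "removed_grains"), 1L)

  # 270 um sphere above threshold is untouched
  v270 <- single_sphere_volume(270, 10)
  f270 <- filter_small_grains(v270, 32)
  expect_identical(f270$labels, v270$labels)
  expect_equal(attr(f270, "removed_grains"), 0L)
})

test_that("filtering matches a brute-force component scan and conserves labels", {
  vox <- 4
  v <- spheres_volume(rbind(c(30, 30, 30), c(90, 90, 90)),
                      c(20, 40), 120, vox)
  oracle <- brute_components(v$labels == PHASE_LABELS[["mineral"]])
  expect_equal(oracle$ncomp, 2L)
  sizes <- tabulate(oracle$labels[oracle$labels > 0], oracle$ncomp)
  small_oracle <- sum((6 * sizes * vox^3 / pi)^(1 / 3) < 32)
  f <- filter_small_grains(v, 32)
  expect_equal(attr(f, "removed_grains"), small_oracle)
  expect_equal(attr(f, "removed_grains"), 1L)
  # the large grain and all non-mineral voxels are bit-identical
  keep <- v$labels != PHASE_LABELS[["mineral"]]
  expect_identical(f$labels[keep], v$labels[keep])
  big <- oracle$labels == which.max(sizes)
  expect_true(all(f$labels[big] == PHASE_LABELS[["mineral"]]))
  # idempotence
  f2 <- filter_small_grains(f, 32)
  expect_identical(f2$labels, f$labels)
  expect_error(filter_small_grains(v, 2), "voxel_size")
})

test_that("cartesian faces report exact area and unit normals", {
  v <- generate_three_phase_soil(c(0.35, 0.325, 0.325), 1860, 20,
                                 100, rng_seed = 5)
  s <- extract_surface(v, "face", axis = "z", side = "low")
  expect_equal(s$area, 1.86^2, tolerance = 1e-12)
  expect_equal(max(abs(sqrt(rowSums(s$normals^2)) - 1)), 0, tolerance = 1e-9)
  expect_true(all(s$normals[, 3] == 1))
  s_hi <- extract_surface(v, "face", axis = "z", side = "high")
  expect_true(all(s_hi$normals[, 3] == -1))
})

test_that("root surface normals are radial and require a root phase", {
  cy <- generate_cylindrical_domain(600, 300, 10, 300,
                                    fractions = c(1, 0, 0))
  s <- extract_surface(cy, "root")
  expect_equal(max(abs(sqrt(rowSums(s$normals^2)) - 1)), 0,
               tolerance = 1e-9)
  d <- dim(cy$labels)
  ctr <- d[1] * cy$voxel_size / 2
  lateral <- abs(s$normals[, 3]) < 0.5
  rad <- cbind(s$points[lateral, 1] - ctr, s$points[lateral, 2] - ctr, 0)
  rad <- rad / sqrt(rowSums(rad^2))
  ang <- acos(pmin(pmax(rowSums(rad * s$normals[lateral, ]), -1), 1))
  expect_gte(mean(ang < 5 * pi / 180), 0.95)

  nr <- uniform_volume("pore", 100, 10)
  expect_error(extract_surface(nr, "root"), "no ROOT phase")
})

test_that("distance maps match analytic forms for plane and cylinder", {
  v <- uniform_volume("pore", 200, 10)
  s <- extract_surface(v, "face", axis = "z", side = "low")
  dm <- distance_from_surface(v, s)
  # distance equals the coordinate offset along the normal, exactly
  p <- rbind(c(55, 87, 5), c(12, 3, 155))
  expect_equal(surface_distance(dm, p), c(5, 155), tolerance = 1e-9)
  # at the surface itself a voxel-sampled map is exact to half a voxel
  expect_lte(max(surface_distance(dm, s$points)), v$voxel_size / 2)
  # the analytic planar reference is exactly zero there
  expect_equal(surface_distance(planar_distance(s), s$points),
               rep(0, nrow(s$points)), tolerance = 1e-12)

  cy <- generate_cylindrical_domain(600, 300, 10, 120,
                                    fractions = c(1, 0, 0))
  sr <- extract_surface(cy, "root")
  dmr <- distance_from_surface(cy, sr)
  ctr <- dim(cy$labels)[1] * cy$voxel_size / 2
  # sample soil points and compare with rho - R
  set.seed(1)
  th <- runif(200, 0, 2 * pi); rho <- runif(200, 320, 580)
  pts <- cbind(ctr + rho * cos(th), ctr + rho * sin(th), 60)
  err <- abs(surface_distance(dmr, pts) - (rho - 300))
  expect_lt(max(err), sqrt(3) * cy$voxel_size)
})
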