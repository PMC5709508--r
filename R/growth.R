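#' Growth model configuration
#'
#' Parameters of the stepwise tip-extension algorithm. The step length `r`
#' must be smaller than the smallest primary mineral grain surviving
#' [filter_small_grains()]: end-point collision tests plus this size rule
#' are what prevent hairs tunnelling through grains. Each growth step
#' places `fan_size` quasi-equally spaced test points on a sphere of radius
#' `r` about the tip, classifies them by angle against the reference
#' heading into `bin_count` sets of width `pi/(2*bin_count)`, and picks
#' uniformly at random among the valid points of the lowest-angle
#' non-empty set.
#'
#' Condition `A0` keeps the reference heading fixed at the seed's initial
#' vector (rigidity-limited tortuosity); `A1` updates it to the previous
#' growth vector (geometry-dominated tortuosity). Condition `F0` lets
#' hairs cross fluid boundaries freely; `F1` confines a hair to the
#' hydrated textural phase once its tip is inside it.
#'
#' @param step_length step length `r`, um (canonical 32).
#' @param fan_size number of test points `n` (>= 8; default 100).
#' @param bin_count number of angular sets `k` (>= 1; default 4).
#' @param condition_A `"A0"` or `"A1"`.
#' @param condition_F `"F0"` or `"F1"`.
#' @param rng_seed integer seed for the population-level RNG substreams.
#' @param max_steps guard on the number of steps per hair.
#' @return Object of class `growth_config`.
#' @export
growth_config <- function(step_length = 32, fan_size = 100, bin_count = 4,
                          condition_A = c("A0", "A1"),
                          condition_F = c("F0", "F1"),
                          rng_seed = 1L, max_steps = 10000L) {
  condition_A <- match.arg(condition_A)
  condition_F <- match.arg(condition_F)
  if (step_length <= 0) stop("step_length must be positive")
  if (fan_size < 8) stop("fan_size must be at least 8")
  if (bin_count < 1) stop("bin_count must be at least 1")
  structure(list(step_length = step_length, fan_size = as.integer(fan_size),
                 bin_count = as.integer(bin_count),
                 condition_A = condition_A, condition_F = condition_F,
                 rng_seed = as.integer(rng_seed),
                 max_steps = as.integer(max_steps)),
            class = "growth_config")
}

#' Quasi-equally spaced points on the unit sphere
#'
#' Generalised spiral construction: heights `z_i = -1 + 2(i-1)/(n-1)` and
#' azimuth increments `3.6 / sqrt(n (1 - z_i^2))`, with the two poles
#' handled explicitly. Deterministic in `n`.
#'
#' @param n number of points (>= 2).
#' @return n x 3 matrix of unit vectors.
#' @export
spiral_points <- function(n) {
  if (n < 2) stop("n must be at least 2")
  z <- -1 + 2 * (seq_len(n) - 1) / (n - 1)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1 || i == n || abs(z[i]) >= 1) {
      phi[i] <- 0
    } else {
      phi[i] <- (phi[i - 1] + 3.6 / sqrt(n * (1 - z[i]^2))) %% (2 * pi)
    }
  }
  s <- sqrt(pmax(1 - z^2, 0))
  m <- cbind(s * cos(phi), s * sin(phi), z)
  dimnames(m) <- NULL
  m
}

#' True included angle between two vectors
#'
#' Computed as `atan2(||a x b||, a . b)`, which is numerically robust near
#' 0 and pi where the naive arccos of the normalised dot product loses
#' precision. Returns radians in `[0, pi]`.
#'
#' @param h_ref,h_test nonzero length-3 vectors.
#' @return Angle in radians.
#' @export
angle_between <- function(h_ref, h_test) {
  if (sum(h_ref^2) == 0 || sum(h_test^2) == 0)
    stop("vectors must be nonzero")
  cr <- c(h_ref[2] * h_test[3] - h_ref[3] * h_test[2],
          h_ref[3] * h_test[1] - h_ref[1] * h_test[3],
          h_ref[1] * h_test[2] - h_ref[2] * h_test[1])
  atan2(sqrt(sum(cr^2)), sum(h_ref * h_test))
}

#' Classify angles into angular sets
#'
#' Angle `a` maps to bin `floor(a / (pi/(2k))) + 1` for `a < pi/2`; angles
#' at or beyond `pi/2` are out of range (`NA`), matching the validity rule
#' that growth never deviates by `pi/2` or more from the reference
#' heading. Bins are half-open `[lower, upper)`.
#'
#' @param angles radians.
#' @param k number of bins.
#' @return Integer bin indices (`NA` = out of range).
#' @export
classify_bins <- function(angles, k) {
  if (k < 1) stop("k must be at least 1")
  w <- pi / (2 * k)
  idx <- floor(angles / w) + 1
  idx[angles >= pi / 2 | angles < 0] <- NA_integer_
  as.integer(idx)
}

#' Build the test fan for one growth step
#'
#' @param tip current tip coordinates, um.
#' @param reference_heading unit reference heading.
#' @param radius step radius, um.
#' @param dirs n x 3 unit directions (from [spiral_points()]).
#' @param k number of angular bins.
#' @return List with `test_points`, `test_vectors`, `angles`, `bin_index`.
#' @export
test_fan <- function(tip, reference_heading, radius, dirs, k) {
  dots <- as.vector(dirs %*% reference_heading)
  dots <- pmin(pmax(dots, -1), 1)
  angles <- atan2(sqrt(pmax(1 - dots^2, 0)), dots)
  list(test_points = radius * dirs +
         matrix(tip, nrow(dirs), 3, byrow = TRUE),
       test_vectors = radius * dirs,
       angles = angles,
       bin_index = classify_bins(angles, k))
}

#' Apply the growth validity tests to a fan
#'
#' Flags each test point: inside the domain (label not OUTSIDE and within
#' the grid), angle in range (below pi/2), end-point not inside a primary
#' mineral grain or the root, and -- under condition F1 when the current
#' tip sits in the hydrated textural phase -- end-point also in the
#' textural phase. A point is selectable iff all flags hold.
#'
#' @param fan from [test_fan()].
#' @param volume a [phase_volume()] or NULL (empty control domain).
#' @param config a [growth_config()].
#' @param seed_in_fluid is the current tip voxel in the textural phase?
#' @return `fan` with added logical fields `in_domain`, `angle_ok`,
#'   `not_mineral`, `fluid_ok`, `valid`.
#' @export
validity_tests <- function(fan, volume, config, seed_in_fluid = FALSE) {
  lab <- voxel_label(volume, fan$test_points)
  fan$in_domain <- lab != PHASE_LABELS[["outside"]]
  fan$angle_ok <- !is.na(fan$bin_index)
  fan$not_mineral <- lab != PHASE_LABELS[["mineral"]] &
    lab != PHASE_LABELS[["root"]]
  fan$fluid_ok <- if (config$condition_F == "F1" && seed_in_fluid)
    lab == PHASE_LABELS[["textural"]] else rep(TRUE, length(lab))
  fan$valid <- fan$in_domain & fan$angle_ok & fan$not_mineral & fan$fluid_ok
  fan$labels <- lab
  fan
}

#' Execute one growth step
#'
#' Selects uniformly at random among the valid test vectors of the
#' lowest-angle non-empty bin. Termination (no valid vector) is a return
#' state, not an error.
#'
#' @param tip current tip, um.
#' @param reference_heading unit reference heading.
#' @param volume a [phase_volume()] or NULL.
#' @param config a [growth_config()].
#' @param radius step radius, um (the final partial step is shorter).
#' @param dirs optional precomputed [spiral_points()] matrix.
#' @return List `(new_tip, chosen_heading, terminated)`; when terminated,
#'   the first two are NULL.
#' @export
grow_step <- function(tip, reference_heading, volume, config,
                      radius = config$step_length, dirs = NULL) {
  if (is.null(dirs)) dirs <- spiral_points(config$fan_size)
  seed_in_fluid <- voxel_label(volume, tip) == PHASE_LABELS[["textural"]]
  fan <- test_fan(tip, reference_heading, radius, dirs, config$bin_count)
  fan <- validity_tests(fan, volume, config, seed_in_fluid)
  if (!any(fan$valid))
    return(list(new_tip = NULL, chosen_heading = NULL, terminated = TRUE))
  jmin <- min(fan$bin_index[fan$valid])
  cand <- which(fan$valid & fan$bin_index == jmin)
  pick <- cand[floor(runif(1) * length(cand)) + 1L]
  list(new_tip = fan$test_points[pick, ],
       chosen_heading = dirs[pick, ],
       terminated = FALSE)
}

#' Grow a single hair
#'
#' Extends a hair tip stepwise from its seed through the collision volume
#' until the virtual growth length `l_v` is reached or growth ceases.
#' `floor(l_v / r)` full steps are taken plus one shorter final step so
#' the achieved length equals `l_v` exactly. Under A0 every step's angle
#' is measured against the seed heading; under A1 against the previous
#' growth vector (the selected growth vector becomes the next step's
#' initiation vector).
#'
#' @param seed a [hair_seed()].
#' @param l_v virtual growth length, um (>= 0).
#' @param volume a [phase_volume()] or NULL (empty control domain).
#' @param config a [growth_config()].
#' @param dirs optional precomputed [spiral_points()] matrix.
#' @param hair_id identifier stored on the path.
#' @return Object of class `hair_path`: `vertices` (m x 3 um, first row =
#'   transition point), `phase` (label per vertex), `headings` (reference
#'   heading per step), `target_length`, `achieved_length`,
#'   `terminated_early`, `terminated_reason`.
#' @export
grow_hair <- function(seed, l_v, volume, config, dirs = NULL, hair_id = 1L) {
  if (l_v < 0) stop("l_v must be >= 0")
  if (is.null(dirs)) dirs <- spiral_points(config$fan_size)
  tip <- seed$transition_point
  tip_lab <- voxel_label(volume, tip)
  if (tip_lab == PHASE_LABELS[["mineral"]])
    stop("seed transition point lies inside a primary mineral grain")

  r <- config$step_length
  m_full <- floor(l_v / r + 1e-9)
  rem <- l_v - m_full * r
  if (rem < 1e-9) rem <- 0
  nsteps <- m_full + (rem > 0)

  verts <- matrix(NA_real_, nsteps + 1, 3)
  verts[1, ] <- tip
  heads <- matrix(NA_real_, max(nsteps, 1), 3)
  ref <- seed$heading
  achieved <- 0
  reason <- NA_character_
  taken <- 0L

  if (tip_lab == PHASE_LABELS[["outside"]]) {
    reason <- "out_of_domain_guard"
  } else if (nsteps > 0) {
    for (s in seq_len(nsteps)) {
      if (s > config$max_steps) { reason <- "max_steps"; break }
      radius <- if (s <= m_full) r else rem
      heads[s, ] <- ref
      st <- grow_step(tip, ref, volume, config, radius = radius,
                      dirs = dirs)
      if (st$terminated) { reason <- "trapped"; break }
      tip <- st$new_tip
      achieved <- achieved + radius
      taken <- taken + 1L
      verts[s + 1, ] <- tip
      if (config$condition_A == "A1") ref <- st$chosen_heading
    }
  }
  verts <- verts[seq_len(taken + 1L), , drop = FALSE]
  heads <- heads[seq_len(max(taken, 1L)), , drop = FALSE]
  structure(list(hair_id = hair_id, vertices = verts,
                 phase = voxel_label(volume, verts),
                 headings = heads, target_length = l_v,
                 achieved_length = achieved,
                 terminated_early = !is.na(reason),
                 terminated_reason = if (is.na(reason)) NULL else reason),
            class = "hair_path")
}

#' Grow a hair population (one computational replicate)
#'
#' Grows one hair per seed. Each hair uses an RNG substream derived from
#' `(config$rng_seed, hair_id)`, so a replicate is reproducible and
#' independent of growth order.
#'
#' @param seeds list of [hair_seed()] objects.
#' @param lengths a `length_assignment` from [assign_lengths()].
#' @param volume a [phase_volume()] or NULL (control replicate).
#' @param config a [growth_config()].
#' @return List of `hair_path` objects.
#' @export
grow_population <- function(seeds, lengths, volume, config) {
  if (length(seeds) != length(lengths$l_v))
    stop("seeds and length assignment differ in length")
  dirs <- spiral_points(config$fan_size)
  lapply(seq_along(seeds), function(i) {
    with_seed(substream_seed(config$rng_seed, i),
              grow_hair(seeds[[i]], lengths$l_v[i], volume, config,
                        dirs = dirs, hair_id = i))
  })
}
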