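#' Construct a hair seed
#'
#' A seed is the starting state of one simulated hair: the transition point
#' `T` at which synthetic growth begins, the initial heading, and the
#' visible length `l_r` of any observed partial segment (0 for fully
#' synthetic hairs). When the initiation point `I` is given, the heading
#' and visible length are derived from the `I -> T` vector.
#'
#' @param transition_point length-3 coordinates, um.
#' @param heading initial growth direction (normalised internally);
#'   ignored when `initiation_point` is given.
#' @param visible_length observed partial length `l_r`, um; ignored when
#'   `initiation_point` is given.
#' @param initiation_point optional length-3 coordinates, um.
#' @return Object of class `hair_seed`.
#' @export
hair_seed <- function(transition_point, heading = NULL, visible_length = 0,
                      initiation_point = NULL) {
  T_ <- as.numeric(transition_point)
  if (!is.null(initiation_point)) {
    I_ <- as.numeric(initiation_point)
    v <- T_ - I_
    len <- sqrt(sum(v^2))
    if (len == 0) stop("initiation and transition points coincide")
    heading <- v / len
    visible_length <- len
  } else {
    I_ <- NULL
    if (is.null(heading)) stop("heading required when no initiation point")
    hn <- sqrt(sum(heading^2))
    if (hn == 0) stop("heading must be a nonzero vector")
    heading <- heading / hn
    if (visible_length < 0) stop("visible_length must be >= 0")
  }
  structure(list(initiation_point = I_, transition_point = T_,
                 heading = heading, visible_length = visible_length),
            class = "hair_seed")
}

#' Sample fully synthetic transition points on a surface
#'
#' Draws `round(density * area_mm2)` seed points uniformly by surface area,
#' each heading along the inward surface normal at the sampled point, with
#' `l_r = 0`. On exact planar faces the points are continuous-uniform over
#' the rectangle; on voxelised root surfaces they are drawn from the
#' surface points weighted equally (the points are approximately
#' equal-area). When a collision `volume` is supplied, seeds whose voxel is
#' primary mineral are resampled (up to 100 attempts) -- a hair cannot
#' initiate inside an impenetrable grain.
#'
#' @param surface a [surface_model()].
#' @param density hair initiation density, hairs per mm^2 (canonical value
#'   121).
#' @param rng_seed optional integer seed.
#' @param volume optional [phase_volume()] used to reject mineral seeds.
#' @return List of [hair_seed()] objects.
#' @export
sample_transition_points <- function(surface, density, rng_seed = NULL,
                                     volume = NULL) {
  if (density < 0) stop("density must be >= 0")
  if (nrow(surface$points) == 0 && density > 0)
    stop("cannot seed an empty surface with positive density")
  count <- as.integer(round_half_up(density * surface$area))
  if (count == 0) return(list())
  with_seed(rng_seed, {
    draw_one <- function() {
      if (!is.null(surface$face)) {
        f <- surface$face
        p <- f$point + runif(1) * f$extent[1] * f$u +
          runif(1) * f$extent[2] * f$v
        list(p = p, n = f$normal)
      } else {
        i <- sample.int(nrow(surface$points), 1)
        list(p = surface$points[i, ], n = surface$normals[i, ])
      }
    }
    lapply(seq_len(count), function(i) {
      for (attempt in 1:100) {
        dr <- draw_one()
        if (is.null(volume)) break
        lab <- voxel_label(volume, dr$p + 1e-6 * dr$n)
        if (lab != PHASE_LABELS[["mineral"]]) break
      }
      hair_seed(transition_point = dr$p, heading = dr$n, visible_length = 0)
    })
  })
}

#' Build seeds from observed partial hair segments
#'
#' Each pair of initiation and transition points yields a seed whose
#' heading is the unit `I -> T` vector and whose visible length is the
#' `I -> T` distance.
#'
#' @param pairs either a list of `list(I = , T = )` pairs or an n x 6
#'   matrix/data.frame with columns `Ix, Iy, Iz, Tx, Ty, Tz` (um).
#' @return List of [hair_seed()] objects.
#' @export
seeds_from_partial_hairs <- function(pairs) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      list(I = as.numeric(pairs[i, 1:3]), T = as.numeric(pairs[i, 4:6])))
  }
  lapply(pairs, function(p)
    hair_seed(transition_point = p$T, initiation_point = p$I))
}

#' Assign total and virtual growth lengths to seeds
#'
#' In `fixed` mode every hair receives total length `l_tot = c`; in
#' `weibull_survival` mode `l_v` is drawn from the future-lifetime law of
#' the supplied Weibull model given each seed's visible length, so that
#' the population of `l_tot = l_r + l_v` follows the fitted distribution.
#' The identity `l_v = l_tot - l_r >= 0` holds for every seed; in fixed
#' mode a seed already longer than `c` clamps to `l_v = 0` with a warning.
#'
#' @param seeds list of [hair_seed()] objects.
#' @param mode `"fixed"` or `"weibull_survival"`.
#' @param c fixed total length, um (canonical value 500).
#' @param model a `weibull_model` (survival mode).
#' @param rng_seed optional integer seed (survival mode).
#' @return Object of class `length_assignment`: fields `l_tot`, `l_v`,
#'   `mode`.
#' @export
assign_lengths <- function(seeds, mode = c("fixed", "weibull_survival"),
                           c = 500, model = NULL, rng_seed = NULL) {
  mode <- match.arg(mode)
  l_r <- vapply(seeds, function(s) s$visible_length, numeric(1))
  if (mode == "fixed") {
    if (length(l_r) && any(l_r > c)) {
      warning(sum(l_r > c),
              " seed(s) have visible length above the fixed total; ",
              "their virtual length clamps to 0")
    }
    l_tot <- ifelse(l_r > c, l_r, c)
    l_v <- l_tot - l_r
  } else {
    if (is.null(model)) stop("weibull_survival mode requires a model")
    l_v <- with_seed(rng_seed,
      vapply(l_r, function(lr) sample_future_length(lr, model), numeric(1)))
    l_tot <- l_r + l_v
  }
  structure(list(l_tot = l_tot, l_v = l_v, mode = mode),
            class = "length_assignment")
}
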