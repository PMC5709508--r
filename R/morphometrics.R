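#' Shell-binned hair length profile
#'
#' Accumulates hair length into distance shells from the initiating
#' surface (default width 50 um). Every path segment is subdivided into
#' ~1 um sub-segments; each sub-segment's length accrues to the shell
#' containing its midpoint's distance. The fluid-coincident profile
#' `L_wet` additionally requires the midpoint voxel to lie in the hydrated
#' textural phase (hairs there are taken to have fluid access over their
#' entire area). Profiles report plain length per shell with no volume
#' normalisation, making cartesian and cylindrical cases directly
#' comparable.
#'
#' @param hairs list of `hair_path` objects.
#' @param dref distance reference: a `distance_map`, [planar_distance()] or
#'   [cylinder_distance()].
#' @param volume a [phase_volume()] or NULL (then `L_wet` is 0).
#' @param shell_width shell width, um.
#' @param n_shells number of shells; default covers the largest observed
#'   distance.
#' @param subsample sub-segment target length, um.
#' @return Object of class `length_profile`: `shell_edges` (length
#'   `n_shells + 1`), `L_tot`, `L_wet`, `shell_width`, `n_shells`.
#' @export
length_profile <- function(hairs, dref, volume = NULL, shell_width = 50,
                           n_shells = NULL, subsample = 1) {
  if (shell_width <= 0) stop("shell_width must be positive")
  mids <- list(); lens <- list()
  for (h in hairs) {
    v <- h$vertices
    if (nrow(v) < 2) next
    a <- v[-nrow(v), , drop = FALSE]
    b <- v[-1, , drop = FALSE]
    seg_len <- sqrt(rowSums((b - a)^2))
    for (s in seq_along(seg_len)) {
      L <- seg_len[s]
      if (L <= 0) next
      m <- max(1L, as.integer(ceiling(L / subsample)))
      t <- (seq_len(m) - 0.5) / m
      mids[[length(mids) + 1]] <-
        matrix(a[s, ], m, 3, byrow = TRUE) +
        t %*% t(b[s, ] - a[s, ])
      lens[[length(lens) + 1]] <- rep(L / m, m)
    }
  }
  if (!length(mids)) {
    n_shells <- n_shells %||% 1L
    return(structure(list(shell_edges = seq(0, n_shells) * shell_width,
                          L_tot = numeric(n_shells),
                          L_wet = numeric(n_shells),
                          shell_width = shell_width, n_shells = n_shells),
                     class = "length_profile"))
  }
  mids <- do.call(rbind, mids)
  lens <- unlist(lens)
  dist <- pmax(surface_distance(dref, mids), 0)
  shell <- as.integer(floor(dist / shell_width)) + 1L
  n_shells <- n_shells %||% max(shell)
  shell[shell > n_shells] <- NA_integer_
  ok <- !is.na(shell)
  L_tot <- vapply(seq_len(n_shells), function(j)
    sum(lens[ok & shell == j]), numeric(1))
  if (!is.null(volume)) {
    wet <- voxel_label(volume, mids) == PHASE_LABELS[["textural"]]
    L_wet <- vapply(seq_len(n_shells), function(j)
      sum(lens[ok & wet & shell == j]), numeric(1))
  } else {
    L_wet <- numeric(n_shells)
  }
  structure(list(shell_edges = seq(0, n_shells) * shell_width,
                 L_tot = L_tot, L_wet = L_wet,
                 shell_width = shell_width, n_shells = n_shells),
            class = "length_profile")
}

#' @export
print.length_profile <- function(x, ...) {
  cat(sprintf("<length_profile> %d shells of %g um; total %.1f um (wet %.1f um)\n",
              x$n_shells, x$shell_width, sum(x$L_tot), sum(x$L_wet)))
  invisible(x)
}

#' Bulk-control approximation of the fluid-coincident profile
#'
#' For homogeneous (control) replicates in which fluid is not explicitly
#' represented, the wet length is approximated as `L_wet = j * L_tot`,
#' where `j` is the volume fraction of the non-primary-mineral
#' (hair-accessible) domain occupied by the hydrated textural phase.
#'
#' @param profile_tot a [length_profile()] (its `L_tot` is used).
#' @param volume the [phase_volume()] from which to compute `j`, or a
#'   numeric `j` directly.
#' @return A [length_profile()] whose `L_wet` is `j * L_tot`.
#' @export
control_wet_approximation <- function(profile_tot, volume) {
  j <- if (is.numeric(volume)) volume else accessible_wet_fraction(volume)
  out <- profile_tot
  out$L_wet <- j * profile_tot$L_tot
  attr(out, "j") <- j
  out
}

#' Textural fraction of the hair-accessible domain
#'
#' `j = vol(textural) / (vol(interior) - vol(mineral) - vol(root))`.
#'
#' @param volume a [phase_volume()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
accessible_wet_fraction <- function(volume) {
  lab <- volume$labels
  n_text <- sum(lab == PHASE_LABELS[["textural"]])
  n_pore <- sum(lab == PHASE_LABELS[["pore"]])
  if (n_text + n_pore == 0) stop("volume has no hair-accessible voxels")
  n_text / (n_text + n_pore)
}

#' Elevation of explicit over control wet length
#'
#' `100 * L_wet_explicit / L_wet_control`, the headline comparison between
#' structurally explicit replicates and their homogeneous-soil controls.
#' Inputs may be totals, [length_profile()]s, or lists of profiles
#' (summed).
#'
#' @param explicit,control wet-length inputs.
#' @return Percentage.
#' @export
elevation_percent <- function(explicit, control) {
  total_wet <- function(x) {
    if (is.numeric(x)) return(sum(x))
    if (inherits(x, "length_profile")) return(sum(x$L_wet))
    if (is.list(x)) return(sum(vapply(x, total_wet, numeric(1))))
    stop("unsupported input")
  }
  ctl <- total_wet(control)
  if (ctl <= 0) stop("control wet length must be positive")
  100 * total_wet(explicit) / ctl
}

#' Path tortuosity
#'
#' Achieved path length divided by end-to-end chord (>= 1). Undefined for
#' single-vertex or zero-chord paths (`NA`).
#'
#' @param hair a `hair_path`.
#' @return Dimensionless tortuosity, or `NA`.
#' @export
tortuosity <- function(hair) {
  v <- hair$vertices
  if (nrow(v) < 2) return(NA_real_)
  chord <- sqrt(sum((v[nrow(v), ] - v[1, ])^2))
  if (chord == 0) return(NA_real_)
  hair$achieved_length / chord
}

#' Per-shell mean and standard deviation over computational replicates
#'
#' @param profiles list of [length_profile()]s with identical shells.
#' @return List with `shell_edges`, `mean_tot`, `sd_tot`, `mean_wet`,
#'   `sd_wet`, `n`.
#' @export
replicate_statistics <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  edges <- profiles[[1]]$shell_edges
  for (p in profiles)
    if (!isTRUE(all.equal(p$shell_edges, edges)))
      stop("profiles have mismatched shells")
  tot <- do.call(rbind, lapply(profiles, `[[`, "L_tot"))
  wet <- do.call(rbind, lapply(profiles, `[[`, "L_wet"))
  list(shell_edges = edges,
       mean_tot = colMeans(tot), sd_tot = apply(tot, 2, sd),
       mean_wet = colMeans(wet), sd_wet = apply(wet, 2, sd),
       n = length(profiles))
}

#' Dominant spatial period of a length profile
#'
#' Detects the periodicity that sphere lattices imprint on hair length
#' profiles. The profile is detrended with a centred moving average
#' (window `detrend_window` shells, reflecting at the ends -- profiles
#' decay away from the surface, and without detrending the decay trend
#' masks the lattice ripple), then the first positive non-zero-lag local
#' maximum of the residual autocorrelation gives the dominant period in
#' um. Flat profiles have no period (`NA`).
#'
#' @param profile a [length_profile()] with at least 8 shells.
#' @param detrend_window moving-average window, shells (odd; must be
#'   shorter than the period sought).
#' @return Period in um, or `NA`.
#' @export
profile_periodicity <- function(profile, detrend_window = 3) {
  y <- profile$L_tot
  if (length(y) < 8) stop("need at least 8 shells")
  if (sd(y) == 0) return(NA_real_)
  n <- length(y)
  half <- (detrend_window - 1) / 2
  trend <- vapply(seq_len(n), function(i) {
    j <- pmin(pmax((i - half):(i + half), 1), n)
    mean(y[j])
  }, numeric(1))
  z <- y - trend
  if (sd(z) == 0) return(NA_real_)
  ac <- vapply(seq_len(n - 2), function(lag)
    sum(z[seq_len(n - lag)] * z[seq_len(n - lag) + lag]) / sum(z^2),
    numeric(1))
  for (l in seq_along(ac)) {
    left <- if (l == 1) 0 else ac[l - 1]
    right <- if (l == length(ac)) -Inf else ac[l + 1]
    if (l > 1 && ac[l] > 0 && ac[l] > left && ac[l] >= right)
      return(l * profile$shell_width)
  }
  NA_real_
}
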