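#' Scenario configuration
#'
#' Bundles everything needed for an end-to-end run: a geometry
#' specification, a seeding specification, a length specification, the
#' growth configuration, replicate count and output directory.
#'
#' Geometry kinds: `sphere_packing` (params `packing`, `sphere_diameter`,
#' `domain_edge`, `voxel_size`), `three_phase` (`fractions`,
#' `domain_edge`, `voxel_size`, `correlation_length`), `cylindrical`
#' (`root_diameter`, `soil_extent`, `voxel_size`, `axial_length`,
#' `fractions`, `correlation_length`), `volume` (`path` to an NRRD file),
#' or `empty` (control-only planar scenario; requires `extent`, um).
#'
#' @param geometry list with `kind` and generator parameters.
#' @param seeding list with `density` (hairs/mm^2) or `file` (seed CSV).
#' @param length list with `mode = "fixed"` and `c`, or
#'   `mode = "weibull"` and either (`alpha`, `beta`) or `file` (measured
#'   lengths CSV to fit).
#' @param growth a [growth_config()].
#' @param replicates number of computational replicates (>= 1).
#' @param output_dir output directory, or NULL to skip writing.
#' @param run_control also grow matching control (empty-domain) replicates?
#' @param shell_width profile shell width, um.
#' @param filter_min_diameter grain filter threshold, um (0 disables;
#'   default = step length).
#' @param face list(`axis`, `side`) selecting the initiating cartesian
#'   face (ignored for cylindrical geometries, which seed the root
#'   surface).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(geometry, seeding, length, growth = growth_config(),
                            replicates = 1L, output_dir = NULL,
                            run_control = TRUE, shell_width = 50,
                            filter_min_diameter = NULL,
                            face = list(axis = "z", side = "low")) {
  if (is.null(geometry$kind) ||
      !geometry$kind %in% c("sphere_packing", "three_phase", "cylindrical",
                            "volume", "empty"))
    stop("config error: unknown geometry kind '",
         geometry$kind %||% "<missing>", "'")
  if (geometry$kind == "volume" &&
      (is.null(geometry$path) || !file.exists(geometry$path)))
    stop("config error: missing input volume: ",
         geometry$path %||% "<unset>")
  if (!is.null(seeding$file) && !file.exists(seeding$file))
    stop("config error: missing seed file: ", seeding$file)
  if (is.null(seeding$density) && is.null(seeding$file))
    stop("config error: seeding needs a density or a seed file")
  if (is.null(length$mode) || !length$mode %in% c("fixed", "weibull"))
    stop("config error: length mode must be 'fixed' or 'weibull'")
  if (length$mode == "weibull" && !is.null(length$file) &&
      !file.exists(length$file))
    stop("config error: missing length file: ", length$file)
  if (replicates < 1) stop("config error: replicates must be >= 1")
  structure(list(geometry = geometry, seeding = seeding, length = length,
                 growth = growth, replicates = as.integer(replicates),
                 output_dir = output_dir, run_control = isTRUE(run_control),
                 shell_width = shell_width,
                 filter_min_diameter = filter_min_diameter %||%
                   growth$step_length,
                 face = face),
            class = "scenario_config")
}

# Build (or load) the collision volume of a scenario; NULL for `empty`.
scenario_volume <- function(config) {
  g <- config$geometry
  switch(g$kind,
    sphere_packing = generate_sphere_packing(
      g$packing, g$sphere_diameter, g$domain_edge, g$voxel_size),
    three_phase = generate_three_phase_soil(
      g$fractions, g$domain_edge, g$voxel_size,
      g$correlation_length %||% 100, g$rng_seed %||% config$growth$rng_seed),
    cylindrical = generate_cylindrical_domain(
      g$root_diameter %||% 600, g$soil_extent %||% 600,
      g$voxel_size %||% 10, g$axial_length %||% 600,
      g$fractions %||% c(0.35, 0.325, 0.325),
      g$correlation_length %||% 100,
      g$rng_seed %||% config$growth$rng_seed),
    volume = read_volume(g$path),
    empty = NULL)
}

# Initiating surface + analytic/discrete distance reference for a scenario.
scenario_surface <- function(config, volume) {
  if (config$geometry$kind == "empty") {
    ext <- rep(config$geometry$extent %||% 1860, length.out = 2)
    surf <- planar_surface(ext)
    return(list(surface = surf, dref = planar_distance(surf)))
  }
  if (!is.null(volume) && volume$geometry_kind == "cylindrical") {
    surf <- extract_surface(volume, "root")
    return(list(surface = surf,
                dref = distance_from_surface(volume, surf)))
  }
  surf <- extract_surface(volume, "face", axis = config$face$axis %||% "z",
                          side = config$face$side %||% "low")
  list(surface = surf, dref = planar_distance(surf))
}

# Length model of a scenario (fixed constant or a weibull_model).
scenario_length_model <- function(config) {
  l <- config$length
  if (l$mode == "fixed") return(list(mode = "fixed", c = l$c %||% 500))
  model <- if (!is.null(l$file)) fit_weibull(read_measured_lengths(l$file))
           else weibull_model(l$alpha, l$beta)
  list(mode = "weibull", model = model)
}

#' Run a complete scenario
#'
#' Builds the geometry (filtering small grains at the configured
#' threshold), extracts the initiating surface, then for every
#' computational replicate: seeds the surface, assigns lengths, grows the
#' explicit population (and a matching control population into an empty
#' domain when requested) and computes shell-binned total and
#' fluid-coincident length profiles. When an output directory is
#' configured, per-replicate paths (CSV + VTK), profiles, replicate
#' mean/SD summaries and a provenance record are written.
#'
#' @param config a [scenario_config()].
#' @return (invisibly) list with `volume`, `surface`, `replicates` (each
#'   holding `seeds`, `paths`, `profile`, and control counterparts),
#'   `summary` (replicate statistics) and `elevation` (explicit over
#'   control wet length, %), when both populations were grown.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  volume <- scenario_volume(config)
  if (!is.null(volume) && config$filter_min_diameter >= volume$voxel_size &&
      any(volume$labels == PHASE_LABELS[["mineral"]])) {
    volume <- filter_small_grains(volume, config$filter_min_diameter)
  }
  ss <- scenario_surface(config, volume)
  lm <- scenario_length_model(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  j_ctl <- if (!is.null(volume)) accessible_wet_fraction(volume) else 0

  reps <- vector("list", config$replicates)
  for (r in seq_len(config$replicates)) {
    rep_seed <- substream_seed(config$growth$rng_seed, 1000 + r)
    seeds <- if (!is.null(config$seeding$file))
      read_seeds_csv(config$seeding$file)
    else
      sample_transition_points(ss$surface, config$seeding$density,
                               rng_seed = rep_seed, volume = volume)
    lengths <- if (lm$mode == "fixed")
      assign_lengths(seeds, "fixed", c = lm$c)
    else
      assign_lengths(seeds, "weibull_survival", model = lm$model,
                     rng_seed = rep_seed)
    gc_rep <- config$growth
    gc_rep$rng_seed <- as.integer(rep_seed %% 2147483647)
    res <- list(seeds = seeds, lengths = lengths)
    if (!is.null(volume)) {
      res$paths <- grow_population(seeds, lengths, volume, gc_rep)
      res$profile <- length_profile(res$paths, ss$dref, volume,
                                    shell_width = config$shell_width)
    }
    if (config$run_control || is.null(volume)) {
      res$control_paths <- grow_population(seeds, lengths, NULL, gc_rep)
      ctl_tot <- length_profile(res$control_paths, ss$dref, NULL,
                                shell_width = config$shell_width)
      res$control_profile <- control_wet_approximation(ctl_tot, j_ctl)
    }
    reps[[r]] <- res
    if (!is.null(out_dir)) {
      tag <- sprintf("rep%02d", r)
      write_seeds_csv(seeds, file.path(out_dir, paste0(tag, "_seeds.csv")))
      write_lengths_csv(lengths,
                        file.path(out_dir, paste0(tag, "_lengths.csv")))
      if (!is.null(res$paths)) {
        write_paths_csv(res$paths,
                        file.path(out_dir, paste0(tag, "_paths.csv")))
        write_paths_vtk(res$paths,
                        file.path(out_dir, paste0(tag, "_paths.vtk")))
        write_profile_csv(res$profile,
                          file.path(out_dir, paste0(tag, "_profile.csv")))
      }
      if (!is.null(res$control_profile))
        write_profile_csv(res$control_profile,
                          file.path(out_dir,
                                    paste0(tag, "_control_profile.csv")))
    }
  }

  out <- list(volume = volume, surface = ss$surface, dref = ss$dref,
              replicates = reps, j = j_ctl)
  explicit_profiles <- Filter(Negate(is.null),
                              lapply(reps, `[[`, "profile"))
  control_profiles <- Filter(Negate(is.null),
                             lapply(reps, `[[`, "control_profile"))
  if (length(explicit_profiles) >= 2)
    out$summary <- replicate_statistics(explicit_profiles)
  if (length(explicit_profiles) && length(control_profiles) &&
      sum(vapply(control_profiles, function(p) sum(p$L_wet),
                 numeric(1))) > 0)
    out$elevation <- elevation_percent(explicit_profiles, control_profiles)

  if (!is.null(out_dir)) {
    prov <- list(package_version = as.character(utils::packageVersion("rhizohair")),
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 config = config_as_list(config))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    if (!is.null(out$summary)) {
      smry <- data.frame(shell_lower_um = out$summary$shell_edges[-length(out$summary$shell_edges)],
                         shell_upper_um = out$summary$shell_edges[-1],
                         mean_L_tot = out$summary$mean_tot,
                         sd_L_tot = out$summary$sd_tot,
                         mean_L_wet = out$summary$mean_wet,
                         sd_L_wet = out$summary$sd_wet)
      write.csv(smry, file.path(out_dir, "summary_profile.csv"),
                row.names = FALSE)
    }
  }
  invisible(out)
}

config_as_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Sweep one growth parameter over a set of values
#'
#' Runs one scenario per value of `step_length`, `fan_size` or
#' `bin_count`, and tabulates total grown length, total wet length and
#' mean tortuosity against the parameter.
#'
#' @param parameter `"step_length"`, `"fan_size"` or `"bin_count"`.
#' @param values numeric vector of parameter values (non-empty).
#' @param base a [scenario_config()] providing all other settings.
#' @return `data.frame` with one row per value.
#' @export
sweep_parameter <- function(parameter, values, base) {
  if (!parameter %in% c("step_length", "fan_size", "bin_count"))
    stop("config error: unknown sweep parameter '", parameter, "'")
  if (!length(values)) stop("config error: empty sweep value list")
  rows <- lapply(values, function(v) {
    cfg <- base
    cfg$growth[[parameter]] <- v
    cfg$output_dir <- NULL
    res <- run_scenario(cfg)
    paths <- unlist(lapply(res$replicates, function(r)
      r$paths %||% r$control_paths), recursive = FALSE)
    profs <- Filter(Negate(is.null), lapply(res$replicates, function(r)
      r$profile %||% r$control_profile))
    tort <- vapply(paths, tortuosity, numeric(1))
    data.frame(parameter = parameter, value = v,
               total_length_um = sum(vapply(paths, function(h)
                 h$achieved_length, numeric(1))),
               wet_length_um = sum(vapply(profs, function(p)
                 sum(p$L_wet), numeric(1))),
               mean_tortuosity = mean(tort, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
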