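#' Write a phase volume to NRRD
#'
#' Volumes are stored as NRRD (uint8) with the voxel size in the `spacings`
#' field and rhizohair metadata (`voxel_size_um`, `origin_um`,
#' `geometry_kind`, `labels`) as NRRD key-value pairs. The label dialect is
#' fixed: pore=0, textural=1, mineral=2, root=3, outside=255. Encoding
#' `"ascii"` produces a plain-text file; `"raw"` is little-endian uint8.
#'
#' @param volume a [phase_volume()].
#' @param path output path (conventionally `.nrrd`).
#' @param encoding `"ascii"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, encoding = c("ascii", "raw")) {
  encoding <- match.arg(encoding)
  d <- dim(volume$labels)
  labjson <- jsonlite::toJSON(as.list(PHASE_LABELS), auto_unbox = TRUE)
  hdr <- c(
    "NRRD0004",
    "# rhizohair labelled phase volume",
    "type: uint8",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.10g %.10g %.10g", volume$voxel_size,
            volume$voxel_size, volume$voxel_size),
    sprintf("encoding: %s", encoding),
    "endian: little",
    sprintf("voxel_size_um:=%.10g", volume$voxel_size),
    sprintf("origin_um:=%.10g %.10g %.10g", volume$origin[1],
            volume$origin[2], volume$origin[3]),
    sprintf("geometry_kind:=%s", volume$geometry_kind),
    sprintf("labels:=%s", as.character(labjson)),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "ascii") {
    writeLines(paste(as.vector(volume$labels), collapse = " "), con)
  } else {
    writeBin(as.raw(as.vector(volume$labels)), con)
  }
  invisible(path)
}

#' Read a phase volume from NRRD
#'
#' Reads files written by [write_volume()] (or any 3D uint8/int NRRD with
#' ascii or raw encoding whose values use the rhizohair label dialect).
#' Files with labels outside the dialect, or without voxel-size metadata,
#' are rejected.
#'
#' @param path NRRD path.
#' @return A [phase_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list(); kv <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    if (grepl("^#", ln)) next
    if (grepl(":=", ln)) {
      p <- regmatches(ln, regexpr(":=", ln), invert = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    } else if (grepl(": ", ln)) {
      p <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
      fields[[tolower(p[1])]] <- p[2]
    }
  }
  if (is.null(fields$sizes)) stop("NRRD header missing 'sizes'")
  d <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(d) != 3) stop("expected a 3D volume, got sizes: ", fields$sizes)
  n <- prod(d)
  enc <- tolower(fields$encoding %||% "raw")
  vals <- if (enc %in% c("ascii", "text", "txt")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    as.integer(readBin(con, "raw", n = n))
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)

  vs <- if (!is.null(kv$voxel_size_um)) as.numeric(kv$voxel_size_um)
        else if (!is.null(fields$spacings))
          as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]][1])
        else NA_real_
  if (is.na(vs))
    stop("volume has no voxel-size metadata (spacings or voxel_size_um)")
  origin <- if (!is.null(kv$origin_um))
    as.numeric(strsplit(trimws(kv$origin_um), "\\s+")[[1]])
  else rep(vs / 2, 3)
  gk <- kv$geometry_kind %||% "cartesian"
  bad <- setdiff(unique(vals), unname(PHASE_LABELS))
  if (length(bad))
    stop("file contains undefined labels: ", paste(sort(bad), collapse = ", "))
  phase_volume(array(vals, dim = d), vs, origin, gk)
}

#' Write a distance map to NRRD
#' @param dmap a `distance_map`.
#' @param path output path.
#' @export
write_distance_nrrd <- function(dmap, path) {
  d <- dim(dmap$distances)
  hdr <- c("NRRD0004", "type: double", "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.10g %.10g %.10g", dmap$voxel_size,
                   dmap$voxel_size, dmap$voxel_size),
           "encoding: ascii", "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeLines(paste(format(as.vector(dmap$distances), digits = 10),
                   collapse = " "), con)
  invisible(path)
}

#' Write hair seeds to CSV
#' @param seeds list of hair seeds (see [sample_transition_points()]).
#' @param path output path.
#' @export
write_seeds_csv <- function(seeds, path) {
  df <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    s <- seeds[[i]]
    I <- s$initiation_point %||% c(NA, NA, NA)
    data.frame(hair_id = i, Ix = I[1], Iy = I[2], Iz = I[3],
               Tx = s$transition_point[1], Ty = s$transition_point[2],
               Tz = s$transition_point[3],
               hx = s$heading[1], hy = s$heading[2], hz = s$heading[3],
               l_r_um = s$visible_length)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read hair seeds from CSV
#' @param path CSV written by [write_seeds_csv()].
#' @return List of hair seeds.
#' @export
read_seeds_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    I <- c(df$Ix[i], df$Iy[i], df$Iz[i])
    hair_seed(transition_point = c(df$Tx[i], df$Ty[i], df$Tz[i]),
              heading = c(df$hx[i], df$hy[i], df$hz[i]),
              visible_length = df$l_r_um[i],
              initiation_point = if (all(is.finite(I))) I else NULL)
  })
}

#' Write assigned lengths to CSV
#' @param assignment a length assignment (see [assign_lengths()]).
#' @param path output path.
#' @export
write_lengths_csv <- function(assignment, path) {
  df <- data.frame(hair_id = seq_along(assignment$l_tot),
                   l_tot_um = assignment$l_tot, l_v_um = assignment$l_v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write hair paths to CSV
#'
#' One row per path vertex: `hair_id, vertex_index, x_um, y_um, z_um,
#' phase_label, terminated_reason`.
#'
#' @param paths list of [grow_hair()] results.
#' @param path output path.
#' @export
write_paths_csv <- function(paths, path) {
  df <- do.call(rbind, lapply(paths, function(h) {
    nv <- nrow(h$vertices)
    data.frame(hair_id = h$hair_id, vertex_index = seq_len(nv),
               x_um = h$vertices[, 1], y_um = h$vertices[, 2],
               z_um = h$vertices[, 3], phase_label = h$phase,
               terminated_reason = h$terminated_reason %||% "")
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write hair paths as VTK legacy polydata
#'
#' One polyline per hair, suitable for 3D rendering of grown populations.
#'
#' @param paths list of [grow_hair()] results.
#' @param path output path (conventionally `.vtk`).
#' @export
write_paths_vtk <- function(paths, path) {
  verts <- do.call(rbind, lapply(paths, function(h) h$vertices))
  counts <- vapply(paths, function(h) nrow(h$vertices), integer(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rhizohair paths", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(verts))), con)
  writeLines(apply(verts, 1, function(p)
    sprintf("%.6g %.6g %.6g", p[1], p[2], p[3])), con)
  writeLines(sprintf("LINES %d %d", length(counts),
                     length(counts) + sum(counts)), con)
  off <- 0L
  for (i in seq_along(counts)) {
    writeLines(paste(c(counts[i], off + seq_len(counts[i]) - 1L),
                     collapse = " "), con)
    off <- off + counts[i]
  }
  invisible(path)
}

#' Write a length profile to CSV
#' @param profile a [length_profile()] result.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(shell_lower_um = profile$shell_edges[-length(profile$shell_edges)],
                   shell_upper_um = profile$shell_edges[-1],
                   L_tot_um = profile$L_tot, L_wet_um = profile$L_wet)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read measured hair lengths from a single-column CSV
#' @param path CSV whose first column holds lengths in um.
#' @return Numeric vector.
#' @export
read_measured_lengths <- function(path) {
  df <- read.csv(path)
  as.numeric(df[[1]])
}
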