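# Trajectory file formats. Two dialects of extended XYZ are written:
#   "xyz"      - interoperable extended XYZ, positions/velocities to 6
#                decimals, readable by standard visualization tools;
#   "archival" - same layout with %.17g fields, which round-trips IEEE
#                doubles exactly and serves for velocity-exact restarts.

.fmt_num <- function(x, archival) {
  if (archival) sprintf("%.17g", x) else sprintf("%.6f", x)
}

.frame_comment <- function(f, traj, archival) {
  lat <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                 .fmt_num(f$box[1], archival), .fmt_num(f$box[2], archival),
                 .fmt_num(f$box[3], archival))
  props <- "Properties=species:S:1:pos:R:3:vel:R:3:mol:I:1:frozen:I:1"
  extra <- sprintf("Time=%s Format=dpdcnt-%s-1 NLipids=%d",
                   .fmt_num(f$time, archival),
                   if (archival) "archival" else "xyz", traj$n_lipids)
  tube <- if (!is.null(traj$tube))
    sprintf(' Tube="%s %s %s %s %s"',
            .fmt_num(traj$tube$radius, archival),
            .fmt_num(traj$tube$length, archival),
            .fmt_num(traj$tube$center[1], archival),
            .fmt_num(traj$tube$center[2], archival),
            .fmt_num(traj$tube$center[3], archival)) else ""
  paste0(lat, " ", props, " ", extra, tube)
}

#' Write a trajectory to disk
#'
#' @param traj A `dpd_trajectory` (or a single `dpd_config`, written as
#'   a one-frame trajectory).
#' @param path Output file path.
#' @param format `"xyz"` (interoperable extended XYZ, 6 decimals) or
#'   `"archival"` (full-precision text; bit-exact round-trip).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "archival")) {
  format <- match.arg(format)
  archival <- format == "archival"
  if (inherits(traj, "dpd_config")) {
    cfg <- traj
    traj <- list(frames = list(list(pos = cfg$pos, vel = cfg$vel,
                                    box = cfg$box, time = 0, step = 0)),
                 type = cfg$type, mol_id = cfg$mol_id, frozen = cfg$frozen,
                 tube = cfg$tube, n_lipids = cfg$n_lipids)
    class(traj) <- "dpd_trajectory"
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    n <- nrow(f$pos)
    writeLines(as.character(n), con)
    writeLines(.frame_comment(f, traj, archival), con)
    if (n > 0) {
      lines <- paste(traj$type,
                     .fmt_num(f$pos[, 1], archival), .fmt_num(f$pos[, 2], archival),
                     .fmt_num(f$pos[, 3], archival),
                     .fmt_num(f$vel[, 1], archival), .fmt_num(f$vel[, 2], archival),
                     .fmt_num(f$vel[, 3], archival),
                     traj$mol_id, as.integer(traj$frozen))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

.parse_comment <- function(line) {
  out <- list()
  m <- regmatches(line, regexec('Lattice="([^"]+)"', line))[[1]]
  if (length(m) == 2) {
    lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
    if (length(lat) == 9) out$box <- lat[c(1, 5, 9)]
    else if (length(lat) == 3) out$box <- lat
  }
  m <- regmatches(line, regexec("Time=([-0-9.eE+]+)", line))[[1]]
  if (length(m) == 2) out$time <- as.numeric(m[2])
  m <- regmatches(line, regexec("NLipids=([0-9]+)", line))[[1]]
  if (length(m) == 2) out$n_lipids <- as.integer(m[2])
  m <- regmatches(line, regexec('Tube="([^"]+)"', line))[[1]]
  if (length(m) == 2) out$tube <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  m <- regmatches(line, regexec("Properties=([^ ]+)", line))[[1]]
  if (length(m) == 2) out$properties <- m[2]
  out
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Validates bead-count consistency across frames and positive box
#' lengths; malformed or truncated frames are rejected with the frame
#' number and file line. Foreign extended-XYZ files without molecule ids
#' load with every bead as its own molecule (and zero velocities when
#' absent), with a warning.
#'
#' @param path File path.
#' @return A `dpd_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  meta <- NULL
  i <- 1L
  frame_no <- 0L
  n_ref <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0)
      stop("frame ", frame_no, " (line ", i, "): invalid bead count '",
           lines[i], "'")
    if (!is.na(n_ref) && n != n_ref)
      stop("frame ", frame_no, " (line ", i, "): bead count ", n,
           " differs from first frame (", n_ref, ")")
    n_ref <- n
    if (i + 1L > length(lines))
      stop("frame ", frame_no, ": truncated (missing comment line)")
    cm <- .parse_comment(lines[i + 1L])
    if (is.null(cm$box) || any(!is.finite(cm$box)) || any(cm$box <= 0))
      stop("frame ", frame_no, " (line ", i + 1L, "): missing or invalid box")
    if (i + 1L + n > length(lines))
      stop("frame ", frame_no, ": truncated (expected ", n,
           " atom lines after line ", i + 1L, ")")
    if (n == 0) {
      frames[[frame_no]] <- list(pos = matrix(numeric(0), 0, 3),
                                 vel = matrix(numeric(0), 0, 3),
                                 box = cm$box,
                                 time = if (!is.null(cm$time)) cm$time else 0,
                                 step = frame_no - 1L)
      if (frame_no == 1)
        meta <- list(type = character(0), mol_id = integer(0),
                     frozen = logical(0), n_lipids = 0L, tube = NULL)
      i <- i + 2L
      next
    }
    atom <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    ncol_atom <- unique(lengths(atom))
    if (length(ncol_atom) != 1)
      stop("frame ", frame_no, ": inconsistent atom-line field counts")
    am <- do.call(rbind, atom)
    species <- am[, 1]
    num <- suppressWarnings(apply(am[, -1, drop = FALSE], 2, as.numeric))
    if (n == 1) num <- matrix(num, nrow = 1)
    if (any(is.na(num[, 1:3])))
      stop("frame ", frame_no, ": non-numeric positions")
    pos <- num[, 1:3, drop = FALSE]
    has_vel <- ncol(num) >= 6
    vel <- if (has_vel) num[, 4:6, drop = FALSE] else matrix(0, n, 3)
    has_mol <- ncol(num) >= 8
    if (frame_no == 1) {
      if (has_mol) {
        mol <- as.integer(num[, 7])
        frozen <- num[, 8] != 0
      } else {
        warning("no molecule ids in '", basename(path),
                "'; inferring singleton molecules")
        mol <- seq_len(n)
        frozen <- rep(FALSE, n)
      }
      meta <- list(type = species, mol_id = mol, frozen = frozen,
                   n_lipids = if (!is.null(cm$n_lipids)) cm$n_lipids else 0L,
                   tube = if (!is.null(cm$tube))
                     list(radius = cm$tube[1], length = cm$tube[2],
                          center = cm$tube[3:5]) else NULL)
    }
    frames[[frame_no]] <- list(pos = pos, vel = vel, box = cm$box,
                               time = if (!is.null(cm$time)) cm$time else
                                 frame_no - 1, step = frame_no - 1L)
    i <- i + 2L + n
  }
  if (frame_no == 0)
    return(structure(list(frames = list(), type = character(0),
                          mol_id = integer(0), frozen = logical(0),
                          tube = NULL, n_lipids = 0L),
                     class = "dpd_trajectory"))
  structure(c(list(frames = frames), meta), class = "dpd_trajectory")
}

#' Serialize or load a system specification
#'
#' @param spec A [system_spec()].
#' @param path YAML file path.
#' @return `write_system_spec()` returns `path` invisibly;
#'   `read_system_spec()` returns a `dpd_system_spec`.
#' @export
write_system_spec <- function(spec, path) {
  stopifnot(inherits(spec, "dpd_system_spec"))
  doc <- list(schema = "dpdcnt-system/1",
              chirality = if (is.null(spec$substrate)) NULL else
                spec$substrate$chirality[1],
              tube_length = if (is.null(spec$substrate)) NULL else
                spec$substrate$length,
              n_lipids = spec$n_lipids, n_water_beads = spec$n_water_beads,
              Ly = spec$Ly, seed = spec$seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_system_spec
#' @export
read_system_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "dpdcnt-system/1"))
    stop("unrecognized system-spec schema")
  sub <- if (is.null(doc$chirality)) NULL else
    nanotube_spec(doc$chirality,
                  length = if (is.null(doc$tube_length)) 15.5 else doc$tube_length)
  system_spec(substrate = sub, n_lipids = doc$n_lipids,
              n_water_beads = doc$n_water_beads, Ly = doc$Ly, seed = doc$seed)
}

#' Export an observable as CSV with a metadata header
#'
#' Writes `# key: value` comment lines (observable class, cutoffs, bins,
#' seed where known) followed by a plain CSV table.
#'
#' @param x An observable object (adsorption series, density profile,
#'   orientation histogram, cluster report or saturation estimate).
#' @param path Output path.
#' @param meta Named list of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_observable <- function(x, path, meta = list()) {
  df <- as.data.frame(x)
  hdr <- c(paste0("# class: ", class(x)[1]),
           vapply(names(meta), function(k)
             paste0("# ", k, ": ", meta[[k]]), character(1)))
  for (fld in c("cutoff", "linkage_cutoff", "n_lipids", "per_lipid_rule")) {
    if (!is.null(x[[fld]]))
      hdr <- c(hdr, paste0("# ", fld, ": ", x[[fld]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.adsorption_series <- function(x, ...) {
  data.frame(time = x$times, fraction_adsorbed = x$fraction_adsorbed,
             fraction_outer = x$fraction_outer,
             fraction_inner = x$fraction_inner, n_adsorbed = x$n_adsorbed)
}

#' @export
as.data.frame.density_profile <- function(x, ...) {
  data.frame(d_lo = x$bin_edges[-length(x$bin_edges)],
             d_hi = x$bin_edges[-1], density = x$density,
             shell_volume = x$shell_volume)
}

#' @export
as.data.frame.orientation_histogram <- function(x, ...) {
  data.frame(theta_lo = x$theta_edges[-length(x$theta_edges)],
             theta_hi = x$theta_edges[-1], probability = x$probability,
             count = x$counts)
}

#' @export
as.data.frame.cluster_report <- function(x, ...) {
  data.frame(cluster = seq_along(x$cluster_sizes), size = x$cluster_sizes)
}

#' @export
as.data.frame.saturation_estimate <- function(x, ...) {
  data.frame(rho_s = x$rho_s, rho_s_inner = x$rho_s_inner,
             n_outer = x$n_outer,
             eq_frame_lo = x$equilibration_window[1],
             eq_frame_hi = x$equilibration_window[2])
}

#' Write a run manifest
#'
#' Every pipeline artifact references a manifest that makes it
#' reproducible: system specification, integrator and barostat settings,
#' package version, seed, timestamp, and output paths.
#'
#' @param path Output YAML path.
#' @param spec A [system_spec()].
#' @param settings An [integrator_settings()] (optional).
#' @param barostat A [barostat_settings()] (optional).
#' @param outputs Character vector of artifact paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, spec, settings = NULL, barostat = NULL,
                           outputs = character(0)) {
  doc <- list(
    schema = "dpdcnt-manifest/1",
    package_version = as.character(utils::packageVersion("dpdcnt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    spec = list(chirality = if (is.null(spec$substrate)) NULL else
                  spec$substrate$chirality[1],
                tube_length = if (is.null(spec$substrate)) NULL else
                  spec$substrate$length,
                n_lipids = spec$n_lipids, n_water_beads = spec$n_water_beads,
                Ly = spec$Ly, seed = spec$seed),
    settings = if (is.null(settings)) NULL else unclass(settings),
    barostat = if (is.null(barostat)) NULL else unclass(barostat),
    outputs = as.list(outputs))
  yaml::write_yaml(doc, path)
  invisible(path)
}
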