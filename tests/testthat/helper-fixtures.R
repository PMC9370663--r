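# Geometric fixtures built in code: hand-placed lipids and synthetic
# trajectories that exercise the analysis stage without running dynamics.

# a straight 12-bead lipid rod starting at `anchor`, pointing along `dir`
# (bead order matches the package layout: head beads 1-4, chains 5-8, 9-12)
lipid_rod <- function(anchor, dir, spacing = 0.35) {
  dir <- dir / sqrt(sum(dir^2))
  t(vapply(0:11, function(k) anchor + k * spacing * dir, numeric(3)))
}

# assemble a dpd_trajectory by hand from a list of frames, each frame a
# list of 12x3 lipid bead matrices; a synthetic two-bead "tube" provides
# the frozen beads whose mean defines the axis position
synthetic_traj <- function(frames_lipids, box, tube = NULL, times = NULL) {
  n_lipids <- length(frames_lipids[[1]])
  cnt_pos <- NULL
  if (!is.null(tube)) {
    cnt_pos <- rbind(tube$center + c(tube$radius, 0, 0),
                     tube$center - c(tube$radius, 0, 0))
  }
  n_cnt <- if (is.null(cnt_pos)) 0L else nrow(cnt_pos)
  type <- c(rep("cnt", n_cnt),
            rep(c("h1", "h2", "h3", "h3", rep("t", 8)), n_lipids))
  mol_id <- c(rep(0L, n_cnt), rep(seq_len(n_lipids), each = 12L))
  frozen <- type == "cnt"
  if (is.null(times)) times <- seq_along(frames_lipids) - 1
  frames <- lapply(seq_along(frames_lipids), function(k) {
    pos <- do.call(rbind, frames_lipids[[k]])
    if (!is.null(cnt_pos)) pos <- rbind(cnt_pos, pos)
    pos <- sweep(pos, 2, box, function(x, L) x - L * floor(x / L))
    list(pos = pos, vel = matrix(0, nrow(pos), 3), box = box,
         time = times[k], step = k - 1L)
  })
  structure(list(frames = frames, type = type, type_id = match(type, c("h1", "h2", "h3", "t", "w", "cnt")),
                 mol_id = mol_id, frozen = frozen, tube = tube,
                 n_lipids = n_lipids),
            class = "dpd_trajectory")
}

# place n lipids as radial rods on the outer tube surface, evenly spread
# over angle and axial position, tails pointing outward from radius r0
radial_rods_on_tube <- function(n, tube, r0 = 0.2, spacing = 0.25) {
  lapply(seq_len(n), function(i) {
    phi <- 2 * pi * (i - 1) / n
    y <- tube$center[2] + (i %% 5 - 2) * tube$length / 6
    e <- c(cos(phi), 0, sin(phi))
    anchor <- tube$center * c(1, 0, 1) + c(0, y, 0) + (tube$radius + r0) * e
    # head outermost, tails toward the surface: rod points inward
    lipid_rod(anchor + 11 * spacing * e, -e, spacing)
  })
}

# water-only configuration at reduced density 3 in a cubic box
water_config <- function(n_beads, seed = 1) {
  build_system(system_spec(NULL, n_lipids = 0, n_water_beads = n_beads,
                           Ly = (n_beads / 3)^(1 / 3), seed = seed))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# exhaustive O(N^2) minimum-image neighbor enumeration
brute_pairs <- function(pos, box, rc) {
  n <- nrow(pos)
  out <- NULL
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    r2 <- rowSums(d^2)
    hit <- which(r2 < rc^2)
    if (length(hit)) out <- rbind(out, cbind(i, i + hit))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else unname(out)
}

# canonical form of a pair list for comparison
sort_pairs <- function(m) {
  if (nrow(m) == 0) return(m)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
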