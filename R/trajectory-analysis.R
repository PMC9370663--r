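# Observables computed from trajectories: adsorption kinetics, aggregate
# clustering, cylindrical density profiles, tail-orientation order, and
# saturation surface density. All distances are measured to the cylinder
# of nanotube bead centers.

.minimg <- function(d, L) d - L * round(d / L)

# tube geometry for one frame: the frozen beads define the axis position
.tube_frame <- function(traj, frame) {
  if (is.null(traj$tube)) stop("trajectory has no nanotube substrate")
  f <- traj$frames[[frame]]
  fro <- traj$frozen
  list(center = c(mean(f$pos[fro, 1]), mean(f$pos[fro, 2]), mean(f$pos[fro, 3])),
       radius = traj$tube$radius, length = traj$tube$length, box = f$box)
}

#' Signed distance from the nanotube surface
#'
#' For beads within the tube's axial extent the distance is the radial
#' distance from the axis minus the bead-center radius; the sign is
#' retained (negative = inside the tube). Beads beyond the tube ends use
#' the (positive) distance to the nearest rim circle. The tube axis runs
#' along y.
#'
#' @param pos n x 3 matrix (or length-3 vector) of wrapped positions.
#' @param tube List with `center` (x, y, z), `radius` (bead-center
#'   radius) and `length` (axial extent), as built by [build_cnt()].
#' @param box Periodic box lengths.
#' @return Numeric vector of signed distances in \eqn{r_C}.
#' @export
surface_distance <- function(pos, tube, box) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  dx <- .minimg(pos[, 1] - tube$center[1], box[1])
  dy <- .minimg(pos[, 2] - tube$center[2], box[2])
  dz <- .minimg(pos[, 3] - tube$center[3], box[3])
  radial <- sqrt(dx^2 + dz^2)
  inside_extent <- abs(dy) <= tube$length / 2
  d <- radial - tube$radius
  over <- abs(dy) - tube$length / 2
  d[!inside_extent] <- sqrt((radial[!inside_extent] - tube$radius)^2 +
                            over[!inside_extent]^2)
  d
}

# per-lipid signed distance of the closest bead, one frame
.lipid_min_distance <- function(traj, frame) {
  tf <- .tube_frame(traj, frame)
  f <- traj$frames[[frame]]
  lip <- traj$mol_id >= 1 & traj$mol_id <= traj$n_lipids & !traj$frozen &
    traj$type != "w"
  d <- surface_distance(f$pos[lip, , drop = FALSE], tf, tf$box)
  mol <- traj$mol_id[lip]
  absmin <- tapply(abs(d), mol, min)
  signmin <- tapply(d, mol, function(v) v[which.min(abs(v))])
  list(abs = as.numeric(absmin), signed = as.numeric(signmin),
       mol = as.integer(names(absmin)))
}

#' Fraction of lipids adsorbed on the tube surface
#'
#' A lipid counts as adsorbed in a frame if at least one of its twelve
#' beads lies within `cutoff` of the tube surface (absolute distance, so
#' inner- and outer-surface contacts both count; they are also reported
#' separately).
#'
#' @param traj A `dpd_trajectory` containing lipids and a tube.
#' @param cutoff Adsorption distance in \eqn{r_C} (default 1.06).
#' @return Object of class `adsorption_series`: list with `times`,
#'   `fraction_adsorbed`, `fraction_outer`, `fraction_inner`,
#'   `n_adsorbed`, `cutoff`, `n_lipids`.
#' @export
adsorbed_fraction <- function(traj, cutoff = 1.06) {
  if (traj$n_lipids == 0) stop("trajectory contains no lipids")
  nf <- length(traj$frames)
  frac <- outer_f <- inner_f <- nads <- numeric(nf)
  times <- vapply(traj$frames, function(f) f$time, numeric(1))
  for (k in seq_len(nf)) {
    md <- .lipid_min_distance(traj, k)
    ads <- md$abs <= cutoff
    frac[k] <- mean(ads)
    outer_f[k] <- mean(ads & md$signed >= 0)
    inner_f[k] <- mean(ads & md$signed < 0)
    nads[k] <- sum(ads)
  }
  structure(list(times = times, fraction_adsorbed = frac,
                 fraction_outer = outer_f, fraction_inner = inner_f,
                 n_adsorbed = nads, cutoff = cutoff,
                 n_lipids = traj$n_lipids),
            class = "adsorption_series")
}

#' Lipid aggregate clustering by tail contact
#'
#' Two lipids join the same aggregate when any pair of their tail beads
#' is closer than `linkage_cutoff`. Aggregates are the connected
#' components of that contact graph, found by union-find; singleton
#' lipids count as clusters of size one, so the sizes always sum to the
#' lipid count.
#'
#' @param traj A `dpd_trajectory`.
#' @param frame Frame index.
#' @param linkage_cutoff Tail-bead contact distance (default 1.0 rC).
#' @return Object of class `cluster_report`: list with `frame`,
#'   `cluster_sizes` (sorted decreasing), `membership` (per lipid),
#'   `linkage_cutoff`.
#' @export
cluster_lipids <- function(traj, frame = length(traj$frames),
                           linkage_cutoff = 1.0) {
  f <- traj$frames[[frame]]
  tail_idx <- which(traj$type == "t")
  nl <- traj$n_lipids
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (length(tail_idx) > 1) {
    pr <- .cell_pairs_cpp(f$pos[tail_idx, , drop = FALSE], f$box, linkage_cutoff)
    if (nrow(pr)) {
      m1 <- traj$mol_id[tail_idx[pr[, 1]]]
      m2 <- traj$mol_id[tail_idx[pr[, 2]]]
      keep <- m1 != m2
      for (e in which(keep)) {
        r1 <- find(m1[e]); r2 <- find(m2[e])
        if (r1 != r2) parent[r1] <- r2
      }
    }
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  membership <- match(roots, unique(roots))
  structure(list(frame = frame,
                 cluster_sizes = sort(as.integer(table(membership)),
                                      decreasing = TRUE),
                 membership = membership,
                 linkage_cutoff = linkage_cutoff),
            class = "cluster_report")
}

#' Count lipids free in solution
#'
#' A lipid is free when it is neither adsorbed on the tube nor a member
#' of an aggregate touching the tube. This is the series whose plateau
#' (near zero at the studied concentrations) defines equilibration.
#'
#' @param traj A `dpd_trajectory`.
#' @param cutoff Adsorption distance (rC).
#' @param linkage_cutoff Aggregate contact distance (rC).
#' @return Integer vector, one free-lipid count per frame.
#' @export
free_lipid_count <- function(traj, cutoff = 1.06, linkage_cutoff = 1.0) {
  nf <- length(traj$frames)
  out <- integer(nf)
  for (k in seq_len(nf)) {
    md <- .lipid_min_distance(traj, k)
    ads <- md$mol[md$abs <= cutoff]
    cl <- cluster_lipids(traj, k, linkage_cutoff)
    attached <- unique(cl$membership[ads])
    out[k] <- sum(!(cl$membership %in% attached))
  }
  out
}

#' Cylindrical number-density profile around the tube
#'
#' Histogram of surface distance for the selected beads, restricted to
#' the tube's axial extent, normalized by the cylindrical-shell volume
#' of each bin and by the frame count, giving a number density in
#' \eqn{r_C^{-3}}.
#'
#' @param traj A `dpd_trajectory`.
#' @param selection Bead selection: a character vector of bead type
#'   names (default the four lipid types) or an integer index vector.
#' @param bin_width Bin width in \eqn{r_C} (default 0.1).
#' @param d_max Largest distance profiled (default 5 rC).
#' @param frames Frame indices to average over (default all).
#' @return Object of class `density_profile`: list with `bin_edges`,
#'   `density`, `shell_volume`, `mean_count`, `n_frames`.
#' @export
radial_density_profile <- function(traj, selection = c("h1", "h2", "h3", "t"),
                                   bin_width = 0.1, d_max = 5,
                                   frames = seq_along(traj$frames)) {
  if (bin_width <= 0) stop("bin width must be positive")
  sel <- if (is.character(selection)) which(traj$type %in% selection)
         else as.integer(selection)
  if (!length(sel)) stop("empty bead selection")
  tf0 <- .tube_frame(traj, frames[1])
  edges <- seq(-tf0$radius, d_max, by = bin_width)
  counts <- numeric(length(edges) - 1)
  for (k in frames) {
    tf <- .tube_frame(traj, k)
    f <- traj$frames[[k]]
    dy <- .minimg(f$pos[sel, 2] - tf$center[2], f$box[2])
    inside <- abs(dy) <= tf$length / 2
    d <- surface_distance(f$pos[sel[inside], , drop = FALSE], tf, f$box)
    d <- d[d >= edges[1] & d < edges[length(edges)]]
    counts <- counts + tabulate(findInterval(d, edges), length(edges) - 1)
  }
  shell <- pi * ((tf0$radius + edges[-1])^2 -
                 (tf0$radius + edges[-length(edges)])^2) * tf0$length
  structure(list(bin_edges = edges,
                 density = counts / (length(frames) * shell),
                 shell_volume = shell,
                 mean_count = sum(counts) / length(frames),
                 n_frames = length(frames)),
            class = "density_profile")
}

# per-lipid orientation angles (degrees in [0, 90]) for one frame;
# optionally restricted to adsorbed lipids
.lipid_orientation_frame <- function(traj, frame, adsorbed_only = TRUE,
                                     cutoff = 1.06) {
  tf <- .tube_frame(traj, frame)
  f <- traj$frames[[frame]]
  nl <- traj$n_lipids
  keep <- seq_len(nl)
  if (adsorbed_only) {
    md <- .lipid_min_distance(traj, frame)
    keep <- md$mol[md$abs <= cutoff]
  }
  if (!length(keep)) return(numeric(0))
  n_cnt <- sum(traj$frozen)
  ang <- vapply(keep, function(m) {
    o <- n_cnt + 12L * (m - 1L)
    chain_angle <- function(first, last) {
      v <- .minimg(f$pos[o + last, ] - f$pos[o + first, ], f$box)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("degenerate zero-length tail vector (lipid ", m, ")")
      mid <- f$pos[o + first, ] + v / 2
      radial <- c(.minimg(mid[1] - tf$center[1], f$box[1]), 0,
                  .minimg(mid[3] - tf$center[3], f$box[3]))
      nr <- sqrt(sum(radial^2))
      if (nr < 1e-12) return(90)  # on-axis midpoint: tangent by convention
      acos(min(1, abs(sum(v * radial)) / (nv * nr))) * 180 / pi
    }
    # tail 1 = beads 5..8, tail 2 = beads 9..12 of the lipid
    (chain_angle(5L, 8L) + chain_angle(9L, 12L)) / 2
  }, numeric(1))
  ang
}

#' Orientation distribution of adsorbed lipid tails
#'
#' For each hydrocarbon chain the tail vector runs from the first tail
#' bead (bonded to the glycerol bead) to the terminal tail bead; the
#' reference is the outward radial unit vector of the tube at the chain
#' midpoint. The angle is folded into \[0, 90\] degrees (0 = radial,
#' i.e. perpendicular to the surface; 90 = tangent) and the two chains
#' of each lipid are averaged. The histogram is reported as a plain
#' normalized frequency over angle bins (no solid-angle correction), so
#' an isotropic sample follows the sine baseline.
#'
#' @param traj A `dpd_trajectory`.
#' @param frames Frame indices pooled into the histogram.
#' @param bin_width Bin width in degrees (default 5).
#' @param adsorbed_only Restrict to adsorbed lipids (default `TRUE`).
#' @param cutoff Adsorption cutoff used for that restriction.
#' @return Object of class `orientation_histogram`: list with
#'   `theta_edges`, `probability` (density per degree, integrating to
#'   1), `counts`, `n`, `per_lipid_rule`.
#' @export
orientation_distribution <- function(traj, frames = seq_along(traj$frames),
                                     bin_width = 5, adsorbed_only = TRUE,
                                     cutoff = 1.06) {
  if (bin_width <= 0) stop("bin width must be positive")
  ang <- unlist(lapply(frames, .lipid_orientation_frame, traj = traj,
                       adsorbed_only = adsorbed_only, cutoff = cutoff))
  edges <- seq(0, 90, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  counts <- tabulate(findInterval(pmin(ang, 90 - 1e-12), edges),
                     length(edges) - 1)
  widths <- diff(edges)
  prob <- if (sum(counts) > 0) counts / sum(counts) / widths else counts * 0
  structure(list(theta_edges = edges, probability = prob, counts = counts,
                 n = sum(counts), per_lipid_rule = "mean of the two chain angles"),
            class = "orientation_histogram")
}

#' Detect equilibration of a time series
#'
#' Finds the earliest frame after which the sliding-window mean of the
#' series stops changing: consecutive non-overlapping windows of length
#' `window` must differ by less than `tol` relative to the series scale
#' (its maximum absolute value) from that frame onward. Frames are
#' 1-based; a series that is flat from the start therefore returns 1.
#'
#' @param x Numeric series (e.g. free-lipid counts per frame) or an
#'   [adsorbed_fraction()] result (its adsorbed fraction is used).
#' @param window Window length in frames (default 10 percent of the
#'   series, at least 3).
#' @param tol Relative tolerance per window (default 1e-3).
#' @param noise_aware If `TRUE`, the stability threshold for each window
#'   pair is widened to `z` standard errors of the window-mean
#'   difference, so a stochastic series whose equilibrium fluctuations
#'   exceed `tol` x scale (e.g. adsorbed-lipid counts with
#'   surface/solution exchange) is still recognized as flat. A trend
#'   larger than its own noise is still rejected.
#' @param z Standard-error multiplier for the noise-aware threshold.
#' @return Earliest equilibrated frame index, or `NA` if the series
#'   never settles. Attribute `window` records the window used.
#' @export
detect_equilibration <- function(x, window = NULL, tol = 1e-3,
                                 noise_aware = FALSE, z = 3) {
  if (inherits(x, "adsorption_series")) x <- x$fraction_adsorbed
  n <- length(x)
  if (is.null(window)) window <- max(3L, floor(0.1 * n))
  window <- as.integer(window)
  if (n < 2L * window)
    stop("series too short for one window pair (need at least ",
         2L * window, " frames)")
  scale <- max(abs(x), 1e-12)
  wm <- vapply(seq_len(n - window + 1L),
               function(t) mean(x[t:(t + window - 1L)]), numeric(1))
  starts <- seq_len(n - 2L * window + 1L)
  delta <- abs(wm[starts + window] - wm[starts])
  thresh <- rep(tol * scale, length(starts))
  if (noise_aware) {
    # frame-to-frame noise from first differences of the series tail:
    # var(diff) = 2 sigma^2 for weakly correlated stationary noise, and
    # unlike the raw window variance it is not inflated by a step or a
    # smooth trend elsewhere in the series
    tail_x <- x[max(1L, n - 2L * window + 1L):n]
    sigma2 <- stats::var(diff(tail_x)) / 2
    if (is.na(sigma2)) sigma2 <- 0
    se <- sqrt(2 * sigma2 / window)
    thresh <- pmax(thresh, z * se)
  }
  ok <- delta < thresh
  # earliest start from which every later window pair is also stable
  stable_from <- rev(cumprod(rev(ok))) > 0
  if (!any(stable_from)) return(structure(NA_integer_, window = window))
  structure(which(stable_from)[1], window = window)
}

#' Saturation surface density of adsorbed lipids
#'
#' Post-equilibration mean count of lipids adsorbed on the outer tube
#' surface divided by the bead-center cylinder area \eqn{\pi D L}.
#' Inner-surface adsorbates (seen in wide tubes) are excluded from the
#' density and reported separately. The estimate is refused when the
#' free-lipid series shows no plateau.
#'
#' @param traj A `dpd_trajectory` with tube and lipids.
#' @param cutoff Adsorption cutoff (rC).
#' @param equilibration_frame Plateau start frame; detected from the
#'   adsorbed-count series when `NULL`.
#' @param tol Relative plateau tolerance handed to
#'   [detect_equilibration()]. The default 0.05 accommodates the
#'   equilibrium exchange fluctuations of a few lipids that the adsorbed
#'   count shows even at saturation.
#'
#' @details When the plateau is auto-detected, the average is taken over
#'   the final third of the trajectory (or the post-detection range if
#'   that is shorter): adsorbed counts often creep slowly toward
#'   saturation well after the noise-level plateau test first passes,
#'   and the tail weights the most-converged data. An explicitly given
#'   `equilibration_frame` is honored as-is.
#' @return Object of class `saturation_estimate`: list with `rho_s`
#'   (outer, per \eqn{r_C^2}), `rho_s_inner`, `rho_s_total` (outer plus
#'   inner adsorbates over the outer area, the materials-balance
#'   convention), `n_outer`, `tube`, `equilibration_window` (frame range
#'   averaged).
#' @export
saturation_density <- function(traj, cutoff = 1.06,
                               equilibration_frame = NULL, tol = 0.05) {
  ads <- adsorbed_fraction(traj, cutoff)
  nf <- length(traj$frames)
  if (is.null(equilibration_frame)) {
    equilibration_frame <- detect_equilibration(ads$n_adsorbed, tol = tol,
                                                noise_aware = TRUE)
    if (is.na(equilibration_frame))
      stop("trajectory shows no adsorption plateau; saturation estimate refused")
    equilibration_frame <- max(as.integer(equilibration_frame),
                               nf - max(3L, nf %/% 3L) + 1L)
  }
  win <- equilibration_frame:nf
  n_outer <- ads$fraction_outer[win] * ads$n_lipids
  n_inner <- ads$fraction_inner[win] * ads$n_lipids
  area <- pi * (2 * traj$tube$radius) * traj$tube$length
  structure(list(rho_s = mean(n_outer) / area,
                 rho_s_inner = mean(n_inner) / area,
                 rho_s_total = mean(n_outer + n_inner) / area,
                 n_outer = mean(n_outer),
                 sd_outer = stats::sd(n_outer),
                 tube = traj$tube,
                 equilibration_window = range(win)),
            class = "saturation_estimate")
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf(
    "Saturation estimate: rho_s = %.4f rC^-2 (outer, %.1f lipids on %.1f rC^2)\n",
    x$rho_s, x$n_outer, pi * 2 * x$tube$radius * x$tube$length))
  if (x$rho_s_inner > 0)
    cat(sprintf("  inner-surface density: %.4f rC^-2\n", x$rho_s_inner))
  cat(sprintf("  averaged over frames %d..%d\n",
              x$equilibration_window[1], x$equilibration_window[2]))
  invisible(x)
}
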