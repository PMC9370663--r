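tube_fix <- list(radius = 1.97, length = 8, center = c(6, 6, 6))
box_fix <- c(12, 12, 12)

test_that("surface distance handles the cylinder body, axis and rims", {
  expect_equal(surface_distance(c(6 + 1.97, 6, 6), tube_fix, box_fix), 0)
  # a bead on the axis of CNT(20,20): minus the radius
  expect_equal(surface_distance(tube_fix$center, tube_fix, box_fix), -1.97)
  # beyond the tube end: rim distance (offsets small enough that the
  # minimum image stays on this side of the periodic box)
  p <- c(6, 6 + tube_fix$length / 2 + 1, 6 + 1.97)
  expect_equal(surface_distance(p, tube_fix, box_fix), 1)
  p2 <- c(6, 6 + tube_fix$length / 2 + 1.5, 6 + 1.97 + 2)
  expect_equal(surface_distance(p2, tube_fix, box_fix), sqrt(1.5^2 + 2^2))
})

test_that("surface distance matches a brute-force point-to-surface minimizer", {
  set.seed(21)
  surf_min <- function(p) {
    obj <- function(par) {
      q <- c(tube_fix$center[1] + tube_fix$radius * cos(par[1]),
             tube_fix$center[2] + max(-tube_fix$length / 2,
                                      min(tube_fix$length / 2, par[2])),
             tube_fix$center[3] + tube_fix$radius * sin(par[1]))
      sqrt(sum((p - q)^2))
    }
    grid <- expand.grid(phi = seq(0, 2 * pi, length.out = 60),
                        y = seq(-4, 4, length.out = 60))
    v <- apply(grid, 1, obj)
    st <- as.numeric(grid[which.min(v), ])
    stats::optim(st, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))$value
  }
  for (rep in 1:12) {
    p <- tube_fix$center + stats::runif(3, -5, 5)
    expect_equal(abs(surface_distance(p, tube_fix, box_fix)), surf_min(p),
                 tolerance = 1e-7)
  }
})

test_that("adsorbed fraction counts lipids touching the surface", {
  # 3 of 10 lipids touch the tube; the rest sit far away
  R <- tube_fix$radius
  near <- lapply(1:3, function(i) {
    phi <- 2 * pi * i / 3
    anchor <- tube_fix$center + c((R + 0.5) * cos(phi), i - 2, (R + 0.5) * sin(phi))
    lipid_rod(anchor, c(0, 1, 0), spacing = 0.2)
  })
  far <- lapply(1:7, function(i)
    lipid_rod(c(0.5, 1 + i, 0.5), c(1, 0, 0), spacing = 0.2))
  traj <- synthetic_traj(list(c(near, far)), box_fix, tube_fix)
  ads <- adsorbed_fraction(traj)
  expect_equal(ads$fraction_adsorbed, 0.3)
  expect_equal(ads$fraction_outer, 0.3)
  expect_equal(ads$fraction_inner, 0)
  expect_equal(ads$cutoff, 1.06)
  # with everything at least 2 rC away the fraction is zero
  traj0 <- synthetic_traj(list(far), box_fix, tube_fix)
  expect_equal(adsorbed_fraction(traj0)$fraction_adsorbed, 0)
  # a lipid inside the wide-tube interior counts as inner-surface adsorbed
  inner <- list(lipid_rod(tube_fix$center + c(1.4, -1, 0), c(0, 1, 0), 0.2))
  traji <- synthetic_traj(list(inner), box_fix, tube_fix)
  adsi <- adsorbed_fraction(traji)
  expect_equal(adsi$fraction_adsorbed, 1)
  expect_equal(adsi$fraction_inner, 1)
})

test_that("a densifying fixture yields non-decreasing adsorbed fractions", {
  R <- tube_fix$radius
  make_frame <- function(n_on) {
    on <- radial_rods_on_tube(n_on, tube_fix)
    off <- lapply(seq_len(10 - n_on), function(i)
      lipid_rod(c(0.5, 0.8 * i, 0.3), c(1, 0, 0), 0.2))
    c(on, off)
  }
  traj <- synthetic_traj(lapply(c(2, 4, 7, 10), make_frame), box_fix, tube_fix)
  ads <- adsorbed_fraction(traj)
  expect_true(all(diff(ads$fraction_adsorbed) >= 0))
  expect_equal(ads$fraction_adsorbed, c(0.2, 0.4, 0.7, 1.0))
})

test_that("clustering matches a breadth-first oracle on random lipid packs", {
  bfs_clusters <- function(pos_list, box, cutoff) {
    nl <- length(pos_list)
    adj <- matrix(FALSE, nl, nl)
    for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
      ti <- pos_list[[i]][5:12, , drop = FALSE]
      tj <- pos_list[[j]][5:12, , drop = FALSE]
      hit <- FALSE
      for (a in 1:8) {
        d <- sweep(tj, 2, ti[a, ])
        d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
        if (any(rowSums(d^2) < cutoff^2)) { hit <- TRUE; break }
      }
      adj[i, j] <- adj[j, i] <- hit
    }
    comp <- rep(0L, nl); cur <- 0L
    for (s in seq_len(nl)) {
      if (comp[s] > 0) next
      cur <- cur + 1L; queue <- s; comp[s] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0)
        comp[nb] <- cur; queue <- c(queue, nb)
      }
    }
    comp
  }
  set.seed(31)
  for (rep in 1:3) {
    pos_list <- lapply(1:50, function(i)
      lipid_rod(stats::runif(3, 0, 12), stats::rnorm(3), spacing = 0.25))
    traj <- synthetic_traj(list(pos_list), box_fix, tube_fix)
    got <- cluster_lipids(traj, 1, linkage_cutoff = 1.0)
    want <- bfs_clusters(pos_list, box_fix, 1.0)
    # same partition up to label permutation
    tab <- table(got$membership, want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    expect_equal(sum(got$cluster_sizes), 50)
  }
  # two lipids in tail contact form one dimer; distant ones stay singletons
  l1 <- lipid_rod(c(2, 2, 2), c(0, 1, 0), 0.25)
  l2 <- lipid_rod(c(2.5, 2, 2), c(0, 1, 0), 0.25)
  l3 <- lipid_rod(c(9, 9, 9), c(0, 1, 0), 0.25)
  traj <- synthetic_traj(list(list(l1, l2, l3)), box_fix, tube_fix)
  expect_equal(cluster_lipids(traj, 1)$cluster_sizes, c(2L, 1L))
})

test_that("density profiles conserve counts and see uniform annuli as flat", {
  # all beads at one distance: a single occupied bin
  d0 <- 1.25
  one <- lapply(1:6, function(i) {
    phi <- 2 * pi * i / 6
    p <- tube_fix$center + c((tube_fix$radius + d0) * cos(phi), 0,
                             (tube_fix$radius + d0) * sin(phi))
    matrix(rep(p, each = 12), ncol = 3)
  })
  traj1 <- synthetic_traj(list(one), box_fix, tube_fix)
  dp1 <- radial_density_profile(traj1, bin_width = 0.1)
  occupied <- which(dp1$density > 0)
  expect_length(occupied, 1)
  expect_true(dp1$bin_edges[occupied] <= d0 && d0 < dp1$bin_edges[occupied + 1])
  # conservation: density times shell volume reconstructs the mean count
  expect_equal(sum(dp1$density * dp1$shell_volume), dp1$mean_count,
               tolerance = 1e-6)
  expect_equal(dp1$mean_count, 72)
  # uniform sampling of an annulus is flat within Poisson error
  set.seed(41)
  n <- 40000
  r <- sqrt(stats::runif(n, (tube_fix$radius + 0.5)^2, (tube_fix$radius + 2.5)^2))
  phi <- stats::runif(n, 0, 2 * pi)
  y <- stats::runif(n, -tube_fix$length / 2, tube_fix$length / 2)
  pos <- cbind(tube_fix$center[1] + r * cos(phi), tube_fix$center[2] + y,
               tube_fix$center[3] + r * sin(phi))
  fake <- lapply(seq_len(n %/% 12), function(i) pos[(12 * i - 11):(12 * i), ])
  traj2 <- synthetic_traj(list(fake), box_fix, tube_fix)
  dp2 <- radial_density_profile(traj2, bin_width = 0.25, d_max = 2.5)
  sel <- dp2$bin_edges[-length(dp2$bin_edges)] >= 0.5 &
    dp2$bin_edges[-1] <= 2.5
  dens <- dp2$density[sel]
  counts <- dens * dp2$shell_volume[sel]
  expect_lt(max(abs(dens - mean(dens)) / mean(dens)), 5 / sqrt(min(counts)))
  expect_error(radial_density_profile(traj2, bin_width = 0))
})

test_that("orientation histograms identify radial and axial archetypes", {
  rad <- radial_rods_on_tube(8, tube_fix, r0 = 0.1, spacing = 0.25)
  traj_r <- synthetic_traj(list(rad), box_fix, tube_fix)
  oh_r <- orientation_distribution(traj_r)
  expect_equal(sum(oh_r$probability * diff(oh_r$theta_edges)), 1,
               tolerance = 1e-6)
  expect_equal(which.max(oh_r$counts), 1)  # mass at 0 degrees (radial)
  axial <- lapply(1:8, function(i) {
    phi <- 2 * pi * i / 8
    anchor <- tube_fix$center + c((tube_fix$radius + 0.3) * cos(phi), -2,
                                  (tube_fix$radius + 0.3) * sin(phi))
    lipid_rod(anchor, c(0, 1, 0), 0.25)
  })
  traj_a <- synthetic_traj(list(axial), box_fix, tube_fix)
  oh_a <- orientation_distribution(traj_a)
  expect_equal(which.max(oh_a$counts), length(oh_a$counts))  # 90 degrees
})

test_that("isotropic tail orientations follow the sine baseline", {
  set.seed(51)
  iso <- lapply(1:2000, function(i) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    phi <- stats::runif(1, 0, 2 * pi)
    anchor <- tube_fix$center + c((tube_fix$radius + 0.2) * cos(phi),
                                  stats::runif(1, -3, 3),
                                  (tube_fix$radius + 0.2) * sin(phi))
    lipid_rod(anchor, u, 0.12)
  })
  traj <- synthetic_traj(list(iso), box_fix, tube_fix)
  oh <- orientation_distribution(traj, bin_width = 15, adsorbed_only = FALSE)
  lo <- oh$theta_edges[-length(oh$theta_edges)] * pi / 180
  hi <- oh$theta_edges[-1] * pi / 180
  expected <- (cos(lo) - cos(hi)) / (hi - lo) * pi / 180  # per-degree density
  # chains share a lipid (mean of two correlated angles), so allow a loose
  # but shape-discriminating agreement with the sine measure
  expect_lt(max(abs(oh$probability - expected) / max(expected)), 0.35)
  expect_gt(stats::cor(oh$probability, expected), 0.9)
})

test_that("equilibration detection finds plateaus and refuses ramps", {
  expect_equal(as.integer(detect_equilibration(rep(5, 50))), 1L)
  stepped <- c(rep(10, 30), rep(0, 70))
  eq <- detect_equilibration(stepped)
  w <- attr(eq, "window")
  expect_lte(as.integer(eq), 31 + w)
  expect_gte(as.integer(eq), 25)
  expect_true(is.na(detect_equilibration(seq_len(100))))
  expect_error(detect_equilibration(1:5, window = 10), "too short")
})

test_that("saturation density is the plateau count over the cylinder area", {
  n_on <- 12
  frames <- replicate(8, radial_rods_on_tube(n_on, tube_fix), simplify = FALSE)
  traj <- synthetic_traj(frames, box_fix, tube_fix)
  sat <- saturation_density(traj, equilibration_frame = 1)
  area <- pi * 2 * tube_fix$radius * tube_fix$length
  expect_equal(sat$rho_s, n_on / area, tolerance = 1e-12)
  expect_equal(sat$rho_s_inner, 0)
  # detection path on a stepped series: k lipids on the tube, the rest far
  step_frame <- function(k, total) {
    on <- radial_rods_on_tube(k, tube_fix)
    off <- lapply(seq_len(total - k), function(i)
      lipid_rod(c(0.4, 0.7 * i, 0.4), c(1, 0, 0), 0.2))
    c(on, off)
  }
  frames2 <- lapply(c(2, 6, rep(12, 10)), step_frame, total = 12)
  traj2 <- synthetic_traj(frames2, box_fix, tube_fix)
  sat2 <- saturation_density(traj2)
  expect_equal(sat2$rho_s, 12 / area, tolerance = 0.2 / area)
  # a never-settling ramp is refused
  frames3 <- lapply(seq(2, 24, by = 2), step_frame, total = 24)
  traj3 <- synthetic_traj(frames3, box_fix, tube_fix)
  expect_error(saturation_density(traj3), "refused")
})
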