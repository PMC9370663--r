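test_that("conservative force is linear in distance and vanishes at cutoff", {
  f <- conservative_force(c(0, 0, 0), c(0.5, 0, 0), 100)
  expect_equal(sqrt(sum(f^2)), 50)
  expect_equal(f, c(-50, 0, 0))  # repulsion pushes i away from j
  expect_equal(conservative_force(c(0, 0, 0), c(1, 0, 0), 130), c(0, 0, 0))
  expect_equal(conservative_force(c(0, 0, 0), c(1.7, 0, 0), 130), c(0, 0, 0))
  # antisymmetry under index swap
  ri <- c(0.3, 0.2, 0.9); rj <- c(0.6, 0.1, 0.5)
  expect_equal(conservative_force(ri, rj, 110),
               -conservative_force(rj, ri, 110))
  # minimum image across the boundary
  f <- conservative_force(c(0.1, 0, 0), c(7.9, 0, 0), 100, box = c(8, 8, 8))
  expect_equal(f, c(100 * 0.8, 0, 0) * sign(1))
})

test_that("dissipative force opposes relative motion and has no transverse part", {
  m <- default_interaction_model()
  ri <- c(0, 0, 0); rj <- c(0.5, 0, 0)
  # separating beads: force on i opposes separation (points toward +x)
  rd <- random_dissipative_forces(ri, rj, vij = c(-2, 0, 0), m, dt = 0.02,
                                  theta = 0)
  expect_equal(rd$random, c(0, 0, 0))
  expect_gt(rd$dissipative[1], 0)
  # transverse relative velocity: no dissipative force
  rd <- random_dissipative_forces(ri, rj, vij = c(0, 3, 0), m, dt = 0.02,
                                  theta = 0)
  expect_equal(rd$dissipative, c(0, 0, 0))
  # random amplitude carries sigma * w / sqrt(dt)
  rd <- random_dissipative_forces(ri, rj, vij = c(0, 0, 0), m, dt = 0.04,
                                  theta = 1)
  expect_equal(sqrt(sum(rd$random^2)), m$sigma * 0.5 / sqrt(0.04))
  expect_error(random_dissipative_forces(ri, rj, c(0, 0, 0), m, dt = 0))
})

test_that("bond force restores the equilibrium length", {
  expect_equal(bond_force(c(0.47, 0, 0), c(0, 0, 0), 512, 0.47), c(0, 0, 0))
  f <- bond_force(c(0.48, 0, 0), c(0, 0, 0), 512, 0.47)
  expect_equal(sqrt(sum(f^2)), 5.12, tolerance = 1e-12)
  expect_lt(f[1], 0)  # stretched bond pulls i back
})

test_that("bonded forces match central-difference energy gradients", {
  set.seed(42)
  h <- 1e-5
  for (rep in 1:5) {
    ri <- stats::rnorm(3, sd = 0.4); rj <- stats::rnorm(3, sd = 0.4)
    f <- bond_force(ri, rj, 512, 0.47)
    num <- vapply(1:3, function(d) {
      e <- rep(0, 3); e[d] <- h
      -(bond_energy(ri + e, rj, 512, 0.47) -
          bond_energy(ri - e, rj, 512, 0.47)) / (2 * h)
    }, numeric(1))
    expect_equal(f, num, tolerance = 1e-6)
  }
  for (rep in 1:5) {
    ri <- stats::rnorm(3); rj <- stats::rnorm(3); rk <- stats::rnorm(3)
    th0 <- sample(c(120, 180), 1)
    F <- angle_force(ri, rj, rk, 6, th0)
    for (bead in 1:3) {
      pts <- list(ri, rj, rk)
      num <- vapply(1:3, function(d) {
        e <- rep(0, 3); e[d] <- h
        p1 <- pts; p1[[bead]] <- p1[[bead]] + e
        p2 <- pts; p2[[bead]] <- p2[[bead]] - e
        -(angle_energy(p1[[1]], p1[[2]], p1[[3]], 6, th0) -
            angle_energy(p2[[1]], p2[[2]], p2[[3]], 6, th0)) / (2 * h)
      }, numeric(1))
      expect_equal(unname(F[bead, ]), num, tolerance = 1e-6)
    }
  }
})

test_that("angle forces vanish at the minimum, sum to zero, exert no net torque", {
  # 120-degree triple at its minimum
  ri <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0); rj <- c(0, 0, 0); rk <- c(1, 0, 0)
  F <- angle_force(ri, rj, rk, 6, 120)
  expect_lt(max(abs(F)), 1e-10)
  # energy reaches its maximum k at theta0 + 180
  expect_equal(angle_energy(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), 6, 0), 6)
  # random geometry: zero total force and zero net torque about the center
  set.seed(7)
  for (rep in 1:5) {
    ri <- stats::rnorm(3); rj <- stats::rnorm(3); rk <- stats::rnorm(3)
    F <- angle_force(ri, rj, rk, 6, 120)
    expect_lt(max(abs(colSums(F))), 1e-10)
    tq <- cross3(ri - rj, F[1, ]) + cross3(rk - rj, F[3, ])
    expect_lt(max(abs(tq)), 1e-10)
  }
})

test_that("compiled forces agree with the pure-R reference on a bonded system", {
  set.seed(11)
  cfg <- build_system(system_spec(NULL, n_lipids = 3, n_water_beads = 150,
                                  Ly = 4.3, seed = 11))
  m <- default_interaction_model()
  res <- dpdcnt:::.dpd_forces_cpp(cfg$pos, cfg$type_id, cfg$frozen, cfg$box,
                                  m$a, cfg$bonds, cfg$bond_k, cfg$bond_r0,
                                  cfg$angles, cfg$angle_k, cfg$angle_theta0)
  n <- nrow(cfg$pos)
  bonded <- matrix(FALSE, n, n)
  bonded[cfg$bonds] <- TRUE
  bonded <- bonded | t(bonded)
  ref <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (bonded[i, j]) next  # directly bonded pairs carry no nonbonded force
    f <- conservative_force(cfg$pos[i, ], cfg$pos[j, ],
                            m$a[cfg$type[i], cfg$type[j]], box = cfg$box)
    ref[i, ] <- ref[i, ] + f
    ref[j, ] <- ref[j, ] - f
  }
  for (b in seq_len(nrow(cfg$bonds))) {
    i <- cfg$bonds[b, 1]; j <- cfg$bonds[b, 2]
    f <- bond_force(cfg$pos[i, ], cfg$pos[j, ], cfg$bond_k[b], cfg$bond_r0[b],
                    box = cfg$box)
    ref[i, ] <- ref[i, ] + f
    ref[j, ] <- ref[j, ] - f
  }
  for (t in seq_len(nrow(cfg$angles))) {
    i <- cfg$angles[t, 1]; j <- cfg$angles[t, 2]; k <- cfg$angles[t, 3]
    F <- angle_force(cfg$pos[i, ], cfg$pos[j, ], cfg$pos[k, ],
                     cfg$angle_k[t], cfg$angle_theta0[t], box = cfg$box)
    ref[i, ] <- ref[i, ] + F[1, ]
    ref[j, ] <- ref[j, ] + F[2, ]
    ref[k, ] <- ref[k, ] + F[3, ]
  }
  expect_equal(res$force, ref, tolerance = 1e-10)
  # Newton's third law: all forces sum to zero in a fully mobile system
  expect_lt(max(abs(colSums(res$force))), 1e-10)
})

test_that("cell-list pair enumeration equals the exhaustive oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 200
    box <- c(4, 4.6, 4.2) + seed * 0.2
    pos <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                 stats::runif(n, 0, box[3]))
    got <- sort_pairs(dpdcnt:::.cell_pairs_cpp(pos, box, 1.0))
    want <- sort_pairs(brute_pairs(pos, box, 1.0))
    expect_identical(unname(got), unname(want))
  }
  # sub-cutoff linkage radius used by the clustering stage
  set.seed(9)
  pos <- cbind(stats::runif(120, 0, 5), stats::runif(120, 0, 5),
               stats::runif(120, 0, 5))
  got <- sort_pairs(dpdcnt:::.cell_pairs_cpp(pos, c(5, 5, 5), 0.6))
  want <- sort_pairs(brute_pairs(pos, c(5, 5, 5), 0.6))
  expect_identical(unname(got), unname(want))
})
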