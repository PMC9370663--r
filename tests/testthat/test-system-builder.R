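test_that("the lipid topology has the canonical census and connectivity", {
  top <- build_dppc_topology()
  expect_length(top$bead_types, 12)
  expect_equal(sum(top$bead_types == "h1"), 1)
  expect_equal(sum(top$bead_types == "h2"), 1)
  expect_equal(sum(top$bead_types == "h3"), 2)
  expect_equal(sum(top$bead_types == "t"), 8)
  expect_equal(nrow(top$bonds), 11)
  tt <- top$bead_types[top$bonds$i] == "t" & top$bead_types[top$bonds$j] == "t"
  expect_equal(sum(tt), 6)  # three per tail
  expect_true(validate_topology(top))
})

test_that("angle terms are instantiated only for tabulated type patterns", {
  top <- build_dppc_topology()
  a <- top$angles
  expect_equal(nrow(a), 8)
  expect_equal(sum(a$theta0 == 120), 1)  # the h2-h3-h3 head kink
  expect_equal(sum(a$theta0 == 180), 7)
  # no term on the h1-h2-h3 triple (not tabulated)
  expect_false(any(a$j == 2))
  # every bond carries the shared force constant and a tabulated length
  expect_true(all(top$bonds$k_bond == 512))
  expect_true(all(top$bonds$r0 %in% c(0.47, 0.31, 0.59)))
})

test_that("topology validation rejects mutated topologies", {
  top <- build_dppc_topology()
  t1 <- top; t1$bead_types <- c(t1$bead_types, "t")
  expect_error(validate_topology(t1), "12 beads")
  t2 <- top; t2$bead_types[1] <- "t"
  expect_error(validate_topology(t2), "census")
  t3 <- top; t3$bonds$j[11] <- 5L  # creates a cycle and disconnects bead 12
  expect_error(validate_topology(t3))
  t4 <- top; t4$bonds$i[1] <- 4L   # h3-h2 pair has no tabulated bond term
  expect_error(validate_topology(t4))
})

test_that("nanotube beads lie exactly on the cylinder at the right extent", {
  for (chir in c(10, 14, 20, 34)) {
    spec <- nanotube_spec(chir)
    cnt <- build_cnt(spec, center = c(5, 10, 5))
    radial <- sqrt((cnt$pos[, 1] - 5)^2 + (cnt$pos[, 3] - 5)^2)
    expect_lt(max(abs(radial - spec$diameter / 2)), 1e-12)
    extent <- diff(range(cnt$pos[, 2]))
    expect_lt(abs(extent - 15.5), 0.5)
  }
  expect_error(nanotube_spec(12))
  expect_error(nanotube_spec(10, length = -1))
})

test_that("tube bead count scales with surface area", {
  n14 <- nrow(build_cnt(nanotube_spec(14))$pos)
  # (14,14) diameter 2.67 doubles (within the catalog) to (34,34)'s 6.2/2.67
  spec14 <- nanotube_spec(14)
  spec_double <- spec14
  spec_double$diameter <- 2 * spec14$diameter
  n28 <- nrow(build_cnt(spec_double)$pos)
  expect_lt(abs(n28 / n14 - 2), 0.1)
  # realized areal density close to the eight-carbon mapping target
  cnt <- build_cnt(spec14)
  area <- pi * spec14$diameter * cnt$length
  expect_lt(abs(nrow(cnt$pos) / area - spec14$bead_surface_density) /
              spec14$bead_surface_density, 0.1)
})

test_that("built systems respect counts, exclusion, wrapping and density", {
  spec <- system_spec(nanotube_spec(14, length = 6), n_lipids = 8,
                      n_water_beads = 1200, Ly = 9, seed = 5)
  cfg <- build_system(spec)
  expect_equal(sum(cfg$type == "w"), 1200)
  expect_equal(sum(cfg$type %in% c("h1", "h2", "h3", "t")), 8 * 12)
  expect_identical(cfg$frozen, cfg$type == "cnt")
  expect_true(all(cfg$vel[cfg$frozen, ] == 0))
  expect_true(all(cfg$pos >= 0 & cfg$pos <= matrix(cfg$box, nrow(cfg$pos), 3,
                                                   byrow = TRUE)))
  # no mobile bead starts inside the tube interior over its axial extent
  mob <- !cfg$frozen
  dx <- cfg$pos[mob, 1] - cfg$box[1] / 2
  dy <- cfg$pos[mob, 2] - cfg$box[2] / 2
  dz <- cfg$pos[mob, 3] - cfg$box[3] / 2
  inside <- abs(dy) <= cfg$tube$length / 2 &
    sqrt(dx^2 + dz^2) < cfg$tube$radius
  expect_equal(sum(inside), 0)
  # accessible-volume density within 5% of the reduced density 3
  v_int <- pi * cfg$tube$radius^2 * cfg$tube$length
  rho <- sum(mob) / (prod(cfg$box) - v_int)
  expect_lt(abs(rho - 3) / 3, 0.05)
  # net mobile momentum is zero by construction
  expect_lt(max(abs(colSums(cfg$vel[mob, ]))), 1e-10)
})

test_that("a lipid-free spec builds water plus tube only", {
  spec <- system_spec(nanotube_spec(10, length = 5), 0, 600, Ly = 8, seed = 2)
  cfg <- build_system(spec)
  expect_equal(sum(!cfg$frozen), 600)
  expect_equal(nrow(cfg$bonds), 0)
})

test_that("the build is bit-reproducible given the seed", {
  spec <- system_spec(nanotube_spec(10, length = 5), 4, 500, Ly = 8, seed = 77)
  c1 <- build_system(spec)
  c2 <- build_system(spec)
  expect_identical(c1$pos, c2$pos)
  expect_identical(c1$vel, c2$vel)
  spec2 <- spec; spec2$seed <- 78L
  c3 <- build_system(spec2)
  expect_false(identical(c1$pos, c3$pos))
})

test_that("an infeasible density is reported as an insertion failure", {
  spec <- system_spec(NULL, 0, 4000, Ly = 4, seed = 1)  # rho far above 3
  spec$n_water_beads <- 4000L
  # shrink the box by hand: Ly small forces Lx = Lz large, so instead
  # demand an impossible minimum distance
  expect_error(build_system(spec, min_dist = 1.0, max_attempts = 50),
               "infeasible")
})

test_that("the catalog enumerates all 44 studied systems", {
  cat44 <- table2_catalog()
  expect_length(cat44, 44)
  expect_true(all(vapply(cat44, function(s) s$n_water_beads, numeric(1)) == 20000))
  ly <- vapply(cat44, function(s) s$eq_box[2], numeric(1))
  expect_true(all(ly >= 22.41 & ly <= 22.66))
  d <- table2_catalog_df()
  expect_setequal(unique(d$n_lipids),
                  c(10, 50, 100, 150, 200, 250, 300, 350, 400, 450, 500))
  expect_equal(length(unique(d$n_lipids)), 11)
  expect_setequal(unique(d$chirality), c(10, 14, 20, 34))
  expect_true(all(table(d$chirality) == 11))
})

test_that("scaled presets preserve composition and density", {
  full <- scaled_preset("cnt2020_300", scale = 1)
  expect_equal(full$n_lipids, 300L)
  expect_equal(full$n_water_beads, 20000L)
  expect_equal(full$substrate$length, 15.5)
  expect_equal(full$Ly, 22.5)
  small <- scaled_preset("cnt2020_300", scale = 0.125)
  expect_equal(small$n_water_beads, 2500L)
  expect_equal(small$n_lipids, 38L)
  expect_equal(small$substrate$length, 15.5 * 0.5)
  expect_error(scaled_preset("cnt2020_300", scale = 0))
  expect_error(scaled_preset("cnt2020_300", scale = 1.5))
  expect_error(scaled_preset("cnt2021_300"))
  expect_error(scaled_preset("cnt2020_123"))
  # a small preset builds at the reduced density
  cfg <- build_system(scaled_preset("cnt1010_100", 0.05, seed = 3))
  v_int <- pi * cfg$tube$radius^2 * cfg$tube$length
  rho <- sum(!cfg$frozen) / (prod(cfg$box) - v_int)
  expect_lt(abs(rho - 3) / 3, 0.05)
})
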