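#' Canonical 12-bead DPPC topology
#'
#' The lipid is coarse-grained into 12 beads: a choline-like `h1`, a
#' phosphate-like `h2`, two glycerol-like `h3` beads, and two hydrocarbon
#' tails of four `t` beads each. The backbone is `h1-h2-h3a`, the two
#' glycerol beads are linked (`h3a-h3b`), and each glycerol bead carries
#' one tail (`h3a-t-t-t-t`, `h3b-t-t-t-t`), giving 11 bonds forming a
#' tree. Angle terms are instantiated for every consecutive bonded triple
#' whose type pattern has a tabulated bending term (`h2-h3-h3` at 120
#' degrees; `h2-h3-t`, `h3-t-t` and `t-t-t` at 180 degrees); triples with
#' no tabulated pattern (e.g. `h1-h2-h3`, `h3-h3-t`) carry none.
#'
#' Bead order: 1 = h1, 2 = h2, 3 = h3a, 4 = h3b, 5-8 = tail 1, 9-12 =
#' tail 2.
#'
#' @return An object of class `dppc_topology`: list with `bead_types`
#'   (character 12), `bonds` (data frame `i, j, k_bond, r0`), `angles`
#'   (data frame `i, j, k, k_angle, theta0`; `j` central).
#' @export
#' @examples
#' top <- build_dppc_topology()
#' length(top$bead_types)   # 12
#' nrow(top$bonds)          # 11
build_dppc_topology <- function() {
  bead_types <- c("h1", "h2", "h3", "h3", rep("t", 8))
  bonds <- data.frame(
    i = c(1, 2, 3, 3, 5, 6, 7, 4, 9, 10, 11),
    j = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  )
  bt <- bond_terms()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  btkey <- key(bt$type_i, bt$type_j)
  idx <- match(key(bead_types[bonds$i], bead_types[bonds$j]), btkey)
  bonds$k_bond <- bt$k_bond[idx]
  bonds$r0 <- bt$r0[idx]

  # consecutive bonded triples, keeping only tabulated type patterns
  triples <- rbind(
    c(1, 2, 3),                      # h1-h2-h3: no tabulated term
    c(2, 3, 4),                      # h2-h3-h3, 120 deg
    c(2, 3, 5),                      # h2-h3-t
    c(4, 3, 5), c(3, 4, 9),          # h3 triples with no tabulated term
    c(3, 5, 6), c(5, 6, 7), c(6, 7, 8),
    c(4, 9, 10), c(9, 10, 11), c(10, 11, 12)
  )
  at <- angle_terms()
  atkey <- paste(pmin(at$type_i, at$type_k), at$type_j, pmax(at$type_i, at$type_k))
  tkey <- paste(pmin(bead_types[triples[, 1]], bead_types[triples[, 3]]),
                bead_types[triples[, 2]],
                pmax(bead_types[triples[, 1]], bead_types[triples[, 3]]))
  aidx <- match(tkey, atkey)
  keep <- !is.na(aidx)
  angles <- data.frame(
    i = triples[keep, 1], j = triples[keep, 2], k = triples[keep, 3],
    k_angle = at$k_angle[aidx[keep]], theta0 = at$theta0[aidx[keep]]
  )
  structure(list(bead_types = bead_types, bonds = bonds, angles = angles),
            class = "dppc_topology")
}

#' Validate a lipid topology against the model's structural invariants
#'
#' Checks bead census (1 h1, 1 h2, 2 h3, 8 t), the 11-bond tree property
#' (connected and acyclic), that every bond pair and angle triple matches
#' a tabulated term, and that each tail is a linear chain of four `t`
#' beads.
#'
#' @param top A `dppc_topology` (or a mutated candidate).
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_topology <- function(top) {
  bt <- top$bead_types
  if (length(bt) != 12) stop("topology must have exactly 12 beads")
  cen <- table(factor(bt, levels = c("h1", "h2", "h3", "t")))
  if (!all(cen == c(h1 = 1, h2 = 1, h3 = 2, t = 8)))
    stop("bead census must be 1 h1, 1 h2, 2 h3, 8 t")
  b <- top$bonds
  if (nrow(b) != 11) stop("topology must have exactly 11 bonds")
  if (any(b$i == b$j)) stop("self-bonds are not allowed")
  # tree check: connected with n-1 edges implies acyclic
  adj <- lapply(seq_len(12), function(v) integer(0))
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  seen <- logical(12); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  if (!all(seen)) stop("bond graph must be connected (a tree on 12 beads)")
  ref <- bond_terms()
  key <- function(a, bb) paste(pmin(a, bb), pmax(a, bb))
  if (!all(key(bt[b$i], bt[b$j]) %in% key(ref$type_i, ref$type_j)))
    stop("every bond's type pair must have a tabulated bond term")
  a <- top$angles
  if (nrow(a)) {
    at <- angle_terms()
    atkey <- paste(pmin(at$type_i, at$type_k), at$type_j, pmax(at$type_i, at$type_k))
    akey <- paste(pmin(bt[a$i], bt[a$k]), bt[a$j], pmax(bt[a$i], bt[a$k]))
    if (!all(akey %in% atkey))
      stop("every angle's type triple must have a tabulated bending term")
  }
  # each h3 bead must start a linear chain of four t beads
  for (h3 in which(bt == "h3")) {
    tails <- adj[[h3]][bt[adj[[h3]]] == "t"]
    if (length(tails) != 1) stop("each h3 bead must carry exactly one tail")
    chain <- tails; prev <- h3
    while (length(chain) < 4) {
      nxt <- setdiff(adj[[chain[length(chain)]]], prev)
      if (length(nxt) != 1 || bt[nxt] != "t") stop("tails must be linear t chains")
      prev <- chain[length(chain)]; chain <- c(chain, nxt)
    }
    if (length(adj[[chain[4]]]) != 1) stop("tail ends must be terminal")
  }
  invisible(TRUE)
}

#' Armchair nanotube specification
#'
#' The four tubes studied are armchair CNTs with reduced diameters of
#' about 1.97, 2.67, 3.94 and 6.2 \eqn{r_C} for chiralities (10,10),
#' (14,14), (20,20) and (34,34). The coarse-grained mapping lumps eight
#' carbon atoms into one frozen bead, giving a surface bead density of
#' graphene's atom areal density divided by eight (about 4.77 nm^-2).
#'
#' @param chirality Integer pair `c(n, n)` or a single `n`; one of 10,
#'   14, 20, 34.
#' @param length Tube length in \eqn{r_C} (default 15.5).
#' @return Object of class `nanotube_spec`: list with `chirality`,
#'   `diameter` (rC), `length` (rC), `bead_surface_density` (per rC^2).
#' @export
#' @examples
#' nanotube_spec(20)$diameter  # 3.94
nanotube_spec <- function(chirality, length = 15.5) {
  n <- chirality[1]
  diam <- c(`10` = 1.97, `14` = 2.67, `20` = 3.94, `34` = 6.2)[as.character(n)]
  if (is.na(diam))
    stop("chirality must be one of the studied tubes: (10,10), (14,14), (20,20), (34,34)")
  if (length <= 0) stop("tube length must be positive")
  us <- default_unit_system()
  structure(list(
    chirality = c(n, n),
    diameter = unname(diam),
    length = length,
    bead_surface_density = 38.2 / 8 * us$rC_nm^2  # per rC^2
  ), class = "nanotube_spec")
}

#' Place frozen nanotube beads on a cylinder
#'
#' Beads are arranged on a triangular lattice wrapped onto a cylinder of
#' the specified diameter, axis along y, at the target areal bead
#' density. Row and circumferential counts are rounded to the nearest
#' lattice-commensurate values, so the realized density deviates from the
#' target only by lattice rounding.
#'
#' @param spec A [nanotube_spec()].
#' @param center Cylinder center `c(x, y, z)` in \eqn{r_C}.
#' @return List with `pos` (n x 3 matrix of bead centers), `radius`,
#'   `length` (realized axial extent), `center`.
#' @export
build_cnt <- function(spec, center = c(0, 0, 0)) {
  stopifnot(inherits(spec, "nanotube_spec"))
  if (spec$diameter <= 0 || spec$length <= 0)
    stop("tube diameter and length must be positive")
  R <- spec$diameter / 2
  dens <- spec$bead_surface_density
  a <- sqrt(2 / (sqrt(3) * dens))      # triangular lattice constant
  dy <- a * sqrt(3) / 2                # row spacing along the axis
  n_rows <- max(2L, as.integer(round(spec$length / dy)) + 1L)
  extent <- (n_rows - 1) * dy
  circ <- pi * spec$diameter
  n_c <- max(3L, as.integer(round(circ / a)))
  ys <- seq(-extent / 2, extent / 2, length.out = n_rows)
  pos <- matrix(0, nrow = n_rows * n_c, ncol = 3)
  k <- 1L
  for (r in seq_len(n_rows)) {
    phi0 <- if (r %% 2 == 0) pi / n_c else 0  # staggered rows
    phi <- phi0 + 2 * pi * (seq_len(n_c) - 1) / n_c
    idx <- k:(k + n_c - 1)
    pos[idx, 1] <- center[1] + R * cos(phi)
    pos[idx, 2] <- center[2] + ys[r]
    pos[idx, 3] <- center[3] + R * sin(phi)
    k <- k + n_c
  }
  list(pos = pos, radius = R, length = extent, center = center)
}

#' System specification
#'
#' A buildable simulation system: one (optional) nanotube substrate, a
#' lipid count, a water-bead count, the fixed box length along the tube
#' axis, and a seed. Box lengths perpendicular to the axis are derived at
#' build time so the mobile-bead density in the accessible volume (box
#' minus tube interior) is the reduced density 3.
#'
#' @param substrate A [nanotube_spec()] or `NULL` for a tube-free box.
#' @param n_lipids Number of DPPC molecules (>= 0).
#' @param n_water_beads Number of water beads (20,000 at full scale).
#' @param Ly Box length along the tube axis (default 22.5 rC); must
#'   exceed the tube length.
#' @param seed Integer seed; the build is bit-reproducible given the seed.
#' @param eq_box Optional reported equilibrium box size carried as
#'   metadata (not used by the builder).
#' @return Object of class `dpd_system_spec`.
#' @export
system_spec <- function(substrate = NULL, n_lipids = 0, n_water_beads = 20000,
                        Ly = 22.5, seed = 1, eq_box = NULL) {
  if (!is.null(substrate)) {
    stopifnot(inherits(substrate, "nanotube_spec"))
    if (Ly <= substrate$length)
      stop("Ly must exceed the tube length")
  }
  if (n_lipids < 0 || n_water_beads < 0) stop("bead counts must be non-negative")
  structure(list(substrate = substrate, n_lipids = as.integer(n_lipids),
                 n_water_beads = as.integer(n_water_beads), Ly = Ly,
                 target_kBT = 1, seed = as.integer(seed), eq_box = eq_box),
            class = "dpd_system_spec")
}

# extended reference conformation used as the rigid insertion template;
# bonds at their equilibrium lengths, head kink at its 120-degree minimum
lipid_template <- function() {
  h1 <- c(0, 0, 0)
  h2 <- c(0.47, 0, 0)
  h3a <- c(0.94, 0, 0)
  h3b <- h3a + c(0.31 * cos(pi / 3), 0.31 * sin(pi / 3), 0)
  t1 <- t(sapply(1:4, function(k) h3a + c(0.59 * k, 0, 0)))
  t2 <- t(sapply(1:4, function(k) h3b + c(0.59 * k, 0, 0)))
  rbind(h1, h2, h3a, h3b, t1, t2, deparse.level = 0)
}

#' Build a concrete particle configuration from a system specification
#'
#' The tube (if any) is placed first, centered in the box with its axis
#' along y. Lipids are inserted as rigid copies of the reference
#' conformation at random positions and orientations, then water beads,
#' by grid-accelerated rejection sampling with a minimum inter-bead
#' distance of `min_dist` and a cylindrical exclusion of the tube
#' interior over its axial extent. Initial velocities are drawn from the
#' Maxwell distribution at \eqn{k_BT = 1} with the net mobile momentum
#' removed; frozen beads have zero velocity. The build is deterministic
#' given the seed.
#'
#' @param spec A [system_spec()].
#' @param min_dist Minimum inter-bead distance at insertion (rC). The
#'   DPD potential is soft, so this is an initialization nicety only.
#' @param max_attempts Insertion attempts per molecule/bead before the
#'   build is declared infeasible.
#' @param box Optional explicit box lengths `c(Lx, Ly, Lz)`; by default
#'   the perpendicular lengths are derived so the accessible-volume
#'   density is 3. An explicit box permits dilute or vacuum systems.
#' @return Object of class `dpd_config`: list with `pos`, `vel` (n x 3),
#'   `type` (character), `type_id` (1..6), `mol_id`, `frozen`, `box`,
#'   `bonds`, `angles` (resolved per system), `tube` (geometry of the
#'   built tube or `NULL`), `n_lipids`, `n_water`, `spec`.
#' @export
build_system <- function(spec, min_dist = 0.5, max_attempts = 2000L,
                         box = NULL) {
  stopifnot(inherits(spec, "dpd_system_spec"))
  top <- build_dppc_topology()
  n_mobile <- spec$n_water_beads + 12L * spec$n_lipids

  tube <- NULL
  v_int <- 0
  if (!is.null(spec$substrate)) {
    R <- spec$substrate$diameter / 2
    v_int <- pi * R^2 * spec$substrate$length
  }
  if (is.null(box)) {
    Ly <- spec$Ly
    Lxz <- sqrt((n_mobile / 3 + v_int) / Ly)
    box <- c(Lxz, Ly, Lxz)
  }
  center <- box / 2

  if (!is.null(spec$substrate)) {
    tube <- build_cnt(spec$substrate, center = center)
    fixed <- tube$pos
    excl_r <- tube$radius
    excl_hl <- tube$length / 2
  } else {
    fixed <- matrix(numeric(0), ncol = 3)
    excl_r <- 0
    excl_hl <- 0
  }

  ins <- .insert_beads_cpp(fixed, box, excl_r, excl_hl, center,
                           lipid_template(), spec$n_lipids,
                           spec$n_water_beads, min_dist,
                           spec$seed, as.integer(max_attempts))

  n_cnt <- nrow(fixed)
  pos <- rbind(fixed, ins$lipid_pos, ins$water_pos)
  n <- nrow(pos)
  type <- c(rep("cnt", n_cnt),
            rep(top$bead_types, times = spec$n_lipids),
            rep("w", spec$n_water_beads))
  type_id <- match(type, bead_types()$name)
  frozen <- type == "cnt"
  mol_id <- c(rep(0L, n_cnt),
              rep(seq_len(spec$n_lipids), each = 12L),
              if (spec$n_water_beads > 0)
                spec$n_lipids + seq_len(spec$n_water_beads) else integer(0))

  # velocities: Maxwell at kBT = 1, zero net mobile momentum
  set.seed(spec$seed)
  vel <- matrix(0, nrow = n, ncol = 3)
  mob <- !frozen
  if (any(mob)) {
    v <- matrix(stats::rnorm(3 * sum(mob)), ncol = 3)
    v <- sweep(v, 2, colMeans(v))
    vel[mob, ] <- v
  }

  bonds <- angles <- NULL
  if (spec$n_lipids > 0) {
    offs <- n_cnt + 12L * (seq_len(spec$n_lipids) - 1L)
    bonds <- do.call(rbind, lapply(offs, function(o)
      cbind(top$bonds$i + o, top$bonds$j + o)))
    bond_k <- rep(top$bonds$k_bond, times = spec$n_lipids)
    bond_r0 <- rep(top$bonds$r0, times = spec$n_lipids)
    angles <- do.call(rbind, lapply(offs, function(o)
      cbind(top$angles$i + o, top$angles$j + o, top$angles$k + o)))
    angle_k <- rep(top$angles$k_angle, times = spec$n_lipids)
    angle_theta0 <- rep(top$angles$theta0, times = spec$n_lipids)
  } else {
    bonds <- matrix(integer(0), ncol = 2)
    bond_k <- bond_r0 <- numeric(0)
    angles <- matrix(integer(0), ncol = 3)
    angle_k <- angle_theta0 <- numeric(0)
  }

  structure(list(
    pos = pos, vel = vel, type = type, type_id = type_id,
    mol_id = mol_id, frozen = frozen, box = box,
    bonds = bonds, bond_k = bond_k, bond_r0 = bond_r0,
    angles = angles, angle_k = angle_k, angle_theta0 = angle_theta0,
    tube = tube, n_lipids = spec$n_lipids, n_water = spec$n_water_beads,
    spec = spec
  ), class = "dpd_config")
}

#' @export
print.dpd_config <- function(x, ...) {
  cat(sprintf("DPD configuration: %d beads (%d frozen), %d lipids, %d water\n",
              nrow(x$pos), sum(x$frozen), x$n_lipids, x$n_water))
  cat(sprintf("  box %.2f x %.2f x %.2f rC\n", x$box[1], x$box[2], x$box[3]))
  if (!is.null(x$tube))
    cat(sprintf("  tube: radius %.3f, length %.2f rC, %d beads\n",
                x$tube$radius, x$tube$length, nrow(x$tube$pos)))
  invisible(x)
}

# all 44 studied systems: substrate, lipid count, reported equilibrium box
.table2_data <- function() {
  eq <- c(
  "17.56 22.53 17.39", "17.66 22.55 17.68", "17.89 22.52 17.93",
  "18.20 22.53 18.10", "18.38 22.53 18.39", "18.66 22.55 18.56",
  "18.95 22.55 18.73", "18.51 22.56 19.62", "18.99 22.41 19.72",
  "18.91 22.48 20.18", "19.03 22.56 20.44",
  "17.49 22.55 17.52", "17.72 22.55 17.69", "17.91 22.53 17.97",
  "18.17 22.53 18.18", "18.41 22.52 18.42", "18.65 22.55 18.66",
  "18.93 22.45 18.88", "19.08 22.58 19.07", "19.27 22.65 19.28",
  "19.62 22.49 19.51", "19.70 22.56 19.79",
  "17.73 22.53 17.41", "17.65 22.55 17.86", "17.96 22.55 18.03",
  "18.32 22.59 18.14", "18.41 22.59 18.51", "18.70 22.55 18.66",
  "18.92 22.45 18.99", "19.08 22.59 19.15", "19.31 22.66 19.31",
  "18.44 22.51 20.83", "18.37 22.58 21.31",
  "17.76 22.55 17.56", "18.15 22.55 17.56", "18.19 22.53 17.99",
  "18.32 22.53 18.32", "18.58 22.52 18.52", "18.66 22.53 18.90",
  "18.97 22.55 19.08", "18.90 22.59 19.49", "19.66 22.44 19.31",
  "19.41 22.52 19.91", "19.80 22.59 19.89")
  m <- do.call(rbind, lapply(strsplit(eq, " "), as.numeric))
  data.frame(
    chirality = rep(c(10, 14, 20, 34), each = 11),
    n_lipids = rep(c(10, 50, 100, 150, 200, 250, 300, 350, 400, 450, 500), 4),
    eq_Lx = m[, 1], eq_Ly = m[, 2], eq_Lz = m[, 3]
  )
}

#' Catalog of the 44 studied systems
#'
#' Enumerates every substrate x lipid-count combination of the study: the
#' four armchair tubes, eleven lipid loadings from 10 to 500, 20,000
#' water beads throughout. Each entry carries the reported equilibrium
#' box size as metadata.
#'
#' @param seed Seed recorded in every spec.
#' @return List of 44 [system_spec()] objects.
#' @export
#' @examples
#' length(table2_catalog())  # 44
table2_catalog <- function(seed = 1) {
  d <- .table2_data()
  lapply(seq_len(nrow(d)), function(r)
    system_spec(substrate = nanotube_spec(d$chirality[r]),
                n_lipids = d$n_lipids[r], n_water_beads = 20000,
                Ly = 22.5, seed = seed,
                eq_box = c(d$eq_Lx[r], d$eq_Ly[r], d$eq_Lz[r])))
}

#' Catalog as a data frame
#'
#' @return Data frame with one row per studied system: `chirality`,
#'   `n_lipids`, `n_water_beads`, reported equilibrium box lengths.
#' @export
table2_catalog_df <- function() {
  d <- .table2_data()
  d$n_water_beads <- 20000L
  d
}

#' Scaled-down preset of a cataloged system
#'
#' Returns a miniature of a named full-scale system: box volume scaled by
#' `scale`, bead counts scaled proportionally (preserving the reduced
#' density 3 and the lipid:water ratio), tube length and axial box length
#' scaled by `scale^(1/3)`; tube diameter is intensive and kept.
#'
#' @param name Preset name of the form `"cnt2020_300"`
#'   (chirality 20, 300 lipids at full scale).
#' @param scale Volume fraction in (0, 1].
#' @param seed Seed for the build.
#' @return A [system_spec()].
#' @export
#' @examples
#' scaled_preset("cnt2020_300", 0.125)$n_water_beads  # 2500
scaled_preset <- function(name, scale = 0.125, seed = 1) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  m <- regmatches(name, regexec("^cnt([0-9]+)_([0-9]+)$", name))[[1]]
  if (length(m) != 3) stop("preset name must look like 'cnt2020_300'")
  digits <- m[2]
  half <- nchar(digits) / 2
  if (half != floor(half) ||
      substr(digits, 1, half) != substr(digits, half + 1, 2 * half))
    stop("chirality in the preset name must be an armchair pair, e.g. 'cnt2020'")
  chir <- as.integer(substr(digits, 1, half)); nl <- as.integer(m[3])
  d <- .table2_data()
  if (!any(d$chirality == chir & d$n_lipids == nl))
    stop("no such cataloged system: ", name)
  lin <- scale^(1 / 3)
  system_spec(substrate = nanotube_spec(chir, length = 15.5 * lin),
              n_lipids = round(nl * scale),
              n_water_beads = round(20000 * scale),
              Ly = 22.5 * lin, seed = seed)
}
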