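#' Bead types of the coarse-grained model
#'
#' The model distinguishes six bead species: three lipid head-group beads
#' (`h1` choline-like, `h2` phosphate-like, `h3` glycerol-like), the
#' hydrocarbon tail bead `t`, the water bead `w` (four water molecules per
#' bead), and the nanotube bead `cnt` (eight carbon atoms per bead). All
#' mobile beads carry unit reduced mass; `cnt` beads are frozen in place
#' during dynamics.
#'
#' @return A data frame with columns `name`, `mass` and `frozen`, one row
#'   per bead type, in the canonical order `h1, h2, h3, t, w, cnt`.
#' @export
#' @examples
#' bead_types()
bead_types <- function() {
  data.frame(
    name   = c("h1", "h2", "h3", "t", "w", "cnt"),
    mass   = rep(1, 6),
    frozen = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Maximum-repulsion matrix and thermostat constants
#'
#' Returns the full DPD interaction model: the symmetric 6x6 matrix of
#' maximum repulsions \eqn{a_{ij}} (units \eqn{k_BT/r_C}) between all bead
#' species, the cutoff \eqn{r_C = 1} and thermal energy \eqn{k_BT = 1} in
#' reduced units, and the thermostat pair (dissipation strength
#' \eqn{\gamma}, noise strength \eqn{\sigma}) tied by the
#' fluctuation-dissipation relation \eqn{\sigma^2 = 2\gamma k_BT}.
#'
#' Like-bead repulsions are 100 except for the two charged head beads
#' (`h1`, `h2`) whose self-repulsion is raised to 110 to fold mean-field
#' electrostatic repulsion into the soft potential. The strongly
#' hydrophobic contacts (tail-water, head-tail, head-cnt) sit at 130.
#'
#' @param gamma Dissipation strength \eqn{\gamma} (default 4.5, standard
#'   DPD practice); \eqn{\sigma} is derived, never set independently.
#' @return An object of class `dpd_interaction_model`: a list with
#'   elements `a` (named 6x6 matrix), `rC`, `kBT`, `gamma`, `sigma`.
#' @export
#' @examples
#' m <- default_interaction_model()
#' m$a["t", "w"]   # tail-water repulsion, 130
default_interaction_model <- function(gamma = 4.5) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  nm <- bead_types()$name
  a <- matrix(c(
    # h1   h2   h3    t    w  cnt
    110, 100, 102, 130,  98, 130, # h1
    100, 110, 102, 130,  98, 130, # h2
    102, 102, 100, 110, 102, 110, # h3
    130, 130, 110, 100, 130, 100, # t
     98,  98, 102, 130, 100, 130, # w
    130, 130, 110, 100, 130, 100  # cnt
  ), nrow = 6, byrow = TRUE, dimnames = list(nm, nm))
  structure(
    list(a = a, rC = 1, kBT = 1, gamma = gamma, sigma = sqrt(2 * gamma * 1)),
    class = "dpd_interaction_model"
  )
}

#' @export
print.dpd_interaction_model <- function(x, ...) {
  cat("DPD interaction model (reduced units)\n")
  cat(sprintf("  rC = %g, kBT = %g, gamma = %g, sigma = %g (sigma^2 = 2 gamma kBT)\n",
              x$rC, x$kBT, x$gamma, x$sigma))
  cat("  maximum repulsions a_ij [kBT/rC]:\n")
  print(x$a)
  invisible(x)
}

#' Harmonic bond terms of the lipid model
#'
#' All bonds share one force constant (512 \eqn{k_BT/r_C^2}); equilibrium
#' lengths depend on the bonded pair: 0.47 within the head group, 0.31 for
#' the short glycerol-glycerol link, and 0.59 along the hydrocarbon tails.
#'
#' @return Data frame with columns `type_i`, `type_j`, `k_bond`, `r0`.
#' @export
bond_terms <- function() {
  data.frame(
    type_i = c("h1", "h2", "h3", "h3", "t"),
    type_j = c("h2", "h3", "h3", "t", "t"),
    k_bond = rep(512, 5),
    r0     = c(0.47, 0.47, 0.31, 0.59, 0.59),
    stringsAsFactors = FALSE
  )
}

#' Angle-bending terms of the lipid model
#'
#' Cosine bending potential \eqn{u = \tfrac12 k (1 - \cos(\theta -
#' \theta_0))} with \eqn{k = 6\,k_BT} for every listed triple. The head
#' kink `h2-h3-h3` prefers 120 degrees; all chain triples are straight
#' (180 degrees).
#'
#' @return Data frame with columns `type_i`, `type_j`, `type_k`
#'   (`type_j` central), `k_angle`, `theta0` (degrees).
#' @export
angle_terms <- function() {
  data.frame(
    type_i  = c("h2", "h2", "h3", "t"),
    type_j  = c("h3", "h3", "t", "t"),
    type_k  = c("h3", "t", "t", "t"),
    k_angle = rep(6, 4),
    theta0  = c(120, 180, 180, 180),
    stringsAsFactors = FALSE
  )
}

#' Reduced-unit system and physical mapping
#'
#' One water bead lumps four water molecules (volume 0.12 nm^3) and the
#' reduced bead number density is \eqn{\rho = 3}, which fixes the physical
#' cutoff length \eqn{r_C = (\rho v_{bead})^{1/3}} nm. The value is stored
#' at full precision; it rounds to 0.71 nm.
#'
#' @return List with `rC_nm`, `beads_per_rC3`, `water_bead_volume_nm3`.
#' @export
#' @examples
#' round(default_unit_system()$rC_nm, 2)  # 0.71
default_unit_system <- function() {
  rho <- 3
  v <- 0.12
  list(rC_nm = derive_rc_nm(rho, v), beads_per_rC3 = rho,
       water_bead_volume_nm3 = v)
}

#' Physical cutoff length from the water mapping
#'
#' With `rho` beads per cubic cutoff length and `bead_volume` nm^3 per
#' bead, the cube of the cutoff must hold `rho` bead volumes, hence
#' \eqn{r_C = (\rho v)^{1/3}} in nm.
#'
#' @param rho Reduced bead number density (beads per \eqn{r_C^3}).
#' @param bead_volume Physical volume of one bead in nm^3.
#' @return Cutoff length in nm.
#' @export
#' @examples
#' derive_rc_nm(3, 0.12)  # 0.711..., rounds to 0.71
derive_rc_nm <- function(rho, bead_volume) {
  stopifnot(is.numeric(rho), is.numeric(bead_volume))
  if (any(rho <= 0) || any(bead_volume <= 0))
    stop("rho and bead_volume must be positive")
  (rho * bead_volume)^(1 / 3)
}

#' Convert a surface density between reduced and physical units
#'
#' Surface densities of adsorbed lipids are naturally reported per
#' \eqn{r_C^2}; dividing by \eqn{r_{C,nm}^2} converts to per nm^2.
#'
#' @param rho_surface Non-negative surface density; per \eqn{r_C^2} when
#'   `inverse = FALSE`, per nm^2 when `inverse = TRUE`.
#' @param units Unit system, see [default_unit_system()].
#' @param inverse If `TRUE`, convert from per nm^2 back to per
#'   \eqn{r_C^2}.
#' @return Converted surface density.
#' @export
#' @examples
#' convert_surface_density(1.22)  # about 2.43 nm^-2
convert_surface_density <- function(rho_surface, units = default_unit_system(),
                                    inverse = FALSE) {
  stopifnot(is.numeric(rho_surface))
  if (any(rho_surface < 0)) stop("surface density must be non-negative")
  if (inverse) rho_surface * units$rC_nm^2 else rho_surface / units$rC_nm^2
}

#' Write or read the shipped parameter configuration
#'
#' The full parameter set (repulsion matrix, bonded terms, unit system) is
#' serialized as a versioned YAML document. `read_parameter_config()`
#' validates the schema and checks the values against the in-code tables.
#'
#' @param path File path of the YAML document.
#' @param gamma Dissipation strength recorded in the document.
#' @return `write_parameter_config()` returns `path` invisibly;
#'   `read_parameter_config()` returns a list mirroring
#'   [default_interaction_model()], [bond_terms()], [angle_terms()] and
#'   [default_unit_system()].
#' @export
write_parameter_config <- function(path, gamma = 4.5) {
  m <- default_interaction_model(gamma)
  doc <- list(
    schema = "dpdcnt-parameters/1",
    interaction = list(
      rC = m$rC, kBT = m$kBT, gamma = m$gamma, sigma = m$sigma,
      bead_order = rownames(m$a),
      a = apply(m$a, 1, as.list, simplify = FALSE)
    ),
    bonds = unname(split(bond_terms(), seq_len(nrow(bond_terms())))),
    angles = unname(split(angle_terms(), seq_len(nrow(angle_terms())))),
    units = default_unit_system()
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_parameter_config
#' @export
read_parameter_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$schema, "dpdcnt-parameters/1"))
    stop("unrecognized parameter schema: ", doc$schema)
  nm <- unlist(doc$interaction$bead_order)
  a <- do.call(rbind, lapply(doc$interaction$a, function(r) unlist(r)))
  dimnames(a) <- list(nm, nm)
  ref <- default_interaction_model(doc$interaction$gamma)
  if (!isTRUE(all.equal(a[rownames(ref$a), colnames(ref$a)], ref$a)))
    stop("parameter config disagrees with the packaged repulsion matrix")
  list(
    interaction = ref,
    bonds = do.call(rbind, lapply(doc$bonds, as.data.frame)),
    angles = do.call(rbind, lapply(doc$angles, as.data.frame)),
    units = doc$units
  )
}
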