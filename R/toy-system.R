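#' Generator parameters for a synthetic ligand-receptor bead system
#'
#' The defaults describe the shipped demo receptor: a restrained 5x5 bead
#' surface plate with its centre bead removed, three "cleft" beads recessed
#' below the resulting mouth (analogs of the pocket-lining residues
#' Val75/Phe93/Phe96), and a weakly restrained three-bead C-terminal tail
#' analog attached at one corner. The ligand is a bead chain whose leading
#' beads form the "head" (ring-A analog) and trailing beads the "tail"
#' (ring-BC analog).
#'
#' `cleft_eps_mult` scales the Lennard-Jones well depth between cleft beads
#' and ligand-head beads relative to the generic surface value `eps`; a
#' multiplier of 1 removes any pocket preference (the "uniform affinity"
#' control ligand).
#'
#' @param n_surface surface plate is `n_surface x n_surface` beads.
#' @param surface_spacing bead spacing of the plate (Angstrom).
#' @param pocket_depth depth of the central cleft bead below the plate (A).
#' @param n_ligand number of ligand beads (>= 2).
#' @param ligand_spacing ligand bond length (A).
#' @param head_size,tail_size bead counts of the ligand head/tail groups.
#' @param eps generic Lennard-Jones well depth (kcal/mol).
#' @param sigma Lennard-Jones diameter (A), shared by all type pairs.
#' @param cleft_eps_mult multiplier on `eps` for cleft-head pairs.
#' @param bond_k,angle_k ligand bond and angle stiffness (kcal/mol/A^2,
#'   kcal/mol/rad^2). Large `angle_k` makes a stiff rod.
#' @param core_restraint_k position-restraint stiffness pinning the receptor
#'   frame (kcal/mol/A^2).
#' @param tail_restraint_k weak position restraint on the tail analog.
#' @param mass bead mass (amu).
#' @return a list of class `"toy_spec"`.
#' @export
toy_spec <- function(n_surface = 5, surface_spacing = 3.0, pocket_depth = 4.0,
                     n_ligand = 4, ligand_spacing = 2.0,
                     head_size = 2, tail_size = 2,
                     eps = 0.2, sigma = 2.8, cleft_eps_mult = 15,
                     bond_k = 50, angle_k = 1,
                     core_restraint_k = 10, tail_restraint_k = 0.5,
                     mass = 12) {
  spec <- list(n_surface = n_surface, surface_spacing = surface_spacing,
               pocket_depth = pocket_depth, n_ligand = n_ligand,
               ligand_spacing = ligand_spacing, head_size = head_size,
               tail_size = tail_size, eps = eps, sigma = sigma,
               cleft_eps_mult = cleft_eps_mult, bond_k = bond_k,
               angle_k = angle_k, core_restraint_k = core_restraint_k,
               tail_restraint_k = tail_restraint_k, mass = mass)
  class(spec) <- "toy_spec"
  spec
}

#' Build a synthetic coarse-grained ligand-receptor complex
#'
#' Constructs a bead receptor with a concave pocket plus a bead-chain ligand,
#' with harmonic bonds/angles, per-type-pair Lennard-Jones parameters, named
#' bead groups, and position restraints pinning the receptor frame and the
#' tail analog. Deterministic for a fixed seed (the seed only jitters the
#' ligand placement to break the exact axial symmetry of the construction).
#'
#' @param spec a [toy_spec()] list.
#' @param seed integer seed for the placement jitter.
#' @return an object of class `"toy_system"` with fields `coords` (N x 3
#'   matrix, Angstrom), `masses`, `bead_types`, `bonds`, `angles`,
#'   `nonbonded` (per-type-pair epsilon/sigma table), `groups` (named index
#'   sets), and `restraints`.
#' @export
build_toy_complex <- function(spec = toy_spec(), seed = 1) {
  if (spec$n_ligand < 2)
    stop("invalid spec: ligand must have at least 2 beads (head/tail undefined)")
  if (spec$head_size < 1 || spec$tail_size < 1)
    stop("invalid spec: head and tail groups need at least one bead each")
  if (spec$head_size + spec$tail_size > spec$n_ligand)
    stop("invalid spec: head and tail groups exceed the ligand bead count")

  ns <- spec$n_surface
  sp <- spec$surface_spacing
  half <- (ns - 1) / 2
  gx <- rep(seq(-half, half) * sp, times = ns)
  gy <- rep(seq(-half, half) * sp, each = ns)
  keep <- !(abs(gx) < sp / 2 & abs(gy) < sp / 2)   # remove the centre bead
  surface <- cbind(gx[keep], gy[keep], 0)

  d <- spec$pocket_depth
  cleft <- rbind(c(0, 0, -d),                       # bottom (Val75 analog)
                 c(0.6 * sp, 0, -(d - 1)),          # side (Phe93 analog)
                 c(-0.6 * sp, 0, -(d - 1)))         # side (Phe96 analog)

  corner <- c(half * sp, half * sp, 0)
  tail_an <- rbind(corner + c(0, 0, 2), corner + c(0, 0, 4), corner + c(0, 0, 6))

  set.seed(seed)
  jit <- matrix(rnorm(spec$n_ligand * 3, sd = 0.02), ncol = 3)
  lig_z0 <- 8
  lig <- cbind(0, 0, lig_z0 + (seq_len(spec$n_ligand) - 1) * spec$ligand_spacing) + jit

  coords <- rbind(surface, cleft, tail_an, lig)
  n_sur <- nrow(surface)
  i_cleft <- n_sur + 1:3
  i_tail <- n_sur + 3 + 1:3
  i_lig <- n_sur + 6 + seq_len(spec$n_ligand)
  n <- nrow(coords)

  bead_types <- c(rep("RS", n_sur), rep("CL", 3), rep("RT", 3),
                  rep("LB", spec$n_ligand))
  bead_types[i_lig[seq_len(spec$head_size)]] <- "LH"
  bead_types[i_lig[spec$n_ligand - seq_len(spec$tail_size) + 1]] <- "LT"

  # bonds: tail chain anchored at the corner surface bead; ligand chain
  corner_id <- which(surface[, 1] == corner[1] & surface[, 2] == corner[2])
  bonds <- rbind(
    data.frame(i = c(corner_id, i_tail[1], i_tail[2]),
               j = c(i_tail[1], i_tail[2], i_tail[3]),
               k = 25, r0 = 2.0),
    if (spec$n_ligand >= 2)
      data.frame(i = i_lig[-spec$n_ligand], j = i_lig[-1],
                 k = spec$bond_k, r0 = spec$ligand_spacing)
  )
  angles <- if (spec$n_ligand >= 3) {
    data.frame(i = i_lig[seq_len(spec$n_ligand - 2)],
               j = i_lig[1 + seq_len(spec$n_ligand - 2)],
               k = i_lig[2 + seq_len(spec$n_ligand - 2)],
               ka = spec$angle_k, theta0 = pi)
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               ka = numeric(), theta0 = numeric())
  }

  types <- c("RS", "CL", "RT", "LH", "LB", "LT")
  nb <- expand.grid(type1 = types, type2 = types, stringsAsFactors = FALSE)
  nb <- nb[match(nb$type1, types) <= match(nb$type2, types), ]
  nb$eps <- spec$eps
  nb$sigma <- spec$sigma
  is_cleft_head <- (nb$type1 == "CL" & nb$type2 == "LH") |
    (nb$type1 == "LH" & nb$type2 == "CL")
  nb$eps[is_cleft_head] <- spec$eps * spec$cleft_eps_mult
  rownames(nb) <- NULL

  groups <- list(
    receptor_core = c(seq_len(n_sur), i_cleft),
    tail = i_tail,
    cleft = i_cleft,
    cleft_V75 = i_cleft[1], cleft_F93 = i_cleft[2], cleft_F96 = i_cleft[3],
    ligand = i_lig,
    ligand_head = i_lig[seq_len(spec$head_size)],
    ligand_tail = i_lig[spec$n_ligand - seq_len(spec$tail_size) + 1],
    ligand_ringA = i_lig[seq_len(spec$head_size)]
  )

  restraints <- list(
    list(ids = groups$receptor_core,
         anchors = coords[groups$receptor_core, , drop = FALSE],
         k = spec$core_restraint_k),
    list(ids = i_tail, anchors = coords[i_tail, , drop = FALSE],
         k = spec$tail_restraint_k)
  )

  sys <- list(coords = coords, masses = rep(spec$mass, n),
              bead_types = bead_types, bonds = bonds, angles = angles,
              nonbonded = nb, groups = groups, restraints = restraints,
              spec = spec)
  class(sys) <- "toy_system"
  validate_toy_system(sys)
  sys
}

#' Build a reduced two-bead system (one receptor group, one ligand group)
#'
#' The minimal system used for analytic validation: two beads joined by a
#' harmonic bond and/or a Lennard-Jones pair, whose single centre-of-mass
#' distance reaction coordinate has a closed-form Boltzmann density
#' (see [analytic_rc_boltzmann()]).
#'
#' @param bond_k,r0 harmonic bond stiffness (kcal/mol/A^2) and rest length
#'   (A); `bond_k = 0` omits the bond (the pair then interacts through the
#'   Lennard-Jones term).
#' @param eps,sigma Lennard-Jones parameters for the pair; ignored when a
#'   bond is present (bonded pairs are excluded from the nonbonded sum).
#' @param mass bead mass (amu).
#' @param r_start initial separation (A).
#' @return a `"toy_system"` with groups `receptor` (bead 1) and `ligand`
#'   (bead 2).
#' @export
build_pair_system <- function(bond_k = 0.5, r0 = 6, eps = 0.2, sigma = 2.8,
                              mass = 12, r_start = r0) {
  coords <- rbind(c(0, 0, 0), c(r_start, 0, 0))
  bonds <- if (bond_k > 0) data.frame(i = 1L, j = 2L, k = bond_k, r0 = r0)
  else data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
  nb <- data.frame(type1 = c("A", "A", "B"), type2 = c("A", "B", "B"),
                   eps = eps, sigma = sigma)
  sys <- list(coords = coords, masses = rep(mass, 2),
              bead_types = c("A", "B"), bonds = bonds,
              angles = data.frame(i = integer(), j = integer(), k = integer(),
                                  ka = numeric(), theta0 = numeric()),
              nonbonded = nb,
              groups = list(receptor = 1L, ligand = 2L),
              restraints = list(), spec = NULL)
  class(sys) <- "toy_system"
  sys
}

#' Validate the internal consistency of a toy system
#'
#' Checks index validity, group containment (e.g. ligand_head within ligand),
#' receptor/ligand disjointness, and parameter sign constraints.
#'
#' @param sys a `"toy_system"`.
#' @return `sys`, invisibly; stops on violation.
#' @export
validate_toy_system <- function(sys) {
  n <- nrow(sys$coords)
  stopifnot(length(sys$masses) == n, length(sys$bead_types) == n)
  idx <- c(unlist(sys$groups), sys$bonds$i, sys$bonds$j,
           sys$angles$i, sys$angles$j, sys$angles$k)
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("toy_system: bead index out of range")
  if (any(sys$bonds$k < 0) || any(sys$angles$ka < 0))
    stop("toy_system: negative bonded stiffness")
  if (any(sys$nonbonded$eps < 0) || any(sys$nonbonded$sigma <= 0))
    stop("toy_system: nonbonded parameters require eps >= 0, sigma > 0")
  g <- sys$groups
  if (!is.null(g$ligand)) {
    for (nm in c("ligand_head", "ligand_tail", "ligand_ringA"))
      if (!is.null(g[[nm]]) && !all(g[[nm]] %in% g$ligand))
        stop("toy_system: group ", nm, " not contained in ligand")
    if (!is.null(g$receptor_core) && length(intersect(g$receptor_core, g$ligand)))
      stop("toy_system: receptor and ligand bead sets overlap")
  }
  for (r in sys$restraints) {
    if (r$k < 0) stop("toy_system: negative restraint stiffness")
    if (nrow(r$anchors) != length(r$ids))
      stop("toy_system: restraint anchor count mismatch")
  }
  invisible(sys)
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Coarse-grained toy system:", nrow(x$coords), "beads\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " restrained sets:", length(x$restraints), "\n")
  cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  invisible(x)
}

# Nonbonded pair list with 1-2 (bond) and 1-3 (angle-end) exclusions,
# plus restraint arrays and wall specs, in the layout the C++ core expects.
.topology <- function(sys, walls = NULL) {
  n <- nrow(sys$coords)
  excl <- character(0)
  if (nrow(sys$bonds))
    excl <- c(excl, paste(pmin(sys$bonds$i, sys$bonds$j),
                          pmax(sys$bonds$i, sys$bonds$j)))
  if (nrow(sys$angles))
    excl <- c(excl, paste(pmin(sys$angles$i, sys$angles$k),
                          pmax(sys$angles$i, sys$angles$k)))
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  keep <- !(paste(pi_, pj_) %in% excl)
  pi_ <- pi_[keep]; pj_ <- pj_[keep]

  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  nbkey <- key(sys$nonbonded$type1, sys$nonbonded$type2)
  pk <- key(sys$bead_types[pi_], sys$bead_types[pj_])
  m <- match(pk, nbkey)
  if (anyNA(m)) stop("toy_system: missing nonbonded parameters for type pair ",
                     pk[which(is.na(m))[1]])
  eps <- sys$nonbonded$eps[m]
  sig <- sys$nonbonded$sigma[m]
  live <- eps > 0
  pairs <- cbind(pi_[live], pj_[live])
  ppar <- cbind(eps[live], sig[live])
  if (!nrow(pairs)) { pairs <- matrix(0L, 0, 2); ppar <- matrix(0, 0, 2) }

  r_idx <- integer(0); r_anchor <- matrix(0, 0, 3); r_k <- numeric(0)
  for (r in sys$restraints) {
    r_idx <- c(r_idx, r$ids)
    r_anchor <- rbind(r_anchor, r$anchors)
    r_k <- c(r_k, rep(r$k, length(r$ids)))
  }

  list(
    bonds = if (nrow(sys$bonds)) cbind(sys$bonds$i, sys$bonds$j) else matrix(0L, 0, 2),
    bpar = if (nrow(sys$bonds)) cbind(sys$bonds$k, sys$bonds$r0) else matrix(0, 0, 2),
    angles = if (nrow(sys$angles)) cbind(sys$angles$i, sys$angles$j, sys$angles$k) else matrix(0L, 0, 3),
    apar = if (nrow(sys$angles)) cbind(sys$angles$ka, sys$angles$theta0) else matrix(0, 0, 2),
    pairs = pairs, ppar = ppar,
    rest_idx = r_idx, rest_anchor = r_anchor, rest_k = r_k,
    walls = if (is.null(walls)) list() else walls
  )
}

# Wall specs for the C++ core from RC definitions + per-RC [lo, hi] bounds.
.wall_specs <- function(sys, rc_defs, bounds, wall_k) {
  lapply(seq_along(rc_defs), function(h) {
    rc <- rc_defs[[h]]
    list(ia = rc$group_A, wa = .center_weights(rc$group_A, rc$weighting, sys$masses),
         ib = rc$group_B, wb = .center_weights(rc$group_B, rc$weighting, sys$masses),
         lo = bounds[h, 1], hi = bounds[h, 2], k = wall_k)
  })
}

.center_weights <- function(ids, weighting, masses) {
  if (weighting == "mass") masses[ids] / sum(masses[ids])
  else rep(1 / length(ids), length(ids))
}

#' Potential energy and forces of a toy system
#'
#' Energy is the sum of harmonic bonds `k_b (r - r0)^2`, harmonic angles
#' `k_a (theta - theta0)^2`, Lennard-Jones `4 eps ((sigma/r)^12 -
#' (sigma/r)^6)` over nonbonded pairs (1-2 and 1-3 neighbours excluded, no
#' cutoff), and position restraints `k_r |x - x_ref|^2`. Forces are the
#' analytic negative gradient.
#'
#' @param sys a `"toy_system"`.
#' @param coords N x 3 coordinate matrix; defaults to `sys$coords`.
#' @param walls optional list of wall specs (internal use by the sampler).
#' @return list with `energy` (kcal/mol) and `forces` (N x 3, kcal/mol/A).
#' @export
potential_energy <- function(sys, coords = sys$coords, walls = NULL) {
  if (nrow(coords) != nrow(sys$coords))
    stop("coords length does not match the system")
  t <- .topology(sys, walls)
  cpp_energy_forces(coords, t$bonds, t$bpar, t$angles, t$apar, t$pairs, t$ppar,
                    as.integer(t$rest_idx), t$rest_anchor, t$rest_k, t$walls)
}

#' Langevin dynamics parameters
#'
#' @param temperature simulation temperature (K).
#' @param dt integration time step (fs).
#' @param friction Langevin friction (1/ps).
#' @param wall_k half-harmonic zone/window wall stiffness (kcal/mol/A^2).
#' @return a list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(temperature = 300, dt = 2, friction = 1,
                            wall_k = 10) {
  stopifnot(temperature > 0, dt > 0, friction > 0, wall_k >= 0)
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 wall_k = wall_k), class = "dynamics_params")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param sys a `"toy_system"`.
#' @param temperature temperature (K).
#' @return N x 3 matrix of velocities (A/fs), drawn from the current RNG
#'   state.
#' @export
maxwell_velocities <- function(sys, temperature) {
  n <- nrow(sys$coords)
  sig <- sqrt(.kB * temperature / (sys$masses / 4.184e-4))
  matrix(rnorm(3 * n), ncol = 3) * sig
}

#' Propagate a toy system with BAOAB Langevin dynamics
#'
#' The BAOAB splitting samples the configurational canonical distribution
#' exactly in the harmonic limit, which the downstream reweighting relies
#' on. Optional half-harmonic walls confine centre-of-mass distance reaction
#' coordinates to a window; the walls are identically zero inside the
#' window, so the confined distribution is the unmodified canonical law
#' restricted to it.
#'
#' @param sys a `"toy_system"`.
#' @param start list with `coords` (N x 3) and optionally `vels`; missing
#'   velocities are drawn from the Maxwell-Boltzmann law.
#' @param n_steps number of steps (>= 0).
#' @param params a [dynamics_params()] object.
#' @param walls optional data.frame-like spec: needs `rc_defs` plus a
#'   `bounds` matrix (one `[lo, hi]` row per RC); pass via
#'   `list(rc_defs = , bounds = )`.
#' @param snapshot_interval store a snapshot every this many steps.
#' @param rc_defs optional RC definitions; when given, each snapshot carries
#'   its RC values.
#' @return a `"trajectory_segment"`: list with `snapshots` (list of N x 3
#'   matrices), `steps`, `rc` (matrix or NULL), `start`, `coords`, `vels`
#'   (final state), `n_steps`.
#' @export
langevin_segment <- function(sys, start, n_steps, params,
                             walls = NULL, snapshot_interval = 1000,
                             rc_defs = NULL) {
  stopifnot(n_steps >= 0, snapshot_interval > 0)
  coords <- start$coords
  vels <- start$vels
  if (is.null(vels)) vels <- maxwell_velocities(sys, params$temperature)

  wall_list <- list()
  if (!is.null(walls))
    wall_list <- .wall_specs(sys, walls$rc_defs, walls$bounds, params$wall_k)

  if (n_steps == 0) {
    seg <- list(snapshots = list(), steps = integer(0), rc = NULL,
                start = list(coords = coords, vels = vels),
                coords = coords, vels = vels, n_steps = 0L)
    class(seg) <- "trajectory_segment"
    return(seg)
  }

  t <- .topology(sys, wall_list)
  out <- tryCatch(
    cpp_baoab(coords, vels, sys$masses, as.integer(n_steps), params$dt,
              params$friction / 1000, .kB * params$temperature,
              as.integer(snapshot_interval),
              t$bonds, t$bpar, t$angles, t$apar, t$pairs, t$ppar,
              as.integer(t$rest_idx), t$rest_anchor, t$rest_k, t$walls),
    error = function(e) stop("integration failure: ", conditionMessage(e),
                             call. = FALSE))
  n <- nrow(coords)
  n_snap <- length(out$snap_steps)
  snaps <- vector("list", n_snap)
  for (s in seq_len(n_snap))
    snaps[[s]] <- out$snapshots[((s - 1) * n + 1):(s * n), , drop = FALSE]
  rc <- NULL
  if (!is.null(rc_defs) && n_snap > 0) {
    m <- vapply(snaps, function(x) rc_values(rc_defs, x, sys$masses),
                numeric(length(rc_defs)))
    rc <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
  }
  seg <- list(snapshots = snaps, steps = out$snap_steps, rc = rc,
              start = list(coords = coords, vels = vels),
              coords = out$coords, vels = out$vels, n_steps = as.integer(n_steps))
  class(seg) <- "trajectory_segment"
  seg
}

#' Analytic Boltzmann density of a separable two-group reaction coordinate
#'
#' For a reduced system whose configurational integral separates into the
#' inter-group distance `r` (a free relative vector in 3D), the canonical
#' density is `p(r) proportional to r^2 exp(-U(r)/kT)`. The density is
#' evaluated on `r_grid` and trapezoid-normalised so that its integral over
#' `r_grid` equals 1 (to better than 1e-8 by construction).
#'
#' @param sys a two-bead `"toy_system"` from [build_pair_system()], or NULL
#'   when `potential` is supplied directly.
#' @param temperature temperature (K).
#' @param r_grid increasing grid of distances (A) bounding the domain.
#' @param potential optional vectorised function `U(r)` (kcal/mol)
#'   overriding the system's pair potential.
#' @return list of class `"rc_density"` with `r`, `density`, `temperature`.
#' @export
analytic_rc_boltzmann <- function(sys = NULL, temperature = 300,
                                  r_grid, potential = NULL) {
  stopifnot(length(r_grid) >= 3, all(diff(r_grid) > 0))
  if (is.null(potential)) {
    if (is.null(sys) || nrow(sys$coords) != 2)
      stop("analytic reference requires a two-bead system or an explicit potential")
    if (length(sys$restraints))
      stop("restraints break the separability of the pair distance")
    potential <- function(r) {
      vapply(r, function(ri) {
        potential_energy(sys, rbind(c(0, 0, 0), c(ri, 0, 0)))$energy
      }, numeric(1))
    }
  }
  u <- potential(r_grid)
  if (any(!is.finite(u) & u < 0)) stop("non-normalizable: potential diverges to -Inf")
  w <- r_grid^2 * exp(-(u - min(u[is.finite(u)])) / (.kB * temperature))
  w[!is.finite(w)] <- 0
  z <- sum((w[-1] + w[-length(w)]) / 2 * diff(r_grid))
  if (!is.finite(z) || z <= 0)
    stop("non-normalizable: Boltzmann weight has no mass on the domain")
  structure(list(r = r_grid, density = w / z, temperature = temperature),
            class = "rc_density")
}

#' Integrate an rc_density over bins (bin probability masses)
#'
#' @param dens an `"rc_density"`.
#' @param edges increasing bin edges covering (a subset of) the density grid.
#' @return numeric vector of bin masses (trapezoid quadrature on the density
#'   grid restricted to each bin).
#' @export
rc_density_bin_mass <- function(dens, edges) {
  vapply(seq_len(length(edges) - 1), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    rr <- sort(unique(c(lo, hi, dens$r[dens$r > lo & dens$r < hi])))
    dd <- approx(dens$r, dens$density, xout = rr, rule = 2)$y
    sum((dd[-1] + dd[-length(dd)]) / 2 * diff(rr))
  }, numeric(1))
}
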