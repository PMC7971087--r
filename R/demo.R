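#' Configuration of the shipped demo systems
#'
#' Two study systems are shipped. The `"binder"` ligand is a short,
#' flexible four-bead chain whose two head beads (the ring-A analog) have a
#' deep Lennard-Jones well with the cleft-lining beads, so it can insert
#' its head into the pocket. The `"rod"` ligand is a longer, stiff six-bead
#' chain with uniform affinity everywhere (cleft multiplier 1), a rigid
#' frame that cannot enter the pocket mouth.
#'
#' Three reaction coordinates span association: cleft-to-head distance,
#' receptor-to-ligand-centre distance, and cleft-to-tail distance, each
#' covered by three half-overlapping zones. Seeding windows hold the ligand
#' away from the cleft, as unbound starting states.
#'
#' @param ligand `"binder"` or `"rod"`.
#' @return a validated `"run_config"` list.
#' @export
demo_config <- function(ligand = c("binder", "rod")) {
  ligand <- match.arg(ligand)
  sys_spec <- if (ligand == "binder") {
    list(n_ligand = 4, head_size = 2, tail_size = 2, angle_k = 1,
         cleft_eps_mult = 15)
  } else {
    list(n_ligand = 6, head_size = 2, tail_size = 2, angle_k = 60,
         cleft_eps_mult = 1)
  }
  cfg <- list(
    system = sys_spec,
    rc = list(
      list(name = "alpha", group_A = "cleft", group_B = "ligand_head",
           range = c(2, 14)),
      list(name = "beta", group_A = "receptor_core", group_B = "ligand",
           range = c(1.5, 13.5)),
      list(name = "gamma", group_A = "cleft", group_B = "ligand_tail",
           range = c(5, 17))),
    zones = list(n_vs = 3, overlap_fraction = 0.5, bin_width = 3),
    windows = list(alpha = c(11, 13), beta = c(10.5, 12.5),
                   gamma = c(15, 16.8)),
    schedule = list(n_iterations = 3, n_runs_per_iteration = 24,
                    steps_per_run = 9000, dt = 4,
                    snapshot_interval_steps = 150,
                    transition_interval_steps = 1500),
    dynamics = list(temperature = 300, friction = 1, wall_k = 10),
    analysis = list(density_spacing = 1.0, orientation_spacing = 2.0,
                    rho0 = 0.001, cluster_level = 0.5, contact_cutoff = 4.0,
                    rdf_bin_width = 0.25, ddf_bin_width = 0.1),
    seed = 1
  )
  validate_run_config(cfg)
}

#' Is a point inside the toy receptor pocket?
#'
#' The pocket region is the mouth cylinder above the cleft beads: within
#' `radius` of the cleft axis in the surface plane, and below `z_max`
#' (the plate sits at z = 0, the cleft bottom at negative z).
#'
#' @param sys a `"toy_system"` built by [build_toy_complex()].
#' @param points matrix (n x 3) or length-3 vector.
#' @param radius cylinder radius (A).
#' @param z_max upper lid of the pocket region (A).
#' @return logical vector.
#' @export
in_pocket <- function(sys, points, radius = 3.0, z_max = 1.0) {
  p <- if (is.matrix(points)) points else matrix(points, nrow = 1)
  axis_xy <- colMeans(sys$coords[sys$groups$cleft, 1:2, drop = FALSE])
  z_min <- min(sys$coords[sys$groups$cleft, 3]) - 1.5
  r_xy <- sqrt((p[, 1] - axis_xy[1])^2 + (p[, 2] - axis_xy[2])^2)
  r_xy < radius & p[, 3] < z_max & p[, 3] > z_min
}

# rc_def list from a run_config, resolved against a built system
.config_rc_defs <- function(cfg, sys) {
  lapply(cfg$rc, function(r)
    rc_def(r$name, sys$groups[[r$group_A]], sys$groups[[r$group_B]],
           weighting = if (is.null(r$weighting)) "geometric" else r$weighting,
           range = r$range))
}

#' Run the full demo pipeline on a shipped system
#'
#' Seed generation, iterative zone-coupled sampling, reweighting, and the
#' complete analysis battery (whole-ligand and head-group density grids
#' with clusters, minimum-distance distributions against the three cleft
#' beads, contact fractions, the head-tail orientation field, and the
#' end-to-end framework flexibility). With `dir` set, every artifact is
#' written to disk (store, OpenDX grids, delimited tables, PDB reference,
#' run log), each stamped with the configuration hash and package version.
#'
#' @param seed root seed of the campaign.
#' @param ligand `"binder"` or `"rod"`.
#' @param dir optional output directory for artifacts.
#' @param config a `"run_config"` (default [demo_config()]).
#' @param verbose print per-iteration progress.
#' @return list with the system, fit, ensemble, and every analysis result.
#' @export
vcmd_demo <- function(seed = 1, ligand = c("binder", "rod"), dir = NULL,
                      config = NULL, verbose = FALSE) {
  ligand <- match.arg(ligand)
  cfg <- if (is.null(config)) demo_config(ligand) else validate_run_config(config)
  cfg$seed <- seed

  sys <- build_toy_complex(do.call(toy_spec, cfg$system), seed = seed)
  rc_defs <- .config_rc_defs(cfg, sys)
  grid <- build_zone_grid(lapply(cfg$rc, `[[`, "range"),
                          n_vs = cfg$zones$n_vs,
                          overlap_fraction = cfg$zones$overlap_fraction,
                          bin_width = cfg$zones$bin_width)
  schedule <- do.call(iteration_schedule, cfg$schedule)
  params <- do.call(dynamics_params, c(cfg$dynamics, list(dt = cfg$schedule$dt)))
  windows <- do.call(rbind, cfg$windows)

  fit <- vcmd(sys, rc_defs, grid, schedule, params, windows = windows,
              seed = seed, verbose = verbose)
  ens <- superpose_ensemble(reweight(fit))

  an <- cfg$analysis
  dens_cg <- spatial_density(ens, "ligand", spacing = an$density_spacing,
                             rho0 = an$rho0)
  dens_head <- spatial_density(ens, "ligand_ringA", spacing = an$density_spacing,
                               rho0 = an$rho0)
  clus_cg <- density_clusters(dens_cg, an$cluster_level)
  clus_head <- density_clusters(dens_head, an$cluster_level)
  rdfs <- lapply(c("cleft_V75", "cleft_F93", "cleft_F96"), function(res)
    distance_distribution(ens, list(type = "group_min", group1 = "ligand",
                                    group2 = res),
                          bin_width = an$rdf_bin_width))
  names(rdfs) <- c("cleft_V75", "cleft_F93", "cleft_F96")
  contacts <- vapply(c("cleft_V75", "cleft_F93", "cleft_F96"), function(res)
    contact_fraction(ens, "ligand_ringA", res, cutoff = an$contact_cutoff),
    numeric(1))
  orient <- orientation_field(ens, spacing = an$orientation_spacing)
  lig_ids <- sys$groups$ligand
  ddf <- distance_distribution(ens, list(type = "atom_pair",
                                         i = lig_ids[1],
                                         j = lig_ids[length(lig_ids)]),
                               bin_width = an$ddf_bin_width)

  out <- list(ligand = ligand, config = cfg, system = sys, fit = fit,
              ensemble = ens, density_cg = dens_cg, density_head = dens_head,
              clusters_cg = clus_cg, clusters_head = clus_head, rdfs = rdfs,
              contacts = contacts, orientation = orient, flexibility = ddf)

  if (!is.null(dir)) .write_demo_artifacts(out, dir)
  out
}

.write_demo_artifacts <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(config_hash = .config_hash(out$config),
             package_version = as.character(utils::packageVersion("vczone")))
  meta <- function(path) {
    writeLines(c(sprintf("# config_hash: %s", stamp[1]),
                 sprintf("# vczone_version: %s", stamp[2])), path)
    path
  }
  write_store(out$fit, file.path(dir, "store.rds"))
  write_store(out$ensemble, file.path(dir, "ensemble.rds"))
  for (nm in c("density_cg", "density_head"))
    write_dx(out[[nm]], file.path(dir, paste0(nm, ".dx")))
  q <- out$fit$q_grids[[length(out$fit$q_grids)]]
  if (length(dim(q$values)) == 3) write_dx(q, file.path(dir, "qgrid.dx"))
  write_pdb(out$system, file.path(dir, "reference.pdb"))
  write_toy_system(out$system, file.path(dir, "system.txt"))

  tabfile <- file.path(dir, "orientation.tsv")
  meta(tabfile)
  suppressWarnings(write.table(out$orientation$table, tabfile, sep = "\t",
                               row.names = FALSE, quote = FALSE, append = TRUE))
  clfile <- file.path(dir, "clusters.tsv")
  meta(clfile)
  suppressWarnings(write.table(cbind(density = "ligand_cg", out$clusters_cg$clusters),
                               clfile, sep = "\t", row.names = FALSE,
                               quote = FALSE, append = TRUE))
  wfile <- file.path(dir, "weights.tsv")
  meta(wfile)
  suppressWarnings(write.table(
    data.frame(snapshot = seq_along(out$ensemble$weights),
               weight = out$ensemble$weights), wfile, sep = "\t",
    row.names = FALSE, quote = FALSE, append = TRUE))
  yaml::write_yaml(c(list(config_hash = unname(stamp[1]),
                          vczone_version = unname(stamp[2])),
                     unclass(out$config)),
                   file.path(dir, "config_echo.yaml"))
  log <- c(sprintf("config_hash %s, vczone %s", stamp[1], stamp[2]),
           sprintf("zones visited: %d / %d", sum(out$fit$visits > 0),
                   n_states(out$fit$grid)),
           sprintf("iteration %d: d = %s",
                   seq_along(out$fit$convergence),
                   ifelse(is.na(out$fit$convergence), "NA",
                          sprintf("%.4f", out$fit$convergence))),
           sprintf("contact fractions: %s",
                   paste(names(out$contacts),
                         sprintf("%.3f", out$contacts), collapse = ", ")))
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}
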