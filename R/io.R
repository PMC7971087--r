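#' Write a volumetric grid as an OpenDX file
#'
#' Writes the standard OpenDX regular-grid text format (origin, per-axis
#' deltas, counts, values in row-major order with the third axis fastest),
#' suitable for contour visualisation. Accepts a `"density_grid"` or a
#' three-dimensional `"q_grid"`.
#'
#' @param grid a `"density_grid"` or 3D `"q_grid"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  if (inherits(grid, "q_grid")) {
    if (length(dim(grid$values)) != 3)
      stop("only 3D Q grids can be exported as OpenDX")
    origin <- vapply(grid$grid$axes, function(a) a$range[1] + a$bin_width / 2,
                     numeric(1))
    spacing <- vapply(grid$grid$axes, `[[`, numeric(1), "bin_width")
    vals <- grid$values
  } else {
    origin <- grid$origin + grid$spacing / 2
    spacing <- rep(grid$spacing, 3)
    vals <- grid$values
  }
  if (any(!is.finite(vals))) stop("export error: non-finite grid values")
  d <- dim(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", origin[1], origin[2], origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", spacing[1]),
    sprintf("delta 0.000000 %.6f 0.000000", spacing[2]),
    sprintf("delta 0.000000 0.000000 %.6f", spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # x slowest, z fastest (DX convention)
  v <- as.numeric(aperm(vals, c(3, 2, 1)))
  pad <- (-length(v)) %% 3
  v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX regular grid written by [write_dx()]
#'
#' @param path OpenDX file.
#' @return list with `origin` (voxel centres' origin), `spacing`, `values`
#'   (3D array).
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  cnt <- as.integer(strsplit(sub(".*counts ", "", lines[1]), " ")[[1]])
  origin <- as.numeric(strsplit(sub("origin ", "", lines[2]), " ")[[1]])
  spacing <- c(as.numeric(strsplit(lines[3], " ")[[1]][2]),
               as.numeric(strsplit(lines[4], " ")[[1]][3]),
               as.numeric(strsplit(lines[5], " ")[[1]][4]))
  i0 <- grep("data follows", lines)[1]
  iend <- grep("^attribute", lines)[1]
  v <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(iend - 1)]), "\\s+")))
  stopifnot(length(v) == prod(cnt))
  vals <- aperm(array(v, dim = rev(cnt)), c(3, 2, 1))
  list(origin = origin, spacing = spacing, values = vals)
}

.STORE_SCHEMA <- "vczone-store"
.STORE_VERSION <- 1L

#' Persist and reload package objects with schema checking
#'
#' Wraps base serialization with an explicit schema tag and version so a
#' foreign or truncated file fails loudly rather than silently. Numeric
#' payloads round-trip bit-exact.
#'
#' @param object any package object (a fit, ensemble, store, grid, ...).
#' @param path file path.
#' @return `path` invisibly (`write_store`); the object (`read_store`).
#' @export
write_store <- function(object, path) {
  saveRDS(list(schema = .STORE_SCHEMA, version = .STORE_VERSION,
               package_version = as.character(utils::packageVersion("vczone")),
               payload = object), path)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  x <- tryCatch(readRDS(path),
                error = function(e) stop("integrity error: cannot read store: ",
                                         conditionMessage(e), call. = FALSE))
  if (!is.list(x) || !identical(x$schema, .STORE_SCHEMA))
    stop("version error: not a vczone store (schema tag missing)")
  if (!identical(x$version, .STORE_VERSION))
    stop("version error: store schema version ", x$version,
         " needs migration to ", .STORE_VERSION)
  x$payload
}

#' Write a toy system to a structured text file (and read it back)
#'
#' The schema is line-oriented with bracketed sections: a bead table
#' (id, type, mass, x, y, z), bond/angle tables, the nonbonded type-pair
#' table, a group table (name + comma-separated ids), and restraint sets.
#'
#' @param sys a `"toy_system"`.
#' @param path output path.
#' @return `path` invisibly (`write_toy_system`); the system
#'   (`read_toy_system`).
#' @export
write_toy_system <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vczone toy_system v1")
  w("[beads]")
  for (i in seq_len(nrow(sys$coords)))
    w("%d\t%s\t%g\t%.8f\t%.8f\t%.8f", i, sys$bead_types[i], sys$masses[i],
      sys$coords[i, 1], sys$coords[i, 2], sys$coords[i, 3])
  w("[bonds]")
  for (i in seq_len(nrow(sys$bonds)))
    w("%d\t%d\t%g\t%g", sys$bonds$i[i], sys$bonds$j[i], sys$bonds$k[i],
      sys$bonds$r0[i])
  w("[angles]")
  for (i in seq_len(nrow(sys$angles)))
    w("%d\t%d\t%d\t%g\t%g", sys$angles$i[i], sys$angles$j[i], sys$angles$k[i],
      sys$angles$ka[i], sys$angles$theta0[i])
  w("[nonbonded]")
  for (i in seq_len(nrow(sys$nonbonded)))
    w("%s\t%s\t%g\t%g", sys$nonbonded$type1[i], sys$nonbonded$type2[i],
      sys$nonbonded$eps[i], sys$nonbonded$sigma[i])
  w("[groups]")
  for (nm in names(sys$groups))
    w("%s\t%s", nm, paste(sys$groups[[nm]], collapse = ","))
  w("[restraints]")
  for (s in seq_along(sys$restraints)) {
    r <- sys$restraints[[s]]
    for (i in seq_along(r$ids))
      w("%d\t%g\t%d\t%.8f\t%.8f\t%.8f", s, r$k, r$ids[i],
        r$anchors[i, 1], r$anchors[i, 2], r$anchors[i, 3])
  }
  invisible(path)
}

#' @rdname write_toy_system
#' @export
read_toy_system <- function(path) {
  lines <- readLines(path)
  if (!grepl("vczone toy_system v1", lines[1]))
    stop("version error: not a vczone toy_system v1 file")
  sec <- cumsum(grepl("^\\[", lines))
  names_sec <- gsub("[][]", "", lines[grepl("^\\[", lines)])
  grab <- function(nm) {
    k <- which(names_sec == nm)
    body <- lines[sec == k]
    body <- body[!grepl("^\\[", body)]
    body[nzchar(body)]
  }
  bd <- read.table(text = grab("beads"), sep = "\t",
                   col.names = c("id", "type", "mass", "x", "y", "z"))
  bonds <- grab("bonds")
  bonds <- if (length(bonds)) read.table(text = bonds, sep = "\t",
                                         col.names = c("i", "j", "k", "r0"))
  else data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
  ang <- grab("angles")
  ang <- if (length(ang)) read.table(text = ang, sep = "\t",
                                     col.names = c("i", "j", "k", "ka", "theta0"))
  else data.frame(i = integer(), j = integer(), k = integer(),
                  ka = numeric(), theta0 = numeric())
  nb <- read.table(text = grab("nonbonded"), sep = "\t",
                   col.names = c("type1", "type2", "eps", "sigma"))
  grp <- strsplit(grab("groups"), "\t")
  groups <- lapply(grp, function(g) as.integer(strsplit(g[2], ",")[[1]]))
  names(groups) <- vapply(grp, `[[`, character(1), 1)
  rs <- grab("restraints")
  restraints <- list()
  if (length(rs)) {
    rt <- read.table(text = rs, sep = "\t",
                     col.names = c("set", "k", "id", "ax", "ay", "az"))
    restraints <- lapply(split(rt, rt$set), function(s)
      list(ids = s$id, anchors = as.matrix(s[, c("ax", "ay", "az")]), k = s$k[1]))
    names(restraints) <- NULL
  }
  sys <- list(coords = as.matrix(bd[, c("x", "y", "z")]), masses = bd$mass,
              bead_types = as.character(bd$type), bonds = bonds, angles = ang,
              nonbonded = nb, groups = groups, restraints = restraints,
              spec = NULL)
  dimnames(sys$coords) <- NULL
  class(sys) <- "toy_system"
  validate_toy_system(sys)
  sys
}

#' Export bead coordinates as a PDB pseudo-atom file
#'
#' Beads become carbon pseudo-atoms; each bead's residue name is the first
#' group that contains it (truncated to three characters), so the named
#' groups survive into visualisation software.
#'
#' @param sys a `"toy_system"`.
#' @param path output path.
#' @param coords optional coordinates (default: the system's).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(sys, path, coords = sys$coords) {
  resname <- rep("UNK", nrow(coords))
  for (nm in rev(names(sys$groups)))
    resname[sys$groups[[nm]]] <- toupper(substr(gsub("[^A-Za-z0-9]", "", nm), 1, 3))
  lig <- if (!is.null(sys$groups$ligand)) sys$groups$ligand else integer(0)
  chain <- ifelse(seq_len(nrow(coords)) %in% lig, "B", "A")
  lines <- vapply(seq_len(nrow(coords)), function(i)
    sprintf("ATOM  %5d  C   %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, resname[i], chain[i], i, coords[i, 1], coords[i, 2],
            coords[i, 3], 1.0, 0.0), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# FNV-1a hash over the serialized object; provenance stamp for artifacts
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

.CONFIG_KEYS <- c("system", "rc", "zones", "windows", "schedule", "dynamics",
                  "analysis", "seed", "output_dir")

#' Read and validate a run configuration file
#'
#' The configuration is a single human-readable YAML file; unknown
#' top-level keys are rejected and missing mandatory blocks raise a schema
#' error before any computation. The validated list is echoed verbatim into
#' every artifact's metadata.
#'
#' @param path YAML file.
#' @return the validated configuration list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("schema error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  for (key in c("system", "rc", "zones", "schedule", "dynamics", "seed"))
    if (is.null(cfg[[key]]))
      stop("schema error: missing configuration key: ", key)
  class(cfg) <- "run_config"
  cfg
}
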