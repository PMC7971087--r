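#' Kabsch least-squares superposition
#'
#' Finds the rigid rotation + translation minimising the RMSD of a selected
#' bead subset onto a reference, and applies it to the whole mobile
#' structure.
#'
#' @param mobile,reference N x 3 coordinate matrices (same bead order).
#' @param selection indices used to fit the transform (>= 3, non-collinear).
#' @return list with `rotation` (3 x 3), `translation`, `rmsd` (A, over the
#'   selection), and `coords` (all mobile coordinates transformed).
#' @export
kabsch_superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (length(selection) < 3)
    stop("degenerate-superposition: need at least 3 selection beads")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  if (s$d[2] < 1e-10 * max(s$d[1], 1))
    stop("degenerate-superposition: selection is (near-)collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B0)^2)))
  coords <- sweep(mobile, 2, ca) %*% t(R)
  coords <- sweep(coords, 2, cb, "+")
  list(rotation = R, translation = cb - as.numeric(R %*% ca), rmsd = rmsd,
       coords = coords)
}

#' Superpose every snapshot of an ensemble onto a reference frame
#'
#' All real-space analyses are carried out in a receptor-fixed frame; this
#' helper Kabsch-fits the receptor-core selection of each snapshot onto the
#' reference structure.
#'
#' @param ensemble a `"canonical_ensemble"` with coordinates and a system.
#' @param reference reference coordinates (default: the system's built
#'   coordinates).
#' @param selection fitting selection (default: the `receptor_core` group).
#' @return the ensemble with transformed coordinates and per-snapshot
#'   `superpose_rmsd`.
#' @export
superpose_ensemble <- function(ensemble, reference = NULL, selection = NULL) {
  sys <- ensemble$system
  if (is.null(reference)) reference <- sys$coords
  if (is.null(selection)) selection <- sys$groups$receptor_core
  res <- lapply(ensemble$coords, kabsch_superpose, reference = reference,
                selection = selection)
  ensemble$coords <- lapply(res, `[[`, "coords")
  ensemble$superpose_rmsd <- vapply(res, `[[`, numeric(1), "rmsd")
  ensemble
}

# resolve a group spec (name or index vector) against an ensemble's system
.resolve_group <- function(ensemble, group) {
  if (is.character(group)) {
    g <- ensemble$system$groups[[group]]
    if (is.null(g)) stop("unknown group: ", group)
    g
  } else as.integer(group)
}

#' Spatial probability density of a selection centre on a voxel grid
#'
#' Accumulates each snapshot's selection centre into a real-space voxel
#' with the snapshot's weight. Voxel values are probabilities and sum to 1;
#' contour levels are conventionally expressed as multiples of the
#' reference constant `rho0 = 0.001`.
#'
#' @param ensemble a (superposed) `"canonical_ensemble"`.
#' @param selection bead indices or a group name (e.g. `"ligand"`,
#'   `"ligand_ringA"`).
#' @param spacing voxel edge length (A).
#' @param origin optional grid origin; default: snapped just below the data
#'   extent.
#' @param dims optional voxel counts per axis.
#' @param center `"geometric"` or `"mass"` centre of the selection.
#' @param rho0 reference density constant for contour levels.
#' @param oob `"grow"` (size the grid to the data; default) or `"drop"`
#'   (drop centres outside a fixed `origin`/`dims` grid, logged).
#' @return an object of class `"density_grid"`: `origin`, `spacing`,
#'   `values` (3D array summing to 1), `rho0`, `selection_label`,
#'   `n_dropped`.
#' @export
spatial_density <- function(ensemble, selection, spacing = 1.0,
                            origin = NULL, dims = NULL,
                            center = c("geometric", "mass"),
                            rho0 = 0.001, oob = c("grow", "drop")) {
  center <- match.arg(center)
  oob <- match.arg(oob)
  label <- if (is.character(selection)) selection else "selection"
  ids <- .resolve_group(ensemble, selection)
  masses <- ensemble$system$masses
  pts <- t(vapply(ensemble$coords, function(x)
    group_center(x, ids, center, masses), numeric(3)))
  w <- ensemble$weights

  if (is.null(origin) || is.null(dims)) {
    lo <- apply(pts, 2, min) - spacing / 2
    hi <- apply(pts, 2, max) + spacing / 2
    origin <- floor(lo / spacing) * spacing
    dims <- pmax(ceiling((hi - origin) / spacing), 1)
  }
  vox <- floor(sweep(pts, 2, origin) / spacing) + 1
  inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  if (oob == "grow" && !all(inside))
    stop("internal: auto-sized grid failed to cover the data")
  n_dropped <- sum(!inside | w == 0)
  if (all(!inside | w == 0))
    stop("empty-grid: every selection centre fell outside the grid")

  vals <- array(0, dim = dims)
  idx <- vox[inside & w > 0, , drop = FALSE]
  ww <- w[inside & w > 0]
  for (i in seq_len(nrow(idx)))
    vals[idx[i, 1], idx[i, 2], idx[i, 3]] <-
    vals[idx[i, 1], idx[i, 2], idx[i, 3]] + ww[i]
  vals <- vals / sum(vals)
  structure(list(origin = origin, spacing = spacing, values = vals,
                 rho0 = rho0, selection_label = label, n_dropped = n_dropped),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid '%s': %s voxels of %g A, origin (%g, %g, %g)\n",
              x$selection_label, paste(dim(x$values), collapse = " x "),
              x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  sum %.10f, max %.3g (= %.2f x rho0)\n", sum(x$values),
              max(x$values), max(x$values) / x$rho0))
  invisible(x)
}

#' High-density clusters of a voxel grid
#'
#' 26-connected components of voxels whose value exceeds
#' `level_multiplier x rho0`, sorted by total probability mass.
#'
#' @param grid a `"density_grid"`.
#' @param level_multiplier contour level as a multiple of `rho0`.
#' @param rho0 reference constant (default: the grid's own).
#' @return object of class `"cluster_report"`: data.frame `clusters`
#'   (mass, n_voxels, peak value, peak and centroid positions in A) plus
#'   `members` (list of voxel-index matrices) and the threshold used.
#' @export
density_clusters <- function(grid, level_multiplier = 0.5, rho0 = grid$rho0) {
  thr <- level_multiplier * rho0
  above <- which(grid$values > thr, arr.ind = TRUE)
  members <- list()
  if (nrow(above)) {
    key <- paste(above[, 1], above[, 2], above[, 3])
    seen <- rep(FALSE, nrow(above))
    lookup <- setNames(seq_len(nrow(above)), key)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    for (s in seq_len(nrow(above))) {
      if (seen[s]) next
      comp <- integer(0); queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        comp <- c(comp, v)
        nb <- sweep(offs, 2, as.numeric(above[v, ]), "+")
        hit <- lookup[paste(nb[, 1], nb[, 2], nb[, 3])]
        hit <- hit[!is.na(hit)]
        new <- hit[!seen[hit]]
        seen[new] <- TRUE
        queue <- c(queue, new)
      }
      members[[length(members) + 1]] <- above[comp, , drop = FALSE]
    }
  }
  stats <- lapply(members, function(m) {
    vals <- grid$values[m]
    ctr <- grid$origin + (colSums(m * vals) / sum(vals) - 0.5) * grid$spacing
    pk <- m[which.max(vals), ]
    data.frame(mass = sum(vals), n_voxels = nrow(m), peak_value = max(vals),
               peak_x = grid$origin[1] + (pk[1] - 0.5) * grid$spacing,
               peak_y = grid$origin[2] + (pk[2] - 0.5) * grid$spacing,
               peak_z = grid$origin[3] + (pk[3] - 0.5) * grid$spacing,
               centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3])
  })
  ord <- order(-vapply(stats, `[[`, numeric(1), "mass"))
  clusters <- if (length(stats)) do.call(rbind, stats[ord])
  else data.frame(mass = numeric(0), n_voxels = integer(0),
                  peak_value = numeric(0), peak_x = numeric(0),
                  peak_y = numeric(0), peak_z = numeric(0),
                  centroid_x = numeric(0), centroid_y = numeric(0),
                  centroid_z = numeric(0))
  structure(list(clusters = clusters, members = members[ord],
                 threshold = thr, level_multiplier = level_multiplier,
                 rho0 = rho0),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Density clusters above %.3g x rho0 (threshold %.3g): %d cluster(s)\n",
              x$level_multiplier, x$threshold, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, digits = 3)
  invisible(x)
}

#' Minimum pairwise distance between two bead groups
#'
#' @param coords N x 3 coordinates.
#' @param group1,group2 nonempty index vectors.
#' @return the minimum Euclidean distance (A).
#' @export
min_group_distance <- function(coords, group1, group2) {
  if (!length(group1) || !length(group2)) stop("invalid-group: empty group")
  a <- coords[group1, , drop = FALSE]
  b <- coords[group2, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Contact indicator and weighted contact fraction
#'
#' A contact is scored when the minimum group-group distance satisfies the
#' strict inequality `r < cutoff` (default 4.0 A).
#'
#' @param r distance(s) (A).
#' @param cutoff contact cutoff (A).
#' @return logical vector.
#' @export
contact_indicator <- function(r, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  r < cutoff
}

#' @rdname contact_indicator
#' @param ensemble a `"canonical_ensemble"`.
#' @param group1,group2 bead groups (names or indices).
#' @return `contact_fraction`: the total weight of contact snapshots.
#' @export
contact_fraction <- function(ensemble, group1, group2, cutoff = 4.0) {
  g1 <- .resolve_group(ensemble, group1)
  g2 <- .resolve_group(ensemble, group2)
  r <- vapply(ensemble$coords, min_group_distance, numeric(1), g1, g2)
  sum(ensemble$weights[contact_indicator(r, cutoff)])
}

#' Weighted distance distribution (minimum-distance RDF or atom-pair DDF)
#'
#' Computes the weighted distribution of either the minimum group-group
#' distance (the "RDF" convention: a normalised minimum-distance
#' distribution, no volume correction) or a designated intramolecular
#' bead-pair distance (the DDF convention). The weighted mean and SD are
#' computed from the unbinned per-snapshot distances; the length-normalised
#' flexibility `sd = SD / mean` is attached.
#'
#' @param ensemble a `"canonical_ensemble"`.
#' @param spec `list(type = "group_min", group1 = , group2 = )` or
#'   `list(type = "atom_pair", i = , j = )` (groups as names or indices).
#' @param bin_width histogram bin width (A).
#' @param range optional `[lo, hi]`; default spans the data.
#' @return object of class `"distance_distribution"`: `breaks`, `density`
#'   (unit integral), `mean`, `SD`, `sd` (= SD/mean), `definition`.
#' @export
distance_distribution <- function(ensemble, spec, bin_width = 0.2,
                                  range = NULL) {
  stopifnot(bin_width > 0)
  r <- switch(spec$type,
    group_min = {
      g1 <- .resolve_group(ensemble, spec$group1)
      g2 <- .resolve_group(ensemble, spec$group2)
      vapply(ensemble$coords, min_group_distance, numeric(1), g1, g2)
    },
    atom_pair = vapply(ensemble$coords, function(x)
      sqrt(sum((x[spec$i, ] - x[spec$j, ])^2)), numeric(1)),
    stop("unknown distance definition: ", spec$type))
  w <- ensemble$weights
  if (sum(w) <= 0) stop("empty-distribution: zero total weight")
  m <- sum(w * r) / sum(w)
  v <- sum(w * (r - m)^2) / sum(w)
  if (is.null(range)) range <- c(floor(min(r) / bin_width) * bin_width,
                                 ceiling(max(r) / bin_width) * bin_width)
  if (range[2] <= range[1]) range[2] <- range[1] + bin_width
  breaks <- seq(range[1], range[2] + bin_width / 2, by = bin_width)
  dist <- reweighted_distribution(ensemble, r, breaks)
  structure(list(breaks = dist$breaks, density = dist$density,
                 mass = dist$mass, mean = m, SD = sqrt(v),
                 sd = sqrt(v) / m, distances = r,
                 definition = spec$type),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("Distance distribution (%s): <r> = %.3f A, SD = %.3f A, sd = %.3g\n",
              x$definition, x$mean, x$SD, x$sd))
  invisible(x)
}

#' @export
plot.distance_distribution <- function(x, ...) {
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  plot(mid, x$density, type = "l", xlab = "r (A)", ylab = "p(r)", ...)
  invisible(x)
}

#' Length-normalised framework flexibility
#'
#' `sd = SD / <r>`: the fluctuation of a framework distance per unit
#' length, which allows comparing the stiffness of molecules of different
#' size. Reported to 3 significant figures.
#'
#' @param mean weighted mean distance (A), > 0.
#' @param SD weighted standard deviation (A), >= 0.
#' @return the dimensionless ratio, rounded to 3 significant figures.
#' @export
flexibility_sd <- function(mean, SD) {
  if (any(mean <= 0)) stop("invalid-input: mean distance must be positive")
  if (any(SD < 0)) stop("invalid-input: SD must be nonnegative")
  signif(SD / mean, 3)
}

#' Per-voxel mean orientation of a ligand
#'
#' For each snapshot the orientation is the unit vector from the
#' tail-group geometric centre to the head-group geometric centre. Vectors
#' are averaged (with the snapshot weights) within real-space cubes indexed
#' by the ligand's centre of mass, and each occupied cube is classified
#' aligned (`|<e>| >= classify_threshold`) or disordered.
#'
#' @param ensemble a (superposed) `"canonical_ensemble"`.
#' @param head_group,tail_group disjoint nonempty bead groups (names or
#'   indices).
#' @param spacing cube edge length (A).
#' @param com_selection beads whose centre of mass indexes the cube
#'   (default: the `ligand` group).
#' @param classify_threshold alignment threshold on `|<e>|`.
#' @return object of class `"orientation_field"`: `origin`, `spacing`,
#'   `table` (one row per occupied voxel: centre, mean vector, magnitude,
#'   supporting weight, class).
#' @export
orientation_field <- function(ensemble, head_group = "ligand_head",
                              tail_group = "ligand_tail", spacing = 2.0,
                              com_selection = "ligand",
                              classify_threshold = 0.5) {
  hg <- .resolve_group(ensemble, head_group)
  tg <- .resolve_group(ensemble, tail_group)
  if (length(intersect(hg, tg))) stop("head and tail groups must be disjoint")
  cg <- .resolve_group(ensemble, com_selection)
  masses <- ensemble$system$masses
  n <- length(ensemble$coords)
  e <- matrix(0, n, 3); com <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    x <- ensemble$coords[[i]]
    v <- group_center(x, hg, "geometric") - group_center(x, tg, "geometric")
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9)
      stop("zero-length-vector: head and tail centres coincide in snapshot ", i)
    e[i, ] <- v / nv
    com[i, ] <- group_center(x, cg, "mass", masses)
  }
  w <- ensemble$weights
  origin <- floor((apply(com, 2, min) - spacing / 2) / spacing) * spacing
  vox <- floor(sweep(com, 2, origin) / spacing) + 1
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  keep <- w > 0
  rows <- lapply(split(which(keep), key[keep]), function(ii) {
    ww <- w[ii]
    me <- colSums(e[ii, , drop = FALSE] * ww) / sum(ww)
    v1 <- vox[ii[1], ]
    data.frame(x = origin[1] + (v1[1] - 0.5) * spacing,
               y = origin[2] + (v1[2] - 0.5) * spacing,
               z = origin[3] + (v1[3] - 0.5) * spacing,
               ex = me[1], ey = me[2], ez = me[3],
               magnitude = sqrt(sum(me^2)), weight = sum(ww))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$class <- ifelse(tab$magnitude >= classify_threshold, "aligned", "disordered")
  structure(list(origin = origin, spacing = spacing, table = tab,
                 classify_threshold = classify_threshold),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("Orientation field: %d occupied cube(s) of %g A; %d aligned (|<e>| >= %g)\n",
              nrow(x$table), x$spacing, sum(x$table$class == "aligned"),
              x$classify_threshold))
  invisible(x)
}
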