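#' Define a centre-of-mass distance reaction coordinate
#'
#' A reaction coordinate (RC) is the Euclidean distance between the centres
#' of two bead groups. Ligand-side groups conventionally use the geometric
#' centre and receptor groups the mass-weighted centre; both are supported.
#'
#' @param name RC label (e.g. `"alpha"`, `"beta"`, `"gamma"`).
#' @param group_A,group_B nonempty, disjoint bead index vectors.
#' @param weighting `"geometric"` or `"mass"`.
#' @param range numeric `[lambda_min, lambda_max]` (A) the RC is confined to.
#' @return an object of class `"rc_def"`.
#' @export
rc_def <- function(name, group_A, group_B, weighting = c("geometric", "mass"),
                   range) {
  weighting <- match.arg(weighting)
  if (!length(group_A) || !length(group_B)) stop("invalid-group: empty RC group")
  if (length(intersect(group_A, group_B))) stop("invalid-group: RC groups overlap")
  stopifnot(length(range) == 2, range[1] < range[2])
  structure(list(name = name, group_A = as.integer(group_A),
                 group_B = as.integer(group_B), weighting = weighting,
                 range = as.numeric(range)), class = "rc_def")
}

#' Centre of a bead group
#'
#' @param coords N x 3 coordinate matrix.
#' @param ids nonempty bead index vector.
#' @param weighting `"geometric"` (plain mean) or `"mass"` (mass-weighted).
#' @param masses per-bead masses; required for mass weighting.
#' @return length-3 numeric position.
#' @export
group_center <- function(coords, ids, weighting = c("geometric", "mass"),
                         masses = NULL) {
  weighting <- match.arg(weighting)
  if (!length(ids)) stop("invalid-group: empty id set")
  x <- coords[ids, , drop = FALSE]
  if (weighting == "mass") {
    if (is.null(masses)) stop("mass weighting requires masses")
    w <- masses[ids] / sum(masses[ids])
    colSums(x * w)
  } else {
    colMeans(x)
  }
}

#' Evaluate the reaction-coordinate values of a configuration
#'
#' @param rc_defs list of [rc_def()] objects.
#' @param coords N x 3 coordinate matrix.
#' @param masses per-bead masses (needed when any RC uses mass weighting).
#' @return named numeric vector of distances (A), one per RC.
#' @export
rc_values <- function(rc_defs, coords, masses = NULL) {
  v <- vapply(rc_defs, function(rc) {
    ca <- group_center(coords, rc$group_A, rc$weighting, masses)
    cb <- group_center(coords, rc$group_B, rc$weighting, masses)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  names(v) <- vapply(rc_defs, `[[`, character(1), "name")
  v
}

#' Build an overlapping-zone grid over the reaction-coordinate space
#'
#' Each RC axis is covered by `n_vs` uniform zones of width
#' `w = span / ((n_vs - 1) (1 - f) + 1)` placed at stride `w (1 - f)`,
#' where `f` is the overlap fraction, so that the union of zones equals the
#' range exactly and adjacent zones overlap by `w f`. The axis is also cut
#' into uniform histogram bins whose edges coincide with every zone
#' boundary (the stitching estimator requires whole bins inside every
#' overlap); the default bin width is half the overlap width.
#'
#' Zone intervals are closed on the left and open on the right, except the
#' last zone which is closed on both ends.
#'
#' @param ranges a numeric `[min, max]` (one RC) or a list of such ranges.
#' @param n_vs zones per RC (scalar or vector, each >= 2).
#' @param overlap_fraction overlap fraction in (0, 1); default 0.5
#'   (half-overlapping zones, the conventional choice).
#' @param bin_width optional bin width per RC; must divide both the zone
#'   width and the stride.
#' @return an object of class `"zone_grid"`: list with `axes`, each holding
#'   `intervals` (n_vs x 2), `bin_edges`, `bin_width`, `n_vs`, `range`.
#' @export
build_zone_grid <- function(ranges, n_vs, overlap_fraction = 0.5,
                            bin_width = NULL) {
  if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
  d <- length(ranges)
  n_vs <- rep_len(n_vs, d)
  overlap_fraction <- rep_len(overlap_fraction, d)
  bin_width <- if (is.null(bin_width)) rep(NA_real_, d) else rep_len(bin_width, d)

  axes <- lapply(seq_len(d), function(h) {
    rg <- as.numeric(ranges[[h]])
    n <- n_vs[h]; f <- overlap_fraction[h]
    stopifnot(n >= 2, f > 0, f < 1, rg[1] < rg[2])
    span <- rg[2] - rg[1]
    w <- span / ((n - 1) * (1 - f) + 1)
    s <- w * (1 - f)
    lo <- rg[1] + (seq_len(n) - 1) * s
    intervals <- cbind(lo, lo + w)
    bw <- bin_width[h]
    if (is.na(bw)) bw <- w * f / 2
    if (bw <= 0 || span / bw < 1) stop("invalid-grid: range too narrow for bins")
    for (q in c(w / bw, s / bw))
      if (abs(q - round(q)) > 1e-9 * max(1, q))
        stop("invalid-grid: bin width must divide the zone width and stride")
    n_bins <- round(span / bw)
    edges <- rg[1] + (0:n_bins) * bw
    list(intervals = intervals, bin_edges = edges, bin_width = bw,
         n_vs = n, range = rg, overlap_fraction = f, zone_width = w,
         stride = s)
  })
  structure(list(axes = axes, d = d), class = "zone_grid")
}

#' @export
print.zone_grid <- function(x, ...) {
  cat("Zone grid over", x$d, "reaction coordinate(s)\n")
  for (h in seq_len(x$d)) {
    a <- x$axes[[h]]
    cat(sprintf("  RC %d: range [%g, %g], %d zones of width %g (stride %g), %d bins of %g A\n",
                h, a$range[1], a$range[2], a$n_vs, a$zone_width, a$stride,
                length(a$bin_edges) - 1, a$bin_width))
  }
  invisible(x)
}

# zone membership on one axis: [lo, hi) except the last zone, [lo, hi]
.axis_zones_containing <- function(lambda, axis) {
  iv <- axis$intervals
  n <- nrow(iv)
  hit <- which(lambda >= iv[, 1] & (lambda < iv[, 2] | (seq_len(n) == n & lambda <= iv[, 2])))
  hit
}

#' Virtual states whose zones contain a reaction-coordinate point
#'
#' Returns the Cartesian product of the per-RC zones containing each
#' component of `lambda`. Values within `tol` outside the outer range are
#' clamped (wall tolerance); values further out raise an error.
#'
#' @param lambda numeric RC triplet (or d-vector).
#' @param grid a `"zone_grid"`.
#' @param tol clamping tolerance (A) beyond the outer range.
#' @return integer matrix, one row per state, one column per RC.
#' @export
states_containing <- function(lambda, grid, tol = 0) {
  stopifnot(length(lambda) == grid$d)
  per_axis <- lapply(seq_len(grid$d), function(h) {
    a <- grid$axes[[h]]
    x <- lambda[h]
    if (x < a$range[1] - tol || x > a$range[2] + tol)
      stop(sprintf("out-of-range: RC %d value %.3f outside [%g, %g] (tol %g)",
                   h, x, a$range[1], a$range[2], tol))
    x <- min(max(x, a$range[1]), a$range[2])
    .axis_zones_containing(x, a)
  })
  as.matrix(expand.grid(per_axis, KEEP.OUT.ATTRS = FALSE))
}

#' Zone centres of a grid axis (or of every state)
#'
#' @param grid a `"zone_grid"`.
#' @return matrix of state centres, one row per virtual state (row order
#'   matches [state_id()] linearisation).
#' @export
zone_centers <- function(grid) {
  per_axis <- lapply(grid$axes, function(a) rowMeans(a$intervals))
  as.matrix(expand.grid(per_axis, KEEP.OUT.ATTRS = FALSE))
}

# ---- state and bin linearisation helpers ------------------------------------

#' Number of virtual states of a grid
#' @param grid a `"zone_grid"`.
#' @return integer.
#' @export
n_states <- function(grid) prod(vapply(grid$axes, `[[`, numeric(1), "n_vs"))

#' Linear id of a virtual state (and back)
#'
#' States are linearised in column-major order over the per-RC zone indices.
#'
#' @param state integer vector (or matrix of rows) of per-RC zone indices.
#' @param grid a `"zone_grid"`.
#' @return integer id(s).
#' @export
state_id <- function(state, grid) {
  nv <- vapply(grid$axes, `[[`, numeric(1), "n_vs")
  m <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  id <- m[, 1]
  mult <- 1
  for (h in seq_len(grid$d)[-1]) {
    mult <- mult * nv[h - 1]
    id <- id + (m[, h] - 1) * mult
  }
  as.integer(id)
}

#' @rdname state_id
#' @param id linear state id(s).
#' @export
state_from_id <- function(id, grid) {
  nv <- vapply(grid$axes, `[[`, numeric(1), "n_vs")
  out <- matrix(0L, length(id), grid$d)
  rem <- as.integer(id) - 1L
  for (h in seq_len(grid$d)) {
    out[, h] <- rem %% nv[h] + 1L
    rem <- rem %/% nv[h]
  }
  out
}

#' Per-axis histogram bin of an RC value
#'
#' Bins are closed on the left, open on the right, except the last bin.
#' Values within `tol` outside the range are clamped; NA is returned for
#' values further outside.
#'
#' @param lambda RC vector (length d) or matrix (rows = points).
#' @param grid a `"zone_grid"`.
#' @param tol clamping tolerance (A).
#' @return integer matrix of per-axis bin indices (NA where out of range).
#' @export
bin_index <- function(lambda, grid, tol = 0) {
  m <- if (is.matrix(lambda)) lambda else matrix(lambda, nrow = 1)
  out <- matrix(NA_integer_, nrow(m), grid$d)
  for (h in seq_len(grid$d)) {
    a <- grid$axes[[h]]
    x <- m[, h]
    ok <- x >= a$range[1] - tol & x <= a$range[2] + tol
    xc <- pmin(pmax(x, a$range[1]), a$range[2])
    b <- floor((xc - a$range[1]) / a$bin_width) + 1L
    b <- pmin(b, length(a$bin_edges) - 1L)
    out[ok, h] <- b[ok]
  }
  out
}

#' Linear bin id from per-axis bin indices (and back)
#' @param bins integer matrix of per-axis bin indices.
#' @param grid a `"zone_grid"`.
#' @return integer linear bin id(s) (NA propagates).
#' @export
bin_id <- function(bins, grid) {
  nb <- vapply(grid$axes, function(a) length(a$bin_edges) - 1L, integer(1))
  m <- if (is.matrix(bins)) bins else matrix(bins, nrow = 1)
  id <- m[, 1]
  mult <- 1
  for (h in seq_len(grid$d)[-1]) {
    mult <- mult * nb[h - 1]
    id <- id + (m[, h] - 1L) * mult
  }
  as.integer(id)
}

#' @rdname bin_id
#' @return total bin count of the grid.
#' @export
n_bins <- function(grid) {
  prod(vapply(grid$axes, function(a) length(a$bin_edges) - 1L, integer(1)))
}

# linear bin ids falling inside a state's zone (whole bins only; zone
# boundaries coincide with bin edges by construction)
.state_bin_ids <- function(state, grid) {
  per_axis <- lapply(seq_len(grid$d), function(h) {
    a <- grid$axes[[h]]
    iv <- a$intervals[state[h], ]
    b_lo <- round((iv[1] - a$range[1]) / a$bin_width) + 1L
    b_hi <- round((iv[2] - a$range[1]) / a$bin_width)
    seq.int(b_lo, b_hi)
  })
  bin_id(as.matrix(expand.grid(per_axis, KEEP.OUT.ATTRS = FALSE)), grid)
}

# centre coordinates of every bin (rows in linear bin order)
.bin_centers <- function(grid) {
  per_axis <- lapply(grid$axes, function(a)
    (a$bin_edges[-1] + a$bin_edges[-length(a$bin_edges)]) / 2)
  as.matrix(expand.grid(per_axis, KEEP.OUT.ATTRS = FALSE))
}
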