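#' Thermodynamic snapshot weights from a distribution estimate
#'
#' Each snapshot in bin `b` receives weight proportional to
#' `Q(b) / raw_counts(b)`: the estimated canonical mass of its bin divided
#' by the number of stored snapshots observed there, normalised to sum to 1.
#' Snapshots in bins whose Q value falls below `q_floor` times the maximum
#' receive zero weight and are flagged.
#'
#' @param rc snapshot RC matrix (one row per snapshot).
#' @param Q a `"q_grid"` (internally renormalised to sum 1).
#' @param raw_counts per-bin total snapshot counts (linear bin order);
#'   defaults to the counts of `rc` itself.
#' @param temperature ensemble temperature (K), carried as metadata.
#' @param q_floor relative Q floor below which snapshots are excluded.
#' @return an object of class `"canonical_ensemble"`: `weights` (sum to 1),
#'   `flagged` (logical), `bin` (linear ids), `temperature`,
#'   `q_iteration`.
#' @export
snapshot_weights <- function(rc, Q, raw_counts = NULL, temperature = 300,
                             q_floor = 1e-8) {
  grid <- Q$grid
  rc <- if (is.matrix(rc)) rc else matrix(rc, ncol = grid$d)
  bid <- bin_id(bin_index(rc, grid, tol = 0.5), grid)
  if (anyNA(bid)) stop("inconsistency: snapshot outside the RC grid")
  qs <- q_normalize(Q, "sum1")
  qv <- as.numeric(qs$values)
  if (is.null(raw_counts)) {
    raw_counts <- numeric(n_bins(grid))
    tab <- table(bid)
    raw_counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  if (any(raw_counts[bid] <= 0))
    stop("inconsistency: snapshot maps to a zero-count bin (store corrupt)")
  w <- qv[bid] / raw_counts[bid]
  flagged <- qv[bid] < q_floor * max(qv)
  w[flagged] <- 0
  if (sum(w) <= 0) stop("empty ensemble: all snapshot weights are zero")
  structure(list(weights = w / sum(w), flagged = flagged, bin = bid,
                 temperature = temperature, q_iteration = Q$iteration),
            class = "canonical_ensemble")
}

#' Reweight a sampling fit into a canonical ensemble
#'
#' Applies [snapshot_weights()] to the snapshots of a [vcmd()] fit using
#' its final (or a chosen) Q estimate. Snapshots that were not counted into
#' the histograms (wall-skin excursions) are excluded with zero weight.
#'
#' @param fit a `"vcmd"` object.
#' @param iteration which Q estimate to use (default: the last).
#' @param q_floor relative Q floor below which snapshots are excluded.
#' @return a `"canonical_ensemble"` carrying the snapshot coordinates
#'   (`coords`), RC values (`rc`), the source system, and weights.
#' @export
reweight <- function(fit, iteration = NULL, q_floor = 1e-8) {
  if (!length(fit$q_grids)) stop("fit holds no Q estimate to reweight with")
  Q <- if (is.null(iteration)) fit$q_grids[[length(fit$q_grids)]]
  else fit$q_grids[[iteration]]
  keep <- fit$store$counted
  rc <- fit$store$rc[keep, , drop = FALSE]
  raw <- colSums(fit$stack$counts)
  ens <- snapshot_weights(rc, Q, raw_counts = raw,
                          temperature = fit$params$temperature,
                          q_floor = q_floor)
  ens$coords <- fit$store$coords[keep]
  ens$rc <- rc
  ens$system <- fit$system
  ens$n_excluded <- sum(!keep) + sum(ens$flagged)
  ens
}

#' Construct a canonical ensemble from externally supplied snapshots
#'
#' The analysis-only entry path: coordinates plus per-snapshot weights from
#' any source (e.g. a store written elsewhere plus a reference structure).
#'
#' @param coords list of N x 3 coordinate matrices.
#' @param weights nonnegative weights (normalised internally).
#' @param system optional `"toy_system"` supplying groups/masses for the
#'   analyses.
#' @param temperature temperature (K).
#' @return a `"canonical_ensemble"`.
#' @export
canonical_ensemble <- function(coords, weights, system = NULL,
                               temperature = 300) {
  stopifnot(length(coords) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  structure(list(coords = coords, weights = weights / sum(weights),
                 flagged = rep(FALSE, length(weights)),
                 system = system, temperature = temperature,
                 q_iteration = NA_integer_),
            class = "canonical_ensemble")
}

#' @export
print.canonical_ensemble <- function(x, ...) {
  cat("Canonical ensemble:", length(x$weights), "snapshots at",
      x$temperature, "K\n")
  cat(sprintf("  weight sum %.12f; %d flagged/excluded\n", sum(x$weights),
              sum(x$flagged)))
  invisible(x)
}

#' @export
weights.canonical_ensemble <- function(object, ...) object$weights

#' Weighted distribution of a per-snapshot observable
#'
#' @param ensemble a `"canonical_ensemble"`.
#' @param observable numeric vector, one finite value per snapshot.
#' @param bins increasing bin edges.
#' @return list of class `"weighted_distribution"` with `breaks`, `density`
#'   (normalised to unit integral), `mass` (per-bin probability).
#' @export
reweighted_distribution <- function(ensemble, observable, bins) {
  w <- ensemble$weights
  stopifnot(length(observable) == length(w), all(is.finite(observable)))
  b <- findInterval(observable, bins, rightmost.closed = TRUE)
  inside <- b >= 1 & b <= length(bins) - 1
  mass <- vapply(seq_len(length(bins) - 1),
                 function(k) sum(w[inside & b == k]), numeric(1))
  if (sum(mass) <= 0)
    stop("empty-distribution: no weight falls inside the requested bins")
  mass <- mass / sum(mass)
  structure(list(breaks = bins, mass = mass,
                 density = mass / diff(bins)),
            class = "weighted_distribution")
}
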