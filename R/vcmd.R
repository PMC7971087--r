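#' Iteration schedule of a virtual-system-coupled sampling campaign
#'
#' @param n_iterations number of iterations.
#' @param n_runs_per_iteration parallel runs per iteration.
#' @param steps_per_run integration steps per run.
#' @param dt time step (fs).
#' @param snapshot_interval_steps store a snapshot every this many steps;
#'   must divide `steps_per_run`.
#' @param transition_interval_steps attempt an inter-state transition every
#'   this many steps; must be a multiple of the snapshot interval and divide
#'   `steps_per_run`.
#' @return a list of class `"iteration_schedule"`.
#' @export
iteration_schedule <- function(n_iterations, n_runs_per_iteration,
                               steps_per_run, dt = 2,
                               snapshot_interval_steps,
                               transition_interval_steps = snapshot_interval_steps) {
  stopifnot(n_iterations > 0, n_runs_per_iteration > 0, steps_per_run > 0,
            dt > 0, snapshot_interval_steps > 0, transition_interval_steps > 0,
            steps_per_run %% snapshot_interval_steps == 0,
            steps_per_run %% transition_interval_steps == 0,
            transition_interval_steps %% snapshot_interval_steps == 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_runs_per_iteration = as.integer(n_runs_per_iteration),
                 steps_per_run = as.integer(steps_per_run), dt = dt,
                 snapshot_interval_steps = as.integer(snapshot_interval_steps),
                 transition_interval_steps = as.integer(transition_interval_steps)),
            class = "iteration_schedule")
}

#' Totals implied by an iteration schedule
#'
#' @param schedule an [iteration_schedule()].
#' @return list with `snapshots_total`, `simulated_time_fs`, and
#'   `simulated_time_us` (`n_iterations x n_runs x steps x dt`).
#' @export
schedule_totals <- function(schedule) {
  snaps <- schedule$n_iterations * schedule$n_runs_per_iteration *
    (schedule$steps_per_run / schedule$snapshot_interval_steps)
  fs <- schedule$n_iterations * schedule$n_runs_per_iteration *
    as.numeric(schedule$steps_per_run) * schedule$dt
  list(snapshots_total = snaps, simulated_time_fs = fs,
       simulated_time_us = fs * 1e-9)
}

#' Create an empty per-state histogram stack
#'
#' @param grid a `"zone_grid"`.
#' @return object of class `"histogram_stack"`: a dense `n_states x n_bins`
#'   count matrix plus the grid geometry.
#' @export
new_histogram_stack <- function(grid) {
  structure(list(counts = matrix(0, n_states(grid), n_bins(grid)),
                 grid = grid), class = "histogram_stack")
}

#' Generate initial seed conformations inside a reaction-coordinate window
#'
#' Runs `n_runs` short flat-bottom-restrained relaxation segments from the
#' system's built configuration (half-harmonic walls pull every RC into its
#' `[lo, hi]` window; the walls vanish inside the window) and returns each
#' run's final frame. Every returned frame satisfies `lo < lambda < hi` on
#' all RCs; a run that cannot reach its window raises a seeding-failure
#' error.
#'
#' @param sys a `"toy_system"`.
#' @param rc_defs list of [rc_def()].
#' @param windows matrix with one `[lo, hi]` row per RC.
#' @param n_runs number of seeds.
#' @param params a [dynamics_params()].
#' @param seed root seed; run `k` uses the derived stream [run_seed()].
#' @param n_steps steps per relaxation segment.
#' @param max_tries additional segments before declaring failure.
#' @return list of seed snapshots: each has `coords`, `vels`, `rc`,
#'   `state` (NA until assigned), `iteration = 0`, `run_id`.
#' @export
generate_initial_seeds <- function(sys, rc_defs, windows, n_runs, params,
                                   seed = 1, n_steps = 4000, max_tries = 10) {
  windows <- as.matrix(windows)
  stopifnot(nrow(windows) == length(rc_defs))
  for (h in seq_along(rc_defs)) {
    rg <- rc_defs[[h]]$range
    if (windows[h, 1] < rg[1] || windows[h, 2] > rg[2])
      stop("seed window outside the RC range for RC ", h)
  }
  walls <- list(rc_defs = rc_defs, bounds = windows)
  check_every <- max(100L, n_steps %/% 20L)
  lapply(seq_len(n_runs), function(k) {
    set.seed(run_seed(seed, k))
    state <- list(coords = sys$coords, vels = NULL)
    for (try in seq_len(max_tries + 1)) {
      seg <- langevin_segment(sys, state, n_steps, params, walls = walls,
                              snapshot_interval = check_every,
                              rc_defs = rc_defs)
      state <- list(coords = seg$coords, vels = seg$vels)
      # accept the latest stored frame with every RC strictly in its window
      ok <- rowSums(sweep(seg$rc, 2, windows[, 1], ">") &
                      sweep(seg$rc, 2, windows[, 2], "<")) == length(rc_defs)
      if (any(ok)) {
        i <- max(which(ok))
        return(list(coords = seg$snapshots[[i]], vels = NULL,
                    rc = seg$rc[i, ], state = NA, iteration = 0L, run_id = k))
      }
    }
    stop("seeding failure: run ", k, " did not reach its RC window after ",
         max_tries + 1, " segments")
  })
}

#' Attempt an inter-state transition of the virtual system
#'
#' The candidate set is every virtual state whose zone contains the current
#' RC point. A new state is drawn with probability proportional to the
#' inverse of its estimated zone mass under `Q_est` (floored at
#' `eps_z x total mass` for unvisited zones), which flattens the
#' virtual-state marginal and drives exploration. With `Q_est = NULL`
#' (first iteration) the draw is uniform over candidates.
#'
#' @param current per-RC zone index vector of the current state.
#' @param lambda current RC values.
#' @param Q_est a `"q_grid"` (any normalisation) or NULL.
#' @param grid the `"zone_grid"`.
#' @param tol wall tolerance (A) for zone membership.
#' @param eps_z floor for unvisited-zone mass, as a fraction of total mass.
#' @return the new state's per-RC zone index vector.
#' @export
attempt_transition <- function(current, lambda, Q_est, grid, tol = 0.5,
                               eps_z = 1e-6) {
  cand <- states_containing(lambda, grid, tol = tol)
  if (nrow(cand) == 0) stop("out-of-range: empty candidate set")
  if (nrow(cand) == 1) return(as.integer(cand[1, ]))
  if (is.null(Q_est)) {
    p <- rep(1, nrow(cand))
  } else {
    total <- sum(Q_est$values)
    z <- vapply(seq_len(nrow(cand)), function(r) {
      sum(Q_est$values[.state_bin_ids(cand[r, ], grid)])
    }, numeric(1))
    p <- 1 / pmax(z, eps_z * total)
  }
  as.integer(cand[sample.int(nrow(cand), 1, prob = p), ])
}

#' Run one iteration of zone-confined sampling
#'
#' Each run alternates Langevin stretches confined to the current virtual
#' state's zone by half-harmonic walls with transition attempts
#' ([attempt_transition()]). Snapshots are recorded at the schedule's
#' snapshot interval and accumulated into the current state's histogram
#' bins (snapshots that sit in the wall skin outside the zone are stored
#' but not counted).
#'
#' @param seeds list of seed snapshots (count must equal
#'   `schedule$n_runs_per_iteration`), each with an assigned `state`
#'   containing its RC point.
#' @param sys,rc_defs,grid,params as elsewhere.
#' @param Q_est current `"q_grid"` estimate (or NULL on iteration 1).
#' @param schedule an [iteration_schedule()].
#' @param iteration iteration number (for bookkeeping).
#' @param stack a `"histogram_stack"` to accumulate into.
#' @param seed root seed; run `k` of iteration `M` uses a derived stream.
#' @param wall_tol bookkeeping tolerance beyond zone boundaries (A).
#' @return list with `store` (snapshot store of this iteration), `stack`
#'   (updated), `visits` (per-state snapshot counts for this iteration).
#' @export
run_vcmd_iteration <- function(seeds, sys, rc_defs, grid, Q_est, schedule,
                               params, iteration, stack = new_histogram_stack(grid),
                               seed = 1, wall_tol = 0.5) {
  n_runs <- schedule$n_runs_per_iteration
  if (length(seeds) != n_runs)
    stop("seed count (", length(seeds), ") must equal runs per iteration (",
         n_runs, ")")
  n_chunks <- schedule$steps_per_run %/% schedule$transition_interval_steps
  snaps_per_chunk <- schedule$transition_interval_steps %/%
    schedule$snapshot_interval_steps

  co_l <- list(); rc_l <- list(); st_l <- list(); it_l <- list()
  run_l <- list(); step_l <- list(); cnt_l <- list()
  visits <- numeric(n_states(grid))

  for (k in seq_len(n_runs)) {
    set.seed(run_seed(seed, iteration * 100003 + k))
    sd_ <- seeds[[k]]
    state <- as.integer(sd_$state)
    if (anyNA(state)) stop("seed ", k, " has no assigned virtual state")
    cur <- list(coords = sd_$coords, vels = sd_$vels)
    zb <- .state_zone_bounds(state, grid)
    lam0 <- rc_values(rc_defs, cur$coords, sys$masses)
    if (any(lam0 < zb[, 1] - wall_tol | lam0 > zb[, 2] + wall_tol))
      stop("seed ", k, " RC values outside its assigned state's zone")

    for (chunk in seq_len(n_chunks)) {
      seg <- tryCatch(
        langevin_segment(sys, cur, schedule$transition_interval_steps,
                         params, walls = list(rc_defs = rc_defs, bounds = zb),
                         snapshot_interval = schedule$snapshot_interval_steps,
                         rc_defs = rc_defs),
        error = function(e) stop("run ", k, ", iteration ", iteration, ": ",
                                 conditionMessage(e), call. = FALSE))
      cur <- list(coords = seg$coords, vels = seg$vels)
      sid <- state_id(state, grid)

      bins <- bin_index(seg$rc, grid, tol = wall_tol)
      bid <- bin_id(bins, grid)
      zone_bids <- .state_bin_ids(state, grid)
      counted <- !is.na(bid) & bid %in% zone_bids
      if (any(counted)) {
        tab <- table(bid[counted])
        stack$counts[sid, as.integer(names(tab))] <-
          stack$counts[sid, as.integer(names(tab))] + as.numeric(tab)
      }
      visits[sid] <- visits[sid] + length(seg$steps)

      co_l[[length(co_l) + 1]] <- seg$snapshots
      rc_l[[length(rc_l) + 1]] <- seg$rc
      st_l[[length(st_l) + 1]] <- rep(sid, length(seg$steps))
      run_l[[length(run_l) + 1]] <- rep(k, length(seg$steps))
      step_l[[length(step_l) + 1]] <- seg$steps +
        (chunk - 1) * schedule$transition_interval_steps
      cnt_l[[length(cnt_l) + 1]] <- counted

      # clamp into the outer RC range: rare wall-skin excursions beyond the
      # grid edge still transition (the next zone's walls recapture them)
      lam <- rc_values(rc_defs, cur$coords, sys$masses)
      for (h in seq_len(grid$d)) {
        rg <- grid$axes[[h]]$range
        lam[h] <- min(max(lam[h], rg[1]), rg[2])
      }
      state <- attempt_transition(state, lam, Q_est, grid, tol = wall_tol)
      zb <- .state_zone_bounds(state, grid)
    }
  }

  rc <- do.call(rbind, rc_l)
  store <- list(coords = do.call(c, co_l), rc = rc,
                state_id = unlist(st_l),
                iteration = rep(iteration, nrow(rc)),
                run_id = unlist(run_l), step = unlist(step_l),
                counted = unlist(cnt_l))
  list(store = store, stack = stack, visits = visits)
}

.state_zone_bounds <- function(state, grid) {
  t(vapply(seq_len(grid$d), function(h)
    grid$axes[[h]]$intervals[state[h], ], numeric(2)))
}

.merge_store <- function(a, b) {
  if (is.null(a)) return(b)
  list(coords = c(a$coords, b$coords), rc = rbind(a$rc, b$rc),
       state_id = c(a$state_id, b$state_id),
       iteration = c(a$iteration, b$iteration),
       run_id = c(a$run_id, b$run_id), step = c(a$step, b$step),
       counted = c(a$counted, b$counted))
}

#' Stitch per-state histograms into a global distribution estimate
#'
#' Per-state bin densities `h_v(b) = c_v(b) / (N_v vol(b))` agree up to an
#' unknown per-state scale wherever zones overlap. The log scale factors
#' `g_v` are solved by weighted least squares over the overlap equations
#' `g_v + ln h_v(b) = g_w + ln h_w(b)` (weight: harmonic mean of the two
#' bin counts; gauge: `g = 0` for the most-sampled state). The stitched
#' estimate on each bin is the count-weighted mean of `exp(g_v) h_v(b)`
#' over the states observing it.
#'
#' @param stack a `"histogram_stack"`.
#' @param min_overlap_count a shared bin enters the overlap equations only
#'   when both states hold at least this many counts in it.
#' @param on_disconnected `"error"` (default: a disconnected overlap graph
#'   is a contract violation) or `"largest"` (stitch the largest connected
#'   component and leave the rest at zero — used by the iteration loop,
#'   where early iterations legitimately hold fragmentary statistics).
#' @return a `"q_grid"` (max-normalised): list with `values` (d-dimensional
#'   array of bin weights), `mode`, `grid`, `iteration`.
#' @export
stitch_histograms <- function(stack, min_overlap_count = 5,
                              on_disconnected = c("error", "largest")) {
  on_disconnected <- match.arg(on_disconnected)
  grid <- stack$grid
  counts <- stack$counts
  N_v <- rowSums(counts)
  visited <- which(N_v > 0)
  if (!length(visited)) stop("empty-estimate: histogram stack holds no counts")
  vol <- prod(vapply(grid$axes, `[[`, numeric(1), "bin_width"))
  sbins <- lapply(seq_len(n_states(grid)), function(s)
    .state_bin_ids(state_from_id(s, grid)[1, ], grid))

  if (length(visited) == 1) {
    v <- visited
    q <- numeric(n_bins(grid))
    q[sbins[[v]]] <- counts[v, sbins[[v]]] / N_v[v]
    return(.make_q_grid(q, grid))
  }

  # overlap equations
  eq_v <- integer(0); eq_w <- integer(0); eq_y <- numeric(0); eq_wt <- numeric(0)
  adj <- matrix(FALSE, length(visited), length(visited))
  for (a in seq_along(visited)) {
    for (b in seq_along(visited)) {
      if (b <= a) next
      v <- visited[a]; w <- visited[b]
      shared <- intersect(sbins[[v]], sbins[[w]])
      if (!length(shared)) next
      cv <- counts[v, shared]; cw <- counts[w, shared]
      ok <- cv >= min_overlap_count & cw >= min_overlap_count
      if (!any(ok)) next
      adj[a, b] <- adj[b, a] <- TRUE
      hv <- cv[ok] / (N_v[v] * vol); hw <- cw[ok] / (N_v[w] * vol)
      eq_v <- c(eq_v, rep(a, sum(ok)))
      eq_w <- c(eq_w, rep(b, sum(ok)))
      eq_y <- c(eq_y, log(hw) - log(hv))
      eq_wt <- c(eq_wt, 2 * cv[ok] * cw[ok] / (cv[ok] + cw[ok]))
    }
  }

  comp <- .graph_components(adj)
  if (length(unique(comp)) > 1) {
    if (on_disconnected == "error") {
      grp <- split(visited, comp)
      stop("stitching error: overlap graph disconnected; components: ",
           paste(vapply(grp, function(g) paste0("{", paste(g, collapse = ","), "}"),
                        character(1)), collapse = " "))
    }
    sizes <- vapply(split(N_v[visited], comp), sum, numeric(1))
    keepc <- comp == as.integer(names(sizes))[which.max(sizes)]
    drop <- visited[!keepc]
    stack$counts[drop, ] <- 0
    return(stitch_histograms(stack, min_overlap_count, "error"))
  }

  ref <- which.max(N_v[visited])
  free <- setdiff(seq_along(visited), ref)
  X <- matrix(0, length(eq_y), length(free))
  col_of <- match(seq_along(visited), free)
  for (e in seq_along(eq_y)) {
    if (!is.na(col_of[eq_v[e]])) X[e, col_of[eq_v[e]]] <- 1
    if (!is.na(col_of[eq_w[e]])) X[e, col_of[eq_w[e]]] <- -1
  }
  fit <- lm.wfit(X, eq_y, eq_wt)
  g <- numeric(length(visited))
  g[free] <- fit$coefficients
  g[is.na(g)] <- 0

  numer <- numeric(n_bins(grid)); denom <- numeric(n_bins(grid))
  for (a in seq_along(visited)) {
    v <- visited[a]
    bs <- sbins[[v]]
    cv <- counts[v, bs]
    hv <- cv / (N_v[v] * vol)
    numer[bs] <- numer[bs] + cv * exp(g[a]) * hv
    denom[bs] <- denom[bs] + cv
  }
  q <- ifelse(denom > 0, numer / denom, 0) * vol   # bin mass, unnormalised
  .make_q_grid(q, grid)
}

.make_q_grid <- function(q_linear, grid, iteration = NA_integer_,
                         mode = "max1") {
  nb <- vapply(grid$axes, function(a) length(a$bin_edges) - 1L, integer(1))
  vals <- array(q_linear, dim = nb)
  if (mode == "max1") {
    m <- max(vals)
    if (m > 0) vals <- vals / m
  } else if (mode == "sum1") {
    s <- sum(vals)
    if (s > 0) vals <- vals / s
  }
  structure(list(values = vals, mode = mode, grid = grid,
                 iteration = iteration), class = "q_grid")
}

#' Renormalise a q_grid
#' @param q a `"q_grid"`.
#' @param mode `"max1"` (reporting convention: highest bin set to 1) or
#'   `"sum1"` (probability masses).
#' @return the renormalised `"q_grid"`.
#' @export
q_normalize <- function(q, mode = c("max1", "sum1")) {
  mode <- match.arg(mode)
  .make_q_grid(as.numeric(q$values), q$grid, q$iteration, mode)
}

#' @export
print.q_grid <- function(x, ...) {
  cat("Q estimate over", length(dim(x$values)), "RC(s);",
      sum(x$values > 0), "of", length(x$values), "bins populated;",
      "normalisation:", x$mode, "\n")
  invisible(x)
}

.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Select seeds for the next iteration (evenness + genetic-algorithm targets)
#'
#' Half the slots are filled round-robin over visited zones in ascending
#' visit count, pushing coverage toward evenness. The other half are
#' genetic-algorithm targets: two parent zones are drawn with probability
#' proportional to inverse visit count, the child takes each per-RC zone
#' index from either parent, then mutates it by one zone with probability
#' `p_mut` (clipped to the grid). Each target zone is mapped to the stored
#' snapshot whose zone-normalised RC position is nearest the target centre
#' (ties: earliest stored).
#'
#' @param store a snapshot store (needs `rc`).
#' @param grid the `"zone_grid"`.
#' @param visit_counts per-state visit counts (length `n_states(grid)`).
#' @param n_runs seeds to produce.
#' @param p_mut per-RC mutation probability.
#' @param seed optional seed (`set.seed` applied when non-NULL).
#' @return list of seeds with `coords = NULL` placeholder resolved to stored
#'   coordinates, assigned `state` (a state containing the snapshot's RC,
#'   nearest the target), `target_state`, and `rc`.
#' @export
select_seeds_next <- function(store, grid, visit_counts, n_runs,
                              p_mut = 0.1, seed = NULL) {
  if (!length(store$rc) || nrow(store$rc) == 0) stop("snapshot store is empty")
  if (!is.null(seed)) set.seed(seed)
  visited <- which(visit_counts > 0)
  if (!length(visited)) stop("no visited zones to seed from")
  ord <- visited[order(visit_counts[visited])]

  n_even <- ceiling(n_runs / 2)
  even_targets <- rep(ord, length.out = n_even)

  n_ga <- n_runs - n_even
  ga_targets <- integer(0)
  if (n_ga > 0) {
    pw <- 1 / visit_counts[visited]
    nv <- vapply(grid$axes, `[[`, numeric(1), "n_vs")
    for (t in seq_len(n_ga)) {
      par <- visited[sample.int(length(visited), 2, replace = TRUE, prob = pw)]
      p1 <- state_from_id(par[1], grid)[1, ]
      p2 <- state_from_id(par[2], grid)[1, ]
      pick <- runif(grid$d) < 0.5
      child <- ifelse(pick, p1, p2)
      mut <- runif(grid$d) < p_mut
      child <- child + ifelse(mut, sample(c(-1L, 1L), grid$d, replace = TRUE), 0L)
      child <- pmin(pmax(child, 1L), nv)
      ga_targets <- c(ga_targets, state_id(child, grid))
    }
  }

  targets <- c(even_targets, ga_targets)
  centers <- zone_centers(grid)
  widths <- vapply(grid$axes, `[[`, numeric(1), "zone_width")
  lapply(targets, function(t_id) {
    ctr <- centers[t_id, ]
    z <- sweep(sweep(store$rc, 2, ctr), 2, widths, "/")
    i <- which.min(rowSums(z^2))
    lam <- store$rc[i, ]
    cand <- states_containing(lam, grid, tol = 0.5)
    tgt <- state_from_id(t_id, grid)[1, ]
    best <- cand[which.min(rowSums(abs(sweep(cand, 2, tgt)))), ]
    list(coords = store$coords[[i]], vels = NULL, rc = lam,
         state = as.integer(best), target_state = as.integer(tgt),
         iteration = store$iteration[i], run_id = store$run_id[i])
  })
}

#' Relative change between two Q estimates on their common support
#'
#' `d = sum |Q_M - Q_{M-1}| / sum Q_M`, restricted to bins where either
#' estimate exceeds `support_threshold` (both estimates max-normalised).
#'
#' @param q_m,q_prev two `"q_grid"` objects on identical bin geometry.
#' @param support_threshold support cut on the max-normalised values.
#' @return nonnegative scalar.
#' @export
convergence_metric <- function(q_m, q_prev, support_threshold = 0.001) {
  if (!identical(dim(q_m$values), dim(q_prev$values)))
    stop("geometry error: Q grids have different bin geometry")
  for (h in seq_along(q_m$grid$axes))
    if (max(abs(q_m$grid$axes[[h]]$bin_edges -
                q_prev$grid$axes[[h]]$bin_edges)) > 1e-9)
      stop("geometry error: Q grids have different bin edges")
  a <- q_normalize(q_m, "max1")$values
  b <- q_normalize(q_prev, "max1")$values
  mask <- pmax(a, b) > support_threshold
  if (!any(mask)) return(0)
  sum(abs(a[mask] - b[mask])) / sum(a[mask])
}

#' Fit a canonical distribution estimate by GA-guided zone-coupled sampling
#'
#' The central fitting loop: generate (or accept) seed conformations, run
#' iterations of zone-confined Langevin sampling with inter-state
#' transitions, accumulate per-state histograms, stitch them into a
#' distribution estimate over the RC space after every iteration, track the
#' convergence metric, and choose the next iteration's seeds for coverage.
#'
#' @param sys a `"toy_system"`.
#' @param rc_defs list of [rc_def()] (1-3 RCs).
#' @param grid a `"zone_grid"` over the same RCs.
#' @param schedule an [iteration_schedule()].
#' @param params a [dynamics_params()]; its `dt` is overridden by the
#'   schedule's.
#' @param windows seed-generation RC windows (matrix `[lo, hi]` per RC);
#'   ignored when `seeds` are supplied.
#' @param seeds optional list of pre-built seeds.
#' @param seed root seed for the whole campaign.
#' @param min_overlap_count stitching overlap threshold.
#' @param convergence_threshold iteration-to-iteration change below which
#'   (twice in a row) the estimate is declared converged.
#' @param support_threshold support cut of the convergence metric.
#' @param p_mut GA mutation probability for seed selection.
#' @param retain_last_k accumulate histograms over all iterations (default
#'   `Inf`) or only the trailing `k`.
#' @param verbose print a per-iteration summary line.
#' @return an object of class `"vcmd"`: the snapshot store, histogram
#'   stack, per-iteration Q estimates and convergence metrics, visit
#'   counts, and the configuration echo.
#' @export
vcmd <- function(sys, rc_defs, grid, schedule, params = dynamics_params(),
                 windows = NULL, seeds = NULL, seed = 1,
                 min_overlap_count = 5, convergence_threshold = 0.1,
                 support_threshold = 0.001, p_mut = 0.1,
                 retain_last_k = Inf, verbose = FALSE) {
  params$dt <- schedule$dt
  if (is.null(seeds)) {
    if (is.null(windows)) stop("either seeds or seed windows must be given")
    seeds <- generate_initial_seeds(sys, rc_defs, windows,
                                    schedule$n_runs_per_iteration, params,
                                    seed = seed)
  }
  seeds <- .assign_seed_states(seeds, grid)

  store <- NULL
  iter_stacks <- list()
  visits <- numeric(n_states(grid))
  q_grids <- list()
  conv <- rep(NA_real_, schedule$n_iterations)
  Q_est <- NULL
  converged_at <- NA_integer_

  for (M in seq_len(schedule$n_iterations)) {
    it <- run_vcmd_iteration(seeds, sys, rc_defs, grid, Q_est, schedule,
                             params, iteration = M,
                             stack = new_histogram_stack(grid), seed = seed)
    iter_stacks[[M]] <- it$stack$counts
    store <- .merge_store(store, it$store)
    visits <- visits + it$visits

    first <- max(1L, M - as.integer(min(retain_last_k, M)) + 1L)
    active <- new_histogram_stack(grid)
    for (m in first:M) active$counts <- active$counts + iter_stacks[[m]]

    Q_M <- tryCatch(stitch_histograms(active, min_overlap_count,
                                      on_disconnected = "largest"),
                    error = function(e) NULL)
    if (!is.null(Q_M)) {
      Q_M$iteration <- M
      if (length(q_grids)) conv[M] <- convergence_metric(Q_M, q_grids[[length(q_grids)]],
                                                         support_threshold)
      q_grids[[length(q_grids) + 1]] <- Q_M
      Q_est <- q_normalize(Q_M, "sum1")
    }
    if (is.na(converged_at) && M >= 2 && !anyNA(conv[(M - 1):M]) &&
        all(conv[(M - 1):M] < convergence_threshold))
      converged_at <- M
    if (verbose)
      message(sprintf("iteration %d: %d zones visited, d = %s", M,
                      sum(visits > 0),
                      ifelse(is.na(conv[M]), "NA", sprintf("%.4f", conv[M]))))
    if (M < schedule$n_iterations)
      seeds <- select_seeds_next(store, grid, pmax(visits, 0),
                                 schedule$n_runs_per_iteration, p_mut = p_mut,
                                 seed = run_seed(seed, 900000 + M))
  }

  stack <- new_histogram_stack(grid)
  first <- max(1L, schedule$n_iterations -
                 as.integer(min(retain_last_k, schedule$n_iterations)) + 1L)
  for (m in first:schedule$n_iterations)
    stack$counts <- stack$counts + iter_stacks[[m]]

  structure(list(system = sys, rc_defs = rc_defs, grid = grid,
                 schedule = schedule, params = params, store = store,
                 stack = stack, q_grids = q_grids, convergence = conv,
                 visits = visits, converged_at = converged_at,
                 seed = seed),
            class = "vcmd")
}

.assign_seed_states <- function(seeds, grid) {
  lapply(seeds, function(s) {
    if (!anyNA(s$state)) return(s)
    cand <- states_containing(s$rc, grid, tol = 0.5)
    ctr <- zone_centers(grid)
    ids <- state_id(cand, grid)
    i <- which.min(rowSums((sweep(ctr[ids, , drop = FALSE], 2, s$rc))^2))
    s$state <- as.integer(cand[i, ])
    s
  })
}

#' @export
print.vcmd <- function(x, ...) {
  tot <- schedule_totals(x$schedule)
  cat("GA-guided zone-coupled sampling fit\n")
  cat(sprintf("  %d iteration(s) x %d runs x %d steps (dt %g fs): %g snapshots, %.4g us\n",
              x$schedule$n_iterations, x$schedule$n_runs_per_iteration,
              x$schedule$steps_per_run, x$schedule$dt, tot$snapshots_total,
              tot$simulated_time_us))
  cat(sprintf("  zones visited: %d / %d\n", sum(x$visits > 0), n_states(x$grid)))
  d <- x$convergence[!is.na(x$convergence)]
  if (length(d)) cat(sprintf("  final convergence d = %.4f%s\n", tail(d, 1),
                             if (!is.na(x$converged_at))
                               paste0(" (converged at iteration ", x$converged_at, ")")
                             else ""))
  invisible(x)
}

#' @export
summary.vcmd <- function(object, ...) {
  print(object)
  cat("  stored snapshots:", length(object$store$coords),
      sprintf("(%d counted in histograms)\n", sum(object$store$counted)))
  cat("  per-iteration convergence d:",
      paste(sprintf("%.3f", object$convergence), collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.vcmd <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  d <- x$convergence
  plot(seq_along(d), d, type = "b", xlab = "iteration",
       ylab = "convergence d", main = "Q convergence", ...)
  q <- x$q_grids[[length(x$q_grids)]]
  a1 <- x$grid$axes[[1]]
  centers <- (a1$bin_edges[-1] + a1$bin_edges[-length(a1$bin_edges)]) / 2
  marg <- apply(q$values, 1, sum)
  plot(centers, marg / max(marg), type = "h", xlab = "RC 1 (A)",
       ylab = "Q (max-normalised marginal)", main = "Final Q estimate")
  invisible(x)
}
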