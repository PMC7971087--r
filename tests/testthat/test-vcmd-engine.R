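test_that("schedule totals reproduce the campaign arithmetic", {
  # 14 x 256 x 3e6 steps at dt 2 fs, snapshot every 1e5 steps
  s1 <- iteration_schedule(14, 256, 3e6, dt = 2, snapshot_interval_steps = 1e5)
  t1 <- schedule_totals(s1)
  expect_equal(t1$snapshots_total, 107520)
  expect_equal(t1$simulated_time_us, 21.504)
  s2 <- iteration_schedule(13, 256, 3e6, dt = 2, snapshot_interval_steps = 1e5)
  expect_equal(schedule_totals(s2)$snapshots_total, 99840)
  expect_equal(schedule_totals(s2)$simulated_time_us, 19.968)
  s3 <- iteration_schedule(27, 256, 3e6, dt = 2, snapshot_interval_steps = 1e5)
  expect_equal(schedule_totals(s3)$snapshots_total, 207360)
  expect_equal(schedule_totals(s3)$simulated_time_us, 41.472)
  # degenerate schedule: one run, interval = steps
  s4 <- iteration_schedule(1, 1, 1000, dt = 2, snapshot_interval_steps = 1000)
  expect_equal(schedule_totals(s4)$snapshots_total, 1)
  expect_error(iteration_schedule(1, 1, 1000, snapshot_interval_steps = 300))
})

test_that("initial seeds land inside their windows, reproducibly", {
  fx <- pair_fixture()
  win <- matrix(c(5.5, 6.5), 1)
  seeds <- generate_initial_seeds(fx$sys, fx$rc, win, n_runs = 8, fx$params,
                                  seed = 3, n_steps = 2000)
  expect_length(seeds, 8)
  for (s in seeds) {
    expect_gt(s$rc[1], 5.5)
    expect_lt(s$rc[1], 6.5)
  }
  seeds2 <- generate_initial_seeds(fx$sys, fx$rc, win, n_runs = 8, fx$params,
                                   seed = 3, n_steps = 2000)
  expect_identical(lapply(seeds, `[[`, "coords"),
                   lapply(seeds2, `[[`, "coords"))
  expect_error(generate_initial_seeds(fx$sys, fx$rc, matrix(c(1, 2), 1), 2,
                                      fx$params), "outside the RC range")
})

test_that("transition draws follow the inverse-zone-mass rule", {
  g1 <- build_zone_grid(c(0, 10), 3, 0.5)   # zones [0,5],[2.5,7.5],[5,10]
  # single candidate: deterministic
  expect_equal(attempt_transition(c(1L), 1.0, NULL, g1), 1L)

  # two candidates, no estimate: symmetric within binomial 3 sigma
  set.seed(7)
  draws <- replicate(1e4, attempt_transition(c(1L), 4.0, NULL, g1))
  p1 <- mean(draws == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 1e4))

  # stated zone masses: empirical frequencies match the normalised 1/Z vector
  qv <- numeric(n_bins(g1))
  qv[vczone:::.state_bin_ids(1L, g1)] <- 0.08   # zone 1 mass fills below
  qv[vczone:::.state_bin_ids(2L, g1)] <- qv[vczone:::.state_bin_ids(2L, g1)] + 0.02
  q <- vczone:::.make_q_grid(qv, g1, mode = "sum1")
  z1 <- sum(q$values[vczone:::.state_bin_ids(1L, g1)])
  z2 <- sum(q$values[vczone:::.state_bin_ids(2L, g1)])
  want <- (1 / z1) / (1 / z1 + 1 / z2)
  set.seed(8)
  draws <- replicate(1e4, attempt_transition(c(1L), 4.0, q, g1))
  expect_lt(abs(mean(draws == 1) - want), 3 * sqrt(want * (1 - want) / 1e4))

  # four candidates in 2D: frequencies match enumeration
  g2 <- build_zone_grid(list(c(0, 10), c(0, 10)), 3, 0.5)
  qv2 <- numeric(n_bins(g2))
  masses <- c(5, 1, 2, 10)   # states (1,1), (2,1), (1,2), (2,2)
  cand <- rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (i in 1:4) {
    ids <- vczone:::.state_bin_ids(cand[i, ], g2)
    qv2[ids] <- qv2[ids] + masses[i] / length(ids)
  }
  q2 <- vczone:::.make_q_grid(qv2, g2, mode = "sum1")
  zs <- vapply(1:4, function(i)
    sum(q2$values[vczone:::.state_bin_ids(cand[i, ], g2)]), numeric(1))
  want <- (1 / zs) / sum(1 / zs)
  set.seed(9)
  draws <- replicate(2e4, paste(attempt_transition(c(1L, 1L), c(4, 4), q2, g2),
                                collapse = ","))
  got <- as.numeric(table(factor(draws, levels = apply(cand, 1, paste,
                                                       collapse = ",")))) / 2e4
  for (i in 1:4)
    expect_lt(abs(got[i] - want[i]), 4 * sqrt(want[i] * (1 - want[i]) / 2e4))
})

test_that("an iteration confines, counts, and books snapshots correctly", {
  fx <- pair_fixture()
  sch <- iteration_schedule(1, 4, 8000, dt = 10, snapshot_interval_steps = 100,
                            transition_interval_steps = 1000)
  seeds <- generate_initial_seeds(fx$sys, fx$rc, matrix(c(5.5, 6.5), 1), 4,
                                  fx$params, seed = 1, n_steps = 2000)
  seeds <- vczone:::.assign_seed_states(seeds, fx$grid)
  it <- run_vcmd_iteration(seeds, fx$sys, fx$rc, fx$grid, NULL, sch, fx$params,
                           iteration = 1, seed = 1)
  # bookkeeping: n_runs x steps / interval snapshots stored
  expect_equal(nrow(it$store$rc), 4 * 8000 / 100)
  expect_equal(sum(it$visits), nrow(it$store$rc))
  # confinement: every snapshot inside its state's zone, almost all within
  # the wall tolerance, none beyond three times it (hard energy bound)
  zb <- t(vapply(it$store$state_id, function(s)
    as.numeric(vczone:::.state_zone_bounds(state_from_id(s, fx$grid)[1, ],
                                           fx$grid)), numeric(2)))
  over <- pmax(zb[, 1] - it$store$rc[, 1], it$store$rc[, 1] - zb[, 2], 0)
  expect_gte(mean(over <= 0.5), 0.99)
  expect_true(all(over < 1.5))
  # counted snapshots are exactly those inside their zone
  expect_equal(it$store$counted, over == 0 |
                 (it$store$rc[, 1] >= zb[, 1] & it$store$rc[, 1] <= zb[, 2]))
  # histogram counts equal the counted snapshots
  expect_equal(sum(it$stack$counts), sum(it$store$counted))
})

test_that("states are visited broadly on a flat landscape", {
  # two free beads: transitions under a uniform estimate must reach and hold
  # every zone of the single RC
  sys <- build_pair_system(bond_k = 0, eps = 0)
  rc <- list(rc_def("r", 1L, 2L, "geometric", c(3, 9)))
  grid <- build_zone_grid(c(3, 9), 3, 0.5)
  sch <- iteration_schedule(1, 6, 10000, dt = 10, snapshot_interval_steps = 100,
                            transition_interval_steps = 1000)
  p <- dynamics_params(temperature = 300, dt = 10, friction = 2)
  seeds <- generate_initial_seeds(sys, rc, matrix(c(5.5, 6.5), 1), 6, p,
                                  seed = 2, n_steps = 2000)
  seeds <- vczone:::.assign_seed_states(seeds, grid)
  it <- run_vcmd_iteration(seeds, sys, rc, grid, NULL, sch, p, 1, seed = 2)
  expect_true(all(it$visits > 0.1 * sum(it$visits) / 3))
})

test_that("stitching recovers a known density and is scale invariant", {
  grid <- build_zone_grid(list(c(0, 10), c(0, 10), c(0, 10)), n_vs = 3)
  ctr <- vczone:::.bin_centers(grid)
  p <- exp(-((ctr[, 1] - 4)^2 / 8 + (ctr[, 2] - 6)^2 / 10 +
               (ctr[, 3] - 5)^2 / 6))
  p <- p / sum(p)
  stack <- density_stack(grid, p, counts_per_zone = 1e4)
  q <- q_normalize(stitch_histograms(stack), "sum1")
  qv <- as.numeric(q$values)
  sup <- p > 0.001 * max(p)
  expect_lt(max(abs(qv - p)[sup] / p[sup]), 0.05)
  # multiplying one zone's counts by 10 leaves the estimate unchanged
  stack2 <- stack
  stack2$counts[14, ] <- stack2$counts[14, ] * 10
  q2 <- q_normalize(stitch_histograms(stack2), "sum1")
  expect_equal(as.numeric(q2$values), qv, tolerance = 1e-12)
  # statistically drawn counts still reconstruct closely in L1
  set.seed(17)
  stack3 <- new_histogram_stack(grid)
  for (s in seq_len(n_states(grid))) {
    st <- state_from_id(s, grid)[1, ]
    bids <- vczone:::.state_bin_ids(st, grid)
    pz <- p[bids] / sum(p[bids])
    stack3$counts[s, bids] <- as.numeric(rmultinom(1, 1e4, pz))
  }
  q3 <- q_normalize(stitch_histograms(stack3), "sum1")
  expect_lt(sum(abs(as.numeric(q3$values) - p)), 0.05)
})

test_that("stitching degenerate cases behave as specified", {
  grid <- build_zone_grid(c(0, 10), 3, 0.5)
  # single visited state: Q is that state's normalised histogram
  stack <- new_histogram_stack(grid)
  bids <- vczone:::.state_bin_ids(1L, grid)
  stack$counts[1, bids] <- c(10, 20, 30, 40, 50)[seq_along(bids)]
  q <- q_normalize(stitch_histograms(stack), "sum1")
  expect_equal(as.numeric(q$values)[bids],
               stack$counts[1, bids] / sum(stack$counts[1, ]))
  # empty stack errors
  expect_error(stitch_histograms(new_histogram_stack(grid)), "empty-estimate")
  # disconnected overlap graph errors with the components listed
  stack2 <- new_histogram_stack(grid)
  stack2$counts[1, vczone:::.state_bin_ids(1L, grid)] <- 100
  stack2$counts[3, vczone:::.state_bin_ids(3L, grid)] <- 100
  expect_error(stitch_histograms(stack2), "disconnected")
  # ... but the largest-component fallback stitches the heavier part
  q2 <- stitch_histograms(stack2, on_disconnected = "largest")
  expect_true(sum(q2$values) > 0)
})

test_that("seed selection balances coverage and targets poor regions", {
  grid <- build_zone_grid(c(0, 10), 3, 0.5)
  set.seed(30)
  rc <- matrix(runif(300, 0, 10), ncol = 1)
  store <- list(rc = rc, coords = lapply(seq_len(300), function(i)
    matrix(rc[i], 1, 3)), iteration = rep(1L, 300), run_id = rep(1L, 300))
  # all zones equally visited: the evenness half is a fair round-robin
  vis <- c(100, 100, 100)
  seeds <- select_seeds_next(store, grid, vis, n_runs = 9, seed = 5)
  even <- vapply(seeds[1:5], function(s) state_id(s$target_state, grid),
                 integer(1))
  expect_true(all(table(even) <= ceiling(5 / 3)))
  # determinism
  seeds2 <- select_seeds_next(store, grid, vis, n_runs = 9, seed = 5)
  expect_identical(lapply(seeds, `[[`, "rc"), lapply(seeds2, `[[`, "rc"))
  # an unvisited zone flanked by heavy parents receives GA attention
  vis2 <- c(500, 500, 0)
  hits <- 0
  for (rep in 1:100) {
    ss <- select_seeds_next(store, grid, vis2, n_runs = 8, seed = 100 + rep)
    tg <- vapply(ss, function(s) state_id(s$target_state, grid), integer(1))
    if (any(tg[5:8] == 3)) hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("the convergence metric follows its defining ratio", {
  grid <- build_zone_grid(c(0, 1.5), 2, 0.5)   # 3 bins of 0.5
  qa <- vczone:::.make_q_grid(c(1, 0.5, 0.0005), grid, mode = "max1")
  qb <- vczone:::.make_q_grid(c(0.8, 0.6, 0.0004), grid, mode = "max1")
  # hand evaluation: bins 1 and 2 are above support in either grid;
  # bin 3 is below 0.001 in both after max-normalisation
  va <- c(1, 0.5, 0.0005); vb <- c(0.8, 0.6, 0.0004) / 0.8
  d_hand <- (abs(va[1] - vb[1]) + abs(va[2] - vb[2])) / (va[1] + va[2])
  expect_equal(convergence_metric(qa, qb), d_hand)
  expect_equal(convergence_metric(qa, qa), 0)
  set.seed(31)
  for (rep in 1:5) {
    q1 <- vczone:::.make_q_grid(runif(3), grid, mode = "max1")
    q2 <- vczone:::.make_q_grid(runif(3), grid, mode = "max1")
    expect_gte(convergence_metric(q1, q2), 0)
  }
  g2 <- build_zone_grid(c(0, 2), 2, 0.5)
  expect_error(convergence_metric(qa, vczone:::.make_q_grid(runif(4), g2)),
               "geometry error")
})

test_that("the full loop stays internally consistent across iterations", {
  fx <- pair_fixture()
  sch <- iteration_schedule(3, 6, 6000, dt = 10, snapshot_interval_steps = 200,
                            transition_interval_steps = 1000)
  fit <- vcmd(fx$sys, fx$rc, fx$grid, sch, fx$params,
              windows = matrix(c(5.5, 6.5), 1), seed = 7)
  tot <- schedule_totals(sch)
  # snapshot accounting is exact
  expect_equal(length(fit$store$coords), tot$snapshots_total)
  expect_equal(nrow(fit$store$rc), tot$snapshots_total)
  # coverage is non-decreasing over iterations
  vis_by_iter <- lapply(1:3, function(m)
    unique(fit$store$state_id[fit$store$iteration <= m]))
  expect_true(all(vis_by_iter[[1]] %in% vis_by_iter[[2]]))
  expect_true(all(vis_by_iter[[2]] %in% vis_by_iter[[3]]))
  # determinism of the whole campaign
  fit2 <- vcmd(fx$sys, fx$rc, fx$grid, sch, fx$params,
               windows = matrix(c(5.5, 6.5), 1), seed = 7)
  expect_identical(fit$store$rc, fit2$store$rc)
  expect_identical(fit$q_grids[[3]]$values, fit2$q_grids[[3]]$values)
})
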